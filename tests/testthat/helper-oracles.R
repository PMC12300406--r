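# Independent brute-force oracles used to validate the closed-form
# statistics and the Mendelian verdict logic.

# all diploid genotypes (sorted pairs) over allele vector `al`
allGenotypes <- function(al) {
    gs <- list()
    for (i in seq_along(al)) for (j in i:length(al))
        gs[[length(gs) + 1L]] <- c(al[i], al[j])
    gs
}

# HWE probability of a sorted genotype pair given named freq vector p
hweProb <- function(g, p) {
    pi_ <- p[as.character(g[1L])]; pj <- p[as.character(g[2L])]
    if (g[1L] == g[2L]) unname(pi_^2) else unname(2 * pi_ * pj)
}

# brute-force probability that two unrelated HWE genotypes are identical
brutePI <- function(p) {
    al <- as.integer(names(p))
    sum(vapply(allGenotypes(al), function(g) hweProb(g, p)^2, numeric(1)))
}

# duo compatibility: share at least one allele
duoOK <- function(child, parent) any(child %in% parent)

# trio compatibility: child assembled from one allele of each parent
trioOK <- function(child, p1, p2) {
    for (i in 1:2) for (j in 1:2)
        if (identical(sort(child), sort(c(p1[i], p2[j])))) return(TRUE)
    FALSE
}

# selfing compatibility: two independent draws from one parent
selfOK <- function(child, parent) trioOK(child, parent, parent)

# brute-force non-exclusion probability, one unknown parent: offspring
# drawn HWE, unrelated candidate drawn HWE, probability candidate is not
# excluded by the share-an-allele rule
bruteNonExclOne <- function(p) {
    al <- as.integer(names(p))
    gs <- allGenotypes(al)
    tot <- 0
    for (o in gs) for (cand in gs)
        if (duoOK(o, cand))
            tot <- tot + hweProb(o, p) * hweProb(cand, p)
    tot
}

# brute-force non-exclusion probability, second parent: true parents M,F
# drawn HWE, offspring Mendelian from them, known parent = M, unrelated
# candidate drawn HWE, not excluded iff trio(offspring, M, candidate) is
# compatible
bruteNonExclSecond <- function(p) {
    al <- as.integer(names(p))
    gs <- allGenotypes(al)
    tot <- 0
    for (m in gs) for (f in gs) {
        pm <- hweProb(m, p) * hweProb(f, p)
        for (i in 1:2) for (j in 1:2) {
            o <- sort(c(m[i], f[j]))
            po <- pm * 0.25
            for (cand in gs)
                if (trioOK(o, m, cand))
                    tot <- tot + po * hweProb(cand, p)
        }
    }
    tot
}

# random frequency vector over k alleles (named by allele size)
randFreq <- function(k, sizes = 100 + 2 * (1:k)) {
    f <- rgamma(k, 1); f <- f / sum(f)
    names(f) <- sizes
    f
}
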