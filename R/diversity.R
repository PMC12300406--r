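#' Allele frequencies at one locus
#'
#' Counts each present allele (two per typed diploid cell) over twice the
#' number of typed accessions; untyped cells are excluded from the
#' denominator.
#'
#' @param x an \code{SSRGenotypes} object.
#' @param locus a locus id.
#' @return an object of class \code{AlleleFrequencyTable}: a list with
#'   \code{locus}, \code{n_typed} and \code{freq} (named numeric vector,
#'   names = allele sizes, summing to 1).
#' @export
alleleFrequencies <- function(x, locus) {
    if (!locus %in% lociIds(x)) stop("unknown locus: ", locus)
    g <- .locusGenotypes(x, locus)
    alleles <- c(g[1L, ], g[2L, ])
    alleles <- alleles[!is.na(alleles)]
    if (!length(alleles))
        stop("no typed accessions at locus ", locus)
    tab <- table(alleles)
    freq <- as.numeric(tab) / length(alleles)
    names(freq) <- names(tab)
    structure(list(locus = locus, n_typed = length(alleles) / 2,
                   freq = freq),
              class = "AlleleFrequencyTable")
}

#' @export
print.AlleleFrequencyTable <- function(x, ...) {
    cat("Allele frequencies at ", x$locus, " (N = ", x$n_typed, "):\n",
        sep = "")
    print(round(x$freq, 4))
    invisible(x)
}

# power sum a_n = sum p_i^n
.psum <- function(p, n) sum(p^n)

# round half-up (report tables follow the printed convention, not IEC 60559)
.round2 <- function(v, digits = 2) floor(v * 10^digits + 0.5) / 10^digits

#' Per-locus diversity statistics
#'
#' Computes the standard SSR marker-informativeness panel for one locus:
#' typed count N, allele count Na, effective allele count
#' \eqn{Ne = 1/\sum p_i^2}, Shannon information index
#' \eqn{I = -\sum p_i \ln p_i}, observed heterozygosity Ho, Nei gene
#' diversity (expected heterozygosity) \eqn{He = 1 - \sum p_i^2}, fixation
#' index \eqn{F = (He - Ho)/He} (0 for monomorphic loci), Botstein
#' polymorphic information content
#' \eqn{PIC = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}, the
#' Hardy-Weinberg probability of identity
#' \eqn{PI = \sum p_i^4 + \sum_{i<j} (2 p_i p_j)^2}, discrimination power
#' \eqn{PD = 1 - PI}, and the count Nra of rare alleles (frequency below
#' \code{rare_threshold}).
#'
#' @param freq an \code{AlleleFrequencyTable} from
#'   \code{\link{alleleFrequencies}}.
#' @param x the \code{SSRGenotypes} the frequencies came from (used for the
#'   observed heterozygote count).
#' @param rare_threshold rare-allele frequency cutoff (default 0.05).
#' @return one-row data.frame with columns \code{Locus, N, Na, Ne, I, Ho,
#'   He, F, PIC, PD, Nra}.
#' @export
locusStats <- function(freq, x, rare_threshold = 0.05) {
    stopifnot(inherits(freq, "AlleleFrequencyTable"))
    p <- freq$freq
    g <- .locusGenotypes(x, freq$locus)
    typed <- !is.na(g[1L, ])
    ho <- sum(g[1L, typed] != g[2L, typed]) / sum(typed)
    a2 <- .psum(p, 2)
    he <- 1 - a2
    # sum over i<j of 2 p_i^2 p_j^2 = (sum_ij p_i^2 p_j^2 - sum_i p_i^4)
    pic <- 1 - a2 - (sum(outer(p^2, p^2)) - .psum(p, 4))
    # PI = sum p_i^4 + sum_{i<j} (2 p_i p_j)^2
    pid <- .psum(p, 4) + (sum(outer(p, p)^2) - .psum(p, 4)) * 2
    data.frame(Locus = freq$locus, N = freq$n_typed, Na = length(p),
               Ne = 1 / a2, I = -sum(p * log(p)), Ho = ho, He = he,
               F = if (he > 0) (he - ho) / he else 0,
               PIC = pic, PD = 1 - pid, PI = pid,
               Nra = sum(p < rare_threshold),
               stringsAsFactors = FALSE)
}

#' Diversity statistics for every locus
#'
#' Applies \code{\link{locusStats}} across the panel and returns the
#' per-locus summary table in the conventional column order, optionally
#' with a Monte Carlo Hardy-Weinberg p-value per locus.
#'
#' @inheritParams locusStats
#' @param x an \code{SSRGenotypes} object.
#' @param hwe logical; add a \code{hwe_p} column via \code{\link{hweTest}}.
#' @param n_mc,seed Monte Carlo settings for the HWE test.
#' @return data.frame, one row per locus.
#' @export
diversityStats <- function(x, rare_threshold = 0.05, hwe = FALSE,
                           n_mc = 1000, seed = NULL) {
    rows <- lapply(lociIds(x), function(l)
        locusStats(alleleFrequencies(x, l), x, rare_threshold))
    out <- do.call(rbind, rows)
    if (hwe)
        out$hwe_p <- vapply(lociIds(x), function(l)
            hweTest(x, l, n_mc = n_mc, seed = seed), numeric(1))
    rownames(out) <- NULL
    out
}

#' Rare and private alleles across the collection
#'
#' Rare alleles have frequency below \code{rare_threshold} at their locus.
#' Private (unique) alleles are carried by exactly one distinct multilocus
#' genotype: accessions with byte-identical full profiles (clones,
#' replicates) count as a single carrier, so a clone group does not
#' disqualify its own private alleles.
#'
#' @param x an \code{SSRGenotypes} object.
#' @param rare_threshold frequency cutoff (default 0.05).
#' @return list with \code{rare} (data.frame locus/allele/frequency),
#'   \code{n_rare}, \code{private} (data.frame locus/allele/accessions),
#'   \code{n_private}, and \code{per_accession} counts of private alleles.
#' @export
rareAndPrivateAlleles <- function(x, rare_threshold = 0.05) {
    keys <- .profileKeys(x)
    rep_of <- match(keys, keys)          # first accession with each profile
    rare <- list(); priv <- list()
    for (l in lociIds(x)) {
        ft <- alleleFrequencies(x, l)
        isr <- ft$freq < rare_threshold
        if (any(isr))
            rare[[l]] <- data.frame(locus = l,
                                    allele = as.integer(names(ft$freq)[isr]),
                                    frequency = unname(ft$freq[isr]))
        g <- .locusGenotypes(x, l)
        for (a in as.integer(names(ft$freq))) {
            carriers <- which(!is.na(g[1L, ]) & (g[1L, ] == a | g[2L, ] == a))
            geno_carriers <- unique(rep_of[carriers])
            if (length(geno_carriers) == 1L)
                priv[[paste(l, a)]] <- data.frame(
                    locus = l, allele = a,
                    accession = accessionIds(x)[geno_carriers])
        }
    }
    rare <- if (length(rare)) do.call(rbind, c(rare, make.row.names = FALSE))
            else data.frame(locus = character(), allele = integer(),
                            frequency = numeric())
    priv <- if (length(priv)) do.call(rbind, c(priv, make.row.names = FALSE))
            else data.frame(locus = character(), allele = integer(),
                            accession = character())
    per_acc <- table(priv$accession)
    list(rare = rare, n_rare = nrow(rare),
         private = priv, n_private = nrow(priv),
         per_accession = per_acc)
}

#' Count alleles flagged in the source table
#'
#' Published profile tables mark private alleles typographically; the
#' reader records those marks in \code{metadata(x)$allele_flags}.  This
#' tallies them overall and per accession.
#'
#' @param x an \code{SSRGenotypes} read with \code{\link{readGenotypes}}.
#' @return list with \code{total} and \code{per_accession} (named table).
#' @export
countFlaggedAlleles <- function(x) {
    fl <- S4Vectors::metadata(x)$allele_flags
    if (is.null(fl)) return(list(total = 0L, per_accession = table(character())))
    list(total = nrow(fl), per_accession = table(fl$accession))
}

#' Monte Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Chi-square statistic of observed vs HWE-expected genotype counts, with
#' the null distribution obtained by permuting the 2N observed allele
#' copies into random diploid genotypes.  Monomorphic loci return 1 by
#' convention.
#'
#' @param x an \code{SSRGenotypes} object.
#' @param locus locus id.
#' @param n_mc number of permutation replicates (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @return p-value in (0, 1].
#' @export
hweTest <- function(x, locus, n_mc = 1000, seed = NULL) {
    g <- .locusGenotypes(x, locus)
    typed <- !is.na(g[1L, ])
    if (sum(typed) < 5L)
        stop("need at least 5 typed accessions for the HWE test")
    a1 <- g[1L, typed]; a2 <- g[2L, typed]
    alleles <- sort(unique(c(a1, a2)))
    if (length(alleles) < 2L) return(1.0)
    if (!is.null(seed)) {
        old <- .saveSeed(); on.exit(.restoreSeed(old))
        set.seed(seed)
    }
    obs <- .hweChisq(a1, a2, alleles)
    pool <- c(a1, a2)
    n <- length(a1)
    hits <- 0L
    for (r in seq_len(n_mc)) {
        perm <- sample(pool)
        s1 <- perm[seq_len(n)]; s2 <- perm[n + seq_len(n)]
        if (.hweChisq(s1, s2, alleles) >= obs - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (n_mc + 1)
}

# chi-square distance between observed genotype counts and HWE expectation
# computed from the sample allele frequencies
.hweChisq <- function(a1, a2, alleles) {
    n <- length(a1)
    k <- length(alleles)
    i1 <- match(pmin(a1, a2), alleles)
    i2 <- match(pmax(a1, a2), alleles)
    obs <- matrix(0, k, k)
    for (t in seq_len(n)) obs[i1[t], i2[t]] <- obs[i1[t], i2[t]] + 1
    cnt <- tabulate(c(i1, i2), nbins = k)
    p <- cnt / (2 * n)
    expm <- outer(p, p) * 2 * n
    diag(expm) <- p^2 * n
    up <- upper.tri(expm, diag = TRUE)
    e <- expm[up]; o <- obs[up]
    keep <- e > 0
    sum((o[keep] - e[keep])^2 / e[keep])
}

.saveSeed <- function()
    if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
.restoreSeed <- function(old) {
    if (is.null(old)) return(invisible())
    assign(".Random.seed", old, envir = globalenv())
}

#' Combined multilocus probability of identity
#'
#' Product of per-locus PI values over the supplied loci; callers restrict
#' the vector to the loci actually compared (e.g. those typed in every
#' member of a match group).
#'
#' @param pi_values numeric vector of per-locus PI values in (0, 1].
#' @return combined probability.
#' @export
combinedIdentity <- function(pi_values) {
    if (!length(pi_values)) stop("no loci supplied")
    stopifnot(all(pi_values > 0), all(pi_values <= 1))
    prod(pi_values)
}

#' Parentage non-exclusion probability at one locus
#'
#' Probability that a random unrelated candidate parent is \emph{not}
#' excluded by Mendelian incompatibility at this locus, under
#' Hardy-Weinberg genotype proportions (Jamieson & Taylor power-sum
#' forms).  Mode \code{"one_parent"}: only the offspring genotype is known
#' (first-candidate-parent form).  Mode \code{"second_parent"}: the
#' genotype of one true parent is also known.  Combined values across loci
#' are the product (\code{\link{combinedNonExclusion}}).
#'
#' @param freq an \code{AlleleFrequencyTable}.
#' @param mode \code{"one_parent"} or \code{"second_parent"}.
#' @return non-exclusion probability in (0, 1].
#' @export
nonExclusionProbability <- function(freq,
                                    mode = c("one_parent", "second_parent")) {
    mode <- match.arg(mode)
    p <- freq$freq
    a2 <- .psum(p, 2); a3 <- .psum(p, 3); a4 <- .psum(p, 4); a5 <- .psum(p, 5)
    excl <- if (mode == "one_parent")
        1 - 4 * a2 + 2 * a2^2 + 4 * a3 - 3 * a4
    else
        1 - 2 * a2 + a3 + 3 * (a2 * a3 - a5) - 2 * (a2^2 - a4)
    1 - excl
}

#' @rdname nonExclusionProbability
#' @param freqs list of \code{AlleleFrequencyTable}s (one per locus).
#' @export
combinedNonExclusion <- function(freqs,
                                 mode = c("one_parent", "second_parent")) {
    mode <- match.arg(mode)
    prod(vapply(freqs, nonExclusionProbability, numeric(1), mode = mode))
}
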