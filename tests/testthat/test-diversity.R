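test_that("allele frequencies count two copies per typed diploid cell", {
    x <- makeGeno(list(one = list(L1 = c(100, 100)),
                       two = list(L1 = c(100, 102))))
    ft <- alleleFrequencies(x, "L1")
    expect_equal(ft$n_typed, 2)
    expect_equal(unname(ft$freq[c("100", "102")]), c(0.75, 0.25))
    # untyped cells leave the denominator
    y <- makeGeno(list(one = list(L1 = NULL), two = list(L1 = c(100, 102))))
    ft <- alleleFrequencies(y, "L1")
    expect_equal(ft$n_typed, 1)
    expect_equal(unname(ft$freq), c(0.5, 0.5))
})

test_that("UDP-022 frequencies in the profile fixture match a hand tally", {
    x <- suppressMessages(readGenotypes(table2Path()))
    ft <- alleleFrequencies(x, "UDP-022")
    expect_equal(ft$n_typed, 12)
    expect_equal(ft$freq,
                 c("157" = 2, "165" = 12, "167" = 3, "169" = 1,
                   "171" = 6) / 24)
})

test_that("closed-form statistics are exact for biallelic and monomorphic loci", {
    x <- makeGeno(list(a = list(L1 = c(100, 102)), b = list(L1 = c(100, 102)),
                       c = list(L1 = c(100, 100)), d = list(L1 = c(102, 102))))
    st <- locusStats(alleleFrequencies(x, "L1"), x)
    expect_equal(st$Ne, 2)
    expect_equal(st$I, log(2))
    expect_equal(st$He, 0.5)
    expect_equal(st$PIC, 0.375)
    expect_equal(st$PI, 0.375)
    expect_equal(st$PD, 0.625)
    expect_equal(st$Ho, 0.5)
    expect_equal(st$F, 0)
    m <- makeGeno(list(a = list(L1 = c(100, 100)), b = list(L1 = c(100, 100))))
    sm <- locusStats(alleleFrequencies(m, "L1"), m)
    expect_equal(unlist(sm[, c("Na", "Ne", "I", "He", "PIC", "PI", "PD", "F")]),
                 c(Na = 1, Ne = 1, I = 0, He = 0, PIC = 0, PI = 1, PD = 0,
                   F = 0))
})

test_that("PD + PI = 1 and PIC < He hold across simulated panels", {
    set.seed(42)
    sim <- simulateCollection(n_accessions = 80, seed = 42)
    st <- diversityStats(sim$genotypes)
    expect_equal(st$PD + st$PI, rep(1, nrow(st)))
    poly <- st$Na >= 2
    expect_true(all(st$PIC[poly] < st$He[poly]))
    expect_true(all(st$Ne >= 1 & st$Ne <= st$Na))
    expect_true(all(st$Ho >= 0 & st$Ho <= 1 & st$He >= 0 & st$He < 1))
    expect_true(all(st$Nra >= 0 & st$Nra <= st$Na))
})

test_that("PI formula equals the brute-force genotype-pair enumeration", {
    set.seed(7)
    for (k in 2:4) {
        p <- randFreq(k)
        # embed the frequencies in a frequency-table object via a dummy
        # matrix carrying one heterozygote (Ho irrelevant to PI)
        x <- makeGeno(list(a = list(L1 = as.integer(names(p)[1:2]))))
        ft <- alleleFrequencies(x, "L1")
        ft$freq <- p
        st <- locusStats(ft, x)
        expect_equal(st$PI, brutePI(p), tolerance = 1e-12)
        expect_equal(st$PD, 1 - brutePI(p), tolerance = 1e-12)
    }
})

test_that("non-exclusion probabilities match exhaustive enumeration", {
    x <- makeGeno(list(a = list(L1 = c(100, 102))))
    # monomorphic: no exclusion power
    ftm <- alleleFrequencies(x, "L1")
    ftm$freq <- c("100" = 1)
    expect_equal(nonExclusionProbability(ftm, "one_parent"), 1)
    expect_equal(nonExclusionProbability(ftm, "second_parent"), 1)
    set.seed(5)
    for (k in 2:4) {
        p <- randFreq(k)
        ft <- alleleFrequencies(x, "L1")
        ft$freq <- p
        expect_equal(nonExclusionProbability(ft, "one_parent"),
                     bruteNonExclOne(p), tolerance = 1e-10)
        expect_equal(nonExclusionProbability(ft, "second_parent"),
                     bruteNonExclSecond(p), tolerance = 1e-10)
    }
    # equifrequent alleles: non-exclusion decreases with allele number
    vals <- sapply(2:6, function(k) {
        ft <- alleleFrequencies(x, "L1")
        ft$freq <- setNames(rep(1 / k, k), 100 + 2 * (1:k))
        nonExclusionProbability(ft, "one_parent")
    })
    expect_true(all(diff(vals) < 0))
})

test_that("combined identity is the product over loci", {
    expect_equal(combinedIdentity(0.375), 0.375)
    expect_equal(combinedIdentity(c(0.375, 0.375)), 0.140625)
    expect_error(combinedIdentity(numeric(0)))
    set.seed(12)
    sim <- simulateCollection(n_accessions = 120, seed = 12)
    st <- diversityStats(sim$genotypes)
    expect_lt(combinedIdentity(st$PI), 1e-5)
})

test_that("rare and private alleles are classified per definition", {
    # allele present once among many diploids: rare and private
    cells <- c(list(carrier = list(L1 = c(100, 198))),
               lapply(setNames(1:30, paste0("acc", 1:30)),
                      function(i) list(L1 = c(100, 100))))
    x <- makeGeno(cells)
    rp <- rareAndPrivateAlleles(x)
    expect_true(198 %in% rp$rare$allele)
    expect_true(198 %in% rp$private$allele)
    expect_equal(rp$private$accession[rp$private$allele == 198], "carrier")
    # an allele in two distinct genotypes is not private
    x2 <- makeGeno(list(u = list(L1 = c(100, 198), L2 = c(150, 150)),
                        v = list(L1 = c(100, 198), L2 = c(152, 152)),
                        w = list(L1 = c(100, 100), L2 = c(150, 152))))
    rp2 <- rareAndPrivateAlleles(x2)
    expect_false(198 %in% rp2$private$allele)
    # clones (identical multilocus profiles) count as one carrier
    cells3 <- list(a = list(L1 = c(100, 198), L2 = c(150, 152)),
                   a_clone = list(L1 = c(100, 198), L2 = c(150, 152)),
                   b = list(L1 = c(100, 100), L2 = c(150, 150)))
    x3 <- makeGeno(cells3)
    rp3 <- rareAndPrivateAlleles(x3)
    expect_true(198 %in% rp3$private$allele)
})

test_that("HWE Monte Carlo test has correct behaviour under null and alternative", {
    # all homozygotes at a 50/50 biallelic locus: emphatic rejection
    cells <- c(lapply(setNames(1:50, paste0("h", 1:50)),
                      function(i) list(L1 = c(100, 100))),
               lapply(setNames(1:50, paste0("k", 1:50)),
                      function(i) list(L1 = c(102, 102))))
    x <- makeGeno(cells)
    expect_lt(hweTest(x, "L1", n_mc = 4999, seed = 1), 0.001)
    # monomorphic convention
    m <- makeGeno(lapply(setNames(1:6, paste0("m", 1:6)),
                         function(i) list(L1 = c(100, 100))))
    expect_equal(hweTest(m, "L1"), 1.0)
    # type-I error close to alpha on HWE data
    set.seed(99)
    rej <- 0L
    n_rep <- 200L
    for (r in seq_len(n_rep)) {
        g1 <- sample(c(100L, 102L), 500, TRUE)
        g2 <- sample(c(100L, 102L), 500, TRUE)
        a1 <- matrix(pmin(g1, g2), 1, 500,
                     dimnames = list("L1", paste0("i", 1:500)))
        a2 <- matrix(pmax(g1, g2), 1, 500)
        dimnames(a2) <- dimnames(a1)
        xx <- SSRGenotypes(a1, a2)
        if (hweTest(xx, "L1", n_mc = 199) < 0.05) rej <- rej + 1L
    }
    expect_gt(rej / n_rep, 0.01)
    expect_lt(rej / n_rep, 0.10)
})
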