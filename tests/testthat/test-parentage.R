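test_that("duo, trio and self locus verdicts follow Mendelian rules", {
    x <- makeGeno(list(
        child  = list(L1 = c(1, 2), L2 = c(1, 1), L3 = c(1, 2), L4 = c(2, 2)),
        par1   = list(L1 = c(2, 3), L2 = c(3, 3), L3 = c(1, 3), L4 = c(1, 2)),
        par2   = list(L1 = c(4, 5), L2 = c(4, 4), L3 = c(2, 4), L4 = c(2, 3))))
    duo <- compatibleDuo(x, "child", "par1")
    expect_equal(unname(duo), c("compatible", "incompatible", "compatible",
                                "compatible"))
    # homozygote/homozygote conflict becomes excusable under null alleles
    duo_null <- compatibleDuo(x, "child", "par1", allow_null = TRUE)
    expect_equal(unname(duo_null[2]), "excusable")
    trio <- compatibleTrio(x, "child", "par1", "par2")
    expect_equal(unname(trio[3]), "compatible")   # 1 from par1, 2 from par2
    expect_equal(unname(trio[1]), "incompatible") # no parent carries 1
    # parent symmetry
    expect_equal(compatibleTrio(x, "child", "par1", "par2"),
                 compatibleTrio(x, "child", "par2", "par1"))
    # selfing: parent (a,b) permits aa/ab/bb; parent (a,a) only aa
    y <- makeGeno(list(p = list(L1 = c(1, 2), L2 = c(1, 1)),
                       caa = list(L1 = c(2, 2), L2 = c(1, 2))))
    sf <- compatibleSelf(y, "caa", "p")
    expect_equal(unname(sf), c("compatible", "incompatible"))
})

test_that("trio verdicts agree with exhaustive enumeration over 3-allele loci", {
    gs <- allGenotypes(1:3)
    for (ci in seq_along(gs)) for (p1 in seq_along(gs))
        for (p2 in seq_along(gs)) {
            x <- makeGeno(list(c_ = list(L1 = gs[[ci]]),
                               a_ = list(L1 = gs[[p1]]),
                               b_ = list(L1 = gs[[p2]])))
            got <- unname(compatibleTrio(x, "c_", "a_", "b_")[1])
            want <- if (trioOK(gs[[ci]], gs[[p1]], gs[[p2]]))
                "compatible" else "incompatible"
            expect_equal(got, want)
        }
})

test_that("null-allele excusal is a monotone relaxation", {
    set.seed(17)
    for (rep in 1:30) {
        x <- randomGeno(3, loci = 6, sizes = seq(100, 106, 2))
        ids <- accessionIds(x)
        plain <- compatibleTrio(x, ids[1], ids[2], ids[3])
        relaxed <- compatibleTrio(x, ids[1], ids[2], ids[3],
                                  allow_null = TRUE)
        # no locus downgraded: compatible stays compatible, incompatible
        # may only become excusable
        expect_true(all(relaxed[plain == "compatible"] == "compatible"))
        expect_true(all(relaxed[plain == "incompatible"] %in%
                            c("incompatible", "excusable")))
    }
})

test_that("simulated offspring always pass their declared check", {
    set.seed(27)
    sim <- simulateCollection(n_accessions = 30, missing_rate = 0,
                              clone_groups = 0, synonym_pairs = 0,
                              mislabel_count = 0, seed = 27)
    x <- sim$genotypes
    ids <- accessionIds(x)
    tri <- simulatePedigreeOffspring(x, ids[1:2], "cross", n = 10, seed = 1)
    for (ch in tri$records$child)
        expect_true(all(compatibleTrio(tri$genotypes, ch, ids[1], ids[2])
                        %in% c("compatible", "untyped")))
    slf <- simulatePedigreeOffspring(x, ids[3], "self", n = 10, seed = 2)
    for (ch in slf$records$child)
        expect_true(all(compatibleSelf(slf$genotypes, ch, ids[3])
                        %in% c("compatible", "untyped")))
    cln <- simulatePedigreeOffspring(x, ids[4], "clone", n = 2, seed = 3)
    for (ch in cln$records$child)
        expect_equal(compatibleClone(cln$genotypes, ch, ids[4]), "match")
    # op offspring are duo-compatible with the seed parent; when the random
    # pollen donor happened to be the seed parent itself the offspring must
    # also pass the selfing check
    op <- simulatePedigreeOffspring(x, ids[5], "op", n = 20, seed = 4)
    for (i in seq_along(op$records$child)) {
        ch <- op$records$child[i]
        expect_true(all(compatibleDuo(op$genotypes, ch, ids[5])
                        %in% c("compatible", "untyped")))
        if (op$donors[i] == ids[5])
            expect_true(all(compatibleSelf(op$genotypes, ch, ids[5])
                            %in% c("compatible", "untyped")))
    }
})

test_that("pedigree verification summarises match rates from counts", {
    set.seed(37)
    sim <- simulateCollection(n_accessions = 40, missing_rate = 0,
                              clone_groups = 0, synonym_pairs = 0,
                              mislabel_count = 0, seed = 37)
    x <- sim$genotypes
    ids <- accessionIds(x)
    tri <- simulatePedigreeOffspring(x, ids[1:2], "cross", n = 8, seed = 5)
    # corrupt three offspring by swapping in an unrelated declared parent
    rec <- tri$records
    rec$parent1[1:3] <- ids[10]
    v <- verifyPedigrees(rec, tri$genotypes)
    expect_equal(v$summary$n_checked[v$summary$pedigree_type ==
                                         "cross_two_parents"], 8)
    expect_equal(v$summary$pct_match[v$summary$pedigree_type == "total"],
                 rnd(100 * sum(v$results$verdict == "match") / 8, 1))
    # the printed-table arithmetic: counts -> percents at 1 decimal
    expect_equal(rnd(100 * 42 / 59, 1), 71.2)
    expect_equal(rnd(100 * 5 / 14, 1), 35.7)
    # unresolvable records are excluded and reported
    rec2 <- rec
    rec2$child[1] <- "ghost"
    v2 <- verifyPedigrees(rec2, tri$genotypes)
    expect_equal(nrow(v2$excluded), 1L)
})

test_that("verdicts demand a minimum number of comparable loci", {
    x <- makeGeno(list(ch = list(L1 = c(1, 2), L2 = NULL, L3 = NULL),
                       pa = list(L1 = c(2, 3), L2 = c(1, 1), L3 = c(1, 1))))
    rec <- data.frame(child = "ch", parent1 = "pa", parent2 = NA,
                      pedigree_type = "open_pollination", resolvable = TRUE)
    v <- verifyPedigrees(rec, x, min_loci = 2)
    expect_equal(v$results$verdict, "insufficient_data")
    v2 <- verifyPedigrees(rec, x, min_loci = 1)
    expect_equal(v2$results$verdict, "match")
})
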