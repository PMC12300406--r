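test_that("profile matching is missing-tolerant, symmetric and thresholded", {
    set.seed(21)
    x <- randomGeno(4, loci = 12)
    a1 <- SummarizedExperiment::assay(x, "allele1")
    a2 <- SummarizedExperiment::assay(x, "allele2")
    a1[, 2] <- a1[, 1]; a2[, 2] <- a2[, 1]          # B duplicates A
    a1[5, 2] <- a2[5, 2] <- NA                       # one locus untyped in B
    a1[, 3] <- a1[, 1]; a2[, 3] <- a2[, 1]
    a1[7, 3] <- a1[7, 1] + 2L; a2[7, 3] <- max(a1[7, 3], a2[7, 3])  # C differs at 1 locus
    x <- SSRGenotypes(a1, a2)
    ids <- accessionIds(x)
    expect_true(profileMatch(x, ids[1], ids[2]))     # 11 shared loci, identical
    expect_true(profileMatch(x, ids[2], ids[1]))     # symmetric
    expect_true(profileMatch(x, ids[1], ids[1]))     # reflexive when typed
    expect_false(profileMatch(x, ids[1], ids[3]))    # 1-locus difference
    # overlap below threshold cannot declare identity
    expect_false(profileMatch(x, ids[1], ids[2], min_overlap = 12))
})

test_that("zero overlapping typed loci is FALSE with a warning", {
    x <- makeGeno(list(a = list(L1 = c(100, 102), L2 = NULL),
                       b = list(L1 = NULL, L2 = c(150, 152))))
    expect_warning(res <- profileMatch(x, "a", "b", min_overlap = 1),
                   "no mutually typed")
    expect_false(res)
})

test_that("match groups are connected components; non-cliques are flagged", {
    # A=B and B=C via missing data, but A and C differ at a typed locus
    x <- makeGeno(list(
        A = list(L1 = c(100, 100), L2 = c(150, 152), L3 = c(200, 200)),
        B = list(L1 = c(100, 100), L2 = c(150, 152), L3 = NULL),
        C = list(L1 = c(100, 100), L2 = c(150, 152), L3 = c(202, 202))))
    expect_warning(g <- buildMatchGroups(x, min_overlap = 2), "non-clique")
    expect_length(g, 1L)
    expect_setequal(g[[1]]$members, c("A", "B", "C"))
    expect_false(g[[1]]$clique)
})

test_that("raising min_overlap never creates new matches", {
    set.seed(31)
    sim <- simulateCollection(n_accessions = 70, seed = 31)
    m_lo <- ssrcurate:::.matchMatrix(sim$genotypes, 6L)$match
    m_hi <- ssrcurate:::.matchMatrix(sim$genotypes, 10L)$match
    expect_true(all(m_lo[m_hi]))   # every high-threshold match exists at low
    expect_true(all(!m_hi[!m_lo])) # and none appears from nowhere
})

test_that("clone groups are recovered exactly without missing data", {
    sim <- simulateCollection(n_accessions = 100, clone_groups = 5,
                              synonym_pairs = 0, mislabel_count = 0,
                              missing_rate = 0, seed = 202)
    x <- sim$genotypes
    g <- buildMatchGroups(x)
    # oracle: partition accessions by exact full-profile equality
    key <- ssrcurate:::.profileKeys(x)
    truthGroups <- unname(Filter(function(v) length(v) > 1,
                                 split(accessionIds(x), key)))
    expect_equal(length(g), length(truthGroups))
    got <- lapply(g, function(gr) sort(gr$members))
    expect_setequal(vapply(got, paste, "", collapse = "|"),
                    vapply(lapply(truthGroups, sort), paste, "",
                           collapse = "|"))
    # every injected clone pair sits in one group
    tr <- sim$truth[!is.na(sim$truth$clone_group), ]
    for (cg in unique(tr$clone_group)) {
        pair <- tr$accession[tr$clone_group == cg]
        inone <- vapply(g, function(gr) all(pair %in% gr$members), logical(1))
        expect_true(any(inone))
    }
})

test_that("replicates consolidate to one entry; homonyms are kept apart", {
    set.seed(55)
    x <- randomGeno(5, loci = 12)
    a1 <- SummarizedExperiment::assay(x, "allele1")
    a2 <- SummarizedExperiment::assay(x, "allele2")
    # same name, same profile: replicate; same name, different: homonym
    a1 <- cbind(a1, rep1 = a1[, 1], rep2 = a1[, 1], homA = a1[, 2],
                homB = a1[, 3])
    a2 <- cbind(a2, rep1 = a2[, 1], rep2 = a2[, 1], homA = a2[, 2],
                homB = a2[, 3])
    nm <- c(colnames(a1)[1:5], "A001", "A001", "Same", "Same")
    colnames(a1) <- colnames(a2) <- make.unique(nm)
    meta <- data.frame(display_name = nm, row.names = colnames(a1))
    x <- SSRGenotypes(a1, a2, meta = meta)
    cons <- consolidateReplicates(x)
    # triplicate A001 (original + 2 replicates) collapses to one
    expect_equal(sum(accessionMeta(cons$matrix)$display_name == "A001"), 1L)
    expect_equal(nrow(cons$confirmations), 1L)
    # 'Same' pair differs: both retained and reported as homonyms
    expect_equal(sum(accessionMeta(cons$matrix)$display_name == "Same"), 2L)
    expect_equal(nrow(cons$homonyms), 1L)
})

test_that("group classification follows the documented precedence", {
    mkmeta <- function(ids, sport = NA, syn = NA) {
        m <- data.frame(display_name = ids,
                        known_sport_of = NA_character_,
                        known_synonym_group = NA_character_,
                        row.names = ids)
        m
    }
    grp <- function(members) structure(list(members = members,
                                            n = length(members),
                                            clique = TRUE,
                                            loci_compared = "L1",
                                            combined_pi = 0.1),
                                       class = "MatchGroup")
    ids <- c("Armking", "Armking Precoce", "V1", "V2", "S1", "S2")
    meta <- mkmeta(ids)
    meta["Armking Precoce", "known_sport_of"] <- "Armking"
    meta[c("S1", "S2"), "known_synonym_group"] <- "sg"
    ped <- data.frame(child = c("V1", "V2"), parent1 = c("Leader", "Leader"),
                      parent2 = c(NA, NA),
                      pedigree_type = "open_pollination", resolvable = TRUE)
    groups <- list(grp(c("Armking", "Armking Precoce")),
                   grp(c("S1", "S2")), grp(c("V1", "V2")))
    rep_ <- classifyGroups(groups, meta, pedigrees = ped, n_total = 10)
    expect_equal(unname(rep_$groups$classification),
                 c("known_mutation", "known_synonymy", "shared_pedigree"))
})

test_that("error rate counts mislabel-group members plus homonym entries", {
    # 10 mislabelled (5 untagged duplicate pairs) + 2 homonyms among 100
    grp <- function(members) structure(list(members = members, n = 2L,
                                            clique = TRUE,
                                            loci_compared = "L1",
                                            combined_pi = 0.1),
                                       class = "MatchGroup")
    ids <- paste0("m", 1:10)
    meta <- data.frame(display_name = ids, known_sport_of = NA_character_,
                       known_synonym_group = NA_character_, row.names = ids)
    groups <- lapply(split(ids, rep(1:5, each = 2)), grp)
    hom <- data.frame(name = "H", ids = "h_a;h_b")
    rep_ <- classifyGroups(groups, meta, n_total = 100, homonyms = hom)
    expect_equal(unname(rep_$counts[["mislabel"]]), 10L)
    expect_equal(rep_$error_rate, 12.0)
    # conservation: classified + homonyms <= total
    expect_lte(rep_$n_grouped + rep_$n_homonym, rep_$n_total)
})
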