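#' Simulate an SSR germplasm collection with known truth
#'
#' Generates a microsatellite collection that emulates the statistical
#' structure of a real clonal-crop genebank panel: a configurable number
#' of loci with 8-19 alleles each on a dinucleotide size ladder,
#' subpopulation allele-frequency divergence (F-model: subpopulation
#' frequencies drawn from a Dirichlet centred on the base frequencies with
#' concentration \code{(1 - d)/d}), excess homozygosity produced
#' mechanistically by generations of partial selfing at rate \code{s}
#' (equilibrium inbreeding \eqn{F = s/(2 - s)}), plus the curation errors
#' a genebank accumulates: clone/sport duplicates, documented synonyms,
#' mislabelled duplicates, null alleles (allele-specific dropouts turning
#' heterozygotes into apparent homozygotes) and per-cell missing data.
#' Every injected feature is recorded in a truth table so downstream
#' detection can be scored exactly.
#'
#' Defaults mirror a two-collection peach panel: 12 loci, three
#' subpopulations, selfing rate 0.42 (equilibrium F of about 0.27) and 5\%
#' missing data, at a desk scale of 150 accessions.
#'
#' @param n_accessions total accessions including injected duplicates
#'   (default 150).
#' @param n_loci number of SSR loci (default 12).
#' @param allele_range min/max alleles per locus (default \code{c(8, 19)}).
#' @param n_subpops number of diverged subpopulations (default 3).
#' @param divergence F-model divergence of subpopulation frequencies from
#'   the base frequencies, in (0, 1) (default 0.15; 0.30 is strong).
#' @param selfing_rate partial-selfing rate s in \[0, 1\] (default 0.42).
#' @param generations selfing generations simulated to reach inbreeding
#'   equilibrium (default 20; F converges geometrically).
#' @param admixed_fraction fraction of accessions drawn as admixed
#'   founders with Dirichlet(1) ancestry instead of pure subpopulation
#'   membership (default 0).
#' @param missing_rate per-cell probability of an untyped call (default
#'   0.05).
#' @param clone_groups number of sport/clone duplicate pairs (default 4).
#' @param synonym_pairs number of documented synonym pairs (default 3).
#' @param mislabel_count number of undocumented duplicate entries, i.e.
#'   mislabels (default 8).
#' @param null_allele_rate per-locus probability that one allele is a
#'   non-amplifying null (default 0).
#' @param seed integer seed; same seed, same collection.
#' @return list with \code{genotypes} (\code{SSRGenotypes} including
#'   metadata columns used by \code{\link{classifyGroups}}) and
#'   \code{truth} (data.frame: accession, subpop, admixture proportions,
#'   clone_group, synonym_tag, mislabel, duplicate_of).
#' @export
simulateCollection <- function(n_accessions = 150, n_loci = 12,
                               allele_range = c(8, 19), n_subpops = 3,
                               divergence = 0.15, selfing_rate = 0.42,
                               generations = 20, admixed_fraction = 0,
                               missing_rate = 0.05, clone_groups = 4,
                               synonym_pairs = 3, mislabel_count = 8,
                               null_allele_rate = 0, seed = NULL) {
    stopifnot(divergence > 0, divergence < 1,
              selfing_rate >= 0, selfing_rate <= 1,
              missing_rate >= 0, missing_rate < 1,
              admixed_fraction >= 0, admixed_fraction <= 1)
    n_copies <- clone_groups + synonym_pairs + mislabel_count
    n_base <- n_accessions - n_copies
    if (n_base < max(2 * n_copies, n_subpops * 2))
        stop("infeasible config: too many injected duplicates for n_accessions")
    if (!is.null(seed)) {
        old <- .saveSeed(); on.exit(.restoreSeed(old))
        set.seed(seed)
    }
    loci <- sprintf("SSR%02d", seq_len(n_loci))
    freqs <- .simLocusPanel(n_loci, allele_range, n_subpops, divergence)

    subpop <- sample(rep_len(seq_len(n_subpops), n_base))
    admixed <- stats::runif(n_base) < admixed_fraction
    qmat <- matrix(0, n_base, n_subpops)
    qmat[cbind(seq_len(n_base), subpop)] <- 1
    if (any(admixed)) {
        qmat[admixed, ] <- .rdirichlet(sum(admixed), rep(1, n_subpops))
        subpop[admixed] <- NA_integer_
    }

    a1 <- a2 <- matrix(NA_integer_, n_loci, n_base)
    for (k in seq_len(n_subpops)) {
        idx <- which(!is.na(subpop) & subpop == k)
        if (!length(idx)) next
        g <- .simSelfingPop(length(idx),
                            lapply(freqs, function(f)
                                list(sizes = f$sizes, freq = f$sub[[k]])),
                            selfing_rate, generations)
        a1[, idx] <- g$a1; a2[, idx] <- g$a2
    }
    for (i in which(admixed)) {   # admixed founders: per-copy origin by Q
        for (l in seq_len(n_loci)) {
            ks <- sample(n_subpops, 2L, replace = TRUE, prob = qmat[i, ])
            dr <- vapply(ks, function(k)
                sample(freqs[[l]]$sizes, 1L, prob = freqs[[l]]$sub[[k]]),
                numeric(1))
            a1[l, i] <- min(dr); a2[l, i] <- max(dr)
        }
    }

    ids <- sprintf("Acc%03d", seq_len(n_base))
    dimnames(a1) <- dimnames(a2) <- list(loci, ids)
    truth <- data.frame(accession = ids, subpop = subpop,
                        clone_group = NA_character_,
                        synonym_tag = NA_character_,
                        mislabel = FALSE, duplicate_of = NA_character_,
                        stringsAsFactors = FALSE)
    truth <- cbind(truth, stats::setNames(as.data.frame(qmat),
                                          paste0("q", seq_len(n_subpops))))
    meta <- data.frame(display_name = ids,
                       collection = sample(c("A", "B"), n_base, TRUE),
                       known_sport_of = NA_character_,
                       known_synonym_group = NA_character_,
                       row.names = ids, stringsAsFactors = FALSE)

    # inject duplicates: sports (documented), synonyms (documented),
    # mislabels (undocumented) -- sources all distinct
    src <- sample(ids, n_copies)
    take <- function(n) { out <- src[seq_len(n)]; src <<- src[-seq_len(n)]; out }
    addCopy <- function(orig, new_id, new_name, sport = FALSE, syn = NA) {
        a1 <<- cbind(a1, a1[, orig]); a2 <<- cbind(a2, a2[, orig])
        colnames(a1)[ncol(a1)] <<- new_id; colnames(a2)[ncol(a2)] <<- new_id
        meta[new_id, ] <<- list(new_name, sample(c("A", "B"), 1L),
                                if (sport) orig else NA_character_,
                                syn)
        tr <- truth[truth$accession == orig, ]
        tr$accession <- new_id
        tr$clone_group <- orig
        tr$synonym_tag <- if (!is.na(syn)) syn else NA_character_
        tr$mislabel <- !sport && is.na(syn)
        tr$duplicate_of <- orig
        truth[truth$accession == orig, "clone_group"] <<- orig
        if (!is.na(syn))
            truth[truth$accession == orig, "synonym_tag"] <<- syn
        truth <<- rbind(truth, tr)
    }
    for (o in take(clone_groups))
        addCopy(o, paste0(o, "_sport"), paste0(o, " Precoce"), sport = TRUE)
    for (o in take(synonym_pairs)) {
        tag <- paste0("syn_", o)
        meta[o, "known_synonym_group"] <- tag
        addCopy(o, paste0(o, "_syn"), paste0("Alias of ", o), syn = tag)
    }
    for (o in take(mislabel_count))
        addCopy(o, paste0(o, "_dup"), paste0("Wrong", substring(o, 4)))

    # null alleles: one dropout allele per affected locus
    for (l in seq_len(n_loci)) {
        if (stats::runif(1) >= null_allele_rate) next
        null_a <- sample(freqs[[l]]$sizes, 1L)
        has1 <- !is.na(a1[l, ]) & a1[l, ] == null_a
        has2 <- !is.na(a2[l, ]) & a2[l, ] == null_a
        both <- has1 & has2
        a1[l, both] <- NA_integer_; a2[l, both] <- NA_integer_
        a1[l, has1 & !both] <- a2[l, has1 & !both]      # show other allele
        a2[l, has2 & !both & !has1] <- a1[l, has2 & !both & !has1]
    }
    if (missing_rate > 0) {
        drop <- matrix(stats::runif(length(a1)) < missing_rate,
                       nrow(a1), ncol(a1))
        a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
    }
    x <- SSRGenotypes(a1, a2, meta = meta)
    list(genotypes = x, truth = truth)
}

# per-locus panel: allele sizes on an even (dinucleotide) ladder, base
# frequencies Dirichlet(1), subpop frequencies F-model around the base
.simLocusPanel <- function(n_loci, allele_range, n_subpops, divergence) {
    conc <- (1 - divergence) / divergence
    lapply(seq_len(n_loci), function(l) {
        na <- sample(seq(allele_range[1L], allele_range[2L]), 1L)
        start <- sample(seq(100L, 240L, by = 2L), 1L)
        sizes <- start + 2L * (seq_len(na) - 1L)
        base <- .rdirichlet(1L, rep(1, na))[1L, ]
        sub <- lapply(seq_len(n_subpops), function(k)
            .rdirichlet(1L, base * conc)[1L, ])
        list(sizes = sizes, base = base, sub = sub)
    })
}

# partial-selfing population: gen 0 drawn HWE from the subpop frequencies,
# then `generations` rounds where each offspring selfs a random parent
# with probability s, else crosses two random parents.  The breeding
# population is kept larger than the sample so that lineage coalescence
# does not flood the sample with identical multilocus genotypes; the
# requested n individuals are drawn from it without replacement.
.simSelfingPop <- function(n, locus_freqs, s, generations, min_pop = 150L) {
    n_out <- n
    n <- max(n, min_pop)
    L <- length(locus_freqs)
    g1 <- g2 <- matrix(NA_integer_, L, n)
    for (l in seq_len(L)) {
        f <- locus_freqs[[l]]
        sizes <- f$sizes
        d1 <- sample(sizes, n, TRUE, prob = f$freq)
        d2 <- sample(sizes, n, TRUE, prob = f$freq)
        g1[l, ] <- pmin(d1, d2); g2[l, ] <- pmax(d1, d2)
    }
    if (s > 0 && generations > 0) {
        for (gen in seq_len(generations)) {
            n1 <- n2 <- matrix(NA_integer_, L, n)
            selfed <- stats::runif(n) < s
            pa <- sample(n, n, TRUE)
            pb <- ifelse(selfed, pa, sample(n, n, TRUE))
            for (l in seq_len(L)) {
                da <- ifelse(stats::runif(n) < 0.5, g1[l, pa], g2[l, pa])
                db <- ifelse(stats::runif(n) < 0.5, g1[l, pb], g2[l, pb])
                n1[l, ] <- pmin(da, db); n2[l, ] <- pmax(da, db)
            }
            g1 <- n1; g2 <- n2
        }
    }
    keep <- sample(n, n_out)
    list(a1 = g1[, keep, drop = FALSE], a2 = g2[, keep, drop = FALSE])
}

.rdirichlet <- function(n, alpha) {
    g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
                n, length(alpha), byrow = TRUE)
    g <- pmax(g, 1e-300)
    g / rowSums(g)
}

#' Simulate Mendelian offspring for declared pedigrees
#'
#' Draws offspring genotypes from typed parents in a collection: crosses
#' take one random allele from each parent; selfings take two independent
#' draws from one parent; open pollination takes one allele from the
#' declared seed parent and one from a random pollen donor in the
#' collection; clones are verbatim copies.  A locus untyped in any
#' contributing parent is untyped in the offspring.
#'
#' @param x an \code{SSRGenotypes} object holding the parents.
#' @param parents character vector: one id (self/op/clone) or two ids
#'   (cross).
#' @param type one of \code{"cross"}, \code{"self"}, \code{"op"},
#'   \code{"clone"}.
#' @param n number of offspring.
#' @param seed optional integer seed.
#' @param prefix id prefix for the offspring (default \code{"off"}).
#' @return list with \code{genotypes} (\code{SSRGenotypes} containing the
#'   parents plus the new offspring) and \code{records} (pedigree
#'   data.frame as from \code{\link{readPedigrees}}, declaring only what a
#'   register would: op records name the seed parent only).
#' @export
simulatePedigreeOffspring <- function(x, parents, type = c("cross", "self",
                                                           "op", "clone"),
                                      n = 1L, seed = NULL, prefix = "off") {
    type <- match.arg(type)
    if (!is.null(seed)) {
        old <- .saveSeed(); on.exit(.restoreSeed(old))
        set.seed(seed)
    }
    stopifnot(all(parents %in% accessionIds(x)))
    if (type == "cross" && length(parents) != 2L)
        stop("cross needs two parents")
    if (type != "cross" && length(parents) != 1L)
        stop(type, " needs exactly one declared source")
    a1 <- SummarizedExperiment::assay(x, "allele1")
    a2 <- SummarizedExperiment::assay(x, "allele2")
    L <- nrow(x)
    o1 <- o2 <- matrix(NA_integer_, L, n)
    gamete <- function(parent, l)
        if (stats::runif(1) < 0.5) a1[l, parent] else a2[l, parent]
    donors <- character(n)
    for (i in seq_len(n)) {
        p1 <- parents[1L]
        p2 <- switch(type,
                     cross = parents[2L],
                     self = parents[1L],
                     op = sample(accessionIds(x), 1L),
                     clone = parents[1L])
        donors[i] <- p2
        for (l in seq_len(L)) {
            if (is.na(a1[l, p1]) || is.na(a1[l, p2])) next
            if (type == "clone") {
                o1[l, i] <- a1[l, p1]; o2[l, i] <- a2[l, p1]
            } else {
                da <- gamete(p1, l); db <- gamete(p2, l)
                o1[l, i] <- min(da, db); o2[l, i] <- max(da, db)
            }
        }
    }
    ids <- sprintf("%s%03d", prefix, seq_len(n))
    dimnames(o1) <- dimnames(o2) <- list(lociIds(x), ids)
    comb1 <- cbind(a1, o1); comb2 <- cbind(a2, o2)
    meta <- accessionMeta(x)
    meta2 <- meta[rep(1L, n), , drop = FALSE]
    meta2[] <- NA
    meta2$display_name <- ids
    rownames(meta2) <- ids
    records <- data.frame(
        child = ids,
        parent1 = parents[1L],
        parent2 = if (type == "cross") parents[2L] else NA_character_,
        pedigree_type = switch(type, cross = "cross_two_parents",
                               self = "self", op = "open_pollination",
                               clone = "clone"),
        resolvable = TRUE, stringsAsFactors = FALSE)
    list(genotypes = SSRGenotypes(comb1, comb2,
                                  meta = rbind(meta, meta2)),
         records = records, donors = donors)
}
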