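#' Compare two multilocus fingerprints
#'
#' Two accessions match when their genotypes are identical at every locus
#' typed in both, and the number of such mutually typed loci reaches
#' \code{min_overlap}.  Loci untyped in either profile carry no evidence
#' and are skipped, so scattered missing data does not break the identity
#' of true replicates.
#'
#' @param x an \code{SSRGenotypes} object.
#' @param a,b accession ids.
#' @param min_overlap minimum number of mutually typed loci required to
#'   declare identity (default 8 of a 12-locus panel, so that a handful of
#'   loci can never establish it).
#' @return \code{TRUE}/\code{FALSE}; zero overlapping typed loci gives
#'   \code{FALSE} with a warning (insufficient evidence).
#' @export
profileMatch <- function(x, a, b, min_overlap = 8L) {
    a1 <- SummarizedExperiment::assay(x, "allele1")
    a2 <- SummarizedExperiment::assay(x, "allele2")
    both <- !is.na(a1[, a]) & !is.na(a1[, b])
    if (!any(both)) {
        warning(sprintf("no mutually typed loci between '%s' and '%s'", a, b))
        return(FALSE)
    }
    same <- a1[both, a] == a1[both, b] & a2[both, a] == a2[both, b]
    all(same) && sum(both) >= min_overlap
}

# n x n logical match matrix plus overlap counts, vectorized per locus pair
.matchMatrix <- function(x, min_overlap = 8L) {
    a1 <- SummarizedExperiment::assay(x, "allele1")
    a2 <- SummarizedExperiment::assay(x, "allele2")
    n <- ncol(x)
    typed <- !is.na(a1)
    overlap <- crossprod(typed + 0L)                 # mutually typed loci
    diff <- matrix(0L, n, n)
    for (l in seq_len(nrow(x))) {
        t1 <- typed[l, ]
        d <- outer(a1[l, ], a1[l, ], "!=") | outer(a2[l, ], a2[l, ], "!=")
        d[!t1, ] <- FALSE; d[, !t1] <- FALSE
        diff <- diff + d
    }
    m <- diff == 0L & overlap >= min_overlap
    diag(m) <- FALSE
    dimnames(m) <- dimnames(overlap) <- list(accessionIds(x), accessionIds(x))
    list(match = m, overlap = overlap)
}

#' Group indistinguishable accessions
#'
#' Builds the pairwise fingerprint-match relation and returns its connected
#' components of size 2 or more.  Because missing data makes matching
#' non-transitive, a component need not be a clique; non-clique components
#' are flagged.  Each group is annotated with the combined probability of
#' identity over the loci typed in every member, using collection-wide
#' allele frequencies.
#'
#' @inheritParams profileMatch
#' @return list of \code{MatchGroup}s; each a list with \code{members},
#'   \code{n}, \code{clique} (logical), \code{loci_compared} (loci typed in
#'   all members) and \code{combined_pi}.
#' @export
buildMatchGroups <- function(x, min_overlap = 8L) {
    mm <- .matchMatrix(x, min_overlap)
    g <- igraph::graph_from_adjacency_matrix(mm$match, mode = "undirected")
    comp <- igraph::components(g)
    ids <- accessionIds(x)
    pis <- vapply(lociIds(x), function(l)
        locusStats(alleleFrequencies(x, l), x)$PI, numeric(1))
    typed <- isTyped(x)
    groups <- list()
    for (k in seq_len(comp$no)) {
        members <- ids[comp$membership == k]
        if (length(members) < 2L) next
        sub <- mm$match[members, members]
        clique <- all(sub[upper.tri(sub)])
        if (!clique)
            warning("non-clique match group: ",
                    paste(members, collapse = ", "),
                    " (identity not transitive under missing data)")
        shared <- lociIds(x)[rowSums(!typed[, members, drop = FALSE]) == 0L]
        groups[[length(groups) + 1L]] <- structure(
            list(members = members, n = length(members), clique = clique,
                 loci_compared = shared,
                 combined_pi = if (length(shared))
                     combinedIdentity(pis[shared]) else NA_real_),
            class = "MatchGroup")
    }
    groups
}

#' @export
print.MatchGroup <- function(x, ...) {
    cat("MatchGroup (", x$n, " accessions",
        if (!x$clique) ", non-clique", "): ",
        paste(x$members, collapse = ", "), "\n",
        "  combined PI over ", length(x$loci_compared), " shared loci: ",
        format(x$combined_pi, digits = 3), "\n", sep = "")
    invisible(x)
}

#' Consolidate replicated entries and detect homonyms
#'
#' Accessions sharing a \code{display_name} are either replicates of one
#' genotype (profiles match: only the first in file order is retained and
#' the identity is recorded as confirmed) or homonyms (profiles differ:
#' all entries are retained under their deterministic suffixed ids).
#'
#' @inheritParams profileMatch
#' @return list with \code{matrix} (consolidated \code{SSRGenotypes}),
#'   \code{confirmations} (data.frame: name, retained id, dropped ids) and
#'   \code{homonyms} (data.frame: name, ids kept).
#' @export
consolidateReplicates <- function(x, min_overlap = 8L) {
    meta <- accessionMeta(x)
    ids <- accessionIds(x)
    mm <- .matchMatrix(x, min_overlap)
    keep <- rep(TRUE, ncol(x))
    conf <- list(); hom <- list()
    for (nm in unique(meta$display_name[duplicated(meta$display_name)])) {
        idx <- which(meta$display_name == nm)
        sub <- mm$match[idx, idx]
        if (all(sub[upper.tri(sub)])) {
            keep[idx[-1L]] <- FALSE
            conf[[nm]] <- data.frame(name = nm, retained = ids[idx[1L]],
                                     dropped = paste(ids[idx[-1L]],
                                                     collapse = ";"))
        } else {
            hom[[nm]] <- data.frame(name = nm,
                                    ids = paste(ids[idx], collapse = ";"))
        }
    }
    list(matrix = x[, keep],
         confirmations = if (length(conf)) do.call(rbind, conf)
                         else data.frame(name = character(),
                                         retained = character(),
                                         dropped = character()),
         homonyms = if (length(hom)) do.call(rbind, hom)
                    else data.frame(name = character(), ids = character()))
}

.CLASS_LEVELS <- c("known_mutation", "known_synonymy", "shared_pedigree",
                   "mislabel")

# classification of one match group by documented-cause precedence
.classifyOne <- function(members, meta, pedigrees) {
    sport_of <- meta[members, "known_sport_of"]
    syn <- meta[members, "known_synonym_group"]
    # a sport link exists if one member is the recorded sport of another,
    # or two members are sports of the same source cultivar
    sport <- any(!is.na(sport_of) & sport_of %in% members) ||
        anyDuplicated(sport_of[!is.na(sport_of)]) > 0
    if (sport) return("known_mutation")
    if (anyDuplicated(syn[!is.na(syn)]) > 0) return("known_synonymy")
    if (!is.null(pedigrees) && nrow(pedigrees)) {
        par <- pedigrees[pedigrees$child %in% members, , drop = FALSE]
        cp <- unique(data.frame(child = rep(par$child, 2L),
                                parent = c(par$parent1, par$parent2)))
        cp <- cp[!is.na(cp$parent) & nzchar(cp$parent), , drop = FALSE]
        if (nrow(cp) && any(table(cp$parent) >= 2L))
            return("shared_pedigree")
    }
    "mislabel"
}

#' Classify match groups and compute the collection error rate
#'
#' Each group of indistinguishable accessions is assigned the
#' highest-precedence documented cause:
#' \code{known_mutation} (a member pair linked by a sport-mutation record)
#' > \code{known_synonymy} (a shared synonym tag) > \code{shared_pedigree}
#' (a declared common parent) > \code{mislabel} (no documented cause; the
#' accessions should be distinct).  The collection error rate is
#' \deqn{100 \cdot (\#accessions\ in\ mislabel\ groups +
#'        \#accessions\ in\ homonym\ pairs) / \#accessions\ analyzed,}
#' with the denominator taken before replicate consolidation.
#'
#' @param groups list of \code{MatchGroup}s from
#'   \code{\link{buildMatchGroups}}.
#' @param meta accession metadata data.frame (rownames = accession ids)
#'   with \code{known_sport_of} / \code{known_synonym_group} columns.
#' @param pedigrees optional pedigree data.frame
#'   (\code{\link{readPedigrees}}).
#' @param n_total total accessions analyzed (pre-consolidation
#'   denominator).
#' @param homonyms homonym table from \code{\link{consolidateReplicates}}
#'   (counts toward the error rate).
#' @return a \code{CurationReport}: list with \code{groups} (data.frame of
#'   members + classification + combined PI), \code{counts} per
#'   classification (accessions, not groups), \code{n_grouped},
#'   \code{n_homonym} and \code{error_rate} (percent).
#' @export
classifyGroups <- function(groups, meta, pedigrees = NULL, n_total,
                           homonyms = NULL) {
    cls <- vapply(groups, function(g)
        .classifyOne(g$members, meta, pedigrees), character(1))
    sizes <- vapply(groups, function(g) g$n, integer(1))
    counts <- vapply(.CLASS_LEVELS, function(cl)
        sum(sizes[cls == cl]), integer(1))
    n_hom <- if (is.null(homonyms)) 0L
             else sum(lengths(strsplit(homonyms$ids, ";")))
    gdf <- data.frame(
        members = vapply(groups, function(g)
            paste(g$members, collapse = ";"), character(1)),
        n = sizes, classification = cls,
        combined_pi = vapply(groups, function(g) g$combined_pi, numeric(1)),
        stringsAsFactors = FALSE)
    structure(list(groups = gdf, counts = counts,
                   n_grouped = sum(sizes), n_homonym = n_hom,
                   n_total = n_total,
                   error_rate = 100 * (counts[["mislabel"]] + n_hom) / n_total),
              class = "CurationReport")
}

#' @export
print.CurationReport <- function(x, ...) {
    cat("Curation report:", nrow(x$groups), "match groups covering",
        x$n_grouped, "accessions of", x$n_total, "\n")
    for (cl in names(x$counts))
        cat(sprintf("  %-16s %4d accessions\n", cl, x$counts[[cl]]))
    cat(sprintf("  homonym entries  %4d\n", x$n_homonym))
    cat(sprintf("  error rate: %.2f%%\n", x$error_rate))
    invisible(x)
}
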