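#' Per-locus Mendelian compatibility of a child with one candidate parent
#'
#' A locus is compatible when child and parent share at least one allele.
#' With \code{allow_null}, a locus where both individuals are homozygous
#' for different alleles is flagged \code{"excusable"} rather than failed:
#' both apparent homozygotes could carry the same non-amplifying (null)
#' allele.  Loci untyped in either profile are skipped.
#'
#' @param x an \code{SSRGenotypes} object.
#' @param child,parent accession ids.
#' @param allow_null logical; enable null-allele excusal (default FALSE).
#' @return named character vector over loci with values
#'   \code{"compatible"}, \code{"incompatible"}, \code{"excusable"} or
#'   \code{"untyped"}.
#' @export
compatibleDuo <- function(x, child, parent, allow_null = FALSE) {
    a1 <- SummarizedExperiment::assay(x, "allele1")
    a2 <- SummarizedExperiment::assay(x, "allele2")
    out <- setNames(rep("untyped", nrow(x)), lociIds(x))
    for (l in seq_len(nrow(x))) {
        cg <- c(a1[l, child], a2[l, child])
        pg <- c(a1[l, parent], a2[l, parent])
        if (anyNA(cg) || anyNA(pg)) next
        if (any(cg %in% pg)) out[l] <- "compatible"
        else if (allow_null && cg[1L] == cg[2L] && pg[1L] == pg[2L])
            out[l] <- "excusable"
        else out[l] <- "incompatible"
    }
    out
}

#' Per-locus Mendelian compatibility of a child with both declared parents
#'
#' A locus is compatible when the child's allele pair can be assembled
#' from one allele of each parent (all four assignments tried).  With
#' \code{allow_null}, apparent homozygotes (child or parent) are extended
#' with a putative shared null allele before the assignments are tried, so
#' a child (a,a) with a parent (b,b) can be explained by both carrying the
#' null.
#'
#' @inheritParams compatibleDuo
#' @param parent1,parent2 accession ids of the declared parents.
#' @return named character vector as in \code{\link{compatibleDuo}};
#'   null-rescued loci are \code{"excusable"}.
#' @export
compatibleTrio <- function(x, child, parent1, parent2, allow_null = FALSE) {
    a1 <- SummarizedExperiment::assay(x, "allele1")
    a2 <- SummarizedExperiment::assay(x, "allele2")
    out <- setNames(rep("untyped", nrow(x)), lociIds(x))
    NULLA <- -1L   # sentinel distinct from any real size
    for (l in seq_len(nrow(x))) {
        cg <- c(a1[l, child], a2[l, child])
        p1 <- c(a1[l, parent1], a2[l, parent1])
        p2 <- c(a1[l, parent2], a2[l, parent2])
        if (anyNA(cg) || anyNA(p1) || anyNA(p2)) next
        if (.trioOK(cg, p1, p2)) { out[l] <- "compatible"; next }
        if (allow_null) {
            ext <- function(g) if (g[1L] == g[2L]) c(g[1L], NULLA) else g
            if (.trioOK(ext(cg), ext(p1), ext(p2), null = NULLA)) {
                out[l] <- "excusable"; next
            }
        }
        out[l] <- "incompatible"
    }
    out
}

# can child pair be one allele from each parent?  with nulls, a child
# carrying the null sentinel means its visible allele came from one parent
# and the null from the other.
.trioOK <- function(cg, p1, p2, null = NA_integer_) {
    for (i in 1:2) for (j in 1:2) {
        want <- sort(c(p1[i], p2[j]))
        if (identical(want, sort(cg))) return(TRUE)
    }
    FALSE
}

#' Per-locus compatibility of a child with a declared selfing parent
#'
#' The child genotype must be producible by two independent draws from the
#' parent's alleles: parent (a,b) permits (a,a), (a,b), (b,b); parent
#' (a,a) permits only (a,a).  Null-allele excusal extends apparent
#' homozygotes with a putative null as in \code{\link{compatibleTrio}}.
#'
#' @inheritParams compatibleDuo
#' @return named character vector as in \code{\link{compatibleDuo}}.
#' @export
compatibleSelf <- function(x, child, parent, allow_null = FALSE) {
    compatibleTrio(x, child, parent, parent, allow_null = allow_null)
}

#' Clone identity check
#'
#' Delegates to \code{\link{profileMatch}}: a declared clone must carry an
#' identical fingerprint at every mutually typed locus.
#'
#' @inheritParams profileMatch
#' @return \code{"match"}, \code{"mismatch"} or \code{"insufficient_data"}.
#' @export
compatibleClone <- function(x, a, b, min_overlap = 8L) {
    ok <- withCallingHandlers(
        profileMatch(x, a, b, min_overlap = min_overlap),
        warning = function(w) invokeRestart("muffleWarning"))
    a1 <- SummarizedExperiment::assay(x, "allele1")
    both <- sum(!is.na(a1[, a]) & !is.na(a1[, b]))
    if (both < min_overlap) return("insufficient_data")
    if (ok) "match" else "mismatch"
}

.verdictFromLoci <- function(loci, min_loci, mismatch_tolerance = 0L) {
    compared <- sum(loci != "untyped")
    if (compared < min_loci) return(list(verdict = "insufficient_data",
                                         mismatching = character(0),
                                         excusable = character(0)))
    mis <- names(loci)[loci == "incompatible"]
    exc <- names(loci)[loci == "excusable"]
    list(verdict = if (length(mis) <= mismatch_tolerance) "match"
                   else "mismatch",
         mismatching = mis, excusable = exc)
}

#' Verify declared pedigrees against SSR profiles
#'
#' Routes every pedigree record to the appropriate Mendelian check
#' (cross to \code{\link{compatibleTrio}}, self to
#' \code{\link{compatibleSelf}}, open pollination to
#' \code{\link{compatibleDuo}} against the declared seed parent, clone to
#' \code{\link{compatibleClone}}), and summarises match rates per pedigree
#' type with percentages computed from the counts.  "Match" means no
#' non-excusable incompatible locus over at least \code{min_loci} compared
#' loci.  For open-pollinated offspring a selfing scan additionally
#' reports which of them are also compatible with pure self-pollination of
#' the seed parent.
#'
#' @param records pedigree data.frame from \code{\link{readPedigrees}}.
#' @param x an \code{SSRGenotypes} object.
#' @param min_loci minimum typed comparable loci for a usable verdict
#'   (default 8).
#' @param allow_null enable null-allele excusal.
#' @param mismatch_tolerance incompatible loci tolerated before declaring
#'   a mismatch (default 0: full matching).
#' @return list with \code{results} (per-record data.frame: verdict,
#'   mismatching and excusable loci, selfing-compatibility for op
#'   records), \code{summary} (per type: n checked, n match, percent
#'   rounded to 1 decimal, plus an overall row) and \code{excluded}
#'   (records with unresolvable accession ids).
#' @export
verifyPedigrees <- function(records, x, min_loci = 8L, allow_null = FALSE,
                            mismatch_tolerance = 0L) {
    ids <- accessionIds(x)
    refs_ok <- records$child %in% ids &
        (is.na(records$parent1) | records$parent1 %in% ids) &
        (is.na(records$parent2) | records$parent2 %in% ids) &
        nzchar(records$parent1) & records$parent1 %in% ids
    excluded <- records[!refs_ok, , drop = FALSE]
    rec <- records[refs_ok, , drop = FALSE]
    res <- vector("list", nrow(rec))
    for (i in seq_len(nrow(rec))) {
        r <- rec[i, ]
        if (r$pedigree_type == "cross_two_parents") {
            loci <- compatibleTrio(x, r$child, r$parent1, r$parent2,
                                   allow_null = allow_null)
            v <- .verdictFromLoci(loci, min_loci, mismatch_tolerance)
        } else if (r$pedigree_type == "self") {
            loci <- compatibleSelf(x, r$child, r$parent1,
                                   allow_null = allow_null)
            v <- .verdictFromLoci(loci, min_loci, mismatch_tolerance)
        } else if (r$pedigree_type == "open_pollination") {
            loci <- compatibleDuo(x, r$child, r$parent1,
                                  allow_null = allow_null)
            v <- .verdictFromLoci(loci, min_loci, mismatch_tolerance)
        } else {
            cv <- compatibleClone(x, r$child, r$parent1, min_overlap = min_loci)
            v <- list(verdict = if (cv == "match") "match"
                      else if (cv == "mismatch") "mismatch"
                      else "insufficient_data",
                      mismatching = character(0), excusable = character(0))
        }
        self_ok <- NA
        if (r$pedigree_type == "open_pollination") {
            sl <- compatibleSelf(x, r$child, r$parent1,
                                 allow_null = allow_null)
            self_ok <- .verdictFromLoci(sl, min_loci,
                                        mismatch_tolerance)$verdict == "match"
        }
        res[[i]] <- data.frame(
            child = r$child, parent1 = r$parent1,
            parent2 = if (is.na(r$parent2)) "" else r$parent2,
            pedigree_type = r$pedigree_type, verdict = v$verdict,
            mismatching_loci = paste(v$mismatching, collapse = ";"),
            null_excusable_loci = paste(v$excusable, collapse = ";"),
            self_compatible = self_ok, stringsAsFactors = FALSE)
    }
    results <- if (length(res)) do.call(rbind, res) else
        data.frame(child = character(), pedigree_type = character(),
                   verdict = character())
    list(results = results,
         summary = parentageSummary(results),
         excluded = excluded)
}

#' Table of parentage match rates by pedigree type
#'
#' @param results per-record verdict data.frame from
#'   \code{\link{verifyPedigrees}}; records with verdict
#'   \code{insufficient_data} are not counted as checked.
#' @return data.frame with one row per pedigree type plus a \code{total}
#'   row: \code{n_checked}, \code{n_match} and \code{pct_match}
#'   (= 100 n_match / n_checked, rounded half-up to 1 decimal).
#' @export
parentageSummary <- function(results) {
    usable <- results[results$verdict %in% c("match", "mismatch"), ,
                      drop = FALSE]
    types <- c("cross_two_parents", "self", "open_pollination", "clone")
    rows <- lapply(types, function(tp) {
        sub <- usable[usable$pedigree_type == tp, , drop = FALSE]
        data.frame(pedigree_type = tp, n_checked = nrow(sub),
                   n_match = sum(sub$verdict == "match"))
    })
    out <- do.call(rbind, rows)
    out <- rbind(out, data.frame(pedigree_type = "total",
                                 n_checked = sum(out$n_checked),
                                 n_match = sum(out$n_match)))
    out$pct_match <- ifelse(out$n_checked > 0,
                            .round2(100 * out$n_match / out$n_checked, 1),
                            NA_real_)
    out
}
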