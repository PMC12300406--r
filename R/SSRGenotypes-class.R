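#' SSRGenotypes: a container for co-dominant microsatellite genotypes
#'
#' \code{SSRGenotypes} extends
#' \code{\link[SummarizedExperiment]{SummarizedExperiment}} to hold diploid
#' SSR (simple sequence repeat) genotype calls for a germplasm collection.
#' Rows are loci, columns are accessions, and the two assays
#' \code{"allele1"} and \code{"allele2"} carry integer allele sizes in base
#' pairs.  Allele pairs are stored in canonical (ascending) order so that
#' genotype comparison is independent of the order alleles were scored in.
#' An untyped cell has \code{NA} in both assays; half-typed cells are
#' invalid.
#'
#' Accession metadata used by the curation workflow lives in
#' \code{colData()}: \code{display_name} (the label as it appears in the
#' collection register, possibly shared between accessions before homonym
#' resolution), \code{collection}, \code{origin_country},
#' \code{fruit_type}, \code{known_sport_of} (accession id of the cultivar
#' this entry is a documented sport mutation of), and
#' \code{known_synonym_group} (tag shared by documented synonyms).
#'
#' @slot .. see \code{SummarizedExperiment}; no additional slots are added.
#'
#' @seealso \code{\link{readGenotypes}}, \code{\link{diversityStats}},
#'   \code{\link{buildMatchGroups}}
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom methods new is validObject
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<-
#' @exportClass SSRGenotypes
setClass("SSRGenotypes", contains = "SummarizedExperiment")

.validSSRGenotypes <- function(object) {
    msg <- character(0)
    an <- names(SummarizedExperiment::assays(object))
    if (!all(c("allele1", "allele2") %in% an))
        return("assays must contain 'allele1' and 'allele2'")
    a1 <- SummarizedExperiment::assay(object, "allele1")
    a2 <- SummarizedExperiment::assay(object, "allele2")
    if (!is.numeric(a1) || !is.numeric(a2))
        return("allele assays must be numeric (integer base-pair sizes)")
    if (any(is.na(a1) != is.na(a2)))
        msg <- c(msg, "half-typed cells: allele1/allele2 NAs must be paired")
    ok <- !is.na(a1)
    if (any(a1[ok] <= 0) || any(a2[!is.na(a2)] <= 0))
        msg <- c(msg, "allele sizes must be positive")
    if (any(a1[ok] > a2[ok]))
        msg <- c(msg, "allele pairs must be stored sorted ascending")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "locus ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "accession ids (colnames) must be present and unique")
    if (!"display_name" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'display_name' column")
    if (length(msg)) msg else TRUE
}

setValidity("SSRGenotypes", .validSSRGenotypes)

.metaDefaults <- c("display_name", "collection", "origin_country",
                   "fruit_type", "known_sport_of", "known_synonym_group",
                   "pedigree_ref")

#' Construct an SSRGenotypes object
#'
#' @param allele1,allele2 integer matrices (loci x accessions) of allele
#'   sizes in base pairs, \code{NA} for untyped cells.  Pairs are
#'   canonicalized (sorted ascending elementwise) by the constructor.
#' @param meta optional data.frame of accession metadata, one row per
#'   accession (matched by rownames or by order).  Missing standard columns
#'   are added as \code{NA}; \code{display_name} defaults to the accession
#'   id.
#' @return an \code{SSRGenotypes} object.
#' @examples
#' a1 <- matrix(c(170L, 190L), 1, 2, dimnames = list("L1", c("acc1", "acc2")))
#' a2 <- matrix(c(190L, 190L), 1, 2, dimnames = list("L1", c("acc1", "acc2")))
#' SSRGenotypes(a1, a2)
#' @export
SSRGenotypes <- function(allele1, allele2, meta = NULL) {
    stopifnot(is.matrix(allele1), is.matrix(allele2),
              all(dim(allele1) == dim(allele2)))
    if (any(is.na(allele1) != is.na(allele2)))
        stop("half-typed cells: a locus is typed (both alleles) or untyped")
    lo <- pmin(allele1, allele2)
    hi <- pmax(allele1, allele2)
    storage.mode(lo) <- "integer"
    storage.mode(hi) <- "integer"
    ids <- colnames(allele1)
    if (is.null(ids)) ids <- paste0("acc", seq_len(ncol(allele1)))
    if (is.null(meta)) meta <- data.frame(row.names = ids)
    meta <- as.data.frame(meta)
    if (!nrow(meta)) meta <- data.frame(row.names = ids)
    if (is.null(rownames(meta)) || all(rownames(meta) == seq_len(nrow(meta))))
        rownames(meta) <- ids
    meta <- meta[ids, , drop = FALSE]
    rownames(meta) <- ids
    for (cc in .metaDefaults)
        if (!cc %in% colnames(meta))
            meta[[cc]] <- if (cc == "display_name") ids else NA_character_
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(allele1 = lo, allele2 = hi),
        colData = S4Vectors::DataFrame(meta))
    colnames(se) <- ids
    new("SSRGenotypes", se)
}

#' @describeIn SSRGenotypes-accessors accession identifiers (unique after
#'   homonym disambiguation)
#' @export
accessionIds <- function(x) colnames(x)

#' Accessors for SSRGenotypes
#'
#' @param x an \code{SSRGenotypes} object.
#' @param accession,locus identifiers (character) or indices.
#' @name SSRGenotypes-accessors
#' @return \code{lociIds}: character vector of locus ids; \code{isTyped}:
#'   logical loci x accessions matrix; \code{allelePair}: integer vector of
#'   length 2 (or \code{c(NA, NA)} when untyped); \code{accessionMeta}:
#'   data.frame of accession metadata.
NULL

#' @rdname SSRGenotypes-accessors
#' @export
lociIds <- function(x) rownames(x)

#' @rdname SSRGenotypes-accessors
#' @export
isTyped <- function(x) !is.na(SummarizedExperiment::assay(x, "allele1"))

#' @rdname SSRGenotypes-accessors
#' @export
allelePair <- function(x, accession, locus) {
    c(SummarizedExperiment::assay(x, "allele1")[locus, accession],
      SummarizedExperiment::assay(x, "allele2")[locus, accession])
}

#' @rdname SSRGenotypes-accessors
#' @export
accessionMeta <- function(x)
    as.data.frame(SummarizedExperiment::colData(x))

#' @importFrom methods show
setMethod("show", "SSRGenotypes", function(object) {
    nt <- sum(isTyped(object))
    cat("SSRGenotypes: ", nrow(object), " loci x ", ncol(object),
        " accessions\n", sep = "")
    cat("  typed cells: ", nt, "/", nrow(object) * ncol(object),
        sprintf(" (%.1f%%)\n", 100 * nt / max(1, nrow(object) * ncol(object))),
        sep = "")
    cat("  loci: ", paste(utils::head(rownames(object), 6), collapse = ", "),
        if (nrow(object) > 6) ", ..." else "", "\n", sep = "")
})

# genotype of every accession at one locus, as a 2 x n matrix
.locusGenotypes <- function(x, locus) {
    rbind(SummarizedExperiment::assay(x, "allele1")[locus, ],
          SummarizedExperiment::assay(x, "allele2")[locus, ])
}

# canonical multilocus profile strings ("-" for untyped) used for exact
# genotype identity (rare/private allele accounting)
.profileKeys <- function(x) {
    a1 <- SummarizedExperiment::assay(x, "allele1")
    a2 <- SummarizedExperiment::assay(x, "allele2")
    cell <- ifelse(is.na(a1), "-", paste0(a1, "/", a2))
    apply(cell, 2, paste, collapse = "|")
}
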