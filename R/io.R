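#' Read a delimited SSR genotype table
#'
#' Reads an accession x locus genotype table in the layout used for SSR
#' fingerprint registers: a header row of locus ids, one row per accession,
#' and each cell holding the two allele sizes of a diploid call
#' (e.g. \code{"170, 190"}) or a missing token.  Allele pairs are
#' canonicalized to ascending order on read.  Cells may carry flag markers
#' (asterisks, e.g. \code{"162, **166**"}) around individual allele sizes,
#' as used in published profile tables to highlight private alleles; the
#' flags are stripped and recorded in
#' \code{metadata(x)$allele_flags}.
#'
#' Duplicate accession names are allowed in the input (replicated entries
#' and homonyms are a curation reality); each duplicate keeps its original
#' label in \code{display_name} and the accession id is disambiguated with
#' a deterministic alphabetic suffix (\code{"_a"}, \code{"_b"}, ...) in
#' file order, with a warning.
#'
#' @param path path to a delimited text file.
#' @param sep field separator; default \code{"\t"}. Use \code{","} for CSV.
#' @param missing_tokens cell values treated as untyped.  Default
#'   \code{c("- -", "-", "", "NA", "0")}.
#' @param meta optional accession metadata data.frame passed on to
#'   \code{\link{SSRGenotypes}} (rownames = display names or ids).
#' @return an \code{\link{SSRGenotypes}} object.  The number of typed and
#'   untyped cells is reported with \code{message()}.
#' @export
readGenotypes <- function(path, sep = "\t",
                          missing_tokens = c("- -", "-", "", "NA", "0"),
                          meta = NULL) {
    raw <- utils::read.table(path, sep = sep, header = TRUE,
                             check.names = FALSE, colClasses = "character",
                             quote = "\"", comment.char = "",
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 2L)
        stop("genotype table needs a key column plus at least one locus")
    names_in <- trimws(raw[[1L]])
    loci <- colnames(raw)[-1L]
    if (anyDuplicated(loci))
        stop("duplicate locus ids in header")
    ids <- .disambiguate(names_in)
    n <- length(ids)
    a1 <- a2 <- matrix(NA_integer_, nrow = length(loci), ncol = n,
                       dimnames = list(loci, ids))
    flags <- list()
    for (j in seq_along(loci)) {
        for (i in seq_len(n)) {
            cellraw <- trimws(raw[i, j + 1L])
            if (cellraw %in% missing_tokens) next
            starred <- .parseCell(cellraw, missing_tokens,
                                  row = names_in[i], col = loci[j])
            if (is.null(starred)) next
            a1[j, i] <- starred$pair[1L]
            a2[j, i] <- starred$pair[2L]
            if (length(starred$flagged))
                flags[[length(flags) + 1L]] <- data.frame(
                    accession = ids[i], locus = loci[j],
                    allele = starred$flagged)
        }
    }
    if (is.null(meta)) {
        meta <- data.frame(display_name = names_in, row.names = ids)
    } else {
        meta <- as.data.frame(meta)
        if (!"display_name" %in% colnames(meta))
            meta$display_name <- rownames(meta)
        key <- if (all(names_in %in% rownames(meta))) names_in else ids
        meta <- meta[key, , drop = FALSE]
        meta$display_name <- names_in
        rownames(meta) <- ids
    }
    x <- SSRGenotypes(a1, a2, meta = meta)
    if (length(flags))
        S4Vectors::metadata(x)$allele_flags <-
            do.call(rbind, flags)
    nt <- sum(isTyped(x))
    message(sprintf("read %d accessions x %d loci: %d typed, %d untyped cells",
                    n, length(loci), nt, length(loci) * n - nt))
    x
}

# parse one genotype cell; returns list(pair=int[2], flagged=int[]) or NULL
.parseCell <- function(cell, missing_tokens, row, col) {
    parts <- strsplit(cell, "[,;/[:space:]]+")[[1L]]
    parts <- parts[nzchar(parts)]
    if (length(parts) == 1L && parts %in% missing_tokens) return(NULL)
    if (length(parts) != 2L)
        stop(sprintf(
            "malformed genotype cell '%s' at accession '%s', locus '%s': %s",
            cell, row, col,
            if (length(parts) < 2L) "one allele only" else "too many alleles"))
    starred <- grepl("\\*", parts)
    vals <- suppressWarnings(as.numeric(gsub("\\*", "", parts)))
    if (any(is.na(vals)))
        stop(sprintf("non-numeric allele in cell '%s' (accession '%s', locus '%s')",
                     cell, row, col))
    if (any(vals != round(vals))) {
        warning(sprintf(
            "fractional allele size in cell '%s' (accession '%s', locus '%s'): rounded",
            cell, row, col))
        vals <- round(vals)
    }
    if (any(vals <= 0))
        stop(sprintf("non-positive allele size in cell '%s' (accession '%s', locus '%s')",
                     cell, row, col))
    o <- order(vals)
    list(pair = as.integer(vals[o]), flagged = as.integer(vals[starred]))
}

# deterministic alphabetic suffixes for duplicated names, in file order
.disambiguate <- function(names_in) {
    ids <- names_in
    dup <- unique(names_in[duplicated(names_in)])
    if (length(dup)) {
        warning(sprintf("%d duplicated accession name(s): %s; suffixes applied",
                        length(dup),
                        paste(utils::head(dup, 5), collapse = ", ")))
        for (nm in dup) {
            idx <- which(names_in == nm)
            ids[idx] <- paste0(nm, "_", letters[seq_along(idx)])
        }
    }
    ids
}

#' Write an SSRGenotypes object as a delimited genotype table
#'
#' Inverse of \code{\link{readGenotypes}}: one row per accession, one
#' column per locus, cells \code{"a1, a2"}, untyped written as
#' \code{"- -"}.  Reading the file back yields an identical object (allele
#' pairs are already canonical).
#'
#' @param x an \code{SSRGenotypes} object.
#' @param path output path.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(x, path, sep = "\t") {
    a1 <- SummarizedExperiment::assay(x, "allele1")
    a2 <- SummarizedExperiment::assay(x, "allele2")
    cell <- ifelse(is.na(a1), "- -", paste0(a1, ", ", a2))
    out <- data.frame(Sample = accessionIds(x), t(cell),
                      check.names = FALSE)
    colnames(out) <- c("Sample", lociIds(x))
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Apply a primer-tag size offset to all allele calls
#'
#' Multiplex-ready SSR genotyping with tagged primers shifts every scored
#' fragment by a fixed number of base pairs relative to the published
#' allele sizes; this subtracts that offset from every present allele.
#' Untyped cells are unchanged.
#'
#' @param x an \code{SSRGenotypes} object.
#' @param offset non-negative integer base pairs to subtract (commonly 30
#'   for tagged-primer protocols; default 0 leaves calls as scored).
#' @return an \code{SSRGenotypes} with shifted allele sizes.
#' @export
applyTagOffset <- function(x, offset) {
    stopifnot(length(offset) == 1L, offset >= 0)
    if (offset == 0) return(x)
    a1 <- SummarizedExperiment::assay(x, "allele1") - as.integer(offset)
    a2 <- SummarizedExperiment::assay(x, "allele2") - as.integer(offset)
    if (any(a1 <= 0, na.rm = TRUE))
        stop("offset produces non-positive allele sizes")
    SummarizedExperiment::assays(x)[["allele1"]] <- a1
    SummarizedExperiment::assays(x)[["allele2"]] <- a2
    validObject(x)
    x
}

#' Export genotypes in the two-row-per-accession STRUCTURE layout
#'
#' Writes the integer table read by the STRUCTURE family of admixture
#' programs: two rows per accession (one per allele copy), one column per
#' locus, missing data encoded by a sentinel integer.
#'
#' @param x an \code{SSRGenotypes} object (non-empty).
#' @param path output path.
#' @param missing_code integer sentinel for missing alleles; must not
#'   collide with any real allele size (default \code{-9}).
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readStructureFormat}} for the matching reader; the
#'   round trip is lossless up to accession metadata.
#' @export
exportStructureFormat <- function(x, path, missing_code = -9L) {
    stopifnot(nrow(x) > 0L, ncol(x) > 0L)
    a1 <- SummarizedExperiment::assay(x, "allele1")
    a2 <- SummarizedExperiment::assay(x, "allele2")
    sizes <- unique(c(a1[!is.na(a1)], a2[!is.na(a2)]))
    if (missing_code %in% sizes)
        stop("missing_code collides with a real allele size")
    r1 <- t(a1); r2 <- t(a2)
    r1[is.na(r1)] <- missing_code
    r2[is.na(r2)] <- missing_code
    n <- ncol(x)
    inter <- matrix(NA_integer_, nrow = 2L * n, ncol = nrow(x))
    inter[seq(1L, 2L * n, by = 2L), ] <- r1
    inter[seq(2L, 2L * n, by = 2L), ] <- r2
    out <- data.frame(id = rep(accessionIds(x), each = 2L), inter)
    colnames(out) <- c("id", lociIds(x))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a two-row-per-accession STRUCTURE-layout genotype table
#'
#' @param path file written by \code{\link{exportStructureFormat}} (or any
#'   two-row integer table with an id column and a locus header).
#' @param missing_code sentinel used for missing alleles.
#' @return an \code{SSRGenotypes} object.
#' @export
readStructureFormat <- function(path, missing_code = -9L) {
    raw <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE)
    if (nrow(raw) %% 2L != 0L)
        stop("STRUCTURE-format file must have two rows per accession")
    odd <- seq(1L, nrow(raw), by = 2L)
    ids <- as.character(raw[[1L]][odd])
    if (!identical(as.character(raw[[1L]][odd + 1L]), ids))
        stop("row pairs carry different accession ids")
    loci <- colnames(raw)[-1L]
    m1 <- t(as.matrix(raw[odd, -1L, drop = FALSE]))
    m2 <- t(as.matrix(raw[odd + 1L, -1L, drop = FALSE]))
    m1[m1 == missing_code] <- NA
    m2[m2 == missing_code] <- NA
    dimnames(m1) <- dimnames(m2) <- list(loci, ids)
    SSRGenotypes(m1, m2)
}

#' Read declared pedigree records
#'
#' Reads a delimited table of declared parentages with columns
#' \code{child}, \code{parent1}, \code{parent2}, \code{type}.  Accepted
#' type tokens: \code{cross} (two known parents), \code{self}
#' (self-pollination of one parent), \code{op} (open pollination of a known
#' seed parent), \code{clone} (vegetative copy of one source accession).
#'
#' @param path delimited text file.
#' @param sep separator (default \code{","}).
#' @param ids optional vector of known accession ids; children not in it
#'   are retained but flagged unresolvable with a warning.
#' @return data.frame with columns \code{child}, \code{parent1},
#'   \code{parent2}, \code{pedigree_type}, \code{resolvable}.
#' @export
readPedigrees <- function(path, sep = ",", ids = NULL) {
    raw <- utils::read.table(path, sep = sep, header = TRUE,
                             colClasses = "character",
                             stringsAsFactors = FALSE)
    colnames(raw) <- tolower(colnames(raw))
    need <- c("child", "parent1", "parent2", "type")
    if (!all(need %in% colnames(raw)))
        stop("pedigree table needs columns child,parent1,parent2,type")
    ptype <- c(cross = "cross_two_parents", self = "self",
               op = "open_pollination", clone = "clone")
    tok <- tolower(trimws(raw$type))
    if (any(!tok %in% names(ptype)))
        stop("unknown pedigree type token(s): ",
             paste(unique(tok[!tok %in% names(ptype)]), collapse = ", "))
    rec <- data.frame(child = trimws(raw$child),
                      parent1 = trimws(raw$parent1),
                      parent2 = trimws(raw$parent2),
                      pedigree_type = unname(ptype[tok]),
                      stringsAsFactors = FALSE)
    rec$parent2[!nzchar(rec$parent2)] <- NA_character_
    bad <- rec$pedigree_type == "cross_two_parents" &
        (is.na(rec$parent2) | !nzchar(rec$parent1))
    if (any(bad))
        stop("cross records must declare both parents: ",
             paste(rec$child[bad], collapse = ", "))
    single <- rec$pedigree_type != "cross_two_parents" & !is.na(rec$parent2)
    if (any(single))
        stop("self/op/clone records must declare exactly one source: ",
             paste(rec$child[single], collapse = ", "))
    rec$resolvable <- TRUE
    if (!is.null(ids)) {
        rec$resolvable <- rec$child %in% ids
        if (any(!rec$resolvable))
            warning(sprintf("%d pedigree child(ren) not found in collection",
                            sum(!rec$resolvable)))
    }
    rec
}
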