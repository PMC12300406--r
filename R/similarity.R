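#' Lynch band-sharing similarity between two accessions
#'
#' Treats each distinct allele at a locus as one band (a homozygote
#' contributes a single band, a heterozygote two) and computes
#' \deqn{S = 2 |B_x \cap B_y| / (|B_x| + |B_y|)}
#' over the loci typed in both accessions (pairwise deletion of untyped
#' loci).  This is the natural dominant (band) encoding of co-dominant SSR
#' profiles.
#'
#' @param x an \code{SSRGenotypes} object.
#' @param a,b accession ids.
#' @return similarity in \[0, 1\]; \code{NA} with a warning when the two
#'   accessions share no typed locus.
#' @export
lynchSimilarity <- function(x, a, b) {
    a1 <- SummarizedExperiment::assay(x, "allele1")
    a2 <- SummarizedExperiment::assay(x, "allele2")
    both <- !is.na(a1[, a]) & !is.na(a1[, b])
    if (!any(both)) {
        warning(sprintf("no mutually typed loci between '%s' and '%s'", a, b))
        return(NA_real_)
    }
    num <- 0; den <- 0
    for (l in which(both)) {
        bx <- unique(c(a1[l, a], a2[l, a]))
        by <- unique(c(a1[l, b], a2[l, b]))
        num <- num + 2 * length(intersect(bx, by))
        den <- den + length(bx) + length(by)
    }
    num / den
}

#' Pairwise Lynch similarity matrix
#'
#' @param x an \code{SSRGenotypes} object with at least two accessions.
#' @return symmetric matrix of similarities with unit diagonal; pairs with
#'   no mutually typed locus are \code{NA}.
#' @export
similarityMatrix <- function(x) {
    ids <- accessionIds(x)
    n <- length(ids)
    stopifnot(n >= 2L)
    s <- diag(1, n)
    dimnames(s) <- list(ids, ids)
    for (i in seq_len(n - 1L))
        for (j in seq(i + 1L, n)) {
            v <- suppressWarnings(lynchSimilarity(x, ids[i], ids[j]))
            s[i, j] <- s[j, i] <- v
        }
    s
}

#' UPGMA clustering of a similarity matrix
#'
#' Agglomerates on the distance \eqn{d = 1 - S} with unweighted
#' average linkage; merge heights are half the average-linkage distance,
#' so two accessions with similarity 0.5 join at height 0.25 and leaves
#' sit at height 0.  Ties are broken toward the lexicographically smallest
#' pair of cluster labels (a cluster is labelled by its smallest leaf), so
#' the tree is deterministic and invariant to input order.  Missing pairs
#' are imputed as similarity 0 with a warning.
#'
#' @param similarities complete symmetric similarity matrix with
#'   dimnames (e.g. from \code{\link{similarityMatrix}}).
#' @return an object of class \code{hclust} (heights already halved);
#'   feed to \code{\link{toNewick}} for export.
#' @export
upgma <- function(similarities) {
    s <- similarities
    stopifnot(is.matrix(s), nrow(s) == ncol(s))
    if (nrow(s) < 2L) stop("need at least two leaves")
    if (anyNA(s)) {
        warning("missing similarity pairs imputed as 0")
        s[is.na(s)] <- 0
    }
    labels <- rownames(s)
    if (is.null(labels)) labels <- paste0("L", seq_len(nrow(s)))
    d <- 1 - s
    diag(d) <- Inf
    n <- nrow(d)
    # active clusters: id < 0 => leaf -id ; id > 0 => merge row id
    cid <- -seq_len(n)
    csize <- rep(1L, n)
    clab <- labels                    # smallest leaf label, for tie-breaks
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    active <- rep(TRUE, n)
    for (step in seq_len(n - 1L)) {
        idx <- which(active)
        dm <- d[idx, idx, drop = FALSE]
        best <- min(dm)
        cand <- which(dm <= best + 1e-12, arr.ind = TRUE)
        cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
        # lexicographic tie-break on the (sorted) pair of cluster labels
        key <- apply(cand, 1L, function(rc) {
            lab <- sort(c(clab[idx[rc[1L]]], clab[idx[rc[2L]]]))
            paste(lab, collapse = "\r")
        })
        pick <- cand[order(key)[1L], ]
        i <- idx[pick[1L]]; j <- idx[pick[2L]]
        merge[step, ] <- c(cid[i], cid[j])
        height[step] <- d[i, j] / 2
        # unweighted average linkage update into slot i
        wi <- csize[i]; wj <- csize[j]
        for (k in idx)
            if (k != i && k != j)
                d[i, k] <- d[k, i] <- (wi * d[i, k] + wj * d[j, k]) / (wi + wj)
        csize[i] <- wi + wj
        clab[i] <- min(clab[i], clab[j])
        cid[i] <- step
        active[j] <- FALSE
        d[j, ] <- d[, j] <- Inf
    }
    hc <- list(merge = merge, height = height,
               order = .hcOrder(merge, n), labels = labels,
               method = "upgma", call = match.call(),
               dist.method = "1 - Lynch similarity (half heights)")
    class(hc) <- "hclust"
    hc
}

# leaf order by left-to-right traversal of the merge tree
.hcOrder <- function(merge, n) {
    walk <- function(node) {
        if (node < 0L) return(-node)
        c(walk(merge[node, 1L]), walk(merge[node, 2L]))
    }
    walk(nrow(merge))
}

#' Newick serialization of an ultrametric dendrogram
#'
#' Writes standard Newick with branch lengths equal to the difference
#' between parent and child heights (leaves at height 0).  Labels
#' containing whitespace, commas, parentheses or quotes are single-quoted.
#' The output parses with any standard tree reader (e.g.
#' \code{ape::read.tree}) preserving topology and heights.
#'
#' @param tree an \code{hclust} object (e.g. from \code{\link{upgma}}).
#' @param path optional path; when given the string is also written there.
#' @return the Newick string, invisibly when \code{path} is given.
#' @export
toNewick <- function(tree, path = NULL) {
    stopifnot(inherits(tree, "hclust"))
    quote_lab <- function(lab) {
        if (grepl("[\\s,;:()'\\[\\]]", lab, perl = TRUE))
            paste0("'", gsub("'", "''", lab), "'")
        else lab
    }
    rec <- function(node, parent_h) {
        if (node < 0L) {
            lab <- quote_lab(tree$labels[-node])
            return(paste0(lab, ":", format(parent_h, digits = 10)))
        }
        h <- tree$height[node]
        kids <- c(rec(tree$merge[node, 1L], h), rec(tree$merge[node, 2L], h))
        paste0("(", paste(kids, collapse = ","), "):",
               format(parent_h - h, digits = 10))
    }
    root <- nrow(tree$merge)
    h <- tree$height[root]
    kids <- c(rec(tree$merge[root, 1L], h), rec(tree$merge[root, 2L], h))
    nwk <- paste0("(", paste(kids, collapse = ","), ");")
    if (!is.null(path)) {
        writeLines(nwk, path)
        return(invisible(nwk))
    }
    nwk
}
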