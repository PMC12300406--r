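#' Fit the admixture model by Gibbs sampling
#'
#' Bayesian clustering of multi-allelic co-dominant genotypes in the style
#' of the STRUCTURE admixture model: each individual owns a vector of
#' membership proportions Q over K clusters, each cluster owns a Dirichlet
#' allele-frequency vector per locus, and a Gibbs sweep alternates between
#' sampling the cluster of origin of every observed allele copy, the
#' cluster allele frequencies, and the individual Q rows.  This
#' implementation uses independent Dirichlet(\code{lambda}) allele
#' frequencies per cluster (not the correlated-frequency prior) and a
#' fixed admixture parameter \code{alpha}.  Missing allele copies are
#' skipped throughout (ignorable missingness).
#'
#' @param x an \code{SSRGenotypes} object; no locus may be fully untyped.
#' @param K number of clusters (>= 1, at most the number of accessions).
#' @param burnin,mcmc Gibbs sweeps to discard / retain (defaults 2000 and
#'   8000: desk-scale runs that recover strong structure; raise both for
#'   production panels).
#' @param alpha Dirichlet admixture parameter (default 1).
#' @param lambda Dirichlet allele-frequency prior (default 1).
#' @param seed integer seed; identical seed + config gives bit-identical
#'   results.
#' @return a \code{StructureRun}: list with \code{Q} (accessions x K
#'   posterior-mean membership, rows summing to 1), \code{P_hat}
#'   (per-locus posterior-mean cluster allele frequencies),
#'   \code{lnL_trace} (data log-likelihood per sweep, burn-in included),
#'   \code{lnP} (estimated ln P(X|K), see \code{\link{estimateLnP}}) and
#'   \code{config}.
#' @export
runGibbs <- function(x, K, burnin = 2000, mcmc = 8000, alpha = 1,
                     lambda = 1, seed = NULL) {
    stopifnot(K >= 1, burnin > 0, mcmc > 0, alpha > 0, lambda > 0)
    if (K > ncol(x)) stop("K exceeds the number of accessions")
    enc <- .encodeAlleles(x)
    if (any(colSums(enc$a1 > 0) == 0L))
        stop("some locus is fully untyped")
    if (!is.null(seed)) {
        old <- .saveSeed(); on.exit(.restoreSeed(old))
        set.seed(seed)
    }
    fit <- .gibbs_admixture(enc$a1, enc$a2, enc$n_alleles, as.integer(K),
                            as.integer(burnin), as.integer(mcmc),
                            alpha, lambda)
    rownames(fit$Q) <- accessionIds(x)
    names(fit$P_hat) <- lociIds(x)
    run <- structure(list(
        Q = fit$Q, P_hat = fit$P_hat, lnL_trace = as.numeric(fit$lnL_trace),
        config = list(K = K, burnin = burnin, mcmc = mcmc, alpha = alpha,
                      lambda = lambda, seed = seed)),
        class = "StructureRun")
    run$lnP <- estimateLnP(run)
    run
}

#' @export
print.StructureRun <- function(x, ...) {
    cat("StructureRun: K =", x$config$K, "|", nrow(x$Q), "accessions |",
        "burnin", x$config$burnin, "+ mcmc", x$config$mcmc, "sweeps\n")
    cat("  ln P(X|K) =", format(x$lnP, digits = 8), "\n")
    invisible(x)
}

# integer allele-index encoding: n x L matrices, 0 = missing
.encodeAlleles <- function(x) {
    a1 <- t(SummarizedExperiment::assay(x, "allele1"))
    a2 <- t(SummarizedExperiment::assay(x, "allele2"))
    L <- ncol(a1)
    e1 <- e2 <- matrix(0L, nrow(a1), L)
    n_alleles <- integer(L)
    levels <- vector("list", L)
    for (l in seq_len(L)) {
        lv <- sort(unique(c(a1[, l], a2[, l])))
        lv <- lv[!is.na(lv)]
        levels[[l]] <- lv
        n_alleles[l] <- length(lv)
        m1 <- match(a1[, l], lv); m2 <- match(a2[, l], lv)
        e1[, l] <- ifelse(is.na(m1), 0L, m1)
        e2[, l] <- ifelse(is.na(m2), 0L, m2)
    }
    list(a1 = e1, a2 = e2, n_alleles = n_alleles, levels = levels)
}

#' Estimate ln P(X|K) from the likelihood trace
#'
#' The standard harmonic-style estimator used for model choice in the
#' STRUCTURE family: \eqn{\widehat{\ln P}(X|K) = \bar{L} - s^2_L / 2}
#' where \eqn{\bar{L}} and \eqn{s^2_L} are the mean and sample variance of
#' the post-burn-in data log-likelihood trace.
#'
#' @param run a \code{StructureRun}, or a numeric trace (then taken as
#'   already post-burn-in).
#' @return the estimate (finite scalar).
#' @export
estimateLnP <- function(run) {
    if (inherits(run, "StructureRun")) {
        trace <- run$lnL_trace[-seq_len(run$config$burnin)]
        if (length(trace) < 10L)
            stop("need at least 10 retained sweeps to estimate ln P(X|K)")
    } else {
        trace <- as.numeric(run)
        if (length(trace) < 1L) stop("empty trace")
    }
    v <- if (length(trace) > 1L) stats::var(trace) else 0
    mean(trace) - v / 2
}

#' Align replicate Q matrices across label switching
#'
#' Cluster labels are arbitrary, so independent replicate runs of the same
#' K come back with permuted columns.  Taking the first run as reference,
#' each subsequent run's columns are permuted to maximize the summed
#' column-wise agreement (dot product of membership columns); the optimum
#' is found by exhaustive search over permutations for K <= 8 and by a
#' greedy assignment beyond.  The consensus is the element-wise mean of
#' the aligned matrices with rows renormalized.
#'
#' @param runs list of \code{StructureRun}s (or bare Q matrices), all with
#'   the same K and accession order.
#' @return list with \code{aligned} (list of permuted Q matrices),
#'   \code{permutations} and \code{consensus}.
#' @export
alignReplicates <- function(runs) {
    Qs <- lapply(runs, function(r)
        if (inherits(r, "StructureRun")) r$Q else as.matrix(r))
    K <- unique(vapply(Qs, ncol, integer(1)))
    if (length(K) != 1L) stop("runs have mixed K")
    ref <- Qs[[1L]]
    perms <- vector("list", length(Qs))
    perms[[1L]] <- seq_len(K)
    aligned <- Qs
    for (r in seq_along(Qs)[-1L]) {
        score <- crossprod(ref, Qs[[r]])     # K x K column agreement
        perm <- .bestPermutation(score)
        perms[[r]] <- perm
        aligned[[r]] <- Qs[[r]][, perm, drop = FALSE]
    }
    cons <- Reduce(`+`, aligned) / length(aligned)
    cons <- cons / rowSums(cons)
    list(aligned = aligned, permutations = perms, consensus = cons)
}

# permutation perm maximizing sum_k score[k, perm[k]]
.bestPermutation <- function(score) {
    K <- nrow(score)
    if (K <= 8L) {
        perms <- .allPerms(K)
        vals <- vapply(perms, function(p)
            sum(score[cbind(seq_len(K), p)]), numeric(1))
        perms[[which.max(vals)]]
    } else {
        perm <- integer(K)
        used <- logical(K)
        for (k in order(-apply(score, 1, max))) {
            j <- order(-score[k, ])
            j <- j[!used[j]][1L]
            perm[k] <- j
            used[j] <- TRUE
        }
        perm
    }
}

.allPerms <- function(K) {
    if (K == 1L) return(list(1L))
    out <- list()
    for (p in .allPerms(K - 1L))
        for (pos in seq_len(K))
            out[[length(out) + 1L]] <- append(p, K, after = pos - 1L)
    out
}

#' Threshold-based cluster assignment
#'
#' @param Q consensus membership matrix (rows sum to 1).
#' @param threshold membership coefficient required for assignment, in
#'   (0.5, 1\]; default 0.80.
#' @return data.frame with \code{accession}, \code{cluster} (integer, or
#'   \code{NA} for admixed), \code{max_q} and \code{admixed} flag.
#' @export
assignMembership <- function(Q, threshold = 0.80) {
    stopifnot(threshold > 0.5, threshold <= 1)
    mx <- apply(Q, 1L, max)
    cl <- apply(Q, 1L, which.max)
    admixed <- mx < threshold
    data.frame(accession = if (is.null(rownames(Q)))
                   as.character(seq_len(nrow(Q))) else rownames(Q),
               cluster = ifelse(admixed, NA_integer_, cl),
               max_q = mx, admixed = admixed,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Scan K with replicate runs
#'
#' Convenience driver: runs \code{\link{runGibbs}} for every K in
#' \code{k_range} with \code{reps} replicates (seeds derived
#' deterministically from \code{seed}), returning the lnP map consumed by
#' \code{\link{evannoTable}} and the per-K runs.
#'
#' @inheritParams runGibbs
#' @param k_range integer vector of K values (e.g. \code{1:6}).
#' @param reps replicates per K (>= 2 for Evanno sd; default 3).
#' @return list with \code{lnP} (named list K -> numeric vector) and
#'   \code{runs} (nested list).
#' @export
structureScan <- function(x, k_range = 1:6, reps = 3, burnin = 2000,
                          mcmc = 8000, alpha = 1, lambda = 1, seed = 1) {
    stopifnot(reps >= 1)
    lnP <- list(); runs <- list()
    for (K in k_range) {
        rr <- lapply(seq_len(reps), function(r)
            runGibbs(x, K, burnin = burnin, mcmc = mcmc, alpha = alpha,
                     lambda = lambda,
                     seed = (seed * 1009L + K * 101L + r) %% .Machine$integer.max))
        runs[[as.character(K)]] <- rr
        lnP[[as.character(K)]] <- vapply(rr, function(z) z$lnP, numeric(1))
    }
    list(lnP = lnP, runs = runs)
}
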