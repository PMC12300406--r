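#' Evanno delta-K table
#'
#' Summarises replicate ln P(X|K) estimates over consecutive K:
#' per-K mean and sample standard deviation, the first difference
#' \eqn{L'(K) = \bar{L}(K) - \bar{L}(K-1)}, the absolute second difference
#' \eqn{|L''(K)| = |L'(K+1) - L'(K)|}, and
#' \eqn{\Delta K = |L''(K)| / sd(K)}.  Delta-K is defined only for
#' interior K with positive sd; interior K with sd = 0 are flagged.
#'
#' @param lnP named list mapping K (as names, consecutive integers, at
#'   least three values) to numeric vectors of replicate ln P(X|K)
#'   estimates (at least two replicates each).
#' @return data.frame with columns \code{K, reps, mean_LnP, sd_LnP, LnP1,
#'   LnP2, deltaK, sd_zero}.
#' @export
evannoTable <- function(lnP) {
    ks <- sort(as.integer(names(lnP)))
    if (length(ks) < 3L) stop("need at least 3 consecutive K values")
    if (any(diff(ks) != 1L)) stop("K values must be consecutive")
    if (any(vapply(lnP, length, integer(1)) < 2L))
        stop("need at least 2 replicates per K for the sd")
    m <- vapply(as.character(ks), function(k) mean(lnP[[k]]), numeric(1))
    s <- vapply(as.character(ks), function(k) stats::sd(lnP[[k]]), numeric(1))
    nk <- length(ks)
    lnp1 <- c(NA, diff(m))                       # mean(K) - mean(K-1)
    lnp2 <- c(NA, abs(diff(lnp1[-1L])), NA)      # |LnP1(K+1) - LnP1(K)|
    dk <- rep(NA_real_, nk)
    interior <- seq(2L, nk - 1L)
    sd_zero <- rep(FALSE, nk)
    for (i in interior) {
        if (s[i] > 0) dk[i] <- lnp2[i] / s[i]
        else sd_zero[i] <- TRUE
    }
    if (any(sd_zero))
        warning("sd = 0 at interior K: ", paste(ks[sd_zero], collapse = ", "),
                "; deltaK undefined there")
    data.frame(K = ks, reps = vapply(lnP[as.character(ks)], length, integer(1)),
               mean_LnP = m, sd_LnP = s, LnP1 = lnp1, LnP2 = lnp2,
               deltaK = dk, sd_zero = sd_zero, row.names = NULL)
}

#' Select K by the Evanno criterion
#'
#' Returns the interior K maximizing delta-K, ties broken toward the
#' smaller K.  The boundary values (K = min, K = max) are never
#' selectable because delta-K is undefined there; inspect
#' \code{mean_LnP} when no delta-K is defined.
#'
#' @param table an Evanno table from \code{\link{evannoTable}}.
#' @return the selected K (integer).
#' @export
selectK <- function(table) {
    ok <- !is.na(table$deltaK)
    if (!any(ok))
        stop("no defined deltaK; inspect mean_LnP for a plateau")
    cand <- table[ok, ]
    cand <- cand[order(-cand$deltaK, cand$K), ]
    as.integer(cand$K[1L])
}
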