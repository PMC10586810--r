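# Nonparametric group inference: sign-permutation tests with a mean/SD
# statistic, Benjamini-Hochberg FDR over time points, and percentile
# bootstrap confidence intervals for peak latencies.

#' Sign-permutation test over participants, per time point
#'
#' The observed statistic at each time point is the across-participant
#' mean divided by the across-participant SD. The null distribution is
#' built by randomly multiplying each participant's whole time course by
#' +1 or -1 (one sign pattern per permutation, shared across time points,
#' preserving temporal dependence). Sampled p-values use the add-one
#' convention \eqn{p = (1 + \#\{null \ge obs\}) / (1 + n_{perm})} (right
#' tail; mirrored for the left tail, doubled minimum for two-tailed).
#' With \code{n_perm = NULL} all \eqn{2^P} sign patterns are enumerated
#' and the p-value is the exact rank \eqn{\#\{null \ge obs\} / 2^P}.
#'
#' @param x participant x time matrix of effect values (a vector is
#'   treated as one time point).
#' @param n_perm number of random sign patterns, or \code{NULL} for
#'   exhaustive enumeration (at most 20 participants).
#' @param tail \code{"right"}, \code{"left"} or \code{"two"}.
#' @param seed optional integer seed for the sign patterns.
#' @return Numeric vector of raw p-values, one per time point. Time points
#'   with zero across-participant SD get p = 1.
#' @export
signPermutationTest <- function(x, n_perm = 10000,
                                tail = c("right", "left", "two"),
                                seed = NULL) {
    tail <- match.arg(tail)
    if (is.vector(x)) x <- matrix(x, ncol = 1L)
    P <- nrow(x); T <- ncol(x)
    if (P < 2) stop("need at least 2 participants")
    if (!is.null(n_perm) && n_perm < 1) stop("n_perm must be at least 1")
    mu <- colMeans(x)
    sdv <- apply(x, 2L, sd)
    ok <- sdv > 0
    obs <- ifelse(ok, mu / sdv, NA_real_)

    if (is.null(n_perm)) {
        if (P > 20) stop("exhaustive enumeration is limited to 20 participants")
        n_all <- 2L^P
        signs <- as.matrix(expand.grid(rep(list(c(1, -1)), P)))
    } else {
        signs <- withSeed(seed,
            matrix(sample(c(1, -1), n_perm * P, replace = TRUE),
                   n_perm, P))
        n_all <- n_perm
    }
    M <- (signs %*% x) / P                       # n_all x T permuted means
    ssq <- colSums(x^2)                          # invariant under sign flips
    V <- sweep(-(M^2) * P, 2L, ssq, "+") / (P - 1)
    V[V < 0] <- 0
    Stat <- M / sqrt(V / P) / sqrt(P)            # = perm mean / perm SD
    p <- rep(1, T)
    eps <- 1e-12
    for (t in seq_len(T)) {
        if (!ok[t]) next
        null_t <- Stat[, t]
        null_t[!is.finite(null_t)] <- 0
        if (is.null(n_perm)) {
            pr <- sum(null_t >= obs[t] - eps) / n_all
            pl <- sum(null_t <= obs[t] + eps) / n_all
        } else {
            pr <- (1 + sum(null_t >= obs[t] - eps)) / (1 + n_all)
            pl <- (1 + sum(null_t <= obs[t] + eps)) / (1 + n_all)
        }
        p[t] <- switch(tail, right = pr, left = pl,
                       two = min(1, 2 * min(pr, pl)))
    }
    p
}

#' Benjamini-Hochberg FDR adjustment and significance mask
#'
#' Standard step-up adjusted p-values (monotone, capped at 1) with the
#' significance mask \code{p_adj <= alpha}.
#'
#' @param p_raw vector of raw p-values in (0, 1].
#' @param alpha FDR level (e.g. .01 for decoding, .05 elsewhere).
#' @return A list with \code{p_adj} and logical \code{mask}; empty inputs
#'   give empty results.
#' @export
bhFDR <- function(p_raw, alpha = 0.05) {
    if (!length(p_raw)) return(list(p_adj = numeric(0), mask = logical(0)))
    if (any(p_raw <= 0 | p_raw > 1 | is.na(p_raw)))
        stop("p-values must lie in (0, 1]")
    p_adj <- p.adjust(p_raw, method = "BH")
    list(p_adj = p_adj, mask = p_adj <= alpha)
}

#' Significance time course: permutation test plus FDR control
#'
#' Convenience wrapper chaining [signPermutationTest()] and [bhFDR()].
#'
#' @inheritParams signPermutationTest
#' @param alpha FDR level.
#' @param times optional bin latencies recorded in the output.
#' @return A list of class \code{"SigTimecourse"}: \code{p_raw},
#'   \code{p_adj}, \code{mask}, \code{tail}, \code{alpha}, \code{times}.
#' @export
sigTimecourse <- function(x, n_perm = 10000, tail = "right", alpha = 0.05,
                          seed = NULL, times = NULL) {
    p_raw <- signPermutationTest(x, n_perm = n_perm, tail = tail, seed = seed)
    adj <- bhFDR(p_raw, alpha)
    structure(list(p_raw = p_raw, p_adj = adj$p_adj, mask = adj$mask,
                   tail = tail, alpha = alpha,
                   times = if (is.null(times)) seq_along(p_raw) else times),
              class = "SigTimecourse")
}

#' @export
print.SigTimecourse <- function(x, ...) {
    cat(sprintf("SigTimecourse: %d time points, %s-tailed, alpha = %g; %d significant\n",
                length(x$p_raw), x$tail, x$alpha, sum(x$mask)))
    invisible(x)
}

#' Bootstrap confidence interval for a peak latency
#'
#' Resamples participants with replacement; each resample's group-mean
#' time course contributes the latency of its maximum (or minimum). The
#' CI is the 2.5/97.5 percentile of that distribution; the point estimate
#' comes from the full sample. Ties in the extremum go to the earliest
#' latency.
#'
#' @param x participant x time matrix.
#' @param times bin latencies in ms.
#' @param n_boot number of bootstrap resamples.
#' @param mode \code{"max"} (e.g. decoding peaks) or \code{"min"} (e.g.
#'   the most negative brain-behavior correlation).
#' @param level confidence level.
#' @param seed optional integer seed.
#' @return A list of class \code{"PeakCI"}: \code{peak_latency},
#'   \code{peak_value}, \code{ci}, \code{n_boot}, \code{boot_latencies}.
#' @export
bootstrapPeakCI <- function(x, times = seq_len(ncol(x)), n_boot = 1000,
                            mode = c("max", "min"), level = 0.95,
                            seed = NULL) {
    mode <- match.arg(mode)
    if (nrow(x) < 2) stop("need at least 2 participants")
    pick <- if (mode == "max") which.max else which.min
    g <- colMeans(x)
    peak_idx <- pick(g)                          # earliest on ties
    boot <- withSeed(seed, {
        P <- nrow(x)
        vapply(seq_len(n_boot), function(b) {
            m <- colMeans(x[sample.int(P, P, replace = TRUE), ,
                            drop = FALSE])
            times[pick(m)]
        }, numeric(1))
    })
    a <- (1 - level) / 2
    structure(list(peak_latency = times[peak_idx], peak_value = g[peak_idx],
                   ci = as.numeric(quantile(boot, c(a, 1 - a))),
                   n_boot = n_boot, boot_latencies = boot),
              class = "PeakCI")
}

#' @export
print.PeakCI <- function(x, ...) {
    cat(sprintf("PeakCI: peak %.3f at %g ms, 95%% CI [%g, %g] (%d resamples)\n",
                x$peak_value, x$peak_latency, x$ci[1L], x$ci[2L], x$n_boot))
    invisible(x)
}

#' Binomial chance band
#'
#' The central \code{level} band of the mean of \code{n} fair Bernoulli
#' outcomes, in percent: the range a chance-level decoding accuracy is
#' expected to stay within.
#'
#' @param n number of independent predictions.
#' @param p chance probability (0.5 for binary decoding).
#' @param level coverage level.
#' @return Two-element vector (low, high) in percent.
#' @export
binomialBand <- function(n, p = 0.5, level = 0.95) {
    a <- (1 - level) / 2
    100 * stats::qbinom(c(a, 1 - a), n, p) / n
}
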