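# Offline preprocessing: baseline correction, bin-average downsampling,
# multivariate noise normalization (whitening), correct-trial filtering.
# Acquisition-side steps (online filtering, artifact rejection) are out of
# scope; synthetic inputs are generated clean instead.

#' Baseline-correct an EpochSet
#'
#' Subtracts, per trial and channel, the mean amplitude over the given
#' latency window (typically the prestimulus period).
#'
#' @param e an [EpochSet-class].
#' @param window two-element ms window; must overlap the epoch's times.
#' @return The corrected [EpochSet-class] (same shape).
#' @export
baselineCorrect <- function(e, window) {
    idx <- which(e@times >= window[1L] & e@times <= window[2L])
    if (!length(idx))
        stop("baseline window [", window[1L], ", ", window[2L],
             "] contains no time points")
    X <- e@data
    nB <- length(idx)
    bl <- X[, , idx[1L]]
    if (nB > 1L) {
        for (t in idx[-1L]) bl <- bl + X[, , t]
        bl <- bl / nB
    }
    e@data <- X - as.vector(bl)   # recycles (trial, channel) over time
    e
}

#' Downsample an EpochSet by bin averaging
#'
#' Replaces consecutive non-overlapping groups of \code{factor} samples by
#' their mean; a trailing remainder shorter than \code{factor} is dropped.
#' New bin latencies are the group centers.
#'
#' @param e an [EpochSet-class].
#' @param factor number of consecutive samples per output bin.
#' @return The downsampled [EpochSet-class].
#' @export
downsampleBins <- function(e, factor) {
    factor <- as.integer(factor)
    if (factor < 1) stop("factor must be at least 1")
    T <- nTimepoints(e)
    if (factor > T) stop("factor (", factor, ") exceeds the epoch length (",
                         T, ")")
    if (factor == 1L) return(e)
    n_out <- T %/% factor
    keep <- n_out * factor
    d <- dim(e@data)
    M <- matrix(e@data[, , seq_len(keep)], d[1L] * d[2L], keep)
    G <- matrix(0, keep, n_out)
    G[cbind(seq_len(keep), rep(seq_len(n_out), each = factor))] <- 1 / factor
    out <- array(M %*% G, c(d[1L], d[2L], n_out))
    times <- colMeans(matrix(e@times[seq_len(keep)], factor, n_out))
    new("EpochSet", data = out, times = as.numeric(times), trials = e@trials,
        channels = e@channels, metadata = e@metadata)
}

# Ledoit-Wolf-style shrinkage covariance: convex combination of the sample
# covariance with a scaled identity, with a data-driven weight.
shrinkageCovariance <- function(X, shrinkage = NULL) {
    n <- nrow(X); p <- ncol(X)
    Xc <- sweep(X, 2L, colMeans(X))
    S <- crossprod(Xc) / n
    m <- sum(diag(S)) / p
    d2 <- sum((S - diag(m, p))^2) / p
    if (is.null(shrinkage)) {
        r2 <- rowSums(Xc^2)
        t1 <- sum(r2^2)
        t2 <- sum((Xc %*% S) * Xc)
        b2bar <- (t1 - 2 * t2 + n * sum(S^2)) / n^2 / p
        b2 <- min(b2bar, d2)
        rho <- if (d2 > 0) b2 / d2 else 1
    } else rho <- shrinkage
    list(sigma = rho * diag(m, p) + (1 - rho) * S, shrinkage = rho)
}

# Unique symmetric PSD inverse square root via eigendecomposition with an
# eigenvalue floor of 1e-10 * max eigenvalue.
invSqrtm <- function(S, advise = TRUE) {
    eg <- eigen(S, symmetric = TRUE)
    floor_ev <- 1e-10 * max(eg$values)
    if (min(eg$values) <= floor_ev) {
        if (advise)
            stop("covariance is rank-deficient; use shrinkage ",
                 "regularization (shrinkage = NULL for the data-driven ",
                 "weight) before inverting")
        eg$values <- pmax(eg$values, floor_ev)
    }
    eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
}

#' Fit a multivariate noise normalization (whitening) operator
#'
#' Estimates the channel covariance from all trials pooled over the entire
#' epoch (or a restricted window), regularizes it by Ledoit-Wolf-style
#' shrinkage toward a scaled identity, and returns its unique symmetric
#' positive-definite inverse square root \eqn{\Sigma^{-1/2}}.
#'
#' @param e an [EpochSet-class]; fit one operator per participant (see
#'   [noiseNormalize()] for the per-participant convenience wrapper).
#' @param window optional ms window to estimate from; default the entire
#'   epoch.
#' @param shrinkage shrinkage weight in \eqn{[0, 1]}; \code{NULL} (default)
#'   uses the data-driven Ledoit-Wolf weight. \code{0} disables
#'   regularization and fails on rank-deficient covariance.
#' @return A [WhitenOperator-class].
#' @export
fitWhitener <- function(e, window = NULL, shrinkage = NULL) {
    if (is.null(window)) window <- range(e@times)
    idx <- which(e@times >= window[1L] & e@times <= window[2L])
    if (!length(idx)) stop("window contains no time points")
    d <- dim(e@data)
    X <- matrix(aperm(e@data[, , idx, drop = FALSE], c(1L, 3L, 2L)),
                d[1L] * length(idx), d[2L])
    if (nrow(X) <= ncol(X))
        stop("need more pooled samples (trials x time points) than channels")
    sc <- shrinkageCovariance(X, shrinkage)
    W <- invSqrtm(sc$sigma)
    W <- (W + t(W)) / 2
    dimnames(W) <- list(e@channels, e@channels)
    new("WhitenOperator", matrix = W, sourceWindow = as.numeric(window),
        shrinkage = sc$shrinkage)
}

#' Apply a whitening operator to an EpochSet
#'
#' Multiplies each time-point channel pattern by \eqn{\Sigma^{-1/2}}.
#'
#' @param e an [EpochSet-class].
#' @param w a [WhitenOperator-class] fit on compatible channels.
#' @return The whitened [EpochSet-class].
#' @export
applyWhitener <- function(e, w) {
    d <- dim(e@data)
    if (nrow(w@matrix) != d[2L])
        stop("operator channel count does not match the data")
    M <- matrix(aperm(e@data, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
    e@data <- aperm(array(w@matrix %*% M, c(d[2L], d[1L], d[3L])),
                    c(2L, 1L, 3L))
    e
}

#' Per-participant multivariate noise normalization
#'
#' Fits one whitening operator per participant (pooled over conditions and
#' the entire epoch) and applies it to that participant's trials.
#'
#' @inheritParams fitWhitener
#' @return The whitened [EpochSet-class].
#' @export
noiseNormalize <- function(e, window = NULL, shrinkage = NULL) {
    X <- e@data
    for (p in unique(e@trials$participant)) {
        idx <- which(e@trials$participant == p)
        sub <- e[idx, , ]
        w <- fitWhitener(sub, window = window, shrinkage = shrinkage)
        d <- dim(sub@data)
        M <- matrix(aperm(sub@data, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
        X[idx, , ] <- aperm(array(w@matrix %*% M, c(d[2L], d[1L], d[3L])),
                            c(2L, 1L, 3L))
    }
    e@data <- X
    e
}

#' Keep only correct trials
#'
#' @param e an [EpochSet-class] whose metadata has a \code{correct} column.
#' @return The filtered [EpochSet-class]. Warns, naming the scenes, if any
#'   scene is left without trials.
#' @export
filterCorrect <- function(e) {
    keep <- which(e@trials$correct)
    lost <- setdiff(unique(e@trials$scene), unique(e@trials$scene[keep]))
    if (length(lost))
        warning("scene(s) left with zero correct trials: ",
                paste(lost, collapse = ", "))
    e[keep, , ]
}
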