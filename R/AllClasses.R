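#' @useDynLib scenedecode, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats cor median quantile rnorm sd p.adjust plogis var dist qbinom
#' @importFrom utils head read.table write.table
NULL

.EPOCHSET_SCHEMA <- "scenedecode-epochs-1"

#' EpochSet: epoched multichannel recordings with trial metadata
#'
#' The common currency of the pipeline: a trial x channel x time tensor of
#' amplitudes together with a per-trial metadata table. Times are in
#' milliseconds relative to stimulus onset at 0 and must be evenly spaced
#' and strictly increasing. The metadata table must carry columns
#' \code{participant}, \code{scene}, \code{category}, \code{task},
#' \code{correct} and \code{rt} (ms; may be \code{NA}); row \code{i} of the
#' table always describes slab \code{i} of the tensor, and every operation
#' in the package preserves that alignment.
#'
#' @slot data three-dimensional numeric array (trial, channel, time).
#' @slot times numeric vector of bin latencies in ms.
#' @slot trials data.frame of per-trial metadata.
#' @slot channels character vector of channel names.
#' @slot metadata list of provenance information (seed, config hash, ...).
#'
#' @seealso [EpochSet()] for construction, [genEpochs()] to simulate one.
#' @export
setClass("EpochSet",
    slots = c(data = "array", times = "numeric", trials = "data.frame",
              channels = "character", metadata = "list"))

setValidity("EpochSet", function(object) {
    d <- dim(object@data)
    msg <- character()
    if (length(d) != 3L)
        return("data must be a 3-d array (trial, channel, time)")
    if (d[1L] != nrow(object@trials))
        msg <- c(msg, "number of trials differs between data and metadata")
    if (d[2L] != length(object@channels))
        msg <- c(msg, "number of channels differs between data and names")
    if (d[3L] != length(object@times))
        msg <- c(msg, "number of time points differs between data and times")
    need <- c("participant", "scene", "category", "task", "correct", "rt")
    miss <- setdiff(need, names(object@trials))
    if (length(miss))
        msg <- c(msg, paste0("trial table lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (length(object@times) > 1L) {
        dt <- diff(object@times)
        if (any(dt <= 0))
            msg <- c(msg, "times must be strictly increasing")
        else if (max(dt) - min(dt) > 1e-8 * max(abs(dt)))
            msg <- c(msg, "times must be evenly spaced")
    }
    if ("rt" %in% names(object@trials)) {
        rt <- object@trials$rt
        if (any(!is.na(rt) & rt <= 0))
            msg <- c(msg, "reaction times must be positive where present")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an EpochSet
#'
#' @param data numeric array (trial, channel, time).
#' @param times bin latencies in ms relative to stimulus onset.
#' @param trials data.frame with columns participant, scene, category,
#'   task, correct, rt.
#' @param channels channel names; defaults to \code{ch01 ...}.
#' @param metadata optional provenance list.
#' @return An [EpochSet-class] object.
#' @examples
#' e <- EpochSet(array(rnorm(2 * 3 * 4), c(2, 3, 4)), times = c(0, 5, 10, 15),
#'     trials = data.frame(participant = 1, scene = c("s1", "s2"),
#'         category = c("natural", "man-made"), task = "categorization",
#'         correct = TRUE, rt = c(400, 450)))
#' nTrials(e)
#' @export
EpochSet <- function(data, times, trials, channels = NULL, metadata = list()) {
    if (is.null(channels)) {
        channels <- if (!is.null(dimnames(data)[[2L]])) dimnames(data)[[2L]]
                    else sprintf("ch%02d", seq_len(dim(data)[2L]))
    }
    new("EpochSet", data = data, times = as.numeric(times),
        trials = as.data.frame(trials), channels = as.character(channels),
        metadata = metadata)
}

#' WhitenOperator: multivariate noise normalization transform
#'
#' Holds the symmetric positive-definite channel x channel matrix
#' \eqn{\Sigma^{-1/2}} estimated from the pooled (shrinkage-regularized)
#' covariance of channel activations, plus the time window the covariance
#' was estimated from and the shrinkage weight used.
#'
#' @slot matrix channel x channel inverse square-root covariance.
#' @slot sourceWindow two-element ms window the covariance came from.
#' @slot shrinkage shrinkage weight toward the scaled identity.
#' @seealso [fitWhitener()], [applyWhitener()]
#' @export
setClass("WhitenOperator",
    slots = c(matrix = "matrix", sourceWindow = "numeric",
              shrinkage = "numeric"))

setValidity("WhitenOperator", function(object) {
    M <- object@matrix
    if (nrow(M) != ncol(M)) return("matrix must be square")
    if (max(abs(M - t(M))) > 1e-8 * max(abs(M)))
        return("matrix must be symmetric")
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return("matrix must be positive definite")
    TRUE
})

#' SceneDecisionValues: per-scene signed classifier decision values
#'
#' Output of category decoding: for each participant, scene and time point,
#' the signed distance (in unitless decision-value units) of the scene's
#' held-out test pattern from the fitted category boundary, averaged over
#' resampling repeats. Positive values lie on the side of the first
#' category level.
#'
#' @slot d numeric array (participant, scene, time).
#' @slot times bin latencies in ms.
#' @slot scenes scene identifiers.
#' @slot category per-scene category labels.
#' @slot participants participant identifiers.
#' @slot task task label the recordings came from.
#' @seealso [decodeCategory()], [dthDistances()]
#' @export
setClass("SceneDecisionValues",
    slots = c(d = "array", times = "numeric", scenes = "character",
              category = "character", participants = "character",
              task = "character"))

setValidity("SceneDecisionValues", function(object) {
    d <- dim(object@d)
    msg <- character()
    if (length(d) != 3L)
        return("d must be a 3-d array (participant, scene, time)")
    if (d[1L] != length(object@participants))
        msg <- c(msg, "participant dimension mismatch")
    if (d[2L] != length(object@scenes) || d[2L] != length(object@category))
        msg <- c(msg, "scene dimension mismatch")
    if (d[3L] != length(object@times))
        msg <- c(msg, "time dimension mismatch")
    if (any(!is.finite(object@d)))
        msg <- c(msg, "decision values must be finite")
    if (length(msg)) msg else TRUE
})

#' StageProbabilities: staged classifier probability trajectories
#'
#' Per-scene, per-stage class-probability vectors from a staged (anytime)
#' classifier, e.g. the readout of a recurrent network across time steps or
#' intermediate readouts of a feedforward network across layers. Each
#' (scene, stage) row is a probability simplex.
#'
#' @slot p numeric array (scene, stage, class).
#' @slot scenes scene identifiers.
#' @slot category per-scene category labels.
#' @slot classes class labels (the readout's categories).
#' @seealso [genStageProbs()], [entropyMatrix()], [extractNetworkRTs()]
#' @export
setClass("StageProbabilities",
    slots = c(p = "array", scenes = "character", category = "character",
              classes = "character"))

setValidity("StageProbabilities", function(object) {
    d <- dim(object@p)
    if (length(d) != 3L)
        return("p must be a 3-d array (scene, stage, class)")
    if (d[1L] != length(object@scenes) || d[1L] != length(object@category))
        return("scene dimension mismatch")
    if (d[3L] != length(object@classes))
        return("class dimension mismatch")
    if (any(object@p < -1e-9)) return("probabilities must be nonnegative")
    sums <- apply(object@p, c(1L, 2L), sum)
    if (any(abs(sums - 1) > 1e-6))
        return("each (scene, stage) row must sum to 1")
    TRUE
})

#' @param p array (scene, stage, class) of probabilities.
#' @param scenes scene identifiers.
#' @param category per-scene category labels.
#' @param classes class labels; defaults to \code{class1 ...}.
#' @rdname StageProbabilities-class
#' @export
StageProbabilities <- function(p, scenes = NULL, category = NULL,
                               classes = NULL) {
    if (is.null(scenes)) scenes <- sprintf("scene%02d", seq_len(dim(p)[1L]))
    if (is.null(category)) category <- rep(NA_character_, dim(p)[1L])
    if (is.null(classes)) classes <- sprintf("class%d", seq_len(dim(p)[3L]))
    new("StageProbabilities", p = p, scenes = as.character(scenes),
        category = as.character(category), classes = as.character(classes))
}
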