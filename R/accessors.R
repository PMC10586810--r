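#' Accessors for EpochSet
#'
#' @param x an [EpochSet-class].
#' @return \code{epochData} the (trial, channel, time) array;
#'   \code{epochTimes} bin latencies in ms; \code{trialInfo} the metadata
#'   table; \code{channelNames} channel labels; \code{nTrials},
#'   \code{nChannels}, \code{nTimepoints} the corresponding counts.
#' @name EpochSet-accessors
NULL

#' @rdname EpochSet-accessors
#' @export
epochData <- function(x) x@data

#' @rdname EpochSet-accessors
#' @export
epochTimes <- function(x) x@times

#' @rdname EpochSet-accessors
#' @export
trialInfo <- function(x) x@trials

#' @rdname EpochSet-accessors
#' @export
channelNames <- function(x) x@channels

#' @rdname EpochSet-accessors
#' @export
nTrials <- function(x) dim(x@data)[1L]

#' @rdname EpochSet-accessors
#' @export
nChannels <- function(x) dim(x@data)[2L]

#' @rdname EpochSet-accessors
#' @export
nTimepoints <- function(x) dim(x@data)[3L]

#' Subset an EpochSet
#'
#' \code{e[i, j, k]} selects trials \code{i}, channels \code{j} (index or
#' name) and time points \code{k}, keeping tensor and metadata aligned.
#'
#' @param x an [EpochSet-class].
#' @param i,j,k trial, channel and time indices (missing = all).
#' @param ... ignored.
#' @param drop ignored; dimensions are always kept.
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
    k <- tryCatch(..1, error = function(e) TRUE)   # empty/missing -> all
    if (missing(i)) i <- TRUE
    if (missing(j)) j <- TRUE
    if (is.character(j)) j <- match(j, x@channels)
    new("EpochSet",
        data = x@data[i, j, k, drop = FALSE],
        times = x@times[k],
        trials = x@trials[i, , drop = FALSE],
        channels = x@channels[j],
        metadata = x@metadata)
})

#' @export
setMethod("show", "EpochSet", function(object) {
    d <- dim(object@data)
    cat(sprintf("EpochSet: %d trials x %d channels x %d time points\n",
                d[1L], d[2L], d[3L]))
    if (d[3L] >= 1L)
        cat(sprintf("  times: %g .. %g ms (step %g ms)\n",
                    object@times[1L], object@times[d[3L]],
                    if (d[3L] > 1L) diff(object@times)[1L] else NA))
    cat(sprintf("  participants: %d | scenes: %d | tasks: %s\n",
                length(unique(object@trials$participant)),
                length(unique(object@trials$scene)),
                paste(unique(object@trials$task), collapse = ", ")))
    invisible(NULL)
})

#' @export
setMethod("show", "WhitenOperator", function(object) {
    cat(sprintf("WhitenOperator: %d x %d, shrinkage %.4f, window [%g, %g] ms\n",
                nrow(object@matrix), ncol(object@matrix), object@shrinkage,
                object@sourceWindow[1L], object@sourceWindow[2L]))
    invisible(NULL)
})

#' @export
setMethod("show", "SceneDecisionValues", function(object) {
    d <- dim(object@d)
    cat(sprintf(
        "SceneDecisionValues: %d participants x %d scenes x %d time points (task: %s)\n",
        d[1L], d[2L], d[3L], object@task))
    invisible(NULL)
})

#' @export
setMethod("show", "StageProbabilities", function(object) {
    d <- dim(object@p)
    cat(sprintf("StageProbabilities: %d scenes x %d stages x %d classes\n",
                d[1L], d[2L], d[3L]))
    invisible(NULL)
})

#' Whitening matrix of a WhitenOperator
#' @param w a [WhitenOperator-class].
#' @return The channel x channel \eqn{\Sigma^{-1/2}} matrix.
#' @export
whitenMatrix <- function(w) w@matrix

#' Decision-value array of a SceneDecisionValues object
#' @param x a [SceneDecisionValues-class].
#' @return Numeric array (participant, scene, time).
#' @export
decisionValues <- function(x) x@d
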