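# Channel-space searchlight: repeat decoding or the distance-to-hyperplane
# statistic on small channel neighborhoods (a channel and its k nearest
# neighbors) at a chosen latency, mapping where the information is
# carried.

#' Construct a channel layout
#'
#' @param names unique channel labels.
#' @param x,y 2-D channel coordinates (arbitrary units), unique per
#'   channel.
#' @return A data.frame of class \code{"ChannelLayout"} with columns
#'   channel, x, y.
#' @export
channelLayout <- function(names, x, y) {
    if (anyDuplicated(names)) stop("channel names must be unique")
    if (anyDuplicated(cbind(round(x, 12), round(y, 12))))
        stop("channel coordinates must be unique")
    structure(data.frame(channel = as.character(names), x = x, y = y),
              class = c("ChannelLayout", "data.frame"))
}

#' Nearest-neighbor map over a channel layout
#'
#' Euclidean k nearest channels per channel (self excluded); distance ties
#' are broken by channel index order, so the map is deterministic. The map
#' need not be symmetric.
#'
#' @param layout a [channelLayout()].
#' @param k neighbors per channel (default 4, so each searchlight patch is
#'   the channel plus its four nearest neighbors).
#' @return A named list mapping each channel to its k neighbor names, with
#'   attribute \code{k}.
#' @export
buildNeighborMap <- function(layout, k = 4) {
    n <- nrow(layout)
    if (k >= n) stop("k must be smaller than the number of channels")
    D <- as.matrix(dist(cbind(layout$x, layout$y)))
    nb <- lapply(seq_len(n), function(i) {
        ord <- order(D[i, ], seq_len(n))     # ties: lower index wins
        ord <- ord[ord != i]
        layout$channel[ord[seq_len(k)]]
    })
    names(nb) <- layout$channel
    attr(nb, "k") <- k
    nb
}

#' Channel searchlight map of a decoding or brain-behavior metric
#'
#' For every channel, restricts the patterns to the channel plus its
#' neighbors and runs the named analysis at a single latency; the
#' per-participant values are then group-averaged into a topographic map.
#'
#' @param e an [EpochSet-class].
#' @param nbmap a [buildNeighborMap()] over this EpochSet's channels.
#' @param latency ms; the nearest bin within the epoch is used.
#' @param metric \code{"identity"} (pairwise scene decoding),
#'   \code{"category"} (category decoding accuracy) or \code{"dth"}
#'   (distance-to-RT Spearman correlation).
#' @param rt RT table; required iff \code{metric = "dth"}.
#' @param repeats,group_size,cost decoding parameters (see
#'   [decodeIdentity()], [decodeCategory()]).
#' @param subset scene subset for the dth metric.
#' @param seed master seed; each channel's analysis uses the same stream,
#'   so a full-scalp patch reproduces the whole-pattern analysis.
#' @return A list of class \code{"SearchlightMap"}: \code{value} (named
#'   group-mean per channel), \code{per_participant} (participant x
#'   channel), \code{latency}, \code{metric}.
#' @export
searchlightMap <- function(e, nbmap, latency,
                           metric = c("category", "identity", "dth"),
                           rt = NULL, repeats = 20,
                           group_size = if (metric == "identity") 4 else 20,
                           cost = 1, subset = "all", seed = NULL) {
    metric <- match.arg(metric)
    if (metric == "dth" && is.null(rt))
        stop("the dth metric requires an RT table")
    if (latency < min(e@times) || latency > max(e@times))
        stop("latency outside the epoch time range")
    t_idx <- which.min(abs(e@times - latency))
    chans <- e@channels
    if (!all(names(nbmap) %in% chans))
        stop("neighbor map does not match the EpochSet channels")
    per <- NULL
    for (ch in chans) {
        patch <- c(ch, nbmap[[ch]])
        sub <- e[, patch, t_idx]
        val <- switch(metric,
            identity = decodeIdentity(sub, repeats = repeats,
                group_size = group_size, cost = cost,
                seed = seed)$accuracy[, 1L],
            category = decodeCategory(sub, repeats = repeats,
                train_group_size = group_size, cost = cost,
                seed = seed)$accuracy[, 1L],
            dth = {
                dec <- decodeCategory(sub, repeats = repeats,
                    train_group_size = group_size, cost = cost, seed = seed)
                dthCorrelate(dec$dvals, rt, subset = subset)$rho[, 1L]
            })
        per <- cbind(per, val)
    }
    colnames(per) <- chans
    structure(list(value = colMeans(per, na.rm = TRUE),
                   per_participant = per,
                   latency = e@times[t_idx], metric = metric),
              class = "SearchlightMap")
}

#' @export
print.SearchlightMap <- function(x, ...) {
    cat(sprintf("SearchlightMap (%s) at %g ms over %d channels; max %.3f at %s\n",
                x$metric, x$latency, length(x$value), max(x$value),
                names(x$value)[which.max(x$value)]))
    invisible(x)
}
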