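# Representational similarity analysis: correlation-distance RDMs from
# pseudotrial patterns per time point, model RDMs from feature matrices,
# Spearman correlation of vectorized upper triangles, and leave-one-out
# noise ceilings.

.checkRDM <- function(m, label = "RDM") {
    if (!is.matrix(m) || nrow(m) != ncol(m))
        stop(label, " must be a square matrix")
    invisible(m)
}

#' Time-resolved EEG RDM series from pseudotrial patterns
#'
#' Per participant and repeat: trial counts are equalized across scenes,
#' trials are averaged into pseudotrials of \code{group_size}, and at each
#' time point the correlation distance (1 - Pearson r over channels) is
#' computed between every cross-scene pair of pseudotrials. Distances are
#' averaged over pseudotrial pairs and repeats (arithmetic mean of
#' distances); the diagonal is zero.
#'
#' @param e an [EpochSet-class].
#' @param group_size trials averaged per pseudotrial (default 5).
#' @param repeats random-assignment repeats (default 100).
#' @param seed optional master seed.
#' @return A list of class \code{"RDMSeries"}: \code{rdm} array (scene,
#'   scene, time, participant), \code{times}, \code{scenes},
#'   \code{category}, \code{participants}.
#' @export
eegRDMSeries <- function(e, group_size = 5, repeats = 100, seed = NULL) {
    parts <- unique(e@trials$participant)
    scene_order <- unique(e@trials$scene)
    S <- length(scene_order)
    if (S < 2) stop("RDMs need at least 2 scenes")
    C <- nChannels(e); T <- nTimepoints(e)
    out <- array(0, c(S, S, T, length(parts)))
    for (pi in seq_along(parts)) {
        idx <- which(e@trials$participant == parts[pi])
        Xflat <- .flatten(e@data[idx, , , drop = FALSE])
        scene_p <- e@trials$scene[idx]
        acc <- array(0, c(S, S, T))
        for (r in seq_len(repeats)) {
            sel <- withSeed(
                if (is.null(seed)) NULL else substream(seed, pi, 300L + r), {
                ss <- .equalizeIndices(scene_p, scenes = scene_order)
                n_eq <- length(ss[[1L]])
                np <- n_eq %/% group_size
                if (np < 1)
                    stop("fewer than group_size = ", group_size,
                         " trials per scene")
                lapply(ss, function(s) {
                    s <- s[sample.int(length(s))]
                    lapply(seq_len(np), function(g)
                        s[(g - 1L) * group_size + seq_len(group_size)])
                })
            })
            np <- length(sel[[1L]])
            G <- matrix(0, S * np, length(idx))
            for (s in seq_len(S)) for (f in seq_len(np))
                G[(s - 1L) * np + f, sel[[s]][[f]]] <- 1 / group_size
            PT <- array(G %*% Xflat, c(S * np, C, T))
            B <- matrix(0, S, S * np)       # block-mean aggregator
            for (s in seq_len(S)) B[s, (s - 1L) * np + seq_len(np)] <- 1 / np
            for (t in seq_len(T)) {
                D <- 1 - cor(t(PT[, , t]))
                acc[, , t] <- acc[, , t] + B %*% D %*% t(B)
            }
        }
        acc <- acc / repeats
        for (t in seq_len(T)) {             # zero diagonal by definition
            m <- acc[, , t]; diag(m) <- 0
            acc[, , t] <- (m + t(m)) / 2
        }
        out[, , , pi] <- acc
    }
    cat_of <- e@trials$category[match(scene_order, e@trials$scene)]
    structure(list(rdm = out, times = e@times, scenes = scene_order,
                   category = cat_of, participants = as.character(parts)),
              class = "RDMSeries")
}

#' @export
print.RDMSeries <- function(x, ...) {
    d <- dim(x$rdm)
    cat(sprintf("RDMSeries: %d x %d conditions x %d time points x %d participants\n",
                d[1L], d[2L], d[3L], d[4L]))
    invisible(x)
}

#' Model RDM from a feature matrix
#'
#' Standardizes features across scenes (zero mean, unit variance per
#' feature; zero-variance features are dropped with a message) and
#' computes the pairwise correlation distance between scene feature
#' vectors.
#'
#' @param features scene x feature numeric matrix.
#' @return Square correlation-distance matrix with zero diagonal, scene
#'   names preserved.
#' @export
modelRDM <- function(features) {
    if (nrow(features) < 2) stop("need at least 2 scenes")
    v <- apply(features, 2L, var)
    zero <- v <= .Machine$double.eps
    if (all(zero)) stop("all features have zero variance across scenes")
    if (any(zero)) {
        message("dropping ", sum(zero), " zero-variance feature(s)")
        features <- features[, !zero, drop = FALSE]
    }
    Z <- scale(features)
    D <- 1 - cor(t(Z))
    diag(D) <- 0
    dimnames(D) <- list(rownames(features), rownames(features))
    D
}

#' Spearman correlation of two RDMs
#'
#' Correlates the vectorized strict upper triangles (no diagonal) with
#' average-rank tie handling.
#'
#' @param a,b square RDMs over the same conditions in the same order.
#' @return Spearman \eqn{\rho}.
#' @export
correlateRDMs <- function(a, b) {
    .checkRDM(a); .checkRDM(b)
    if (nrow(a) != nrow(b)) stop("RDMs have different sizes")
    ut <- upper.tri(a)
    cor(a[ut], b[ut], method = "spearman")
}

#' Time-resolved RSA between an RDM series and model RDMs
#'
#' Correlates each participant's RDM at each time point with each model
#' RDM (per layer and stage), restricted to a scene subset; per-layer
#' curves take the median over stages, then the mean over participants.
#'
#' @param series an [eegRDMSeries()] result.
#' @param models a list of model RDMs; each element needs attributes or
#'   list fields \code{rdm}, \code{layer}, \code{stage} (see
#'   [modelRDMSet()]).
#' @param subset \code{"all"}, \code{"A"} or \code{"B"} (categories in
#'   first-appearance order).
#' @return A list of class \code{"RsaTimecourse"}: \code{rho} (layer x
#'   time group means), \code{per_participant} (participant x time x
#'   layer), \code{peak_latency} per layer, \code{times}, \code{layers}.
#' @export
rsaTimecourse <- function(series, models, subset = "all") {
    keep <- .sceneSubset(series$category, subset)
    if (length(keep) < 3) stop("subset must contain at least 3 conditions")
    layers <- unique(vapply(models, function(m) m$layer, ""))
    P <- length(series$participants); T <- length(series$times)
    per <- array(NA_real_, c(P, T, length(layers)),
                 dimnames = list(NULL, NULL, layers))
    for (li in seq_along(layers)) {
        ms <- Filter(function(m) m$layer == layers[li], models)
        sub_models <- lapply(ms, function(m) {
            .checkRDM(m$rdm)
            if (nrow(m$rdm) != length(series$scenes))
                stop("model RDM size does not match the EEG conditions")
            m$rdm[keep, keep, drop = FALSE]
        })
        for (p in seq_len(P)) for (t in seq_len(T)) {
            eeg <- series$rdm[keep, keep, t, p]
            rhos <- vapply(sub_models, function(mr) {
                ut <- upper.tri(mr)
                suppressWarnings(cor(eeg[ut], mr[ut], method = "spearman"))
            }, numeric(1))
            per[p, t, li] <- median(rhos, na.rm = TRUE)
        }
    }
    grp <- apply(per, c(3L, 2L), mean, na.rm = TRUE)
    peak <- series$times[apply(grp, 1L, which.max)]
    names(peak) <- layers
    structure(list(rho = grp, per_participant = per,
                   peak_latency = peak, times = series$times,
                   layers = layers, subset = subset),
              class = "RsaTimecourse")
}

#' Bundle model RDMs with layer and stage labels
#'
#' @param rdms list of square RDMs.
#' @param layer layer label per RDM (e.g. early/mid/late).
#' @param stage stage index per RDM (1 for stageless models).
#' @return A list usable as the \code{models} argument of
#'   [rsaTimecourse()].
#' @export
modelRDMSet <- function(rdms, layer, stage = rep(1L, length(rdms))) {
    Map(function(r, l, s) list(rdm = r, layer = l, stage = s),
        rdms, layer, stage)
}

#' Noise ceiling of an RDM series
#'
#' Lower bound: mean over participants of the Spearman correlation of each
#' participant's RDM with the element-wise mean RDM of the remaining
#' participants. Upper bound: the same with the all-participant mean
#' (which includes the participant of interest).
#'
#' @param series an [eegRDMSeries()] result with at least 2 participants.
#' @return A list of class \code{"NoiseCeiling"}: \code{lower},
#'   \code{upper} (per time), \code{times}.
#' @export
noiseCeiling <- function(series) {
    P <- length(series$participants)
    if (P < 2) stop("the noise ceiling needs at least 2 participants")
    T <- length(series$times)
    lo <- hi <- matrix(NA_real_, P, T)
    total <- apply(series$rdm, c(1L, 2L, 3L), sum)
    allm <- total / P
    for (p in seq_len(P)) {
        own <- array(series$rdm[, , , p], dim(series$rdm)[1:3])
        loo <- (total - own) / (P - 1)
        for (t in seq_len(T)) {
            lo[p, t] <- correlateRDMs(own[, , t], loo[, , t])
            hi[p, t] <- correlateRDMs(own[, , t], allm[, , t])
        }
    }
    structure(list(lower = colMeans(lo), upper = colMeans(hi),
                   times = series$times),
              class = "NoiseCeiling")
}
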