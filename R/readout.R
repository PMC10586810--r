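# Entropy-threshold readout: convert staged classifier probability
# trajectories into integer "reaction times" (the first stage whose
# Shannon entropy falls to a criterion), select the criterion by
# leave-one-participant-out correlation with human RTs, and report
# human-model RT correlations.

#' Shannon entropy of probability simplexes
#'
#' \eqn{H = -\sum_i p_i \log p_i} with \eqn{0 \log 0 := 0}. The default
#' base is 2 (bits); note that entropy-threshold grids are base-dependent,
#' so the base is an explicit argument throughout.
#'
#' @param p a probability vector, or a matrix whose rows are simplexes.
#' @param base logarithm base (2 = bits, \code{exp(1)} = nats).
#' @return Entropy value(s); one per row for a matrix.
#' @export
shannonEntropy <- function(p, base = 2) {
    if (is.matrix(p)) return(apply(p, 1L, shannonEntropy, base = base))
    if (any(p < -1e-9)) stop("probabilities must be nonnegative")
    if (abs(sum(p) - 1) > 1e-6) stop("probabilities must sum to 1")
    p <- pmax(p, 0)
    nz <- p > 0
    -sum(p[nz] * log(p[nz], base = base))
}

#' Scene x stage entropy matrix of staged probabilities
#'
#' @param sp a [StageProbabilities-class].
#' @param base logarithm base.
#' @return Matrix (scene x stage) of Shannon entropies, scene names as row
#'   names.
#' @export
entropyMatrix <- function(sp, base = 2) {
    d <- dim(sp@p)
    H <- matrix(NA_real_, d[1L], d[2L], dimnames = list(sp@scenes, NULL))
    for (s in seq_len(d[1L])) for (k in seq_len(d[2L]))
        H[s, k] <- shannonEntropy(sp@p[s, k, ], base = base)
    H
}

#' Network reaction times from an entropy matrix
#'
#' For each scene, the first stage at which entropy reaches the threshold
#' ("reached" meaning \eqn{H \le} threshold, inclusive); if no stage
#' reaches it, the RT is S + 1.
#'
#' @param H scene x stage entropy matrix (see [entropyMatrix()]).
#' @param threshold positive entropy threshold.
#' @return Integer vector of RTs in \code{1..S+1}, named by scene, with
#'   attribute \code{threshold}.
#' @export
extractNetworkRTs <- function(H, threshold) {
    if (threshold <= 0) stop("threshold must be positive")
    S <- ncol(H)
    rt <- apply(H <= threshold, 1L, function(row) {
        hit <- which(row)
        if (length(hit)) hit[1L] else S + 1L
    })
    rt <- as.integer(rt)
    names(rt) <- rownames(H)
    attr(rt, "threshold") <- threshold
    rt
}

#' Leave-one-participant-out entropy-threshold selection
#'
#' For each fold (one held-out participant): network RTs are extracted at
#' each grid threshold and Pearson-correlated with the median human RTs
#' over the remaining participants; the argmax threshold is selected
#' (thresholds where the network RTs are constant are excluded; ties go to
#' the lowest threshold), and the held-out participant's RTs are
#' Pearson-correlated with the selected network RTs, for all scenes and
#' each category separately.
#'
#' @param H scene x stage entropy matrix; row names must match the RT
#'   table's scenes.
#' @param human RT table (participant, scene, rt, optionally category).
#' @param grid candidate thresholds; default 10 linearly spaced values
#'   over \eqn{[0.01, 0.1]}.
#' @param category optional per-scene category labels (taken from
#'   \code{human$category} when present) enabling the per-category
#'   correlations.
#' @return A list of class \code{"CvSelection"}: \code{grid},
#'   \code{folds} (data.frame: fold participant, selected threshold,
#'   held-out r for all/A/B), \code{mean_r} (named vector), \code{rts}
#'   (network RTs at the modal selected threshold), \code{threshold} (that
#'   threshold).
#' @export
selectThresholdCV <- function(H, human, grid = seq(0.01, 0.1, length.out = 10),
                              category = NULL) {
    if (!length(grid)) stop("the threshold grid is empty")
    parts <- unique(human$participant)
    if (length(parts) < 2) stop("need at least 2 participants")
    scenes <- rownames(H)
    if (is.null(scenes)) stop("H needs scene row names")
    if (is.null(category) && "category" %in% names(human))
        category <- human$category[match(scenes, human$scene)]
    rts_by_thr <- lapply(grid, function(th) extractNetworkRTs(H, th))
    sub_idx <- list(all = seq_along(scenes))
    if (!is.null(category)) {
        lv <- unique(category)
        sub_idx$A <- which(category == lv[1L])
        sub_idx$B <- which(category == lv[2L])
    }
    folds <- lapply(seq_along(parts), function(f) {
        held <- parts[f]
        med <- medianRTs(human[human$participant != held, , drop = FALSE])
        mrt <- med$median_rt[match(scenes, med$scene)]
        r_grid <- vapply(rts_by_thr, function(nrt) {
            if (length(unique(nrt)) == 1L) return(NA_real_)  # r undefined
            cor(as.numeric(nrt), mrt)
        }, numeric(1))
        if (all(is.na(r_grid)))
            stop("network RTs are constant at every grid threshold")
        sel <- which.max(r_grid)              # ties/NAs: lowest threshold
        own <- human[human$participant == held, , drop = FALSE]
        own_rt <- own$rt[match(scenes, own$scene)]
        nrt <- as.numeric(rts_by_thr[[sel]])
        r_held <- vapply(sub_idx, function(ix) {
            if (length(unique(nrt[ix])) == 1L ||
                length(unique(own_rt[ix])) == 1L) return(NA_real_)
            cor(nrt[ix], own_rt[ix])
        }, numeric(1))
        c(list(participant = held, threshold = grid[sel],
               r_grid_max = r_grid[sel]), as.list(r_held))
    })
    fold_df <- do.call(rbind, lapply(folds, function(x)
        as.data.frame(x, stringsAsFactors = FALSE)))
    mean_r <- colMeans(fold_df[, names(sub_idx), drop = FALSE], na.rm = TRUE)
    thr_tab <- table(fold_df$threshold)
    final_thr <- as.numeric(names(thr_tab)[which.max(thr_tab)])
    structure(list(grid = grid, folds = fold_df, mean_r = mean_r,
                   threshold = final_thr,
                   rts = extractNetworkRTs(H, final_thr)),
              class = "CvSelection")
}

#' @export
print.CvSelection <- function(x, ...) {
    cat(sprintf("CvSelection: %d folds, selected threshold %.3g\n",
                nrow(x$folds), x$threshold))
    cat("  mean held-out Pearson r:",
        paste(sprintf("%s = %.3f", names(x$mean_r), x$mean_r),
              collapse = ", "), "\n")
    invisible(x)
}

#' Map per-layer intermediate readouts onto stages
#'
#' Adapter for staged readouts trained after every \code{stride}-th layer
#' of a feedforward model: selects every \code{stride}-th layer's
#' probability vector and stacks them as stages 1..S, so the downstream
#' entropy readout (with never-reached value S + 1) applies unchanged.
#'
#' @param prob_list list of scene x class probability matrices, one per
#'   layer, in layer order.
#' @param stride take every \code{stride}-th layer (default 2).
#' @param scenes,category,classes labels passed to
#'   [StageProbabilities()].
#' @return A [StageProbabilities-class] with \code{floor(L / stride)}
#'   stages.
#' @export
stageAdapter <- function(prob_list, stride = 2, scenes = NULL,
                         category = NULL, classes = NULL) {
    L <- length(prob_list)
    pick <- seq(stride, L, by = stride)
    if (!length(pick)) stop("stride exceeds the number of layers")
    n_scene <- nrow(prob_list[[1L]])
    n_class <- ncol(prob_list[[1L]])
    p <- array(NA_real_, c(n_scene, length(pick), n_class))
    for (k in seq_along(pick)) {
        m <- prob_list[[pick[k]]]
        if (any(m < -1e-9) || any(abs(rowSums(m) - 1) > 1e-6))
            stop("layer ", pick[k], " rows are not probability simplexes")
        p[, k, ] <- m
    }
    StageProbabilities(p, scenes = scenes, category = category,
                       classes = classes)
}
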