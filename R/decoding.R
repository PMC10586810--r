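# Time-resolved decoding on pseudotrials with a linear max-margin
# classifier (L1-hinge linear SVM, fixed cost, trained per time point by
# dual coordinate descent in compiled code). Scene-identity decoding is
# pairwise with leave-one-pseudotrial-out; category decoding uses a
# half-split with scene-resolved test patterns so each scene yields one
# signed decision value per time point and repeat.

# Flatten one participant's tensor to (trials) x (channels*times).
.flatten <- function(X) {
    d <- dim(X)
    matrix(X, d[1L], d[2L] * d[3L])
}

# Random per-scene selection of n_eq trials each, using the current RNG.
.equalizeIndices <- function(scene, n_eq = NULL, scenes = unique(scene)) {
    counts <- vapply(scenes, function(s) sum(scene == s), integer(1))
    if (is.null(n_eq)) n_eq <- min(counts)
    if (n_eq == 0) stop("at least one scene has zero trials")
    lapply(scenes, function(s) {
        idx <- which(scene == s)
        idx[sample.int(length(idx), n_eq)]
    })
}

#' Equalize trial counts across scenes
#'
#' Randomly downsamples every scene to the per-participant minimum trial
#' count, so classifier training is not biased by unequal condition sizes.
#'
#' @param e an [EpochSet-class].
#' @param seed optional integer seed for the selection.
#' @return The downsampled [EpochSet-class].
#' @export
equalizeTrials <- function(e, seed = NULL) {
    withSeed(seed, {
        keep <- integer(0)
        for (p in unique(e@trials$participant)) {
            idx <- which(e@trials$participant == p)
            sel <- .equalizeIndices(e@trials$scene[idx])
            keep <- c(keep, sort(idx[unlist(sel)]))
        }
        e[keep, , ]
    })
}

#' Average trials into pseudotrials
#'
#' Randomly partitions the trials of each condition into groups of
#' \code{group_size} and replaces each group by its mean pattern; trials
#' left over after grouping are dropped. No trial contributes to more than
#' one pseudotrial.
#'
#' @param patterns trial x feature matrix.
#' @param labels condition label per trial.
#' @param group_size trials averaged per pseudotrial.
#' @param seed optional integer seed.
#' @return A list with \code{patterns} (pseudotrial x feature),
#'   \code{labels}, \code{group_size} and \code{assignment} (list of the
#'   trial indices behind each pseudotrial).
#' @export
makePseudotrials <- function(patterns, labels, group_size, seed = NULL) {
    withSeed(seed, {
        conds <- unique(labels)
        groups <- list()
        for (cond in conds) {
            idx <- which(labels == cond)
            if (length(idx) < group_size)
                stop("condition '", cond, "' has ", length(idx),
                     " trials, fewer than group_size = ", group_size)
            idx <- idx[sample.int(length(idx))]
            ng <- length(idx) %/% group_size
            for (g in seq_len(ng))
                groups[[length(groups) + 1L]] <- list(
                    cond = cond,
                    trials = idx[(g - 1L) * group_size + seq_len(group_size)])
        }
        pt <- do.call(rbind, lapply(groups, function(g)
            colMeans(patterns[g$trials, , drop = FALSE])))
        list(patterns = pt,
             labels = vapply(groups, function(g) g$cond, labels[1L]),
             group_size = group_size,
             assignment = lapply(groups, function(g) g$trials))
    })
}

.checkBinaryCategory <- function(category) {
    lv <- unique(category)
    if (length(lv) != 2L)
        stop("decoding requires exactly two categories, found: ",
             paste(lv, collapse = ", "))
    lv
}

#' Time-resolved scene-category decoding with scene-resolved test outputs
#'
#' For each participant, time point and resampling repeat: trial counts are
#' equalized across scenes, each scene's trials are split into halves, the
#' training halves are pooled within category and averaged into
#' pseudotrials of \code{train_group_size} trials, a linear SVM is fit on
#' the category labels, and the held-out half of every scene is averaged
#' into one test pattern whose correctness and signed decision value are
#' recorded. Repeats are aggregated by arithmetic mean. The positive
#' decision-value side is the first category in scene order; a decision
#' value of exactly zero is mapped to that category.
#'
#' @param e an [EpochSet-class] (one task; whitened/preprocessed upstream).
#' @param repeats number of random reselection repeats.
#' @param train_group_size trials averaged per training pseudotrial.
#' @param cost SVM cost parameter C.
#' @param seed optional master seed; per-participant x repeat streams are
#'   derived from it.
#' @return A list with \code{accuracy} (participant x time matrix, percent
#'   correct), \code{dvals} (a [SceneDecisionValues-class]),
#'   \code{scheme = "category"}, \code{task}, \code{times}.
#' @export
decodeCategory <- function(e, repeats = 100, train_group_size = 20,
                           cost = 1, seed = NULL) {
    parts <- unique(e@trials$participant)
    times <- e@times
    C <- nChannels(e); T <- nTimepoints(e)
    scene_order <- unique(e@trials$scene)
    cat_of <- e@trials$category[match(scene_order, e@trials$scene)]
    lv <- .checkBinaryCategory(cat_of)
    S <- length(scene_order)
    ypos <- lv[1L]

    acc <- matrix(0, length(parts), T,
                  dimnames = list(parts, NULL))
    dv <- array(0, c(length(parts), S, T))
    for (pi in seq_along(parts)) {
        idx <- which(e@trials$participant == parts[pi])
        Xflat <- .flatten(e@data[idx, , , drop = FALSE])
        scene_p <- e@trials$scene[idx]
        n_p <- length(idx)
        acc_p <- numeric(T); dv_p <- matrix(0, S, T)
        for (r in seq_len(repeats)) {
            res <- withSeed(
                if (is.null(seed)) NULL else substream(seed, pi, 100L + r), {
                sel <- .equalizeIndices(scene_p, scenes = scene_order)
                n_eq <- length(sel[[1L]])
                if (n_eq < 2)
                    stop("need at least 2 trials per scene to split halves")
                n_tr <- n_eq %/% 2L
                train_idx <- lapply(sel, function(s) s[seq_len(n_tr)])
                test_idx <- lapply(sel, function(s) s[(n_tr + 1L):n_eq])
                # category-pooled training pseudotrials
                rows <- list(); ylab <- integer(0)
                for (cat in lv) {
                    pool <- unlist(train_idx[cat_of == cat])
                    pool <- pool[sample.int(length(pool))]
                    np <- length(pool) %/% train_group_size
                    if (np < 1)
                        stop("too few training trials for pseudotrials of ",
                             train_group_size)
                    for (g in seq_len(np)) {
                        rows[[length(rows) + 1L]] <-
                            pool[(g - 1L) * train_group_size +
                                 seq_len(train_group_size)]
                        ylab <- c(ylab, if (cat == ypos) 1L else -1L)
                    }
                }
                list(rows = rows, ylab = ylab, test_idx = test_idx)
            })
            nr <- length(res$rows)
            G <- matrix(0, nr + S, n_p)
            for (g in seq_len(nr))
                G[g, res$rows[[g]]] <- 1 / length(res$rows[[g]])
            for (s in seq_len(S))
                G[nr + s, res$test_idx[[s]]] <- 1 / length(res$test_idx[[s]])
            A <- G %*% Xflat
            Xtr <- array(A[seq_len(nr), , drop = FALSE], c(nr, C, T))
            Xte <- array(A[nr + seq_len(S), , drop = FALSE], c(S, C, T))
            d_r <- .lsvm_decode_batch(Xtr, res$ylab, Xte, cost)
            pred_pos <- d_r >= 0
            truth_pos <- cat_of == ypos
            acc_p <- acc_p + colMeans(pred_pos == truth_pos)
            dv_p <- dv_p + d_r
        }
        acc[pi, ] <- 100 * acc_p / repeats
        dv[pi, , ] <- dv_p / repeats
    }
    task <- unique(e@trials$task)
    dvals <- new("SceneDecisionValues", d = dv, times = times,
                 scenes = scene_order, category = cat_of,
                 participants = as.character(parts),
                 task = paste(task, collapse = "+"))
    list(accuracy = acc, dvals = dvals, scheme = "category",
         task = paste(task, collapse = "+"), times = times)
}

#' Time-resolved pairwise scene-identity decoding
#'
#' For each participant, repeat and scene pair: trial counts are equalized
#' across scenes, each scene's trials are partitioned into pseudotrials of
#' \code{group_size}, and a linear SVM is trained leave-one-pseudotrial-out
#' (per fold, one pseudotrial of each scene is held out and tested).
#' Accuracy is averaged over folds, pairs and repeats.
#'
#' @param e an [EpochSet-class].
#' @param repeats number of random reselection repeats.
#' @param group_size trials averaged per pseudotrial.
#' @param cost SVM cost parameter C.
#' @param seed optional master seed.
#' @return A list with \code{accuracy} (participant x time, percent),
#'   \code{scheme = "identity"}, \code{task}, \code{times}.
#' @export
decodeIdentity <- function(e, repeats = 100, group_size = 4, cost = 1,
                           seed = NULL) {
    parts <- unique(e@trials$participant)
    C <- nChannels(e); T <- nTimepoints(e)
    scene_order <- unique(e@trials$scene)
    S <- length(scene_order)
    if (S < 2) stop("identity decoding needs at least 2 scenes")
    prs <- utils::combn(S, 2L)

    acc <- matrix(0, length(parts), T, dimnames = list(parts, NULL))
    for (pi in seq_along(parts)) {
        idx <- which(e@trials$participant == parts[pi])
        Xflat <- .flatten(e@data[idx, , , drop = FALSE])
        scene_p <- e@trials$scene[idx]
        acc_p <- numeric(T)
        for (r in seq_len(repeats)) {
            sel <- withSeed(
                if (is.null(seed)) NULL else substream(seed, pi, 200L + r), {
                ss <- .equalizeIndices(scene_p, scenes = scene_order)
                n_eq <- length(ss[[1L]])
                np <- n_eq %/% group_size
                if (np < 2)
                    stop("need at least 2 pseudotrials per scene; have ",
                         n_eq, " trials for group_size = ", group_size)
                lapply(ss, function(s) {
                    s <- s[sample.int(length(s))]
                    lapply(seq_len(np), function(g)
                        s[(g - 1L) * group_size + seq_len(group_size)])
                })
            })
            np <- length(sel[[1L]])
            # pseudotrial tensor, scene-major: row (s-1)*np + f
            G <- matrix(0, S * np, length(idx))
            for (s in seq_len(S)) for (f in seq_len(np))
                G[(s - 1L) * np + f, sel[[s]][[f]]] <- 1 / group_size
            PT <- array(G %*% Xflat, c(S * np, C, T))
            acc_r <- numeric(T)
            y <- rep(c(1L, -1L), each = np - 1L)
            for (pr in seq_len(ncol(prs))) {
                a <- prs[1L, pr]; b <- prs[2L, pr]
                ra <- (a - 1L) * np; rb <- (b - 1L) * np
                for (f in seq_len(np)) {
                    tr_rows <- c(ra + seq_len(np)[-f], rb + seq_len(np)[-f])
                    te_rows <- c(ra + f, rb + f)
                    d_r <- .lsvm_decode_batch(
                        PT[tr_rows, , , drop = FALSE], y,
                        PT[te_rows, , , drop = FALSE], cost)
                    acc_r <- acc_r + (d_r[1L, ] >= 0) + (d_r[2L, ] < 0)
                }
            }
            acc_p <- acc_p + acc_r / (2 * np * ncol(prs))
        }
        acc[pi, ] <- 100 * acc_p / repeats
    }
    task <- unique(e@trials$task)
    list(accuracy = acc, scheme = "identity",
         task = paste(task, collapse = "+"), times = e@times)
}
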