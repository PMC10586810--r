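# Distance-to-hyperplane statistic: rank-correlate per-scene neural
# boundary distances with per-scene reaction times, per participant and
# time point. A negative correlation (farther from the boundary = faster)
# indicates representations formatted for decision-making.

#' Distances to the category boundary from decision values
#'
#' The distance is the absolute decision value, regardless of whether the
#' scene was classified correctly. The signed-by-true-category variant is
#' available for sensitivity analysis.
#'
#' @param dv a [SceneDecisionValues-class].
#' @param signed if \code{TRUE}, return the decision value multiplied by
#'   the sign of the scene's true category (positive when the pattern lies
#'   on the correct side) instead of the absolute value.
#' @return Numeric array (participant, scene, time) of distances.
#' @export
dthDistances <- function(dv, signed = FALSE) {
    if (!signed) return(abs(dv@d))
    lv <- unique(dv@category)
    sgn <- ifelse(dv@category == lv[1L], 1, -1)
    sweep(dv@d, 2L, sgn, "*")
}

.sceneSubset <- function(category, subset) {
    lv <- unique(category)
    switch(subset,
           all = seq_along(category),
           A = which(category == lv[1L]),
           B = which(category == lv[2L]),
           stop("subset must be one of 'all', 'A', 'B'"))
}

#' Correlate boundary distances with reaction times over scenes
#'
#' For each participant and time point, the Spearman rank correlation
#' between the per-scene distances and the scene-level median reaction
#' times (median over participants), optionally restricted to one
#' category. Time points where either input is constant give \code{NA}.
#'
#' @param dist distance array (participant, scene, time) from
#'   [dthDistances()], or a [SceneDecisionValues-class] (absolute values
#'   are taken).
#' @param rt an RT table (columns participant, scene, rt) as from
#'   [genRTs()]; scene-level medians are computed internally.
#' @param scenes scene identifiers matching the second dimension of
#'   \code{dist} (taken from the decision values when those are passed).
#' @param category per-scene category labels (likewise).
#' @param subset \code{"all"}, \code{"A"} (first category) or \code{"B"}.
#' @param pairing two-element label (EEG task, RT task) recorded in the
#'   output; purely descriptive.
#' @param times bin latencies for the output.
#' @return A list of class \code{"DthTimecourse"}: \code{rho} (participant
#'   x time), \code{group} (mean over participants, \code{NA} dropped with
#'   counts in \code{n_used}), \code{times}, \code{pairing},
#'   \code{subset}.
#' @export
dthCorrelate <- function(dist, rt, scenes = NULL, category = NULL,
                         subset = "all",
                         pairing = c("categorization", "categorization"),
                         times = NULL) {
    if (is(dist, "SceneDecisionValues")) {
        scenes <- dist@scenes; category <- dist@category
        if (is.null(times)) times <- dist@times
        dist <- dthDistances(dist)
    }
    if (is.null(scenes))
        stop("scene identifiers are required alongside a raw distance array")
    med <- medianRTs(rt)
    missing_sc <- setdiff(scenes, med$scene)
    extra_sc <- setdiff(med$scene, scenes)
    if (length(missing_sc) || length(extra_sc))
        stop("scene inventories differ; missing from RTs: {",
             paste(missing_sc, collapse = ", "), "}, missing from distances: {",
             paste(extra_sc, collapse = ", "), "}")
    mrt <- med$median_rt[match(scenes, med$scene)]
    keep <- .sceneSubset(category, subset)
    if (length(keep) < 3)
        stop("need at least 3 scenes in the subset")
    P <- dim(dist)[1L]; T <- dim(dist)[3L]
    rho <- matrix(NA_real_, P, T)
    y <- mrt[keep]
    y_const <- length(unique(y)) == 1L
    for (p in seq_len(P)) for (t in seq_len(T)) {
        x <- dist[p, keep, t]
        if (y_const || length(unique(x)) == 1L) next   # rho undefined
        rho[p, t] <- cor(x, y, method = "spearman")
    }
    structure(list(rho = rho,
                   group = colMeans(rho, na.rm = TRUE),
                   n_used = colSums(!is.na(rho)),
                   times = if (is.null(times)) seq_len(T) else times,
                   pairing = pairing, subset = subset),
              class = "DthTimecourse")
}

#' Cross-task distance-to-hyperplane pairing
#'
#' Runs [dthCorrelate()] with neural distances from one task and reaction
#' times from the other, recording the pairing. Errors if the two sources
#' disagree on the scene inventory.
#'
#' @param dv a [SceneDecisionValues-class] from the EEG task.
#' @param rt an RT table from the (possibly different) behavioral task.
#' @param subset scene subset as in [dthCorrelate()].
#' @return A \code{"DthTimecourse"} with the crossed pairing recorded.
#' @export
dthCrossTask <- function(dv, rt, subset = "all") {
    rt_task <- if ("task" %in% names(rt)) unique(rt$task) else "unknown"
    dthCorrelate(dv, rt, subset = subset,
                 pairing = c(dv@task, paste(rt_task, collapse = "+")))
}

#' @export
print.DthTimecourse <- function(x, ...) {
    cat(sprintf(
        "DthTimecourse: %d participants x %d time points (EEG: %s, RT: %s, scenes: %s)\n",
        nrow(x$rho), ncol(x$rho), x$pairing[1L], x$pairing[2L], x$subset))
    cat(sprintf("  group rho range: [%.3f, %.3f]\n",
                min(x$group, na.rm = TRUE), max(x$group, na.rm = TRUE)))
    invisible(x)
}
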