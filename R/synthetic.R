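# Synthetic data with planted ground truth. The generator embodies the
# linking model the empirical analyses assume: a binary category signal
# confined to a latency window, per-exemplar latent margins, spatially
# correlated channel noise, reaction times negatively coupled to the
# latent margin, and staged classifier probabilities that sharpen over
# stages at a rate increasing with the margin.

# Evaluate a function with a locally seeded RNG, restoring global state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

# Counter-based substream: one global seed expands into deterministic
# per-unit seeds so generation is reproducible independent of iteration
# order or parallel scheduling. Kept below 2^31 - 1.
substream <- function(seed, counter, salt = 0L) {
    ((as.double(seed) %% 1e6) * 2063 + counter * 7919 + salt * 104729) %%
        2147483647 + 1
}

#' Simulation configuration
#'
#' Defines the conditions of a synthetic study. Defaults describe a
#' moderately sized recovery design: 20 participants, 20 scenes (half
#' "natural", half "man-made"), 16 channels, 120 5-ms bins with the
#' category signal confined to 95--195 ms after onset, reaction times
#' around 500 ms negatively coupled to the latent category margin.
#'
#' @param n_participants number of simulated participants.
#' @param n_scenes number of scene exemplars; must be even (half per
#'   category).
#' @param n_channels number of recording channels.
#' @param n_timepoints number of time bins per epoch.
#' @param sample_period ms per time bin.
#' @param t_start latency of the first bin in ms (negative values give a
#'   prestimulus period).
#' @param effect_window two-element ms window (relative to onset at 0)
#'   within which the category signal is nonzero.
#' @param category_separation dimensionless mean margin between the two
#'   categories.
#' @param exemplar_spread SD of the per-scene latent margin around the
#'   category mean.
#' @param noise_sd scale of the channel noise (SD of each channel before
#'   correlation).
#' @param noise_cov channel covariance descriptor: \code{"identity"},
#'   \code{list(type = "diagonal", values = ...)}, or
#'   \code{list(type = "exponential", rate = r)} giving
#'   \eqn{\Sigma_{ij} = \exp(-r |i-j|)}.
#' @param trials_per_scene trials recorded per scene and participant.
#' @param rt_base mean reaction time in ms for a zero-margin scene.
#' @param rt_coupling ms of RT decrease per unit of absolute margin
#'   (\eqn{\lambda \ge 0}).
#' @param rt_noise_sd SD in ms of the per-participant RT noise.
#' @param rt_floor lower clip for reaction times in ms; fixed default of
#'   150 ms keeps noisy draws physiologically plausible.
#' @param n_stages number of stages for staged model outputs.
#' @param stage_gain logit units of confidence gained per stage and unit
#'   of absolute margin.
#' @param stage_noise_sd SD of logit noise added to staged confidences.
#' @param channel_weights optional fixed per-channel projection vector of
#'   the category signal; default: a seeded random unit-norm vector.
#' @param seed integer master seed; all randomness derives from it.
#' @return A validated list of class \code{"SimConfig"}.
#' @examples
#' cfg <- simConfig(n_participants = 2, n_scenes = 4, trials_per_scene = 8)
#' @export
simConfig <- function(n_participants = 20, n_scenes = 20, n_channels = 16,
                      n_timepoints = 120, sample_period = 5, t_start = 0,
                      effect_window = c(95, 195), category_separation = 1.5,
                      exemplar_spread = 0.5, noise_sd = 1,
                      noise_cov = list(type = "exponential", rate = 0.5),
                      trials_per_scene = 20, rt_base = 500, rt_coupling = 60,
                      rt_noise_sd = 30, rt_floor = 150, n_stages = 8,
                      stage_gain = 1, stage_noise_sd = 0,
                      channel_weights = NULL, seed = 1) {
    cfg <- list(n_participants = n_participants, n_scenes = n_scenes,
                n_channels = n_channels, n_timepoints = n_timepoints,
                sample_period = sample_period, t_start = t_start,
                effect_window = effect_window,
                category_separation = category_separation,
                exemplar_spread = exemplar_spread, noise_sd = noise_sd,
                noise_cov = noise_cov, trials_per_scene = trials_per_scene,
                rt_base = rt_base, rt_coupling = rt_coupling,
                rt_noise_sd = rt_noise_sd, rt_floor = rt_floor,
                n_stages = n_stages, stage_gain = stage_gain,
                stage_noise_sd = stage_noise_sd,
                channel_weights = channel_weights, seed = seed)
    class(cfg) <- "SimConfig"
    validateSimConfig(cfg)
    cfg
}

validateSimConfig <- function(cfg) {
    stopifnot(cfg$n_scenes %% 2 == 0, cfg$n_scenes >= 2,
              cfg$n_participants >= 1, cfg$n_channels >= 1,
              cfg$n_timepoints >= 1, cfg$sample_period > 0,
              cfg$rt_noise_sd >= 0, cfg$rt_coupling >= 0,
              cfg$rt_floor > 0, cfg$trials_per_scene >= 1,
              cfg$exemplar_spread >= 0, cfg$noise_sd >= 0)
    times <- simTimes(cfg)
    if (cfg$effect_window[1L] > cfg$effect_window[2L])
        stop("effect_window must be [start, end] with start <= end")
    if (cfg$effect_window[1L] < times[1L] ||
        cfg$effect_window[2L] > times[length(times)])
        stop("effect_window must lie within the epoch time range")
    if (!is.null(cfg$channel_weights) &&
        length(cfg$channel_weights) != cfg$n_channels)
        stop("channel_weights must have one entry per channel")
    invisible(cfg)
}

simTimes <- function(cfg)
    cfg$t_start + (seq_len(cfg$n_timepoints) - 1L) * cfg$sample_period

# Build the channel noise covariance from its descriptor.
noiseCovariance <- function(spec, n_channels, noise_sd = 1) {
    S <- if (identical(spec, "identity") ||
             identical(spec$type, "identity")) {
        diag(n_channels)
    } else if (identical(spec$type, "diagonal")) {
        v <- spec$values
        if (length(v) != n_channels || any(v < 0))
            stop("diagonal covariance needs one nonnegative value per channel")
        diag(v, n_channels)
    } else if (identical(spec$type, "exponential")) {
        if (is.null(spec$rate) || spec$rate < 0)
            stop("exponential covariance needs a nonnegative decay rate")
        idx <- seq_len(n_channels)
        exp(-spec$rate * abs(outer(idx, idx, "-")))
    } else {
        stop("unknown noise covariance type: ",
             deparse(if (is.list(spec)) spec$type else spec))
    }
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev)))
        stop("noise covariance is not positive semidefinite; ",
             "check the descriptor values")
    noise_sd^2 * S
}

# Raised-cosine signal amplitude profile: 0 outside the window, a smooth
# bump peaking mid-window inside it; avoids edge artifacts in
# time-resolved decoding.
raisedCosineProfile <- function(times, window) {
    a <- numeric(length(times))
    inside <- times >= window[1L] & times <= window[2L]
    span <- window[2L] - window[1L]
    if (span > 0)
        a[inside] <- 0.5 * (1 - cos(2 * pi * (times[inside] - window[1L]) / span))
    else a[inside] <- 1
    a
}

simScenes <- function(cfg) sprintf("scene%02d", seq_len(cfg$n_scenes))

simCategories <- function(cfg)
    rep(c("natural", "man-made"), each = cfg$n_scenes / 2)

# Latent per-scene margins and the projection they share. The absolute
# value keeps the margin sign constant within category even at large
# exemplar spread.
genGroundTruth <- function(cfg) {
    withSeed(substream(cfg$seed, 0L, 1L), {
        sgn <- ifelse(simCategories(cfg) == "natural", 1, -1)
        mag <- abs(cfg$category_separation / 2 +
                   rnorm(cfg$n_scenes, 0, cfg$exemplar_spread))
        w <- cfg$channel_weights
        if (is.null(w)) {
            w <- rnorm(cfg$n_channels)
            w <- w / sqrt(sum(w^2))
        }
        truth <- list(scene_margin = sgn * mag,
                      signal_profile = raisedCosineProfile(
                          simTimes(cfg), cfg$effect_window),
                      channel_weights = as.numeric(w),
                      scenes = simScenes(cfg),
                      category = simCategories(cfg))
        class(truth) <- "GroundTruth"
        truth
    })
}

#' Generate synthetic epoched recordings with planted ground truth
#'
#' Each trial is \eqn{a(t) \, m_s \, w + \epsilon_t}: the scene's latent
#' signed margin \eqn{m_s} projected onto a channel weight vector \eqn{w},
#' modulated by a raised-cosine amplitude profile \eqn{a(t)} confined to
#' the configured effect window, plus channel noise with the configured
#' spatial covariance (white over time). Trial metadata carries
#' participant, scene, category, task, \code{correct = TRUE} and the
#' reaction time from [genRTs()]. Generation is a pure function of the
#' config seed: per-participant noise streams derive from it by a
#' counter-based scheme.
#'
#' @param cfg a [simConfig()].
#' @param task task label recorded in the metadata.
#' @param truth optionally reuse a ground truth (e.g. to generate a second
#'   task's recordings of the same latent scenes).
#' @return A list with elements \code{epochs} (an [EpochSet-class]) and
#'   \code{truth} (scene margins, signal profile, channel weights).
#' @examples
#' sim <- genEpochs(simConfig(n_participants = 1, n_scenes = 4,
#'     n_timepoints = 30, trials_per_scene = 6, seed = 7))
#' sim$epochs
#' @export
genEpochs <- function(cfg, task = "categorization", truth = NULL) {
    validateSimConfig(cfg)
    if (is.null(truth)) truth <- genGroundTruth(cfg)
    times <- simTimes(cfg)
    Sig <- noiseCovariance(cfg$noise_cov, cfg$n_channels, cfg$noise_sd)
    L <- if (cfg$noise_sd > 0) t(chol(Sig + diag(1e-12, cfg$n_channels)))
         else matrix(0, cfg$n_channels, cfg$n_channels)
    base <- outer(truth$channel_weights, truth$signal_profile) # C x T
    ntr <- cfg$n_scenes * cfg$trials_per_scene
    C <- cfg$n_channels; T <- cfg$n_timepoints
    scene_of_trial <- rep(seq_len(cfg$n_scenes), each = cfg$trials_per_scene)
    rt_tab <- genRTs(truth, cfg, task = task)

    data <- array(0, c(ntr * cfg$n_participants, C, T))
    rows <- vector("list", cfg$n_participants)
    for (p in seq_len(cfg$n_participants)) {
        noise <- withSeed(substream(cfg$seed, p, 2L), {
            Z <- matrix(rnorm(C * ntr * T), C, ntr * T)
            L %*% Z
        })
        Xp <- aperm(array(noise, c(C, ntr, T)), c(2L, 1L, 3L))
        Xp <- Xp + outer(truth$scene_margin[scene_of_trial], base)
        idx <- (p - 1L) * ntr + seq_len(ntr)
        data[idx, , ] <- Xp
        pid <- sprintf("P%02d", p)
        rt_p <- rt_tab$rt[rt_tab$participant == pid]
        rows[[p]] <- data.frame(
            participant = pid,
            scene = truth$scenes[scene_of_trial],
            category = truth$category[scene_of_trial],
            task = task, correct = TRUE,
            rt = rt_p[scene_of_trial])
    }
    trials <- do.call(rbind, rows)
    epochs <- EpochSet(data, times, trials,
                       metadata = list(seed = cfg$seed, task = task,
                                       config_hash = configHash(cfg)))
    list(epochs = epochs, truth = truth)
}

#' Generate reaction times coupled to the latent margin
#'
#' Implements the linking model under study: scenes farther from the
#' category boundary are categorized faster,
#' \deqn{rt_{p,s} = rt_{base} - \lambda |m_s| + \mathcal{N}(0, \sigma_{rt}),}
#' clipped below at \code{cfg$rt_floor} (default 150 ms).
#'
#' @param truth ground truth from [genEpochs()].
#' @param cfg the [simConfig()].
#' @param task task label; RT noise uses a task-specific stream so the two
#'   tasks get independent behavioral noise over the same latent margins.
#' @return A data.frame (participant, scene, category, task, rt).
#' @export
genRTs <- function(truth, cfg, task = "categorization") {
    seed_rt <- substream(cfg$seed, sum(utf8ToInt(task)) %% 1000L, 3L)
    withSeed(seed_rt, {
        P <- cfg$n_participants; S <- cfg$n_scenes
        noise <- matrix(rnorm(P * S, 0, cfg$rt_noise_sd), P, S)
        rt <- cfg$rt_base - cfg$rt_coupling * abs(
            matrix(truth$scene_margin, P, S, byrow = TRUE)) + noise
        rt <- pmax(rt, cfg$rt_floor)
        data.frame(participant = rep(sprintf("P%02d", seq_len(P)), each = S),
                   scene = rep(truth$scenes, P),
                   category = rep(truth$category, P),
                   task = task, rt = as.numeric(t(rt)))
    })
}

#' Per-scene median reaction times over participants
#'
#' @param rt an RT table as returned by [genRTs()] (columns participant,
#'   scene, rt; optionally category).
#' @return A data.frame (scene, category if available, median_rt), scenes
#'   in first-appearance order.
#' @export
medianRTs <- function(rt) {
    scenes <- unique(rt$scene)
    med <- vapply(scenes, function(s)
        median(rt$rt[rt$scene == s], na.rm = TRUE), numeric(1))
    out <- data.frame(scene = scenes, median_rt = as.numeric(med))
    if ("category" %in% names(rt))
        out$category <- rt$category[match(scenes, rt$scene)]
    out
}

#' Generate staged classifier probability trajectories
#'
#' For each scene the confidence in the true category follows
#' \eqn{p_k = \text{logistic}(g \, k \, |m_s| + \eta_k)} over stages
#' \eqn{k = 1..S}: uninformative scenes (\eqn{m_s = 0}) stay at (0.5, 0.5)
#' while high-margin scenes saturate early, so entropy-threshold readout
#' times decrease with the margin.
#'
#' @param truth ground truth from [genEpochs()].
#' @param cfg the [simConfig()]; uses \code{n_stages}, \code{stage_gain},
#'   \code{stage_noise_sd}.
#' @return A [StageProbabilities-class] with classes
#'   \code{c("natural", "man-made")}.
#' @export
genStageProbs <- function(truth, cfg) {
    if (cfg$n_stages < 2) stop("n_stages must be at least 2")
    withSeed(substream(cfg$seed, 0L, 4L), {
        S <- length(truth$scene_margin); K <- cfg$n_stages
        logit <- cfg$stage_gain * outer(abs(truth$scene_margin), seq_len(K))
        if (cfg$stage_noise_sd > 0)
            logit <- logit + matrix(rnorm(S * K, 0, cfg$stage_noise_sd), S, K)
        conf <- plogis(logit)                 # P(true category)
        p <- array(0, c(S, K, 2L))
        nat <- truth$category == "natural"
        p[nat, , 1L] <- conf[nat, ];  p[nat, , 2L] <- 1 - conf[nat, ]
        p[!nat, , 2L] <- conf[!nat, ]; p[!nat, , 1L] <- 1 - conf[!nat, ]
        StageProbabilities(p, scenes = truth$scenes,
                           category = truth$category,
                           classes = c("natural", "man-made"))
    })
}

#' Deterministic concentric-ring channel layout
#'
#' Places channels on concentric rings of capacity 8, 12, 16, ... at radii
#' 1, 2, 3, ...; channels within a ring are equally spaced over the ring's
#' occupied positions. With 8 channels this is a single evenly spaced
#' ring.
#'
#' @param n_channels number of channels (at least 5).
#' @param names optional channel names.
#' @return A [channelLayout()] data.frame (channel, x, y).
#' @export
genLayout <- function(n_channels, names = NULL) {
    if (n_channels < 5) stop("a layout needs at least 5 channels")
    if (is.null(names)) names <- sprintf("ch%02d", seq_len(n_channels))
    xs <- numeric(0); ys <- numeric(0)
    remaining <- n_channels; ring <- 1L
    while (remaining > 0) {
        cap <- 4L + 4L * ring
        k <- min(cap, remaining)
        ang <- 2 * pi * (seq_len(k) - 1L) / k
        xs <- c(xs, ring * cos(ang)); ys <- c(ys, ring * sin(ang))
        remaining <- remaining - k; ring <- ring + 1L
    }
    channelLayout(names, xs, ys)
}
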