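test_that("generation is a pure function of the seed", {
    cfg <- simConfig(n_participants = 2, n_scenes = 4, n_channels = 6,
                     n_timepoints = 20, effect_window = c(30, 70),
                     trials_per_scene = 6, seed = 11)
    a <- genEpochs(cfg)
    b <- genEpochs(cfg)
    expect_identical(epochData(a$epochs), epochData(b$epochs))
    expect_identical(a$truth$scene_margin, b$truth$scene_margin)
    expect_identical(genRTs(a$truth, cfg), genRTs(b$truth, cfg))
    cfg2 <- simConfig(n_participants = 2, n_scenes = 4, n_channels = 6,
                      n_timepoints = 20, effect_window = c(30, 70),
                      trials_per_scene = 6, seed = 12)
    expect_false(identical(epochData(a$epochs),
                           epochData(genEpochs(cfg2)$epochs)))
})

test_that("zero-effect configuration plants no signal", {
    cfg <- simConfig(n_participants = 1, n_scenes = 4, n_channels = 6,
                     n_timepoints = 20, effect_window = c(30, 70),
                     category_separation = 0, exemplar_spread = 0,
                     trials_per_scene = 4, seed = 5)
    sim <- genEpochs(cfg)
    expect_equal(sim$truth$scene_margin, rep(0, 4))
    # pure noise: epochs identical to the same config with any separation
    # removed, i.e. signal contribution is exactly zero
    expect_equal(mean(abs(outer(sim$truth$scene_margin,
                                sim$truth$channel_weights))), 0)
})

test_that("noiseless limit reproduces the planted signal exactly", {
    C <- 4
    cfg <- simConfig(n_participants = 1, n_scenes = 2, n_channels = C,
                     n_timepoints = 20, effect_window = c(30, 70),
                     category_separation = 2, exemplar_spread = 0,
                     noise_sd = 0, trials_per_scene = 3,
                     channel_weights = rep(1, C), seed = 2)
    sim <- genEpochs(cfg)
    X <- epochData(sim$epochs)
    a <- sim$truth$signal_profile
    m <- sim$truth$scene_margin
    tr <- trialInfo(sim$epochs)
    for (i in seq_len(nTrials(sim$epochs))) {
        ms <- m[match(tr$scene[i], sim$truth$scenes)]
        expect_equal(X[i, , ], outer(rep(1, C), a * ms), tolerance = 1e-12)
    }
    # signal profile is zero outside the effect window, in [0, 1] inside
    tms <- epochTimes(sim$epochs)
    expect_true(all(a[tms < 30 | tms > 70] == 0))
    expect_true(all(a >= 0 & a <= 1))
})

test_that("spatially correlated noise matches the requested covariance", {
    rate <- 0.5; C <- 8
    cfg <- simConfig(n_participants = 1, n_scenes = 2, n_channels = C,
                     n_timepoints = 2, effect_window = c(0, 5),
                     category_separation = 0, exemplar_spread = 0,
                     noise_cov = list(type = "exponential", rate = rate),
                     trials_per_scene = 5000, seed = 9)
    sim <- genEpochs(cfg)
    X <- epochData(sim$epochs)
    samples <- rbind(X[, , 1], X[, , 2])        # 2e4 noise-only patterns
    emp <- cov(samples)
    target <- exp(-rate * abs(outer(1:C, 1:C, "-")))
    rel <- norm(emp - target, "F") / norm(target, "F")
    expect_lt(rel, 0.05)
})

test_that("invalid covariance descriptors are rejected with explanation", {
    expect_error(simConfig(noise_cov = list(type = "diagonal",
                                            values = c(-1, rep(1, 15)))),
                 NA) # config itself does not build the matrix
    cfg <- simConfig(n_channels = 3, seed = 1,
                     noise_cov = list(type = "diagonal", values = c(-1, 1, 1)))
    expect_error(genEpochs(cfg), "nonnegative")
    cfg2 <- simConfig(n_channels = 3, seed = 1,
                      noise_cov = list(type = "unknown"))
    expect_error(genEpochs(cfg2), "unknown noise covariance")
})

test_that("reaction times follow the linking model", {
    cfg <- simConfig(n_participants = 8, n_scenes = 40, rt_base = 500,
                     rt_coupling = 50, rt_noise_sd = 0, seed = 3)
    truth <- list(scene_margin = c(1, rep(0.5, 39)),
                  scenes = sprintf("scene%02d", 1:40),
                  category = rep(c("natural", "man-made"), each = 20))
    rt <- genRTs(truth, cfg)
    # arithmetic: 500 - 50 * 1 = 450, exactly, for every participant
    expect_equal(rt$rt[rt$scene == "scene01"], rep(450, 8))
    # noiseless coupling: perfect monotone decrease with |margin|
    truth$scene_margin <- seq(0.1, 2, length.out = 40) *
        rep(c(1, -1), each = 20)
    rt <- genRTs(truth, cfg)
    one <- rt[rt$participant == "P01", ]
    expect_equal(cor(abs(truth$scene_margin), one$rt, method = "spearman"), -1)
    # no coupling: RTs independent of margins
    cfg0 <- simConfig(n_participants = 1, n_scenes = 40, rt_coupling = 0,
                      rt_noise_sd = 20, seed = 4)
    rt0 <- genRTs(truth, cfg0)
    expect_lt(abs(cor(abs(truth$scene_margin), rt0$rt,
                      method = "spearman")), 0.4)
    # floor respected
    cfgf <- simConfig(n_participants = 2, n_scenes = 40, rt_base = 160,
                      rt_coupling = 100, rt_noise_sd = 50, seed = 5)
    rtf <- genRTs(truth, cfgf)
    expect_true(all(rtf$rt >= 150))
})

test_that("staged probabilities sharpen with stage and margin", {
    cfg <- simConfig(n_scenes = 4, n_stages = 8, stage_gain = 1,
                     stage_noise_sd = 0, seed = 6)
    mk_truth <- function(m) list(
        scene_margin = m, scenes = sprintf("scene%02d", seq_along(m)),
        category = rep(c("natural", "man-made"), each = length(m) / 2))
    # saturation: huge margin -> certainty from stage 1, entropy 0
    sp <- genStageProbs(mk_truth(c(1e6, 1e6, -1e6, -1e6)), cfg)
    H <- entropyMatrix(sp)
    expect_equal(max(H), 0)
    expect_equal(sp@p[1, 1, ], c(1, 0))
    # uninformative scene stays at (0.5, 0.5), entropy maximal
    sp0 <- genStageProbs(mk_truth(c(0, 0, 0, 0)), cfg)
    expect_true(all(abs(sp0@p - 0.5) < 1e-12))
    expect_equal(as.vector(entropyMatrix(sp0)), rep(1, 4 * 8))
    # monotonicity: larger margin -> earlier threshold crossing, at any
    # threshold
    sp2 <- genStageProbs(mk_truth(c(2, 0.5, -2, -0.5)), cfg)
    H2 <- entropyMatrix(sp2)
    for (th in seq(0.01, 0.9, by = 0.05)) {
        rt <- extractNetworkRTs(H2, th)
        expect_lte(rt[1], rt[2])
        expect_lte(rt[3], rt[4])
    }
})

test_that("concentric layout geometry and neighbor structure", {
    lay <- genLayout(8)            # single ring of 8 equally spaced
    nb <- buildNeighborMap(lay, k = 4)
    for (i in 1:8) {
        expected <- sprintf("ch%02d", sort(((i + c(-2, -1, 1, 2) - 1) %% 8) + 1))
        expect_setequal(nb[[sprintf("ch%02d", i)]], expected)
    }
    expect_error(genLayout(4), "at least 5")
    expect_error(channelLayout(c("a", "b"), c(0, 0), c(1, 1)), "unique")
    expect_error(channelLayout(c("a", "a"), c(0, 1), c(0, 1)), "unique")
    # larger layouts fill outer rings without duplicate positions
    lay2 <- genLayout(16)
    expect_equal(nrow(lay2), 16)
    expect_false(anyDuplicated(lay2[, c("x", "y")]) > 0)
})

test_that("trial metadata carries RTs consistent with the RT table", {
    cfg <- simConfig(n_participants = 2, n_scenes = 4, n_channels = 5,
                     n_timepoints = 20, effect_window = c(30, 70),
                     trials_per_scene = 3, seed = 8)
    sim <- genEpochs(cfg)
    rt <- genRTs(sim$truth, cfg)
    tr <- trialInfo(sim$epochs)
    for (i in seq_len(nrow(tr))) {
        expect_equal(tr$rt[i],
                     rt$rt[rt$participant == tr$participant[i] &
                           rt$scene == tr$scene[i]])
    }
})
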