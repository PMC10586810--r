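mkSeries <- function(rdm, times = NULL, scenes = NULL, category = NULL) {
    d <- dim(rdm)
    if (is.null(times)) times <- (seq_len(d[3]) - 1) * 5
    if (is.null(scenes)) scenes <- sprintf("scene%02d", seq_len(d[1]))
    if (is.null(category))
        category <- rep(c("natural", "man-made"), each = d[1] / 2)
    structure(list(rdm = rdm, times = times, scenes = scenes,
                   category = category,
                   participants = sprintf("P%02d", seq_len(d[4]))),
              class = "RDMSeries")
}

randomRDM <- function(S) {
    m <- matrix(runif(S * S, 0, 2), S, S)
    m <- (m + t(m)) / 2; diag(m) <- 0
    m
}

test_that("EEG RDMs hit the limiting correlation distances", {
    # identical scene patterns -> distance 0
    centers <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
    e <- clusterEpochs(centers, trials_per_scene = 5, noise_sd = 0,
                       n_time = 2, seed = 61)
    ser <- eegRDMSeries(e, group_size = 5, repeats = 2, seed = 61)
    expect_equal(ser$rdm[1, 2, , 1], c(0, 0), tolerance = 1e-12)
    # exactly anti-correlated patterns -> distance 2
    centers2 <- rbind(c(1, 2, 3, 4), -c(1, 2, 3, 4) + 5)
    e2 <- clusterEpochs(centers2, trials_per_scene = 5, noise_sd = 0,
                        n_time = 1, seed = 62)
    ser2 <- eegRDMSeries(e2, group_size = 5, repeats = 1, seed = 62)
    expect_equal(ser2$rdm[1, 2, 1, 1], 2, tolerance = 1e-12)
    # invariance under positive affine transform of one pattern
    centers3 <- rbind(c(1, 2, 3, 4), 3 * c(1, 2, 3, 4) + 7)
    e3 <- clusterEpochs(centers3, trials_per_scene = 5, noise_sd = 0,
                        n_time = 1, seed = 63)
    ser3 <- eegRDMSeries(e3, group_size = 5, repeats = 1, seed = 63)
    expect_equal(ser3$rdm[1, 2, 1, 1], 0, tolerance = 1e-12)
})

test_that("generated RDM series are valid dissimilarity structures", {
    cfg <- simConfig(n_participants = 2, n_scenes = 4, n_channels = 6,
                     n_timepoints = 10, effect_window = c(10, 40),
                     trials_per_scene = 10, seed = 64)
    sim <- genEpochs(cfg)
    ser <- eegRDMSeries(sim$epochs, group_size = 5, repeats = 5, seed = 64)
    for (p in 1:2) for (t in 1:10) {
        m <- ser$rdm[, , t, p]
        expect_equal(m, t(m))
        expect_equal(diag(m), rep(0, 4))
        expect_true(all(m >= 0 & m <= 2))
    }
})

test_that("model RDMs standardize features and match the direct formula", {
    withr::with_seed(65, {
        F3 <- rbind(c(1, 2, 3, 4), c(2, 1, 4, 3), c(4, 3, 2, 1))
        rownames(F3) <- c("a", "b", "c")
        rdm <- modelRDM(F3)
        Z <- scale(F3)
        for (i in 1:3) for (j in 1:3) {
            zi <- Z[i, ]; zj <- Z[j, ]
            r <- sum((zi - mean(zi)) * (zj - mean(zj))) /
                sqrt(sum((zi - mean(zi))^2) * sum((zj - mean(zj))^2))
            expected <- if (i == j) 0 else 1 - r
            expect_equal(rdm[i, j], expected, tolerance = 1e-12)
        }
        # duplicated scene rows -> off-diagonal zero
        F2 <- rbind(c(1, 5, 2, 8), c(1, 5, 2, 8), c(3, 1, 9, 2))
        expect_equal(modelRDM(F2)[1, 2], 0, tolerance = 1e-12)
        # feature permutation leaves the RDM unchanged
        Fp <- matrix(rnorm(4 * 6), 4, 6)
        expect_equal(modelRDM(Fp), modelRDM(Fp[, sample(6)]))
        # zero-variance features dropped with message; all-zero errors
        expect_message(modelRDM(cbind(Fp, 1)), "zero-variance")
        expect_error(modelRDM(matrix(1, 3, 2)), "zero variance")
    })
})

test_that("RDM correlation uses the strict upper triangle, Spearman", {
    withr::with_seed(66, {
        a <- randomRDM(6)
        expect_equal(correlateRDMs(a, a), 1)
        # strictly increasing transform preserves rho = 1
        b <- a^3 / 2
        expect_equal(correlateRDMs(a, b), 1)
        # reversed ranks give -1
        rev_b <- max(a) - a; diag(rev_b) <- 0
        expect_equal(correlateRDMs(a, rev_b), -1)
        expect_error(correlateRDMs(a, randomRDM(5)), "different sizes")
        # oracle: brute-force average-rank Spearman on the triangles
        c2 <- randomRDM(6)
        ut <- upper.tri(a)
        expect_equal(correlateRDMs(a, c2), bruteSpearman(a[ut], c2[ut]))
    })
})

test_that("RSA timecourse peaks where the model structure is planted", {
    withr::with_seed(67, {
        S <- 6; T <- 8; P <- 3
        target <- randomRDM(S)
        rdm <- array(0, c(S, S, T, P))
        for (p in 1:P) for (t in 1:T) {
            rdm[, , t, p] <- if (t == 5) target else randomRDM(S)
        }
        ser <- mkSeries(rdm)
        models <- modelRDMSet(list(target), layer = "late")
        out <- rsaTimecourse(ser, models)
        expect_equal(unname(out$peak_latency["late"]), ser$times[5])
        expect_equal(max(out$rho), 1)
        # subset restriction of identical RDMs still gives rho = 1
        outA <- rsaTimecourse(ser, models, subset = "A")
        expect_equal(max(outA$rho), 1)
        # a model unrelated to every EEG RDM stays near zero on average
        out0 <- rsaTimecourse(ser, modelRDMSet(list(randomRDM(S)), "late"))
        expect_lt(mean(abs(out0$rho[, -5])), 0.35)
        # median over stages within layer
        models2 <- modelRDMSet(list(target, randomRDM(S), randomRDM(S)),
                               layer = rep("late", 3), stage = 1:3)
        out2 <- rsaTimecourse(ser, models2)
        expect_lt(out2$rho["late", 5], 1)     # median, not max
    })
})

test_that("noise ceiling bounds behave at the limits", {
    withr::with_seed(68, {
        S <- 6; T <- 4; P <- 5
        # all participants share one RDM -> lower = upper = 1
        shared <- randomRDM(S)
        rdm <- array(rep(shared, T * P), c(S, S, T, P))
        nc <- noiseCeiling(mkSeries(rdm))
        expect_equal(nc$lower, rep(1, T))
        expect_equal(nc$upper, rep(1, T))
        # independent random RDMs -> both bounds near zero, lower <= upper
        P2 <- 12
        rdm2 <- array(0, c(S, S, T, P2))
        for (p in 1:P2) for (t in 1:T) rdm2[, , t, p] <- randomRDM(S)
        nc2 <- noiseCeiling(mkSeries(rdm2))
        expect_true(all(nc2$lower <= nc2$upper + 1e-12))
        expect_lt(mean(abs(nc2$upper)), 0.4)
        expect_error(noiseCeiling(mkSeries(rdm2[, , , 1, drop = FALSE])),
                     "2 participants")
    })
})

test_that("averaging RDMs across repeats preserves symmetry", {
    cfg <- simConfig(n_participants = 1, n_scenes = 4, n_channels = 5,
                     n_timepoints = 6, effect_window = c(5, 20),
                     trials_per_scene = 10, seed = 69)
    sim <- genEpochs(cfg)
    ser <- eegRDMSeries(sim$epochs, group_size = 5, repeats = 4, seed = 69)
    for (t in 1:6)
        expect_equal(ser$rdm[, , t, 1], t(ser$rdm[, , t, 1]))
})
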