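test_that("pseudotrial averaging partitions trials without reuse", {
    v <- c(1, 2, 3)
    pat <- matrix(rep(v, each = 8), 8, 3)
    pt <- makePseudotrials(pat, rep("a", 8), group_size = 4, seed = 1)
    expect_equal(nrow(pt$patterns), 2)
    expect_equal(pt$patterns[1, ], v)
    expect_equal(pt$patterns[2, ], v)
    # 10 trials, group size 4 -> 2 pseudotrials, 2 trials dropped
    pat10 <- matrix(rnorm(10 * 2), 10, 2)
    pt10 <- makePseudotrials(pat10, rep("a", 10), group_size = 4, seed = 2)
    expect_equal(nrow(pt10$patterns), 2)
    used <- unlist(pt10$assignment)
    expect_equal(length(used), 8)
    expect_false(any(duplicated(used)))          # no trial reused
    # group size 1: pseudotrials are the trials, order permuted
    pt1 <- makePseudotrials(pat10, rep(c("a", "b"), 5), group_size = 1,
                            seed = 3)
    expect_equal(nrow(pt1$patterns), 10)
    expect_setequal(unlist(pt1$assignment), 1:10)
    expect_error(makePseudotrials(pat10, rep("a", 10), group_size = 11),
                 "fewer than group_size")
})

test_that("trial equalization downsamples to the per-participant minimum", {
    X <- array(rnorm(46 * 2 * 2), c(46, 2, 2))
    scene <- c(rep("s1", 25), rep("s2", 21))
    e <- toyEpochs(X, scene = scene,
                   category = ifelse(scene == "s1", "natural", "man-made"))
    out <- equalizeTrials(e, seed = 4)
    expect_equal(as.vector(table(trialInfo(out)$scene)), c(21L, 21L))
    # deterministic given the seed
    out2 <- equalizeTrials(e, seed = 4)
    expect_identical(epochData(out), epochData(out2))
})

test_that("the linear SVM agrees with libsvm on decision structure", {
    skip_if_not_installed("e1071")
    withr::with_seed(31, {
        n <- 40; d <- 8
        X <- rbind(matrix(rnorm(n / 2 * d, 1), n / 2, d),
                   matrix(rnorm(n / 2 * d, -1), n / 2, d))
        y <- rep(c(1L, -1L), each = n / 2)
        fit <- scenedecode:::.lsvm_fit(X, y, C = 1)
        dv_ours <- X %*% fit$w + fit$b
        m <- e1071::svm(X, factor(y, levels = c(1, -1)), kernel = "linear",
                        cost = 1, scale = FALSE)
        dv_libsvm <- attr(predict(m, X, decision.values = TRUE),
                          "decision.values")
        # same labelling on all points and near-collinear decision values
        expect_equal(sign(dv_ours), sign(dv_libsvm), ignore_attr = TRUE)
        expect_gt(cor(as.numeric(dv_ours), as.numeric(dv_libsvm)), 0.98)
    })
})

test_that("identity decoding is perfect in the separable limit", {
    centers <- rbind(c(10, 0, 0), c(-10, 0, 0))
    e <- clusterEpochs(centers, trials_per_scene = 8, noise_sd = 0.01,
                       n_time = 2, seed = 32)
    out <- decodeIdentity(e, repeats = 2, group_size = 2, seed = 32)
    expect_equal(as.vector(out$accuracy), rep(100, 2))
})

test_that("identity decoding is at chance for shuffled labels", {
    withr::with_seed(33, {
        X <- array(rnorm(64 * 4 * 3), c(64, 4, 3))
        sc <- sample(rep(sprintf("s%d", 1:4), 16))
        e <- toyEpochs(X, scene = sc,
                       category = ifelse(sc %in% c("s1", "s2"),
                                         "natural", "man-made"))
        out <- decodeIdentity(e, repeats = 5, group_size = 4, seed = 33)
        band <- binomialBand(6 * 4 * 2 * 3)   # pairs x folds x sides x times
        m <- mean(out$accuracy)
        expect_gt(m, band[1]); expect_lt(m, band[2])
    })
})

test_that("category decoding recovers margins and orders decision values", {
    # noiseless: accuracy 100 and |decision value| ordered by |margin|
    margins <- c(2, 1, -1, -2)
    centers <- outer(margins, c(1, 0.5, -0.5))
    e <- clusterEpochs(centers, trials_per_scene = 8, noise_sd = 1e-4,
                       n_time = 2, seed = 34)
    out <- decodeCategory(e, repeats = 3, train_group_size = 4, seed = 34)
    expect_equal(as.vector(out$accuracy), rep(100, 2))
    d <- decisionValues(out$dvals)[1, , 1]
    expect_gt(abs(d[1]), abs(d[2]))
    expect_gt(abs(d[4]), abs(d[3]))
    # sign convention: first category's scenes on the positive side
    expect_true(all(d[1:2] > 0) && all(d[3:4] < 0))
})

test_that("category decoding is at chance on pure noise", {
    # repeats reuse the same trials, so the independent predictions per
    # dataset are scenes x times; average over several noise datasets
    ms <- vapply(1:6, function(s) withr::with_seed(3500 + s, {
        X <- array(rnorm(48 * 4 * 4), c(48, 4, 4))
        sc <- rep(sprintf("s%d", 1:4), each = 12)
        e <- toyEpochs(X, scene = sc,
                       category = ifelse(sc %in% c("s1", "s2"),
                                         "natural", "man-made"))
        mean(decodeCategory(e, repeats = 10, train_group_size = 6,
                            seed = s)$accuracy)
    }), numeric(1))
    band <- binomialBand(6 * 4 * 4)           # datasets x scenes x times
    m <- mean(ms)
    expect_gt(m, band[1]); expect_lt(m, band[2])
})

test_that("a boundary test pattern gets decision value zero", {
    # symmetric clusters around the origin; the midpoint sits on the
    # fitted boundary
    X <- rbind(matrix(rep(c(2, 1), each = 6), 6),
               matrix(rep(c(-2, -1), each = 6), 6))
    fit <- scenedecode:::.lsvm_fit(X, rep(c(1L, -1L), each = 6), C = 1)
    expect_lt(abs(as.numeric(c(0, 0) %*% fit$w + fit$b)), 1e-4)
})

test_that("accuracy is invariant to a consistent channel permutation", {
    centers <- outer(c(1.5, 0.8, -0.8, -1.5), c(1, -0.5, 0.25, 0.7))
    e <- clusterEpochs(centers, trials_per_scene = 8, noise_sd = 0.5,
                       n_time = 2, seed = 36)
    perm <- c(3, 1, 4, 2)
    e_perm <- e[, perm, ]
    out <- decodeCategory(e, repeats = 4, train_group_size = 4, seed = 99)
    out_perm <- decodeCategory(e_perm, repeats = 4, train_group_size = 4,
                               seed = 99)
    expect_equal(out$accuracy, out_perm$accuracy, tolerance = 1e-9)
    expect_equal(decisionValues(out$dvals), decisionValues(out_perm$dvals),
                 tolerance = 1e-8)
})

test_that("uninformative noisy channels do not destroy decoding", {
    withr::with_seed(37, {
        margins <- c(2, 1.2, -1.2, -2)
        centers_inf <- cbind(margins, 0, 0, 0, 0)
        e_clean <- clusterEpochs(centers_inf[, 1, drop = FALSE],
                                 trials_per_scene = 12, noise_sd = 0.3,
                                 n_time = 1, seed = 38)
        e_noisy <- clusterEpochs(centers_inf, trials_per_scene = 12,
                                 noise_sd = 0.3, n_time = 1, seed = 38)
        a1 <- mean(decodeCategory(e_clean, repeats = 8,
                                  train_group_size = 6, seed = 1)$accuracy)
        a2 <- mean(decodeCategory(e_noisy, repeats = 8,
                                  train_group_size = 6, seed = 1)$accuracy)
        expect_lt(abs(a1 - a2), 8)   # within sampling error
    })
})

test_that("decoding errors are actionable", {
    X <- array(rnorm(8 * 2 * 2), c(8, 2, 2))
    e_one_cat <- toyEpochs(X, scene = rep(c("s1", "s2"), 4),
                           category = "natural")
    expect_error(decodeCategory(e_one_cat, repeats = 1,
                                train_group_size = 2), "two categories")
    e_single <- toyEpochs(X, scene = rep("s1", 8),
                          category = rep("natural", 8))
    expect_error(decodeIdentity(e_single, repeats = 1), "2 scenes")
})
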