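# Shared fixture builders and independent oracles. Oracles are written
# from the definitions and stay independent of the package code paths they
# check.

# Minimal EpochSet around a given tensor.
toyEpochs <- function(data, times = NULL, participant = "P01",
                      scene = NULL, category = NULL,
                      task = "categorization", correct = TRUE, rt = 400) {
    n <- dim(data)[1L]
    if (is.null(times)) times <- (seq_len(dim(data)[3L]) - 1L) * 5
    if (is.null(scene)) scene <- sprintf("scene%02d", seq_len(n))
    if (is.null(category))
        category <- rep(c("natural", "man-made"), length.out = n)
    EpochSet(data, times, data.frame(
        participant = participant, scene = scene, category = category,
        task = task, correct = correct, rt = rt))
}

# Epochs with per-scene mean patterns `centers` (scene x channel) plus iid
# noise, constant over time.
clusterEpochs <- function(centers, trials_per_scene, noise_sd = 0,
                          n_time = 1, participant = "P01", seed = 1) {
    withr::with_seed(seed, {
        S <- nrow(centers); C <- ncol(centers)
        n <- S * trials_per_scene
        sc <- rep(seq_len(S), each = trials_per_scene)
        pat <- centers[sc, , drop = FALSE] +
            matrix(rnorm(n * C, 0, noise_sd), n, C)
        data <- array(rep(pat, n_time), c(n, C, n_time))
        toyEpochs(data,
                  scene = sprintf("scene%02d", sc),
                  category = ifelse(sc <= S / 2, "natural", "man-made"),
                  participant = participant)
    })
}

# Spearman rho with average ranks, from first principles: ranks by
# exhaustive pairwise counting, then the Pearson formula written out.
bruteSpearman <- function(x, y) {
    brute_rank <- function(v)
        vapply(seq_along(v), function(i)
            sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
    rx <- brute_rank(x); ry <- brute_rank(y)
    mx <- sum(rx) / length(rx); my <- sum(ry) / length(ry)
    num <- sum((rx - mx) * (ry - my))
    den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
    num / den
}

# Exhaustive sign-permutation p-value (right tail) for one time point.
bruteSignPerm <- function(x, tail = "right") {
    P <- length(x)
    obs <- mean(x) / sd(x)
    stats <- vapply(seq_len(2^P) - 1L, function(bits) {
        s <- ifelse(bitwAnd(bits, 2L^(seq_len(P) - 1L)) > 0, -1, 1)
        v <- s * x
        st <- mean(v) / sd(v)
        if (!is.finite(st)) 0 else st
    }, numeric(1))
    pr <- sum(stats >= obs - 1e-12) / 2^P
    pl <- sum(stats <= obs + 1e-12) / 2^P
    switch(tail, right = pr, left = pl, two = min(1, 2 * min(pr, pl)))
}

# Benjamini-Hochberg step-up from the definition: find the largest k with
# p_(k) <= k * alpha / m; adjusted p by the explicit min-over-tail formula.
bruteBH <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj_sorted <- vapply(seq_len(m), function(k)
        min(1, min(ps[k:m] * m / (k:m))), numeric(1))
    adj <- numeric(m); adj[o] <- adj_sorted
    k_max <- 0L
    for (k in seq_len(m)) if (ps[k] <= k * alpha / m) k_max <- k
    mask <- logical(m)
    if (k_max > 0) mask[o[seq_len(k_max)]] <- TRUE
    list(p_adj = adj, mask = mask)
}

# First stage whose entropy reaches the threshold, by explicit scan.
bruteExtractRT <- function(H, threshold) {
    apply(H, 1L, function(row) {
        for (s in seq_along(row)) if (row[s] <= threshold) return(s)
        length(row) + 1L
    })
}
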