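# Pipeline orchestration: chains the stages over on-disk artifacts, with a
# machine-readable run manifest stamping every artifact with the config
# hash that produced it. A thin command-line wrapper over these functions
# ships in inst/scripts/scenedecode.R.

#' Load and validate a pipeline configuration
#'
#' Accepts a YAML or JSON file (or an already-parsed list) with optional
#' blocks \code{sim} (arguments of [simConfig()]), \code{decode}
#' (\code{repeats}, \code{train_group_size}, \code{cost}), \code{dth}
#' (\code{subset}), and \code{stats} (\code{n_perm}, \code{alpha},
#' \code{tail}). Unknown fields are rejected with their path.
#'
#' @param config path to a YAML/JSON file, or a list.
#' @return A validated configuration list of class
#'   \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(config = list()) {
    if (is.character(config)) {
        config <- if (grepl("\\.json$", config))
            jsonlite::read_json(config, simplifyVector = TRUE)
        else yaml::read_yaml(config)
    }
    defaults <- list(
        sim = list(),
        decode = list(repeats = 20, train_group_size = 20, cost = 1),
        dth = list(subset = "all"),
        stats = list(n_perm = 1000, alpha = 0.05, tail = "left"))
    known <- names(defaults)
    bad <- setdiff(names(config), known)
    if (length(bad))
        stop("unknown config field(s): ", paste(bad, collapse = ", "))
    for (blk in known) {
        extra <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
        if (blk != "sim" && length(extra))
            stop("unknown config field(s): ",
                 paste(paste0(blk, "$", extra), collapse = ", "))
        defaults[[blk]][names(config[[blk]])] <- config[[blk]]
    }
    if (length(defaults$sim)) do.call(simConfig, defaults$sim)  # validates
    class(defaults) <- "PipelineConfig"
    defaults
}

.manifestPath <- function(out_dir) file.path(out_dir, "manifest.json")

.readManifest <- function(out_dir) {
    mp <- .manifestPath(out_dir)
    if (file.exists(mp)) jsonlite::read_json(mp, simplifyVector = FALSE)
    else list(artifacts = list())
}

.stampManifest <- function(out_dir, stage, files, hash, seed) {
    man <- .readManifest(out_dir)
    man$artifacts[[stage]] <- list(files = as.list(files),
                                   config_hash = hash, seed = seed)
    jsonlite::write_json(man, .manifestPath(out_dir), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
}

.requireArtifact <- function(path, producer) {
    missing <- path[!file.exists(path)]
    if (length(missing))
        stop("missing upstream artifact(s) ",
             paste(basename(missing), collapse = ", "),
             "; run the '", producer, "' stage first")
    invisible(path)
}

#' Run pipeline stages over an artifact directory
#'
#' Stages: \code{simulate} (synthetic epochs + RT table), \code{preprocess}
#' (per-participant multivariate noise normalization), \code{decode}
#' (category decoding; accuracy time course and scene decision values),
#' \code{d2h} (distance-to-hyperplane correlation time course),
#' \code{stats} (sign-permutation test + FDR on the d2h time course), and
#' \code{report} (summary table with peak value, peak latency, bootstrap
#' CI and significant windows). Each stage reads its inputs from
#' \code{out_dir} and fails, naming the producing stage, if they are
#' absent; every artifact is stamped with the config hash and
#' \code{report} refuses to mix hashes.
#'
#' @param config a [pipelineConfig()] (or anything it accepts).
#' @param out_dir artifact directory; created if needed.
#' @param stages character vector of stages to run, in order.
#' @param seed integer seed recorded in the config hash and used by every
#'   stochastic stage.
#' @return The manifest list, invisibly.
#' @export
runPipeline <- function(config = list(), out_dir,
                        stages = c("simulate", "preprocess", "decode",
                                   "d2h", "stats", "report"),
                        seed = 1) {
    cfg <- pipelineConfig(config)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg$sim$seed <- seed
    scfg <- do.call(simConfig, cfg$sim)
    hash <- configHash(c(unclass(cfg), list(seed = seed)))
    pth <- function(...) file.path(out_dir, ...)

    for (stage in stages) {
        switch(stage,
        simulate = {
            sim <- genEpochs(scfg)
            writeEpochSet(sim$epochs, pth("epochs"))
            writeRTTable(genRTs(sim$truth, scfg), pth("rts.tsv"))
            jsonlite::write_json(
                list(scene = sim$truth$scenes,
                     category = sim$truth$category,
                     margin = sim$truth$scene_margin),
                pth("truth.json"), auto_unbox = TRUE, digits = NA)
            .stampManifest(out_dir, "simulate",
                           c("epochs.bin", "epochs.json", "rts.tsv",
                             "truth.json"), hash, seed)
        },
        preprocess = {
            .requireArtifact(pth(c("epochs.bin", "epochs.json")), "simulate")
            e <- readEpochSet(pth("epochs"))
            e <- filterCorrect(e)
            e <- noiseNormalize(e)
            writeEpochSet(e, pth("epochs_prep"))
            .stampManifest(out_dir, "preprocess",
                           c("epochs_prep.bin", "epochs_prep.json"),
                           hash, seed)
        },
        decode = {
            .requireArtifact(pth(c("epochs_prep.bin", "epochs_prep.json")),
                             "preprocess")
            e <- readEpochSet(pth("epochs_prep"))
            dec <- do.call(decodeCategory,
                           c(list(e = e, seed = seed), cfg$decode))
            acc <- dec$accuracy
            tidy <- data.frame(
                participant = rep(rownames(acc), ncol(acc)),
                time = rep(dec$times, each = nrow(acc)),
                scheme = "category", value = as.vector(acc))
            write.table(tidy, pth("decoding.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            writeDecisionValues(dec$dvals, pth("dvals"))
            .stampManifest(out_dir, "decode",
                           c("decoding.tsv", "dvals.bin", "dvals.json"),
                           hash, seed)
        },
        d2h = {
            .requireArtifact(pth(c("dvals.bin", "dvals.json")), "decode")
            .requireArtifact(pth("rts.tsv"), "simulate")
            dv <- readDecisionValues(pth("dvals"))
            rt <- readRTTable(pth("rts.tsv"))
            dth <- dthCorrelate(dv, rt, subset = cfg$dth$subset)
            tidy <- data.frame(
                participant = rep(dv@participants, ncol(dth$rho)),
                time = rep(dth$times, each = nrow(dth$rho)),
                pairing = paste(dth$pairing, collapse = "|"),
                subset = dth$subset, rho = as.vector(dth$rho))
            write.table(tidy, pth("dth.tsv"), sep = "\t", quote = FALSE,
                        row.names = FALSE)
            grp <- data.frame(time = dth$times, mean_rho = dth$group,
                              sem = apply(dth$rho, 2L, sd) /
                                  sqrt(pmax(dth$n_used, 1L)),
                              n = dth$n_used)
            write.table(grp, pth("dth_group.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            .stampManifest(out_dir, "d2h", c("dth.tsv", "dth_group.tsv"),
                           hash, seed)
        },
        stats = {
            .requireArtifact(pth("dth.tsv"), "d2h")
            tidy <- read.table(pth("dth.tsv"), sep = "\t", header = TRUE)
            parts <- unique(tidy$participant)
            times <- sort(unique(tidy$time))
            rho <- matrix(NA_real_, length(parts), length(times))
            for (i in seq_along(parts)) {
                sub <- tidy[tidy$participant == parts[i], ]
                rho[i, ] <- sub$rho[match(times, sub$time)]
            }
            sig <- sigTimecourse(rho, n_perm = cfg$stats$n_perm,
                                 tail = cfg$stats$tail,
                                 alpha = cfg$stats$alpha,
                                 seed = seed, times = times)
            out <- data.frame(time = times, p_raw = sig$p_raw,
                              p_adj = sig$p_adj, significant = sig$mask)
            write.table(out, pth("dth_sig.tsv"), sep = "\t", quote = FALSE,
                        row.names = FALSE)
            .stampManifest(out_dir, "stats", "dth_sig.tsv", hash, seed)
        },
        report = {
            man <- .readManifest(out_dir)
            hashes <- unique(vapply(man$artifacts, function(a)
                a$config_hash, ""))
            if (length(hashes) > 1)
                stop("artifact config hashes disagree (",
                     paste(hashes, collapse = " vs "),
                     "); refusing to mix runs in one report")
            .requireArtifact(pth(c("decoding.tsv", "dth.tsv",
                                   "dth_sig.tsv")), "stats")
            dec <- read.table(pth("decoding.tsv"), sep = "\t", header = TRUE)
            times <- sort(unique(dec$time))
            parts <- unique(dec$participant)
            accm <- matrix(NA_real_, length(parts), length(times))
            for (i in seq_along(parts)) {
                sub <- dec[dec$participant == parts[i], ]
                accm[i, ] <- sub$value[match(times, sub$time)]
            }
            dth <- read.table(pth("dth.tsv"), sep = "\t", header = TRUE)
            rhom <- matrix(NA_real_, length(parts), length(times))
            for (i in seq_along(parts)) {
                sub <- dth[dth$participant == parts[i], ]
                rhom[i, ] <- sub$rho[match(times, sub$time)]
            }
            sig <- read.table(pth("dth_sig.tsv"), sep = "\t", header = TRUE)
            acc_ci <- bootstrapPeakCI(accm, times, mode = "max", seed = seed)
            rho_ci <- bootstrapPeakCI(rhom, times, mode = "min", seed = seed)
            windows <- .maskWindows(sig$significant, times)
            rep_df <- data.frame(
                analysis = c("category decoding", "distance-to-hyperplane"),
                peak_value = c(acc_ci$peak_value, rho_ci$peak_value),
                peak_latency = c(acc_ci$peak_latency, rho_ci$peak_latency),
                ci_low = c(acc_ci$ci[1L], rho_ci$ci[1L]),
                ci_high = c(acc_ci$ci[2L], rho_ci$ci[2L]),
                significant_windows = c(NA, windows))
            write.table(rep_df, pth("report.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            .stampManifest(out_dir, "report", "report.tsv", hash, seed)
        },
        stop("unknown stage: ", stage))
    }
    invisible(.readManifest(out_dir))
}

# Compact "start:end" description of contiguous significant windows.
.maskWindows <- function(mask, times) {
    if (!any(mask)) return("none")
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    paste(sprintf("%g:%g", times[starts[r$values]], times[ends[r$values]]),
          collapse = ", ")
}
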