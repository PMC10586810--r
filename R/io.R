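# File formats: a binary tensor container with JSON sidecar for epochs and
# decision values, TSV for RT tables and RDMs, matrix + JSON sidecar for
# staged probabilities. All text is UTF-8, header row, "." decimal.

.DV_SCHEMA <- "scenedecode-dvals-1"
.SP_SCHEMA <- "scenedecode-stageprobs-1"

#' Hash a configuration
#'
#' MD5 of the canonical JSON serialization; used to stamp artifacts so a
#' report never mixes outputs of different configurations.
#'
#' @param cfg any list-like configuration.
#' @return Hex digest string.
#' @export
configHash <- function(cfg) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                             digits = 15, null = "null")),
               tmp)
    unname(tools::md5sum(tmp))
}

.writeTensor <- function(x, prefix, sidecar) {
    writeBin(as.numeric(x), paste0(prefix, ".bin"), size = 8,
             endian = "little")
    jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
}

.readTensor <- function(prefix, schema) {
    side <- jsonlite::read_json(paste0(prefix, ".json"),
                                simplifyVector = TRUE)
    if (is.null(side$schema) || side$schema != schema)
        stop("unknown schema version '", side$schema, "' (expected '",
             schema, "'); regenerate the artifact with this package version")
    n <- prod(unlist(side$dims))
    x <- readBin(paste0(prefix, ".bin"), what = "numeric", n = n + 1L,
                 size = 8, endian = "little")
    if (length(x) != n)
        stop("tensor size (", length(x), ") does not match the sidecar dims (",
             n, ")")
    list(x = array(x, unlist(side$dims)), side = side)
}

#' Write / read an EpochSet container
#'
#' Stores the (trial, channel, time) tensor as little-endian doubles in
#' \code{<prefix>.bin} with a JSON sidecar \code{<prefix>.json} carrying
#' dims, times, channel names, the trial metadata table, a schema version
#' and provenance. The round trip is loss-free.
#'
#' @param e an [EpochSet-class].
#' @param prefix file path prefix (without extension).
#' @return \code{writeEpochSet} the prefix, invisibly; \code{readEpochSet}
#'   the restored [EpochSet-class].
#' @export
writeEpochSet <- function(e, prefix) {
    .writeTensor(e@data, prefix, list(
        schema = .EPOCHSET_SCHEMA, dims = dim(e@data), times = e@times,
        channels = e@channels, trials = e@trials, provenance = e@metadata))
    invisible(prefix)
}

#' @rdname writeEpochSet
#' @export
readEpochSet <- function(prefix) {
    r <- .readTensor(prefix, .EPOCHSET_SCHEMA)
    trials <- as.data.frame(r$side$trials)
    if (nrow(trials) != dim(r$x)[1L])
        stop("sidecar trial table has ", nrow(trials),
             " rows but the tensor has ", dim(r$x)[1L], " trials")
    EpochSet(r$x, r$side$times, trials, r$side$channels,
             metadata = as.list(r$side$provenance))
}

#' Write / read scene decision values
#'
#' Same container scheme as [writeEpochSet()].
#'
#' @param dv a [SceneDecisionValues-class].
#' @param prefix file path prefix.
#' @export
writeDecisionValues <- function(dv, prefix) {
    .writeTensor(dv@d, prefix, list(
        schema = .DV_SCHEMA, dims = dim(dv@d), times = dv@times,
        scenes = dv@scenes, category = dv@category,
        participants = dv@participants, task = dv@task))
    invisible(prefix)
}

#' @rdname writeDecisionValues
#' @export
readDecisionValues <- function(prefix) {
    r <- .readTensor(prefix, .DV_SCHEMA)
    new("SceneDecisionValues", d = r$x, times = r$side$times,
        scenes = r$side$scenes, category = r$side$category,
        participants = r$side$participants, task = r$side$task)
}

#' Write / read an RT table as TSV
#'
#' @param rt data.frame (participant, scene, rt, ...).
#' @param path TSV path.
#' @export
writeRTTable <- function(rt, path) {
    write.table(rt, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeRTTable
#' @export
readRTTable <- function(path) {
    rt <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    if (!all(c("participant", "scene", "rt") %in% names(rt)))
        stop("RT table must have columns participant, scene, rt")
    rt
}

#' Write / read an RDM as square TSV with condition header
#'
#' @param rdm square dissimilarity matrix.
#' @param path TSV path.
#' @export
writeRDM <- function(rdm, path) {
    .checkRDM(rdm)
    df <- as.data.frame(rdm)
    names(df) <- if (!is.null(colnames(rdm))) colnames(rdm)
                 else sprintf("c%03d", seq_len(ncol(rdm)))
    write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeRDM
#' @export
readRDM <- function(path) {
    m <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE))
    .checkRDM(m, "file content")
    rownames(m) <- colnames(m)
    m
}

#' Write / read staged probabilities (matrix + JSON sidecar)
#'
#' The scene x (stage, class) probabilities go to \code{<prefix>.tsv}
#' (columns \code{stage<k>_<class>}), labels and schema to
#' \code{<prefix>.json}.
#'
#' @param sp a [StageProbabilities-class].
#' @param prefix file path prefix.
#' @export
writeStageProbs <- function(sp, prefix) {
    d <- dim(sp@p)
    M <- matrix(sp@p, d[1L], d[2L] * d[3L])
    colnames(M) <- as.vector(outer(seq_len(d[2L]), sp@classes,
                                   function(k, cl) sprintf("stage%d_%s", k, cl)))
    df <- data.frame(scene = sp@scenes, M, check.names = FALSE)
    write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(list(schema = .SP_SCHEMA, scenes = sp@scenes,
                              category = sp@category, classes = sp@classes,
                              n_stages = d[2L]),
                         paste0(prefix, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(prefix)
}

#' @rdname writeStageProbs
#' @export
readStageProbs <- function(prefix) {
    side <- jsonlite::read_json(paste0(prefix, ".json"),
                                simplifyVector = TRUE)
    if (is.null(side$schema) || side$schema != .SP_SCHEMA)
        stop("unknown schema version '", side$schema,
             "'; regenerate the artifact with this package version")
    df <- read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE,
                     check.names = FALSE)
    if (nrow(df) != length(side$scenes))
        stop("probability table row count does not match the sidecar scenes")
    M <- as.matrix(df[, -1L, drop = FALSE])
    p <- array(M, c(nrow(df), side$n_stages, length(side$classes)))
    StageProbabilities(p, scenes = side$scenes, category = side$category,
                       classes = side$classes)
}
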