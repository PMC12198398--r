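# Plain-text formats binding the pipeline together: per-subject gaze CSVs,
# frame-matrix TSVs, quality and clustering reports, POI annotations, a YAML
# run configuration and a JSON run manifest.

#' Default run configuration
#'
#' All thresholds default to the reference protocol: 60 ms blink
#' padding, z > 2 outlier exclusion, 5% / floor-4 minimum cluster size,
#' 5 s / 1 s smoothing, 0.5-45 Hz EEG band, 1 s epochs, 100 uV peak-to-peak,
#' more than 3 bad channels per bad epoch, more than 30% bad epochs per
#' excluded subject.
#'
#' @param ... named overrides of the nested defaults (top-level keys only).
#' @return nested named list.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    video = list(fps = 25, duration = 946.56, width = 1680, height = 1050),
    sampling_rate = 500,
    smoothing = list(window = 5, step = 1),
    clustering = list(min_size_floor = 4, fraction = 0.05,
                      epsilon_rule = "robust"),
    preprocessing = list(blink_pad_ms = 60, velocity_k = 5, outlier_z = 2),
    eeg = list(band = c(0.5, 45), epoch_len = 1, p2p_limit = 100,
               max_bad_channels = 3, max_bad_fraction = 0.30),
    seed = 1)
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  cfg
}

#' Read a run configuration from YAML
#'
#' Missing keys fall back to [defaultRunConfig()].
#'
#' @param path YAML file.
#' @return nested named list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else cfg[[k]] <- user[[k]]
  }
  cfg
}

#' Write one gaze recording as CSV
#'
#' Dialect: header `t_ms,x_px,y_px,pupil`, one row per sample, missing
#' positions as empty fields; the file name carries the subject id.
#'
#' @param rec a [GazeRecording-class].
#' @param dir output directory.
#' @return the file path, invisibly.
#' @export
writeGazeCSV <- function(rec, dir) {
  stopifnot(is(rec, "GazeRecording"))
  path <- file.path(dir, paste0(rec@subject, ".csv"))
  df <- data.frame(t_ms = rec@t,
                   x_px = ifelse(rec@valid, rec@x, NA_real_),
                   y_px = ifelse(rec@valid, rec@y, NA_real_),
                   pupil = rec@pupil)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read one gaze CSV
#'
#' @param path CSV file in the dialect of [writeGazeCSV()].
#' @param rate sampling rate to record on the object; default inferred from
#'   the median sample spacing.
#' @return a [GazeRecording-class].
#' @export
readGazeCSV <- function(path, rate = NULL) {
  raw <- read.csv(path, colClasses = "character")
  need <- c("t_ms", "x_px", "y_px", "pupil")
  if (!all(need %in% names(raw)))
    stop("'", path, "': expected header t_ms,x_px,y_px,pupil")
  num <- function(col) {
    v <- raw[[col]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!(v == "" | v == "NA") & is.na(out))
    if (length(bad))
      stop("'", basename(path), "': non-numeric ", col, " on line ",
           bad[1] + 1L)  # +1 for the header line
    out
  }
  t <- num("t_ms"); x <- num("x_px"); y <- num("y_px"); p <- num("pupil")
  if (anyNA(t)) stop("'", basename(path), "': missing timestamps")
  if (is.null(rate)) rate <- 1000 / stats::median(diff(t))
  new("GazeRecording",
      subject = sub("\\.csv$", "", basename(path)),
      rate = rate, t = t, x = x, y = y, pupil = p,
      valid = !is.na(x) & !is.na(y))
}

#' Read a directory of gaze CSVs
#'
#' @param path directory of per-subject CSV files.
#' @param rate optional sampling rate passed to [readGazeCSV()].
#' @return list of [GazeRecording-class] in lexicographic subject order.
#' @export
readGazeDir <- function(path, rate = NULL) {
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop("no gaze CSV files found in '", path, "'")
  ids <- sub("\\.csv$", "", basename(files))
  if (anyDuplicated(ids)) stop("duplicate subject ids in '", path, "'")
  lapply(files, readGazeCSV, rate = rate)
}

#' Write and read the frame-matrix TSV
#'
#' Long TSV with columns `frame`, `subject`, `x`, `y` (missing cells as
#' empty), plus a `#` comment header embedding fps, duration and screen so
#' the matrix round-trips exactly.
#'
#' @param fgm a [FrameGazeMatrix-class].
#' @param path output TSV file.
#' @return `writeFrameMatrix` the path invisibly; `readFrameMatrix` the
#'   reconstructed [FrameGazeMatrix-class].
#' @export
writeFrameMatrix <- function(fgm, path) {
  X <- SummarizedExperiment::assay(fgm, "x")
  Y <- SummarizedExperiment::assay(fgm, "y")
  hdr <- sprintf("# fps=%.10g duration=%.10g width=%.10g height=%.10g",
                 videoFps(fgm), videoDuration(fgm),
                 screenDims(fgm)[1], screenDims(fgm)[2])
  long <- data.frame(frame = rep(seq_len(nrow(X)) - 1L, ncol(X)),
                     subject = rep(colnames(X), each = nrow(X)),
                     x = as.vector(X), y = as.vector(Y))
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.table(long, con, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  close(con)
  invisible(path)
}

#' @rdname writeFrameMatrix
#' @export
readFrameMatrix <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z]+=[0-9.eE+-]+", hdr))[[1]]
  meta <- as.list(as.numeric(sub(".*=", "", kv)))
  names(meta) <- sub("=.*", "", kv)
  long <- read.csv(path, sep = "\t", skip = 1L)
  subs <- unique(long$subject)
  nF <- round(meta$duration * meta$fps)
  X <- matrix(NA_real_, nF, length(subs), dimnames = list(NULL, subs))
  Y <- X
  idx <- cbind(long$frame + 1L, match(long$subject, subs))
  X[idx] <- long$x
  Y[idx] <- long$y
  frameGazeMatrix(X, Y, fps = meta$fps, duration = meta$duration,
                  screen = c(meta$width, meta$height))
}

#' Write per-frame clustering and smoothed-series tables
#'
#' @param clustering a [GazeClustering-class].
#' @param series an [AttentionSeries-class].
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
writeClusterTables <- function(clustering, series, dir) {
  p1 <- file.path(dir, "frame_clustering.tsv")
  lab <- clustering@labels
  long <- data.frame(frame = rep(seq_len(nrow(lab)) - 1L, ncol(lab)),
                     subject = rep(colnames(lab), each = nrow(lab)),
                     label = as.vector(lab))
  long <- merge(long, clustering@params, by = "frame", sort = TRUE)
  utils::write.table(long[order(long$frame, long$subject), ], p1,
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  p2 <- file.path(dir, "smoothed_series.tsv")
  sm <- data.frame(second = series@grid,
                   cluster_count = series@smoothedClusterCount,
                   series@smoothedGCM, check.names = FALSE)
  utils::write.table(sm, p2, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  p3 <- file.path(dir, "gcm_summary.csv")
  write.csv(data.frame(subject = names(series@gcm) %||%
                         colnames(series@membership),
                       gcm = series@gcm), p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read a POI annotation CSV
#'
#' @param path CSV with columns start, end, label (seconds).
#' @return data.frame sorted by start.
#' @export
readPOICSV <- function(path) {
  poi <- read.csv(path)
  need <- c("start", "end", "label")
  if (!all(need %in% names(poi))) stop("POI file needs start,end,label")
  poi[order(poi$start), need]
}

#' Write the JSON run manifest
#'
#' Embeds the full effective configuration, package version, seed and
#' per-stage counts so every artifact is auditable; the timestamp is the
#' only field expected to differ between identical runs.
#'
#' @param path output JSON file.
#' @param config effective configuration list.
#' @param counts named list of per-stage counts.
#' @return the path, invisibly.
#' @export
writeManifest <- function(path, config, counts) {
  manifest <- list(package = "gazecluster",
                   version = as.character(packageVersion("gazecluster")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = config, counts = counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
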