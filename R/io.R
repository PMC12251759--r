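#' Write a recording (and labels) to CSV with a JSON sidecar
#'
#' One CSV per trial, columns = channels with a header row of channel names,
#' comma-separated, `.` decimal, UTF-8; motion labels in a companion
#' `<trial>_labels.csv` at 20 Hz; metadata (sampling rate, channel names,
#' position tag, ids) in a JSON sidecar `<trial>.json`.
#'
#' @param rec An [emg_recording()].
#' @param dir Output directory (created if needed).
#' @param labels Optional [motion_labels()].
#' @return The path prefix (`dir/trial_id`), invisibly.
#' @export
write_recording <- function(rec, dir, labels = NULL) {
  stopifnot(inherits(rec, "emg_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- file.path(dir, rec$trial_id)
  df <- as.data.frame(t(rec$signal))
  names(df) <- rec$channel_names
  data.table::fwrite(df, paste0(prefix, ".csv"))
  meta <- list(trial_id = rec$trial_id, subject_id = rec$subject_id,
               position_tag = rec$position_tag, fs = rec$fs,
               channel_names = rec$channel_names,
               n_samples = ncol(rec$signal))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "motion_labels"))
    utils::write.csv(data.frame(label = labels$labels),
                     paste0(prefix, "_labels.csv"), row.names = FALSE)
  }
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#'
#' Validates finiteness (an `NA`/`NaN` cell raises an error naming its row and
#' column) and, when `expect_fs` is given, the sampling rate — a mismatch is
#' an explicit error, never a silent resample.
#'
#' @param prefix Path prefix (`dir/trial_id`, without extension).
#' @param expect_fs Optional expected sampling rate in Hz.
#' @return List with `recording` ([emg_recording()]) and `labels`
#'   ([motion_labels()] or `NULL` if no labels file exists).
#' @export
read_recording <- function(prefix, expect_fs = NULL) {
  csv <- paste0(prefix, ".csv")
  side <- paste0(prefix, ".json")
  if (!file.exists(csv)) stop("no such file: ", csv, call. = FALSE)
  if (!file.exists(side))
    stop("missing JSON sidecar: ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  df <- data.table::fread(csv, check.names = FALSE, data.table = FALSE)
  if (nrow(df) < 1L) stop("empty trial: ", csv, call. = FALSE)
  mat <- as.matrix(df)
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite sample in ", csv, " at row ", bad[1L, 1L], ", column '",
         colnames(mat)[bad[1L, 2L]], "'", call. = FALSE)
  if (length(meta$channel_names) != ncol(mat))
    stop("sidecar declares ", length(meta$channel_names),
         " channels but CSV has ", ncol(mat), call. = FALSE)
  # re-map CSV columns to the sidecar channel order by name
  if (!identical(colnames(mat), meta$channel_names)) {
    if (!setequal(colnames(mat), meta$channel_names))
      stop("channel names disagree between CSV and sidecar", call. = FALSE)
    mat <- mat[, meta$channel_names, drop = FALSE]
  }
  if (!is.null(expect_fs) && meta$fs != expect_fs)
    stop("sampling rate mismatch: file has ", meta$fs, " Hz, expected ",
         expect_fs, " Hz (no silent resampling)", call. = FALSE)
  rec <- emg_recording(t(mat), fs = meta$fs, channel_names = meta$channel_names,
                       position_tag = meta$position_tag,
                       trial_id = meta$trial_id, subject_id = meta$subject_id)
  labels <- NULL
  labf <- paste0(prefix, "_labels.csv")
  if (file.exists(labf))
    labels <- motion_labels(utils::read.csv(labf)$label)
  list(recording = rec, labels = labels)
}

#' Write a generated benchmark to disk
#'
#' One CSV + sidecar per trial plus a `manifest.json` listing subject, trial,
#' position, seed and sampling rate for every trial — the self-describing
#' dataset layout the CLI consumes.
#'
#' @param bench A [generate_benchmark()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(bench$trials)) {
    tr <- bench$trials[[key]]
    rec <- tr$recording
    rec$trial_id <- key   # unique on disk across positions
    write_recording(rec, dir, tr$labels)
  }
  jsonlite::write_json(bench$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a benchmark directory written by [write_benchmark()]
#'
#' @param dir Directory containing per-trial CSVs and `manifest.json`.
#' @return A list like [generate_benchmark()]'s: `trials`, `manifest`.
#' @export
read_benchmark <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest.json in ", dir, call. = FALSE)
  manifest <- tibble::as_tibble(jsonlite::read_json(mf, simplifyVector = TRUE))
  trials <- list()
  for (key in manifest$key) {
    r <- read_recording(file.path(dir, key))
    trials[[key]] <- list(recording = r$recording, labels = r$labels)
  }
  list(trials = trials, manifest = manifest)
}
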