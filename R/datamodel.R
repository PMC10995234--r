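#' Class labels
#'
#' Cough is the positive class throughout the package. Labels are stored
#' as the strings `"cough"` and `"non_cough"`.
#' @name labels
#' @keywords internal
NULL

.LABELS <- c("cough", "non_cough")
.POSITIVE <- "cough"

check_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || !label %in% .LABELS) {
    stop("label must be one of: ", paste(.LABELS, collapse = ", "),
         call. = FALSE)
  }
  label
}

#' Construct a single accelerometer recording
#'
#' A recording is one fixed-duration tri-axial acceleration trace with its
#' subject identity and class label. The three axis vectors must have equal,
#' positive length. Acceleration units are arbitrary but must be consistent
#' across a cohort; the pipeline is unit-agnostic.
#'
#' @param record_id Unique identifier of the recording.
#' @param subject_id Identifier of the subject who produced it.
#' @param label `"cough"` or `"non_cough"`.
#' @param fs Sampling rate in Hz (> 0).
#' @param ax,ay,az Numeric sample vectors for the x (lateral), y (vertical)
#'   and z (anterior-posterior) axes.
#' @return An object of class `"recording"`.
#' @export
recording <- function(record_id, subject_id, label, fs, ax, ay, az) {
  n <- length(ax)
  if (n == 0L || length(ay) != n || length(az) != n) {
    stop("record '", record_id, "': ax, ay, az must be non-empty and of ",
         "equal length", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("record '", record_id, "': fs must be a positive scalar",
         call. = FALSE)
  }
  structure(
    list(record_id = as.character(record_id),
         subject_id = as.character(subject_id),
         label = check_label(label),
         fs = as.numeric(fs),
         ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az)),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s> subject %s, %s, %d samples @ %g Hz\n",
              x$record_id, x$subject_id, x$label, length(x$ax), x$fs))
  invisible(x)
}

#' Construct a cohort manifest
#'
#' The manifest lists every recording in a cohort together with its subject,
#' label and (optionally) the CSV file holding its samples. All record ids
#' must be unique; one sampling rate applies to the whole cohort.
#'
#' @param records A data frame with columns `record_id`, `subject_id`,
#'   `label` and optionally `path`.
#' @param fs Sampling rate in Hz shared by all recordings.
#' @return An object of class `"cohort_manifest"` (a data frame with an
#'   `fs` attribute).
#' @export
cohort_manifest <- function(records, fs) {
  need <- c("record_id", "subject_id", "label")
  if (!all(need %in% names(records))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(records$record_id)) {
    stop("record_ids must be unique", call. = FALSE)
  }
  if (!all(records$label %in% .LABELS)) {
    stop("manifest labels must be 'cough' or 'non_cough'", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar", call. = FALSE)
  }
  records$record_id <- as.character(records$record_id)
  records$subject_id <- as.character(records$subject_id)
  out <- as.data.frame(records, stringsAsFactors = FALSE)
  attr(out, "fs") <- as.numeric(fs)
  class(out) <- c("cohort_manifest", "data.frame")
  out
}

#' Write a cohort to disk
#'
#' Materializes a list of recordings as one CSV per record (columns
#' `sample_index`, `ax`, `ay`, `az`), a `manifest.csv` naming each record's
#' subject, label and file, and a `cohort.json` sidecar holding the sampling
#' rate. All values are written with 17 significant digits so a read-back
#' reproduces the samples bit-exactly.
#'
#' @param recordings A list of [recording()] objects sharing one `fs`.
#' @param dir Output directory (created if absent).
#' @return The path to the written `manifest.csv`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(recordings, dir) {
  if (!length(recordings)) stop("no recordings to write", call. = FALSE)
  fs <- unique(vapply(recordings, `[[`, numeric(1), "fs"))
  if (length(fs) != 1L) stop("recordings disagree on fs", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec_dir <- file.path(dir, "records")
  dir.create(rec_dir, showWarnings = FALSE)
  rows <- lapply(recordings, function(r) {
    path <- file.path("records", paste0(r$record_id, ".csv"))
    df <- data.frame(sample_index = seq_along(r$ax) - 1L,
                     ax = r$ax, ay = r$ay, az = r$az)
    write_csv_exact(df, file.path(dir, path))
    data.frame(record_id = r$record_id, subject_id = r$subject_id,
               label = r$label, path = path, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(fs = fs), file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.csv"))
}

#' Read a cohort from disk
#'
#' Reads a `manifest.csv` written by [write_cohort()] (or prepared by hand
#' in the same layout) plus its `cohort.json` sampling-rate sidecar, and
#' loads every per-record CSV. Paths in the manifest are resolved relative
#' to the manifest's directory.
#'
#' @param manifest_path Path to `manifest.csv`.
#' @return A list with elements `manifest` (a [cohort_manifest()]) and
#'   `recordings` (a list of [recording()] objects in manifest order).
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest file not found: ", manifest_path, call. = FALSE)
  }
  dir <- dirname(manifest_path)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  side <- file.path(dir, "cohort.json")
  if (!file.exists(side)) stop("missing sidecar: ", side, call. = FALSE)
  fs <- jsonlite::read_json(side)$fs
  manifest <- cohort_manifest(man, fs)
  recordings <- lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(dir, man$path[i])
    if (!file.exists(path)) {
      stop("record '", man$record_id[i], "': file not found: ", path,
           call. = FALSE)
    }
    df <- read.csv(path)
    need <- c("sample_index", "ax", "ay", "az")
    if (!all(need %in% names(df))) {
      stop("record '", man$record_id[i], "': expected columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    recording(man$record_id[i], man$subject_id[i], man$label[i], fs,
              df$ax, df$ay, df$az)
  })
  list(manifest = manifest, recordings = recordings)
}

# CSV writer preserving 17 significant digits — enough to round-trip
# any double bit-exactly.
write_csv_exact <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17,
                                                 format = "g"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' The 43 time-domain feature names
#'
#' Returns the fixed, ordered registry of feature column names: ten
#' statistics (minimum, maximum, range, RMS, skewness, kurtosis,
#' interquartile range, variance, approximate entropy, median absolute
#' deviation) on each of the four channels (x, y, z axes and the vector
#' magnitude), plus the three inter-axis Pearson correlations.
#'
#' @return A character vector of length 43.
#' @export
feature_names <- function() {
  stats <- c("Min", "Max", "Diff", "RMS", "Skewness", "Kurtosis",
             "IQR", "Var", "Ent", "MAD")
  chans <- c("X", "Y", "Z", "Mag")
  c(as.vector(t(outer(stats, chans, paste, sep = "_"))),
    "Corr_xy", "Corr_yz", "Corr_xz")
}

.META_COLS <- c("window_id", "record_id", "subject_id", "label")

#' Construct / validate a feature table
#'
#' A feature table is a data frame with the four metadata columns
#' `window_id`, `record_id`, `subject_id`, `label` followed by the 43
#' feature columns in registry order ([feature_names()]). No missing
#' values are allowed.
#'
#' @param df A data frame containing all required columns.
#' @return The validated data frame with class `"feature_table"`.
#' @export
feature_table <- function(df) {
  fn <- feature_names()
  missing_cols <- setdiff(c(.META_COLS, fn), names(df))
  if (length(missing_cols)) {
    stop("feature table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, c(.META_COLS, fn)]
  if (nrow(df) && anyNA(df[, fn])) {
    stop("feature table contains missing values", call. = FALSE)
  }
  if (nrow(df) && !all(df$label %in% .LABELS)) {
    stop("feature table labels must be 'cough' or 'non_cough'",
         call. = FALSE)
  }
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Extract the numeric feature matrix from a feature table
#' @param table A [feature_table()].
#' @return A numeric matrix with the 43 feature columns.
#' @keywords internal
#' @export
feature_matrix <- function(table) {
  as.matrix(table[, feature_names(), drop = FALSE])
}

#' Write / read a feature table CSV
#'
#' The CSV header is the four metadata columns followed by the 43 feature
#' names in registry order. Values round-trip at 15 significant digits.
#'
#' @param table A [feature_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a [feature_table()] (reader).
#' @export
write_feature_table <- function(table, path) {
  table <- feature_table(table)
  write_csv_exact(as.data.frame(table), path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(window_id = "character",
                                record_id = "character",
                                subject_id = "character",
                                label = "character"))
  feature_table(df)
}

#' Construct a feature ranking result
#'
#' Ranks must be a permutation of `1..43` over the registry feature names,
#' with rank 1 the most important feature.
#'
#' @param method Method identifier (e.g. `"XGBoost"`, `"RFE_10"`).
#' @param ranks Named integer vector: feature name -> rank.
#' @param scores Optional named numeric vector of the raw importance
#'   scores the ranks were derived from.
#' @return An object of class `"ranking_result"`.
#' @export
ranking_result <- function(method, ranks, scores = NULL) {
  fn <- feature_names()
  if (!setequal(names(ranks), fn)) {
    stop("ranks must be named by the 43 registry features", call. = FALSE)
  }
  ranks <- as.integer(ranks[fn])
  names(ranks) <- fn
  if (!setequal(ranks, seq_along(fn))) {
    stop("ranks must be a permutation of 1..", length(fn), call. = FALSE)
  }
  structure(list(method = method, ranks = ranks, scores = scores),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  top <- names(sort(x$ranks))[1:5]
  cat(sprintf("<ranking %s> top 5: %s\n", x$method,
              paste(top, collapse = ", ")))
  invisible(x)
}

#' Top-k feature set of a ranking
#' @param ranking A [ranking_result()].
#' @param k Number of features.
#' @return Character vector of the k features ranked 1..k.
#' @export
top_features <- function(ranking, k) {
  names(sort(ranking$ranks))[seq_len(k)]
}

#' Confusion counts
#'
#' @param TP,TN,FP,FN Nonnegative integer counts; cough is the positive
#'   class.
#' @return An object of class `"confusion_counts"`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  }
  structure(as.list(setNames(as.integer(round(v)), names(v))),
            class = "confusion_counts")
}
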