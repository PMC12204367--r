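#' Read ABR waveforms from a wide CSV file
#'
#' The wide dialect carries one waveform per row: header columns `subject`,
#' `frequency_khz`, `level_db`, optionally `source`, followed by sample
#' columns `t0..t{K-1}`. Rows are grouped into stacks keyed by
#' (subject, frequency) and sorted by level, loudest first. Voltages are kept
#' at their native length; resampling onto the canonical grid is a separate
#' step ([resample_to_grid()]).
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal separator).
#' @param unit Unit of the voltage columns: `"uV"` (default, no conversion)
#'   or `"V"` (converted to uV on ingest).
#' @return List of [abr_stack()], named `"subject|frequency"`.
#' @seealso [read_abr_tsv()] for the long dialect.
#' @export
read_abr_csv <- function(path, unit = c("uV", "V")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("subject", "frequency_khz", "level_db")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("wide CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  tcols <- grep("^t[0-9]+$", names(df), value = TRUE)
  if (length(tcols) == 0L) {
    stop("wide CSV has no sample columns (expected t0, t1, ...)")
  }
  tcols <- tcols[order(as.integer(sub("^t", "", tcols)))]
  if (nrow(df) == 0L) return(list())

  freq <- suppressWarnings(as.numeric(df$frequency_khz))
  lev <- suppressWarnings(as.numeric(df$level_db))
  bad <- which(!is.finite(freq) | !is.finite(lev))
  if (length(bad) > 0L) {
    stop("non-numeric frequency/level in data row(s): ",
         paste(bad, collapse = ", "))
  }
  key <- paste(df$subject, freq, lev, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (subject, frequency, level) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  src <- if ("source" %in% names(df)) df$source else rep("default", nrow(df))
  scale <- if (unit == "V") 1e6 else 1

  waves <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    v <- suppressWarnings(as.numeric(unlist(df[i, tcols], use.names = FALSE)))
    if (anyNA(v)) {
      stop(sprintf("non-numeric voltage value in data row %d", i))
    }
    waves[[i]] <- abr_waveform(df$subject[i], freq[i], lev[i], v * scale,
                               source_label = src[i])
  }
  group_into_stacks(waves)
}

#' Read ABR waveforms from a long TSV file
#'
#' The long dialect carries one sample per row with columns `subject`,
#' `frequency_khz`, `level_db`, `time_ms`, `voltage_uv` (plus optional
#' `source`). Within each (subject, frequency, level) group `time_ms` must be
#' strictly increasing; the native time grid is retained per waveform.
#'
#' @inheritParams read_abr_csv
#' @return List of [abr_stack()], named `"subject|frequency"`. A header-only
#'   file yields an empty list.
#' @export
read_abr_tsv <- function(path, unit = c("uV", "V")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("subject", "frequency_khz", "level_db", "time_ms",
                "voltage_uv")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("long TSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) return(list())
  scale <- if (unit == "V") 1e6 else 1
  src <- if ("source" %in% names(df)) df$source else rep("default", nrow(df))

  key <- paste(df$subject, df$frequency_khz, df$level_db, sep = "|")
  waves <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    tms <- as.numeric(df$time_ms[idx])
    if (any(diff(tms) <= 0)) {
      stop("time_ms not strictly increasing within group ", k)
    }
    waves[[length(waves) + 1L]] <- abr_waveform(
      df$subject[idx[1]], df$frequency_khz[idx[1]], df$level_db[idx[1]],
      as.numeric(df$voltage_uv[idx]) * scale, times_ms = tms,
      source_label = src[idx[1]])
  }
  group_into_stacks(waves)
}

group_into_stacks <- function(waves) {
  key <- vapply(waves, function(w) paste(w$subject_id, w$frequency_khz,
                                         sep = "|"), character(1))
  out <- lapply(split(waves, factor(key, levels = unique(key))), abr_stack)
  out[unique(key)]
}

metrics_columns <- c("subject", "frequency_khz", "level_db",
                     "wave1_amplitude_uv", "wave1_latency_ms", "threshold_db")

#' Write a per-waveform metrics table to CSV
#'
#' Columns are emitted in a fixed order (subject, frequency_khz, level_db,
#' wave1_amplitude_uv, wave1_latency_ms, threshold_db) and rows sorted by
#' subject, then frequency ascending, then level descending. A stack with no
#' detectable response at any level has threshold `Inf`, written as the
#' literal `NR` ("no response"); missing per-waveform metrics are written as
#' empty cells.
#'
#' @param rows Data frame with (at least) the columns above; `threshold_db`
#'   may contain `Inf` for no-response stacks.
#' @param path Output path.
#' @return Invisibly, the sorted data frame that was written.
#' @export
write_metrics_csv <- function(rows, path) {
  miss <- setdiff(metrics_columns, names(rows))
  if (length(miss) > 0L) {
    stop("metrics table is missing column(s): ", paste(miss, collapse = ", "))
  }
  rows <- rows[metrics_columns]
  ord <- order(rows$subject, rows$frequency_khz, -rows$level_db)
  rows <- rows[ord, , drop = FALSE]
  out <- rows
  out$threshold_db <- ifelse(is.infinite(rows$threshold_db), "NR",
                             as.character(rows$threshold_db))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(rows)
}

#' Read back a metrics CSV written by [write_metrics_csv()]
#'
#' @param path Path to the metrics CSV.
#' @return Data frame with numeric columns; the `NR` sentinel becomes `Inf`.
#' @export
read_metrics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(metrics_columns, names(df))
  if (length(miss) > 0L) {
    stop("metrics CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  thr <- ifelse(df$threshold_db == "NR", Inf,
                suppressWarnings(as.numeric(df$threshold_db)))
  data.frame(
    subject = df$subject,
    frequency_khz = as.numeric(df$frequency_khz),
    level_db = as.numeric(df$level_db),
    wave1_amplitude_uv = suppressWarnings(as.numeric(df$wave1_amplitude_uv)),
    wave1_latency_ms = suppressWarnings(as.numeric(df$wave1_latency_ms)),
    threshold_db = thr,
    stringsAsFactors = FALSE)
}

#' Write a list of stacks to the wide CSV dialect
#'
#' Inverse of [read_abr_csv()] for waveforms sharing one common length.
#'
#' @param stacks List of [abr_stack()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_abr_csv <- function(stacks, path) {
  m <- stacks_to_matrix(stacks)
  df <- data.frame(subject = m$meta$subject_id,
                   frequency_khz = m$meta$frequency_khz,
                   level_db = m$meta$level_db,
                   source = m$meta$source_label,
                   stringsAsFactors = FALSE)
  volt <- as.data.frame(m$x)
  names(volt) <- paste0("t", seq_len(ncol(m$x)) - 1L)
  utils::write.csv(cbind(df, volt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
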