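# CSV + JSON-sidecar record dialect and annotation files.
# The CSV carries two numeric columns (time, amplitude_mV); the sidecar
# carries {record_id, fs, lead} and optionally time_unit ("s" or "ms").

#' Read an ECG record from the CSV/JSON dialect
#'
#' The CSV must have two numeric columns, time and amplitude in mV; the JSON
#' sidecar supplies `record_id`, `fs` (Hz), `lead` and optionally
#' `time_unit` (`"s"`, the default, or `"ms"`). The time column is checked
#' against the sidecar sampling rate: any timestamp deviating from its
#' nominal position by more than half a sample period rejects the file.
#'
#' @param path CSV file path.
#' @param sidecar_path JSON sidecar path.
#' @return An [ecg_record].
#' @export
read_csv_record <- function(path, sidecar_path) {
  if (!file.exists(path)) stop("CSV format error: missing file ", path)
  if (!file.exists(sidecar_path)) {
    stop("CSV format error: missing sidecar ", sidecar_path)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (field in c("record_id", "fs", "lead")) {
    if (is.null(meta[[field]])) {
      stop("CSV format error: sidecar lacks field '", field, "'")
    }
  }
  fs <- as.numeric(meta$fs)
  unit <- if (is.null(meta$time_unit)) "s" else meta$time_unit
  if (!unit %in% c("s", "ms")) {
    stop("CSV format error: time_unit must be 's' or 'ms', got '", unit, "'")
  }
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("CSV format error: need two columns, got ", ncol(df))
  tm <- as.numeric(df[[1L]])
  amp <- as.numeric(df[[2L]])
  if (anyNA(amp)) {
    stop("CSV format error: NaN amplitude at row ", which(is.na(amp))[1L])
  }
  if (anyNA(tm)) stop("CSV format error: non-numeric time at row ", which(is.na(tm))[1L])
  if (length(tm) > 1L && any(diff(tm) <= 0)) {
    stop("CSV format error: non-monotone time column at row ",
         which(diff(tm) <= 0)[1L] + 1L)
  }
  t_s <- if (unit == "ms") tm / 1000 else tm
  nominal <- t_s[1L] + (seq_along(t_s) - 1L) / fs
  if (any(abs(t_s - nominal) > 0.5 / fs)) {
    stop("CSV format error: timestamps inconsistent with fs=", fs,
         " Hz at row ", which(abs(t_s - nominal) > 0.5 / fs)[1L])
  }
  ecg_record(amp, fs = fs, record_id = meta$record_id, lead = meta$lead,
             adc_resolution_bits = if (is.null(meta$adc_resolution_bits)) NULL
                                   else meta$adc_resolution_bits)
}

#' Write an ECG record in the CSV/JSON dialect
#'
#' @param record An [ecg_record].
#' @param path Output CSV path.
#' @param sidecar_path Output JSON sidecar path.
#' @param digits Decimal places kept for time and amplitude columns.
#' @param time_unit `"s"` or `"ms"` for the time column (recorded in the
#'   sidecar so the reader recovers identical seconds).
#' @return Invisibly, `path`.
#' @export
write_csv_record <- function(record, path, sidecar_path, digits = 6,
                             time_unit = "s") {
  stopifnot(inherits(record, "ecg_record"))
  t_s <- (seq_len(n_samples(record)) - 1L) / record$fs
  tm <- if (time_unit == "ms") t_s * 1000 else t_s
  df <- data.frame(
    time = round(tm, digits),
    amplitude_mV = round(record$samples, digits)
  )
  names(df)[1L] <- if (time_unit == "ms") "time_ms" else "time_s"
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(record_id = record$record_id, fs = record$fs,
               lead = record$lead, time_unit = time_unit)
  if (!is.null(record$adc_resolution_bits)) {
    meta$adc_resolution_bits <- record$adc_resolution_bits
  }
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Allowed annotation vocabulary for the package's own files: WFDB beat
# mnemonics plus the record-level rhythm labels.
.annotation_vocab <- function() {
  unique(c(unname(.WFDB_ANN_CODES), label_vocabulary(), "NORMAL"))
}

#' Write beat annotations
#'
#' @param path Output path.
#' @param annotations A [beat_annotations] data frame (sorted by `r_index`).
#' @param format `"json"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(path, annotations, format = c("json", "csv")) {
  format <- match.arg(format)
  if (nrow(annotations) > 1L && any(diff(annotations$r_index) <= 0L)) {
    stop("write_annotations: annotations must be sorted by r_index")
  }
  bad <- setdiff(unique(annotations$label), .annotation_vocab())
  if (length(bad)) {
    stop("write_annotations: unknown label code(s) ",
         paste(bad, collapse = ", "), "; allowed: ",
         paste(.annotation_vocab(), collapse = " "))
  }
  if (format == "json") {
    jsonlite::write_json(
      lapply(seq_len(nrow(annotations)), function(i) {
        list(r_index = annotations$r_index[i],
             label = annotations$label[i],
             source = annotations$source[i])
      }),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(annotations, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read beat annotations written by [write_annotations()]
#'
#' @param path Annotation file path.
#' @param format `"json"` or `"csv"`; guessed from the extension by default.
#' @return A [beat_annotations] data frame.
#' @export
read_annotations <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (format == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (length(x) == 0L) return(beat_annotations(integer(0)))
    beat_annotations(x$r_index, label = x$label, source = x$source)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!nrow(df)) return(beat_annotations(integer(0)))
    beat_annotations(df$r_index, label = df$label, source = df$source)
  }
}
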