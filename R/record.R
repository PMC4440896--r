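#' Construct a single-lead ECG record
#'
#' The central data container of the package: a uniformly sampled voltage
#' trace with its sampling metadata. Amplitudes are always stored in
#' millivolts; unit conversion happens at I/O boundaries only. Sample
#' indexing throughout the package is 0-based and windows are half-open
#' `[start, end)`.
#'
#' @param samples Numeric vector of amplitudes in mV (length >= 2, finite).
#' @param fs Sampling rate in Hz (> 0).
#' @param record_id Character record identifier.
#' @param lead Lead label (free text, e.g. `"I"` or `"MLII"`).
#' @param adc_resolution_bits Optional integer ADC resolution.
#' @return An object of class `ecg_record` with fields `record_id`,
#'   `samples`, `fs`, `lead`, `adc_resolution_bits` and derived
#'   `duration_s = n_samples / fs`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1 * seq(0, 5, by = 1 / 256)), fs = 256)
#' rec$duration_s
#' @export
ecg_record <- function(samples, fs, record_id = "record", lead = "I",
                       adc_resolution_bits = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("ecg_record: need at least 2 samples, got ", length(samples))
  }
  if (!all(is.finite(samples))) {
    stop("ecg_record: all amplitudes must be finite; first bad sample at index ",
         which(!is.finite(samples))[1L] - 1L)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("ecg_record: fs must be a single positive number")
  }
  structure(
    list(
      record_id = as.character(record_id)[1L],
      samples = samples,
      fs = as.numeric(fs),
      lead = as.character(lead)[1L],
      adc_resolution_bits = if (is.null(adc_resolution_bits)) NULL
                            else as.integer(adc_resolution_bits),
      duration_s = length(samples) / fs
    ),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d samples @ %g Hz (%.2f s), lead %s\n",
              x$record_id, length(x$samples), x$fs, x$duration_s, x$lead))
  invisible(x)
}

#' Number of samples in an ECG record
#' @param record An `ecg_record`.
#' @return Integer sample count.
#' @export
n_samples <- function(record) length(record$samples)

#' Construct a beat annotation table
#'
#' Carrier for reference annotations (e.g. WFDB `.atr` content) and for
#' detector output. Indices are 0-based sample positions of R peaks and
#' must be strictly increasing.
#'
#' @param r_index Integer vector of 0-based R-peak sample indices.
#' @param label Character vector of beat/rhythm codes (recycled if length 1).
#' @param source Either `"reference"` or `"detected"` (recycled).
#' @param n_samples Optional record length used to bound-check indices.
#' @return A `data.frame` with columns `r_index`, `label`, `source`.
#' @export
beat_annotations <- function(r_index, label = "N", source = "reference",
                             n_samples = NULL) {
  r_index <- as.integer(r_index)
  if (length(r_index) && any(r_index < 0L)) {
    stop("beat_annotations: negative r_index")
  }
  if (!is.null(n_samples) && length(r_index) && any(r_index >= n_samples)) {
    stop("beat_annotations: r_index beyond record end")
  }
  if (length(r_index) > 1L && any(diff(r_index) <= 0L)) {
    stop("beat_annotations: r_index must be strictly increasing")
  }
  src <- rep_len(as.character(source), length(r_index))
  if (length(r_index) && !all(src %in% c("reference", "detected"))) {
    stop("beat_annotations: source must be 'reference' or 'detected'")
  }
  data.frame(
    r_index = r_index,
    label = rep_len(as.character(label), length(r_index)),
    source = src,
    stringsAsFactors = FALSE
  )
}
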