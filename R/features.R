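# Record-level feature extraction: the wavelet statistics block, the
# peak-segment block built on the delineated fiducials, and the per-beat
# rule features consumed by the premature-beat detector.

#' Feature-extraction configuration
#'
#' @param scales Odd beat-window sizes over which local RR / R-amplitude
#'   statistics are pooled.
#' @param levels Wavelet decomposition depth.
#' @param stat_levels Detail levels pooled by [wavelet_features()].
#' @return A list of class `features_config`.
#' @export
features_config <- function(scales = c(3L, 5L, 9L), levels = 4L,
                            stat_levels = c(3L, 4L)) {
  if (any(scales %% 2L != 1L) || any(scales < 1L)) {
    stop("features_config: scales must be odd positive integers")
  }
  structure(list(scales = as.integer(scales), levels = as.integer(levels),
                 stat_levels = as.integer(stat_levels)),
            class = "features_config")
}

# mean over sliding windows of w consecutive values of a statistic
.windowed_stat <- function(v, w, fun) {
  m <- length(v)
  if (m == 0L) return(NA_real_)
  if (m <= w) return(fun(v))
  mean(vapply(seq_len(m - w + 1L), function(i) fun(v[i:(i + w - 1L)]),
              numeric(1)))
}

#' Peak-segment feature block
#'
#' Local statistics of RR widths and R amplitudes in sliding windows of
#' `scales` consecutive beats (record-level value = mean over windows),
#' the average count of strict signal maxima between consecutive R peaks,
#' the missing-P ("fake P") rate, and the mean segment lengths, wave
#' widths and P/T amplitudes.
#'
#' @param fiducials A `fiducial_set` from [delineate()].
#' @param fs Sampling rate (Hz).
#' @param scales Odd beat-window sizes.
#' @param signal Optional preprocessed signal (mV) for the
#'   maxima-between-R count; skipped (NA) when missing.
#' @return Named numeric vector. With fewer than two beats every entry is
#'   NA and a warning is emitted.
#' @export
peak_segment_features <- function(fiducials, fs, scales = c(3L, 5L, 9L),
                                  signal = NULL) {
  per_scale <- c("rr_lmax", "rr_lmin", "rr_lmean", "rr_lvar",
                 "ramp_lmax", "ramp_lmin", "ramp_lmean")
  nm <- c(vapply(scales, function(w) paste0(per_scale, "_w", w), character(7)))
  nm <- c(nm, "n_local_maxima_between_r", "fake_p_rate",
          "mean_pr_s", "mean_qt_s", "mean_st_s", "mean_qrs_s",
          "mean_p_width_s", "mean_t_width_s", "mean_p_amp", "mean_t_amp")
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (nrow(fiducials) < 2L) {
    warning("peak_segment_features: fewer than 2 beats; all features NA")
    return(out)
  }
  rr <- diff(fiducials$r_index) / fs
  ramp <- fiducials$r_amp
  for (w in scales) {
    out[paste0("rr_lmax_w", w)] <- .windowed_stat(rr, w, max)
    out[paste0("rr_lmin_w", w)] <- .windowed_stat(rr, w, min)
    out[paste0("rr_lmean_w", w)] <- .windowed_stat(rr, w, mean)
    out[paste0("rr_lvar_w", w)] <- .windowed_stat(rr, w, function(v)
      if (length(v) > 1L) stats::var(v) else 0)
    out[paste0("ramp_lmax_w", w)] <- .windowed_stat(ramp, w, max)
    out[paste0("ramp_lmin_w", w)] <- .windowed_stat(ramp, w, min)
    out[paste0("ramp_lmean_w", w)] <- .windowed_stat(ramp, w, mean)
  }
  if (!is.null(signal)) {
    r1 <- fiducials$r_index + 1L
    counts <- vapply(seq_len(length(r1) - 1L), function(b) {
      seg <- signal[r1[b]:r1[b + 1L]]
      if (length(seg) < 3L) return(0)
      sum(seg[2:(length(seg) - 1L)] > seg[1:(length(seg) - 2L)] &
          seg[2:(length(seg) - 1L)] > seg[3:length(seg)])
    }, numeric(1))
    out["n_local_maxima_between_r"] <- mean(counts)
  }
  out["fake_p_rate"] <- mean(is.na(fiducials$p_index))
  seg_mean <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  out["mean_pr_s"] <- seg_mean(fiducials$pr_len_s)
  out["mean_qt_s"] <- seg_mean(fiducials$qt_len_s)
  out["mean_st_s"] <- seg_mean(fiducials$st_len_s)
  out["mean_qrs_s"] <- seg_mean(fiducials$qrs_width_s)
  out["mean_p_width_s"] <- seg_mean(fiducials$p_width_s)
  out["mean_t_width_s"] <- seg_mean(fiducials$t_width_s)
  out["mean_p_amp"] <- seg_mean(fiducials$p_amp)
  out["mean_t_amp"] <- seg_mean(fiducials$t_amp)
  out
}

#' Per-beat rule features
#'
#' Amplitude and timing evidence for the rule-based premature-beat
#' detector. The local average RR is the mean over up to
#' `local_half_window` beats on each side of the beat, excluding the beat
#' itself.
#'
#' @param fiducials A `fiducial_set`.
#' @param beat_index 1-based beat row number.
#' @param local_half_window Beats pooled on each side.
#' @return A list: `r_amp`, `s_amp`, `amp_ratio` (|R| over the larger of
#'   |S|, |Q|; NA when that denominator is 0 or unknown), `qs_dist_s`,
#'   `rs_dist_s`, `qr_dist_s`, `rr_ratio` (current RR over local average
#'   RR; NA for the first beat).
#' @export
beat_rule_features <- function(fiducials, beat_index, local_half_window = 2L) {
  fs <- attr(fiducials, "fs")
  n <- nrow(fiducials)
  stopifnot(beat_index >= 1L, beat_index <= n)
  b <- fiducials[beat_index, ]
  rr <- c(NA_real_, diff(fiducials$r_index) / fs)
  denom <- max(abs(b$s_amp), abs(b$q_amp), na.rm = FALSE)
  amp_ratio <- if (is.na(denom) || denom == 0) NA_real_ else abs(b$r_amp) / denom
  rr_ratio <- NA_real_
  if (beat_index > 1L) {
    nb <- setdiff(max(1L, beat_index - local_half_window):
                  min(n, beat_index + local_half_window), beat_index)
    local_rr <- rr[nb]
    local_rr <- local_rr[!is.na(local_rr)]
    if (length(local_rr)) rr_ratio <- rr[beat_index] / mean(local_rr)
  }
  list(
    r_amp = b$r_amp, s_amp = b$s_amp, amp_ratio = amp_ratio,
    qs_dist_s = (b$s_index - b$q_index) / fs,
    rs_dist_s = (b$s_index - b$r_index) / fs,
    qr_dist_s = (b$r_index - b$q_index) / fs,
    rr_ratio = rr_ratio
  )
}

#' Extract the full record-level feature vector
#'
#' Concatenates the 12 wavelet statistics (computed on the preprocessed,
#' whole-record signal) with the peak-segment block, in a stable named
#' order. Deterministic for fixed inputs.
#'
#' @param record An [ecg_record].
#' @param fiducials A `fiducial_set` for the record (from [delineate()]).
#' @param cfg A [features_config()].
#' @param preprocessed Set `TRUE` when `record` already carries the
#'   analysis band.
#' @return Named numeric vector with attribute `record_id`.
#' @export
extract_features <- function(record, fiducials, cfg = features_config(),
                             preprocessed = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  rec <- if (preprocessed) record else preprocess_record(record)
  wv <- wavelet_features(rec$samples, cfg$levels, cfg$stat_levels)
  ps <- suppressWarnings(
    peak_segment_features(fiducials, rec$fs, cfg$scales, rec$samples))
  out <- c(wv, ps)
  if (anyDuplicated(names(out))) stop("extract_features: duplicate feature names")
  attr(out, "record_id") <- record$record_id
  out
}

#' Feature matrix for a list of records
#'
#' Delineates and extracts features for each record; rows are records,
#' columns the stable feature schema.
#'
#' @param records List of [ecg_record] objects.
#' @param del_cfg,feat_cfg Stage configurations.
#' @return Numeric matrix with rownames = record ids.
#' @export
corpus_features <- function(records, del_cfg = delineation_config(),
                            feat_cfg = features_config()) {
  rows <- lapply(records, function(rec) {
    pre <- preprocess_record(rec)
    fid <- withCallingHandlers(
      delineate(pre, del_cfg, preprocessed = TRUE),
      warning = function(w) invokeRestart("muffleWarning"))
    suppressWarnings(extract_features(pre, fid, feat_cfg, preprocessed = TRUE))
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(records, function(r) r$record_id, character(1))
  mat
}
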