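# PQRST delineation: R-peak detection (candidate sifting -> adaptive
# threshold -> search-back) followed by Q/S curvature search and P/T
# matched filtering with a Mexican-hat (Ricker) template.
#
# R detection runs on a slope-emphasis signal: the moving average of the
# absolute centred derivative. QRS complexes carry the steepest slopes of
# the ECG, so this transform suppresses P and T waves (slow slopes) by an
# order of magnitude while remaining linear in amplitude and exactly
# polarity-invariant. Candidate and threshold arithmetic happens in that
# domain; reported R indices are refined back to the extremum of the
# band-passed ECG.

#' Delineation configuration
#'
#' All durations in seconds. The defaults are physiological choices for
#' adult single-lead ECG at 80-ish bpm, exposed so they can be tuned per
#' device.
#'
#' @param candidate_window_s Neighbourhood half-width used for candidate
#'   sifting (a candidate must dominate its neighbourhood).
#' @param refractory_s Minimum distance between accepted R peaks.
#' @param threshold_alpha Exponential smoothing factor of the running
#'   threshold, in (0,1).
#' @param threshold_beta Fraction of the accepted peak height fed into the
#'   threshold, in (0,1).
#' @param searchback_factor RR gaps longer than this multiple of the running
#'   mean RR are re-scanned with a halved threshold.
#' @param integration_s Width of the slope-integration window.
#' @param qs_window_s Search window on each side of R for the Q and S troughs.
#' @param p_window_s,t_window_s Search windows before Q (P) and after S (T).
#' @param mexican_hat_scale_p_s,mexican_hat_scale_t_s Ricker template scales.
#' @param p_presence_threshold Minimum normalized matched-filter correlation
#'   for a P wave to be declared present; below it the beat is scored as a
#'   missing ("fake") P wave.
#' @param p_min_amp_mv Minimum absolute amplitude for a detected P peak;
#'   smaller deflections (e.g. fibrillatory oscillation) do not count as a
#'   P wave even when well correlated with the template.
#' @param p_max_amp_mv Maximum P amplitude; a larger deflection in the P
#'   window (typically a preceding T wave crowding a short RR interval) is
#'   not accepted as a P wave.
#' @return A list of class `delineation_config`.
#' @export
delineation_config <- function(candidate_window_s = 0.25,
                               refractory_s = 0.20,
                               threshold_alpha = 0.875,
                               threshold_beta = 0.5,
                               searchback_factor = 1.66,
                               integration_s = 0.10,
                               qs_window_s = 0.12,
                               p_window_s = 0.30,
                               t_window_s = 0.45,
                               mexican_hat_scale_p_s = 0.03,
                               mexican_hat_scale_t_s = 0.05,
                               p_presence_threshold = 0.4,
                               p_min_amp_mv = 0.08,
                               p_max_amp_mv = 0.18) {
  cfg <- list(candidate_window_s = candidate_window_s,
              refractory_s = refractory_s,
              threshold_alpha = threshold_alpha,
              threshold_beta = threshold_beta,
              searchback_factor = searchback_factor,
              integration_s = integration_s,
              qs_window_s = qs_window_s,
              p_window_s = p_window_s,
              t_window_s = t_window_s,
              mexican_hat_scale_p_s = mexican_hat_scale_p_s,
              mexican_hat_scale_t_s = mexican_hat_scale_t_s,
              p_presence_threshold = p_presence_threshold,
              p_min_amp_mv = p_min_amp_mv,
              p_max_amp_mv = p_max_amp_mv)
  durs <- unlist(cfg[grepl("_s$", names(cfg))])
  if (any(durs <= 0)) stop("delineation_config: durations must be > 0")
  if (threshold_alpha <= 0 || threshold_alpha >= 1 ||
      threshold_beta <= 0 || threshold_beta >= 1) {
    stop("delineation_config: alpha and beta must lie in (0,1)")
  }
  if (searchback_factor <= 1) {
    stop("delineation_config: searchback_factor must exceed 1")
  }
  structure(cfg, class = "delineation_config")
}

# slope-emphasis detection signal: moving average of |centred derivative|
.detection_signal <- function(x, fs, cfg) {
  n <- length(x)
  d <- c(x[2L] - x[1L], (x[3:n] - x[1:(n - 2L)]) / 2, x[n] - x[n - 1L]) * fs
  win <- max(3L, round(cfg$integration_s * fs))
  if (win %% 2L == 0L) win <- win + 1L
  .fir_zero_phase(abs(d), rep(1 / win, win))
}

#' Detect R-peak candidates
#'
#' A sample is a candidate when the slope-emphasis signal attains its
#' neighbourhood maximum there (half-open neighbourhood of
#' `candidate_window_s` on each side, ties to the earlier sample) and
#' exceeds a small floor relative to the record maximum. Each candidate is
#' then refined to the extremum of `|signal|` inside its window, so both
#' polarities are handled and a negated record yields identical candidates.
#'
#' @param signal Numeric vector, preprocessed (analysis band) ECG in mV.
#' @param fs Sampling rate (Hz).
#' @param cfg A [delineation_config()].
#' @return A data frame with 0-based columns `index` (refined R location),
#'   `amp` (signal value there) and `det` (detection-signal height used by
#'   the threshold stages), ordered by `index`.
#' @export
detect_r_candidates <- function(signal, fs, cfg = delineation_config()) {
  n <- length(signal)
  w <- as.integer(round(cfg$candidate_window_s * fs))
  if (n < w || n < 5L) {
    return(data.frame(index = integer(0), amp = numeric(0), det = numeric(0)))
  }
  d <- .detection_signal(signal, fs, cfg)
  dmax <- max(d)
  if (dmax <= 0) {
    return(data.frame(index = integer(0), amp = numeric(0), det = numeric(0)))
  }
  floor_val <- 0.02 * dmax
  cand <- integer(0)
  i <- 1L
  while (i <= n) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    seg <- d[lo:hi]
    if (d[i] >= floor_val && d[i] == max(seg) &&
        which.max(seg) == (i - lo + 1L)) {
      cand <- c(cand, i)
      i <- i + w            # nothing in (i, i+w] can dominate its window
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand)) {
    return(data.frame(index = integer(0), amp = numeric(0), det = numeric(0)))
  }
  # refine to the |ECG| extremum inside the half-open candidate window
  ref <- vapply(cand, function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w - 1L)
    lo + which.max(abs(signal[lo:hi])) - 1L
  }, integer(1))
  keep <- !duplicated(ref)
  out <- data.frame(index = ref[keep] - 1L,
                    amp = signal[ref[keep]],
                    det = d[cand[keep]])
  out[order(out$index), , drop = FALSE]
}

#' Adaptive peak-height thresholding
#'
#' Candidates are scanned in time order. The running threshold starts at
#' `beta` times the 95th percentile of the detection signal over the first
#' two seconds and is updated on every accepted peak as
#' `thr <- alpha * thr + (1 - alpha) * beta * height`. A candidate is
#' accepted when its height reaches the threshold and it lies outside the
#' refractory period of the previously accepted peak.
#'
#' @param candidates Data frame from [detect_r_candidates()].
#' @param signal Preprocessed ECG (mV), used to size the initial threshold.
#' @param fs Sampling rate (Hz).
#' @param cfg A [delineation_config()].
#' @return A list: `accepted` (0-based R indices), `rejected` (data frame of
#'   remaining candidates with the threshold each one faced) and
#'   `final_threshold`.
#' @export
adaptive_threshold_filter <- function(candidates, signal, fs,
                                      cfg = delineation_config()) {
  if (!nrow(candidates)) {
    return(list(accepted = integer(0),
                rejected = cbind(candidates, thr = numeric(0)),
                final_threshold = 0))
  }
  d <- .detection_signal(signal, fs, cfg)
  init_span <- seq_len(min(length(d), round(2 * fs)))
  thr <- cfg$threshold_beta *
    stats::quantile(d[init_span], 0.95, names = FALSE, type = 7)
  refr <- as.integer(round(cfg$refractory_s * fs))
  accepted <- integer(0)
  rej_idx <- integer(0); rej_thr <- numeric(0)
  last <- -Inf
  for (k in seq_len(nrow(candidates))) {
    idx <- candidates$index[k]; h <- candidates$det[k]
    if (h >= thr && (idx - last) >= refr) {
      accepted <- c(accepted, idx)
      last <- idx
      thr <- cfg$threshold_alpha * thr +
        (1 - cfg$threshold_alpha) * cfg$threshold_beta * h
    } else {
      rej_idx <- c(rej_idx, k); rej_thr <- c(rej_thr, thr)
    }
  }
  list(accepted = accepted,
       rejected = cbind(candidates[rej_idx, , drop = FALSE], thr = rej_thr),
       final_threshold = thr)
}

#' Search-back over long RR gaps
#'
#' Whenever the gap between consecutive accepted peaks exceeds
#' `searchback_factor` times the running mean RR, the strongest previously
#' rejected candidate inside the gap is re-examined against half the
#' threshold it originally faced, and inserted if it passes and respects
#' the refractory distance to both neighbours. With
#' `searchback_factor = Inf` the operation is the identity.
#'
#' @param accepted 0-based accepted R indices (sorted).
#' @param rejected Rejected-candidate data frame from
#'   [adaptive_threshold_filter()] (columns `index`, `det`, `thr`).
#' @param fs Sampling rate (Hz).
#' @param cfg A [delineation_config()].
#' @return Sorted 0-based R indices including any recovered beats.
#' @export
search_back <- function(accepted, rejected, fs, cfg = delineation_config()) {
  if (length(accepted) < 2L || !is.finite(cfg$searchback_factor)) {
    return(accepted)
  }
  refr <- as.integer(round(cfg$refractory_s * fs))
  out <- accepted
  repeat {
    rr <- diff(out)
    mean_rr <- mean(rr)
    gaps <- which(rr > cfg$searchback_factor * mean_rr)
    if (!length(gaps)) break
    inserted <- FALSE
    for (g in gaps) {
      lo <- out[g]; hi <- out[g + 1L]
      inside <- rejected$index > lo + refr & rejected$index < hi - refr
      if (!any(inside)) next
      cand <- rejected[inside, , drop = FALSE]
      cand <- cand[cand$det >= cand$thr / 2, , drop = FALSE]
      if (!nrow(cand)) next
      best <- cand[which.max(cand$det), , drop = FALSE]
      out <- sort(c(out, best$index))
      rejected <- rejected[rejected$index != best$index, , drop = FALSE]
      inserted <- TRUE
      break
    }
    if (!inserted) break
  }
  out
}

#' Detect R peaks (full chain)
#'
#' Convenience composition of [detect_r_candidates()],
#' [adaptive_threshold_filter()] and [search_back()].
#'
#' @inheritParams detect_r_candidates
#' @return Sorted 0-based R-peak indices.
#' @export
detect_r_peaks <- function(signal, fs, cfg = delineation_config()) {
  cand <- detect_r_candidates(signal, fs, cfg)
  flt <- adaptive_threshold_filter(cand, signal, fs, cfg)
  search_back(flt$accepted, flt$rejected, fs, cfg)
}

#' Locate Q and S troughs around each R peak
#'
#' Q is searched in `[r - qs_window, r)` and S in `(r, r + qs_window]` as
#' the extremum of polarity opposite to R, located where the second-order
#' difference of the signal changes sign (a curvature trough). When the
#' window contains no curvature sign change (e.g. a linear ramp), the
#' window extremum is used as a fallback. A fiducial whose window is
#' clipped below 3 samples by the record boundary is reported absent.
#'
#' @param signal Preprocessed ECG (mV).
#' @param r_indices 0-based R indices.
#' @param fs Sampling rate (Hz).
#' @param cfg A [delineation_config()].
#' @return Data frame with 0-based `q_index`, `s_index` (NA when absent).
#' @export
detect_qs <- function(signal, r_indices, fs, cfg = delineation_config()) {
  n <- length(signal)
  w <- max(2L, as.integer(round(cfg$qs_window_s * fs)))
  one_side <- function(r1, side) {
    # r1 is 1-based; side -1 for Q, +1 for S
    if (side < 0) { lo <- max(1L, r1 - w); hi <- r1 - 1L }
    else          { lo <- r1 + 1L; hi <- min(n, r1 + w) }
    if (hi - lo + 1L < 3L) return(NA_integer_)
    seg <- if (signal[r1] >= 0) signal[lo:hi] else -signal[lo:hi]
    d2 <- diff(seg, differences = 2L)
    # trough: curvature flips from negative to positive around a local min
    troughs <- which(seg[2:(length(seg) - 1L)] <= seg[1:(length(seg) - 2L)] &
                     seg[2:(length(seg) - 1L)] <= seg[3:length(seg)] &
                     d2 > 0) + 1L
    pick <- if (length(troughs)) {
      if (side < 0) troughs[length(troughs)] else troughs[1L]
    } else {
      which.min(seg)   # degenerate curvature fallback
    }
    lo + pick - 1L
  }
  r1 <- r_indices + 1L
  data.frame(
    q_index = vapply(r1, one_side, integer(1), side = -1L) - 1L,
    s_index = vapply(r1, one_side, integer(1), side = +1L) - 1L
  )
}

#' Discrete Mexican-hat (Ricker) template
#'
#' `psi(t) = (1 - (t/sigma)^2) * exp(-t^2 / (2 sigma^2))` sampled on the
#' integer grid over `[-4 sigma, 4 sigma]`, then mean-centred so the
#' discrete sum is exactly zero.
#'
#' @param scale_s Template scale sigma in seconds (must span >= 2 samples).
#' @param fs Sampling rate (Hz).
#' @return Numeric kernel of odd length, peak at the centre.
#' @export
mexican_hat_kernel <- function(scale_s, fs) {
  sigma <- scale_s * fs
  if (sigma < 2) {
    stop("mexican_hat_kernel: scale too small for fs (sigma = ", sigma,
         " samples, need >= 2)")
  }
  half <- ceiling(4 * sigma)
  t <- (-half):half
  k <- (1 - (t / sigma)^2) * exp(-t^2 / (2 * sigma^2))
  k - mean(k)
}

# Zero-phase matched-filter response and normalized correlation. The
# local-energy denominator spans only the template's main lobe (+/- 2
# sigma), so a neighbouring wave just outside the lobe does not deflate
# the correlation, and it is floored at 10% of the record-wide RMS so
# near-flat segments cannot produce spurious 0/0-style correlations.
.matched_filter <- function(x, kernel, sigma_samples) {
  resp <- .fir_zero_phase(x, kernel)
  e_k <- sqrt(sum(kernel^2))
  lobe <- 2L * as.integer(ceiling(2 * sigma_samples)) + 1L
  win <- rep(1, lobe)
  e_x <- sqrt(pmax(.fir_zero_phase(x^2, win), 0))
  e_floor <- 0.1 * sqrt(mean(x^2) * length(kernel))
  list(resp = resp,
       ncorr = resp / (e_k * pmax(e_x, e_floor, .Machine$double.eps)))
}

#' Locate P and T peaks by Mexican-hat matched filtering
#'
#' The preprocessed signal is correlated with Ricker templates at the P and
#' T scales and each peak is placed at the lag of strongest normalized
#' correlation (response over local signal energy, which suppresses QRS
#' leakage into the search windows): P in `[q - p_window, q)`, T in
#' `(s, s + t_window]`. A P whose normalized correlation falls below
#' `p_presence_threshold` is declared absent (a missing, "fake", P wave);
#' a T window truncated below 3 samples by the record end yields an absent
#' T. Wave widths span the matched-filter response zero-crossings
#' bracketing each peak.
#'
#' @param signal Preprocessed ECG (mV).
#' @param r_indices 0-based R indices.
#' @param qs Data frame from [detect_qs()].
#' @param fs Sampling rate (Hz).
#' @param cfg A [delineation_config()].
#' @return Data frame with 0-based `p_index`, `t_index` (NA when absent),
#'   `p_amp`, `t_amp` (mV) and `p_width_s`, `t_width_s`.
#' @export
detect_pt <- function(signal, r_indices, qs, fs, cfg = delineation_config()) {
  n <- length(signal)
  sig_p <- cfg$mexican_hat_scale_p_s * fs
  sig_t <- cfg$mexican_hat_scale_t_s * fs
  mf_p <- .matched_filter(signal, mexican_hat_kernel(cfg$mexican_hat_scale_p_s, fs), sig_p)
  mf_t <- .matched_filter(signal, mexican_hat_kernel(cfg$mexican_hat_scale_t_s, fs), sig_t)
  wp <- as.integer(round(cfg$p_window_s * fs))
  wt <- as.integer(round(cfg$t_window_s * fs))
  # guard zones keep the template's main lobe clear of the QRS edges
  guard_p <- as.integer(ceiling(2 * sig_p))
  guard_t <- as.integer(ceiling(2 * sig_t))

  width_at <- function(resp, peak1) {
    sgn <- sign(resp[peak1])
    if (sgn == 0) return(NA_real_)
    left <- peak1
    while (left > 1L && sign(resp[left - 1L]) == sgn) left <- left - 1L
    right <- peak1
    while (right < length(resp) && sign(resp[right + 1L]) == sgn) right <- right + 1L
    (right - left) / fs
  }

  # P search is signed (an upright wave in this lead convention); T search
  # uses the absolute response so an inverted T is still localized.
  find_in <- function(mf, lo1, hi1, presence_thr, min_amp = 0,
                      max_amp = Inf, signed = FALSE) {
    if (hi1 - lo1 + 1L < 3L || lo1 < 1L || hi1 > n) {
      return(list(idx = NA_integer_, amp = NA_real_, width = NA_real_))
    }
    seg <- mf$resp[lo1:hi1]
    pk <- lo1 + (if (signed) which.max(seg) else which.max(abs(seg))) - 1L
    score <- if (signed) mf$ncorr[pk] else abs(mf$ncorr[pk])
    if (!is.na(presence_thr) &&
        (score < presence_thr || abs(signal[pk]) < min_amp ||
         abs(signal[pk]) > max_amp)) {
      return(list(idx = NA_integer_, amp = NA_real_, width = NA_real_))
    }
    list(idx = pk, amp = signal[pk], width = width_at(mf$resp, pk))
  }

  m <- length(r_indices)
  out <- data.frame(p_index = rep(NA_integer_, m), t_index = rep(NA_integer_, m),
                    p_amp = rep(NA_real_, m), t_amp = rep(NA_real_, m),
                    p_width_s = rep(NA_real_, m), t_width_s = rep(NA_real_, m))
  for (b in seq_len(m)) {
    q1 <- qs$q_index[b] + 1L
    s1 <- qs$s_index[b] + 1L
    if (!is.na(q1) && q1 >= 2L) {
      p <- find_in(mf_p, max(1L, q1 - wp), q1 - 1L - guard_p,
                   cfg$p_presence_threshold, min_amp = cfg$p_min_amp_mv,
                   max_amp = cfg$p_max_amp_mv, signed = TRUE)
      out$p_index[b] <- if (is.na(p$idx)) NA_integer_ else p$idx - 1L
      out$p_amp[b] <- p$amp; out$p_width_s[b] <- p$width
    }
    if (!is.na(s1) && s1 < n) {
      hi1 <- min(n, s1 + wt)
      # stop before the next beat's QRS so a premature next beat cannot
      # masquerade as this beat's T wave
      if (b < m && !is.na(qs$q_index[b + 1L])) {
        hi1 <- min(hi1, qs$q_index[b + 1L] - 1L - guard_t)
      }
      tt <- find_in(mf_t, s1 + 1L + guard_t, hi1, NA)
      out$t_index[b] <- if (is.na(tt$idx)) NA_integer_ else tt$idx - 1L
      out$t_amp[b] <- tt$amp; out$t_width_s[b] <- tt$width
    }
  }
  out
}

#' Delineate a full record
#'
#' Runs preprocessing (baseline removal + analysis-band FIR), R-peak
#' detection, Q/S curvature search and P/T matched filtering, and derives
#' per-beat segment durations. Deterministic for a given record and
#' configuration.
#'
#' @param record An [ecg_record] of at least 2 s.
#' @param cfg A [delineation_config()].
#' @param preprocessed Set `TRUE` when `record` already carries the analysis
#'   band (skips the internal preprocessing).
#' @return A `fiducial_set`: a data frame with one row per beat — 0-based
#'   indices `p_index`, `q_index`, `r_index`, `s_index`, `t_index` (NA when
#'   absent), amplitudes `*_amp` in mV, widths `p_width_s`, `t_width_s`,
#'   and derived `pr_len_s`, `qt_len_s`, `st_len_s`, `qrs_width_s` — with
#'   attributes `fs` and `record_id`.
#' @export
delineate <- function(record, cfg = delineation_config(),
                      preprocessed = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  if (record$duration_s < 2) stop("delineate: record must be at least 2 s")
  rec <- if (preprocessed) record else preprocess_record(record)
  x <- rec$samples
  fs <- rec$fs
  r_idx <- detect_r_peaks(x, fs, cfg)
  if (!length(r_idx)) {
    warning("delineate: no beats found in record ", record$record_id)
    return(empty_fiducial_set(fs, record$record_id))
  }
  qs <- detect_qs(x, r_idx, fs, cfg)
  pt <- detect_pt(x, r_idx, qs, fs, cfg)
  # enforce intra-beat ordering: out-of-order P/T are demoted to absent
  bad_p <- !is.na(pt$p_index) & !is.na(qs$q_index) & pt$p_index >= qs$q_index
  pt$p_index[bad_p] <- NA_integer_; pt$p_amp[bad_p] <- NA_real_
  pt$p_width_s[bad_p] <- NA_real_
  bad_t <- !is.na(pt$t_index) & !is.na(qs$s_index) & pt$t_index <= qs$s_index
  pt$t_index[bad_t] <- NA_integer_; pt$t_amp[bad_t] <- NA_real_
  pt$t_width_s[bad_t] <- NA_real_

  amp_at <- function(idx) ifelse(is.na(idx), NA_real_, x[idx + 1L])
  fid <- data.frame(
    p_index = pt$p_index, q_index = qs$q_index, r_index = r_idx,
    s_index = qs$s_index, t_index = pt$t_index,
    p_amp = pt$p_amp, q_amp = amp_at(qs$q_index), r_amp = x[r_idx + 1L],
    s_amp = amp_at(qs$s_index), t_amp = pt$t_amp,
    p_width_s = pt$p_width_s, t_width_s = pt$t_width_s
  )
  fid$pr_len_s <- (fid$q_index - fid$p_index) / fs
  fid$qt_len_s <- (fid$t_index - fid$q_index) / fs
  fid$st_len_s <- (fid$t_index - fid$s_index) / fs
  fid$qrs_width_s <- (fid$s_index - fid$q_index) / fs
  structure(fid, class = c("fiducial_set", "data.frame"),
            fs = fs, record_id = record$record_id)
}

#' An empty fiducial set
#' @param fs Sampling rate attribute.
#' @param record_id Record identifier attribute.
#' @return A zero-row `fiducial_set`.
#' @export
empty_fiducial_set <- function(fs = NA_real_, record_id = NA_character_) {
  cols <- c("p_index", "q_index", "r_index", "s_index", "t_index",
            "p_amp", "q_amp", "r_amp", "s_amp", "t_amp",
            "p_width_s", "t_width_s",
            "pr_len_s", "qt_len_s", "st_len_s", "qrs_width_s")
  fid <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  structure(fid, class = c("fiducial_set", "data.frame"),
            fs = fs, record_id = record_id)
}
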