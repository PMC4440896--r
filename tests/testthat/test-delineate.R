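# R-peak detection chain and PQRST fiducials.

make_single_beat_record <- function(center_s = 2.0, fs = 256, dur = 5,
                                    amp = 1.2) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  ecg_record(amp * exp(-(t - center_s)^2 / (2 * 0.01^2)), fs = fs)
}

test_that("a single beat yields exactly one candidate at its apex", {
  rec <- make_single_beat_record()
  cand <- detect_r_candidates(rec$samples, rec$fs)
  expect_equal(nrow(cand), 1L)
  expect_lt(abs(cand$index - round(2.0 * 256)), 2.5)
})

test_that("candidate detection is invariant to lead inversion", {
  sim <- synth_record(clean_cfg("SINUS", seed = 13))
  x <- preprocess_record(sim$record)$samples
  a <- detect_r_candidates(x, 256)
  b <- detect_r_candidates(-x, 256)
  expect_equal(a$index, b$index)
  expect_equal(a$det, b$det)
  expect_equal(a$amp, -b$amp)
})

test_that("candidates cover every true beat and obey the window-argmax rule", {
  cfg <- delineation_config()
  sim <- synth_record(clean_cfg("SINUS", seed = 77, heart_rate_bpm = 80))
  x <- preprocess_record(sim$record)$samples
  cand <- detect_r_candidates(x, 256, cfg)
  truth <- sim$truth$beats$r_index
  for (r in truth) {
    expect_true(min(abs(cand$index - r)) <= 10)
  }
  # each refined candidate is the |signal| argmax of its half-open window
  w <- as.integer(round(cfg$candidate_window_s * 256))
  for (i in cand$index) {
    lo <- max(0L, i - w); hi <- min(length(x) - 1L, i + w - 1L)
    seg <- abs(x[(lo + 1L):(hi + 1L)])
    expect_equal(abs(x[i + 1L]), max(seg))
  }
})

test_that("adaptive thresholding keeps equal peaks and enforces refractory", {
  fs <- 256
  x <- numeric(10 * fs)
  at <- seq(2 * fs, 9 * fs, by = round(0.75 * fs))
  for (c0 in at) x <- x + 1.2 * exp(-((seq_along(x) - c0) / 2.56)^2 / 2)
  cand <- detect_r_candidates(x, fs)
  flt <- adaptive_threshold_filter(cand, x, fs)
  expect_equal(length(flt$accepted), length(at))   # all equal-amp accepted
  # two candidates 50 ms apart: only the larger survives the refractory
  cand2 <- data.frame(index = c(1000L, 1013L), amp = c(1, 1.3),
                      det = c(10, 13))
  flt2 <- adaptive_threshold_filter(cand2, x, fs,
                                    delineation_config(refractory_s = 0.2))
  expect_equal(length(flt2$accepted), 1L)
  skip_msg <- "larger of the close pair must win when it comes first"
  cand3 <- data.frame(index = c(1000L, 1013L), amp = c(1.3, 1),
                      det = c(13, 10))
  flt3 <- adaptive_threshold_filter(cand3, x, fs)
  expect_equal(flt3$accepted, 1000L, label = skip_msg)
})

test_that("a low-amplitude noise spike is rejected by the threshold", {
  sim <- synth_record(clean_cfg("SINUS", seed = 9))
  x <- preprocess_record(sim$record)$samples
  fs <- 256
  truth <- sim$truth$beats$r_index
  spike_at <- truth[5] + round(0.35 * fs)   # mid-diastole
  t_idx <- seq_along(x)
  x_spiked <- x + 0.36 * exp(-((t_idx - spike_at) / (0.005 * fs))^2 / 2)
  r <- detect_r_peaks(x_spiked, fs)
  cc <- match_beats(r, truth, fs)
  expect_equal(cc$fn, 0L)
  expect_equal(cc$fp, 0L)   # spike did not get in
})

test_that("search-back recovers an attenuated beat and honours its gates", {
  sim <- synth_record(clean_cfg("SINUS", seed = 15))
  x <- preprocess_record(sim$record)$samples
  fs <- 256
  truth <- sim$truth$beats$r_index
  # attenuate one mid-record beat to 40%
  k <- truth[8]
  span <- max(1, k - 30):min(length(x), k + 30)
  x_att <- x; x_att[span] <- x_att[span] * 0.4
  cand <- detect_r_candidates(x_att, fs)
  flt <- adaptive_threshold_filter(cand, x_att, fs)
  cc_before <- match_beats(flt$accepted, truth, fs)
  expect_gt(cc_before$fn, 0L)          # the beat is actually missed
  r <- search_back(flt$accepted, flt$rejected, fs, delineation_config())
  cc <- match_beats(r, truth, fs)
  expect_equal(cc$fn, 0L)              # and recovered
  # no qualifying gap: identity
  cand0 <- detect_r_candidates(x, fs)
  flt0 <- adaptive_threshold_filter(cand0, x, fs)
  expect_identical(search_back(flt0$accepted, flt0$rejected, fs,
                               delineation_config()), flt0$accepted)
  # disabled search-back is always the identity
  inf_cfg <- delineation_config(searchback_factor = Inf)
  expect_identical(search_back(flt$accepted, flt$rejected, fs, inf_cfg),
                   flt$accepted)
})

test_that("Q and S troughs sit within 3 samples of simulator truth", {
  sim <- synth_record(clean_cfg("SINUS", seed = 19))
  x <- preprocess_record(sim$record)$samples
  tb <- sim$truth$beats
  qs <- detect_qs(x, tb$r_index, 256)
  expect_true(all(abs(qs$q_index - tb$q_index) <= 3))
  expect_true(all(abs(qs$s_index - tb$s_index) <= 3))
  # R at index 1: Q window collapses, S survives
  qs_edge <- detect_qs(x, c(1L, tb$r_index[3]), 256)
  expect_true(is.na(qs_edge$q_index[1]))
  expect_false(is.na(qs_edge$s_index[1]))
  # linear ramp has no curvature sign change: falls back to window extremum
  ramp <- seq(0, 1, length.out = 200)
  qs_ramp <- detect_qs(ramp, 100L, 256)
  expect_false(is.na(qs_ramp$q_index))
})

test_that("the Mexican-hat template is even, zero-mean, self-peaked", {
  k <- mexican_hat_kernel(0.05, 256)
  expect_equal(k, rev(k))
  expect_lt(abs(sum(k)), 1e-6 * max(abs(k)) * length(k))
  # exhaustive lag scan: autocorrelation peaks at zero lag
  lags <- -20:20
  ac <- vapply(lags, function(L) {
    n <- length(k)
    i <- seq_len(n - abs(L))
    sum(k[i] * k[i + abs(L)])
  }, numeric(1))
  expect_equal(lags[which.max(ac)], 0L)
  expect_error(mexican_hat_kernel(0.004, 256), "scale too small")
})

test_that("P and T localization matches truth; missing P is flagged", {
  sim <- synth_record(clean_cfg("SINUS", seed = 23))
  x <- preprocess_record(sim$record)$samples
  tb <- sim$truth$beats
  qs <- detect_qs(x, tb$r_index, 256)
  pt <- detect_pt(x, tb$r_index, qs, 256)
  inner <- 2:(nrow(tb) - 1L)
  expect_true(all(abs(pt$p_index[inner] - tb$p_index[inner]) <= 5))
  expect_true(all(abs(pt$t_index[inner] - tb$t_index[inner]) <= 5))
  expect_true(all(!is.na(pt$p_index[inner])))
  # fibrillatory baseline instead of P: flagged absent
  af <- synth_record(clean_cfg("AF", seed = 3, rr_cv = 0.25,
                               p_absent_prob = 0.9))
  xf <- preprocess_record(af$record)$samples
  tbf <- af$truth$beats
  qsf <- detect_qs(xf, tbf$r_index, 256)
  ptf <- detect_pt(xf, tbf$r_index, qsf, 256)
  expect_gte(mean(is.na(ptf$p_index)), 0.8)
  # truncated T window at the record end: absent, no error
  last_r <- length(x) - 10L
  qs_end <- detect_qs(x, last_r, 256)
  pt_end <- detect_pt(x, last_r, qs_end, 256)
  expect_true(is.na(pt_end$t_index))
})

test_that("full delineation is deterministic and complete on sinus rhythm", {
  flat <- ecg_record(rep(0, 4 * 256), fs = 256)
  expect_warning(fid0 <- delineate(flat), "no beats")
  expect_equal(nrow(fid0), 0L)

  sim <- synth_record(clean_cfg("SINUS", seed = 7, heart_rate_bpm = 80))
  fid <- delineate(sim$record)
  expect_s3_class(fid, "fiducial_set")
  expect_true(abs(nrow(fid) - 20) <= 1)   # 15 s at 80 bpm
  tb <- sim$truth$beats
  expect_true(all(abs(fid$r_index - tb$r_index) <= 2))
  expect_true(all(abs(fid$q_index - tb$q_index) <= 3))
  expect_true(all(abs(fid$s_index - tb$s_index) <= 3))
  ok <- !is.na(fid$p_index)
  expect_true(all(abs(fid$p_index[ok] - tb$p_index[ok]) <= 5))
  # intra-beat ordering and non-negative derived lengths
  full <- stats::complete.cases(fid[, c("p_index", "q_index", "r_index",
                                        "s_index", "t_index")])
  with(fid[full, ], {
    expect_true(all(p_index < q_index & q_index < r_index &
                    r_index < s_index & s_index < t_index))
  })
  expect_true(all(fid$qrs_width_s >= 0, na.rm = TRUE))
  expect_identical(as.data.frame(delineate(sim$record)), as.data.frame(fid))
})

test_that("delineation is equivariant to a circular time shift", {
  sim <- synth_record(clean_cfg("SINUS", seed = 29))
  x <- sim$record$samples
  k <- 400L
  shifted <- ecg_record(c(x[(k + 1L):length(x)], x[seq_len(k)]), fs = 256)
  f0 <- delineate(sim$record)
  f1 <- delineate(shifted)
  truth0 <- sim$truth$beats$r_index
  truth1 <- sort((truth0 - k) %% length(x))
  interior0 <- truth0[truth0 > k + 256 & truth0 < length(x) - 256]
  interior1 <- (interior0 - k)
  m0 <- match_beats(f0$r_index, interior0, 256)
  m1 <- match_beats(f1$r_index, sort(interior1), 256)
  expect_equal(m0$tp, m1$tp)
})

test_that("detection quality degrades monotonically with added noise", {
  rms_levels <- c(0, 0.05, 0.1, 0.2)
  ses <- vapply(rms_levels, function(rms) {
    tps <- 0L; pos <- 0L
    for (sd in 1:5) {
      sim <- synth_record(clean_cfg("SINUS", seed = sd,
                                    white_noise_rms_mv = rms))
      fid <- suppressWarnings(delineate(sim$record))
      cc <- match_beats(fid$r_index, sim$truth$beats$r_index, 256)
      tps <- tps + cc$tp; pos <- pos + cc$tp + cc$fn
    }
    tps / pos
  }, numeric(1))
  expect_true(all(diff(ses) <= 1e-9))
  expect_equal(ses[1], 1)
})
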