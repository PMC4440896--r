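# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (loops, closed forms, exhaustive search)
# rather than calling the implementation paths they check.

# zero-phase FIR by explicit reflection padding + naive convolution loop
conv_fir_oracle <- function(x, taps) {
  n <- length(x)
  half <- (length(taps) - 1L) %/% 2L
  pad <- min(half, n - 1L)
  xe <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_along(taps)) {
      acc <- acc + taps[k] * xe[i + pad + half - (k - 1L)]
    }
    out[i] <- acc
  }
  out
}

# direct DTFT magnitude of a tap vector at frequency f (Hz)
dtft_gain_oracle <- function(taps, f, fs) {
  k <- seq_along(taps) - 1L
  Mod(sum(taps * exp(-2i * pi * f * k / fs)))
}

# One level of spline 5/3 analysis written as plain textbook loops on a
# whole-point symmetrically extended signal: boundary details are computed
# directly from the reflected samples rather than via index bookkeeping.
lift53_oracle <- function(x) {
  n <- length(x)
  xs <- function(k) {             # 0-based sample with reflection
    if (k < 0L) k <- -k
    if (k > n - 1L) k <- 2L * (n - 1L) - k
    x[k + 1L]
  }
  dfun <- function(i) xs(2L * i + 1L) - (xs(2L * i) + xs(2L * i + 2L)) / 2
  nd <- n %/% 2L
  ne <- as.integer(ceiling(n / 2))
  d <- vapply(0:(nd - 1L), dfun, numeric(1))
  s <- vapply(0:(ne - 1L), function(j) {
    xs(2L * j) + (dfun(j - 1L) + dfun(j)) / 4
  }, numeric(1))
  list(approx = s, detail = d)
}

# maximum-cardinality matching between two sorted index sets under a
# tolerance, by exhaustive recursion (small n only)
bipartite_match_oracle <- function(detected, truth, tol) {
  best <- 0L
  recurse <- function(di, used) {
    if (di > length(detected)) {
      best <<- max(best, sum(used))
      return(invisible())
    }
    # upper-bound prune
    if (sum(used) + (length(detected) - di + 1L) <= best) return(invisible())
    cand <- which(!used & abs(truth - detected[di]) <= tol)
    for (tj in cand) {
      used[tj] <- TRUE
      recurse(di + 1L, used)
      used[tj] <- FALSE
    }
    recurse(di + 1L, used)
  }
  recurse(1L, rep(FALSE, length(truth)))
  best
}

# windowed local statistics by explicit loops (features oracle)
windowed_stat_oracle <- function(v, w, fun) {
  m <- length(v)
  if (m == 0L) return(NA_real_)
  if (m <= w) return(fun(v))
  vals <- numeric(m - w + 1L)
  for (i in seq_len(m - w + 1L)) vals[i] <- fun(v[i:(i + w - 1L)])
  mean(vals)
}

# build a minimal fiducial_set data frame by hand (for rule/feature tests)
toy_fiducials <- function(r_index, fs = 256, qrs_samples = 22L,
                          p_offset = -41L, t_offset = 74L,
                          r_amp = 1.2, q_amp = -0.1, s_amp = -0.25,
                          t_amp = 0.3, p_amp = 0.15,
                          qrs_width_s = NULL, p_absent = FALSE) {
  m <- length(r_index)
  q <- r_index - qrs_samples %/% 2L
  s <- r_index + qrs_samples %/% 2L
  fid <- data.frame(
    p_index = if (p_absent) rep(NA_integer_, m) else q + p_offset,
    q_index = q, r_index = r_index, s_index = s, t_index = s + t_offset,
    p_amp = rep(if (p_absent) NA_real_ else p_amp, m),
    q_amp = rep(q_amp, m), r_amp = rep(r_amp, m), s_amp = rep(s_amp, m),
    t_amp = rep(t_amp, m),
    p_width_s = rep(0.08, m), t_width_s = rep(0.16, m)
  )
  fid$pr_len_s <- (fid$q_index - fid$p_index) / fs
  fid$qt_len_s <- (fid$t_index - fid$q_index) / fs
  fid$st_len_s <- (fid$t_index - fid$s_index) / fs
  fid$qrs_width_s <- if (is.null(qrs_width_s)) (fid$s_index - fid$q_index) / fs
                     else rep_len(qrs_width_s, m)
  structure(fid, class = c("fiducial_set", "data.frame"),
            fs = fs, record_id = "toy")
}

# a clean (noise-free by default) simulation config
clean_cfg <- function(cls, seed, wander_amp_mv = 0, white_noise_rms_mv = 0,
                      ...) {
  simulation_config(cls, seed = seed, wander_amp_mv = wander_amp_mv,
                    white_noise_rms_mv = white_noise_rms_mv, ...)
}
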