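# Discrete wavelet transforms used by the feature extractor: the
# LeGall/spline 5/3 and CDF 9/7 biorthogonal wavelets via the lifting
# scheme, and Daubechies db4 via its orthogonal filter bank. Signal
# extension is whole-point symmetric for the lifting transforms and
# periodic for db4. Each returns per-level detail coefficients; the
# feature block consumes summary statistics of selected levels.

# Whole-point symmetric reflection of a 0-based full-signal position into
# [0, n-1] (single bounce; lifting steps only overhang by one position).
.wps_refl <- function(k, n) {
  k <- ifelse(k < 0L, -k, k)
  ifelse(k > n - 1L, 2L * (n - 1L) - k, k)
}

# 1-based even-subsequence position of full-signal index 2i+2 (i 0-based)
.next_even <- function(i, n) .wps_refl(2L * i + 2L, n) %/% 2L + 1L
# 1-based detail positions of full-signal indices 2j-1 and 2j+1 (j 0-based)
.prev_odd <- function(j, n) (.wps_refl(2L * j - 1L, n) - 1L) %/% 2L + 1L
.curr_odd <- function(j, n) (.wps_refl(2L * j + 1L, n) - 1L) %/% 2L + 1L

# one level of the spline 5/3 lifting analysis on a whole-point
# symmetrically extended signal
# predict: d[i] = x[2i+1] - (x[2i] + x[2i+2]) / 2
# update:  s[i] = x[2i] + (d[i-1] + d[i]) / 4
.dwt53_level <- function(x) {
  n <- length(x)
  ne <- as.integer(ceiling(n / 2)); nd <- n %/% 2L
  even <- x[seq(1L, n, by = 2L)]                       # x[0], x[2], ...
  odd  <- x[seq.int(2L, length.out = nd, by = 2L)]     # x[1], x[3], ...
  i <- 0:(nd - 1L)
  d <- odd - (even[i + 1L] + even[.next_even(i, n)]) / 2
  j <- 0:(ne - 1L)
  s <- even + (d[.prev_odd(j, n)] + d[.curr_odd(j, n)]) / 4
  list(approx = s, detail = d)
}

# one level of the CDF 9/7 lifting analysis (standard lifting constants)
.CDF97 <- list(alpha = -1.586134342059924, beta = -0.052980118572961,
               gamma = 0.882911075530934, delta = 0.443506852043971,
               zeta = 1.149604398860241)
.dwt97_level <- function(x) {
  n <- length(x)
  ne <- as.integer(ceiling(n / 2)); nd <- n %/% 2L
  s <- x[seq(1L, n, by = 2L)]
  d <- x[seq.int(2L, length.out = nd, by = 2L)]
  cs <- .CDF97
  i <- 0:(nd - 1L); j <- 0:(ne - 1L)
  lift_d <- function(d, s, coef) {
    d + coef * (s[i + 1L] + s[.next_even(i, n)])
  }
  lift_s <- function(s, d, coef) {
    s + coef * (d[.prev_odd(j, n)] + d[.curr_odd(j, n)])
  }
  d <- lift_d(d, s, cs$alpha)
  s <- lift_s(s, d, cs$beta)
  d <- lift_d(d, s, cs$gamma)
  s <- lift_s(s, d, cs$delta)
  list(approx = s * cs$zeta, detail = d / cs$zeta)
}

# db4 (4 vanishing moments, 8 taps) orthogonal decomposition filters
.DB4_LO <- c(-0.010597401784997278, 0.032883011666982945,
             0.030841381835986965, -0.18703481171888114,
             -0.02798376941698385, 0.6308807679295904,
             0.7148465705525415, 0.23037781330885523)
.DB4_HI <- rev(.DB4_LO) * c(-1, 1, -1, 1, -1, 1, -1, 1)

# one level of db4 with periodic extension
.dwt_db4_level <- function(x) {
  n <- length(x)
  if (n %% 2L == 1L) { x <- c(x, x[n]); n <- n + 1L }
  L <- 8L
  conv_down <- function(h) {
    out <- numeric(n / 2L)
    for (k in seq_len(n / 2L)) {
      # output k uses x[2k-1 .. 2k-1+L-1] reversed against the filter
      idx <- ((2L * k - 2L + seq_len(L) - 1L) %% n) + 1L
      out[k] <- sum(rev(h) * x[idx])
    }
    out
  }
  list(approx = conv_down(.DB4_LO), detail = conv_down(.DB4_HI))
}

#' Multi-level discrete wavelet decomposition
#'
#' @param x Numeric signal.
#' @param wavelet One of `"spline53"`, `"cdf97"`, `"db4"`.
#' @param levels Decomposition depth (default 4).
#' @return A list with `details` (list of detail-coefficient vectors, level
#'   1 = finest) and `approx` (coarsest approximation).
#' @export
dwt_decompose <- function(x, wavelet = c("spline53", "cdf97", "db4"),
                          levels = 4L) {
  wavelet <- match.arg(wavelet)
  if (length(x) < 2^levels) {
    stop("dwt_decompose: signal length ", length(x),
         " below minimum 2^levels = ", 2^levels)
  }
  step <- switch(wavelet,
    spline53 = .dwt53_level,
    cdf97 = .dwt97_level,
    db4 = .dwt_db4_level
  )
  details <- vector("list", levels)
  cur <- as.numeric(x)
  for (lev in seq_len(levels)) {
    out <- step(cur)
    details[[lev]] <- out$detail
    cur <- out$approx
  }
  list(details = details, approx = cur)
}

#' Wavelet feature block: 12 summary statistics
#'
#' For each of the three transforms (spline 5/3, CDF 9/7, Daubechies db4) a
#' 4-level decomposition is computed and the maximum, minimum, mean and
#' variance of the concatenated detail coefficients of levels 3-4 (the
#' 8-32 Hz band at 256 Hz, where QRS energy lives) are returned, in fixed
#' order: spline53, cdf97, db4 by (max, min, mean, var).
#'
#' @param signal Numeric signal (mV), length at least `2^levels`.
#' @param levels Decomposition depth.
#' @param stat_levels Detail levels pooled for the statistics.
#' @return Named numeric vector of length 12.
#' @export
wavelet_features <- function(signal, levels = 4L, stat_levels = c(3L, 4L)) {
  wl <- c("spline53", "cdf97", "db4")
  out <- numeric(0)
  for (w in wl) {
    dec <- dwt_decompose(signal, w, levels)
    coefs <- unlist(dec$details[stat_levels])
    v <- if (length(coefs) > 1L) stats::var(coefs) else 0
    block <- c(max(coefs), min(coefs), mean(coefs), v)
    names(block) <- paste0("wv_", w, "_", c("max", "min", "mean", "var"))
    out <- c(out, block)
  }
  out
}
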