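# Synthetic ECG generator: morphology, class statistics, determinism.

test_that("a default beat has five extrema at its reported fiducials", {
  beat <- synth_beat(fs = 256)
  y <- beat$samples
  n <- length(y)
  loc_ext <- which((y[2:(n - 1)] - y[1:(n - 2)]) *
                   (y[3:n] - y[2:(n - 1)]) < 0) + 1L
  # keep extrema that are not numerically negligible
  loc_ext <- loc_ext[abs(y[loc_ext]) > 1e-3]
  expect_equal(length(loc_ext), 5L)
  fid_idx <- round((beat$fiducials$center_s - beat$offset_s) * 256) + 1L
  for (fi in fid_idx) expect_true(min(abs(loc_ext - fi)) <= 1)
  # r_amp = 0 drops the R extremum but keeps Q and S
  beat0 <- synth_beat(fs = 256, r_amp = 0)
  expect_setequal(beat0$fiducials$wave, c("p", "q", "s", "t"))
  # beat integral equals the closed-form sum of Gaussian areas within 1%
  got <- sum(beat$samples) / 256
  bumps <- telecg:::.beat_bumps(0.16, 0.09, 0.38, 0.15, -0.10, 1.2, -0.25, 0.30)
  want <- sum(bumps$amp * bumps$sigma_s * sqrt(2 * pi))
  expect_lt(abs(got - want), 0.01 * abs(want))
  expect_error(synth_beat(fs = 256, pr_s = 0.01), "parameter error")
})

test_that("sinus timing statistics follow the configuration", {
  sim <- synth_record(clean_cfg("SINUS", seed = 7, heart_rate_bpm = 80))
  tb <- sim$truth$beats
  expect_true(abs(nrow(tb) - 20) <= 1)
  rr <- diff(tb$r_index) / 256
  expect_lte(stats::sd(rr) / mean(rr), 0.05)
  expect_equal(sim$truth$labels, "SINUS")
})

test_that("AF records have irregular RR and mostly missing P in truth", {
  sim <- synth_record(clean_cfg("AF", seed = 11))
  tb <- sim$truth$beats
  rr <- diff(tb$r_index) / 256
  expect_gte(stats::sd(rr) / mean(rr), 0.15)
  expect_gte(mean(is.na(tb$p_index)), 0.8)
})

test_that("class-defining morphology appears in the ground truth", {
  avb <- synth_record(clean_cfg("AVB1", seed = 2))
  pr <- (avb$truth$beats$q_index - avb$truth$beats$p_index) / 256
  expect_true(all(abs(pr - 0.26) <= 2 / 256, na.rm = TRUE))
  vpc <- synth_record(clean_cfg("VPC", seed = 2, ectopic_rate = 0.3))
  expect_true(any(vpc$truth$beats$label == "VPC"))
  ect <- vpc$truth$beats$label == "VPC"
  w <- (vpc$truth$beats$s_index - vpc$truth$beats$q_index) / 256
  expect_gt(mean(w[ect]), 1.5 * mean(w[!ect]))
  qt <- synth_record(clean_cfg("QT_GT_450", seed = 2))
  expect_gt(mean((qt$truth$beats$t_index - qt$truth$beats$q_index) / 256,
                 na.rm = TRUE), 0.45)
  noise <- synth_record(simulation_config("NOISE", seed = 2))
  expect_equal(nrow(noise$truth$beats), 0L)
  expect_gt(stats::sd(noise$record$samples), 0.2)
})

test_that("noise-free truth fiducials coincide with waveform extrema", {
  is_local_ext <- function(y, i1) {
    lo <- max(2L, i1 - 1L); hi <- min(length(y) - 1L, i1 + 1L)
    any(vapply(lo:hi, function(j) {
      (y[j] >= y[j - 1L] && y[j] >= y[j + 1L]) ||
      (y[j] <= y[j - 1L] && y[j] <= y[j + 1L])
    }, logical(1)))
  }
  for (cls in c("SINUS", "AF", "TWI", "AVB1", "VPC")) {
    for (sd in 1:5) {
      sim <- synth_record(clean_cfg(cls, seed = sd))
      y <- sim$record$samples
      tb <- sim$truth$beats
      for (col in c("p_index", "r_index", "t_index")) {
        idx <- tb[[col]]
        idx <- idx[!is.na(idx)]
        ok <- vapply(idx + 1L, is_local_ext, logical(1), y = y)
        expect_true(all(ok),
                    info = sprintf("%s seed %d col %s", cls, sd, col))
      }
    }
  }
})

test_that("default-parameter records stay inside the device dynamic range", {
  for (cls in setdiff(label_vocabulary(), "UNCERTAIN")) {
    sim <- synth_record(simulation_config(cls, seed = 4))
    expect_lte(max(abs(sim$record$samples)), 2,
               label = paste("range for", cls))
  }
})

test_that("generation is bit-identical under a repeated seed", {
  a <- synth_record(simulation_config("AF", seed = 123))
  b <- synth_record(simulation_config("AF", seed = 123))
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$truth$beats, b$truth$beats)
  c1 <- make_corpus(c(SINUS = 2, AF = 2), seed = 5)
  c2 <- make_corpus(c(SINUS = 2, AF = 2), seed = 5)
  expect_identical(lapply(c1$records, `[[`, "samples"),
                   lapply(c2$records, `[[`, "samples"))
})

test_that("corpus generation matches requested counts and labels", {
  empty <- make_corpus(c(SINUS = 0, AF = 0), seed = 1)
  expect_length(empty$records, 0L)
  expect_equal(nrow(empty$labels), 0L)
  classes <- setdiff(label_vocabulary(), "UNCERTAIN")
  corp <- make_corpus(stats::setNames(rep(2, length(classes)), classes),
                      seed = 1)
  expect_length(corp$records, 2L * length(classes))
  expect_equal(nrow(corp$labels), 2L * length(classes))
  expect_setequal(unique(corp$labels$label), classes)
  # written corpus round-trips through the CSV dialect
  dir <- file.path(tempdir(), "corpus_io")
  make_corpus(c(SINUS = 1), seed = 3, dir = dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  rec <- read_csv_record(file.path(dir, "SINUS_001.csv"),
                         file.path(dir, "SINUS_001.json"))
  expect_equal(n_samples(rec), 3840L)
  expect_error(simulation_config("NOT_A_CLASS"), "unknown rhythm_class")
})
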