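# Seeded synthetic single-lead ECG generator. Beats are sums of five
# Gaussian bumps (P, Q, R, S, T) whose analytic centres provide exact
# fiducial ground truth; rhythm classes modulate RR statistics, P-wave
# presence and morphology; noise layers (sinusoidal baseline wander,
# powerline, white Gaussian) are added last. Everything is reproducible
# from the configuration seed.

#' Diagnosis label vocabulary
#'
#' @return Character vector of the supported record-level labels: sinus
#'   rhythm, ten disease classes, noise and uncertain.
#' @export
label_vocabulary <- function() {
  c("SINUS", "AF", "AFL", "PACEMAKER", "APC", "VPC", "TWI", "ST_DOWN",
    "AVB1", "JEB", "QT_GT_450", "NOISE", "UNCERTAIN")
}

# evaluate expr with a private RNG stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Simulation configuration
#'
#' Defaults mirror a 15-s, 256-Hz single-lead home-telehealth recording
#' with a +/-2 mV dynamic range; morphology defaults are textbook adult
#' values (PR 0.16 s measured P peak to Q trough, QRS 0.09 s, QT 0.38 s
#' measured Q to T peak, R 1.2 mV, T 0.3 mV). Class-specific fields are
#' filled automatically from `rhythm_class` unless overridden.
#'
#' @param rhythm_class One of [label_vocabulary()] except `"UNCERTAIN"`.
#' @param duration_s,fs Record length (s) and sampling rate (Hz).
#' @param heart_rate_bpm Mean heart rate.
#' @param rr_cv RR coefficient of variation.
#' @param pr_s,qrs_s,qt_s Segment durations (s).
#' @param p_amp,q_amp,r_amp,s_amp,t_amp Wave amplitudes (mV).
#' @param p_absent_prob Per-beat probability that the P wave is missing.
#' @param ectopic_rate Per-beat probability of an ectopic (APC/VPC/JEB) event.
#' @param wander_amp_mv,wander_freq_hz Sinusoidal baseline wander.
#' @param white_noise_rms_mv Additive white Gaussian noise RMS.
#' @param powerline_amp_mv 60 Hz interference amplitude.
#' @param seed RNG seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(rhythm_class = "SINUS", duration_s = 15,
                              fs = 256, heart_rate_bpm = 80, rr_cv = NULL,
                              pr_s = 0.16, qrs_s = 0.09, qt_s = 0.38,
                              p_amp = 0.15, q_amp = -0.10, r_amp = 1.2,
                              s_amp = -0.25, t_amp = 0.30,
                              p_absent_prob = NULL, ectopic_rate = NULL,
                              wander_amp_mv = 0.10, wander_freq_hz = 0.25,
                              white_noise_rms_mv = 0.02,
                              powerline_amp_mv = 0, seed = 1L) {
  if (!rhythm_class %in% setdiff(label_vocabulary(), "UNCERTAIN")) {
    stop("simulation_config: unknown rhythm_class '", rhythm_class, "'")
  }
  if (fs <= 80) stop("simulation_config: fs must exceed 80 Hz")
  if (duration_s < 2) stop("simulation_config: duration must be >= 2 s")
  # class-conditional defaults
  if (is.null(rr_cv)) {
    rr_cv <- switch(rhythm_class, AF = 0.25, NOISE = 0, 0.03)
  }
  if (is.null(p_absent_prob)) {
    p_absent_prob <- switch(rhythm_class, AF = 0.9, AFL = 1, PACEMAKER = 1, 0)
  }
  if (is.null(ectopic_rate)) {
    ectopic_rate <- switch(rhythm_class, APC = 0.2, VPC = 0.2, JEB = 0.2, 0)
  }
  if (rhythm_class == "AVB1" && pr_s < 0.21) pr_s <- 0.26
  if (rhythm_class == "QT_GT_450" && qt_s <= 0.45) qt_s <- 0.50
  if (rhythm_class == "QT_GT_450" && heart_rate_bpm >= 80) {
    # a long QT must end before the next P wave; pair it with the slower
    # rate at which such intervals are actually observed
    heart_rate_bpm <- 65
  }
  if (rhythm_class == "TWI") t_amp <- -abs(t_amp)
  if (rhythm_class == "NOISE") {
    white_noise_rms_mv <- max(white_noise_rms_mv, 0.30)
    wander_amp_mv <- max(wander_amp_mv, 0.40)
  }
  if (p_absent_prob < 0 || p_absent_prob > 1 ||
      ectopic_rate < 0 || ectopic_rate > 1) {
    stop("simulation_config: probabilities must lie in [0,1]")
  }
  structure(list(
    rhythm_class = rhythm_class, duration_s = duration_s, fs = fs,
    heart_rate_bpm = heart_rate_bpm, rr_cv = rr_cv,
    pr_s = pr_s, qrs_s = qrs_s, qt_s = qt_s,
    p_amp = p_amp, q_amp = q_amp, r_amp = r_amp, s_amp = s_amp,
    t_amp = t_amp, p_absent_prob = p_absent_prob,
    ectopic_rate = ectopic_rate, wander_amp_mv = wander_amp_mv,
    wander_freq_hz = wander_freq_hz,
    white_noise_rms_mv = white_noise_rms_mv,
    powerline_amp_mv = powerline_amp_mv, seed = as.integer(seed)
  ), class = "simulation_config")
}

# Gaussian bump description of one beat; centres in seconds relative to R.
# Widths (sigma) are fixed physiological fractions of the segment lengths.
.beat_bumps <- function(pr_s, qrs_s, qt_s, p_amp, q_amp, r_amp, s_amp, t_amp,
                        p_sigma_s = 0.020, t_sigma_s = 0.035) {
  q_c <- -qrs_s / 2
  data.frame(
    wave = c("p", "q", "r", "s", "t"),
    center_s = c(q_c - pr_s, q_c, 0, qrs_s / 2, q_c + qt_s),
    sigma_s = c(p_sigma_s, qrs_s / 11, qrs_s / 9, qrs_s / 11, t_sigma_s),
    amp = c(p_amp, q_amp, r_amp, s_amp, t_amp),
    stringsAsFactors = FALSE
  )
}

#' Synthesize one heartbeat
#'
#' A beat is the sum of five Gaussian bumps. The returned fiducials are the
#' analytic bump centres (the waveform extrema when the bumps are well
#' separated).
#'
#' @param fs Sampling rate (Hz).
#' @param pr_s,qrs_s,qt_s Segment durations (s); `pr_s` must exceed the P
#'   width or the P and Q waves would overlap.
#' @param p_amp,q_amp,r_amp,s_amp,t_amp Amplitudes (mV); a zero amplitude
#'   drops that wave.
#' @return A list: `samples` (mV), `offset_s` (time of the first sample
#'   relative to the R peak) and `fiducials` (data frame of wave,
#'   `center_s` relative to R, `amp`).
#' @export
synth_beat <- function(fs, pr_s = 0.16, qrs_s = 0.09, qt_s = 0.38,
                       p_amp = 0.15, q_amp = -0.10, r_amp = 1.2,
                       s_amp = -0.25, t_amp = 0.30) {
  if (qrs_s >= qt_s) stop("synth_beat: qrs_s must be smaller than qt_s")
  bumps <- .beat_bumps(pr_s, qrs_s, qt_s, p_amp, q_amp, r_amp, s_amp, t_amp)
  if (pr_s < 2 * bumps$sigma_s[bumps$wave == "p"]) {
    stop("synth_beat: parameter error - PR shorter than the P-wave width")
  }
  lo <- min(bumps$center_s) - 4 * max(bumps$sigma_s)
  hi <- max(bumps$center_s) + 4 * max(bumps$sigma_s)
  t <- seq(floor(lo * fs), ceiling(hi * fs)) / fs
  y <- numeric(length(t))
  for (i in seq_len(nrow(bumps))) {
    if (bumps$amp[i] == 0) next
    y <- y + bumps$amp[i] * exp(-(t - bumps$center_s[i])^2 /
                                  (2 * bumps$sigma_s[i]^2))
  }
  list(samples = y, offset_s = t[1L],
       fiducials = bumps[bumps$amp != 0, c("wave", "center_s", "amp")])
}

#' Synthesize a full annotated record
#'
#' Generates the beat train for the configured rhythm class, adds the
#' class-specific morphology (fibrillatory P replacement for AF, flutter
#' sawtooth for AFL, pacing spikes, premature narrow/wide ectopics, ST
#' depression, pauses with escape beats, ...), then the noise layers.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `record` (an [ecg_record]) and `truth`, which holds
#'   `beats` (per-beat 0-based fiducial indices, NA for absent waves, and a
#'   per-beat label in NORMAL/APC/VPC/ESCAPE), `labels` (record-level label
#'   set), and the noise descriptors.
#' @export
synth_record <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  .with_seed(cfg$seed, .synth_record_impl(cfg))
}

.synth_record_impl <- function(cfg) {
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  y <- numeric(n)
  beats <- data.frame(p_index = integer(0), q_index = integer(0),
                      r_index = integer(0), s_index = integer(0),
                      t_index = integer(0), label = character(0),
                      stringsAsFactors = FALSE)
  if (cfg$rhythm_class != "NOISE") {
    rr_mean <- 60 / cfg$heart_rate_bpm
    # lay out beats: R centres
    r_times <- numeric(0); beat_kind <- character(0)
    cur <- 0.45
    repeat {
      rr <- max(0.35, stats::rnorm(1, rr_mean, cfg$rr_cv * rr_mean))
      kind <- "NORMAL"
      if (cfg$rhythm_class %in% c("APC", "VPC") && length(r_times) >= 2 &&
          stats::runif(1) < cfg$ectopic_rate) {
        rr <- rr * if (cfg$rhythm_class == "VPC") 0.65 else 0.6
        kind <- cfg$rhythm_class
      }
      if (cfg$rhythm_class == "JEB" && length(r_times) >= 2 &&
          stats::runif(1) < cfg$ectopic_rate) {
        rr <- rr * 1.8                       # sinus pause, escape beat ends it
        kind <- "ESCAPE"
      }
      nxt <- if (length(r_times)) r_times[length(r_times)] + rr else cur
      if (nxt > cfg$duration_s - 0.55) break
      r_times <- c(r_times, nxt)
      beat_kind <- c(beat_kind, kind)
    }
    rows <- vector("list", length(r_times))
    for (b in seq_along(r_times)) {
      kind <- beat_kind[b]
      qrs <- cfg$qrs_s; ra <- cfg$r_amp; sa <- cfg$s_amp
      pa <- cfg$p_amp; pr <- cfg$pr_s; qt <- cfg$qt_s
      p_absent <- stats::runif(1) < cfg$p_absent_prob
      if (kind == "VPC") {
        qrs <- qrs * 2; ra <- ra * 1.4; sa <- sa * 1.8; p_absent <- TRUE
      }
      if (kind == "ESCAPE") p_absent <- TRUE
      if (p_absent) pa <- 0
      bumps <- .beat_bumps(pr, qrs, qt, pa, cfg$q_amp, ra, sa, cfg$t_amp)
      for (i in seq_len(nrow(bumps))) {
        if (bumps$amp[i] == 0) next
        c_t <- r_times[b] + bumps$center_s[i]
        y <- y + bumps$amp[i] * exp(-(t - c_t)^2 / (2 * bumps$sigma_s[i]^2))
      }
      idx_of <- function(w) {
        i <- round((r_times[b] + bumps$center_s[bumps$wave == w]) * fs)
        if (i < 0 || i >= n) NA_integer_ else as.integer(i)
      }
      rows[[b]] <- data.frame(
        p_index = if (p_absent) NA_integer_ else idx_of("p"),
        q_index = idx_of("q"), r_index = idx_of("r"),
        s_index = idx_of("s"), t_index = idx_of("t"),
        label = if (kind == "ESCAPE") "NORMAL" else kind,
        stringsAsFactors = FALSE
      )
      # class-specific extras tied to this beat
      if (cfg$rhythm_class == "PACEMAKER") {
        spike_t <- r_times[b] - qrs / 2 - 0.02
        y <- y + 0.8 * exp(-(t - spike_t)^2 / (2 * 0.002^2))
      }
      if (cfg$rhythm_class == "AF" && p_absent) {
        # fibrillatory oscillation where the P wave would sit
        span <- t > r_times[b] - pr - 0.10 & t < r_times[b] - qrs / 2 - 0.02
        y[span] <- y[span] +
          0.05 * sin(2 * pi * 7 * t[span] + stats::runif(1, 0, 2 * pi))
      }
      if (cfg$rhythm_class == "ST_DOWN") {
        # depressed plateau over the S-T segment with a gradual return to
        # baseline (cosine-tapered edges) as seen in ischemic depression
        lo_t <- r_times[b] + qrs / 2 + 0.02
        hi_t <- r_times[b] - qrs / 2 + qt + 2 * 0.035
        ramp <- 0.06
        up <- pmin(1, pmax(0, (t - lo_t) / ramp))
        dn <- pmin(1, pmax(0, (hi_t + ramp - t) / ramp))
        w_pl <- (1 - cos(pi * up)) / 2 * (1 - cos(pi * dn)) / 2
        y <- y - 0.15 * w_pl
      }
    }
    if (length(rows)) beats <- do.call(rbind, rows)
    if (cfg$rhythm_class == "AFL") {
      # continuous ~5 Hz sawtooth flutter waves, attenuated during QRS
      saw <- 0.15 * (2 * ((5 * t) %% 1) - 1)
      qrs_mask <- rep(1, n)
      for (rt in r_times) {
        qrs_mask[t > rt - cfg$qrs_s & t < rt + cfg$qrs_s] <- 0
      }
      y <- y + saw * qrs_mask
    }
    if (nrow(beats)) {
      # snap truth indices to the actual extrema of the noise-free waveform:
      # overlapping wave tails (e.g. a T wave brushing a long-PR P wave)
      # shift an apex by a sample or two relative to the analytic centre
      snap <- function(idx, polarity, drop_fused = FALSE) {
        vapply(idx, function(i) {
          if (is.na(i)) return(NA_integer_)
          lo <- max(0L, i - 3L); hi <- min(n - 1L, i + 3L)
          seg <- y[(lo + 1L):(hi + 1L)] * polarity
          k <- lo + which.max(seg) - 1L
          if (drop_fused) {
            # a wave swallowed by a neighbour's slope has no apex of its
            # own; the emitted waveform then carries no such peak at all
            v <- y[k + 1L] * polarity
            nb <- y[c(max(1L, k), min(n, k + 2L))] * polarity
            if (any(v < nb)) return(NA_integer_)
          }
          k
        }, integer(1))
      }
      beats$p_index <- snap(beats$p_index, +1, drop_fused = TRUE)
      beats$q_index <- snap(beats$q_index, -1)
      beats$r_index <- snap(beats$r_index, sign(cfg$r_amp))
      beats$s_index <- snap(beats$s_index, -1)
      beats$t_index <- snap(beats$t_index, sign(cfg$t_amp),
                            drop_fused = TRUE)
    }
  }
  noise <- list(wander_amp_mv = cfg$wander_amp_mv,
                wander_freq_hz = cfg$wander_freq_hz,
                white_noise_rms_mv = cfg$white_noise_rms_mv,
                powerline_amp_mv = cfg$powerline_amp_mv)
  if (cfg$wander_amp_mv > 0) {
    y <- y + cfg$wander_amp_mv *
      sin(2 * pi * cfg$wander_freq_hz * t + stats::runif(1, 0, 2 * pi))
  }
  if (cfg$powerline_amp_mv > 0) {
    y <- y + cfg$powerline_amp_mv * sin(2 * pi * 60 * t)
  }
  if (cfg$white_noise_rms_mv > 0) {
    y <- y + stats::rnorm(n, 0, cfg$white_noise_rms_mv)
  }
  rec_id <- sprintf("sim_%s_%d", cfg$rhythm_class, cfg$seed)
  record <- ecg_record(y, fs = fs, record_id = rec_id, lead = "I")
  labels <- cfg$rhythm_class
  list(record = record,
       truth = list(beats = beats, labels = labels, noise = noise,
                    config = cfg))
}

#' Generate a labelled corpus of simulated records
#'
#' Per-record seeds are derived deterministically from the master seed, so
#' two corpora built from the same arguments are identical.
#'
#' @param class_counts Named integer vector: records per rhythm class.
#' @param seed Master seed.
#' @param dir Optional output directory; when given, each record is written
#'   in the CSV/JSON dialect together with its truth JSON, plus a
#'   `labels.csv` table.
#' @param ... Extra arguments forwarded to [simulation_config()].
#' @return Invisibly (when `dir` is given) or visibly, a list with
#'   `records` (list of [ecg_record]), `truths` (per-record truth lists)
#'   and `labels` (data frame `record_id`, `label`).
#' @export
make_corpus <- function(class_counts, seed = 1L, dir = NULL, ...) {
  stopifnot(all(class_counts >= 0))
  classes <- names(class_counts)
  if (is.null(classes)) stop("make_corpus: class_counts must be named")
  records <- list(); truths <- list()
  ids <- character(0); labs <- character(0)
  k <- 0L
  for (ci in seq_along(classes)) {
    for (rep in seq_len(class_counts[[ci]])) {
      k <- k + 1L
      sub_seed <- (as.numeric(seed) * 7919 + ci * 1009 + rep) %% 2147483647
      cfg <- simulation_config(rhythm_class = classes[ci],
                               seed = as.integer(sub_seed), ...)
      sim <- synth_record(cfg)
      sim$record$record_id <- sprintf("%s_%03d", classes[ci], rep)
      records[[k]] <- sim$record
      truths[[k]] <- sim$truth
      ids <- c(ids, sim$record$record_id)
      labs <- c(labs, classes[ci])
    }
  }
  labels <- data.frame(record_id = ids, label = labs, stringsAsFactors = FALSE)
  out <- list(records = records, truths = truths, labels = labels)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(records)) {
      id <- records[[k]]$record_id
      write_csv_record(records[[k]], file.path(dir, paste0(id, ".csv")),
                       file.path(dir, paste0(id, ".json")))
      jsonlite::write_json(
        list(beats = truths[[k]]$beats, labels = truths[[k]]$labels),
        file.path(dir, paste0(id, ".truth.json")),
        auto_unbox = TRUE, digits = NA, na = "null")
    }
    utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
    return(invisible(out))
  }
  out
}
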