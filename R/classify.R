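# Hybrid multi-label diagnosis: one-vs-rest RBF SVM heads for the rhythm
# classes and noise, a rule-based weighted-Bayesian detector for premature
# beats, and a staged integration that combines the two by conjunction
# rather than plain OR (the rule flag alone cannot assert APC/VPC, and a
# high noise score pre-empts every disease label).

#' SVM configuration
#'
#' @param slack_C Soft-margin cost (default 100).
#' @param gamma RBF kernel width, a positive number or `"scale"` for the
#'   data-adaptive heuristic `1 / (n_features * var(X))` computed on the
#'   standardized training matrix.
#' @param seed Seed stored with the model (training itself is
#'   deterministic).
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(slack_C = 100, gamma = "scale", seed = 1L) {
  if (slack_C <= 0) stop("svm_config: slack_C must be positive")
  if (is.numeric(gamma) && gamma <= 0) stop("svm_config: gamma must be positive")
  structure(list(slack_C = slack_C, gamma = gamma, seed = as.integer(seed)),
            class = "svm_config")
}

#' Rule-classifier configuration
#'
#' Evidence terms per beat: (1) prematurity `rr_ratio < 1 - delta`,
#' (2) wide QRS `width > qrs_wide_factor * local mean width`,
#' (3) elevated amplitudes (|R|, |S| and |Q| all above their local means).
#' The posterior is a logistic function of the weighted evidence sum; with
#' the default unit weights a single positive term yields a posterior of
#' about 0.27, so the default decision threshold 0.25 lets one strong
#' evidence term carry a detection while an evidence-free beat (posterior
#' 0.05) stays NORMAL.
#'
#' @param rule_weights Non-negative weights for the three evidence terms.
#' @param decision_threshold Posterior cut in (0,1).
#' @param qrs_wide_factor Width ratio defining a wide QRS.
#' @param local_window Number of beats whose neighbourhood defines the
#'   local averages (half-window on each side = `(local_window - 1) / 2`).
#' @param delta Prematurity margin on the RR ratio.
#' @return A list of class `rule_classifier_config`.
#' @export
rule_classifier_config <- function(rule_weights = c(1, 1, 1),
                                   decision_threshold = 0.25,
                                   qrs_wide_factor = 1.5,
                                   local_window = 5L, delta = 0.1) {
  if (length(rule_weights) != 3L || any(rule_weights < 0) ||
      any(!is.finite(rule_weights))) {
    stop("rule_classifier_config: need three finite non-negative weights")
  }
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    stop("rule_classifier_config: decision_threshold must lie in (0,1)")
  }
  if (qrs_wide_factor <= 1) {
    stop("rule_classifier_config: qrs_wide_factor must exceed 1")
  }
  structure(list(rule_weights = rule_weights,
                 decision_threshold = decision_threshold,
                 qrs_wide_factor = qrs_wide_factor,
                 local_window = as.integer(local_window), delta = delta),
            class = "rule_classifier_config")
}

#' Integration gates
#'
#' @param noise_threshold NOISE score at or above which the record is
#'   labelled noise and nothing else.
#' @param min_beats_apc,min_beats_vpc Minimum rule-flagged beats required.
#' @param veto_floor Minimum SVM score required alongside the rule flags
#'   (the conjunction that replaces plain OR).
#' @param label_threshold SVM score cut for the rhythm labels.
#' @param uncertain_band Records with every disease score below this band
#'   and no label assigned are called sinus; otherwise uncertain.
#' @param qt_limit_s Mean QT beyond which the long-QT label is set
#'   (deterministic rule, not an SVM head).
#' @return A list of class `integration_config`.
#' @export
integration_config <- function(noise_threshold = 0.5, min_beats_apc = 2L,
                               min_beats_vpc = 1L, veto_floor = 0.3,
                               label_threshold = 0.5, uncertain_band = 0.35,
                               qt_limit_s = 0.450) {
  structure(list(noise_threshold = noise_threshold,
                 min_beats_apc = as.integer(min_beats_apc),
                 min_beats_vpc = as.integer(min_beats_vpc),
                 veto_floor = veto_floor, label_threshold = label_threshold,
                 uncertain_band = uncertain_band, qt_limit_s = qt_limit_s),
            class = "integration_config")
}

#' Construct a label set
#'
#' Enforces the vocabulary invariants: NOISE and UNCERTAIN exclude every
#' other label; SINUS excludes disease labels; disease labels may co-occur.
#'
#' @param labels Character vector from [label_vocabulary()].
#' @param confidence Named numeric confidences in `[0,1]`.
#' @return A `label_set` list.
#' @export
label_set <- function(labels, confidence = NULL) {
  labels <- unique(as.character(labels))
  bad <- setdiff(labels, label_vocabulary())
  if (length(bad)) stop("label_set: unknown label(s) ", paste(bad, collapse = ", "))
  if (("NOISE" %in% labels || "UNCERTAIN" %in% labels) && length(labels) > 1L) {
    stop("label_set: NOISE/UNCERTAIN must be exclusive")
  }
  if ("SINUS" %in% labels && length(labels) > 1L) {
    stop("label_set: SINUS excludes disease labels")
  }
  if (is.null(confidence)) {
    confidence <- stats::setNames(rep(1, length(labels)), labels)
  }
  structure(list(labels = labels, confidence = confidence),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat("<label_set>", paste(x$labels, collapse = "+"), "\n")
  invisible(x)
}

# labels learned by SVM heads (long QT is a deterministic rule; sinus and
# uncertain are fall-throughs)
.svm_head_labels <- function() {
  c("AF", "AFL", "PACEMAKER", "APC", "VPC", "TWI", "ST_DOWN", "AVB1",
    "JEB", "NOISE")
}

# deterministic content hash of the model's defining numbers
.bundle_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(obj, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}

#' Train the one-vs-rest SVM bundle
#'
#' One binary RBF SVM per disease label plus one for noise. Features are
#' mean-imputed and z-scored with training-set statistics that are stored
#' in the bundle; a head whose label never (or always) occurs in the
#' training data is skipped with a warning.
#'
#' @param features Numeric matrix, one row per record, named columns.
#' @param labels Character vector (multi-labels joined by `+`), one per row.
#' @param cfg An [svm_config()].
#' @return A `svm_bundle` list: `heads` (fitted models), `feature_names`,
#'   `center`, `scale`, `impute`, `cfg`, `gamma`, and a deterministic
#'   `hash` of the model content.
#' @export
train_svm <- function(features, labels, cfg = svm_config()) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (is.null(colnames(features))) stop("train_svm: features must be named")
  impute <- apply(features, 2L, function(v) {
    m <- mean(v, na.rm = TRUE); if (is.finite(m)) m else 0
  })
  x <- features
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- impute[j]
  center <- colMeans(x)
  scale_ <- apply(x, 2L, stats::sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  g <- if (identical(cfg$gamma, "scale")) {
    v <- stats::var(as.vector(xs)); 1 / (ncol(xs) * max(v, 1e-12))
  } else cfg$gamma
  lab_list <- strsplit(labels, "\\+")
  heads <- list()
  for (lab in .svm_head_labels()) {
    y_pos <- vapply(lab_list, function(v) lab %in% v, logical(1))
    if (length(unique(y_pos)) < 2L) {
      warning("train_svm: label ", lab,
              " has a single class in training data; head skipped")
      next
    }
    y <- factor(ifelse(y_pos, "pos", "neg"), levels = c("pos", "neg"))
    heads[[lab]] <- .with_seed(cfg$seed,
      e1071::svm(xs, y, kernel = "radial", cost = cfg$slack_C, gamma = g,
                 scale = FALSE))
  }
  bundle <- list(heads = heads, feature_names = colnames(features),
                 center = center, scale = scale_, impute = impute,
                 cfg = cfg, gamma = g)
  core <- lapply(bundle$heads, function(m)
    list(sv = m$SV, coefs = m$coefs, rho = m$rho))
  bundle$hash <- .bundle_hash(list(core, center, scale_, impute, g,
                                   cfg$slack_C))
  class(bundle) <- "svm_bundle"
  bundle
}

#' Score a feature vector with every SVM head
#'
#' Columns are matched by name (order-insensitive); a missing or unknown
#' column raises a schema error naming it. Decision values are mapped to
#' `[0,1]` by the logistic function, a monotone calibration of the margin.
#'
#' @param bundle A `svm_bundle` from [train_svm()].
#' @param features Named numeric vector or one-row matrix.
#' @return Named numeric scores in `[0,1]`, one per trained head.
#' @export
svm_predict <- function(bundle, features) {
  if (is.matrix(features)) features <- features[1L, ]
  nm <- names(features)
  miss <- setdiff(bundle$feature_names, nm)
  if (length(miss)) {
    stop("svm_predict: feature schema mismatch; missing column '",
         miss[1L], "'")
  }
  x <- features[bundle$feature_names]
  x[is.na(x)] <- bundle$impute[is.na(x)]
  xs <- (x - bundle$center) / bundle$scale
  xs <- matrix(xs, nrow = 1L, dimnames = list(NULL, bundle$feature_names))
  out <- vapply(bundle$heads, function(m) {
    dvm <- attr(stats::predict(m, xs, decision.values = TRUE),
                "decision.values")
    dv <- dvm[1L]
    # libsvm orients the margin toward whichever class it saw first
    if (identical(colnames(dvm)[1L], "neg/pos")) dv <- -dv
    stats::plogis(dv)
  }, numeric(1))
  out
}

#' Rule-based premature-beat detection
#'
#' Scans every beat with [beat_rule_features()] evidence: prematurity of
#' the RR interval, QRS widening, and elevated R/S/Q amplitudes relative
#' to the local neighbourhood. The weighted evidence sum is squashed
#' through a logistic posterior; a beat above the decision threshold is
#' VPC when its QRS is wide and APC when it is premature but narrow.
#'
#' @param fiducials A `fiducial_set`.
#' @param rule_cfg A [rule_classifier_config()].
#' @return Data frame with one row per beat: `label`
#'   (NORMAL/APC/VPC) and `posterior`. With fewer beats than
#'   `local_window` every beat is NORMAL and a warning is emitted.
#' @export
rule_classify_beats <- function(fiducials, rule_cfg = rule_classifier_config()) {
  n <- nrow(fiducials)
  out <- data.frame(label = rep("NORMAL", n), posterior = rep(0, n),
                    stringsAsFactors = FALSE)
  if (n < rule_cfg$local_window) {
    warning("rule_classify_beats: fewer beats (", n,
            ") than local_window; all beats NORMAL")
    return(out)
  }
  half <- (rule_cfg$local_window - 1L) %/% 2L
  w <- rule_cfg$rule_weights
  qrs <- fiducials$qrs_width_s
  for (b in seq_len(n)) {
    nb <- setdiff(max(1L, b - half):min(n, b + half), b)
    rf <- beat_rule_features(fiducials, b, local_half_window = half)
    e1 <- !is.na(rf$rr_ratio) && rf$rr_ratio < 1 - rule_cfg$delta
    local_qrs <- mean(qrs[nb], na.rm = TRUE)
    e2 <- !is.na(qrs[b]) && is.finite(local_qrs) &&
      qrs[b] > rule_cfg$qrs_wide_factor * local_qrs
    amp_gt <- function(v) {
      cur <- abs(v[b]); loc <- mean(abs(v[nb]), na.rm = TRUE)
      !is.na(cur) && is.finite(loc) && cur > loc
    }
    e3 <- amp_gt(fiducials$r_amp) && amp_gt(fiducials$s_amp) &&
      amp_gt(fiducials$q_amp)
    post <- stats::plogis(sum(w * (2 * c(e1, e2, e3) - 1)))
    out$posterior[b] <- post
    if (post >= rule_cfg$decision_threshold) {
      if (e2) out$label[b] <- "VPC"
      else if (e1) out$label[b] <- "APC"
    }
  }
  out
}

#' Integrate SVM scores and rule flags into a label set
#'
#' Staged decision: (i) a noise score at or above the gate yields NOISE
#' and stops; (ii) APC/VPC require both enough rule-flagged beats and an
#' SVM score above the veto floor — a conjunction, not a union; (iii)
#' rhythm labels come from SVM scores above the label threshold, and the
#' long-QT label from the deterministic mean-QT rule; (iv) with no label
#' assigned, the record is sinus when every disease score sits below the
#' uncertain band, otherwise uncertain.
#'
#' @param svm_scores Named scores from [svm_predict()].
#' @param rule_beats Data frame from [rule_classify_beats()].
#' @param gates An [integration_config()].
#' @param mean_qt_s Record mean QT (s), NA when unknown.
#' @return A [label_set()].
#' @export
integrate <- function(svm_scores, rule_beats, gates = integration_config(),
                      mean_qt_s = NA_real_) {
  score <- function(lab) {
    if (lab %in% names(svm_scores)) unname(svm_scores[[lab]]) else 0
  }
  if (score("NOISE") >= gates$noise_threshold) {
    return(label_set("NOISE", c(NOISE = score("NOISE"))))
  }
  labels <- character(0); conf <- numeric(0)
  n_apc <- sum(rule_beats$label == "APC")
  n_vpc <- sum(rule_beats$label == "VPC")
  if (n_apc >= gates$min_beats_apc && score("APC") >= gates$veto_floor) {
    labels <- c(labels, "APC")
    conf <- c(conf, APC = max(score("APC"),
                              max(rule_beats$posterior[rule_beats$label == "APC"])))
  }
  if (n_vpc >= gates$min_beats_vpc && score("VPC") >= gates$veto_floor) {
    labels <- c(labels, "VPC")
    conf <- c(conf, VPC = max(score("VPC"),
                              max(rule_beats$posterior[rule_beats$label == "VPC"])))
  }
  for (lab in c("AF", "AFL", "PACEMAKER", "AVB1", "TWI", "ST_DOWN", "JEB")) {
    if (score(lab) >= gates$label_threshold) {
      labels <- c(labels, lab)
      conf <- c(conf, stats::setNames(score(lab), lab))
    }
  }
  if (!is.na(mean_qt_s) && mean_qt_s > gates$qt_limit_s) {
    labels <- c(labels, "QT_GT_450")
    conf <- c(conf, QT_GT_450 = 1)
  }
  if (length(labels)) return(label_set(labels, conf))
  disease <- setdiff(.svm_head_labels(), "NOISE")
  dscores <- vapply(disease, score, numeric(1))
  if (all(dscores < gates$uncertain_band)) {
    label_set("SINUS", c(SINUS = 1 - max(dscores, 0)))
  } else {
    label_set("UNCERTAIN", c(UNCERTAIN = max(dscores)))
  }
}

#' Classify a record end to end
#'
#' Preprocess, delineate, extract features, score the SVM heads, run the
#' rule-based beat detector, and integrate. A record in which delineation
#' finds no beats is labelled UNCERTAIN (unless the noise gate fires).
#'
#' @param record An [ecg_record].
#' @param bundle A trained `svm_bundle`.
#' @param del_cfg,feat_cfg,rule_cfg,gates Stage configurations.
#' @return A [label_set()].
#' @export
classify_record <- function(record, bundle,
                            del_cfg = delineation_config(),
                            feat_cfg = features_config(),
                            rule_cfg = rule_classifier_config(),
                            gates = integration_config()) {
  rec <- preprocess_record(record)
  fid <- withCallingHandlers(
    delineate(rec, del_cfg, preprocessed = TRUE),
    warning = function(w) invokeRestart("muffleWarning"))
  fv <- extract_features(rec, fid, feat_cfg, preprocessed = TRUE)
  scores <- svm_predict(bundle, fv)
  if (nrow(fid) == 0L) {
    if (("NOISE" %in% names(scores)) &&
        scores[["NOISE"]] >= gates$noise_threshold) {
      return(label_set("NOISE", c(NOISE = scores[["NOISE"]])))
    }
    return(label_set("UNCERTAIN", c(UNCERTAIN = 1)))
  }
  rule_beats <- withCallingHandlers(
    rule_classify_beats(fid, rule_cfg),
    warning = function(w) invokeRestart("muffleWarning"))
  mean_qt <- if (all(is.na(fid$qt_len_s))) NA_real_ else
    mean(fid$qt_len_s, na.rm = TRUE)
  integrate(scores, rule_beats, gates, mean_qt_s = mean_qt)
}
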