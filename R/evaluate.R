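# Beat-matching and classification scoring.
#
# Detector metrics follow the standard confusion-count definitions:
#   SE  = TP / (TP + FN)            sensitivity
#   +P  = TP / (TP + FP)            positive prediction rate
#   DER = (FP + FN) / (TP + FN)     detection error rate (may exceed 100%)
#   SP  = TN / (TN + FP)            specificity
#   ACC = (TP + TN) / (TP + TN + FP + FN)
# Values are kept at full precision internally; presentation rounds
# half-up to two decimals.

#' Confusion counts
#' @param tp,fn,fp True positives, false negatives, false positives.
#' @param tn True negatives, or NA for beat detection where the negative
#'   class is undefined.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fn, fp, tn = NA_integer_) {
  vals <- c(tp = tp, fn = fn, fp = fp)
  if (any(vals < 0) || (!is.na(tn) && tn < 0)) {
    stop("confusion_counts: counts must be non-negative")
  }
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_counts")
}

#' Match detected beats against reference beats
#'
#' Greedy one-to-one matching: scanning both sorted index sequences from
#' the left, each detection is paired with the earliest unmatched reference
#' beat within `tolerance_s`. For 1-D sequences this attains the maximum
#' possible number of pairs. Unmatched reference beats are false negatives;
#' unmatched detections are false positives. TN is undefined for beat
#' detection and reported NA.
#'
#' @param detected,truth Sorted 0-based sample indices.
#' @param fs Sampling rate (Hz).
#' @param tolerance_s Matching half-window (default 0.150 s).
#' @return A [confusion_counts()].
#' @export
match_beats <- function(detected, truth, fs, tolerance_s = 0.150) {
  if (is.unsorted(detected, strictly = FALSE) ||
      is.unsorted(truth, strictly = FALSE)) {
    stop("match_beats: inputs must be sorted")
  }
  tol <- tolerance_s * fs
  i <- 1L; j <- 1L; tp <- 0L
  nd <- length(detected); nt <- length(truth)
  while (i <= nd && j <= nt) {
    dt <- detected[i] - truth[j]
    if (abs(dt) <= tol) {
      tp <- tp + 1L; i <- i + 1L; j <- j + 1L
    } else if (dt < 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  confusion_counts(tp = tp, fn = nt - tp, fp = nd - tp)
}

# round half-up at two decimals (presentation only)
.round2 <- function(x) {
  ifelse(is.na(x), NA_real_, sign(x) * floor(abs(x) * 100 + 0.5) / 100)
}

.pct <- function(num, den) {
  if (is.na(den) || den <= 0) return(NA_real_)
  100 * num / den
}

#' Sensitivity SE = TP / (TP + FN)
#' @param counts A [confusion_counts()].
#' @return Percentage at full precision (NA when the denominator is 0).
#' @export
se <- function(counts) .pct(counts$tp, counts$tp + counts$fn)

#' Positive prediction rate +P = TP / (TP + FP)
#' @inheritParams se
#' @return Percentage at full precision.
#' @export
ppv <- function(counts) .pct(counts$tp, counts$tp + counts$fp)

#' Detection error rate DER = (FP + FN) / (TP + FN)
#' @inheritParams se
#' @return Percentage at full precision (can exceed 100).
#' @export
der <- function(counts) .pct(counts$fp + counts$fn, counts$tp + counts$fn)

#' Specificity SP = TN / (TN + FP)
#' @inheritParams se
#' @return Percentage at full precision.
#' @export
sp <- function(counts) {
  if (is.na(counts$tn)) return(NA_real_)
  .pct(counts$tn, counts$tn + counts$fp)
}

#' Accuracy ACC = (TP + TN) / (TP + TN + FP + FN)
#' @inheritParams se
#' @return Percentage at full precision.
#' @export
acc <- function(counts) {
  if (is.na(counts$tn)) return(NA_real_)
  .pct(counts$tp + counts$tn,
       counts$tp + counts$tn + counts$fp + counts$fn)
}

#' Round a percentage for presentation (half-up, two decimals)
#' @param x Numeric percentage(s).
#' @return Rounded value(s).
#' @export
format_pct <- function(x) .round2(x)

#' Per-label one-vs-rest classification report
#'
#' Scores record-level multi-label predictions against reference labels.
#' Each vocabulary label yields a one-vs-rest confusion row; three
#' aggregate rows follow the conventional summary layout: `Sinus`
#' (positive class = sinus), `Disease/All` (positive = any disease label)
#' and `Noise`.
#'
#' @param predictions,truth Data frames with columns `record_id` and
#'   `labels` (multi-labels joined by `+`).
#' @return A `performance_report` data frame: `label`, `tp`, `fn`, `fp`,
#'   `tn`, `acc_pct`, `se_pct`, `sp_pct`, `ppv_pct`, `der_pct`
#'   (presentation-rounded percentages).
#' @export
evaluate_classifier <- function(predictions, truth) {
  missing_ids <- setdiff(truth$record_id, predictions$record_id)
  extra_ids <- setdiff(predictions$record_id, truth$record_id)
  if (length(missing_ids) || length(extra_ids)) {
    stop("evaluate_classifier: record id mismatch; missing: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         "; unexpected: ", paste(utils::head(extra_ids, 5), collapse = ", "))
  }
  pred <- predictions[match(truth$record_id, predictions$record_id), ]
  split_labels <- function(x) strsplit(as.character(x), "\\+")
  p_lab <- split_labels(pred$labels)
  t_lab <- split_labels(truth$labels)
  disease <- setdiff(label_vocabulary(), c("SINUS", "NOISE", "UNCERTAIN"))
  has <- function(lst, lab) vapply(lst, function(v) lab %in% v, logical(1))
  has_any <- function(lst, labs) vapply(lst, function(v) any(v %in% labs),
                                        logical(1))
  one_row <- function(name, p_pos, t_pos) {
    cc <- confusion_counts(tp = sum(p_pos & t_pos), fn = sum(!p_pos & t_pos),
                           fp = sum(p_pos & !t_pos), tn = sum(!p_pos & !t_pos))
    data.frame(label = name, tp = cc$tp, fn = cc$fn, fp = cc$fp, tn = cc$tn,
               acc_pct = .round2(acc(cc)), se_pct = .round2(se(cc)),
               sp_pct = .round2(sp(cc)), ppv_pct = .round2(ppv(cc)),
               der_pct = .round2(der(cc)), stringsAsFactors = FALSE)
  }
  rows <- lapply(setdiff(label_vocabulary(), "UNCERTAIN"), function(lab) {
    one_row(lab, has(p_lab, lab), has(t_lab, lab))
  })
  rows <- c(rows, list(
    one_row("Sinus", has(p_lab, "SINUS"), has(t_lab, "SINUS")),
    one_row("Disease/All", has_any(p_lab, disease), has_any(t_lab, disease)),
    one_row("Noise", has(p_lab, "NOISE"), has(t_lab, "NOISE"))
  ))
  out <- do.call(rbind, rows)
  class(out) <- c("performance_report", "data.frame")
  out
}
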