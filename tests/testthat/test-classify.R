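# SVM heads, rule-based beat detector, integration gates, end-to-end.

make_toy_training <- function(n = 40, seed = 1) {
  set.seed(seed)
  x1 <- cbind(rnorm(n, -2, 0.3), rnorm(n, -2, 0.3))
  x2 <- cbind(rnorm(n, 2, 0.3), rnorm(n, 2, 0.3))
  fm <- rbind(x1, x2)
  colnames(fm) <- c("f1", "f2")
  labels <- c(rep("AF", n), rep("SINUS", n))
  list(features = fm, labels = labels)
}

test_that("a separable toy problem is fit perfectly and reproducibly", {
  toy <- make_toy_training()
  expect_warning(bundle <- train_svm(toy$features, toy$labels),
                 "single class")   # only the AF head is trainable
  expect_named(bundle$heads, "AF")
  scores <- apply(toy$features, 1L, function(row) {
    svm_predict(bundle, row)[["AF"]]
  })
  expect_true(all((scores > 0.5) == (toy$labels == "AF")))
  # identical data + seed => identical content hash
  expect_warning(bundle2 <- train_svm(toy$features, toy$labels))
  expect_identical(bundle$hash, bundle2$hash)
})

test_that("prediction is order-insensitive and schema-checked", {
  toy <- make_toy_training()
  suppressWarnings(bundle <- train_svm(toy$features, toy$labels))
  v <- c(f1 = -2, f2 = -2)
  expect_identical(svm_predict(bundle, v), svm_predict(bundle, v[c(2, 1)]))
  expect_error(svm_predict(bundle, c(f1 = 0, other = 1)),
               "missing column 'f2'")
  # deep inside the positive class: confident score
  expect_gt(svm_predict(bundle, c(f1 = -2, f2 = -2))[["AF"]], 0.5)
  expect_lt(svm_predict(bundle, c(f1 = 2, f2 = 2))[["AF"]], 0.5)
})

test_that("rule classifier implements the three-evidence decision", {
  # premature narrow beat among regular ones -> APC
  rr <- c(0.8, 0.8, 0.48, 1.12, 0.8, 0.8, 0.8, 0.8)
  r_idx <- as.integer(round(cumsum(c(0.5, rr)) * 256))
  fid <- toy_fiducials(r_idx)
  out <- rule_classify_beats(fid)
  expect_equal(out$label[4], "APC")
  expect_true(all(out$label[-4] == "NORMAL"))
  # wide, amplified beat -> VPC
  fid2 <- toy_fiducials(seq(100L, by = 192L, length.out = 7L))
  fid2$qrs_width_s[4] <- fid2$qrs_width_s[4] * 1.8
  fid2$r_amp[4] <- 1.7; fid2$s_amp[4] <- -0.5; fid2$q_amp[4] <- -0.2
  out2 <- rule_classify_beats(fid2)
  expect_equal(out2$label[4], "VPC")
  # perfectly regular uniform morphology: nothing flagged
  fid3 <- toy_fiducials(seq(100L, by = 192L, length.out = 12L))
  out3 <- rule_classify_beats(fid3)
  expect_true(all(out3$label == "NORMAL"))
  expect_true(all(out3$posterior < 0.25))
  # too few beats: all NORMAL with a warning
  expect_warning(out4 <- rule_classify_beats(toy_fiducials(c(100L, 300L))),
                 "fewer beats")
  expect_true(all(out4$label == "NORMAL"))
})

test_that("integration gates combine rules and scores by conjunction", {
  rb_none <- data.frame(label = rep("NORMAL", 10), posterior = rep(0.05, 10))
  rb_apc <- rb_none; rb_apc$label[c(3, 7, 9)] <- "APC"
  rb_apc$posterior[c(3, 7, 9)] <- 0.73
  zero <- setNames(rep(0, 10), telecg:::.svm_head_labels())
  # nothing at all -> sinus
  expect_equal(integrate(zero, rb_none)$labels, "SINUS")
  # noise gate wins over a high disease score
  s <- zero; s["NOISE"] <- 0.95; s["AF"] <- 0.9
  expect_equal(integrate(s, rb_none)$labels, "NOISE")
  # rules + supporting SVM score -> APC; same rules without support -> not
  s_apc <- zero; s_apc["APC"] <- 0.7
  expect_true("APC" %in% integrate(s_apc, rb_apc)$labels)
  s_apc_lo <- zero; s_apc_lo["APC"] <- 0.1
  expect_false("APC" %in% integrate(s_apc_lo, rb_apc)$labels)
  # SVM rhythm label from score alone
  s_af <- zero; s_af["AF"] <- 0.8
  expect_true("AF" %in% integrate(s_af, rb_none)$labels)
  # deterministic long-QT rule
  expect_true("QT_GT_450" %in%
              integrate(zero, rb_none, mean_qt_s = 0.47)$labels)
  # moderate evidence below threshold -> uncertain, not sinus
  s_mid <- zero; s_mid["AF"] <- 0.45
  expect_equal(integrate(s_mid, rb_none)$labels, "UNCERTAIN")
})

test_that("raising a disease score never removes that disease label", {
  rb_none <- data.frame(label = rep("NORMAL", 10), posterior = rep(0.05, 10))
  zero <- setNames(rep(0, 10), telecg:::.svm_head_labels())
  for (lab in c("AF", "TWI", "AVB1")) {
    s <- zero; s[lab] <- 0.55
    had <- lab %in% integrate(s, rb_none)$labels
    s2 <- s; s2[lab] <- 0.9
    still <- lab %in% integrate(s2, rb_none)$labels
    expect_true(!had || still)
    expect_true(still)
  }
})

test_that("label sets enforce the vocabulary invariants", {
  expect_error(label_set(c("NOISE", "AF")), "exclusive")
  expect_error(label_set(c("UNCERTAIN", "AF")), "exclusive")
  expect_error(label_set(c("SINUS", "AF")), "SINUS excludes")
  expect_error(label_set("WAT"), "unknown label")
  expect_silent(label_set(c("AF", "APC")))     # diseases may co-occur
})

test_that("the trained pipeline classifies held-out simulated records", {
  classes <- c("SINUS", "AF", "VPC", "NOISE")
  corp <- make_corpus(setNames(rep(8, length(classes)), classes), seed = 17)
  fm <- corpus_features(corp$records)
  idx_tr <- unlist(lapply(split(seq_len(nrow(fm)), corp$labels$label),
                          function(i) i[1:5]))
  idx_va <- setdiff(seq_len(nrow(fm)), idx_tr)
  suppressWarnings(bundle <- train_svm(fm[idx_tr, ],
                                       corp$labels$label[idx_tr]))
  get_pred <- function(i) classify_record(corp$records[[i]], bundle)$labels
  preds <- lapply(idx_va, get_pred)
  truth <- corp$labels$label[idx_va]
  expect_true(all(vapply(preds[truth == "SINUS"],
                         function(p) identical(p, "SINUS"), logical(1))))
  expect_true(all(vapply(preds[truth == "AF"],
                         function(p) "AF" %in% p, logical(1))))
  # determinism across repeated classification
  expect_identical(get_pred(idx_va[1]), get_pred(idx_va[1]))
})

test_that("pure-noise records never receive a disease label", {
  classes <- c("SINUS", "AF", "NOISE")
  corp <- make_corpus(setNames(rep(6, 3), classes), seed = 31)
  fm <- corpus_features(corp$records)
  suppressWarnings(bundle <- train_svm(fm, corp$labels$label))
  disease <- setdiff(label_vocabulary(), c("SINUS", "NOISE", "UNCERTAIN"))
  for (sd in 101:105) {
    wn <- ecg_record(stats::rnorm(3840, 0, 0.4), fs = 256,
                     record_id = paste0("wn", sd))
    labs <- suppressWarnings(classify_record(wn, bundle))$labels
    expect_length(intersect(labs, disease), 0L)
  }
})
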