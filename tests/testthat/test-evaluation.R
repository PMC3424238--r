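test_that("confusion counts use score >= threshold as positive", {
  cc <- confusion_counts(c(0.9, 0.1), c(1L, 0L), 0.5)
  expect_equal(cc, c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  cc <- confusion_counts(c(0.1, 0.2, 0.3), c(1L, 1L, 1L), 0.5)
  expect_equal(cc[["FN"]], 3L)
  # boundary rule: score exactly at the threshold counts positive
  cc <- confusion_counts(0.5, 1L, 0.5)
  expect_equal(cc[["TP"]], 1L)
  expect_error(confusion_counts(c(0.1), c(1L, 0L)), "mismatch")
})

test_that("threshold metrics follow the standard definitions, NA when undefined", {
  m <- classification_metrics(c(TP = 1, TN = 0, FP = 0, FN = 1))
  expect_equal(m$sn, 0.5)
  expect_true(is.na(m$sp))
  m <- classification_metrics(c(TP = 1, TN = 1, FP = 1, FN = 1))
  expect_equal(m$acc, 0.5)
  expect_equal(m$f, 0.5)
  m <- classification_metrics(c(TP = 3, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(m), c(sn = 1, sp = 1, acc = 1, f = 1))
})

test_that("rank-based AUC equals pair counting and handles ties", {
  expect_equal(auc_score(c(0.9, 0.1), c(1L, 0L)), 1)
  expect_equal(auc_score(c(0.1, 0.9), c(1L, 0L)), 0)
  expect_equal(auc_score(rep(0.3, 10), rep(c(1L, 0L), 5)), 0.5)
  expect_error(auc_score(c(0.1, 0.2), c(1L, 1L)), "undefined")
  withr::with_seed(13, {
    for (i in 1:50) {
      n <- sample(5:40, 1)
      labels <- rbinom(n, 1, 0.4)
      if (sum(labels) %in% c(0, n)) next
      scores <- round(runif(n), 1)  # force ties
      expect_equal(auc_score(scores, labels), pair_count_auc(scores, labels))
    }
  })
})

test_that("rank-based AUC agrees with an independent package implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(14, {
    for (i in 1:5) {
      labels <- rbinom(50, 1, 0.3)
      if (sum(labels) %in% c(0, 50)) next
      scores <- runif(50)
      ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(auc_score(scores, labels), ref)
    }
  })
})

test_that("LOOCV folds are antigen-level, leak-free and deterministic", {
  cfg <- synthetic_preset("single-signal", seed = 41)
  cfg$n_antigens <- 3
  cfg$chain_length <- c(40, 50)
  cfg$chains_per_antigen <- c(2, 2)  # multi-chain antigens
  d <- simulate_epitope_dataset(cfg)

  rep1 <- evaluate_loocv(d, encoders = "composition", L = 9,
                         weights = "uniform", ntree = 30, seed = 3)
  expect_s3_class(rep1, "epitope_loocv")
  expect_equal(nrow(rep1$per_antigen), 3)
  expect_length(rep1$folds, 3)
  for (f in rep1$folds) {
    expect_false(f$test %in% f$train)                   # no leakage
    expect_setequal(c(f$test, f$train), unique(d$antigen_id))
  }
  # a multi-chain antigen is never split: its fold predictions span
  # both chains and nothing else
  p1 <- rep1$predictions[rep1$predictions$fold == 1, ]
  expect_equal(unique(p1$antigen_id), rep1$folds[[1]]$test)
  expect_setequal(unique(p1$chain_id), c("A", "B"))

  rep2 <- evaluate_loocv(d, encoders = "composition", L = 9,
                         weights = "uniform", ntree = 30, seed = 3)
  expect_identical(rep2$per_antigen, rep1$per_antigen)
  expect_identical(rep2$mean_auc, rep1$mean_auc)

  expect_error(evaluate_loocv(d[d$antigen_id == d$antigen_id[1], ],
                              encoders = "composition"),
               "at least 2")
})

test_that("mean AUC averages per-antigen AUCs and the report is tidy-able", {
  d <- tiny_dataset(3, c(40, 50), seed = 43, preset = "single-signal")
  rep <- evaluate_loocv(d, encoders = "composition", L = 9,
                        weights = "uniform", ntree = 30, seed = 5)
  expect_equal(rep$mean_auc, mean(rep$per_antigen$auc))
  per <- rep$predictions |>
    dplyr::group_by(antigen_id) |>
    dplyr::summarise(auc = auc_score(score, label))
  expect_equal(sort(per$auc), sort(rep$per_antigen$auc))
  expect_identical(tidy(rep), rep$per_antigen)
  gl <- glance(rep)
  expect_equal(gl$mean_auc, rep$mean_auc)
  sw <- threshold_sweep(rep, c(0.3, 0.5, 0.7))
  expect_equal(nrow(sw), 3)
  expect_true(all(diff(sw$sn) <= 0))  # sensitivity falls as threshold rises
  plt <- ggplot2::autoplot(rep)
  expect_s3_class(plt, "ggplot")
})
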