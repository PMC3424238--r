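#' Confusion counts at a threshold
#'
#' A residue is called an epitope when its score is greater than or equal
#' to the threshold (the boundary counts as positive).
#'
#' @param scores Numeric score vector.
#' @param labels Integer 0/1 vector of the same length.
#' @param threshold Classification threshold (default 0.5).
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stop("scores / labels length mismatch")
  stopifnot(all(labels %in% c(0L, 1L)))
  pred <- scores >= threshold
  c(TP = sum(pred & labels == 1L), TN = sum(!pred & labels == 0L),
    FP = sum(pred & labels == 0L), FN = sum(!pred & labels == 1L))
}

#' Threshold classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy and
#' F-measure `2*P*SN/(P+SN)` with precision `P = TP/(TP+FP)`.  A metric
#' whose denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param cc Confusion counts from [confusion_counts()].
#' @return A one-row tibble with columns `sn`, `sp`, `acc`, `f`.
#' @export
classification_metrics <- function(cc) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sn <- safe_div(cc[["TP"]], cc[["TP"]] + cc[["FN"]])
  sp <- safe_div(cc[["TN"]], cc[["TN"]] + cc[["FP"]])
  acc <- safe_div(cc[["TP"]] + cc[["TN"]], sum(cc))
  p <- safe_div(cc[["TP"]], cc[["TP"]] + cc[["FP"]])
  f <- if (is.na(p) || is.na(sn) || p + sn == 0) NA_real_ else 2 * p * sn / (p + sn)
  tibble::tibble(sn = sn, sp = sp, acc = acc, f = f)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with average ranks for ties; equal to the
#' trapezoidal area under the ROC curve.
#'
#' @param scores Numeric score vector.
#' @param labels Integer 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_score(c(0.9, 0.1), c(1, 0))
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores / labels length mismatch")
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0 || nneg == 0) {
    stop("AUC undefined: need at least one positive and one negative")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Out-of-fold per-residue predictions under antigen-level LOOCV
#'
#' For each antigen in turn, trains the full pipeline (ensembles,
#' normalization, weights) on all other antigens and scores every residue
#' of the held-out antigen's chains — an antigen's chains are never split
#' across train and test.  Normalization parameters (and searched weights,
#' if requested) are fitted inside each fold only.
#'
#' @inheritParams train_epitope_model
#' @param progress Emit a message per fold.
#' @return A tibble of per-residue predictions (as
#'   [predict.epitope_model()] with `type = "sub"`) plus a `fold` column;
#'   attribute `"folds"` records each fold's train/test antigen ids.
#' @export
loocv_predictions <- function(data, encoders = NULL, L = 9,
                              weights = "default",
                              strategy = c("weighted", "mean", "median"),
                              threshold = 0.5, c = 0.01, seed = 1L,
                              ntree = 500,
                              sample_mode = c("partition", "bootstrap"),
                              terminal_policy = c("full_ensemble", "composition_only"),
                              normalization_scope = c("per_subclassifier", "per_instance"),
                              step = 0.05, progress = FALSE) {
  data <- validate_epitope_dataset(data)
  antigens <- unique(data$antigen_id)
  if (length(antigens) < 2) stop("LOOCV needs at least 2 antigens")
  if (any(vapply(data$labels, is.null, logical(1)))) {
    stop("LOOCV needs labels on every chain")
  }
  folds <- list()
  preds <- vector("list", length(antigens))
  for (i in seq_along(antigens)) {
    a <- antigens[i]
    if (progress) message("LOOCV fold ", i, "/", length(antigens), ": ", a)
    train <- data[data$antigen_id != a, ]
    test <- data[data$antigen_id == a, ]
    model <- train_epitope_model(
      train, encoders = encoders, L = L, weights = weights,
      strategy = strategy, threshold = threshold, c = c,
      seed = seed + i, ntree = ntree, sample_mode = sample_mode,
      terminal_policy = terminal_policy,
      normalization_scope = normalization_scope, step = step
    )
    p <- suppressMessages(predict(model, test, type = "sub"))
    p$fold <- i
    preds[[i]] <- p
    folds[[i]] <- list(test = a, train = setdiff(antigens, a))
  }
  out <- dplyr::bind_rows(preds)
  attr(out, "folds") <- folds
  out
}

#' Antigen-level leave-one-out cross-validation
#'
#' Runs [loocv_predictions()] and summarizes: per antigen, the AUC of the
#' fused scores over its labeled residues plus threshold metrics; in
#' aggregate, the unweighted mean AUC over antigens having both an epitope
#' and a non-epitope residue (antigens lacking either class are excluded
#' with a message), and the pooled-residue confusion metrics and AUC.
#'
#' @inheritParams loocv_predictions
#' @return An `epitope_loocv` object: list with `per_antigen` (tibble),
#'   `mean_auc`, `pooled` (one-row tibble), `predictions`, `folds` and
#'   `config`; has `tidy()`, `glance()` and `autoplot()` methods.
#' @export
evaluate_loocv <- function(data, encoders = NULL, L = 9, weights = "default",
                           strategy = c("weighted", "mean", "median"),
                           threshold = 0.5, c = 0.01, seed = 1L, ntree = 500,
                           sample_mode = c("partition", "bootstrap"),
                           terminal_policy = c("full_ensemble", "composition_only"),
                           normalization_scope = c("per_subclassifier", "per_instance"),
                           step = 0.05, progress = FALSE) {
  strategy <- match.arg(strategy)
  preds <- loocv_predictions(
    data, encoders = encoders, L = L, weights = weights, strategy = strategy,
    threshold = threshold, c = c, seed = seed, ntree = ntree,
    sample_mode = sample_mode, terminal_policy = terminal_policy,
    normalization_scope = normalization_scope, step = step, progress = progress
  )
  summarize_predictions(preds, threshold = threshold,
                        config = list(L = L, strategy = strategy,
                                      weights = weights, threshold = threshold,
                                      seed = seed, ntree = ntree))
}

summarize_predictions <- function(preds, threshold = 0.5, config = list()) {
  per_antigen <- preds |>
    dplyr::group_by(.data$antigen_id) |>
    dplyr::summarise(
      n_residues = dplyr::n(),
      pos = sum(.data$label == 1L),
      auc = if (sum(.data$label == 1L) > 0 && sum(.data$label == 0L) > 0) {
        auc_score(.data$score, .data$label)
      } else NA_real_,
      classification_metrics(confusion_counts(.data$score, .data$label, threshold)),
      .groups = "drop"
    )
  if (anyNA(per_antigen$auc)) {
    message(sum(is.na(per_antigen$auc)),
            " antigen(s) lack one class; excluded from mean AUC")
  }
  cc <- confusion_counts(preds$score, preds$label, threshold)
  pooled <- dplyr::bind_cols(
    tibble::as_tibble(as.list(cc)),
    classification_metrics(cc),
    tibble::tibble(auc = auc_score(preds$score, preds$label))
  )
  structure(list(
    per_antigen = per_antigen,
    mean_auc = mean(per_antigen$auc, na.rm = TRUE),
    pooled = pooled,
    predictions = preds,
    folds = attr(preds, "folds"),
    config = config
  ), class = "epitope_loocv")
}

#' @export
print.epitope_loocv <- function(x, ...) {
  cat("Antigen-level LOOCV over", nrow(x$per_antigen), "antigens\n")
  cat("  mean per-antigen AUC:", format(x$mean_auc, digits = 4), "\n")
  cat("  pooled AUC:", format(x$pooled$auc, digits = 4),
      " ACC:", format(x$pooled$acc, digits = 4), "\n")
  invisible(x)
}

#' Per-antigen LOOCV metrics
#' @param x An `epitope_loocv` report.
#' @param ... Unused.
#' @return Tibble with one row per antigen.
#' @export
tidy.epitope_loocv <- function(x, ...) x$per_antigen

#' One-row LOOCV summary
#' @param x An `epitope_loocv` report.
#' @param ... Unused.
#' @return A one-row tibble with the mean per-antigen AUC and pooled metrics.
#' @export
glance.epitope_loocv <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(mean_auc = x$mean_auc,
                                  n_antigens = nrow(x$per_antigen)),
                   dplyr::rename_with(x$pooled, ~ paste0("pooled_", .x)))
}

#' Sweep the classification threshold
#'
#' Recomputes the pooled confusion metrics of a LOOCV report over a grid
#' of thresholds; AUC is threshold-free and unchanged.
#'
#' @param report An `epitope_loocv` report.
#' @param thresholds Numeric vector of thresholds.
#' @return A tibble with one row per threshold.
#' @export
threshold_sweep <- function(report, thresholds = seq(0.1, 0.9, by = 0.1)) {
  purrr::map_dfr(thresholds, function(t) {
    cc <- confusion_counts(report$predictions$score, report$predictions$label, t)
    dplyr::bind_cols(tibble::tibble(threshold = t), classification_metrics(cc))
  })
}
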