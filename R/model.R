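#' Canonical fusion order of the candidate sub-classifiers
#' @return Character vector of encoder names.
#' @export
fusion_encoder_order <- function() {
  c("propensity", "functional_composition", "evolutionary", "sparse",
    "ss", "rasa", "pair_profile")
}

#' Train the full epitope prediction model
#'
#' Fits, for each requested encoder, a bootstrap ensemble of random
#' forests on the labeled window instances of `data`
#' ([train_bootstrap_ensemble()]), then the tanh-estimator normalization
#' parameters on the training scores, and attaches the fusion weights —
#' either a supplied vector, the published defaults, uniform weights, or
#' weights found by an internal simplex grid search on the (normalized)
#' training scores with the mean per-antigen AUC objective.
#'
#' @param data Labeled chain tibble ([epitope_dataset()]).
#' @param encoders Encoder names to use as sub-classifiers; defaults to the
#'   seven-candidate fusion set when the needed tracks are present.
#' @param L Odd window length (default 9).
#' @param weights `"default"` (published weights when the encoders are the
#'   canonical seven, otherwise uniform), `"uniform"`, `"search"`, or a
#'   named nonnegative vector summing to 1 over `encoders`.
#' @param strategy Fusion rule: `"weighted"`, `"mean"` or `"median"`.
#' @param threshold Classification threshold on the fused score.
#' @param c Tanh-estimator constant (see [normalize_score()]).
#' @param seed Integer seed; the whole fit is reproducible under it.
#' @param ntree Trees per member forest.
#' @param sample_mode Negative-sampling mode ([make_balanced_samples()]).
#' @param terminal_policy `"full_ensemble"` (default: terminal residues go
#'   through the same fused pipeline on X-padded windows) or
#'   `"composition_only"` (the first and last `(L-1)/2` residues are scored
#'   by the composition sub-classifier alone, which is then always fitted).
#' @param normalization_scope `"per_subclassifier"` (default: stored
#'   training mu/sigma per encoder) or `"per_instance"` (mu/sigma taken
#'   across the k raw scores of each instance at prediction time).
#' @param step Grid step when `weights = "search"`.
#' @return An `epitope_model` object with [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
train_epitope_model <- function(data, encoders = NULL, L = 9,
                                weights = "default",
                                strategy = c("weighted", "mean", "median"),
                                threshold = 0.5, c = 0.01, seed = 1L,
                                ntree = 500,
                                sample_mode = c("partition", "bootstrap"),
                                terminal_policy = c("full_ensemble", "composition_only"),
                                normalization_scope = c("per_subclassifier", "per_instance"),
                                step = 0.05) {
  data <- validate_epitope_dataset(data)
  strategy <- match.arg(strategy)
  terminal_policy <- match.arg(terminal_policy)
  normalization_scope <- match.arg(normalization_scope)
  sample_mode <- match.arg(sample_mode)
  check_window_length(L)

  if (is.null(encoders)) encoders <- available_encoders(data)
  encoders <- vapply(encoders, match.arg, "", choices = feature_encoders()$encoder)
  encoders <- unname(encoders[order(match(encoders, c(fusion_encoder_order(),
                                                      feature_encoders()$encoder)))])
  fit_encoders <- encoders
  if (terminal_policy == "composition_only" && !"composition" %in% fit_encoders) {
    fit_encoders <- c(fit_encoders, "composition")
  }
  missing_tracks <- check_tracks(data, fit_encoders)
  if (length(missing_tracks)) {
    stop("missing track(s) for requested encoder(s): ",
         paste(names(missing_tracks), "(needs ", missing_tracks, ")",
               sep = "", collapse = ", "))
  }

  meta <- extract_windows(data, L, padded = TRUE)
  if (anyNA(meta$label)) stop("training data must be fully labeled")
  labels <- meta$label

  ensembles <- list()
  raw_scores <- matrix(NA_real_, nrow(meta), length(fit_encoders),
                       dimnames = list(NULL, fit_encoders))
  for (j in seq_along(fit_encoders)) {
    enc <- fit_encoders[j]
    design <- dataset_design(data, enc, L)
    e <- train_bootstrap_ensemble(design$x, labels,
                                  seed = seed + 101L * j, ntree = ntree,
                                  mode = sample_mode, encoder = enc)
    ensembles[[enc]] <- e
    raw_scores[, j] <- predict(e, design$x)
  }
  norm <- fit_normalization(raw_scores)

  normalized <- normalize_matrix(raw_scores[, encoders, drop = FALSE],
                                 norm, c, normalization_scope)
  w <- resolve_weights(weights, encoders, normalized, labels,
                       meta$antigen_id, step)

  structure(list(
    encoders = encoders, L = L, ensembles = ensembles, norm = norm,
    weights = w, strategy = strategy, threshold = threshold, c = c,
    terminal_policy = terminal_policy,
    normalization_scope = normalization_scope,
    seed = seed, ntree = ntree, sample_mode = sample_mode,
    training = list(
      n_antigens = length(unique(data$antigen_id)),
      n_chains = nrow(data), n_windows = nrow(meta),
      pos = sum(labels == 1L), neg = sum(labels == 0L)
    )
  ), class = "epitope_model")
}

available_encoders <- function(data) {
  cand <- fusion_encoder_order()
  have <- c(
    pssm = all(!vapply(data$pssm, is.null, logical(1))),
    ss = all(!is.na(data$ss)),
    rasa = all(!vapply(data$rasa, is.null, logical(1)))
  )
  keep <- vapply(cand, function(e) {
    all(have[encoder_requires(e)])
  }, logical(1))
  cand[keep]
}

# named character vector encoder -> missing track, empty when all satisfied
check_tracks <- function(data, encoders) {
  out <- character()
  for (e in encoders) {
    for (tr in encoder_requires(e)) {
      ok <- switch(tr,
        pssm = all(!vapply(data$pssm, is.null, logical(1))),
        ss = all(!is.na(data$ss)),
        rasa = all(!vapply(data$rasa, is.null, logical(1)))
      )
      if (!ok) out[e] <- tr
    }
  }
  out
}

normalize_matrix <- function(raw, norm, c, scope) {
  if (scope == "per_instance") {
    mu <- rowMeans(raw)
    sigma <- pmax(apply(raw, 1, stats::sd), 1e-9)
    return(0.5 * (tanh(c * (raw - mu) / sigma) + 1))
  }
  out <- raw
  for (j in seq_len(ncol(raw))) {
    p <- norm[norm$encoder == colnames(raw)[j], ]
    out[, j] <- normalize_score(raw[, j], p$mu, p$sigma, c)
  }
  out
}

resolve_weights <- function(weights, encoders, normalized, labels, groups, step) {
  if (is.character(weights)) {
    weights <- match.arg(weights, c("default", "uniform", "search"))
    if (weights == "search") {
      return(grid_search_weights(normalized, labels, groups, step)$weights)
    }
    if (weights == "default" && setequal(encoders, fusion_encoder_order())) {
      return(default_fusion_weights()[encoders])
    }
    w <- rep(1 / length(encoders), length(encoders))
    names(w) <- encoders
    return(w)
  }
  if (is.null(names(weights))) names(weights) <- encoders
  if (!setequal(names(weights), encoders)) {
    stop("weight names must match the model's encoders")
  }
  w <- weights[encoders]
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("weights must be nonnegative and sum to 1")
  }
  w
}

#' Predict per-residue epitope scores
#'
#' Scores every residue of every chain in `data` with the fused model.
#' Encoders whose fusion weight is exactly 0 are pruned (their tracks are
#' not required).  Under `terminal_policy = "composition_only"` the first
#' and last `(L-1)/2` residues of each chain take the composition
#' sub-classifier's normalized score instead of the fused score.
#'
#' @param object An `epitope_model`.
#' @param data Chain tibble; tracks required by the active encoders must be
#'   present.
#' @param type `"fused"` (default) for final scores, `"sub"` to also get
#'   one normalized-score column per sub-classifier.
#' @param ... Unused.
#' @return A tibble with `antigen_id`, `chain_id`, `position` (1-based),
#'   `residue`, `label` (NA when the chain is unlabeled), `score` and
#'   `predicted_label` (`score >= threshold`); with `type = "sub"`, one
#'   extra column per encoder.
#' @export
predict.epitope_model <- function(object, data, type = c("fused", "sub"), ...) {
  type <- match.arg(type)
  data <- validate_epitope_dataset(data)
  active <- object$encoders
  if (object$strategy == "weighted") {
    used <- active[object$weights[active] > 0]
    if (length(used) == 0) stop("all fusion weights are zero")
    pruned <- setdiff(active, used)
    active <- used
    if (length(pruned)) {
      message("encoders with zero weight pruned at prediction: ",
              paste(pruned, collapse = ", "))
    }
  }
  need <- active
  if (object$terminal_policy == "composition_only") need <- union(need, "composition")
  missing_tracks <- check_tracks(data, need)
  if (length(missing_tracks)) {
    stop("missing track(s) for model encoder(s): ",
         paste(names(missing_tracks), collapse = ", "))
  }

  meta <- extract_windows(data, object$L, padded = TRUE)
  raw <- matrix(NA_real_, nrow(meta), length(need), dimnames = list(NULL, need))
  for (enc in need) {
    design <- dataset_design(data, enc, object$L)
    raw[, enc] <- predict(object$ensembles[[enc]], design$x)
  }
  normalized <- normalize_matrix(raw, object$norm, object$c,
                                 object$normalization_scope)
  score <- switch(object$strategy,
    weighted = fuse_weighted(normalized[, active, drop = FALSE],
                             object$weights[active] / sum(object$weights[active])),
    mean = fuse_mean(normalized[, active, drop = FALSE]),
    median = fuse_median(normalized[, active, drop = FALSE])
  )
  if (object$terminal_policy == "composition_only") {
    half <- (object$L - 1) / 2
    n_chain <- nchar(data$sequence)[match(paste(meta$antigen_id, meta$chain_id),
                                          paste(data$antigen_id, data$chain_id))]
    terminal <- meta$center <= half | meta$center > n_chain - half
    score[terminal] <- normalized[terminal, "composition"]
  }
  out <- meta |>
    dplyr::transmute(
      .data$antigen_id, .data$chain_id, position = .data$center,
      residue = substr(.data$window, (object$L + 1) / 2, (object$L + 1) / 2),
      label = .data$label, score = score,
      predicted_label = as.integer(score >= object$threshold)
    )
  if (type == "sub") {
    out <- dplyr::bind_cols(out, tibble::as_tibble(normalized))
  }
  out
}

#' @export
print.epitope_model <- function(x, ...) {
  cat("Epitope prediction model (", x$strategy, " fusion, L = ", x$L, ")\n", sep = "")
  cat("  sub-classifiers:", paste(x$encoders, collapse = ", "), "\n")
  if (x$strategy == "weighted") {
    cat("  weights:", paste(sprintf("%s=%.2f", x$encoders, x$weights[x$encoders]),
                            collapse = " "), "\n")
  }
  cat("  trained on", x$training$n_antigens, "antigen(s),",
      x$training$pos, "pos /", x$training$neg, "neg windows\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an epitope model
#'
#' One row per sub-classifier: fusion weight, normalization parameters and
#' ensemble size.
#'
#' @param x An `epitope_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.epitope_model <- function(x, ...) {
  tibble::tibble(
    encoder = x$encoders,
    weight = if (x$strategy == "weighted") unname(x$weights[x$encoders]) else NA_real_,
    mu = x$norm$mu[match(x$encoders, x$norm$encoder)],
    sigma = x$norm$sigma[match(x$encoders, x$norm$encoder)],
    n_forests = vapply(x$ensembles[x$encoders], function(e) e$n, integer(1))
  )
}

#' One-row model summary
#'
#' @param x An `epitope_model`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.epitope_model <- function(x, ...) {
  tibble::tibble(
    n_antigens = x$training$n_antigens, n_chains = x$training$n_chains,
    n_windows = x$training$n_windows, pos = x$training$pos,
    neg = x$training$neg, L = x$L, strategy = x$strategy,
    threshold = x$threshold, seed = x$seed
  )
}
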