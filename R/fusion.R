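#' Published default fusion weights
#'
#' The default convex weights for the seven candidate sub-classifiers, in
#' the canonical fusion order: 0.1 physicochemical propensities, 0.0
#' functional composition, 0.5 evolutionary profile, 0.0 sparse profile,
#' 0.1 secondary structure, 0.2 RASA, 0.1 pair profile.  They let a model
#' predict without re-running the grid search; encoders with weight 0 are
#' pruned at prediction time, so PSSM-free tracks are not demanded for
#' zero-weight encoders.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_fusion_weights <- function() {
  c(propensity = 0.1, functional_composition = 0.0, evolutionary = 0.5,
    sparse = 0.0, ss = 0.1, rasa = 0.2, pair_profile = 0.1)
}

#' Fit tanh-estimator normalization parameters
#'
#' For each sub-classifier, the mean and (sample, `ddof = 1`) standard
#' deviation of its scores over the training instances.  A constant score
#' list gets its standard deviation floored at `1e-9` with a warning.
#'
#' @param scores Numeric matrix (instances x sub-classifiers) or a named
#'   list of score vectors.
#' @return A tibble with columns `encoder`, `mu`, `sigma`.
#' @export
fit_normalization <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- do.call(cbind, scores)
  }
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop("need at least 2 scores per sub-classifier")
  mu <- colMeans(scores)
  sigma <- apply(scores, 2, stats::sd)
  if (any(sigma < 1e-9)) {
    warning("constant sub-classifier score(s); standard deviation floored at 1e-9")
    sigma <- pmax(sigma, 1e-9)
  }
  nm <- colnames(scores)
  tibble::tibble(
    encoder = if (is.null(nm)) paste0("sub", seq_along(mu)) else nm,
    mu = unname(mu), sigma = unname(sigma)
  )
}

#' tanh-estimator score normalization
#'
#' Z-scores a raw sub-classifier score and squashes it with the tanh
#' estimator: `0.5 * (tanh(c * (s - mu) / sigma) + 1)`.  Strictly
#' increasing in `s`, maps `mu` to 0.5 and saturates at 0 and 1, so all
#' sub-classifiers are put on one comparable (0, 1) scale before fusion.
#'
#' @param s Raw score(s).
#' @param mu,sigma Normalization parameters ([fit_normalization()]).
#' @param c Tanh-estimator constant (default 0.01, the conventional value;
#'   small `c` keeps the map near-linear over the typical score range).
#' @return Normalized score(s) in (0, 1).
#' @export
normalize_score <- function(s, mu, sigma, c = 0.01) {
  stopifnot(all(sigma > 0))
  0.5 * (tanh(c * (s - mu) / sigma) + 1)
}

#' Fuse normalized sub-classifier scores
#'
#' `fuse_weighted()` is the weighted-scoring rule: the convex combination
#' `sum(w_i * s_i)` with weights on the probability simplex.  Weight vector
#' `e_i` reproduces sub-classifier `i` exactly, and uniform weights equal
#' mean scoring.  `fuse_mean()` and `fuse_median()` are the alternative
#' combination rules.
#'
#' @param normalized Numeric vector of the `k` normalized scores of one
#'   instance, or an `n x k` matrix for many instances.
#' @param w Nonnegative weight vector of length `k` summing to 1.
#' @return Fused score(s).
#' @export
fuse_weighted <- function(normalized, w) {
  if (is.matrix(normalized)) {
    if (ncol(normalized) != length(w)) stop("weight / score dimension mismatch")
    return(as.numeric(normalized %*% w))
  }
  if (length(normalized) != length(w)) stop("weight / score dimension mismatch")
  if (abs(sum(w) - 1) > 1e-8 || any(w < 0)) stop("weights must be a point on the simplex")
  sum(normalized * w)
}

#' @rdname fuse_weighted
#' @export
fuse_mean <- function(normalized) {
  if (is.matrix(normalized)) return(rowMeans(normalized))
  if (length(normalized) == 0) stop("no scores to fuse")
  mean(normalized)
}

#' @rdname fuse_weighted
#' @export
fuse_median <- function(normalized) {
  if (is.matrix(normalized)) return(apply(normalized, 1, stats::median))
  if (length(normalized) == 0) stop("no scores to fuse")
  stats::median(normalized)
}

#' Enumerate the weight simplex grid
#'
#' All vectors of `k` nonnegative multiples of `step` summing to 1 — the
#' exhaustive search space of the weighted-scoring grid search.  There are
#' `choose(1/step + k - 1, k - 1)` of them (stars and bars); rows are in
#' ascending lexicographic order.
#'
#' @param k Number of sub-classifiers.
#' @param step Grid step; `1/step` must be an integer (default 0.05).
#' @return A numeric matrix with `k` columns, one row per weight vector.
#' @export
#' @examples
#' nrow(enumerate_weight_grid(3, 0.5))
enumerate_weight_grid <- function(k, step = 0.05) {
  m <- 1 / step
  if (abs(m - round(m)) > 1e-9) stop("1/step must be an integer")
  m <- as.integer(round(m))
  stopifnot(k >= 1)
  if (k == 1) return(matrix(1, 1, 1))
  bars <- utils::combn(m + k - 1, k - 1)
  counts <- rbind(bars, m + k) - rbind(0, bars) - 1
  t(counts) * step
}

#' Mean per-antigen AUC of a score vector
#'
#' Splits the instances by antigen (`groups`), computes the rank-based AUC
#' within each antigen and averages; antigens whose labels are single-class
#' are dropped (`NA` removed).  This is the grid-search objective and the
#' headline LOOCV summary statistic.
#'
#' @param scores Numeric score vector.
#' @param labels Integer 0/1 labels.
#' @param groups Antigen identifier per instance.
#' @return The mean per-antigen AUC.
#' @export
mean_antigen_auc <- function(scores, labels, groups) {
  per <- vapply(split(seq_along(labels), groups), function(ix) {
    l <- labels[ix]
    if (all(l == 1L) || all(l == 0L)) return(NA_real_)
    auc_score(scores[ix], l)
  }, numeric(1))
  mean(per, na.rm = TRUE)
}

#' Exhaustive grid search for fusion weights
#'
#' Scans every weight vector on the simplex grid and returns the one
#' maximizing the objective: the mean per-antigen AUC of the fused score
#' (or the pooled AUC when no grouping is given).  Ties are broken in
#' favour of the lexicographically smallest weight vector.  The intended
#' input is a table of out-of-fold normalized sub-classifier scores from
#' [loocv_predictions()], mirroring the protocol of determining the optimal
#' weights once on a reference dataset and reusing them.
#'
#' @param scores `n x k` matrix (or data frame) of normalized
#'   sub-classifier scores; column names name the sub-classifiers.
#' @param labels Integer 0/1 vector of length `n`.
#' @param groups Optional antigen id per instance; when given the
#'   objective is the mean per-antigen AUC over antigens with both classes.
#' @param step Grid step (default 0.05).
#' @return A list with `weights` (named best vector), `objective` (its
#'   objective value) and `results` (tibble of every grid vector with its
#'   objective), class `"weight_search"`.
#' @export
grid_search_weights <- function(scores, labels, groups = NULL, step = 0.05) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(labels))
  grid <- enumerate_weight_grid(ncol(scores), step)
  if (nrow(grid) == 0) stop("empty weight grid")
  objective <- numeric(nrow(grid))
  chunk <- 500L
  split_ix <- if (!is.null(groups)) split(seq_along(labels), groups) else NULL
  for (start in seq(1, nrow(grid), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(grid))
    fused <- scores %*% t(grid[rows, , drop = FALSE])
    objective[rows] <- vapply(seq_along(rows), function(j) {
      if (is.null(split_ix)) {
        auc_score(fused[, j], labels)
      } else {
        per <- vapply(split_ix, function(ix) {
          l <- labels[ix]
          if (all(l == 1L) || all(l == 0L)) return(NA_real_)
          auc_score(fused[ix, j], l)
        }, numeric(1))
        mean(per, na.rm = TRUE)
      }
    }, numeric(1))
  }
  best <- which.max(objective)  # rows are lexicographic: first max = smallest tie
  w <- grid[best, ]
  names(w) <- colnames(scores)
  results <- tibble::as_tibble(grid, .name_repair = "minimal")
  names(results) <- if (is.null(colnames(scores))) {
    paste0("w", seq_len(ncol(grid)))
  } else colnames(scores)
  results$objective <- objective
  structure(list(weights = w, objective = objective[best], results = results),
            class = "weight_search")
}

#' @export
print.weight_search <- function(x, ...) {
  cat("Weight grid search over", nrow(x$results), "simplex points\n")
  cat("best objective:", format(x$objective, digits = 4), "\n")
  print(round(x$weights, 4))
  invisible(x)
}
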