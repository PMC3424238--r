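#' Number of rebalanced bootstrap samples
#'
#' Epitope window instances are heavily outnumbered by non-epitope ones, so
#' one balanced sample cannot use all the data.  The number of rebalanced
#' samples (and hence of random forests per sub-classifier) is the
#' majority/minority ratio `max(1, round(neg / pos))`, so that the shuffled
#' negative pool can be spread across the samples.
#'
#' @param pos,neg Positive / negative instance counts (`pos >= 1`,
#'   `neg >= 1`).
#' @return The integer number of samples `n`.
#' @export
#' @examples
#' compute_n(100, 300)
compute_n <- function(pos, neg) {
  if (pos < 1) stop("no positive instances: cannot train a classifier")
  if (neg < 1) stop("no negative instances: cannot train a classifier")
  max(1L, as.integer(round(neg / pos)))
}

#' Build class-balanced training samples
#'
#' Every sample contains all positive instances plus an equally sized draw
#' of negatives.  The negative pool is shuffled once under `seed` and
#' sliced into `n` consecutive chunks of `pos` instances, cycling through
#' the shuffled pool when a chunk runs past its end — so every negative
#' appears in at least one sample whenever `neg <= n * pos`.  With
#' `mode = "bootstrap"` each sample instead draws `pos` negatives
#' independently with replacement.
#'
#' @param labels Integer 0/1 vector over the instances.
#' @param n Number of samples ([compute_n()]).
#' @param seed Integer seed; same seed, same samples.
#' @param mode `"partition"` (default, the shuffled-slice scheme) or
#'   `"bootstrap"`.
#' @return A list of `n` integer index vectors into the instance set.
#' @export
make_balanced_samples <- function(labels, n, seed,
                                  mode = c("partition", "bootstrap")) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  pos_idx <- which(labels == 1L)
  neg_idx <- which(labels == 0L)
  npos <- length(pos_idx)
  nneg <- length(neg_idx)
  if (npos == 0) stop("no positive instances")
  if (nneg == 0) stop("no negative instances")
  withr::with_seed(seed, {
    # index via sample.int: sample(x) on a length-one x permutes 1:x
    shuffled <- neg_idx[sample.int(nneg)]
    lapply(seq_len(n), function(i) {
      negs <- if (mode == "partition") {
        take <- ((i - 1L) * npos + seq_len(npos) - 1L) %% nneg + 1L
        shuffled[take]
      } else {
        neg_idx[sample.int(nneg, npos, replace = TRUE)]
      }
      c(pos_idx, negs)
    })
  })
}

#' Train a bootstrap ensemble of random forests for one encoding
#'
#' Fits `n = compute_n(pos, neg)` random forests, one per balanced sample,
#' on the feature matrix of a single encoder.  The base learner is a
#' classification random forest with the library defaults apart from an
#' adjustable tree count; each member is seeded deterministically from
#' `seed` so the whole ensemble is reproducible.
#'
#' @param x Numeric feature matrix, one row per window instance.
#' @param labels Integer 0/1 vector, one per row of `x`.
#' @param seed Integer seed.
#' @param ntree Trees per forest (default 500, the randomForest default).
#' @param mode Negative-sampling mode, see [make_balanced_samples()].
#' @param encoder Optional encoder name recorded in the object.
#' @return A `bootstrap_ensemble` object.
#' @export
train_bootstrap_ensemble <- function(x, labels, seed = 1L, ntree = 500,
                                     mode = c("partition", "bootstrap"),
                                     encoder = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(x) == length(labels))
  if (anyNA(labels)) stop("unlabeled instances cannot be used for training")
  cc <- c(pos = sum(labels == 1L), neg = sum(labels == 0L))
  n <- compute_n(cc[["pos"]], cc[["neg"]])
  samples <- make_balanced_samples(labels, n, seed, mode)
  members <- lapply(seq_len(n), function(i) {
    rows <- samples[[i]]
    y <- factor(labels[rows], levels = c(0L, 1L))
    withr::with_seed(seed + i, {
      randomForest::randomForest(x[rows, , drop = FALSE], y, ntree = ntree)
    })
  })
  structure(
    list(members = members, n = n, encoder = encoder, seed = seed,
         ntree = ntree, mode = mode, class_counts = cc),
    class = "bootstrap_ensemble"
  )
}

#' Score windows with a bootstrap ensemble
#'
#' The ensemble score of an instance is the arithmetic mean over the `n`
#' member forests of the fraction of trees voting for the epitope class;
#' it always lies in `[0, 1]` and within the range of the member scores.
#'
#' @param object A `bootstrap_ensemble`.
#' @param newdata Feature matrix with the training column layout.
#' @param ... Unused.
#' @return Numeric score vector in `[0, 1]`, one per row of `newdata`.
#' @export
predict.bootstrap_ensemble <- function(object, newdata, ...) {
  if (length(object$members) == 0) stop("unfitted ensemble")
  votes <- vapply(object$members, function(m) {
    stats::predict(m, newdata, type = "prob")[, "1"]
  }, numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) votes <- matrix(votes, nrow = 1)
  rowMeans(votes)
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat("Bootstrap ensemble", if (!is.null(x$encoder)) paste0("(", x$encoder, ")"),
      "-", x$n, "random forest(s),", x$ntree, "trees each;",
      x$class_counts[["pos"]], "pos /", x$class_counts[["neg"]], "neg\n")
  invisible(x)
}
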