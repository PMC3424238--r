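test_that("normalization parameters are per-sub-classifier mean and sample sd", {
  p <- fit_normalization(cbind(a = c(0, 1), b = c(0.3, 0.5)))
  expect_equal(p$mu, c(0.5, 0.4))
  expect_equal(p$sigma[1], sd(c(0, 1)))  # ddof = 1 documented choice

  expect_warning(pc <- fit_normalization(cbind(a = c(0.3, 0.3))), "floored")
  expect_equal(pc$sigma, 1e-9)

  s <- runif(20)
  p1 <- fit_normalization(cbind(x = s))
  p2 <- fit_normalization(cbind(x = s + 0.2))
  expect_equal(p2$mu, p1$mu + 0.2)
  expect_equal(p2$sigma, p1$sigma)

  expect_error(fit_normalization(cbind(a = 1)), "at least 2")
})

test_that("tanh-estimator normalization is centred, bounded and monotone", {
  expect_equal(normalize_score(0.4, mu = 0.4, sigma = 0.1), 0.5)
  expect_equal(normalize_score(1e9, 0, 1), 1)
  expect_equal(normalize_score(-1e9, 0, 1), 0)
  d <- 0.37
  expect_equal(normalize_score(0.5 + d, 0.5, 0.2) +
                 normalize_score(0.5 - d, 0.5, 0.2), 1)
  s <- seq(0, 1, by = 0.01)
  expect_true(all(diff(normalize_score(s, 0.5, 0.1)) > 0))
})

test_that("weighted fusion identities hold", {
  s <- c(0.2, 0.8)
  expect_equal(fuse_weighted(s, c(0.5, 0.5)), 0.5)
  expect_equal(fuse_weighted(s, c(1, 0)), 0.2)   # e_i reproduces sub-classifier i
  expect_equal(fuse_weighted(s, c(0, 1)), 0.8)
  expect_equal(fuse_weighted(rep(0.42, 5), rep(0.2, 5)), 0.42)  # convexity
  withr::with_seed(8, {
    sc <- runif(4)
    w <- c(0.3, 0.2, 0.4, 0.1)
    expect_gte(fuse_weighted(sc, w), min(sc))
    expect_lte(fuse_weighted(sc, w), max(sc))
    expect_equal(fuse_weighted(sc, rep(0.25, 4)), fuse_mean(sc))
  })
  expect_error(fuse_weighted(c(0.1, 0.2), c(1)), "mismatch")
})

test_that("mean and median fusion behave as stated", {
  s <- c(0.2, 0.4, 0.9)
  expect_equal(fuse_mean(s), 0.5)
  expect_equal(fuse_median(s), 0.4)
  expect_equal(fuse_mean(0.7), 0.7)
  expect_equal(fuse_median(0.7), 0.7)
  m <- matrix(c(0.2, 0.4, 0.6, 0.8), 2)
  expect_equal(fuse_mean(m), c(0.4, 0.6))
  expect_error(fuse_mean(numeric()), "no scores")
})

test_that("the weight grid matches stars-and-bars counts and a brute-force oracle", {
  g <- enumerate_weight_grid(2, 0.5)
  expect_equal(nrow(g), 3)
  expect_setequal(apply(g, 1, paste, collapse = ","), c("0,1", "0.5,0.5", "1,0"))

  # brute-force oracle at k = 3, step = 0.5
  oracle <- list()
  for (a in seq(0, 1, 0.5)) for (b in seq(0, 1 - a + 1e-9, 0.5)) {
    oracle[[length(oracle) + 1]] <- c(a, b, 1 - a - b)
  }
  g3 <- enumerate_weight_grid(3, 0.5)
  expect_equal(nrow(g3), length(oracle))  # 6
  expect_setequal(apply(g3, 1, paste, collapse = ","),
                  vapply(oracle, paste, "", collapse = ","))

  g05 <- enumerate_weight_grid(3, 0.05)
  expect_equal(nrow(g05), choose(22, 2))  # 231
  expect_true(all(abs(rowSums(g05) - 1) < 1e-9))
  expect_true(all(g05 >= 0))
  expect_error(enumerate_weight_grid(3, 0.3), "integer")
})

test_that("grid search puts all weight on a perfectly predictive sub-classifier", {
  withr::with_seed(5, {
    labels <- rep(c(1L, 0L), each = 50)
    # separable, but with a margin so thin that mixing in any noise at
    # grid resolution breaks the perfect ranking: only (1, 0, 0) attains 1
    good <- ifelse(labels == 1L, runif(100, 0.51, 0.52), runif(100, 0.48, 0.49))
    noise1 <- runif(100)
    noise2 <- runif(100)
    gs <- grid_search_weights(cbind(good = good, n1 = noise1, n2 = noise2),
                              labels, step = 0.25)
    expect_equal(unname(gs$weights), c(1, 0, 0))
    expect_equal(gs$objective, 1)
  })
})

test_that("ties between identical sub-classifiers resolve to the smallest vector", {
  withr::with_seed(6, {
    labels <- rep(c(1L, 0L), 20)
    s <- runif(40)
    gs <- grid_search_weights(cbind(a = s, b = s), labels, step = 0.5)
    # objective constant along the exchange; lexicographically smallest wins
    expect_equal(unname(gs$weights), c(0, 1))
    expect_equal(length(unique(round(gs$results$objective, 12))), 1L)
  })
})

test_that("AUC is invariant under the monotone normalization", {
  withr::with_seed(9, {
    for (i in 1:10) {
      s <- runif(60)
      labels <- rbinom(60, 1, 0.3)
      if (sum(labels) %in% c(0, 60)) next
      raw <- auc_score(s, labels)
      norm <- auc_score(normalize_score(s, mean(s), sd(s)), labels)
      expect_equal(norm, raw)
      # per-instance scope is monotone per instance too (same mu/sigma per col)
      expect_equal(auc_score(normalize_score(s, 0.2, 0.05), labels), raw)
    }
  })
})

test_that("published default weights are a simplex point in the canonical order", {
  w <- default_fusion_weights()
  expect_equal(names(w), fusion_encoder_order())
  expect_equal(sum(w), 1)
  expect_equal(unname(w), c(0.1, 0.0, 0.5, 0.0, 0.1, 0.2, 0.1))
})
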