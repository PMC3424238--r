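test_that("training and prediction cover every residue, reproducibly", {
  d <- tiny_dataset(3, c(40, 50), seed = 31)
  m <- train_epitope_model(d, encoders = c("composition", "rasa"),
                           L = 9, ntree = 50, seed = 2)
  p <- predict(m, d)
  expect_equal(nrow(p), sum(nchar(d$sequence)))
  expect_true(all(p$score >= 0 & p$score <= 1))
  expect_equal(p$residue,
               unlist(strsplit(d$sequence, "")))

  m2 <- train_epitope_model(d, encoders = c("composition", "rasa"),
                            L = 9, ntree = 50, seed = 2)
  expect_identical(predict(m2, d)$score, p$score)

  # chain shorter than the window still yields full-length output
  short <- epitope_dataset("s1", "A", "KVFGR",
                           labels = list(c(1L, 0L, 0L, 0L, 0L)),
                           rasa = list(c(50, 40, 30, 20, 10)))
  ps <- predict(m, short)
  expect_equal(nrow(ps), 5)
})

test_that("zero-weight encoders are pruned so their tracks are not required", {
  d <- tiny_dataset(3, c(40, 50), seed = 32)
  w <- c(composition = 0.6, rasa = 0.4, ss = 0)
  m <- train_epitope_model(d, encoders = c("composition", "rasa", "ss"),
                           weights = w, L = 9, ntree = 50, seed = 2)
  no_ss <- d
  no_ss$ss <- NA_character_
  expect_message(p <- predict(m, no_ss), "pruned")
  expect_equal(nrow(p), sum(nchar(d$sequence)))
  # but a needed track missing is an actionable error
  no_rasa <- d
  no_rasa$rasa <- vector("list", nrow(d))
  expect_error(suppressMessages(predict(m, no_rasa)), "rasa")
})

test_that("missing training tracks name the offending encoder", {
  d <- tiny_dataset(2, c(40, 45), seed = 33)
  d$pssm <- vector("list", nrow(d))
  expect_error(
    train_epitope_model(d, encoders = c("composition", "evolutionary"),
                        L = 9, ntree = 20),
    "evolutionary"
  )
})

test_that("terminal policy switches how flank residues are scored", {
  d <- tiny_dataset(3, c(40, 50), seed = 34)
  m <- train_epitope_model(d, encoders = c("composition", "rasa"),
                           L = 15, ntree = 50, seed = 2,
                           terminal_policy = "composition_only")
  chain8 <- epitope_dataset("c8", "A", "KVFGRCEL",
                            rasa = list(rep(50, 8)))
  p <- predict(m, chain8, type = "sub")
  # (L-1)/2 = 7 per side: the whole 8-residue chain is terminal,
  # so every residue takes the composition sub-classifier's score
  expect_equal(p$score, p$composition)

  m_full <- train_epitope_model(d, encoders = c("composition", "rasa"),
                                L = 15, ntree = 50, seed = 2,
                                terminal_policy = "full_ensemble")
  p_full <- predict(m_full, chain8, type = "sub")
  expect_equal(p_full$score,
               as.numeric(as.matrix(p_full[, c("rasa", "composition")]) %*%
                            m_full$weights[c("rasa", "composition")]))
})

test_that("mean and median strategies fuse the normalized sub scores", {
  d <- tiny_dataset(3, c(40, 50), seed = 35)
  for (strat in c("mean", "median")) {
    m <- train_epitope_model(d, encoders = c("composition", "rasa"),
                             strategy = strat, L = 9, ntree = 30, seed = 4)
    p <- predict(m, d[1, ], type = "sub")
    sub <- as.matrix(p[, c("rasa", "composition")])
    expected <- if (strat == "mean") rowMeans(sub) else apply(sub, 1, median)
    expect_equal(p$score, expected)
  }
})

test_that("an internal weight search returns a simplex point over the encoders", {
  d <- tiny_dataset(4, c(40, 50), seed = 36)
  m <- train_epitope_model(d, encoders = c("composition", "rasa"),
                           weights = "search", step = 0.25,
                           L = 9, ntree = 30, seed = 4)
  expect_setequal(names(m$weights), c("composition", "rasa"))
  expect_equal(sum(m$weights), 1)
})

test_that("model bundles survive a save/load round trip", {
  d <- tiny_dataset(2, c(40, 45), seed = 37)
  m <- train_epitope_model(d, encoders = c("composition", "rasa"),
                           L = 9, ntree = 30, seed = 6)
  f <- withr::local_tempfile(fileext = ".rds")
  save_epitope_model(m, f)
  m2 <- load_epitope_model(f)
  expect_identical(predict(m2, d)$score, predict(m, d)$score)
  expect_error(load_epitope_model(withr::local_tempfile(fileext = ".rds") |>
                                    (\(p) { saveRDS(1:3, p); p })()),
               "bundle")
})

test_that("tidy and glance summarize the fitted model", {
  d <- tiny_dataset(2, c(40, 45), seed = 38)
  m <- train_epitope_model(d, encoders = c("composition", "rasa"),
                           L = 9, ntree = 30, seed = 6)
  td <- tidy(m)
  expect_equal(nrow(td), 2)
  expect_true(all(c("encoder", "weight", "mu", "sigma", "n_forests") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$n_antigens, 2)
  expect_equal(gl$L, 9)
})
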