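test_that("every encoder emits its declared dimension for all odd L in 5..15", {
  for (L in seq(5, 15, by = 2)) {
    tw <- tracked_window(L, seed = L)
    for (enc in feature_encoders()$encoder) {
      v <- encode_window(tw$window, enc, pssm = tw$pssm, ss = tw$ss, rasa = tw$rasa)
      expect_length(v, encoder_dim(enc, L))
      expect_true(all(is.finite(v)))
    }
  }
})

test_that("propensity encoding looks up the six bundled scales, zero at X", {
  expect_equal(encode_window(strrep("X", 5), "propensity"), rep(0, 30))
  v <- encode_window("XXAXX", "propensity")
  scales <- propensity_scales()
  a_row <- as.numeric(scales[scales$residue == "A", -1])
  expect_equal(v[13:18], a_row)
  expect_equal(v[-(13:18)], rep(0, 24))
  # padded flank does not change the non-X block
  v2 <- encode_window("KVAGR", "propensity")
  expect_equal(v2[13:18], a_row)
})

test_that("sparse profile is one-hot in canonical order", {
  v <- encode_window("XXAXX", "sparse")
  expect_equal(which(v == 1), 41L)  # third position block, bit 1 = A
  expect_equal(sum(v), 1)
  v <- encode_window("KVFGR", "sparse")
  expect_equal(sum(v), 5)
})

test_that("composition is the non-X residue fraction and sums to 1", {
  v <- encode_window("AAAAA", "composition")
  expect_equal(unname(v[1]), 1)
  expect_equal(sum(v), 1)
  v <- encode_window("XXKXX", "composition")
  expect_equal(unname(v["K"]), 1)
  v <- encode_window("KVFGR", "composition")
  expect_equal(sort(unique(unname(v[v > 0]))), 0.2)
  expect_error(encode_window("XXXXX", "composition"), "all-X")
})

test_that("function groups follow the printed 13-class partition", {
  fg <- aa_function_groups()
  expect_equal(unname(fg[c("R", "K")]), c(1L, 1L))
  expect_equal(unname(fg[c("E", "D")]), c(2L, 2L))
  expect_equal(unname(fg[c("S", "T")]), c(3L, 3L))
  expect_equal(unname(fg[c("L", "V", "I")]), rep(4L, 3))
  expect_equal(unname(fg[c("Q", "N")]), c(5L, 5L))
  expect_equal(unname(fg[c("W", "F")]), c(6L, 6L))
  expect_equal(unname(fg[c("A", "C", "G", "H", "M", "P", "Y")]), 7:13)
  expect_equal(sort(unique(fg)), 1:13)

  vR <- encode_window("XXRXX", "function_group")
  vK <- encode_window("XXKXX", "function_group")
  expect_equal(vR, vK)  # same class
  expect_equal(which(vR == 1), 2 * 13 + 1)
  vY <- encode_window("XXYXX", "function_group")
  expect_equal(which(vY == 1), 2 * 13 + 13)
  expect_equal(sum(encode_window("KVFGR", "function_group")), 5)
})

test_that("functional composition aggregates composition by class", {
  v <- encode_window("XXRKX", "functional_composition")
  expect_equal(v[1], 1)
  v <- encode_window("STLVI", "functional_composition")
  expect_equal(v[3], 0.4)
  expect_equal(v[4], 0.6)
  # oracle: aggregate the 20-dim composition through the class map
  withr::with_seed(3, {
    for (i in 1:20) {
      w <- random_chain(9, seed = i)
      comp <- encode_window(w, "composition")
      fg <- aa_function_groups()
      agg <- vapply(1:13, function(k) sum(comp[names(fg)[fg == k]]), numeric(1))
      expect_equal(encode_window(w, "functional_composition"), agg)
    }
  })
})

test_that("evolutionary profile concatenates rescaled PSSM rows, zero at padding", {
  L <- 5
  pssm <- matrix(0L, L, 20)
  v <- encode_window("KVFGR", "evolutionary", pssm = pssm)
  expect_equal(v, rep(0.5, 100))  # logistic(0) = 0.5
  v <- encode_window("XKVFX", "evolutionary", pssm = pssm)
  expect_equal(v[1:20], rep(0, 20))
  expect_equal(v[81:100], rep(0, 20))
  expect_equal(v[21:40], rep(0.5, 20))
  expect_error(encode_window("KVFGR", "evolutionary"), "PSSM")
})

test_that("pair profile counts ordered adjacent non-X pairs", {
  v <- encode_window("XAAAX", "pair_profile")
  expect_equal(v[pair_idx <- 1], 1)  # AA is pair 1
  expect_equal(sum(v), 1)
  v <- encode_window("XXKVX", "pair_profile")
  kv <- (which(aa_alphabet() == "K") - 1) * 20 + which(aa_alphabet() == "V")
  expect_equal(v[kv], 1)
  v <- encode_window("XKVKX", "pair_profile")
  vk <- (which(aa_alphabet() == "V") - 1) * 20 + which(aa_alphabet() == "K")
  expect_equal(unname(v[c(kv, vk)]), c(0.5, 0.5))
  expect_error(encode_window("XXKXX", "pair_profile"), "pair")
})

test_that("SS and RASA encodings follow the declared maps", {
  expect_equal(encode_window("XXAXX", "ss", ss = "--H--")[7:9], c(1, 0, 0))
  expect_equal(encode_window("XXAXX", "ss", ss = "--E--")[7:9], c(0, 1, 0))
  expect_equal(encode_window("XXAXX", "ss", ss = "--C--")[7:9], c(0, 0, 1))
  expect_equal(encode_window("XXXXX", "ss", ss = "HHHHH"), rep(0, 15))

  expect_equal(encode_window("XXAXX", "rasa", rasa = c(0, 0, 100, 0, 0))[3], 1)
  expect_equal(encode_window("XXAXX", "rasa", rasa = c(9, 9, 0, 9, 9)), rep(0, 5))
  lo <- encode_window("XXAXX", "rasa", rasa = c(0, 0, 40, 0, 0))
  hi <- encode_window("XXAXX", "rasa", rasa = c(0, 0, 80, 0, 0))
  expect_lt(lo[3], hi[3])
})

test_that("chain-level encoding agrees with the per-window reference", {
  d <- tiny_dataset(1, c(25, 25), seed = 21)
  L <- 7
  half <- (L - 1) / 2
  seq_chars <- strsplit(d$sequence[1], "")[[1]]
  n <- length(seq_chars)
  padded_pssm <- rbind(matrix(0L, half, 20), d$pssm[[1]], matrix(0L, half, 20))
  padded_ss <- paste0(strrep("-", half), d$ss[1], strrep("-", half))
  padded_rasa <- c(rep(0, half), d$rasa[[1]], rep(0, half))
  for (enc in feature_encoders()$encoder) {
    m <- encode_chain(d$sequence[1], enc, L, pssm = d$pssm[[1]],
                      ss = d$ss[1], rasa = d$rasa[[1]])
    expect_equal(dim(m), c(n, encoder_dim(enc, L)))
    for (i in c(1, 2, n %/% 2, n)) {
      w <- substr(pad_sequence(d$sequence[1], L), i, i + L - 1)
      v <- encode_window(
        w, enc,
        pssm = padded_pssm[i:(i + L - 1), , drop = FALSE],
        ss = substr(padded_ss, i, i + L - 1),
        rasa = padded_rasa[i:(i + L - 1)]
      )
      expect_equal(unname(m[i, ]), unname(v), tolerance = 1e-12,
                   label = paste(enc, "row", i))
    }
  }
})

test_that("encoders are pure: identical input gives identical output", {
  tw <- tracked_window(9, seed = 2)
  for (enc in c("composition", "pair_profile", "evolutionary")) {
    v1 <- encode_window(tw$window, enc, pssm = tw$pssm, ss = tw$ss, rasa = tw$rasa)
    v2 <- encode_window(tw$window, enc, pssm = tw$pssm, ss = tw$ss, rasa = tw$rasa)
    expect_identical(v1, v2)
  }
})
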