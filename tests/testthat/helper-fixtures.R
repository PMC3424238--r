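# Small in-code fixtures shared across test files.

# deterministic random chain over the canonical alphabet
random_chain <- function(n, seed) {
  withr::with_seed(seed, paste0(sample(aa_alphabet(), n, replace = TRUE),
                                collapse = ""))
}

# a tiny fully tracked dataset (fast to train on)
tiny_dataset <- function(n_antigens = 3, len = c(50, 60), seed = 101,
                         preset = "complementary-signals") {
  cfg <- synthetic_preset(preset, seed = seed)
  cfg$n_antigens <- n_antigens
  cfg$chain_length <- len
  simulate_epitope_dataset(cfg)
}

# a window with all tracks, for encoder-dimension checks
tracked_window <- function(L, seed = 7) {
  withr::with_seed(seed, {
    w <- paste0(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
    list(
      window = w,
      pssm = matrix(sample(-5:8, 20 * L, replace = TRUE), L, 20),
      ss = paste0(sample(c("H", "E", "C"), L, replace = TRUE), collapse = ""),
      rasa = round(runif(L, 0, 100), 1)
    )
  })
}

# linearly separable two-class feature fixture
separable_fixture <- function(npos = 20, nneg = 60, p = 5, seed = 9) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(npos * p, mean = 2), npos, p),
      matrix(rnorm(nneg * p, mean = -2), nneg, p)
    )
    list(x = x, labels = c(rep(1L, npos), rep(0L, nneg)))
  })
}

# brute-force O(n^2) pair-counting AUC oracle
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
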