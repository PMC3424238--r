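#' Feature encoders
#'
#' The nine window encodings.  Each maps a length-`L` window (plus optional
#' per-residue tracks) to a fixed-length numeric vector:
#'
#' | name                     | length | needs |
#' |--------------------------|--------|-------|
#' | `propensity`             | `6L`   |       |
#' | `sparse`                 | `20L`  |       |
#' | `composition`            | `20`   |       |
#' | `function_group`         | `13L`  |       |
#' | `functional_composition` | `13`   |       |
#' | `evolutionary`           | `20L`  | pssm  |
#' | `pair_profile`           | `400`  |       |
#' | `ss`                     | `3L`   | ss    |
#' | `rasa`                   | `L`    | rasa  |
#'
#' Per-residue encodings are concatenated across the window in sequence
#' order (position-major).  An `'X'` — terminal padding or an unknown
#' residue — contributes an all-zero block to per-residue encodings and is
#' excluded from both numerator and denominator of the composition and
#' pair-profile encodings.
#'
#' @return A tibble with columns `encoder` and `requires` (list-column of
#'   required track names).
#' @export
feature_encoders <- function() {
  tibble::tibble(
    encoder = c("propensity", "sparse", "composition", "function_group",
                "functional_composition", "evolutionary", "pair_profile",
                "ss", "rasa"),
    requires = list(character(), character(), character(), character(),
                    character(), "pssm", character(), "ss", "rasa")
  )
}

#' Output length of an encoder
#'
#' @param encoder Encoder name (see [feature_encoders()]).
#' @param L Odd window length.
#' @return The encoded vector length.
#' @export
#' @examples
#' encoder_dim("sparse", 9)
encoder_dim <- function(encoder, L) {
  check_window_length(L)
  switch(match.arg(encoder, feature_encoders()$encoder),
    propensity = 6L * L,
    sparse = 20L * L,
    composition = 20L,
    function_group = 13L * L,
    functional_composition = 13L,
    evolutionary = 20L * L,
    pair_profile = 400L,
    ss = 3L * L,
    rasa = L
  )
}

encoder_requires <- function(encoder) {
  reg <- feature_encoders()
  reg$requires[[match(encoder, reg$encoder)]]
}

# ---- shared low-level pieces ------------------------------------------------

# one-hot N x k matrix from integer class indices (NA rows -> zero)
onehot_matrix <- function(idx, k) {
  m <- matrix(0, length(idx), k)
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

# pad a per-position matrix with `half` zero rows at each end
pad_zero_rows <- function(m, half) {
  z <- matrix(0, half, ncol(m))
  rbind(z, m, z)
}

# concatenate the L window slices of a padded per-position matrix:
# row i of the result is positions i..i+L-1 of `padded`, position-major
gather_window <- function(padded, n, L) {
  do.call(cbind, lapply(0:(L - 1), function(o) {
    padded[seq_len(n) + o, , drop = FALSE]
  }))
}

# sliding column sums over `span` consecutive rows of `m`
sliding_sums <- function(m, n_windows, span) {
  cs <- rbind(0, apply(m, 2, cumsum))
  cs[seq_len(n_windows) + span, , drop = FALSE] -
    cs[seq_len(n_windows), , drop = FALSE]
}

pair_index <- function(ia, ib) (ia - 1L) * 20L + ib

# ---- chain-level encoding ---------------------------------------------------

#' Encode every residue window of a chain
#'
#' Vectorized encoding: returns the feature matrix whose row `i` is the
#' encoding of the X-padded window centred on residue `i`.
#'
#' @param sequence Amino-acid string (may contain 'X').
#' @param encoder Encoder name (see [feature_encoders()]).
#' @param L Odd window length.
#' @param pssm Raw integer `N x 20` PSSM in canonical column order
#'   (required by `evolutionary`; rescaled internally with
#'   [logistic_rescale()]).
#' @param ss Length-N H/E/C string (required by `ss`).
#' @param rasa Length-N numeric vector in `[0, 100]` (required by `rasa`).
#' @return An `N x encoder_dim(encoder, L)` numeric matrix.
#' @export
encode_chain <- function(sequence, encoder, L = 9,
                         pssm = NULL, ss = NULL, rasa = NULL) {
  encoder <- match.arg(encoder, feature_encoders()$encoder)
  check_window_length(L)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  idx <- aa_index(chars)          # NA for 'X'
  half <- (L - 1) / 2

  need <- encoder_requires(encoder)
  if ("pssm" %in% need && is.null(pssm)) {
    stop("encoder 'evolutionary' requires a PSSM track")
  }
  if ("ss" %in% need && (is.null(ss) || is.na(ss))) {
    stop("encoder 'ss' requires a secondary-structure track")
  }
  if ("rasa" %in% need && is.null(rasa)) {
    stop("encoder 'rasa' requires a RASA track")
  }

  per_position <- switch(encoder,
    propensity = {
      m <- matrix(0, n, 6)
      ok <- !is.na(idx)
      m[ok, ] <- propensity_matrix()[idx[ok], , drop = FALSE]
      m
    },
    sparse = onehot_matrix(idx, 20),
    function_group = onehot_matrix(unname(aa_function_groups())[idx], 13),
    evolutionary = {
      if (nrow(pssm) != n) stop("PSSM row count != sequence length")
      m <- logistic_rescale(pssm)
      m[is.na(idx), ] <- 0
      unname(as.matrix(m))
    },
    ss = {
      s_idx <- match(strsplit(ss, "")[[1]], c("H", "E", "C"))
      if (length(s_idx) != n) stop("ss track length != sequence length")
      m <- onehot_matrix(s_idx, 3)
      m[is.na(idx), ] <- 0
      m
    },
    rasa = {
      if (length(rasa) != n) stop("rasa track length != sequence length")
      m <- matrix(rasa / 100, ncol = 1)
      m[is.na(idx), ] <- 0
      m
    },
    NULL
  )
  if (!is.null(per_position)) {
    return(gather_window(pad_zero_rows(per_position, half), n, L))
  }

  if (encoder %in% c("composition", "functional_composition")) {
    k <- if (encoder == "composition") 20L else 13L
    cls <- if (encoder == "composition") idx else unname(aa_function_groups())[idx]
    counts <- sliding_sums(pad_zero_rows(onehot_matrix(cls, k), half), n, L)
    denom <- rowSums(counts)
    if (any(denom == 0)) {
      stop("undefined composition: window with no standard residue at centre ",
           which(denom == 0)[1])
    }
    return(counts / denom)
  }

  # pair_profile: ordered adjacent pairs within the padded window
  pc_idx <- c(rep(NA_integer_, half), idx, rep(NA_integer_, half))
  ia <- pc_idx[-length(pc_idx)]
  ib <- pc_idx[-1]
  valid <- !is.na(ia) & !is.na(ib)
  p_idx <- ifelse(valid, pair_index(ia, ib), NA_integer_)
  counts <- sliding_sums(onehot_matrix(p_idx, 400), n, L - 1)
  denom <- rowSums(counts)
  if (any(denom == 0)) {
    stop("undefined pair profile: window with no valid adjacent residue pair ",
         "at centre ", which(denom == 0)[1])
  }
  counts / denom
}

# ---- window-level encoding --------------------------------------------------

#' Encode a single window
#'
#' Reference per-window implementation of each encoding; [encode_chain()]
#' is the vectorized equivalent and the two agree exactly.  Track slices
#' are aligned to the window: entries at positions whose window character
#' is `'X'` are ignored.
#'
#' @param window Length-`L` string over the 20 amino acids + 'X'.
#' @param encoder Encoder name.
#' @param pssm Optional `L x 20` raw PSSM slice aligned to the window.
#' @param ss Optional length-`L` H/E/C string (any character at 'X'
#'   positions).
#' @param rasa Optional length-`L` numeric vector.
#' @return A numeric vector of length `encoder_dim(encoder, nchar(window))`.
#' @export
#' @examples
#' encode_window("XXKXX", "composition")["K"]
encode_window <- function(window, encoder, pssm = NULL, ss = NULL, rasa = NULL) {
  encoder <- match.arg(encoder, feature_encoders()$encoder)
  L <- nchar(window)
  check_window_length(L)
  chars <- strsplit(window, "")[[1]]
  idx <- aa_index(chars)
  ok <- !is.na(idx)

  out <- switch(encoder,
    propensity = {
      m <- matrix(0, L, 6)
      m[ok, ] <- propensity_matrix()[idx[ok], , drop = FALSE]
      as.numeric(t(m))
    },
    sparse = as.numeric(t(onehot_matrix(idx, 20))),
    function_group = as.numeric(t(onehot_matrix(unname(aa_function_groups())[idx], 13))),
    composition = {
      if (!any(ok)) stop("undefined composition: all-X window")
      counts <- tabulate(idx[ok], nbins = 20)
      stats::setNames(counts / sum(counts), aa_alphabet())
    },
    functional_composition = {
      if (!any(ok)) stop("undefined functional composition: all-X window")
      counts <- tabulate(unname(aa_function_groups())[idx[ok]], nbins = 13)
      counts / sum(counts)
    },
    evolutionary = {
      if (is.null(pssm)) stop("encoder 'evolutionary' requires a PSSM slice")
      stopifnot(nrow(pssm) == L, ncol(pssm) == 20)
      m <- logistic_rescale(as.matrix(pssm))
      m[!ok, ] <- 0
      as.numeric(t(m))
    },
    pair_profile = {
      ia <- idx[-L]
      ib <- idx[-1]
      valid <- !is.na(ia) & !is.na(ib)
      if (!any(valid)) stop("undefined pair profile: no valid adjacent pair")
      counts <- tabulate(pair_index(ia[valid], ib[valid]), nbins = 400)
      counts / sum(counts)
    },
    ss = {
      if (is.null(ss)) stop("encoder 'ss' requires a secondary-structure slice")
      s_idx <- match(strsplit(ss, "")[[1]], c("H", "E", "C"))
      stopifnot(length(s_idx) == L)
      m <- onehot_matrix(s_idx, 3)
      m[!ok, ] <- 0
      as.numeric(t(m))
    },
    rasa = {
      if (is.null(rasa)) stop("encoder 'rasa' requires a RASA slice")
      stopifnot(length(rasa) == L)
      v <- rasa / 100
      v[!ok] <- 0
      v
    }
  )
  as.numeric(out) |> stats::setNames(names(out))
}

# design matrix + window metadata for a chain table under one encoder
dataset_design <- function(data, encoder, L) {
  meta <- extract_windows(data, L, padded = TRUE)
  mats <- lapply(seq_len(nrow(data)), function(i) {
    encode_chain(data$sequence[i], encoder, L,
                 pssm = data$pssm[[i]], ss = data$ss[i], rasa = data$rasa[[i]])
  })
  list(meta = meta, x = do.call(rbind, mats))
}
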