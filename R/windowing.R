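#' Pad a sequence with terminal 'X's
#'
#' Adds `(L - 1) / 2` `'X'` characters to each terminus so that a sliding
#' window of odd length `L` can be centred on every residue, including the
#' first and last.  With `L = 15`, seven 'X's are added per side, and the
#' window centred on the first residue of a chain starting `KVFGRCEL` reads
#' `XXXXXXXKVFGRCEL`.
#'
#' @param sequence Amino-acid string.
#' @param L Odd window length (>= 3).
#' @return The padded string, of length `nchar(sequence) + L - 1`.
#' @export
#' @examples
#' pad_sequence("KVF", 3)
pad_sequence <- function(sequence, L) {
  check_window_length(L)
  pad <- strrep("X", (L - 1) / 2)
  paste0(pad, sequence, pad)
}

check_window_length <- function(L) {
  if (length(L) != 1 || is.na(L) || L < 3 || L %% 2 != 1) {
    stop("window length L must be an odd integer >= 3, got ", L)
  }
  invisible(L)
}

#' Extract one window instance per residue
#'
#' Slides a length-`L` window over the X-padded chain so every residue gets
#' exactly one window centred on it; the window inherits the label of its
#' central residue.  With `padded = FALSE` the classical unpadded extraction
#' is performed instead, yielding `max(0, N - L + 1)` segments (centres
#' `(L-1)/2 + 1 ... N - (L-1)/2`), retained for bookkeeping.
#'
#' @param data A chain tibble ([epitope_dataset()]), or a single sequence
#'   string.
#' @param L Odd window length.
#' @param padded Use terminal X-padding (default) so that every residue is
#'   covered.
#' @return A tibble with one row per window: `antigen_id`, `chain_id`,
#'   `center` (1-based residue index in the unpadded chain), `window`
#'   (length-`L` string over the 20 amino acids + 'X') and `label`
#'   (integer or `NA` when the chain is unlabeled).
#' @export
extract_windows <- function(data, L = 9, padded = TRUE) {
  check_window_length(L)
  if (is.character(data)) {
    data <- tibble::tibble(antigen_id = "seq", chain_id = "A", sequence = data,
                           labels = vector("list", length(data)))
  }
  half <- (L - 1) / 2
  purrr::map_dfr(seq_len(nrow(data)), function(i) {
    seq_i <- data$sequence[i]
    n <- nchar(seq_i)
    lab <- if ("labels" %in% names(data)) data$labels[[i]] else NULL
    if (padded) {
      centers <- seq_len(n)
      padded_seq <- pad_sequence(seq_i, L)
      windows <- substring(padded_seq, centers, centers + L - 1)
    } else {
      if (n < L) return(NULL)
      centers <- seq.int(half + 1, n - half)
      windows <- substring(seq_i, centers - half, centers + half)
    }
    tibble::tibble(
      antigen_id = data$antigen_id[i],
      chain_id = data$chain_id[i],
      center = centers,
      window = windows,
      label = if (is.null(lab)) NA_integer_ else as.integer(lab[centers])
    )
  })
}

#' Count positive and negative window instances
#'
#' Epitope residues are a small minority of most antigens, so the window
#' instances are heavily imbalanced; this count drives the number of
#' rebalanced bootstrap samples ([compute_n()]).
#'
#' @param windows A window tibble from [extract_windows()] (or any tibble
#'   with an integer `label` column).
#' @return A named integer vector `c(pos = ..., neg = ...)`.
#' @export
class_counts <- function(windows) {
  lab <- windows$label
  if (anyNA(lab)) stop("cannot count classes: unlabeled instances present")
  c(pos = sum(lab == 1L), neg = sum(lab == 0L))
}
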