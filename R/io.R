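#' Read antigen sequences from a FASTA file
#'
#' Sequences are uppercased and any letter outside the 20 canonical amino
#' acids is mapped to `'X'` (with a warning naming the offending records).
#' `'X'` is a legal input character and is treated by every encoder the same
#' way as terminal padding.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  canonical <- paste0(aa_alphabet(), collapse = "")
  cleaned <- gsub(paste0("[^", canonical, "X]"), "X", seqs)
  changed <- cleaned != seqs
  if (any(changed)) {
    warning("non-canonical residue letters mapped to 'X' in: ",
            paste(ids[changed], collapse = ", "))
  }
  tibble::tibble(id = unname(ids), sequence = unname(cleaned))
}

#' Write sequences to a FASTA file
#'
#' @param ids,sequences Character vectors of equal length.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  set <- Biostrings::BStringSet(sequences)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read per-residue epitope labels
#'
#' The label table is tab-separated with columns `antigen_id`, `chain_id`,
#' `position` (1-based), `residue` and `label` (0 = non-epitope,
#' 1 = epitope).  When `sequences` is supplied (a tibble with `antigen_id`,
#' `chain_id`, `sequence`) each row is cross-checked: the position must be
#' within range and the residue must match the sequence.
#'
#' @param path Path to the label TSV.
#' @param sequences Optional chain table for validation.
#' @return A tibble `antigen_id`, `chain_id`, `position`, `residue`, `label`.
#' @export
read_labels <- function(path, sequences = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    antigen_id = readr::col_character(),
    chain_id = readr::col_character(),
    position = readr::col_integer(),
    residue = readr::col_character(),
    label = readr::col_integer()
  ), comment = "#")
  if (!all(tbl$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  key <- paste(tbl$antigen_id, tbl$chain_id, tbl$position)
  if (anyDuplicated(key)) {
    stop("duplicate label records for: ", key[duplicated(key)][1])
  }
  if (!is.null(sequences)) {
    idx <- match(paste(tbl$antigen_id, tbl$chain_id),
                 paste(sequences$antigen_id, sequences$chain_id))
    if (anyNA(idx)) stop("label records for unknown chains")
    seqs <- sequences$sequence[idx]
    if (any(tbl$position < 1 | tbl$position > nchar(seqs))) {
      stop("label position out of sequence range")
    }
    actual <- substr(seqs, tbl$position, tbl$position)
    bad <- actual != tbl$residue
    if (any(bad)) {
      stop("residue mismatch between label file and sequence at e.g. ",
           tbl$antigen_id[bad][1], "/", tbl$chain_id[bad][1],
           " position ", tbl$position[bad][1])
    }
  }
  tbl
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the `-out_ascii_pssm` dialect: a free-text header, a column-label
#' line naming the 20 amino acids, then one row per query residue starting
#' with the position and residue followed by 20 integer log-odds (files with
#' the additional 20 percentage columns are accepted; only the first 20
#' numeric columns are used).  Columns are remapped from the file's own
#' order to the canonical alphabet [aa_alphabet()].
#'
#' @param path Path to the PSSM file.
#' @return An `N x 20` integer matrix, one row per residue, columns in
#'   canonical order; the query sequence is attached as attribute `"residues"`.
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  # the column-label line holds >= 20 single amino-acid letters and nothing else
  is_header <- vapply(lines, function(x) {
    toks <- strsplit(trimws(x), "\\s+")[[1]]
    length(toks) >= 20 && all(toks %in% aa_alphabet())
  }, logical(1), USE.NAMES = FALSE)
  hi <- which(is_header)[1]
  if (is.na(hi)) stop("malformed PSSM: no amino-acid column header found in ", path)
  file_order <- strsplit(trimws(lines[hi]), "\\s+")[[1]][1:20]
  if (anyDuplicated(file_order)) stop("malformed PSSM header: duplicated columns")

  rows <- list()
  residues <- character()
  for (line in lines[-seq_len(hi)]) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(toks) == 0 || is.na(suppressWarnings(as.integer(toks[1])))) {
      if (length(rows) > 0) break  # footer (K, Lambda ...) ends the matrix
      next
    }
    if (length(toks) < 22) stop("truncated PSSM row: ", line)
    vals <- suppressWarnings(as.integer(toks[3:22]))
    if (anyNA(vals)) stop("non-integer log-odds in PSSM row: ", line)
    pos <- as.integer(toks[1])
    if (pos != length(rows) + 1L) stop("non-contiguous PSSM positions at row ", pos)
    rows[[pos]] <- vals
    residues[pos] <- toks[2]
  }
  if (length(rows) == 0) stop("malformed PSSM: no data rows in ", path)
  m <- do.call(rbind, rows)
  m <- m[, match(aa_alphabet(), file_order), drop = FALSE]
  colnames(m) <- aa_alphabet()
  attr(m, "residues") <- paste0(residues, collapse = "")
  m
}

#' Write an integer PSSM in PSI-BLAST ASCII dialect
#'
#' @param pssm `N x 20` integer matrix with canonical column order.
#' @param sequence The query sequence (length `N`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, sequence, path) {
  n <- nrow(pssm)
  stopifnot(ncol(pssm) == 20, nchar(sequence) == n)
  res <- strsplit(sequence, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed",
    paste0("     ", paste(sprintf("%3s", aa_alphabet()), collapse = " "))
  ), con)
  for (i in seq_len(n)) {
    writeLines(paste0(
      sprintf("%4d %s ", i, res[i]),
      paste(sprintf("%3d", pssm[i, ]), collapse = " ")
    ), con)
  }
  invisible(path)
}

#' Logistic rescaling of PSSM log-odds
#'
#' Maps each raw integer log-odds entry `e` to `1 / (1 + exp(-e))`, the
#' standard logistic function, so every entry lies in (0, 1) and 0 maps
#' to 0.5.
#'
#' @param pssm Numeric matrix (or vector) of raw log-odds.
#' @return Object of the same shape with entries in (0, 1).
#' @export
#' @examples
#' logistic_rescale(c(-2, 0, 2))
logistic_rescale <- function(pssm) {
  out <- 1 / (1 + exp(-pssm))
  attr(out, "residues") <- NULL
  out
}

#' Read predicted secondary structure and RASA
#'
#' Tab-separated columns `position` (1-based, contiguous from 1), `ss`
#' (one of H/E/C) and `rasa` (0-100, the percentage of the residue's
#' surface exposed to solvent).
#'
#' @param path Path to the structure TSV.
#' @return A list with `ss` (a length-N string over HEC) and `rasa`
#'   (numeric vector of length N).
#' @export
read_structprops <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    position = readr::col_integer(),
    ss = readr::col_character(),
    rasa = readr::col_double()
  ), comment = "#")
  if (!identical(tbl$position, seq_len(nrow(tbl)))) {
    stop("structure table positions must be contiguous from 1")
  }
  if (!all(tbl$ss %in% c("H", "E", "C"))) {
    stop("secondary-structure symbols must be H, E or C")
  }
  if (any(tbl$rasa < 0 | tbl$rasa > 100)) {
    stop("RASA values must lie in [0, 100]")
  }
  list(ss = paste0(tbl$ss, collapse = ""), rasa = tbl$rasa)
}

#' Write a per-residue structure table
#'
#' @param ss Length-N string over H/E/C.
#' @param rasa Numeric vector of length N in `[0, 100]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structprops <- function(ss, rasa, path) {
  stopifnot(nchar(ss) == length(rasa))
  readr::write_tsv(tibble::tibble(
    position = seq_along(rasa),
    ss = strsplit(ss, "")[[1]],
    rasa = rasa
  ), path)
  invisible(path)
}

#' Write per-residue epitope predictions
#'
#' @param predictions A tibble with columns `antigen_id`, `chain_id`,
#'   `position` (1-based), `residue` and `score` in `[0, 1]` (as returned
#'   by [predict.epitope_model()]).
#' @param path Output path.
#' @param threshold Classification threshold; a residue is called an
#'   epitope when `score >= threshold`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, threshold = 0.5) {
  required <- c("antigen_id", "chain_id", "position", "residue", "score")
  stopifnot(all(required %in% names(predictions)))
  if (nrow(predictions) == 0) stop("no predictions to write")
  if (any(predictions$score < 0 | predictions$score > 1)) {
    stop("scores must lie in [0, 1]")
  }
  out <- predictions |>
    dplyr::select(dplyr::all_of(required)) |>
    dplyr::arrange(.data$antigen_id, .data$chain_id, .data$position) |>
    dplyr::mutate(
      score = round(.data$score, 6),
      predicted_label = as.integer(.data$score >= threshold)
    )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#'
#' @param path Path to the prediction TSV.
#' @return A tibble with the written columns.
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    antigen_id = readr::col_character(),
    chain_id = readr::col_character(),
    position = readr::col_integer(),
    residue = readr::col_character(),
    score = readr::col_double(),
    predicted_label = readr::col_integer()
  ), comment = "#")
}
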