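#' Build an antigen chain table
#'
#' The package's central container is a plain tibble with one row per
#' antigen chain and columns `antigen_id`, `chain_id`, `sequence`, plus
#' optional per-residue tracks as list-columns: `labels` (integer 0/1),
#' `pssm` (N x 20 integer matrix, canonical column order), `ss` (length-N
#' string over H/E/C, `NA` if absent) and `rasa` (numeric, 0-100).
#' Leave-one-out cross-validation always holds out all chains sharing an
#' `antigen_id` together, since one antigen may have several chains.
#'
#' @param antigen_id,chain_id,sequence Character vectors, one element per chain.
#' @param labels,pssm,rasa Optional lists (one element per chain, `NULL`
#'   elements allowed) of label vectors, PSSM matrices and RASA vectors.
#' @param ss Optional character vector of H/E/C strings (`NA` allowed).
#' @return A validated chain tibble.
#' @export
epitope_dataset <- function(antigen_id, chain_id, sequence,
                            labels = NULL, pssm = NULL, ss = NULL, rasa = NULL) {
  n <- length(sequence)
  null_col <- function(x) if (is.null(x)) vector("list", n) else x
  data <- tibble::tibble(
    antigen_id = antigen_id,
    chain_id = chain_id,
    sequence = toupper(sequence),
    labels = null_col(labels),
    pssm = null_col(pssm),
    ss = if (is.null(ss)) rep(NA_character_, n) else ss,
    rasa = null_col(rasa)
  )
  validate_epitope_dataset(data)
}

#' Validate a chain table
#'
#' Checks the structural invariants of the container: unique
#' (antigen, chain) keys, sequences over the 20-letter alphabet plus 'X',
#' and every optional track, when present, exactly as long as its chain;
#' labels binary; RASA within `[0, 100]`; SS over H/E/C.  Called by every
#' entry point before any computation so malformed inputs fail early.
#'
#' @param data A chain tibble (see [epitope_dataset()]).
#' @return `data`, invisibly usable, returned unchanged on success.
#' @export
validate_epitope_dataset <- function(data) {
  required <- c("antigen_id", "chain_id", "sequence")
  if (!all(required %in% names(data))) {
    stop("chain table needs columns: ", paste(required, collapse = ", "))
  }
  if (nrow(data) == 0) stop("chain table is empty")
  for (col in c("labels", "pssm", "rasa")) {
    if (!col %in% names(data)) data[[col]] <- vector("list", nrow(data))
  }
  if (!"ss" %in% names(data)) data$ss <- NA_character_
  key <- paste(data$antigen_id, data$chain_id)
  if (anyDuplicated(key)) stop("duplicate (antigen_id, chain_id): ", key[duplicated(key)][1])
  if (any(!nzchar(data$antigen_id))) stop("empty antigen_id")
  ok_alpha <- grepl(paste0("^[", paste0(aa_alphabet(), collapse = ""), "X]+$"), data$sequence)
  if (!all(ok_alpha)) {
    stop("sequence with letters outside the amino-acid alphabet (+X): ",
         key[!ok_alpha][1])
  }
  n <- nchar(data$sequence)
  for (i in seq_len(nrow(data))) {
    lab <- data$labels[[i]]
    if (!is.null(lab)) {
      if (length(lab) != n[i]) stop("labels length != sequence length for ", key[i])
      if (!all(lab %in% c(0L, 1L))) stop("labels must be 0/1 for ", key[i])
    }
    p <- data$pssm[[i]]
    if (!is.null(p)) {
      if (nrow(p) != n[i] || ncol(p) != 20) stop("pssm must be N x 20 for ", key[i])
    }
    if (!is.na(data$ss[i])) {
      if (nchar(data$ss[i]) != n[i]) stop("ss length != sequence length for ", key[i])
      if (!grepl("^[HEC]+$", data$ss[i])) stop("ss must be over H/E/C for ", key[i])
    }
    r <- data$rasa[[i]]
    if (!is.null(r)) {
      if (length(r) != n[i]) stop("rasa length != sequence length for ", key[i])
      if (any(r < 0 | r > 100)) stop("rasa outside [0, 100] for ", key[i])
    }
  }
  data
}

chain_key <- function(data) paste0(data$antigen_id, "_", data$chain_id)

#' Write a chain table to a dataset directory
#'
#' Emits the plain-text layout read back by [read_epitope_dataset()]:
#' `sequences.fasta` (record ids `antigen|chain`), `labels.tsv`,
#' `pssm/<antigen>_<chain>.pssm` (PSI-BLAST ASCII dialect) and
#' `struct/<antigen>_<chain>.tsv`, each track written only where present.
#'
#' @param data A chain tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epitope_dataset <- function(data, dir) {
  data <- validate_epitope_dataset(data)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(paste0(data$antigen_id, "|", data$chain_id), data$sequence,
              file.path(dir, "sequences.fasta"))
  has_lab <- !vapply(data$labels, is.null, logical(1))
  if (any(has_lab)) {
    lab_tbl <- dplyr::bind_rows(lapply(which(has_lab), function(i) {
      tibble::tibble(
        antigen_id = data$antigen_id[i], chain_id = data$chain_id[i],
        position = seq_len(nchar(data$sequence[i])),
        residue = strsplit(data$sequence[i], "")[[1]],
        label = as.integer(data$labels[[i]])
      )
    }))
    readr::write_tsv(lab_tbl, file.path(dir, "labels.tsv"))
  }
  keys <- chain_key(data)
  for (i in seq_len(nrow(data))) {
    if (!is.null(data$pssm[[i]])) {
      dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
      write_pssm(data$pssm[[i]], data$sequence[i],
                 file.path(dir, "pssm", paste0(keys[i], ".pssm")))
    }
    if (!is.na(data$ss[i]) && !is.null(data$rasa[[i]])) {
      dir.create(file.path(dir, "struct"), showWarnings = FALSE)
      write_structprops(data$ss[i], data$rasa[[i]],
                        file.path(dir, "struct", paste0(keys[i], ".tsv")))
    }
  }
  invisible(dir)
}

#' Read a dataset directory into a chain table
#'
#' Reads the layout written by [write_epitope_dataset()].  FASTA record ids
#' of the form `antigen|chain` are split on the first `|`; ids without a
#' separator become single-chain antigens with chain id `"A"`.  Tracks are
#' attached where the corresponding files exist and validated against the
#' sequences.
#'
#' @param dir Dataset directory.
#' @return A validated chain tibble.
#' @export
read_epitope_dataset <- function(dir) {
  fa <- read_fasta(file.path(dir, "sequences.fasta"))
  has_sep <- grepl("\\|", fa$id)
  antigen_id <- ifelse(has_sep, sub("\\|.*$", "", fa$id), fa$id)
  chain_id <- ifelse(has_sep, sub("^[^|]*\\|", "", fa$id), "A")
  data <- tibble::tibble(
    antigen_id = antigen_id, chain_id = chain_id, sequence = fa$sequence,
    labels = vector("list", nrow(fa)), pssm = vector("list", nrow(fa)),
    ss = NA_character_, rasa = vector("list", nrow(fa))
  )
  lab_path <- file.path(dir, "labels.tsv")
  if (file.exists(lab_path)) {
    lab <- read_labels(lab_path, sequences = data)
    lab_split <- split(lab, paste(lab$antigen_id, lab$chain_id))
    for (i in seq_len(nrow(data))) {
      part <- lab_split[[paste(data$antigen_id[i], data$chain_id[i])]]
      if (is.null(part)) next
      v <- integer(nchar(data$sequence[i]))
      v[part$position] <- part$label
      if (nrow(part) != length(v)) {
        # partial annotation: only fully annotated chains get a label track
        stop("incomplete label annotation for ", data$antigen_id[i], "/",
             data$chain_id[i], "; every residue needs a label row")
      }
      data$labels[[i]] <- v
    }
  }
  keys <- chain_key(data)
  for (i in seq_len(nrow(data))) {
    pf <- file.path(dir, "pssm", paste0(keys[i], ".pssm"))
    if (file.exists(pf)) {
      p <- read_pssm(pf)
      attr(p, "residues") <- NULL
      data$pssm[[i]] <- p
    }
    sf <- file.path(dir, "struct", paste0(keys[i], ".tsv"))
    if (file.exists(sf)) {
      sp <- read_structprops(sf)
      data$ss[i] <- sp$ss
      data$rasa[[i]] <- sp$rasa
    }
  }
  validate_epitope_dataset(data)
}
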