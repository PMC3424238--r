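#' Canonical amino-acid alphabet and residue classifications
#'
#' All 20-dimensional axes in the package (sparse profile, composition,
#' PSSM columns, pair profile) use the alphabetical single-letter ordering
#' `ACDEFGHIKLMNPQRSTVWY`.  PSSM files carry their own column order in the
#' header and are remapped to this ordering on read.
#'
#' @format `aa_alphabet()` returns a character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Amino-acid function groups
#'
#' Partition of the 20 residues into 13 classes by R-group chemistry, used
#' by the function-group one-hot and functional-composition encodings:
#' class 1 = R,K; 2 = E,D; 3 = S,T; 4 = L,V,I; 5 = Q,N; 6 = W,F; 7 = A;
#' 8 = C; 9 = G; 10 = H; 11 = M; 12 = P; 13 = Y.
#'
#' @return A named integer vector mapping each residue to its class (1-13).
#' @export
#' @examples
#' aa_function_groups()[c("R", "K", "Y")]
aa_function_groups <- function() {
  groups <- list(
    c("R", "K"), c("E", "D"), c("S", "T"), c("L", "V", "I"),
    c("Q", "N"), c("W", "F"), "A", "C", "G", "H", "M", "P", "Y"
  )
  out <- integer(20)
  names(out) <- aa_alphabet()
  for (i in seq_along(groups)) out[groups[[i]]] <- i
  out
}

# residue character vector -> integer index in the canonical alphabet
# (NA for 'X' or any non-canonical letter)
aa_index <- function(chars) {
  match(chars, aa_alphabet())
}

#' Physicochemical propensity scales
#'
#' The six per-residue scales used by the propensity encoding: flexibility
#' (Karplus & Schulz normalized B-factors), hydrophilicity (Parker HPLC
#' scale), surface exposure (Janin interior-to-surface transfer free
#' energy), polarity (the Grantham-type polarity values conventionally used
#' with the Ponnuswamy citation in epitope-propensity tools), beta-turn
#' (Chou-Fasman-type turn propensities as used by Pellequer) and
#' accessibility (Emini surface probability).  Published variants of some
#' scales differ slightly; the exact values shipped are the data file
#' `inst/extdata/propensity_scales.tsv`, one row per residue.
#'
#' @return A tibble with column `residue` followed by the six numeric
#'   scale columns, rows in canonical alphabet order.
#' @export
propensity_scales <- function() {
  cached <- .epifuse_env$propensity_scales
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "propensity_scales.tsv", package = "epifuse")
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    residue = readr::col_character(), .default = readr::col_double()
  ))
  stopifnot(identical(sort(tbl$residue), sort(aa_alphabet())))
  tbl <- tbl[match(aa_alphabet(), tbl$residue), ]
  .epifuse_env$propensity_scales <- tbl
  tbl
}

.epifuse_env <- new.env(parent = emptyenv())

# 20 x 6 matrix of scale values, rownames = canonical alphabet
propensity_matrix <- function() {
  tbl <- propensity_scales()
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl$residue
  m
}

#' Names of the six propensity scales, in encoding order
#' @export
propensity_scale_names <- function() {
  setdiff(names(propensity_scales()), "residue")
}
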