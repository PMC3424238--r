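MODEL_BUNDLE_VERSION <- 1L

#' Save / load a fitted epitope model bundle
#'
#' The bundle is a versioned RDS file holding the sub-ensembles, the
#' normalization parameters, the fusion weights and every configuration
#' field needed to predict (window length, strategy, tanh constant,
#' terminal policy, seed, training class counts).
#'
#' @param model An `epitope_model`.
#' @param path Output path (conventionally `.rds`).
#' @return `path` invisibly for `save_epitope_model()`; the restored
#'   `epitope_model` for `load_epitope_model()`.
#' @export
save_epitope_model <- function(model, path) {
  stopifnot(inherits(model, "epitope_model"))
  saveRDS(list(version = MODEL_BUNDLE_VERSION, model = model), path)
  invisible(path)
}

#' @rdname save_epitope_model
#' @export
load_epitope_model <- function(path) {
  bundle <- readRDS(path)
  if (!is.list(bundle) || is.null(bundle$version)) {
    stop("not an epitope model bundle: ", path)
  }
  if (bundle$version > MODEL_BUNDLE_VERSION) {
    stop("model bundle version ", bundle$version, " is newer than supported")
  }
  stopifnot(inherits(bundle$model, "epitope_model"))
  bundle$model
}
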