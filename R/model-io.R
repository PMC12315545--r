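# Checkpoint serialization. Parameters are written as JSON (dims + flat
# values, column-major) so checkpoints are plain text and reload bit-close
# (full double precision via digits = NA).

#' Save a trained model to a checkpoint directory
#'
#' Writes `params.json`, `config.json` and `metrics.json`.
#' @param model a `pretrain_model`.
#' @param dir output directory (created if needed).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ser <- function(p) {
    lapply(p, function(x) {
      if (is.matrix(x)) list(dim = dim(x), values = as.numeric(x))
      else list(dim = length(x), values = as.numeric(x))
    })
  }
  par <- model$params
  nv <- par$n_vocab
  par$n_vocab <- NULL
  jsonlite::write_json(ser(par), file.path(dir, "params.json"),
                       auto_unbox = FALSE, digits = NA)
  jsonlite::write_json(
    list(mconfig = unclass(model$mconfig), pconfig = unclass(model$pconfig),
         n_vocab = nv),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(model$metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a model checkpoint
#' @param dir directory written by [save_model()].
#' @return a `pretrain_model`.
#' @export
load_model <- function(dir) {
  raw <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  params <- lapply(raw, function(e) {
    if (length(e$dim) == 2L) matrix(e$values, e$dim[1], e$dim[2])
    else if (e$dim == 1L && length(e$values) == 1L) e$values
    else e$values
  })
  cfgs <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  mconfig <- do.call(model_config, cfgs$mconfig[
    c("hidden_dim", "n_layers", "fusion", "pooling", "dropout", "seed")])
  pconfig <- do.call(pretrain_config, cfgs$pconfig[
    c("mask_ratio", "strategy", "epochs_stage1", "epochs_stage2",
      "batch_size", "lr", "seed", "lambda_frag", "heldout_fraction")])
  params$n_vocab <- as.integer(cfgs$n_vocab)
  class(params) <- "pt_params"
  metrics <- tryCatch(
    jsonlite::read_json(file.path(dir, "metrics.json"), simplifyVector = TRUE),
    error = function(e) NULL
  )
  structure(list(params = params, mconfig = mconfig, pconfig = pconfig,
                 metrics = metrics, n_vocab = cfgs$n_vocab),
            class = "pretrain_model")
}
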