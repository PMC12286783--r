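#' Read a run configuration from YAML
#'
#' A run config has a `model` section (fields of [encoder_config()] plus
#' `num_classes`, `in_channels`, `window`) and a `train` section (fields of
#' [train_config()]). Missing fields fall back to the defaults.
#'
#' @param path YAML file path.
#' @return List with `model_config`, `train_config`, `num_classes`,
#'   `in_channels`, `window`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  m <- y$model %||% list()
  t <- y$train %||% list()
  mc_args <- m[intersect(names(m), names(formals(encoder_config)))]
  tc_args <- t[intersect(names(t), names(formals(train_config)))]
  if (!is.null(tc_args$loss_weights)) {
    tc_args$loss_weights <- unlist(tc_args$loss_weights)
  }
  list(model_config = do.call(encoder_config, mc_args),
       train_config = do.call(train_config, tc_args),
       num_classes = as.integer(m$num_classes %||% 2L),
       in_channels = as.integer(m$in_channels %||% 1L),
       window = as.integer(m$window %||% c(64L, 64L, 64L)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint itself is an opaque binary (RDS); a JSON sidecar
#' (`<path>.json`) records the configuration hash, shapes and class count so
#' a checkpoint can be identified without deserializing it.
#'
#' @param model An `afno_model` (typically `train(...)$model`).
#' @param path Checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "afno_model"))
  saveRDS(model, path)
  sidecar <- list(
    config_hash = spec_hash(model$config),
    mixing_mode = model$config$mixing_mode,
    stage_channels = model$config$stage_channels,
    input_shape = model$input_shape,
    in_channels = model$in_channels,
    num_classes = model$num_classes)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the `afno_model`.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "afno_model")) stop("not an afno_model checkpoint")
  model
}
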