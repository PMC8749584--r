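#' Save a trained model checkpoint
#'
#' Writes the named-parameter container to a single file and a JSON manifest
#' (`<path>.json`) alongside it carrying the configuration, branch kind,
#' vocabulary hash and best epoch. Auxiliary fine-tuning heads are not part
#' of a fused model's exported parameter set.
#'
#' @param model A `triage_branch` or `triage_fused`.
#' @param path Checkpoint file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "triage_branch")) {
    manifest <- list(kind = model$branch_kind, config = unclass(model$config),
                     vocab_hash = model$vocab_hash, best_epoch = model$best_epoch)
    payload <- list(type = "branch", params = model$params,
                    config = model$config, branch_kind = model$branch_kind,
                    vocab = model$vocab, vocab_hash = model$vocab_hash,
                    history = model$history, best_epoch = model$best_epoch)
  } else if (inherits(model, "triage_fused")) {
    manifest <- list(kind = "fused", dropout = model$dropout,
                     rnn_config = unclass(model$rnn_config),
                     cnn_config = unclass(model$cnn_config),
                     vocab_hash = model$vocab_hash)
    payload <- list(type = "fused",
                    params = model$params,   # headless branches + fusion head
                    dropout = model$dropout, rnn_config = model$rnn_config,
                    cnn_config = model$cnn_config, vocab = model$vocab,
                    vocab_hash = model$vocab_hash, seed = model$seed,
                    history = model$history)
  } else stop("save_checkpoint: unsupported model type")
  saveRDS(payload, path)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path previously given to [save_checkpoint()].
#' @return The reconstructed `triage_branch` or `triage_fused`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  x <- readRDS(path)
  if (identical(x$type, "branch")) {
    structure(list(params = x$params, config = x$config,
                   branch_kind = x$branch_kind, vocab = x$vocab,
                   vocab_hash = x$vocab_hash, history = x$history,
                   best_epoch = x$best_epoch), class = "triage_branch")
  } else if (identical(x$type, "fused")) {
    structure(list(params = x$params, aux = NULL, dropout = x$dropout,
                   rnn_config = x$rnn_config, cnn_config = x$cnn_config,
                   vocab = x$vocab, vocab_hash = x$vocab_hash, seed = x$seed,
                   history = x$history), class = "triage_fused")
  } else stop("load_checkpoint: unrecognized checkpoint payload")
}
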