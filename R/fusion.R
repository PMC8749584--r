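# Model synthesis: delete both branch softmax heads, concatenate the two
# 64-unit penultimate layers into a 128-d joint representation, apply
# dropout, and attach a fresh 2-class softmax head. During fine-tuning all
# carried-over branch weights remain trainable; lightweight auxiliary
# readout heads (initialized from the deleted branch heads) can supply the
# per-branch cross-entropy terms of the joint loss and are dropped at
# export.

#' Fuse a trained recurrent and convolutional branch
#'
#' Both branches must have been trained against the same vocabulary and
#' sequence length (checked via the vocabulary hash stored in each model).
#' The fused parameter set contains no branch output-layer parameters; the
#' original branch heads are kept aside only as auxiliary readouts for the
#' fine-tuning loss.
#'
#' @param rnn A `triage_branch` of kind `"rnn"`.
#' @param cnn A `triage_branch` of kind `"cnn"`.
#' @param dropout Dropout rate applied to the 128-d joint representation
#'   during fine-tuning (default 0.5).
#' @param seed Seed for the new head's initialization.
#' @return An object of class `triage_fused`.
#' @export
fuse <- function(rnn, cnn, dropout = 0.5, seed = 1L) {
  stopifnot(inherits(rnn, "triage_branch"), inherits(cnn, "triage_branch"))
  if (rnn$branch_kind != "rnn" || cnn$branch_kind != "cnn")
    stop("fuse: arguments must be an rnn branch and a cnn branch, in that order")
  if (!identical(rnn$vocab_hash, cnn$vocab_hash))
    stop("fuse: branches were trained on different vocabularies (hash mismatch)")
  if (!identical(rnn$config$max_len, cnn$config$max_len))
    stop("fuse: branches use different max_len")
  if (dropout < 0 || dropout >= 1) stop("fuse: dropout must be in [0, 1)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  drop_head <- function(p) p[setdiff(names(p), c("head_W", "head_b"))]
  d_joint <- rnn$config$dense_units + cnn$config$dense_units
  params <- c(prefix_names(drop_head(rnn$params), "rnn."),
              prefix_names(drop_head(cnn$params), "cnn."))
  params$fuse_W <- glorot(d_joint, 2L)
  params$fuse_b <- numeric(2L)
  aux <- list(rnn.head_W = rnn$params$head_W, rnn.head_b = rnn$params$head_b,
              cnn.head_W = cnn$params$head_W, cnn.head_b = cnn$params$head_b)
  structure(list(params = params, aux = aux, dropout = dropout,
                 rnn_config = rnn$config, cnn_config = cnn$config,
                 vocab = rnn$vocab, vocab_hash = rnn$vocab_hash,
                 seed = as.integer(seed), history = NULL),
            class = "triage_fused")
}

#' @export
print.triage_fused <- function(x, ...) {
  cat(sprintf("triage_fused: 128-d joint representation, dropout %.2f, vocab %s\n",
              x$dropout, x$vocab_hash))
  invisible(x)
}

# batched fused forward; dropout active only when training = TRUE
fused_forward_batch <- function(model, ids, lengths, training = FALSE,
                                want_grad = FALSE) {
  rnn_p <- strip_prefix(model$params, "rnn.")
  cnn_p <- strip_prefix(model$params, "cnn.")
  fr <- rnn_forward_batch(rnn_p, model$rnn_config, ids, lengths, want_grad)
  fc <- cnn_forward_batch(cnn_p, model$cnn_config, ids, lengths, want_grad)
  z <- cbind(fr$penultimate, fc$penultimate)
  dropmask <- NULL
  if (training && model$dropout > 0) {
    keep <- 1 - model$dropout
    dropmask <- matrix(rbinom(length(z), 1L, keep), nrow(z), ncol(z)) / keep
    z_used <- z * dropmask
  } else {
    z_used <- z
  }
  logits <- dense_forward(z_used, model$params$fuse_W, model$params$fuse_b)
  probs <- softmax_rows(logits)
  out <- list(probs = probs, joint = z, rnn = fr, cnn = fc)
  if (want_grad) out$cache <- list(z_used = z_used, dropmask = dropmask)
  out
}

fused_backward_batch <- function(model, fw, labels, aux_heads = NULL,
                                 loss_mode = c("aux", "fused-only")) {
  loss_mode <- match.arg(loss_mode)
  rnn_p <- strip_prefix(model$params, "rnn.")
  cnn_p <- strip_prefix(model$params, "cnn.")
  dlog_f <- softmax_ce_dlogits(fw$probs, labels)
  hb <- dense_backward(fw$cache$z_used, model$params$fuse_W, dlog_f)
  dz <- hb$dx
  if (!is.null(fw$cache$dropmask)) dz <- dz * fw$cache$dropmask
  du <- model$rnn_config$dense_units
  dpen_r <- dz[, seq_len(du), drop = FALSE]
  dpen_c <- dz[, du + seq_len(model$cnn_config$dense_units), drop = FALSE]
  aux_grads <- NULL
  dlog_r <- dlog_c <- NULL
  if (loss_mode == "aux") {
    pr <- softmax_rows(dense_forward(fw$rnn$penultimate, aux_heads$rnn.head_W,
                                     aux_heads$rnn.head_b))
    pc <- softmax_rows(dense_forward(fw$cnn$penultimate, aux_heads$cnn.head_W,
                                     aux_heads$cnn.head_b))
    dlr <- softmax_ce_dlogits(pr, labels)
    dlc <- softmax_ce_dlogits(pc, labels)
    rb <- dense_backward(fw$rnn$penultimate, aux_heads$rnn.head_W, dlr)
    cb <- dense_backward(fw$cnn$penultimate, aux_heads$cnn.head_W, dlc)
    aux_grads <- list(rnn.head_W = rb$dW, rnn.head_b = rb$db,
                      cnn.head_W = cb$dW, cnn.head_b = cb$db)
    dpen_r <- dpen_r + rb$dx
    dpen_c <- dpen_c + cb$dx
  }
  gr <- rnn_backward_batch(rnn_p, model$rnn_config, fw$rnn, dlogits = NULL,
                           dpen = dpen_r)
  gc_ <- cnn_backward_batch(cnn_p, model$cnn_config, fw$cnn, dlogits = NULL,
                            dpen = dpen_c)
  grads <- c(prefix_names(gr, "rnn."), prefix_names(gc_, "cnn."))
  grads$fuse_W <- hb$dW
  grads$fuse_b <- hb$db
  list(grads = grads, aux_grads = aux_grads)
}

#' Fused-model forward pass on one encoded visit
#'
#' Inference is deterministic: dropout is applied only when
#' `training = TRUE`.
#'
#' @param encoded An encoding from [encode()].
#' @param model A `triage_fused`.
#' @param training Whether dropout is active.
#' @return List with `probabilities` (2-simplex; second entry is the
#'   admission-class probability) and `joint` (the 128-d representation).
#' @export
fused_forward <- function(encoded, model, training = FALSE) {
  stopifnot(inherits(model, "triage_fused"))
  fw <- fused_forward_batch(model, matrix(encoded$ids, nrow = 1L),
                            encoded$true_length, training = training)
  list(probabilities = as.numeric(fw$probs), joint = as.numeric(fw$joint))
}

#' Joint training loss
#'
#' The reported loss decomposes as `l_total = l_cnn + l_rnn`. In pretrain
#' mode the two components are each branch's own cross-entropy against the
#' labels; in finetune mode they come from the auxiliary readout heads on
#' the branch penultimate layers, and the fused head's cross-entropy is
#' carried separately (it is additionally minimized but is not part of
#' `l_total`).
#'
#' @param labels Integer 0/1 labels.
#' @param cnn_probs,rnn_probs Per-branch 2-column probability matrices.
#' @param fused_probs Optional fused-head probability matrix (finetune mode).
#' @param mode `"pretrain"` or `"finetune"`.
#' @return An object of class `triage_loss`: `l_total`, `l_cnn`, `l_rnn`,
#'   and `l_fused` (`NA` in pretrain mode).
#' @export
joint_loss <- function(labels, cnn_probs, rnn_probs, fused_probs = NULL,
                       mode = c("pretrain", "finetune")) {
  mode <- match.arg(mode)
  l_cnn <- cross_entropy(cnn_probs, labels)
  l_rnn <- cross_entropy(rnn_probs, labels)
  l_fused <- if (mode == "finetune") {
    if (is.null(fused_probs)) stop("finetune mode requires fused_probs")
    cross_entropy(fused_probs, labels)
  } else NA_real_
  structure(list(l_total = l_cnn + l_rnn, l_cnn = l_cnn, l_rnn = l_rnn,
                 l_fused = l_fused, mode = mode),
            class = "triage_loss")
}

#' @export
print.triage_loss <- function(x, ...) {
  cat(sprintf("triage_loss (%s): l_total %.4f = l_cnn %.4f + l_rnn %.4f%s\n",
              x$mode, x$l_total, x$l_cnn, x$l_rnn,
              if (is.finite(x$l_fused)) sprintf(" (fused head %.4f)", x$l_fused) else ""))
  invisible(x)
}
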