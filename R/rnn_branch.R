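# The long-sentence branch: embedding lookup -> bidirectional GRU ->
# stacked feed-forward attention pooling -> 64-unit ELU dense -> softmax
# head. Forward and analytic backward are implemented over time-major
# flattened batches; the GRU time loop runs in compiled code.

init_rnn_params <- function(vocab_size, config, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  w <- config$emb_dim; H <- config$hidden; D <- 2L * H
  p <- list(emb = {
    E <- matrix(runif(vocab_size * w, -0.05, 0.05), vocab_size, w)
    E[1L, ] <- 0
    E
  })
  for (dir in c("f", "b")) {
    p[[paste0("gru_W", dir)]] <- glorot(w, 3L * H)
    b <- numeric(3L * H)
    # update-gate bias +1 biases the cell toward carrying state, which lets
    # gradients reach distant positions early in training (the recurrent
    # analogue of the LSTM forget-gate-bias-1 convention)
    b[(H + 1L):(2L * H)] <- 1
    p[[paste0("gru_b", dir)]] <- b
    p[[paste0("gru_U", dir)]] <- glorot(H, 3L * H)
  }
  p <- c(p, init_attention(config$att_layers, D, config$att_hidden))
  p$dense_W <- glorot(D, config$dense_units)
  p$dense_b <- numeric(config$dense_units)
  p$head_W <- glorot(config$dense_units, 2L)
  p$head_b <- numeric(2L)
  p
}

# row permutation that reverses time for a time-major (B*T) x . matrix
time_reverse_rows <- function(B, T) {
  rep((T:1) - 1L, each = B) * B + rep(seq_len(B), T)
}

batch_mask <- function(lengths, T) {
  outer(lengths, seq_len(T), ">=") * 1
}

#' Run a bidirectional GRU over a token matrix
#'
#' Standard GRU recurrences run left-to-right and right-to-left over the
#' live (non-masked) positions; the output at position t concatenates the
#' forward and backward states, and masked positions output zeros.
#'
#' @param x `h x w` token matrix (one sequence), e.g. from [lookup()].
#' @param params Named list with `gru_Wf`, `gru_bf`, `gru_Uf` and the `b`
#'   counterparts (as inside an rnn branch model).
#' @param mask Logical vector of live positions (default: all).
#' @return `h x 2H` matrix of concatenated hidden states.
#' @export
bigru_encode <- function(x, params, mask = rep(TRUE, nrow(x))) {
  if (!any(mask)) stop("bigru_encode: input is entirely padding")
  Tn <- nrow(x)
  fw <- bigru_forward(params, x, matrix(as.numeric(mask), 1L, Tn), B = 1L, T = Tn)
  fw$H
}

# internal batched biGRU; Xf (B*T) x w. Returns H ((B*T) x 2H) + caches.
bigru_forward <- function(params, Xf, mask, B, T) {
  Hn <- ncol(params$gru_Uf)  / 3L
  Xp_f <- dense_forward(Xf, params$gru_Wf, params$gru_bf)
  fwd <- .gru_forward_cpp(Xp_f, params$gru_Uf, mask, B, T, Hn)
  rev <- time_reverse_rows(B, T)
  mask_rev <- mask[, T:1, drop = FALSE]
  Xp_b <- dense_forward(Xf, params$gru_Wb, params$gru_bb)
  bwd <- .gru_forward_cpp(Xp_b[rev, , drop = FALSE], params$gru_Ub, mask_rev, B, T, Hn)
  out_b <- bwd$out[rev, , drop = FALSE]
  list(H = cbind(fwd$out, out_b), fwd = fwd, bwd = bwd, Xp_f = Xp_f,
       rev = rev, mask_rev = mask_rev)
}

bigru_backward <- function(params, fw, Xf, dH, mask, B, T) {
  Hn <- ncol(params$gru_Uf) / 3L
  dOf <- dH[, seq_len(Hn), drop = FALSE]
  dOb <- dH[, Hn + seq_len(Hn), drop = FALSE]
  gf <- .gru_backward_cpp(dOf, fw$fwd$hprev, fw$fwd$r, fw$fwd$z, fw$fwd$n,
                          fw$fwd$hun, params$gru_Uf, mask, B, T, Hn)
  rev <- fw$rev
  gb <- .gru_backward_cpp(dOb[rev, , drop = FALSE], fw$bwd$hprev, fw$bwd$r,
                          fw$bwd$z, fw$bwd$n, fw$bwd$hun, params$gru_Ub,
                          fw$mask_rev, B, T, Hn)
  dXp_b <- gb$dXp[rev, , drop = FALSE]
  dXf <- gf$dXp %*% t(params$gru_Wf) + dXp_b %*% t(params$gru_Wb)
  grads <- list(
    gru_Wf = crossprod(Xf, gf$dXp), gru_bf = colSums(gf$dXp), gru_Uf = gf$dU,
    gru_Wb = crossprod(Xf, dXp_b), gru_bb = colSums(dXp_b), gru_Ub = gb$dU)
  list(dXf = dXf, grads = grads)
}

# embedding gradient: scatter-add flat rows back onto table rows; PAD frozen
embedding_grad <- function(dXf, idx, vocab_size, w) {
  agg <- rowsum(dXf, group = idx)
  dE <- matrix(0, vocab_size, w)
  dE[as.integer(rownames(agg)), ] <- agg
  dE[1L, ] <- 0
  attr(dE, "freeze_rows") <- 1L
  dE
}

# Full branch forward over a batch. ids: B x Tfull (0-based). Trims the
# batch to its longest live sequence (outputs are unchanged by trailing
# padding). Returns probs, penultimate, and caches when want_grad.
rnn_forward_batch <- function(params, config, ids, lengths, want_grad = FALSE) {
  B <- nrow(ids)
  T <- max(1L, min(ncol(ids), max(lengths)))
  ids <- ids[, seq_len(T), drop = FALSE]
  if (any(lengths < 1L)) stop("rnn branch: encountered an all-padding input")
  mask <- batch_mask(pmin(lengths, T), T)
  idx <- as.vector(ids) + 1L
  Xf <- params$emb[idx, , drop = FALSE]
  enc <- bigru_forward(params, Xf, mask, B, T)
  att <- attention_forward(params, config$att_layers, enc$H, mask, B, T)
  pen_pre <- dense_forward(att$context, params$dense_W, params$dense_b)
  pen <- elu(pen_pre)
  probs <- if (!is.null(params$head_W))       # headless after fusion
    softmax_rows(dense_forward(pen, params$head_W, params$head_b)) else NULL
  out <- list(probs = probs, penultimate = pen, attention = att$weights)
  if (want_grad)
    out$cache <- list(Xf = Xf, idx = idx, enc = enc, att = att,
                      pen_pre = pen_pre, pen = pen, mask = mask, B = B, T = T)
  out
}

# Backward from (optional) head-logit grad and/or extra penultimate grad.
rnn_backward_batch <- function(params, config, fw, dlogits = NULL, dpen = NULL) {
  cc <- fw$cache
  grads <- list()
  dpen_total <- if (is.null(dpen)) matrix(0, cc$B, config$dense_units) else dpen
  if (!is.null(dlogits)) {
    hb <- dense_backward(fw$penultimate, params$head_W, dlogits)
    grads$head_W <- hb$dW; grads$head_b <- hb$db
    dpen_total <- dpen_total + hb$dx
  }
  dpen_pre <- dpen_total * elu_grad(cc$pen_pre)
  db <- dense_backward(cc$att$context, params$dense_W, dpen_pre)
  grads$dense_W <- db$dW; grads$dense_b <- db$db
  ab <- attention_backward(params, config$att_layers, cc$att, db$dx, cc$mask,
                           cc$B, cc$T)
  grads <- c(grads, ab$grads)
  gb <- bigru_backward(params, cc$enc, cc$Xf, ab$dH, cc$mask, cc$B, cc$T)
  grads <- c(grads, gb$grads)
  grads$emb <- embedding_grad(gb$dXf, cc$idx, nrow(params$emb), ncol(params$emb))
  grads
}

#' Forward pass of the recurrent branch on one encoded visit
#'
#' @param encoded An encoding from [encode()].
#' @param model A `triage_branch` with `branch_kind == "rnn"`.
#' @return List with `penultimate` (length-64 vector), `probabilities`
#'   (2-vector on the simplex: P(negative), P(positive)), and `attention`
#'   (per-layer weight vectors).
#' @export
rnn_forward <- function(encoded, model) {
  stopifnot(inherits(model, "triage_branch"), model$branch_kind == "rnn")
  fw <- rnn_forward_batch(model$params, model$config,
                          matrix(encoded$ids, nrow = 1L), encoded$true_length)
  list(penultimate = as.numeric(fw$penultimate),
       probabilities = as.numeric(fw$probs),
       attention = lapply(fw$attention, as.numeric))
}
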