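# The short-sentence branch: three pyramid convolution stacks (kernel sizes
# 3/4/5, stride 1) over the stacked word vectors, each built from
# pre-activation residual blocks (two same-length convolutions with an
# identity shortcut) followed by window-3 stride-2 max pooling that halves
# the sequence (ceiling), then per-kernel feed-forward attention pooling of
# the surviving "keyword vectors", concatenation of the three contexts,
# dense-64 (ELU) and a softmax head. Padding rows are zeroed after every
# convolution and replaced by a large negative sentinel before max pooling
# so they can never win a pooling window.

POOL_SENTINEL <- -1e30

block_rows <- function(ts, B) rep((ts - 1L) * B, each = B) + rep(seq_len(B), length(ts))

# same-length 1-d convolution over time-major flat rows; W is (k*Cin) x Cout
# with offset j occupying row block ((j-1)*Cin+1):(j*Cin). The k shifted
# views of the input are gathered into one (B*T) x (k*Cin) matrix so that
# each layer costs a single BLAS product in both directions (im2col).
conv1d_fw <- function(Xf, W, b, k, B, T, mvec) {
  Xc <- .conv_unfold_cpp(Xf, k, B, T)
  Y <- Xc %*% W
  list(Y = (Y + rep(b, each = nrow(Y))) * mvec, Xc = Xc)
}

conv1d_bw <- function(dY, Xc, W, k, B, T, mvec) {
  dY <- dY * mvec
  dXc <- dY %*% t(W)
  list(dX = .conv_fold_cpp(dXc, k, B, T, ncol(Xc) / k),
       dW = crossprod(Xc, dY), db = colSums(dY))
}

# window-3 stride-2 max pooling; output length ceiling(T/2); masked or
# out-of-range inputs enter as the sentinel and all-dead outputs emit 0
maxpool_fw <- function(Uf, B, T, mask) {
  C <- ncol(Uf)
  Tout <- as.integer(ceiling(T / 2))
  mflat <- as.vector(mask)
  cand <- vector("list", 3L)
  mask_out <- matrix(0, B, Tout)
  for (o in 0:2) {
    M <- matrix(POOL_SENTINEL, B * Tout, C)
    pv <- which(2L * seq_len(Tout) - 1L + o <= T)
    if (length(pv)) {
      in_rows <- block_rows(2L * pv - 1L + o, B)
      out_rows <- block_rows(pv, B)
      M[out_rows, ] <- Uf[in_rows, , drop = FALSE]
      dead <- out_rows[mflat[in_rows] == 0]
      if (length(dead)) M[dead, ] <- POOL_SENTINEL
      mask_out[, pv] <- pmax(mask_out[, pv, drop = FALSE],
                             mask[, 2L * pv - 1L + o, drop = FALSE])
    }
    cand[[o + 1L]] <- M
  }
  val <- pmax(cand[[1]], cand[[2]], cand[[3]])
  w1 <- cand[[1]] == val
  w2 <- !w1 & cand[[2]] == val
  w3 <- !(w1 | w2)
  out <- val * as.vector(mask_out)
  list(out = out, mask_out = mask_out, Tout = Tout, Tin = T,
       winners = list(w1, w2, w3))
}

maxpool_bw <- function(dOut, pc, B, C) {
  dOut <- dOut * as.vector(pc$mask_out)
  dU <- matrix(0, B * pc$Tin, C)
  for (o in 0:2) {
    pv <- which(2L * seq_len(pc$Tout) - 1L + o <= pc$Tin)
    if (!length(pv)) next
    in_rows <- block_rows(2L * pv - 1L + o, B)
    out_rows <- block_rows(pv, B)
    dU[in_rows, ] <- dU[in_rows, ] +
      dOut[out_rows, , drop = FALSE] * pc$winners[[o + 1L]][out_rows, , drop = FALSE]
  }
  dU
}

# one full pyramid stack for kernel size k; p holds unprefixed params
# (in_W/in_b, blk{b}_c1_W/..., see init_cnn_params)
pyramid_fw <- function(p, k, blocks, Xf, B, T, mask, want_grad = FALSE) {
  if (T < k)
    stop(sprintf("pyramid conv: sequence length %d < kernel %d; increase max_len or use a smaller kernel", T, k))
  mvec <- as.vector(mask)
  cv0 <- conv1d_fw(Xf, p$in_W, p$in_b, k, B, T, mvec)
  U <- cv0$Y
  in_Xc <- if (want_grad) cv0$Xc else NULL
  caches <- if (want_grad) vector("list", blocks) else NULL
  for (b in seq_len(blocks)) {
    a1 <- relu(U)
    cv1 <- conv1d_fw(a1, p[[paste0("blk", b, "_c1_W")]], p[[paste0("blk", b, "_c1_b")]],
                     k, B, T, mvec)
    a2 <- relu(cv1$Y)
    cv2 <- conv1d_fw(a2, p[[paste0("blk", b, "_c2_W")]], p[[paste0("blk", b, "_c2_b")]],
                     k, B, T, mvec)
    V <- U + cv2$Y
    pool <- maxpool_fw(V, B, T, mask)
    if (want_grad)
      caches[[b]] <- list(U = U, c1 = cv1$Y, Xc1 = cv1$Xc, Xc2 = cv2$Xc,
                          pool = pool, T = T, mask = mask, mvec = mvec)
    U <- pool$out
    mask <- pool$mask_out
    T <- pool$Tout
    mvec <- as.vector(mask)
  }
  list(K = U, mask = mask, T = T, caches = caches, in_Xc = in_Xc)
}

pyramid_bw <- function(p, k, blocks, fw, dK, Xf, B, mask0, T0) {
  grads <- list()
  dU <- dK
  for (b in rev(seq_len(blocks))) {
    cc <- fw$caches[[b]]
    dV <- maxpool_bw(dU, cc$pool, B, ncol(dU))
    bw2 <- conv1d_bw(dV, cc$Xc2, p[[paste0("blk", b, "_c2_W")]], k, B, cc$T, cc$mvec)
    grads[[paste0("blk", b, "_c2_W")]] <- bw2$dW
    grads[[paste0("blk", b, "_c2_b")]] <- bw2$db
    dc1 <- bw2$dX * (cc$c1 > 0)
    bw1 <- conv1d_bw(dc1, cc$Xc1, p[[paste0("blk", b, "_c1_W")]], k, B, cc$T, cc$mvec)
    grads[[paste0("blk", b, "_c1_W")]] <- bw1$dW
    grads[[paste0("blk", b, "_c1_b")]] <- bw1$db
    dU <- dV + bw1$dX * (cc$U > 0)   # shortcut + pre-activation path
  }
  bwi <- conv1d_bw(dU, fw$in_Xc, p$in_W, k, B, T0, as.vector(mask0))
  grads$in_W <- bwi$dW
  grads$in_b <- bwi$db
  list(dXf = bwi$dX, grads = grads)
}

init_cnn_params <- function(vocab_size, config, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  w <- config$emb_dim; C <- config$channels
  p <- list(emb = {
    E <- matrix(runif(vocab_size * w, -0.05, 0.05), vocab_size, w)
    E[1L, ] <- 0
    E
  })
  for (k in config$kernels) {
    pk <- list(in_W = glorot(k * w, C), in_b = numeric(C))
    for (b in seq_len(config$blocks)) {
      pk[[paste0("blk", b, "_c1_W")]] <- glorot(k * C, C)
      pk[[paste0("blk", b, "_c1_b")]] <- numeric(C)
      pk[[paste0("blk", b, "_c2_W")]] <- glorot(k * C, C)
      pk[[paste0("blk", b, "_c2_b")]] <- numeric(C)
    }
    pk <- c(pk, init_attention(1L, C, config$att_hidden))
    p <- c(p, prefix_names(pk, sprintf("k%d_", k)))
  }
  p$dense_W <- glorot(length(config$kernels) * C, config$dense_units)
  p$dense_b <- numeric(config$dense_units)
  p$head_W <- glorot(config$dense_units, 2L)
  p$head_b <- numeric(2L)
  p
}

cnn_forward_batch <- function(params, config, ids, lengths, want_grad = FALSE) {
  B <- nrow(ids)
  T <- max(1L, min(ncol(ids), max(lengths)))
  ids <- ids[, seq_len(T), drop = FALSE]
  if (any(lengths < 1L)) stop("cnn branch: encountered an all-padding input")
  mask <- batch_mask(pmin(lengths, T), T)
  idx <- as.vector(ids) + 1L
  Xf <- params$emb[idx, , drop = FALSE]
  Xf <- Xf * as.vector(mask)   # defensive: padding rows stay zero
  ctxs <- list(); pyrs <- list(); atts <- list()
  for (k in config$kernels) {
    pk <- strip_prefix(params, sprintf("k%d_", k))
    pyr <- pyramid_fw(pk, k, config$blocks, Xf, B, T, mask, want_grad)
    att <- attention_forward(pk, 1L, pyr$K, pyr$mask, B, pyr$T)
    ctxs[[as.character(k)]] <- att$context
    pyrs[[as.character(k)]] <- pyr
    atts[[as.character(k)]] <- att
  }
  ctx <- do.call(cbind, unname(ctxs))        # B x (3*C)
  pen_pre <- dense_forward(ctx, params$dense_W, params$dense_b)
  pen <- elu(pen_pre)
  probs <- if (!is.null(params$head_W))       # headless after fusion
    softmax_rows(dense_forward(pen, params$head_W, params$head_b)) else NULL
  out <- list(probs = probs, penultimate = pen,
              attention = lapply(atts, function(a) a$weights[[1]]))
  if (want_grad)
    out$cache <- list(Xf = Xf, idx = idx, pyrs = pyrs, atts = atts, ctx = ctx,
                      pen_pre = pen_pre, mask = mask, B = B, T = T)
  out
}

cnn_backward_batch <- function(params, config, fw, dlogits = NULL, dpen = NULL) {
  cc <- fw$cache
  grads <- list()
  dpen_total <- if (is.null(dpen)) matrix(0, cc$B, config$dense_units) else dpen
  if (!is.null(dlogits)) {
    hb <- dense_backward(fw$penultimate, params$head_W, dlogits)
    grads$head_W <- hb$dW; grads$head_b <- hb$db
    dpen_total <- dpen_total + hb$dx
  }
  dpen_pre <- dpen_total * elu_grad(cc$pen_pre)
  db <- dense_backward(cc$ctx, params$dense_W, dpen_pre)
  grads$dense_W <- db$dW; grads$dense_b <- db$db
  C <- config$channels
  dXf <- matrix(0, nrow(cc$Xf), ncol(cc$Xf))
  for (i in seq_along(config$kernels)) {
    k <- config$kernels[i]
    key <- as.character(k)
    pk <- strip_prefix(params, sprintf("k%d_", k))
    dctx_k <- db$dx[, ((i - 1L) * C + 1L):(i * C), drop = FALSE]
    pyr <- cc$pyrs[[key]]
    ab <- attention_backward(pk, 1L, cc$atts[[key]], dctx_k, pyr$mask, cc$B, pyr$T)
    pb <- pyramid_bw(pk, k, config$blocks, pyr, ab$dH, cc$Xf, cc$B, cc$mask, cc$T)
    gk <- c(ab$grads, pb$grads)
    grads <- c(grads, prefix_names(gk, sprintf("k%d_", k)))
    dXf <- dXf + pb$dXf
  }
  dXf <- dXf * as.vector(cc$mask)
  grads$emb <- embedding_grad(dXf, cc$idx, nrow(params$emb), ncol(params$emb))
  grads
}

#' Run one pyramid convolution stack over a token matrix
#'
#' Region convolution at kernel size `k` followed by pre-activation residual
#' blocks, each ending in window-3 stride-2 max pooling, so `blocks`
#' applications leave `ceiling(h / 2^blocks)` keyword-vector positions.
#'
#' @param x `h x w` token matrix (one sequence).
#' @param params Unprefixed pyramid parameter list (`in_W`, `in_b`,
#'   `blk1_c1_W`, ...), e.g. one kernel's slice of a cnn branch model.
#' @param k Kernel size.
#' @param blocks Number of pyramid blocks.
#' @param mask Logical live-position vector (default: all live).
#' @return List with `keywords` (`ceiling(h/2^blocks) x C` matrix) and
#'   `mask` (live keyword positions).
#' @export
pyramid_conv <- function(x, params, k, blocks, mask = rep(TRUE, nrow(x))) {
  Tn <- nrow(x)
  fw <- pyramid_fw(params, k, blocks, x, B = 1L, T = Tn,
                   mask = matrix(as.numeric(mask), 1L, Tn))
  list(keywords = fw$K, mask = as.logical(fw$mask))
}

#' Forward pass of the convolutional branch on one encoded visit
#'
#' @param encoded An encoding from [encode()].
#' @param model A `triage_branch` with `branch_kind == "cnn"`.
#' @return List with `penultimate` (length-64 vector), `probabilities`
#'   (2-simplex), and `attention` (per-kernel weight vectors over the
#'   surviving keyword positions).
#' @export
cnn_forward <- function(encoded, model) {
  stopifnot(inherits(model, "triage_branch"), model$branch_kind == "cnn")
  fw <- cnn_forward_batch(model$params, model$config,
                          matrix(encoded$ids, nrow = 1L), encoded$true_length)
  list(penultimate = as.numeric(fw$penultimate),
       probabilities = as.numeric(fw$probs),
       attention = lapply(fw$attention, as.numeric))
}
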