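# Shared numerical machinery for the hand-authored networks: activations,
# Glorot initialization, dense layers, stable softmax / cross-entropy, and
# the Adam optimizer over flat named parameter lists. All gradients in this
# package are analytic; the test suite checks them against central finite
# differences on small instances.

elu <- function(x) {
  if (is.matrix(x)) return(.elu_cpp(x))
  i <- x < 0
  x[i] <- expm1(x[i])
  x
}
elu_grad <- function(x) {
  if (is.matrix(x)) return(.elu_grad_cpp(x))
  g <- x
  i <- x < 0
  g[!i] <- 1
  g[i] <- exp(x[i])
  g
}
relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Stable row-wise softmax.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Glorot-uniform weight matrix; draws consume the current RNG stream so that
# model initialization is reproducible from a single seed.
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

dense_forward <- function(x, W, b) {
  y <- x %*% W
  y + rep(b, each = nrow(y))
}

# returns list(dx, dW, db) for y = xW + b given upstream dy
dense_backward <- function(x, W, dy) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

# Mean cross-entropy of 2-class probability rows against 0/1 labels.
cross_entropy <- function(probs, labels) {
  stopifnot(ncol(probs) == 2L, nrow(probs) == length(labels))
  if (any(probs < -1e-6) || any(abs(rowSums(probs) - 1) > 1e-4))
    stop("cross_entropy: predictions must be probability simplex rows")
  p <- probs[cbind(seq_along(labels), labels + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

# Gradient of mean softmax cross-entropy w.r.t. the logits.
softmax_ce_dlogits <- function(probs, labels) {
  d <- probs
  d[cbind(seq_along(labels), labels + 1L)] <-
    d[cbind(seq_along(labels), labels + 1L)] - 1
  d / length(labels)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam step over a flat named parameter list; `freeze` names parameters
# (or rows, via attr(grad, "freeze_rows")) excluded from the update.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, freeze = character()) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% freeze) next
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    fr <- attr(g, "freeze_rows")
    if (!is.null(fr)) step[fr, ] <- 0
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

# Global-norm gradient clipping (stabilizes the recurrent branch early in
# training; a no-op once gradients are moderate).
clip_grads <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (total > max_norm) {
    scale <- max_norm / (total + 1e-12)
    grads <- lapply(grads, function(g) {
      fr <- attr(g, "freeze_rows")
      g <- g * scale
      attr(g, "freeze_rows") <- fr
      g
    })
  }
  grads
}

# elementwise sum of two grad lists (names union)
accumulate_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

# prefix every name in a parameter/grad list
prefix_names <- function(lst, prefix) {
  names(lst) <- paste0(prefix, names(lst))
  lst
}

strip_prefix <- function(lst, prefix) {
  sel <- startsWith(names(lst), prefix)
  out <- lst[sel]
  names(out) <- substring(names(out), nchar(prefix) + 1L)
  out
}
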