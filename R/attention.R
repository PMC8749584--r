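# Feed-forward attention pooling, shared by both branches. Each layer scores
# every live position with a two-dense-sublayer network (ELU hidden, width
# `att_hidden`, scalar output), normalizes the scores with a masked softmax,
# and pools. In a stack of L layers the first L-1 layers re-weight the
# sequence position-wise -- position t is scaled by (T_live * alpha_t), so a
# uniform attention layer is exactly the identity -- and the final layer
# pools to the context vector sum_t alpha_t v_t. Masked positions get weight
# exactly 0, so each layer's weights form a probability distribution over
# live positions.

# parameter names for attention layer `l` with input width D:
#   att{l}_A1 (D x hidden), att{l}_b1, att{l}_a2 (hidden x 1), att{l}_b2
init_attention <- function(n_layers, d_in, hidden) {
  p <- list()
  for (l in seq_len(n_layers)) {
    p[[sprintf("att%d_A1", l)]] <- glorot(d_in, hidden)
    p[[sprintf("att%d_b1", l)]] <- numeric(hidden)
    p[[sprintf("att%d_a2", l)]] <- glorot(hidden, 1L)
    p[[sprintf("att%d_b2", l)]] <- 0
  }
  p
}

# Hf: (B*T) x D time-major; mask: B x T (0/1). Returns context (B x D),
# per-layer weights (list of B x T), cache for backward.
attention_forward <- function(params, n_layers, Hf, mask, B, T) {
  tlive <- rowSums(mask)
  if (any(tlive < 1)) stop("attention: every sequence needs at least one live position")
  grp <- rep(seq_len(B), T)
  input <- Hf
  caches <- vector("list", n_layers)
  weights <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    A1 <- params[[sprintf("att%d_A1", l)]]
    b1 <- params[[sprintf("att%d_b1", l)]]
    a2 <- params[[sprintf("att%d_a2", l)]]
    b2 <- params[[sprintf("att%d_b2", l)]]
    S_pre <- dense_forward(input, A1, b1)
    S <- elu(S_pre)
    logits <- matrix(S %*% a2 + b2, B, T)
    logits[mask == 0] <- -Inf
    alpha <- softmax_rows(logits)
    alpha[mask == 0] <- 0
    weights[[l]] <- alpha
    caches[[l]] <- list(input = input, S_pre = S_pre, S = S, alpha = alpha)
    if (l < n_layers) {
      scale <- alpha * tlive           # uniform attention == identity
      input <- input * as.vector(scale)
      caches[[l]]$scale <- scale
    } else {
      context <- rowsum(input * as.vector(alpha), group = grp)
    }
  }
  list(context = context, weights = weights, caches = caches, tlive = tlive)
}

# dcontext: B x D. Returns list(dH = (B*T) x D, grads = named list).
attention_backward <- function(params, n_layers, fw, dcontext, mask, B, T) {
  grads <- list()
  grp_expand <- rep(seq_len(B), T)
  dinput <- NULL
  for (l in rev(seq_len(n_layers))) {
    cc <- fw$caches[[l]]
    alpha <- cc$alpha
    a2 <- params[[sprintf("att%d_a2", l)]]
    A1 <- params[[sprintf("att%d_A1", l)]]
    if (l == n_layers) {
      dC_exp <- dcontext[grp_expand, , drop = FALSE]
      dinput_l <- dC_exp * as.vector(alpha)
      dalpha <- matrix(rowSums(cc$input * dC_exp), B, T)
    } else {
      dV <- dinput                      # upstream grad on this layer's output
      dinput_l <- dV * as.vector(cc$scale)
      dscale <- matrix(rowSums(cc$input * dV), B, T)
      dalpha <- dscale * fw$tlive
    }
    # masked softmax backward (alpha is 0 at masked positions)
    dlogits <- alpha * (dalpha - rowSums(alpha * dalpha))
    dl_f <- matrix(as.vector(dlogits), ncol = 1L)
    dS <- dl_f %*% t(a2)
    grads[[sprintf("att%d_a2", l)]] <- crossprod(cc$S, dl_f)
    grads[[sprintf("att%d_b2", l)]] <- sum(dl_f)
    dS_pre <- dS * elu_grad(cc$S_pre)
    grads[[sprintf("att%d_A1", l)]] <- crossprod(cc$input, dS_pre)
    grads[[sprintf("att%d_b1", l)]] <- colSums(dS_pre)
    dinput_l <- dinput_l + dS_pre %*% t(A1)
    dinput <- dinput_l
  }
  list(dH = dinput, grads = grads)
}

#' Attention-pool a hidden sequence
#'
#' Standalone entry point over one sequence: scores each position with the
#' stacked feed-forward attention and returns the pooled context vector plus
#' every layer's weights for inspection.
#'
#' @param hidden `T x D` matrix of position vectors (e.g. biGRU states).
#' @param params Named attention parameter list (as produced inside a
#'   branch model, names `att1_A1`, ...).
#' @param n_layers Number of stacked attention layers.
#' @param mask Logical/0-1 vector of length `T`; `TRUE` = live position.
#' @return List with `context` (length `D`) and `weights` (list of length-`T`
#'   weight vectors, one per layer; each sums to 1 over live positions).
#' @export
attention_pool <- function(hidden, params, n_layers = 2L,
                           mask = rep(TRUE, nrow(hidden))) {
  stopifnot(nrow(hidden) == length(mask))
  if (!any(mask)) stop("attention: all positions masked")
  Tn <- nrow(hidden)
  fw <- attention_forward(params, n_layers, hidden, matrix(as.numeric(mask), 1L, Tn),
                          B = 1L, T = Tn)
  list(context = as.numeric(fw$context),
       weights = lapply(fw$weights, as.numeric))
}
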