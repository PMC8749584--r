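# Shared fixtures and independent oracles used across test files. All
# fixtures are built in code; nothing is read from disk except the schema
# fixture shipped under inst/extdata.

ns <- asNamespace("edtriage")

# a three-feature schema exercising every feature kind
tiny_schema <- function() {
  feature_schema(list(
    feature_spec("temperature", "continuous", "body temperature",
                 units = "degrees", precision = 1L, range = c(25, 45)),
    feature_spec("pain_scale", "continuous", "pain index",
                 precision = 0L, range = c(0, 10)),
    feature_spec("sex", "binary", "sex", levels = c("female", "male"))
  ), outcome = "admitted")
}

tiny_records <- function() {
  data.frame(visit_id = c("a", "b", "c"),
             temperature = c(36.5, 38.2, 37.0),
             pain_scale = c(5, 2, 9),
             sex = c("female", "male", "female"),
             admitted = c(1L, 0L, 1L),
             stringsAsFactors = FALSE)
}

# small-network config for structural and gradient tests
tiny_config <- function(...) {
  triage_config("fast", emb_dim = 5L, hidden = 4L, channels = 3L,
                blocks = 1L, att_hidden = 6L, dense_units = 7L, ...)
}

# random encoded batch with right-padding (never uses PAD inside a sequence)
random_batch <- function(B, Tn, V, seed = 1L, min_len = 1L) {
  set.seed(seed)
  lengths <- sample(min_len:Tn, B, replace = TRUE)
  ids <- matrix(0L, B, Tn)
  for (b in seq_len(B)) ids[b, seq_len(lengths[b])] <-
      sample(2:(V - 1L), lengths[b], replace = TRUE)
  list(ids = ids, lengths = lengths)
}

# ---- independent oracles ---------------------------------------------------

# exhaustive pairwise concordance AUROC (ties count half)
auroc_pairwise <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# reference single-sequence GRU (same gate conventions, plain R loops)
ref_gru <- function(x, W, b, U, H) {
  Tn <- nrow(x)
  h <- numeric(H)
  out <- matrix(0, Tn, H)
  for (t in seq_len(Tn)) {
    a <- as.numeric(x[t, ] %*% W) + b + as.numeric(h %*% U)
    r <- 1 / (1 + exp(-a[1:H]))
    z <- 1 / (1 + exp(-a[(H + 1):(2 * H)]))
    n <- tanh(as.numeric(x[t, ] %*% W)[(2 * H + 1):(3 * H)] + b[(2 * H + 1):(3 * H)] +
                r * as.numeric(h %*% U)[(2 * H + 1):(3 * H)])
    h <- z * h + (1 - z) * n
    out[t, ] <- h
  }
  out
}

# reference same-length 1-d convolution (naive loops); W is (k*Cin) x Cout
ref_conv1d <- function(x, W, b, k) {
  Tn <- nrow(x); Cin <- ncol(x); Cout <- ncol(W)
  padL <- (k - 1) %/% 2
  out <- matrix(0, Tn, Cout)
  for (t in seq_len(Tn)) {
    acc <- b
    for (j in seq_len(k)) {
      s <- t + j - 1 - padL
      if (s >= 1 && s <= Tn)
        acc <- acc + as.numeric(x[s, ] %*% W[((j - 1) * Cin + 1):(j * Cin), , drop = FALSE])
    }
    out[t, ] <- acc
  }
  out
}

# reference window-3 stride-2 max pooling over rows
ref_maxpool <- function(x) {
  Tn <- nrow(x)
  Tout <- ceiling(Tn / 2)
  out <- matrix(0, Tout, ncol(x))
  for (p in seq_len(Tout)) {
    win <- (2 * p - 1):min(2 * p + 1, Tn)
    out[p, ] <- apply(x[win, , drop = FALSE], 2, max)
  }
  out
}

# central-difference numerical gradient over a named parameter list
num_grad <- function(params, fwd_loss, eps = 1e-5, names_sel = names(params)) {
  g <- list()
  for (nm in names_sel) {
    p <- params[[nm]]
    gp <- p * 0
    for (i in seq_along(p)) {
      pp <- params; pp[[nm]][i] <- p[i] + eps
      lp <- fwd_loss(pp)
      pp[[nm]][i] <- p[i] - eps
      lm <- fwd_loss(pp)
      gp[i] <- (lp - lm) / (2 * eps)
    }
    g[[nm]] <- gp
  }
  g
}

max_rel_err <- function(analytic, numeric) {
  worst <- 0
  for (nm in names(numeric)) {
    a <- as.numeric(analytic[[nm]]); n <- as.numeric(numeric[[nm]])
    worst <- max(worst, max(abs(a - n)) / max(1e-6, max(abs(a)), max(abs(n))))
  }
  worst
}
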