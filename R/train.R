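# Training recipe and evaluation protocol: Adam with the production
# hyperparameters (learning rate 1e-5, batch 64, 60 epochs, biGRU hidden
# 128, kernels 3/4/5 at stride 1, dropout 0.5, 2 attention layers), a
# stratified 72/8/20 split by largest-remainder allocation, per-epoch
# validation-AUROC checkpointing, repeated model selection, and the
# six-metric report.

#' Build a training configuration
#'
#' `profile = "production"` carries the published recipe; `profile = "fast"`
#' is the documented desk-scale profile (embedding 32, hidden 32, 16
#' channels, 2 pyramid blocks, 10 epochs at learning rate 1e-3) used by the
#' test-scale experiments. Any field can be overridden.
#'
#' @param profile `"production"` or `"fast"`.
#' @param ... Named overrides of individual fields.
#' @return An object of class `triage_config`.
#' @export
triage_config <- function(profile = c("production", "fast"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    lr = 1e-5, batch = 64L, epochs = 60L, hidden = 128L,
    kernels = c(3L, 4L, 5L), stride = 1L, dropout = 0.5, att_layers = 2L,
    att_hidden = 64L, max_len = 160L, emb_dim = 300L, channels = 128L,
    blocks = 3L, dense_units = 64L, seed = 1L, min_count = 1L,
    finetune_loss = "aux", finetune_epochs = NULL, clip = 5,
    fractions = c(train = 0.72, validation = 0.08, test = 0.20),
    threshold = 0.5, profile = profile)
  if (profile == "fast") {
    cfg$emb_dim <- 32L; cfg$hidden <- 32L; cfg$channels <- 16L
    cfg$blocks <- 2L; cfg$epochs <- 4L; cfg$lr <- 1e-3
    cfg$finetune_epochs <- 2L
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  if (is.null(cfg$finetune_epochs)) cfg$finetune_epochs <- cfg$epochs
  stopifnot(cfg$lr > 0, cfg$batch >= 1L, cfg$epochs >= 1L,
            abs(sum(cfg$fractions) - 1) < 1e-8)
  structure(cfg, class = "triage_config")
}

#' Stratified train/validation/test split
#'
#' Within each outcome class, indices are shuffled by `seed` and allocated
#' to the three splits by largest-remainder rounding of the class size times
#' the fractions, so each split's prevalence sits within `1/|split|` of the
#' global prevalence.
#'
#' @param labels Integer 0/1 outcome vector.
#' @param fractions Length-3 fractions (train, validation, test) summing
#'   to 1; default `c(0.72, 0.08, 0.20)`.
#' @param seed Integer seed.
#' @return An object of class `triage_split`: index vectors `train`,
#'   `validation`, `test`, plus `fractions` and `seed`.
#' @export
stratified_split <- function(labels, fractions = c(0.72, 0.08, 0.20), seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  if (length(unique(labels)) < 2L)
    stop("stratified_split: both classes must be present")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  parts <- list(train = integer(0), validation = integer(0), test = integer(0))
  for (cls in c(0L, 1L)) {
    idx <- sample(which(labels == cls))
    quota <- length(idx) * fractions
    base <- floor(quota)
    rem <- quota - base
    extra <- length(idx) - sum(base)
    if (extra > 0L)
      base[order(-rem, seq_along(rem))[seq_len(extra)]] <-
        base[order(-rem, seq_along(rem))[seq_len(extra)]] + 1L
    cuts <- cumsum(base)
    parts$train <- c(parts$train, idx[seq_len(base[1])])
    parts$validation <- c(parts$validation,
                          if (base[2] > 0) idx[(cuts[1] + 1L):cuts[2]] else integer(0))
    parts$test <- c(parts$test,
                    if (base[3] > 0) idx[(cuts[2] + 1L):cuts[3]] else integer(0))
  }
  for (nm in names(parts)) {
    part_labels <- labels[parts[[nm]]]
    if (length(part_labels) == 0L || length(unique(part_labels)) < 2L)
      stop(sprintf("stratified_split: the %s split would lack one of the classes", nm))
  }
  structure(list(train = sort(parts$train), validation = sort(parts$validation),
                 test = sort(parts$test), fractions = fractions,
                 seed = as.integer(seed)), class = "triage_split")
}

#' Prepare a cohort for training
#'
#' Filters unusable records, renders them to sentences, splits stratified by
#' the config seed, builds the vocabulary on the training split only, and
#' encodes every record. Deterministic from (cohort, config).
#'
#' @param cohort A `triage_cohort`, or a list with `records` and `schema`.
#' @param config A `triage_config`.
#' @return List with `encoded` (a `triage_encoded` over all kept records),
#'   `labels`, `split`, `vocab`, `schema`, `filter_report`.
#' @export
prepare_triage_data <- function(cohort, config = triage_config("fast")) {
  schema <- cohort$schema
  flt <- filter_records(cohort$records, schema)
  records <- flt$kept
  labels <- as.integer(records[[schema$outcome]])
  sentences <- transform_records(records, schema)
  split <- stratified_split(labels, config$fractions, seed = config$seed)
  vocab <- build_vocab(sentences[split$train], min_count = config$min_count)
  encoded <- suppressMessages(
    encode_records(sentences, vocab, max_len = config$max_len, labels = labels))
  list(encoded = encoded, labels = labels, split = split, vocab = vocab,
       schema = schema, filter_report = flt$report)
}

# minibatch scoring; returns positive-class scores
score_batches <- function(forward_fn, ids, lengths, idx, batch = 256L) {
  out <- numeric(length(idx))
  for (start in seq(1L, length(idx), by = batch)) {
    sel <- idx[start:min(start + batch - 1L, length(idx))]
    fw <- forward_fn(ids[sel, , drop = FALSE], lengths[sel])
    out[start:(start + length(sel) - 1L)] <- fw$probs[, 2L]
  }
  out
}

# Shared epoch loop. step_fn(sel) must run fwd+bwd+update and return the
# batch loss; snapshot_fn()/restore captures the best-validation parameters.
run_epochs <- function(epochs, batch, train_idx, val_score_fn, step_fn,
                       snapshot_fn, verbose) {
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auroc = numeric(0))
  best <- list(auroc = -Inf, snap = NULL, epoch = 0L)
  for (ep in seq_len(epochs)) {
    perm <- sample(train_idx)
    losses <- numeric(0)
    for (start in seq(1L, length(perm), by = batch)) {
      sel <- perm[start:min(start + batch - 1L, length(perm))]
      loss <- step_fn(sel)
      if (!is.finite(loss))
        stop(sprintf("training diverged: non-finite loss at epoch %d, step %d",
                     ep, (start - 1L) %/% batch + 1L))
      losses <- c(losses, loss)
    }
    va <- val_score_fn()
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = mean(losses), val_auroc = va))
    if (verbose)
      message(sprintf("[%s] epoch %2d  train loss %.4f  val AUROC %.4f",
                      format(Sys.time(), "%H:%M:%S"), ep, mean(losses), va))
    if (va > best$auroc) best <- list(auroc = va, snap = snapshot_fn(), epoch = ep)
  }
  list(best = best, history = history)
}

#' Train one branch of the triage engine
#'
#' Minimizes the branch cross-entropy with Adam over minibatches; after
#' each epoch the validation AUROC is logged and the parameters of the best
#' validation epoch are returned.
#'
#' @param kind `"rnn"` or `"cnn"`.
#' @param cohort A `triage_cohort` (or anything [prepare_triage_data()]
#'   accepts).
#' @param config A `triage_config`.
#' @param data Optional pre-built result of [prepare_triage_data()] so that
#'   both branches (and the fused fine-tune) share one split and vocabulary.
#' @param verbose Print per-epoch log lines.
#' @return A `triage_branch`: `params`, `config`, `branch_kind`, `vocab`,
#'   `vocab_hash`, `history` (per-epoch data.frame), `best_epoch`.
#' @export
train_branch <- function(kind = c("rnn", "cnn"), cohort,
                         config = triage_config("fast"), data = NULL,
                         verbose = FALSE) {
  kind <- match.arg(kind)
  if (is.null(data)) data <- prepare_triage_data(cohort, config)
  ids <- data$encoded$ids; lengths <- data$encoded$lengths
  labels <- data$labels
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  params <- if (kind == "rnn") init_rnn_params(data$vocab$size, config, config$seed)
            else init_cnn_params(data$vocab$size, config, config$seed)
  fwd_fn <- if (kind == "rnn") rnn_forward_batch else cnn_forward_batch
  bwd_fn <- if (kind == "rnn") rnn_backward_batch else cnn_backward_batch
  state <- adam_init(params)
  set.seed(config$seed + 1L)   # shuffling / any stochastic layer
  val_idx <- data$split$validation
  res <- run_epochs(
    config$epochs, config$batch, data$split$train,
    val_score_fn = function() {
      sc <- score_batches(function(i, l) fwd_fn(params, config, i, l),
                          ids, lengths, val_idx)
      auroc(labels[val_idx], sc)
    },
    step_fn = function(sel) {
      fw <- fwd_fn(params, config, ids[sel, , drop = FALSE], lengths[sel],
                   want_grad = TRUE)
      y <- labels[sel]
      loss <- cross_entropy(fw$probs, y)
      grads <- bwd_fn(params, config, fw, dlogits = softmax_ce_dlogits(fw$probs, y))
      grads <- clip_grads(grads, config$clip)
      upd <- adam_step(params, grads, state, lr = config$lr)
      params <<- upd$params; state <<- upd$state
      loss
    },
    snapshot_fn = function() params,
    verbose = verbose)
  structure(list(params = res$best$snap, config = config, branch_kind = kind,
                 vocab = data$vocab, vocab_hash = data$encoded$vocab_hash,
                 history = res$history, best_epoch = res$best$epoch),
            class = "triage_branch")
}

#' @export
print.triage_branch <- function(x, ...) {
  cat(sprintf("triage_branch (%s): best epoch %d, val AUROC %.4f\n",
              x$branch_kind, x$best_epoch, max(x$history$val_auroc)))
  invisible(x)
}

#' Fine-tune a fused model
#'
#' All carried-over branch weights remain trainable. With
#' `config$finetune_loss = "aux"` (default) the optimized objective adds the
#' two auxiliary-head cross-entropies (`l_total = l_cnn + l_rnn`) to the
#' fused head's cross-entropy; with `"fused-only"` only the fused
#' cross-entropy is minimized.
#'
#' @param model A `triage_fused` from [fuse()].
#' @param cohort The cohort both branches were trained on.
#' @param config The same `triage_config` used for the branches.
#' @param data Optional shared [prepare_triage_data()] result.
#' @param verbose Print per-epoch log lines.
#' @return The fine-tuned `triage_fused` (best validation epoch), with
#'   `history` attached.
#' @export
finetune_fused <- function(model, cohort, config = triage_config("fast"),
                           data = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "triage_fused"))
  if (is.null(data)) data <- prepare_triage_data(cohort, config)
  if (!identical(data$encoded$vocab_hash, model$vocab_hash))
    stop("finetune_fused: data vocabulary does not match the fused model")
  ids <- data$encoded$ids; lengths <- data$encoded$lengths
  labels <- data$labels
  loss_mode <- match.arg(config$finetune_loss, c("aux", "fused-only"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  params <- model$params
  aux <- model$aux
  state <- adam_init(params)
  aux_state <- adam_init(aux)
  set.seed(model$seed + 1L)
  val_idx <- data$split$validation
  mdl <- model
  res <- run_epochs(
    config$finetune_epochs, config$batch, data$split$train,
    val_score_fn = function() {
      mdl$params <- params
      sc <- score_batches(function(i, l) fused_forward_batch(mdl, i, l),
                          ids, lengths, val_idx)
      auroc(labels[val_idx], sc)
    },
    step_fn = function(sel) {
      mdl$params <- params
      fw <- fused_forward_batch(mdl, ids[sel, , drop = FALSE], lengths[sel],
                                training = TRUE, want_grad = TRUE)
      y <- labels[sel]
      loss <- cross_entropy(fw$probs, y)
      bw <- fused_backward_batch(mdl, fw, y, aux_heads = aux, loss_mode = loss_mode)
      grads <- clip_grads(bw$grads, config$clip)
      upd <- adam_step(params, grads, state, lr = config$lr)
      params <<- upd$params; state <<- upd$state
      if (!is.null(bw$aux_grads)) {
        upd2 <- adam_step(aux, bw$aux_grads, aux_state, lr = config$lr)
        aux <<- upd2$params; aux_state <<- upd2$state
      }
      loss
    },
    snapshot_fn = function() params,
    verbose = verbose)
  model$params <- res$best$snap
  model$history <- res$history
  model$best_epoch <- res$best$epoch
  model
}

#' Train the full triage engine on a cohort
#'
#' Pretrains both branches on the shared split, fuses them, fine-tunes, and
#' evaluates everything on the hold-out test set.
#'
#' @param cohort A `triage_cohort`.
#' @param config A `triage_config`.
#' @param verbose Print per-epoch log lines.
#' @return List with `rnn`, `cnn`, `fused` (trained models), `data` (the
#'   shared split/vocab), and `metrics` (test-set `triage_metrics` for each
#'   of the three models).
#' @export
train_triage_engine <- function(cohort, config = triage_config("fast"),
                                verbose = FALSE) {
  data <- prepare_triage_data(cohort, config)
  rnn <- train_branch("rnn", cohort, config, data = data, verbose = verbose)
  cnn <- train_branch("cnn", cohort, config, data = data, verbose = verbose)
  fused <- fuse(rnn, cnn, dropout = config$dropout, seed = config$seed)
  fused <- finetune_fused(fused, cohort, config, data = data, verbose = verbose)
  metrics <- list(rnn = evaluate_model(rnn, data, "test", config$threshold),
                  cnn = evaluate_model(cnn, data, "test", config$threshold),
                  fused = evaluate_model(fused, data, "test", config$threshold))
  list(rnn = rnn, cnn = cnn, fused = fused, data = data, metrics = metrics)
}

#' Evaluate a trained model on one split
#'
#' @param model A `triage_branch` or `triage_fused`.
#' @param data A [prepare_triage_data()] result.
#' @param part `"train"`, `"validation"` or `"test"`.
#' @param threshold Decision threshold for the confusion metrics.
#' @return A `triage_metrics` report.
#' @export
evaluate_model <- function(model, data, part = "test", threshold = 0.5) {
  idx <- data$split[[match.arg(part, c("train", "validation", "test"))]]
  scores <- predict_scores(model, data, idx)
  confusion_metrics(data$labels[idx], scores, threshold)
}

#' Positive-class scores for a set of records
#'
#' @param model A `triage_branch` or `triage_fused`.
#' @param data A [prepare_triage_data()] result (or a `triage_encoded`).
#' @param idx Row indices to score (default: all).
#' @return Numeric vector of admission probabilities.
#' @export
predict_scores <- function(model, data, idx = NULL) {
  enc <- if (inherits(data, "triage_encoded")) data else data$encoded
  if (is.null(idx)) idx <- seq_len(nrow(enc$ids))
  fn <- if (inherits(model, "triage_fused")) {
    function(i, l) fused_forward_batch(model, i, l)
  } else if (model$branch_kind == "rnn") {
    function(i, l) rnn_forward_batch(model$params, model$config, i, l)
  } else {
    function(i, l) cnn_forward_batch(model$params, model$config, i, l)
  }
  score_batches(fn, enc$ids, enc$lengths, idx)
}

#' Repeat the full protocol and select the best model
#'
#' Re-splits and retrains `repeats` times with seeds `config$seed + 0 ..
#' repeats-1`. In `"internal"` mode the best model is chosen by hold-out
#' test AUROC (the internal-comparison protocol; it leaks test information
#' and the report says so); in `"external"` mode selection uses validation
#' AUROC and the selected model is evaluated once on its hold-out set.
#'
#' @param cohort A `triage_cohort`.
#' @param config A `triage_config`.
#' @param repeats Number of repetitions (default 20).
#' @param mode `"internal"` or `"external"`.
#' @param kind Which model to train each repeat: `"fused"` (full engine),
#'   `"rnn"` or `"cnn"`.
#' @param verbose Print progress.
#' @return List with `model` (selected), `reports` (per-repeat
#'   `triage_metrics` on the hold-out set), `selection` (per-repeat selection
#'   metric), `selected` (index), `mode`.
#' @export
repeat_select <- function(cohort, config = triage_config("fast"), repeats = 20L,
                          mode = c("internal", "external"),
                          kind = c("fused", "rnn", "cnn"), verbose = FALSE) {
  mode <- match.arg(mode)
  kind <- match.arg(kind)
  stopifnot(repeats >= 1L)
  reports <- vector("list", repeats)
  models <- vector("list", repeats)
  sel_metric <- numeric(repeats)
  for (r in seq_len(repeats)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    if (kind == "fused") {
      run <- train_triage_engine(cohort, cfg, verbose = verbose)
      model <- run$fused; data <- run$data
    } else {
      data <- prepare_triage_data(cohort, cfg)
      model <- train_branch(kind, cohort, cfg, data = data, verbose = verbose)
    }
    reports[[r]] <- evaluate_model(model, data, "test", cfg$threshold)
    sel_metric[r] <- if (mode == "internal") reports[[r]]$auroc
                     else max(model$history$val_auroc)
    models[[r]] <- model
    if (verbose)
      message(sprintf("repeat %d/%d: test AUROC %.4f", r, repeats,
                      reports[[r]]$auroc))
  }
  best <- which.max(sel_metric)
  list(model = models[[best]], reports = reports, selection = sel_metric,
       selected = best, mode = mode)
}
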