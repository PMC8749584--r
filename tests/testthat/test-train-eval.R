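# Metrics, stratified splitting, and the training protocol.

test_that("auroc matches hand-computed and oracle values", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.3, 0.4)), 1.0)
  expect_equal(auroc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "both classes")
  expect_error(auroc(c(0, 1), c(NA, 0.3)), "finite")
})

test_that("auroc equals exhaustive pairwise concordance on random instances", {
  set.seed(14)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1))   # coarse rounding forces ties
    expect_equal(auroc(labels, scores), auroc_pairwise(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("auroc agrees with an independent ROC implementation", {
  set.seed(27)
  for (i in 1:5) {
    labels <- c(0L, 1L, sample(0:1, 48, replace = TRUE))
    scores <- round(runif(50), 2)
    expect_equal(auroc(labels, scores),
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("auroc is invariant under strictly monotone score transforms", {
  set.seed(15)
  labels <- sample(0:1, 40, replace = TRUE, prob = c(0.6, 0.4))
  scores <- runif(40)
  base <- auroc(labels, scores)
  expect_equal(auroc(labels, qlogis(scores)), base)
  expect_equal(auroc(labels, scores^3 + 2 * scores), base)
  expect_equal(auroc(labels, rank(scores)), base)
})

test_that("confusion metrics reproduce the definitional identities", {
  m <- confusion_metrics(c(1, 1, 0, 0), c(0.9, 0.2, 0.1, 0.3), threshold = 0.5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$accuracy, 0.75)
  m0 <- confusion_metrics(c(1, 1, 0, 0), c(0.9, 0.2, 0.1, 0.3), threshold = 0)
  expect_equal(m0$sensitivity, 1.0)
  mall <- confusion_metrics(c(1, 0), c(0.1, 0.2), threshold = 0.9)
  expect_equal(mall$precision, 0)
  expect_true(mall$precision_undefined)

  set.seed(16)
  for (i in 1:10) {
    n <- sample(10:80, 1)
    labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    scores <- runif(n)
    th <- runif(1)
    m <- confusion_metrics(labels, scores, th)
    expect_equal(m$accuracy, (m$tp + m$tn) / n)
    expect_equal(m$tp + m$fp + m$tn + m$fn, n)
    if (!m$precision_undefined && (m$precision + m$sensitivity) > 0)
      expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                           (m$precision + m$sensitivity))
    expect_equal(m$auroc, auroc(labels, scores))
  }
})

test_that("stratified splitting allocates by largest remainder", {
  labels <- rep(c(1L, 0L), c(300L, 700L))
  sp <- stratified_split(labels, c(0.72, 0.08, 0.20), seed = 2L)
  expect_length(sp$train, 720L)
  expect_length(sp$validation, 80L)
  expect_length(sp$test, 200L)
  expect_equal(sum(labels[sp$train]), 216L)
  expect_equal(sum(labels[sp$validation]), 24L)
  expect_equal(sum(labels[sp$test]), 60L)
  # disjoint and exhaustive
  all_idx <- c(sp$train, sp$validation, sp$test)
  expect_equal(sort(all_idx), 1:1000)
  # deterministic
  sp2 <- stratified_split(labels, c(0.72, 0.08, 0.20), seed = 2L)
  expect_identical(sp, sp2)
  expect_false(identical(sp$train,
                         stratified_split(labels, seed = 3L)$train))
  expect_error(stratified_split(labels, c(1, 0, 0), seed = 1L), "lack")
  expect_error(stratified_split(rep(1L, 10), seed = 1L), "both classes")
})

test_that("per-split prevalence stays within 1/|split| of the global rate", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(200:900, 1)
    prev <- runif(1, 0.15, 0.5)
    labels <- rbinom(n, 1L, prev)
    if (sum(labels) < 10 || sum(1 - labels) < 10) next
    sp <- stratified_split(labels, seed = i)
    g <- mean(labels)
    for (part in list(sp$train, sp$validation, sp$test))
      expect_lt(abs(mean(labels[part]) - g), 1 / length(part) + 1e-12)
  }
})

test_that("branch training descends and is bit-reproducible", {
  co <- generate_cohort(700, seed = 19)
  cfg <- tiny_config(epochs = 3L, seed = 19L, fractions = c(0.6, 0.2, 0.2))
  m1 <- train_branch("cnn", co, cfg)
  m2 <- train_branch("cnn", co, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_lt(m1$history$train_loss[3], m1$history$train_loss[1])
  expect_equal(nrow(m1$history), 3L)
  expect_equal(m1$best_epoch, which.max(m1$history$val_auroc))
  # scoring the same records twice is identical
  data <- prepare_triage_data(co, cfg)
  s1 <- predict_scores(m1, data, idx = 1:50)
  s2 <- predict_scores(m1, data, idx = 1:50)
  expect_identical(s1, s2)
})

test_that("training a null cohort stays near chance", {
  co <- generate_cohort(2500, effect = effect_spec(intercept = -0.8), seed = 23)
  cfg <- tiny_config(epochs = 2L, seed = 23L)
  m <- train_branch("cnn", co, cfg)
  expect_gt(max(m$history$val_auroc), 0.40)
  expect_lt(max(m$history$val_auroc), 0.60)
})

test_that("repeat_select accounts for every repeat and takes the argmax", {
  co <- generate_cohort(600, seed = 29)
  cfg <- tiny_config(epochs = 1L, seed = 29L, fractions = c(0.6, 0.2, 0.2))
  rs <- repeat_select(co, cfg, repeats = 2L, mode = "internal", kind = "cnn")
  expect_length(rs$reports, 2L)
  expect_equal(rs$selected, which.max(rs$selection))
  expect_equal(rs$selection[rs$selected], max(rs$selection))
  expect_equal(rs$selection,
               vapply(rs$reports, function(r) r$auroc, numeric(1)))
  # repeats = 1 degenerates to a single train/evaluate run
  rs1 <- repeat_select(co, cfg, repeats = 1L, mode = "external", kind = "cnn")
  single <- train_branch("cnn", co, cfg)
  expect_identical(rs1$model$params, single$params)
})

test_that("checkpoints round-trip through disk with their manifests", {
  co <- generate_cohort(400, seed = 37)
  cfg <- tiny_config(epochs = 1L, seed = 37L, fractions = c(0.6, 0.2, 0.2))
  data <- prepare_triage_data(co, cfg)
  rnn <- train_branch("rnn", co, cfg, data = data)
  cnn <- train_branch("cnn", co, cfg, data = data)
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(rnn, path)
  expect_true(file.exists(paste0(path, ".json")))
  manifest <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(manifest$kind, "rnn")
  back <- load_checkpoint(path)
  expect_identical(back$params, rnn$params)
  expect_identical(predict_scores(back, data, idx = 1:20),
                   predict_scores(rnn, data, idx = 1:20))
  fm <- fuse(rnn, cnn, dropout = 0.5, seed = 1L)
  fpath <- tempfile(fileext = ".ckpt")
  save_checkpoint(fm, fpath)
  fback <- load_checkpoint(fpath)
  expect_identical(fback$params, fm$params)
  expect_false(any(grepl("head", names(fback$params))))
})
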