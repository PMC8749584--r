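# Synthetic emergency-visit cohorts. The generator draws each feature from a
# declared marginal (truncated normal within the schema range for continuous
# features, stated level probabilities for categorical ones) and plants a
# logistic outcome model over standardized features: main effects plus
# cross-feature interactions. Because the true admission probability p(x) is
# known per record, the Bayes-optimal AUROC on any generated cohort is
# measurable and serves as the ceiling against which trained models are
# judged.

#' Default emergency-visit schema
#'
#' A compact schema structurally modelled on a US ED survey extract:
#' demographics, arrival mode, triage acuity, six vital signs, pain scale,
#' two comorbidity flags and two imaging flags, with hospital admission as
#' the outcome. Small enough for fast experiments while exercising every
#' feature kind.
#'
#' @return A `triage_schema` with 15 features and outcome
#'   `"hospital_admission"`.
#' @export
default_triage_schema <- function() {
  feature_schema(list(
    feature_spec("age", "continuous", "age", units = "years",
                 precision = 0L, range = c(0, 100)),
    feature_spec("sex", "binary", "sex", levels = c("female", "male")),
    feature_spec("arrival_mode", "categorical", "arrival mode",
                 levels = c("walk in", "ambulance", "transfer")),
    feature_spec("triage_level", "categorical", "triage level",
                 levels = c("1", "2", "3", "4", "5")),
    feature_spec("temperature", "continuous", "body temperature",
                 units = "degrees", precision = 1L, range = c(34, 42)),
    feature_spec("heart_rate", "continuous", "heart rate", units = "beats",
                 precision = 0L, range = c(30, 200)),
    feature_spec("respiratory_rate", "continuous", "respiratory rate",
                 units = "times", precision = 0L, range = c(5, 60)),
    feature_spec("systolic_bp", "continuous", "systolic pressure",
                 units = "mmhg", precision = 0L, range = c(60, 240)),
    feature_spec("diastolic_bp", "continuous", "diastolic pressure",
                 units = "mmhg", precision = 0L, range = c(30, 140)),
    feature_spec("pulse_oximetry", "continuous", "pulse oximetry",
                 units = "percent", precision = 0L, range = c(50, 100)),
    feature_spec("pain_scale", "continuous", "pain index",
                 precision = 0L, range = c(0, 10)),
    feature_spec("diabetes", "binary", "diabetes",
                 levels = c("absent", "present")),
    feature_spec("heart_failure", "binary", "heart failure",
                 levels = c("absent", "present")),
    feature_spec("chest_xray", "binary", "x ray",
                 levels = c("not done", "done")),
    feature_spec("ct_scan", "binary", "ct scan",
                 levels = c("not done", "done"))
  ), outcome = "hospital_admission")
}

#' Default generating marginals
#'
#' Per-feature sampling distributions for [generate_cohort()]: continuous
#' features as `list(mean, sd)` of the (range-truncated) normal, categorical
#' features as `list(prob)` over their levels. Features without a stored
#' default get a mid-range normal (sd = range width / 6) or uniform levels.
#'
#' @param schema A `triage_schema`.
#' @return Named list of marginal descriptions, one per feature.
#' @export
default_marginals <- function(schema = default_triage_schema()) {
  known <- list(
    age              = list(mean = 45,   sd = 22),
    sex              = list(prob = c(0.52, 0.48)),
    arrival_mode     = list(prob = c(0.70, 0.25, 0.05)),
    triage_level     = list(prob = c(0.03, 0.12, 0.45, 0.30, 0.10)),
    temperature      = list(mean = 36.8, sd = 0.7),
    heart_rate       = list(mean = 88,   sd = 18),
    respiratory_rate = list(mean = 17,   sd = 4),
    systolic_bp      = list(mean = 132,  sd = 22),
    diastolic_bp     = list(mean = 78,   sd = 14),
    pulse_oximetry   = list(mean = 97,   sd = 2.5),
    pain_scale       = list(mean = 4,    sd = 2.8),
    diabetes         = list(prob = c(0.82, 0.18)),
    heart_failure    = list(prob = c(0.92, 0.08)),
    chest_xray       = list(prob = c(0.65, 0.35)),
    ct_scan          = list(prob = c(0.80, 0.20))
  )
  out <- lapply(schema$features, function(f) {
    m <- known[[f$name]]
    if (!is.null(m)) {
      if (f$kind == "continuous" && !is.null(m$prob))
        stop(sprintf("marginal for '%s' does not match its kind", f$name))
      return(m)
    }
    if (f$kind == "continuous") {
      rg <- if (is.null(f$range)) c(0, 1) else f$range
      list(mean = mean(rg), sd = diff(rg) / 6)
    } else {
      list(prob = rep(1 / length(f$levels), length(f$levels)))
    }
  })
  names(out) <- schema_feature_names(schema)
  out
}

#' Declare a planted outcome model
#'
#' The linear predictor is
#' `eta(x) = intercept + sum(main effects) + sum(interactions)`, with
#' continuous and binary features entering standardized (zero mean, unit
#' variance under their generating marginal) and categorical features via
#' per-level one-hot weights. Interactions multiply two standardized
#' (continuous/binary) features, so a pure interaction contributes no
#' marginal main effect.
#'
#' @param intercept Log-odds intercept.
#' @param main_effects Named list: scalar weight for continuous/binary
#'   features, or a named per-level weight vector for categorical features.
#' @param interactions List of `list(f1, f2, weight)` triples.
#' @return An object of class `triage_effect`.
#' @export
effect_spec <- function(intercept = 0, main_effects = list(), interactions = list()) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  structure(list(intercept = intercept, main_effects = main_effects,
                 interactions = interactions), class = "triage_effect")
}

#' Default planted outcome model
#'
#' Admission-like signal: triage acuity dominates (per-level log-odds from
#' +1.6 at level 1 to -1.6 at level 5), with moderate effects of age, pain,
#' low oxygen saturation and diabetes — all local phrase-adjacent patterns a
#' convolutional window can see — plus one pure long-range interaction,
#' sex x CT scan, whose two features render roughly forty tokens apart and
#' carry no main effect, so only a model integrating distant context can
#' exploit it. The intercept is calibrated so the admission prevalence under
#' the default marginals is about 0.3.
#'
#' @return A `triage_effect`.
#' @export
default_effect_spec <- function() {
  effect_spec(
    intercept = -1.1,
    main_effects = list(
      age = 0.4,
      triage_level = c("1" = 1.6, "2" = 0.8, "3" = 0, "4" = -0.8, "5" = -1.6),
      pulse_oximetry = -0.4,
      pain_scale = 0.4,
      diabetes = 0.4
    ),
    interactions = list(list("sex", "ct_scan", 1.8))
  )
}

# mean/sd of a feature under its generating marginal (continuous: analytic
# truncated-normal moments; binary: Bernoulli moments of the second level)
feature_moments <- function(spec, marginal) {
  if (spec$kind == "continuous") {
    mu <- marginal$mean; sg <- marginal$sd
    rg <- if (is.null(spec$range)) c(-Inf, Inf) else spec$range
    a <- (rg[1] - mu) / sg; b <- (rg[2] - mu) / sg
    Z <- pnorm(b) - pnorm(a)
    m <- mu + sg * (dnorm(a) - dnorm(b)) / Z
    an <- ifelse(is.finite(a), a * dnorm(a), 0)
    bn <- ifelse(is.finite(b), b * dnorm(b), 0)
    v <- sg^2 * (1 + (an - bn) / Z - ((dnorm(a) - dnorm(b)) / Z)^2)
    list(mean = m, sd = sqrt(v))
  } else if (length(spec$levels) == 2L) {
    p <- marginal$prob[2]
    list(mean = p, sd = sqrt(p * (1 - p)))
  } else {
    NULL  # categorical >2: one-hot, no standardization
  }
}

standardized_value <- function(spec, marginal, values) {
  mo <- feature_moments(spec, marginal)
  if (is.null(mo))
    stop(sprintf("feature '%s': interactions require a continuous or binary feature",
                 spec$name))
  x <- if (spec$kind == "continuous") as.numeric(values)
       else as.numeric(values == spec$levels[2])
  (x - mo$mean) / mo$sd
}

# linear predictor eta(x) of a planted effect over a visit table
effect_eta <- function(records, schema, effect, marginals) {
  nms <- schema_feature_names(schema)
  for (w in names(effect$main_effects))
    if (!(w %in% nms)) stop(sprintf("effect references unknown feature '%s'", w))
  for (ia in effect$interactions)
    for (w in c(ia[[1]], ia[[2]]))
      if (!(w %in% nms)) stop(sprintf("effect references unknown feature '%s'", w))
  eta <- rep(effect$intercept, nrow(records))
  for (nm in names(effect$main_effects)) {
    spec <- schema$features[[nm]]
    w <- effect$main_effects[[nm]]
    if (spec$kind == "categorical" && length(spec$levels) > 2L) {
      if (is.null(names(w)) || !all(spec$levels %in% names(w)))
        stop(sprintf("categorical effect on '%s' needs a weight per level", nm))
      eta <- eta + unname(w[as.character(records[[nm]])])
    } else {
      eta <- eta + w * standardized_value(spec, marginals[[nm]], records[[nm]])
    }
  }
  for (ia in effect$interactions) {
    z1 <- standardized_value(schema$features[[ia[[1]]]], marginals[[ia[[1]]]],
                             records[[ia[[1]]]])
    z2 <- standardized_value(schema$features[[ia[[2]]]], marginals[[ia[[2]]]],
                             records[[ia[[2]]]])
    eta <- eta + ia[[3]] * z1 * z2
  }
  eta
}

#' Generate a synthetic emergency-visit cohort
#'
#' Fully reproducible from `seed`: features are drawn from the marginals
#' (continuous values are rounded to schema precision, exactly as an EMR
#' would store them), the linear predictor is evaluated on the stored
#' values, and labels are drawn Bernoulli(logistic(eta)).
#'
#' @param n Number of visits.
#' @param schema A `triage_schema`.
#' @param effect A `triage_effect`.
#' @param seed Integer seed.
#' @param marginals Per-feature marginals as from [default_marginals()].
#' @return An object of class `triage_cohort`: `records` (visit data.frame
#'   including the outcome column), `true_probabilities` (Bayes score per
#'   record), `effect`, `schema`, `seed`, `prevalence`.
#' @export
generate_cohort <- function(n, schema = default_triage_schema(),
                            effect = default_effect_spec(), seed = 1L,
                            marginals = default_marginals(schema)) {
  stopifnot(n >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  records <- data.frame(visit_id = sprintf("v%06d", seq_len(n)),
                        stringsAsFactors = FALSE)
  for (f in schema$features) {
    m <- marginals[[f$name]]
    if (is.null(m)) stop(sprintf("no marginal declared for feature '%s'", f$name))
    if (f$kind == "continuous") {
      rg <- if (is.null(f$range)) c(-Inf, Inf) else f$range
      lo <- pnorm((rg[1] - m$mean) / m$sd)
      hi <- pnorm((rg[2] - m$mean) / m$sd)
      x <- m$mean + m$sd * qnorm(runif(n, lo, hi))
      x <- pmin(pmax(round(x, f$precision), rg[1]), rg[2])
      records[[f$name]] <- x
    } else {
      if (length(m$prob) != length(f$levels))
        stop(sprintf("marginal for '%s' must give one probability per level", f$name))
      records[[f$name]] <- sample(f$levels, n, replace = TRUE, prob = m$prob)
    }
  }
  p <- plogis(effect_eta(records, schema, effect, marginals))
  if (any(p <= 0 | p >= 1)) stop("planted model produced degenerate probabilities")
  records[[schema$outcome]] <- rbinom(n, 1L, p)
  structure(list(records = records, true_probabilities = p, effect = effect,
                 schema = schema, marginals = marginals, seed = as.integer(seed),
                 prevalence = mean(records[[schema$outcome]])),
            class = "triage_cohort")
}

#' @export
print.triage_cohort <- function(x, ...) {
  cat(sprintf("triage_cohort: %d visits, prevalence %.3f, seed %d\n",
              nrow(x$records), x$prevalence, x$seed))
  invisible(x)
}

#' Bayes-optimal AUROC of a synthetic cohort
#'
#' Scores the drawn labels with the generator's own true probabilities using
#' the same [auroc()] routine as model evaluation. Up to sampling noise this
#' is the best AUROC any classifier can reach on the cohort.
#'
#' @param cohort A `triage_cohort`.
#' @return AUROC of `true_probabilities` against the drawn labels.
#' @export
bayes_auroc <- function(cohort) {
  stopifnot(inherits(cohort, "triage_cohort"))
  auroc(cohort$records[[cohort$schema$outcome]], cohort$true_probabilities)
}
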