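#' Declare a single visit feature
#'
#' A feature spec describes one column of a visit table: its type, the human
#' phrase used when the record is rendered to text, and (for continuous
#' features) units, decimal precision and plausibility bounds used by the
#' missing/unusable-data filter.
#'
#' @param name Column name in the visit table (unique within a schema).
#' @param kind One of `"continuous"`, `"categorical"`, `"binary"`.
#' @param display Human phrase used in text rendering, e.g. `"body temperature"`.
#'   Defaults to `name` with underscores replaced by spaces.
#' @param units Units phrase appended after a continuous value (`""` for none).
#' @param precision Decimal places used to render a continuous value.
#' @param levels Character vector of level labels (categorical/binary).
#' @param required If `TRUE`, records missing this feature are dropped by
#'   [filter_records()].
#' @param range Optional numeric `c(lo, hi)`; continuous values outside it are
#'   treated as unusable.
#' @return An object of class `triage_feature`.
#' @export
feature_spec <- function(name, kind, display = gsub("_", " ", name),
                         units = "", precision = 0L, levels = character(),
                         required = TRUE, range = NULL) {
  kind <- match.arg(kind, c("continuous", "categorical", "binary"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("feature 'name' must be a nonempty string")
  if (!nzchar(trimws(display)))
    stop(sprintf("feature '%s': display phrase must be nonempty", name))
  if (kind == "continuous") {
    precision <- as.integer(precision)
    if (is.na(precision) || precision < 0L)
      stop(sprintf("feature '%s': precision must be a finite integer >= 0", name))
    if (!is.null(range)) {
      range <- as.numeric(range)
      if (length(range) != 2L || any(!is.finite(range)) || range[1] >= range[2])
        stop(sprintf("feature '%s': range must be finite c(lo, hi) with lo < hi", name))
    }
  } else {
    levels <- as.character(levels)
    if (kind == "binary" && length(levels) != 2L)
      stop(sprintf("feature '%s': binary features need exactly 2 levels", name))
    if (kind == "categorical" && length(unique(levels)) < 2L)
      stop(sprintf("feature '%s': categorical features need >= 2 distinct levels", name))
    if (anyDuplicated(levels))
      stop(sprintf("feature '%s': duplicate levels", name))
    if (any(!nzchar(trimws(levels))))
      stop(sprintf("feature '%s': empty level label", name))
    range <- NULL
  }
  structure(list(name = name, kind = kind, display = tolower(trimws(display)),
                 units = tolower(trimws(units)), precision = as.integer(precision),
                 levels = levels, required = isTRUE(required), range = range),
            class = "triage_feature")
}

#' Assemble an ordered feature schema
#'
#' The schema fixes both the set of features and their order; the order
#' defines the sentence template used by [transform_record()].
#'
#' @param features List of [feature_spec()] objects.
#' @param outcome Name of the binary outcome column (not itself a feature).
#'   The same pipeline retargets to ICU admission or mortality by pointing
#'   `outcome` at a different column.
#' @return An object of class `triage_schema`.
#' @export
feature_schema <- function(features, outcome) {
  if (length(features) == 0L) stop("schema must declare at least one feature")
  ok <- vapply(features, inherits, logical(1), "triage_feature")
  if (!all(ok)) stop("all schema entries must be feature_spec() objects")
  nms <- vapply(features, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop(sprintf("duplicate feature name(s): %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  if (!is.character(outcome) || length(outcome) != 1L || !nzchar(outcome))
    stop("'outcome' must be a single column name")
  if (outcome %in% nms)
    stop(sprintf("outcome '%s' must not also be a feature", outcome))
  names(features) <- nms
  structure(list(features = features, outcome = outcome), class = "triage_schema")
}

#' @export
print.triage_schema <- function(x, ...) {
  cat(sprintf("triage_schema: %d features, outcome '%s'\n",
              length(x$features), x$outcome))
  for (f in x$features) {
    extra <- switch(f$kind,
      continuous = sprintf("precision %d%s%s", f$precision,
                           if (nzchar(f$units)) paste0(", units '", f$units, "'") else "",
                           if (!is.null(f$range)) sprintf(", range [%g, %g]", f$range[1], f$range[2]) else ""),
      sprintf("levels: %s", paste(f$levels, collapse = "/")))
    cat(sprintf("  %-18s %-11s %s%s\n", f$name, f$kind, extra,
                if (f$required) "" else " (optional)"))
  }
  invisible(x)
}

#' Load a feature schema from YAML or JSON
#'
#' The file dialect is a top-level `outcome` string and a `features` list;
#' each entry carries `name`, `kind`, and optionally `display`, `units`,
#' `precision`, `levels`, `required`, `range`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` schema file.
#' @return A validated `triage_schema`.
#' @export
load_schema <- function(path) {
  if (!file.exists(path)) stop(sprintf("schema file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  schema_from_list(raw, where = path)
}

# Build a schema from a plain R list (shared by load_schema and the CLI).
schema_from_list <- function(raw, where = "schema") {
  if (is.null(raw$features) || length(raw$features) == 0L)
    stop(sprintf("%s: no 'features' list", where))
  if (is.null(raw$outcome))
    stop(sprintf("%s: missing 'outcome' field", where))
  feats <- lapply(raw$features, function(f) {
    if (is.null(f$name)) stop(sprintf("%s: a feature entry lacks 'name'", where))
    if (is.null(f$kind)) stop(sprintf("%s: feature '%s' lacks 'kind'", where, f$name))
    feature_spec(
      name = f$name, kind = f$kind,
      display = if (is.null(f$display)) gsub("_", " ", f$name) else f$display,
      units = if (is.null(f$units)) "" else f$units,
      precision = if (is.null(f$precision)) 0L else f$precision,
      levels = if (is.null(f$levels)) character() else unlist(f$levels),
      required = if (is.null(f$required)) TRUE else isTRUE(f$required),
      range = if (is.null(f$range)) NULL else unlist(f$range))
  })
  feature_schema(feats, outcome = raw$outcome)
}

#' Write a schema to YAML
#'
#' Inverse of [load_schema()] for the YAML dialect.
#'
#' @param schema A `triage_schema`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "triage_schema"))
  feats <- lapply(schema$features, function(f) {
    out <- list(name = f$name, kind = f$kind, display = f$display,
                required = f$required)
    if (f$kind == "continuous") {
      out$units <- f$units
      out$precision <- f$precision
      if (!is.null(f$range)) out$range <- as.numeric(f$range)
    } else {
      out$levels <- as.list(f$levels)
    }
    out
  })
  yaml::write_yaml(list(outcome = schema$outcome, features = unname(feats)), path)
  invisible(path)
}

schema_feature_names <- function(schema) {
  vapply(schema$features, `[[`, character(1), "name")
}
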