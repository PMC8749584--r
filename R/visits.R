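#' Read a visit table against a schema
#'
#' Reads a delimited visit table (CSV/TSV; delimiter auto-detected by
#' `data.table::fread` unless given) and types every column according to the
#' schema. Cells that fail to parse under their declared kind are marked
#' missing (`NA`) and left for [filter_records()] to act on; nothing is
#' dropped here.
#'
#' @param path Delimited text file with a header row.
#' @param schema A `triage_schema`.
#' @param delim Optional single-character delimiter; default auto-detect.
#' @return A `data.frame` with one row per visit: `visit_id`, one typed column
#'   per feature (numeric for continuous, character for categorical/binary),
#'   and the outcome column as integer 0/1 when present in the file.
#' @export
read_visits <- function(path, schema, delim = NULL) {
  stopifnot(inherits(schema, "triage_schema"))
  if (!file.exists(path)) stop(sprintf("visit table not found: %s", path))
  dt <- if (is.null(delim)) {
    data.table::fread(path, colClasses = "character", data.table = FALSE,
                      na.strings = c("", "NA"))
  } else {
    data.table::fread(path, sep = delim, colClasses = "character",
                      data.table = FALSE, na.strings = c("", "NA"))
  }
  nms <- schema_feature_names(schema)
  absent <- setdiff(nms, names(dt))
  if (length(absent) > 0L)
    stop(sprintf("visit table lacks required column(s): %s",
                 paste(absent, collapse = ", ")))
  n <- nrow(dt)
  out <- data.frame(
    visit_id = if ("visit_id" %in% names(dt)) as.character(dt$visit_id)
               else as.character(seq_len(n)),
    stringsAsFactors = FALSE)
  for (f in schema$features) {
    col <- dt[[f$name]]
    if (f$kind == "continuous") {
      out[[f$name]] <- suppressWarnings(as.numeric(col))
    } else {
      v <- tolower(trimws(col))
      v[!(v %in% tolower(f$levels)) | is.na(v)] <- NA_character_
      # map back to canonical level spelling
      idx <- match(v, tolower(f$levels))
      out[[f$name]] <- ifelse(is.na(idx), NA_character_, f$levels[idx])
    }
  }
  oc <- schema$outcome
  if (oc %in% names(dt)) {
    y <- suppressWarnings(as.integer(dt[[oc]]))
    y[!(y %in% c(0L, 1L))] <- NA_integer_
    out[[oc]] <- y
  }
  out
}

#' Write a visit table at schema precision
#'
#' Inverse of [read_visits()]: continuous values are rendered with the
#' schema's decimal precision so that a write/read round trip is exact.
#'
#' @param records Visit `data.frame` (as from [read_visits()] or
#'   [generate_cohort()]).
#' @param schema A `triage_schema`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(records, schema, path) {
  stopifnot(inherits(schema, "triage_schema"))
  out <- data.frame(visit_id = as.character(records$visit_id),
                    stringsAsFactors = FALSE)
  for (f in schema$features) {
    col <- records[[f$name]]
    if (f$kind == "continuous") {
      out[[f$name]] <- ifelse(is.na(col), "",
                              formatC(col, format = "f", digits = f$precision))
    } else {
      out[[f$name]] <- ifelse(is.na(col), "", as.character(col))
    }
  }
  oc <- schema$outcome
  if (oc %in% names(records)) out[[oc]] <- records[[oc]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Filter unusable or missing records
#'
#' A record is kept iff every required feature has a present value that is
#' in range (continuous, when the spec declares bounds) or among the declared
#' levels (categorical/binary), and — when the outcome column is present —
#' the label is 0 or 1. No imputation is performed. The drop report tallies,
#' per feature, how many records it caused to be dropped; a record failing on
#' several features increments each of their counters.
#'
#' @param records Visit `data.frame` from [read_visits()] or
#'   [generate_cohort()].
#' @param schema A `triage_schema`.
#' @return A list with `kept` (the surviving rows), `dropped` (the rest),
#'   and `report` (named integer vector of per-feature drop counts, plus the
#'   outcome column when labels were present but invalid).
#' @export
filter_records <- function(records, schema) {
  stopifnot(inherits(schema, "triage_schema"))
  n <- nrow(records)
  bad <- matrix(FALSE, nrow = n, ncol = 0L)
  report <- integer(0)
  for (f in schema$features) {
    if (!f$required) next
    col <- records[[f$name]]
    miss <- is.na(col)
    if (f$kind == "continuous") {
      miss <- miss | !is.finite(col)
      if (!is.null(f$range))
        miss <- miss | (!is.na(col) & (col < f$range[1] | col > f$range[2]))
    } else {
      miss <- miss | !(col %in% f$levels)
    }
    bad <- cbind(bad, miss)
    report[f$name] <- sum(miss)
  }
  oc <- schema$outcome
  if (oc %in% names(records)) {
    miss <- !(records[[oc]] %in% c(0L, 1L))
    bad <- cbind(bad, miss)
    report[oc] <- sum(miss)
  }
  drop <- if (ncol(bad) > 0L) rowSums(bad) > 0L else rep(FALSE, n)
  list(kept = records[!drop, , drop = FALSE],
       dropped = records[drop, , drop = FALSE],
       report = report)
}
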