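# Data-to-text serialization: every visit record renders to one lower-case
# sentence, feature by feature in schema order ("body temperature 36.5
# degrees pain index 5 ..."), with no punctuation tokens. The rendering is
# injective on filtered records; parse_transcript() is its exact inverse and
# is used by the round-trip tests.

split_tokens <- function(x) strsplit(trimws(tolower(x)), "[[:space:]]+")

format_value <- function(value, precision) {
  # fixed "." decimal mark, no thousands separators, locale-independent
  formatC(value, format = "f", digits = precision, decimal.mark = ".",
          big.mark = "")
}

is_number_token <- function(tok) grepl("^-?[0-9]+(\\.[0-9]+)?$", tok)

#' Render one feature value to its token phrase
#'
#' Continuous features render as display phrase + value at schema precision +
#' units phrase (if any); categorical/binary as display phrase + level label.
#'
#' @param spec A [feature_spec()].
#' @param value A single value conforming to the spec.
#' @return Character vector of lower-case tokens (length >= 2).
#' @export
render_feature <- function(spec, value) {
  stopifnot(inherits(spec, "triage_feature"))
  if (length(value) != 1L || is.na(value))
    stop(sprintf("feature '%s': cannot render a missing value; run filter_records() first",
                 spec$name))
  toks <- split_tokens(spec$display)[[1]]
  if (spec$kind == "continuous") {
    if (!is.numeric(value)) stop(sprintf("feature '%s': value must be numeric", spec$name))
    toks <- c(toks, format_value(value, spec$precision))
    if (nzchar(spec$units)) toks <- c(toks, split_tokens(spec$units)[[1]])
  } else {
    if (!(value %in% spec$levels))
      stop(sprintf("feature '%s': value '%s' is not a declared level", spec$name, value))
    toks <- c(toks, split_tokens(as.character(value))[[1]])
  }
  toks
}

# Vectorized rendering of one feature column to one string per record.
render_column <- function(spec, values) {
  if (anyNA(values))
    stop(sprintf("feature '%s': missing values; run filter_records() first", spec$name))
  head_phrase <- spec$display
  if (spec$kind == "continuous") {
    body <- format_value(values, spec$precision)
    if (nzchar(spec$units)) body <- paste(body, spec$units)
  } else {
    if (!all(values %in% spec$levels))
      stop(sprintf("feature '%s': undeclared level present", spec$name))
    body <- tolower(as.character(values))
  }
  paste(head_phrase, body)
}

#' Transform one visit record into a transcript
#'
#' @param record A one-row visit `data.frame` (or named list) whose values
#'   passed [filter_records()].
#' @param schema A `triage_schema`.
#' @return An object of class `triage_transcript`: `tokens` (character
#'   vector) and `provenance` (data.frame feature/start/end giving each
#'   feature's contiguous token span, jointly covering all tokens).
#' @export
transform_record <- function(record, schema) {
  stopifnot(inherits(schema, "triage_schema"))
  tokens <- character(0)
  prov <- vector("list", length(schema$features))
  for (i in seq_along(schema$features)) {
    f <- schema$features[[i]]
    tk <- render_feature(f, record[[f$name]])
    prov[[i]] <- data.frame(feature = f$name, start = length(tokens) + 1L,
                            end = length(tokens) + length(tk),
                            stringsAsFactors = FALSE)
    tokens <- c(tokens, tk)
  }
  structure(list(tokens = tokens, provenance = do.call(rbind, prov)),
            class = "triage_transcript")
}

#' Transform a visit table into sentences
#'
#' Vectorized form of [transform_record()]: one sentence string per record,
#' features concatenated in schema order.
#'
#' @param records Visit `data.frame` whose rows passed [filter_records()].
#' @param schema A `triage_schema`.
#' @return Character vector of sentences, one per row of `records`.
#' @export
transform_records <- function(records, schema) {
  stopifnot(inherits(schema, "triage_schema"))
  cols <- lapply(schema$features, function(f) render_column(f, records[[f$name]]))
  do.call(paste, cols)
}

#' Parse a transcript back into a visit record
#'
#' Exact inverse of [transform_record()] under the same schema; used to prove
#' that serialization loses no information at schema precision.
#'
#' @param transcript A `triage_transcript`, or a character vector of tokens,
#'   or a single sentence string.
#' @param schema A `triage_schema`.
#' @return A one-row visit `data.frame` (continuous columns numeric at schema
#'   precision, categorical columns at canonical level spelling).
#' @export
parse_transcript <- function(transcript, schema) {
  stopifnot(inherits(schema, "triage_schema"))
  tokens <- if (inherits(transcript, "triage_transcript")) transcript$tokens
            else if (length(transcript) == 1L && grepl("[[:space:]]", transcript))
              split_tokens(transcript)[[1]]
            else as.character(transcript)
  pos <- 1L
  out <- list()
  take <- function(k, what) {
    if (pos + k - 1L > length(tokens))
      stop(sprintf("parse error: transcript ends inside %s", what))
    tk <- tokens[pos:(pos + k - 1L)]
    pos <<- pos + k
    tk
  }
  for (f in schema$features) {
    disp <- split_tokens(f$display)[[1]]
    got <- take(length(disp), sprintf("display phrase of '%s'", f$name))
    if (!identical(got, disp))
      stop(sprintf("parse error at token %d: expected phrase '%s' of feature '%s', saw '%s'",
                   pos - length(disp), f$display, f$name, paste(got, collapse = " ")))
    if (f$kind == "continuous") {
      val <- take(1L, sprintf("value of '%s'", f$name))
      if (!is_number_token(val))
        stop(sprintf("parse error: non-numeric value token '%s' for feature '%s'",
                     val, f$name))
      out[[f$name]] <- as.numeric(val)
      if (nzchar(f$units)) {
        un <- split_tokens(f$units)[[1]]
        got <- take(length(un), sprintf("units of '%s'", f$name))
        if (!identical(got, un))
          stop(sprintf("parse error: expected units '%s' for feature '%s'", f$units, f$name))
      }
    } else {
      # greedy longest-level-first match so multi-token levels are unambiguous
      lev_toks <- split_tokens(f$levels)
      ord <- order(lengths(lev_toks), decreasing = TRUE)
      hit <- NA_integer_
      for (j in ord) {
        lt <- lev_toks[[j]]
        if (pos + length(lt) - 1L <= length(tokens) &&
            identical(tokens[pos:(pos + length(lt) - 1L)], lt)) {
          hit <- j
          break
        }
      }
      if (is.na(hit))
        stop(sprintf("parse error at token %d: no level of feature '%s' matches", pos, f$name))
      pos <- pos + length(lev_toks[[hit]])
      out[[f$name]] <- f$levels[hit]
    }
  }
  if (pos <= length(tokens))
    stop(sprintf("parse error: %d trailing token(s) after last feature",
                 length(tokens) - pos + 1L))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Build a vocabulary over a corpus of transcripts
#'
#' Indices are 0-based with reserved `PAD = 0` and `UNK = 1`; surface tokens
#' with frequency >= `min_count` get indices from 2 in deterministic order
#' (frequency descending, then lexicographic).
#'
#' @param transcripts Character vector of sentences, list of token vectors,
#'   or list of `triage_transcript`s.
#' @param min_count Minimum corpus frequency for a token to get its own index.
#' @return An object of class `triage_vocab`: `table` (data.frame token/
#'   index/freq), `size` (including the 2 reserved indices), `map` (named
#'   integer lookup).
#' @export
build_vocab <- function(transcripts, min_count = 1L) {
  stopifnot(min_count >= 1L)
  toks <- corpus_tokens(transcripts)
  if (length(toks) == 0L) stop("cannot build a vocabulary from an empty corpus")
  tab <- table(toks)
  freq <- as.integer(tab)
  token <- names(tab)
  keep <- freq >= min_count
  token <- token[keep]; freq <- freq[keep]
  ord <- order(-freq, token, method = "radix")
  token <- token[ord]; freq <- freq[ord]
  index <- if (length(token)) seq_along(token) + 1L else integer(0)
  map <- index
  names(map) <- token
  structure(list(
    table = data.frame(token = token, index = index, freq = freq,
                       stringsAsFactors = FALSE),
    size = length(token) + 2L, map = map,
    pad = 0L, unk = 1L), class = "triage_vocab")
}

corpus_tokens <- function(transcripts) {
  if (is.character(transcripts)) {
    unlist(split_tokens(transcripts), use.names = FALSE)
  } else if (is.list(transcripts)) {
    unlist(lapply(transcripts, function(t) {
      if (inherits(t, "triage_transcript")) t$tokens else as.character(t)
    }), use.names = FALSE)
  } else stop("unsupported corpus type")
}

#' @export
print.triage_vocab <- function(x, ...) {
  cat(sprintf("triage_vocab: %d tokens (+ PAD/UNK), top: %s\n", x$size - 2L,
              paste(utils::head(x$table$token, 5), collapse = ", ")))
  invisible(x)
}

#' Encode a transcript as a fixed-length index sequence
#'
#' Tokens map to vocabulary indices (UNK for out-of-vocabulary), right-padded
#' with PAD to `max_len`; longer transcripts are truncated at the end.
#'
#' @param transcript A `triage_transcript`, token vector, or sentence string.
#' @param vocab A `triage_vocab`.
#' @param max_len Fixed sequence length (default 160).
#' @return List with `ids` (integer vector of length `max_len`, 0-based),
#'   `true_length` (`min(n_tokens, max_len)`), `truncated` flag, and `label`
#'   carried through when present on the transcript.
#' @export
encode <- function(transcript, vocab, max_len = 160L) {
  stopifnot(inherits(vocab, "triage_vocab"), max_len >= 1L)
  tokens <- if (inherits(transcript, "triage_transcript")) transcript$tokens
            else if (length(transcript) == 1L && grepl("[[:space:]]", transcript))
              split_tokens(transcript)[[1]]
            else as.character(transcript)
  ids <- unname(vocab$map[tokens])
  ids[is.na(ids)] <- vocab$unk
  truncated <- length(ids) > max_len
  if (truncated) ids <- ids[seq_len(max_len)]
  true_length <- length(ids)
  ids <- c(as.integer(ids), rep(vocab$pad, max_len - true_length))
  list(ids = ids, true_length = true_length, truncated = truncated)
}

#' Encode many sentences into an index matrix
#'
#' @param sentences Character vector of sentences (or list of token vectors).
#' @param vocab A `triage_vocab`.
#' @param max_len Fixed sequence length.
#' @param labels Optional integer 0/1 labels carried alongside.
#' @return An object of class `triage_encoded`: `ids` (n x max_len integer
#'   matrix, 0-based), `lengths`, `labels`, `n_truncated`, `vocab_size`,
#'   `vocab_hash`, `max_len`.
#' @export
encode_records <- function(sentences, vocab, max_len = 160L, labels = NULL) {
  stopifnot(inherits(vocab, "triage_vocab"), max_len >= 1L)
  tok_lists <- if (is.character(sentences)) split_tokens(sentences) else sentences
  n <- length(tok_lists)
  ids <- matrix(vocab$pad, nrow = n, ncol = max_len)
  lens <- integer(n)
  n_trunc <- 0L
  for (i in seq_len(n)) {
    v <- unname(vocab$map[tok_lists[[i]]])
    v[is.na(v)] <- vocab$unk
    if (length(v) > max_len) {
      v <- v[seq_len(max_len)]
      n_trunc <- n_trunc + 1L
    }
    lens[i] <- length(v)
    if (length(v)) ids[i, seq_along(v)] <- v
  }
  if (n_trunc > 0L)
    message(sprintf("encode_records: truncated %d of %d transcripts to max_len=%d",
                    n_trunc, n, max_len))
  structure(list(ids = ids, lengths = lens, labels = labels,
                 n_truncated = n_trunc, vocab_size = vocab$size,
                 vocab_hash = vocab_hash(vocab), max_len = as.integer(max_len)),
            class = "triage_encoded")
}

# FNV-1a over the ordered token list; ties checkpoints to the vocabulary
# they were trained with without needing an external digest dependency.
vocab_hash <- function(vocab) {
  bytes <- utf8ToInt(paste(vocab$table$token, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply in 16-bit halves to stay inside double precision
    h <- (h %% 65536 * 16777619 + (h %/% 65536 * 16777619) %% 65536 * 65536) %% 2^32
  }
  sprintf("fnv1a-%08x", as.integer(h %% 2^31))
}
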