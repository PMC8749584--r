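#' Initialize an embedding matrix over a vocabulary
#'
#' Random initialization draws every non-PAD row i.i.d. uniform(-0.05, 0.05)
#' from `seed`; with a pretrained word-vector file (standard text format:
#' first line "count dim", then "token v1 ... vw"), covered tokens copy
#' their pretrained vector and the rest are random-initialized, with the
#' coverage fraction reported. The PAD row is all zeros and is excluded
#' from gradient updates during training.
#'
#' @param vocab A `triage_vocab`.
#' @param w Embedding dimension.
#' @param source `"random-init"` or the path of a pretrained vector file.
#' @param seed Integer seed for the random rows.
#' @return An object of class `triage_embedding`: `E` (`vocab$size` x `w`
#'   matrix; row 1 is PAD, row 2 is UNK), `w`, `trainable`, `source`,
#'   `coverage` (fraction of surface tokens found in the pretrained file;
#'   `NA` for random init).
#' @export
init_embeddings <- function(vocab, w, source = "random-init", seed = 1L) {
  stopifnot(inherits(vocab, "triage_vocab"), w >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  E <- matrix(runif(vocab$size * w, -0.05, 0.05), vocab$size, w)
  E[1L, ] <- 0  # PAD
  coverage <- NA_real_
  if (!identical(source, "random-init")) {
    pre <- read_word_vectors(source)
    if (ncol(pre$vectors) != w)
      stop(sprintf("pretrained vectors have dimension %d but w = %d requested",
                   ncol(pre$vectors), w))
    hit <- match(vocab$table$token, pre$tokens)
    covered <- which(!is.na(hit))
    if (length(covered))
      E[vocab$table$index[covered] + 1L, ] <- pre$vectors[hit[covered], , drop = FALSE]
    coverage <- length(covered) / max(1L, nrow(vocab$table))
    message(sprintf("init_embeddings: pretrained coverage %.1f%% (%d/%d tokens)",
                    100 * coverage, length(covered), nrow(vocab$table)))
  }
  structure(list(E = E, w = as.integer(w), trainable = TRUE,
                 source = if (identical(source, "random-init")) "random-init" else "pretrained",
                 coverage = coverage),
            class = "triage_embedding")
}

#' Read word vectors in the standard text format
#'
#' @param path File whose first line is "count dim" followed by one
#'   "token v1 ... vw" line per token.
#' @return List with `tokens` and a numeric `vectors` matrix.
#' @export
read_word_vectors <- function(path) {
  if (!file.exists(path)) stop(sprintf("word vector file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr))
    stop("word vector file: first line must be 'count dim'")
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  parts <- strsplit(trimws(body), "[[:space:]]+")
  tokens <- vapply(parts, `[[`, character(1), 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  if (any(!is.finite(vecs))) stop("word vector file: non-numeric vector entry")
  list(tokens = tokens, vectors = vecs)
}

#' Stack word vectors for one encoded visit
#'
#' Maps an encoded index sequence to the `h x w` token matrix consumed by
#' both branches, with a mask marking non-PAD positions. PAD positions are
#' all-zero rows.
#'
#' @param encoded A single encoding from [encode()].
#' @param embedding A `triage_embedding`.
#' @return List with `matrix` (`h x w`), `mask` (logical length `h`).
#' @export
lookup <- function(encoded, embedding) {
  stopifnot(inherits(embedding, "triage_embedding"))
  ids <- encoded$ids
  if (any(ids < 0L) || any(ids + 1L > nrow(embedding$E)))
    stop("lookup: token index outside the embedding table")
  X <- embedding$E[ids + 1L, , drop = FALSE]
  mask <- seq_along(ids) <= encoded$true_length
  X[!mask, ] <- 0
  list(matrix = X, mask = mask)
}

# Batched time-major lookup: ids is B x T (0-based); returns (B*T) x w with
# column-major flattening so row block t holds the batch at time t.
lookup_flat <- function(ids, E) {
  idx <- as.vector(ids) + 1L
  if (any(idx < 1L) || any(idx > nrow(E)))
    stop("lookup: token index outside the embedding table")
  E[idx, , drop = FALSE]
}
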