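test_that("feature rendering matches the sentence template", {
  temp <- feature_spec("temperature", "continuous", "body temperature",
                       units = "degrees", precision = 1L)
  pain <- feature_spec("pain_scale", "continuous", "pain index", precision = 0L)
  rr <- feature_spec("respiratory_rate", "continuous", "respiratory rate",
                     units = "times", precision = 0L)
  expect_identical(render_feature(temp, 36.5),
                   c("body", "temperature", "36.5", "degrees"))
  expect_identical(render_feature(pain, 5), c("pain", "index", "5"))
  expect_identical(render_feature(rr, 15),
                   c("respiratory", "rate", "15", "times"))
  lvl <- feature_spec("sex", "binary", "sex", levels = c("female", "male"))
  expect_identical(render_feature(lvl, "male"), c("sex", "male"))
  expect_error(render_feature(temp, NA), "missing")
})

test_that("rendering is locale-fixed: point decimal, no separators", {
  spec <- feature_spec("x", "continuous", "value", precision = 2L)
  expect_identical(render_feature(spec, 1234.5), c("value", "1234.50"))
  expect_identical(render_feature(spec, 0.125), c("value", "0.12"))
})

test_that("transcripts cover every token exactly once, in schema order", {
  sch <- tiny_schema()
  tr <- transform_record(tiny_records()[1, ], sch)
  expect_s3_class(tr, "triage_transcript")
  prov <- tr$provenance
  expect_identical(prov$feature, unname(schema_feature_names(sch)))
  expect_equal(prov$start[1], 1L)
  expect_equal(prov$end[nrow(prov)], length(tr$tokens))
  expect_true(all(prov$start[-1] == prov$end[-nrow(prov)] + 1L))  # contiguous
  expect_true(all(prov$end - prov$start + 1L >= 2L))              # phrase + value
})

test_that("rendering is local: changing one feature only changes its span", {
  sch <- tiny_schema()
  a <- tiny_records()[1, ]
  b <- a
  b$pain_scale <- 8
  ta <- transform_record(a, sch)
  tb <- transform_record(b, sch)
  span <- ta$provenance[ta$provenance$feature == "pain_scale", ]
  outside <- setdiff(seq_along(ta$tokens), span$start:span$end)
  expect_identical(ta$tokens[outside], tb$tokens[outside])
  expect_false(identical(ta$tokens[span$start:span$end],
                         tb$tokens[span$start:span$end]))
})

test_that("parse_transcript inverts transform_record on random records", {
  sch <- default_triage_schema()
  co <- generate_cohort(200, sch, seed = 3)
  sentences <- transform_records(co$records, sch)
  for (i in seq_len(nrow(co$records))) {
    back <- parse_transcript(sentences[i], sch)
    for (f in sch$features)
      expect_identical(back[[f$name]], co$records[[f$name]][i], label = f$name)
  }
})

test_that("parse_transcript rejects malformed transcripts", {
  sch <- tiny_schema()
  tr <- transform_record(tiny_records()[1, ], sch)
  expect_error(parse_transcript(tr$tokens[-3], sch), "parse error")       # value deleted
  expect_error(parse_transcript(c(tr$tokens, "extra"), sch), "trailing")
  swapped <- tr$tokens
  swapped[1] <- "zzz"
  expect_error(parse_transcript(swapped, sch), "expected phrase")
})

test_that("vocabulary building is deterministic with reserved indices", {
  corp <- c("pain index 5 pain index 5", "pain index 3")
  v <- build_vocab(corp, min_count = 1L)
  expect_equal(v$size, length(unique(unlist(strsplit(corp, " ")))) + 2L)
  expect_equal(v$pad, 0L)
  expect_equal(v$unk, 1L)
  expect_true(all(v$table$index >= 2L))
  # frequency-descending then lexicographic
  expect_equal(v$table$token[1:2], c("index", "pain"))
  v2 <- build_vocab(corp, min_count = 1L)
  expect_identical(v$map, v2$map)

  # min_count above every frequency leaves only the reserved indices
  v3 <- build_vocab(corp, min_count = 100L)
  expect_equal(v3$size, 2L)
  expect_equal(nrow(v3$table), 0L)

  expect_error(build_vocab(character(0)), "empty corpus")
})

test_that("encoding pads, truncates, and maps unknowns to UNK", {
  v <- build_vocab("a b c d e")
  e1 <- encode(c("a", "b", "c", "d", "e"), v, max_len = 8L)
  expect_equal(e1$true_length, 5L)
  expect_equal(e1$ids[6:8], rep(0L, 3))
  expect_false(e1$truncated)

  e2 <- encode(rep(c("a", "b"), 5), v, max_len = 8L)
  expect_equal(e2$true_length, 8L)
  expect_true(e2$truncated)
  expect_length(e2$ids, 8L)

  e3 <- encode(c("zz", "qq"), v, max_len = 4L)
  expect_equal(e3$ids[1:2], c(1L, 1L))

  # true_length == min(len, max_len) over random cases
  set.seed(4)
  for (i in 1:25) {
    n <- sample(1:12, 1)
    ml <- sample(1:12, 1)
    e <- encode(sample(letters[1:5], n, replace = TRUE), v, max_len = ml)
    expect_equal(e$true_length, min(n, ml))
    expect_true(all(e$ids[seq_len(ml) > e$true_length] == 0L))
  }
})

test_that("encode_records reports truncation and carries labels", {
  v <- build_vocab("a b c")
  expect_message(
    enc <- encode_records(c("a b c a b c", "a b"), v, max_len = 4L,
                          labels = c(1L, 0L)),
    "truncated 1")
  expect_equal(dim(enc$ids), c(2L, 4L))
  expect_equal(enc$lengths, c(4L, 2L))
  expect_equal(enc$n_truncated, 1L)
  expect_equal(enc$labels, c(1L, 0L))
})
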