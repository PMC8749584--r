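test_that("schemas load from YAML and JSON with validation", {
  sch <- tiny_schema()
  yml <- tempfile(fileext = ".yaml")
  write_schema(sch, yml)
  sch2 <- load_schema(yml)
  expect_identical(schema_feature_names(sch2), schema_feature_names(sch))
  expect_identical(sch2$outcome, "admitted")
  expect_identical(sch2$features$temperature$precision, 1L)
  expect_identical(sch2$features$temperature$range, c(25, 45))

  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(yaml::read_yaml(yml), jsn, auto_unbox = TRUE, digits = NA)
  sch3 <- load_schema(jsn)
  expect_identical(schema_feature_names(sch3), schema_feature_names(sch))
})

test_that("the bundled survey-style schema covers the full 37-column record", {
  path <- system.file("extdata", "nhamcs_like_schema.yaml", package = "edtriage")
  sch <- load_schema(path)
  # 36 features plus the hospital-admission outcome column = 37 columns
  expect_length(sch$features, 36L)
  expect_identical(sch$outcome, "hospital_admission")
  expect_identical(sch$features[[1]]$name, "month")
  kinds <- vapply(sch$features, `[[`, character(1), "kind")
  expect_setequal(unique(kinds), c("continuous", "categorical", "binary"))
})

test_that("schema validation rejects malformed declarations", {
  f <- feature_spec("a", "continuous", precision = 0L)
  expect_error(feature_schema(list(f, f), outcome = "y"), "duplicate")
  expect_error(feature_schema(list(), outcome = "y"), "at least one")
  expect_error(feature_schema(list(f), outcome = "a"), "must not also be a feature")
  expect_error(feature_spec("x", "categorical", levels = c("one")), "2 distinct")
  expect_error(feature_spec("x", "categorical", levels = character()), "2 distinct")
  expect_error(feature_spec("x", "binary", levels = c("a", "b", "c")), "exactly 2")
  expect_error(feature_spec("x", "continuous", precision = -1), "precision")
  expect_error(feature_spec("x", "continuous", display = "  "), "nonempty")
})

test_that("read_visits types columns and marks unparseable cells missing", {
  sch <- tiny_schema()
  csv <- tempfile(fileext = ".csv")
  writeLines(c("visit_id,temperature,pain_scale,sex,admitted",
               "a,36.5,5,female,1",
               "b,abc,2,male,0",
               "c,37.0,9,unknownlevel,1"), csv)
  v <- read_visits(csv, sch)
  expect_equal(nrow(v), 3L)
  expect_true(is.na(v$temperature[2]))    # unparseable continuous cell
  expect_true(is.na(v$sex[3]))            # undeclared level
  expect_equal(v$admitted, c(1L, 0L, 1L))

  # outcome column absent -> prediction-only records, no label column
  csv2 <- tempfile(fileext = ".csv")
  writeLines(c("temperature,pain_scale,sex", "36.5,5,female"), csv2)
  v2 <- read_visits(csv2, sch)
  expect_false("admitted" %in% names(v2))

  # missing required header is an error naming the column
  csv3 <- tempfile(fileext = ".csv")
  writeLines(c("temperature,sex", "36.5,female"), csv3)
  expect_error(read_visits(csv3, sch), "pain_scale")
})

test_that("filter_records drops incomplete/out-of-range rows with per-feature accounting", {
  sch <- tiny_schema()
  rec <- tiny_records()[rep(1:3, length.out = 10), ]
  rec$visit_id <- as.character(1:10)
  rec$temperature[c(2, 5)] <- NA          # two missing vitals
  flt <- filter_records(rec, sch)
  expect_equal(nrow(flt$kept), 8L)
  expect_equal(unname(flt$report["temperature"]), 2L)
  expect_equal(nrow(flt$kept) + nrow(flt$dropped), nrow(rec))

  # all complete -> identity, all-zero report
  flt2 <- filter_records(tiny_records(), sch)
  expect_identical(flt2$kept, tiny_records())
  expect_true(all(flt2$report == 0L))

  # out-of-range temperature is unusable (schema range 25-45)
  rec3 <- tiny_records()
  rec3$temperature[1] <- 48.2
  flt3 <- filter_records(rec3, sch)
  expect_equal(nrow(flt3$kept), 2L)
  expect_equal(unname(flt3$report["temperature"]), 1L)
  expect_false("a" %in% flt3$kept$visit_id)

  # idempotence: filtering the kept set changes nothing
  again <- filter_records(flt$kept, sch)
  expect_identical(again$kept, flt$kept)
  expect_true(all(again$report == 0L))

  # a record failing several features increments each counter
  rec4 <- tiny_records()
  rec4$temperature[1] <- NA
  rec4$sex[1] <- NA
  flt4 <- filter_records(rec4, sch)
  expect_equal(unname(flt4$report["temperature"]), 1L)
  expect_equal(unname(flt4$report["sex"]), 1L)
  expect_equal(nrow(flt4$dropped), 1L)
})

test_that("visit tables round-trip through CSV exactly at schema precision", {
  sch <- default_triage_schema()
  co <- generate_cohort(50, sch, seed = 11)
  path <- tempfile(fileext = ".csv")
  write_visits(co$records, sch, path)
  back <- read_visits(path, sch)
  for (f in sch$features)
    expect_identical(back[[f$name]], co$records[[f$name]], label = f$name)
  expect_identical(back[[sch$outcome]], co$records[[sch$outcome]])
})
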