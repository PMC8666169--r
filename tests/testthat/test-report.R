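test_that("config validation collects every error with field paths", {
  ok <- validate_config("fixture: qrisk2\nformats: [markdown]\n")
  expect_s3_class(ok, "report_config")
  expect_equal(ok$fixture, "qrisk2")
  expect_equal(ok$population, 1000L)

  two <- validate_config("fixture: qrisk2\npredictions: x.csv\n")
  expect_s3_class(two, "config_errors")
  expect_match(two[1], "fixture.*predictions|multiple sources")

  multi <- validate_config(
    "fixture: nope\npopulation: -5\nformats: [pdf]\n")
  expect_s3_class(multi, "config_errors")
  expect_true(any(grepl("fixture", multi)))
  expect_true(any(grepl("population", multi)))
  expect_true(any(grepl("formats", multi)))

  bad_sum <- validate_config(
    "summary:\n  sensitivity: 1.4\n  specificity: 0.8\n  prevalence: 0.1\n")
  expect_true(any(grepl("summary\\[1\\]\\.sensitivity", bad_sum)))

  expect_s3_class(validate_config("formats: []\nfixture: csrs\n"),
                  "config_errors")
  expect_s3_class(validate_config("::not yaml::"), "config_errors")
})

test_that("json configs parse through the same validator", {
  cfg <- validate_config(
    '{"fixture": "qrisk2", "formats": ["csv"], "population": 500}')
  expect_s3_class(cfg, "report_config")
  expect_equal(cfg$population, 500L)
})

test_that("a fixture report narrates the counts it tabulates", {
  out <- withr::local_tempdir()
  bundle <- run_report("fixture: qrisk2\nformats: [svg, csv, markdown]\n",
                       out_dir = out, quiet = TRUE)
  nar <- bundle$narratives[[1]]
  expect_match(nar, "36 of 90")
  expect_match(nar, "146 are classified as at risk")
  expect_match(nar, "another\\s+3 will be flagged unnecessarily")

  # narrative numbers equal the table cells they came from
  t <- bundle$sweep$rows[[1]]$table
  expect_equal(c(t$tp, t$fp, t$fn, t$tn), c(36, 110, 54, 800))

  # re-deriving from the printed percentages instead is one rounding apart
  b2 <- run_report(
    "fixture: qrisk2\nsource: summaries\nformats: [csv]\n", quiet = TRUE)
  t2 <- b2$sweep$rows[[1]]$table
  expect_equal(c(t2$tp, t2$fp, t2$fn, t2$tn), c(36, 109, 54, 801))

  files <- list.files(out)
  expect_true("sweep.csv" %in% files)
  expect_true("report.md" %in% files)
  expect_true(any(grepl("^diagram-.*\\.svg$", files)))
})

test_that("a report config with invalid formats refuses to run", {
  expect_error(run_report("fixture: csrs\nformats: []\n", quiet = TRUE),
               "formats")
})

test_that("the csrs report shades one icon per event", {
  bundle <- run_report("fixture: csrs\nsource: summaries\nformats: [svg]\n",
                       quiet = TRUE)
  style <- nf_style()
  # diagram-caption specificity variant
  svg <- bundle$diagrams[["low risk (diagram specificity)"]]
  shaded <- sum(gregexpr(paste0('fill="', style$event_col, '"'),
                         svg, fixed = TRUE)[[1]] > 0)
  expect_equal(shaded, 36 + 2)   # 36 events + 2 legend swatches
})

test_that("identical configs produce byte-identical artifacts", {
  cfg <- "fixture: csrs\nformats: [svg, csv, markdown, html]\n"
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run_report(cfg, out_dir = out1, quiet = TRUE)
  run_report(cfg, out_dir = out2, quiet = TRUE)
  f1 <- sort(list.files(out1))
  expect_identical(f1, sort(list.files(out2)))
  for (f in f1) {
    expect_identical(readBin(file.path(out1, f), "raw", 1e7),
                     readBin(file.path(out2, f), "raw", 1e7),
                     label = f)
  }
})

test_that("prediction-driven reports run end to end", {
  d <- simulate_scores(300, 0.2, 0.85, seed = 3)
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, csv, row.names = FALSE)
  cfg <- sprintf(
    "predictions: %s\ncutpoints: [0.1, 0.2, 0.4]\nformats: [csv]\n", csv)
  bundle <- run_report(cfg, quiet = TRUE)
  expect_length(bundle$sweep$rows, 3)
  expect_equal(bundle$sweep$rows[[1]]$table$population, 300)
})
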