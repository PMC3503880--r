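responder_config <- function() {
  system.file("extdata", "config_responder.json", package = "smrdetect")
}
null_config <- function() {
  system.file("extdata", "config_null.json", package = "smrdetect")
}

test_that("config validation fills defaults and rejects malformed input", {
  cfg <- validate_config(list(seed = 3))
  expect_equal(cfg$preprocess$target_rate, 100)
  expect_equal(cfg$spectral$cluster_alpha, 0.0125)
  expect_equal(cfg$classify$alpha, 0.025)
  expect_error(validate_config(list(bogus_key = 1)), class = "smr_config_error")
  expect_error(validate_config(list(classify = list(alpha = 2))),
               class = "smr_config_error")
  expect_error(validate_config(list(classify = list(bands = list("gamma")))),
               class = "smr_config_error")
})

test_that("responder demo: significant cluster and classification; null demo: neither", {
  out <- withr::local_tempdir()
  rep_r <- run_pipeline(responder_config(), out_dir = out)
  left <- rep_r$comparisons$left_vs_rest
  expect_gte(left$n_significant_clusters, 1)
  expect_gte(left$n_significant_timepoints, 1)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "report.md")))
  expect_true(file.exists(file.path(out, "classification_left.json")))

  rep_n <- run_pipeline(null_config())
  for (comp in rep_n$comparisons) {
    expect_equal(comp$n_significant_clusters, 0)
    expect_equal(comp$n_significant_timepoints, 0)
  }
})

test_that("pipeline reruns are byte-identical; report regenerates identically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_pipeline(responder_config(), out_dir = d1)
  run_pipeline(responder_config(), out_dir = d2)
  for (f in c("report.json", "clusters_left.json", "classification_left.json",
              "report.md")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  orig_md <- readLines(file.path(d1, "report.md"))
  regenerate_report(d1)
  expect_identical(readLines(file.path(d1, "report.md")), orig_md)
})

test_that("accuracy formatting follows the '67% (1250 ms)*' convention", {
  fmt <- smrdetect:::format_acc
  expect_equal(fmt(0.67, 1250, TRUE), "67% (1250 ms)*")
  expect_equal(fmt(0.67, 1250, FALSE), "67% (1250 ms)")
  expect_equal(fmt(0.505, -1000, FALSE), "50% (-1000 ms)")
})

test_that("tabulate_results reflects the report's maxima and stars", {
  report <- structure(list(comparisons = list(
    left_vs_rest = list(max_smoothed = 0.67, max_smoothed_time_ms = 1250,
                        max_unsmoothed = 0.74, max_unsmoothed_time_ms = 1150,
                        significant = TRUE, n_significant_clusters = 1L),
    right_vs_rest = list(max_smoothed = 0.59, max_smoothed_time_ms = 900,
                         max_unsmoothed = 0.68, max_unsmoothed_time_ms = 550,
                         significant = FALSE, n_significant_clusters = 0L))),
    class = "assessment_report")
  tab <- tabulate_results(report)
  expect_equal(tab$max_smoothed, c("67% (1250 ms)*", "59% (900 ms)"))
  expect_equal(tab$max_unsmoothed, c("74% (1150 ms)", "68% (550 ms)"))
})

test_that("CLI dispatch: simulate writes a readable recording; errors map to exit codes", {
  tmp <- withr::local_tempdir()
  cfgp <- file.path(tmp, "cfg.json")
  jsonlite::write_json(list(seed = 7, simulate = list(n_blocks = 1,
                                                      artifact_rate = 0)),
                       cfgp, auto_unbox = TRUE)
  out <- file.path(tmp, "rec.csv")
  expect_equal(cli_main(c("simulate", "--config", cfgp, "--out", out)), 0L)
  rec <- read_recording(out, "csv", srate = 256)
  expect_equal(nrow(rec$events), 36)

  bad <- file.path(tmp, "bad.json")
  jsonlite::write_json(list(bogus = 1), bad, auto_unbox = TRUE)
  expect_equal(cli_main(c("simulate", "--config", bad, "--out", out)), 2L)
  expect_equal(cli_main(c("frobnicate")), 64L)
  expect_equal(cli_main(character(0)), 64L)
})
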