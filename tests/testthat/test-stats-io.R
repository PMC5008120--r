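test_that("rare/common ratio handles extinct alleles under both conventions", {
  expect_equal(rare_common_ratio(c(50, 50)), 1)
  expect_equal(rare_common_ratio(c(10, 40)), 0.25)
  expect_equal(rare_common_ratio(c(0, 30, 10)), 1 / 3)
  expect_equal(rare_common_ratio(c(0, 30, 10), include_extinct = TRUE), 0)
  expect_error(rare_common_ratio(c(0, 0)), "all zero")
  expect_error(rare_common_ratio(c(-1, 3)), "non-negative")
})

test_that("Wilson intervals match an independent reference and bound the estimate", {
  expect_equal(wilson_interval(0, 10)[["lower"]], 0)
  expect_equal(wilson_interval(10, 10)[["upper"]], 1)
  # reference values computed with an independent published implementation
  expect_equal(unname(wilson_interval(5, 10, 0.95)),
               c(0.2365931, 0.7634069), tolerance = 1e-6)
  expect_equal(unname(wilson_interval(3, 17, 0.95)),
               c(0.0619113, 0.4102946), tolerance = 1e-6)
  for (s in c(0, 1, 7, 20)) {
    ci <- wilson_interval(s, 20)
    expect_true(ci[["lower"]] <= s / 20 && s / 20 <= ci[["upper"]])
  }
  expect_error(wilson_interval(5, 4), "successes")
})

test_that("tables round-trip numeric values at full precision", {
  df <- data.frame(round = 0:2, ratio = c(1, 1 / 3, 0.123456789012345))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(df, path)
  lines <- readLines(path)
  expect_identical(lines[[1]], "round\tratio")
  back <- read.delim(path)
  expect_equal(back$ratio, df$ratio, tolerance = 1e-14)
})

test_that("config files parse, reject unknown keys, and respect defaults", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# experiment base", "N = 40", "g = 7",
               "mating_mode = speedy", "seed = 9"), path)
  p <- read_config(path)
  expect_identical(p$N, 40L)
  expect_identical(p$g, 7L)
  expect_identical(p$mating_mode, "speedy")
  expect_identical(p$m, 2L)     # untouched fields keep documented defaults
  expect_identical(p$c, 0)

  writeLines("bogus_key = 3", path)
  expect_error(read_config(path), "bogus_key")
  writeLines("N = -5", path)
  expect_error(read_config(path), "'N'", class = "switchsim_validation_error")

  writeLines("seed = 123", path)
  p2 <- read_config(path)
  expect_identical(p2$seed, 123L)
  expect_identical(p2$N, .subset2(lifecycle_params(), "N"))
})

test_that("config overrides take precedence over file values", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("N = 40", "g = 7"), path)
  p <- read_config(path, overrides = list(N = 20))
  expect_identical(p$N, 20L)
  expect_identical(p$g, 7L)
})

test_that("run manifests round-trip through JSON", {
  params <- lifecycle_params(N = 30, g = 3, seed = 5)
  man <- run_manifest(params, "fixation", 200,
                      extra = list(mutant_ps = 0.5))
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(man, path)
  back <- read_manifest(path)
  expect_identical(back$harness, "fixation")
  expect_equal(back$parameters$N, 30)
  expect_equal(back$parameters$g, 3)
  expect_equal(back$replicates, 200)
  expect_equal(back$settings$mutant_ps, 0.5)
})
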