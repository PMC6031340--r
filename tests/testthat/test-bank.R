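# Bank construction and classification use shorter records (1 s) and two
# volumes where four are not needed, to keep the suite fast; the full
# four-volume experiment is exercised in test-acceptance.R.

two_volumes <- list(bladder_spec(2, "small"), bladder_spec(4, "large"))

test_that("bank construction stores one entry per volume with unique labels", {
  bank <- build_bank(default_volumes(), growl_spec(), default_env,
                     duration = 1, method = "demod")
  expect_length(bank$entries, 4L)
  expect_identical(vapply(bank$entries, `[[`, character(1), "label"),
                   c("R1.5cm", "R2cm", "R3cm", "R4cm"))
  dup <- list(bladder_spec(2, "a"), bladder_spec(3, "a"))
  expect_error(build_bank(dup, growl_spec(), default_env, method = "demod"),
               "duplicate")
  expect_error(build_bank(list(), growl_spec(), default_env), "at least one")
})

test_that("bank building is deterministic given the seeds", {
  b1 <- build_bank(two_volumes, growl_spec(), default_env, duration = 1,
                   method = "demod")
  b2 <- build_bank(two_volumes, growl_spec(), default_env, duration = 1,
                   method = "demod")
  expect_identical(b1$entries[[1]]$feature$values,
                   b2$entries[[1]]$feature$values)
  c1 <- build_bank(two_volumes, growl_spec(), default_env, duration = 1,
                   method = "cyclo")
  c2 <- build_bank(two_volumes, growl_spec(), default_env, duration = 1,
                   method = "cyclo")
  expect_equal(c1$entries[[2]]$feature$values, c2$entries[[2]]$feature$values,
               tolerance = 1e-12)
})

test_that("a single-volume bank always returns its only label", {
  bank <- build_bank(list(bladder_spec(3, "only")), growl_spec(), default_env,
                     duration = 1, method = "demod")
  src <- generate_growl(growl_spec(seed = 999), duration = 1)
  rec <- transmit_through_volume(src, bladder_spec(1.5), default_env, 185)
  rep <- classify(rec, bank)
  expect_identical(rep$best_label, "only")
  expect_true(is.na(rep$margin))
})

test_that("template source records classify to their own label", {
  for (method in c("demod", "cyclo")) {
    bank <- build_bank(two_volumes, growl_spec(), default_env, duration = 1,
                       method = method)
    src <- generate_growl(growl_spec(), duration = 1)
    rec <- transmit_through_volume(src, two_volumes[[1]], default_env, 185)
    rep <- classify(rec, bank)
    expect_identical(rep$best_label, "small")
    expect_gt(rep$margin, 0)
  }
})

test_that("classification is invariant to global input gain", {
  for (method in c("demod", "cyclo")) {
    bank <- build_bank(two_volumes, growl_spec(), default_env, duration = 1,
                       method = method)
    src <- generate_growl(growl_spec(seed = 777), duration = 1)
    rec <- transmit_through_volume(src, two_volumes[[2]], default_env, 185)
    rec10 <- acoustic_record(10 * rec$samples, rec$fs)
    r1 <- classify(rec, bank)
    r2 <- classify(rec10, bank)
    expect_identical(r2$best_label, r1$best_label)
    expect_equal(r2$table$peak, r1$table$peak, tolerance = 1e-9)
  }
})

test_that("classification margin degrades as the input gets noisier", {
  bank <- build_bank(default_volumes(), growl_spec(), default_env,
                     method = "demod")
  vol <- default_volumes()[[3]]
  median_margin <- function(snr) {
    stats::median(vapply(1:11, function(k) {
      gs <- growl_spec(snr_db = snr, seed = 5000L + k)
      rec <- transmit_through_volume(generate_growl(gs), vol, default_env, 185)
      classify(rec, bank)$margin
    }, numeric(1)))
  }
  meds <- vapply(c(30, 0, -10, -20), median_margin, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("classify rejects incompatible inputs with the failing stage named", {
  bank <- build_bank(two_volumes, growl_spec(), default_env, duration = 1,
                     method = "demod")
  expect_error(classify(acoustic_record(rnorm(100), 8000), bank),
               "sampling rate")
  expect_error(
    suppressWarnings(classify(acoustic_record(numeric(10000), 10000), bank)),
    "failed")
})

test_that("template banks round-trip through the tabular serialization", {
  for (method in c("demod", "cyclo")) {
    bank <- build_bank(two_volumes, growl_spec(), default_env, duration = 1,
                       method = method)
    path <- withr::local_tempfile(fileext = ".txt")
    write_bank(bank, path)
    back <- read_bank(path)
    expect_identical(back$method, method)
    for (i in seq_along(bank$entries)) {
      expect_identical(back$entries[[i]]$label, bank$entries[[i]]$label)
      expect_equal(unname(back$entries[[i]]$feature$values),
                   unname(bank$entries[[i]]$feature$values),
                   tolerance = 1e-12)
    }
    src <- generate_growl(growl_spec(seed = 321), duration = 1)
    rec <- transmit_through_volume(src, two_volumes[[1]], default_env, 185)
    expect_identical(classify(rec, back)$best_label,
                     classify(rec, bank)$best_label)
  }
})

test_that("experiment configs are validated field-by-field", {
  cfg <- default_experiment_config()
  cfg$volumes[[2]]$radius <- NULL
  expect_error(read_experiment_config(cfg), "volumes\\[2\\]: missing field 'radius'")
  cfg2 <- default_experiment_config()
  cfg2$forcing_frequency <- NULL
  expect_error(read_experiment_config(cfg2), "missing field 'forcing_frequency'")
  cfg3 <- default_experiment_config()
  cfg3$methods <- c("demod", "nope")
  expect_error(read_experiment_config(cfg3), "subset")
})

test_that("a reduced experiment runs end to end and writes its reports", {
  cfg <- default_experiment_config()
  cfg$volumes <- cfg$volumes[1:2]
  cfg$duration <- 1
  cfg$methods <- "demod"
  out <- withr::local_tempdir()
  res <- run_experiment(cfg, output_dir = out, verbose = FALSE)
  expect_equal(nrow(res$report), 2L)
  expect_true(all(res$report$correct))
  expect_true(file.exists(file.path(out, "report.csv")))
  expect_true(file.exists(file.path(out, "correlations_demod.csv")))
  expect_true(file.exists(file.path(out, "summary.txt")))
  expect_true(file.exists(file.path(out, "resolved_config.yaml")))
  # reproducible bit-for-bit under fixed seeds
  res2 <- run_experiment(cfg, verbose = FALSE)
  expect_identical(res2$report, res$report)
  expect_identical(res2$correlations, res$correlations)
})
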