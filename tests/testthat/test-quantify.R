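test_that("calibration on a perfect line is exact with zero LOD", {
  cc <- fit_calibration(data.frame(concentration = c(1, 2, 4),
                                   area = c(10, 20, 40)))
  expect_equal(cc$slope, 10)
  expect_equal(cc$intercept, 0)
  expect_equal(cc$r_squared, 1)
  expect_equal(cc$lod, 0)
  expect_equal(cc$loq, 0)
})

test_that("LOQ is exactly 10/3 of LOD for any fit", {
  set.seed(8)
  for (i in 1:20) {
    conc <- 100 / 2^(0:9)
    area <- 5e4 * conc + rnorm(10, 0, 2e3)
    cc <- fit_calibration(data.frame(concentration = conc, area = area))
    expect_equal(cc$loq / cc$lod, 10 / 3, tolerance = 1e-12)
    expect_equal(cc$lod, 3 * summary(cc$fit)$sigma / cc$slope)
  }
})

test_that("calibration input validation rejects degenerate designs", {
  expect_error(fit_calibration(data.frame(concentration = c(1, 1, 1),
                                          area = c(1, 2, 3))), "distinct")
  expect_error(fit_calibration(data.frame(concentration = c(0, 1, 2),
                                          area = c(0, 1, 2))), "> 0")
  expect_error(fit_calibration(data.frame(concentration = c(1, 2),
                                          area = c(1, 2))), "at least 3")
})

test_that("blank-derived SD is honored when requested", {
  pts <- data.frame(concentration = c(1, 2, 4), area = c(10, 20, 40))
  cc <- fit_calibration(pts, sd_source = "blank", blank_sd = 3)
  expect_equal(cc$lod, 3 * 3 / 10)
  expect_error(fit_calibration(pts, sd_source = "blank"), "blank_sd")
})

test_that("simulated dilution series recovers the response factor as slope", {
  panel <- fu_panel()
  study <- simulate_study(
    study_design(n_replicates = 1, include_untreated = FALSE,
                 include_qc = FALSE, include_blank = FALSE),
    matrix = matrix_spec(),               # noiseless
    acq = acquisition_params(mz_sd_ppm = 0),
    seed = 41, response_factor = 2e5)
  cc <- calibrate_study(study$runs, study$sample_sheet, panel[["FdUMP"]])
  # total area = precursor + 4 fragments at default yield 0.2
  expect_equal(cc$slope, 2e5 * 1.8, tolerance = 1e-3)
  expect_gt(cc$r_squared, 0.9999)
})

test_that("normalization is a plain ratio and invariant to batch-wide scaling", {
  expect_equal(normalize_to_reference(500, 1000), 0.5)
  expect_equal(normalize_to_reference(1000, 1000), 1.0)
  expect_error(normalize_to_reference(1, 0), "positive")
  k <- 3.7
  expect_equal(normalize_to_reference(k * 500, k * 1000),
               normalize_to_reference(500, 1000))
})

test_that("group comparison handles identical, separated and degenerate input", {
  same <- compare_groups(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  set.seed(10)
  sep <- compare_groups(c(1, 1, 1) + rnorm(3, 0, 1e-4),
                        c(2, 2, 2) + rnorm(3, 0, 1e-4))
  expect_lt(sep$p_value, 0.01)
  expect_equal(sep$fold_change, 2, tolerance = 1e-3)
  # sem = sd/sqrt(n)
  g <- c(1, 2, 3, 4)
  cmp <- compare_groups(g, g + 1)
  expect_equal(cmp$sem_a, sd(g) / 2)
  # matches stats::t.test wholesale
  ht <- t.test(g, g + 2, var.equal = TRUE)
  cmp2 <- compare_groups(g, g + 2)
  expect_equal(cmp2$t, unname(ht$statistic))
  expect_equal(cmp2$p_value, ht$p.value)
})

test_that("type-I error of the pooled t-test is nominal under the null", {
  # null draws mimic the study's biological scatter model
  set.seed(1234)
  n <- 10; reps <- 1000
  sdlog <- sqrt(log(1 + 0.2^2))
  rejections <- 0L
  for (i in seq_len(reps)) {
    a <- rlnorm(n, -sdlog^2 / 2, sdlog)
    b <- rlnorm(n, -sdlog^2 / 2, sdlog)
    if (compare_groups(a, b)$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / reps, 0.03)
  expect_lt(rejections / reps, 0.07)
})

test_that("study summary flags reduced compounds and below-detection species", {
  study <- simulate_study(study_design(n_replicates = 3), seed = 11)
  res <- analyze_study(study$runs, study$sample_sheet)
  s <- res$summary
  row <- function(cp) s[s$compound == cp, ]
  expect_equal(row("FUTP")$status, "below detection")
  expect_equal(row("FdUTP")$status, "below detection")
  expect_true(is.na(row("FUTP")$p_value))
  expect_equal(row("FdUMP")$status, "quantified")
  expect_true(row("FdUMP")$significant)
  expect_lt(row("FdUMP")$fold_change, 1)
  expect_equal(row("dUMP")$status, "quantified")
  expect_equal(row("dUMP")$n_parental, 3)
  # sem columns populated for tested rows
  expect_true(is.finite(row("FURD")$sem_parental))
})

test_that("summary drops non-detects from testing instead of imputing zero", {
  sheet <- data.frame(
    sample_id = paste0("s", 1:8),
    group = rep(c("parental", "resistant"), each = 4),
    treatment = "treated", matrix = "lysate",
    replicate = rep(1:4, 2), role = "test",
    calibrant_concentration = NA_real_)
  meas <- data.frame(sample_id = paste0("s", 1:8), compound = "X",
                     detected = c(TRUE, TRUE, TRUE, FALSE,
                                  TRUE, TRUE, TRUE, TRUE),
                     ratio = c(1, 1.1, 0.9, NA, 0.5, 0.55, 0.45, 0.5))
  s <- summarize_study(meas, sheet)
  expect_equal(s$n_parental, 3L)
  expect_equal(s$n_resistant, 4L)
  expect_equal(s$mean_parental, 1, tolerance = 1e-9)
})
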