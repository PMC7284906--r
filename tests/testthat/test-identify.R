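panel <- fu_panel()

sim_pair <- function(compounds, conc, seed, control_compounds = character(0),
                     baseline = 200) {
  mk <- function(nms) lapply(nms, function(nm) analyte_spec(panel[[nm]], conc))
  treated <- simulate_run(mk(compounds), matrix_spec(baseline = baseline),
                          targets = panel, seed = seed, sample_id = "treated")
  control <- simulate_run(mk(control_compounds),
                          matrix_spec(baseline = baseline),
                          targets = panel, seed = seed + 1,
                          sample_id = "control")
  list(treated = treated$run, control = control$run)
}

test_that("treatment-derived analytes are detected against a clean control", {
  p <- sim_pair("FURD", conc = 2, seed = 31)
  d <- detect_compound(p$treated, p$control, panel[["FURD"]])
  expect_true(d$detected)
  expect_false(d$control_veto)
  expect_gte(d$n_fragments_present, 1L)
  expect_gt(d$total_area, 0)
})

test_that("a matching signal in the untreated control vetoes the call", {
  p <- sim_pair("FURD", conc = 2, seed = 32, control_compounds = "FURD")
  d <- detect_compound(p$treated, p$control, panel[["FURD"]])
  expect_true(d$control_veto)
  expect_false(d$detected)
})

test_that("absent compounds and missing fragments are not detected", {
  p <- sim_pair("FURD", conc = 2, seed = 33)
  d <- detect_compound(p$treated, p$control, panel[["FdUMP"]])
  expect_false(d$detected)
  # precursor present but MS2 never acquired: strip the MS2 scans
  ms1_only <- ms_run(Filter(function(s) s$ms_level == 1L, p$treated$spectra),
                     sample_id = "ms1only")
  d2 <- detect_compound(ms1_only, NULL, panel[["FURD"]])
  expect_false(d2$detected)
  expect_false(is.null(d2$precursor))
  expect_equal(d2$n_fragments_present, 0L)
})

test_that("detection is reliable across seeded noisy simulations", {
  for (seed in 1:10) {
    p <- sim_pair(c("FdUMP", "5-FU"), conc = 1.5, seed = 100 + seed,
                  control_compounds = "5-FU")
    expect_true(detect_compound(p$treated, p$control, panel[["FdUMP"]])$detected)
    expect_true(detect_compound(p$treated, p$control, panel[["5-FU"]])$control_veto)
    expect_false(detect_compound(p$treated, p$control, panel[["FURD"]])$detected)
  }
})

test_that("isotope score is 100 on exact agreement and 0 without the monoisotopic peak", {
  pat <- isotope_pattern(panel[["FdUMP"]]$composition, adduct = "[M-H]-")
  measured <- data.frame(mz = pat$mz, intensity = pat$abundance * 5e5)
  expect_equal(isotope_pattern_score(measured, pat), 100)
  # uniform intensity scaling leaves the score unchanged
  scaled <- measured; scaled$intensity <- scaled$intensity * 37.5
  expect_equal(isotope_pattern_score(scaled, pat),
               isotope_pattern_score(measured, pat))
  # drop the monoisotopic peak
  expect_equal(isotope_pattern_score(measured[-1, ], pat), 0)
})

test_that("simulated envelopes at instrument-level mass error score high", {
  a <- analyte_spec(panel[["FdUMP"]], 5, rt_jitter_sd = 0, response_factor = 1e6)
  sim <- simulate_run(list(a), matrix_spec(), targets = panel, seed = 17)
  # pull the apex SIM scan for the FdUMP window
  sims <- Filter(function(s) s$ms_level == 1L &&
                   !is.null(s$sim_window) &&
                   abs(mean(as.numeric(s$sim_window)) - 325.024) < 0.1,
                 sim$run$spectra)
  apex <- sims[[which.max(vapply(sims, function(s) sum(s$intensity), 0))]]
  pat <- isotope_pattern(panel[["FdUMP"]]$composition, adduct = "[M-H]-")
  score <- isotope_pattern_score(data.frame(mz = apex$mz,
                                            intensity = apex$intensity), pat)
  expect_gt(score, 90)
})

test_that("fragment validation explains the FdUMP fingerprint with small deviation", {
  v <- validate_fragments(panel[["FdUMP"]], c(195.006, 129.01, 96.969, 78.959),
                          tol = 10)
  expect_equal(v$n_explained, 4L)
  expect_equal(v$fragment_score, 100)
  expect_lt(abs(v$median_ppm), 5)
  expect_true(v$pass_5ppm)
})

test_that("impossible fragments and empty observations degrade gracefully", {
  v <- validate_fragments(panel[["5-FU"]], 600.0, tol = 10)
  expect_equal(v$n_explained, 0L)
  expect_equal(v$fragment_score, 0)
  expect_true(is.na(v$median_ppm))
  v0 <- validate_fragments(panel[["5-FU"]], numeric(0))
  expect_equal(v0$fragment_score, 0)
  expect_true(is.na(v0$median_ppm))
})

test_that("validation deviation on simulated fragments stays within twice the m/z error", {
  # a target whose fragment list carries exact subformula anion masses,
  # so the only deviation left is the simulator's 1 ppm mass error
  e_mass <- 0.000548579909065
  exact <- vapply(c("C5H8O6P", "C4H2FN2O2", "H2O4P", "O3P"),
                  function(f) monoisotopic_mass(f) + e_mass, 0)
  tg <- target_compound("FdUMP", "C9H12FN2O8P", fragments = unname(exact),
                        expected_rt = 1.4)
  a <- analyte_spec(tg, 5, rt_jitter_sd = 0)
  sim <- simulate_run(list(a), matrix_spec(), targets = list(FdUMP = tg),
                      seed = 23, acq = acquisition_params(mz_sd_ppm = 1))
  ms2 <- Filter(function(s) s$ms_level == 2L, sim$run$spectra)
  apex <- ms2[[which.max(vapply(ms2, function(s) max(s$intensity), 0))]]
  v <- validate_fragments(tg, apex$mz, tol = 10)
  expect_equal(v$n_explained, length(apex$mz))
  expect_lt(abs(v$median_ppm), 2)
  # with the printed fingerprint values the deviation still sits inside
  # the 5 ppm acceptance gate
  vp <- validate_fragments(panel[["FdUMP"]], panel[["FdUMP"]]$fragments,
                           tol = 10)
  expect_true(vp$pass_5ppm)
})
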