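# runs built by hand, one scan per time point
xic_run <- function(rts, peaklists, window = NULL) {
  ms_run(lapply(seq_along(rts), function(i) {
    ms_spectrum(1L, rts[i], peaklists[[i]]$mz, peaklists[[i]]$intensity,
                sim_window = window)
  }))
}

test_that("XIC extraction sums centroids inside the window per scan", {
  run <- ms_run(list(
    ms_spectrum(1L, 1.0, c(129.0106, 130.5), c(5000, 70)),
    ms_spectrum(1L, 1.1, c(128.0, 129.0107), c(11, 2500))))
  w <- ppm_window(129.0106, 5)
  xic <- extract_xic(run, w, ms_level = 1L)
  expect_equal(xic$rt, c(1.0, 1.1))
  expect_equal(xic$intensity, c(5000, 2500))
  # disjoint window gives explicit zero points, not an empty trace
  far <- extract_xic(run, ppm_window(200, 5), ms_level = 1L)
  expect_equal(far$intensity, c(0, 0))
})

test_that("SIM scans only contribute to windows they isolate", {
  run <- ms_run(list(
    ms_spectrum(1L, 1.0, 129.0106, 100, sim_window = sim_window(129.0109, 4)),
    ms_spectrum(1L, 1.1, 325.0242, 900, sim_window = sim_window(325.024, 4))))
  xic <- extract_xic(run, ppm_window(129.0106, 5), ms_level = 1L)
  expect_equal(nrow(xic), 1L)
  expect_equal(xic$intensity, 100)
})

test_that("MS2 extraction is restricted to matching precursor targets", {
  run <- ms_run(list(
    ms_spectrum(2L, 1.0, 96.9691, 500, precursor = 325.024),
    ms_spectrum(2L, 1.1, 96.9691, 400, precursor = 307.033)))
  xic <- extract_xic(run, ppm_window(96.9691, 10), ms_level = 2L,
                     precursor_filter = 325.024)
  expect_equal(nrow(xic), 1L)
  expect_equal(xic$intensity, 500)
  # no filter given: nothing qualifies
  expect_equal(nrow(extract_xic(run, ppm_window(96.9691, 10), ms_level = 2L)), 0L)
})

test_that("doubling intensities doubles every integrated area", {
  xic <- gaussian_xic(1000, 1.5, 0.05)
  x2 <- xic; x2$intensity <- 2 * x2$intensity
  b <- c(1.3, 1.7)
  expect_equal(integrate_peak(x2, b), 2 * integrate_peak(xic, b))
})

test_that("peak detection finds clean Gaussians and ignores flat traces", {
  flat <- gaussian_xic(0, 1.5, 0.05)
  expect_equal(nrow(detect_peaks(flat)), 0L)
  one <- gaussian_xic(1000, 1.5, 0.05)
  pk <- detect_peaks(one)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$apex_rt, 1.5, tolerance = 0.011)  # one sample spacing
  two <- gaussian_xic(1000, 1.3, 0.03)
  two$intensity <- two$intensity + 800 * exp(-(two$rt - 1.9)^2 / (2 * 0.03^2))
  pk2 <- detect_peaks(two)
  expect_equal(nrow(pk2), 2L)
  expect_equal(sort(pk2$apex_rt), c(1.3, 1.9), tolerance = 0.011)
  # ranked by area descending
  expect_true(all(diff(pk2$area) <= 0))
})

test_that("trapezoidal integration matches closed forms", {
  # rectangle: height 100 over 1 minute, integrated from baseline to
  # baseline (the step edges add ~1% under the trapezoid rule)
  rect <- data.frame(rt = seq(0, 2, by = 0.01),
                     intensity = ifelse(seq(0, 2, by = 0.01) >= 0.5 &
                                        seq(0, 2, by = 0.01) <= 1.5, 100, 0))
  class(rect) <- c("tq_xic", "data.frame")
  expect_equal(integrate_peak(rect, c(0.45, 1.55)), 100, tolerance = 0.02)
  # all-zero trace integrates to zero
  zero <- gaussian_xic(0, 1, 0.05)
  expect_equal(integrate_peak(zero, c(0.5, 1.5)), 0)
  expect_error(integrate_peak(zero, c(1.5, 0.5)), "inverted")
  expect_error(integrate_peak(zero, c(-1, 1)), "outside")
})

test_that("noiseless Gaussians integrate to their analytic area within 1%", {
  set.seed(42)
  for (i in 1:100) {
    amp <- runif(1, 100, 1e6)
    sigma <- runif(1, 0.02, 0.08)
    mu <- runif(1, 0.8, 2.2)
    xic <- gaussian_xic(amp, mu, sigma, rt = seq(0, 3, by = 0.005))
    got <- integrate_peak(xic, c(mu - 4 * sigma, mu + 4 * sigma))
    expect_equal(got, amp * sigma * sqrt(2 * pi), tolerance = 0.01)
  }
})

test_that("fragment evidence requires co-elution with the precursor apex", {
  # MS1 precursor peak at 1.5 plus MS2 fragment traces
  rts <- seq(1.2, 1.8, by = 0.01)
  spectra <- list()
  for (t in rts) {
    inten <- 1e5 * exp(-(t - 1.5)^2 / (2 * 0.04^2))
    spectra[[length(spectra) + 1L]] <-
      ms_spectrum(1L, t, 325.0242, inten, sim_window = sim_window(325.024, 4))
    # co-eluting fragment at 96.969, displaced spike at 78.959
    fmz <- c(78.9590, 96.9691)
    fint <- c(5e4 * exp(-(t - 1.26)^2 / (2 * 0.01^2)),
              0.3 * inten)
    keep <- fint > 1
    if (any(keep)) {
      spectra[[length(spectra) + 1L]] <-
        ms_spectrum(2L, t + 0.004, fmz[keep], fint[keep], precursor = 325.024)
    }
  }
  run <- ms_run(spectra, sample_id = "frag")
  target <- fu_panel()[["FdUMP"]]
  xic <- extract_xic(run, ppm_window(target$precursor_mz, 5), 1L)
  pk <- detect_peaks(xic)[1, ]
  ev <- collect_fragment_evidence(run, target, pk)
  ev96 <- ev[abs(ev$fragment_mz - 96.969) < 0.01, ]
  ev78 <- ev[abs(ev$fragment_mz - 78.959) < 0.01, ]
  expect_true(ev96$present)
  expect_false(ev78$present)   # spike far from the precursor apex
  # fragments with no MS2 signal at all are absent
  ev195 <- ev[abs(ev$fragment_mz - 195.006) < 0.01, ]
  expect_false(ev195$present)
})
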