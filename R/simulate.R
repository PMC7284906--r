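# Ground-truth simulator of tSIM-ddMS2 acquisitions.
#
# The instrument model: each duty cycle emits one MS1 SIM scan per
# inclusion-list target (narrow isolation window around the precursor),
# followed by data-dependent MS2 scans for up to loop_count targets
# whose precursor signal exceeds the trigger threshold. Analytes elute
# as Gaussian profiles; the manifest records the exact areas and apex
# times, so downstream extraction and quantification can be checked
# against closed-form truth.

#' Acquisition parameters for the simulator
#'
#' Defaults mirror a high-resolution Orbitrap tSIM-ddMS2 method: 4.0 m/z
#' SIM isolation windows, data-dependent HCD MS2 with a loop count of 4,
#' and a duty cycle of 0.01 min. The simulated RT range covers the
#' elution window of the polar panel (all targets elute between 1.4 and
#' 2.1 min on the F5 column).
#'
#' @param rt_min,rt_max Acquisition RT range in minutes.
#' @param cycle_time Duty cycle in minutes.
#' @param isolation_width MS1 SIM isolation width in m/z.
#' @param ms2_isolation MS2 isolation width in m/z.
#' @param trigger_threshold Precursor intensity above which an MS2 scan
#'   is triggered.
#' @param loop_count Maximum MS2 scans per duty cycle.
#' @param mz_sd_ppm Gaussian m/z error SD in ppm (instrument mass
#'   accuracy; default 1 ppm).
#' @param nce Normalized collision energy label attached to MS2 scans.
#' @return A named list.
#' @export
acquisition_params <- function(rt_min = 1.0, rt_max = 2.6, cycle_time = 0.01,
                               isolation_width = 4.0, ms2_isolation = 1.2,
                               trigger_threshold = 1e4, loop_count = 4L,
                               mz_sd_ppm = 1, nce = 25) {
  stopifnot(rt_min < rt_max, cycle_time > 0, isolation_width > 0)
  list(rt_min = rt_min, rt_max = rt_max, cycle_time = cycle_time,
       isolation_width = isolation_width, ms2_isolation = ms2_isolation,
       trigger_threshold = trigger_threshold, loop_count = as.integer(loop_count),
       mz_sd_ppm = mz_sd_ppm, nce = nce)
}

#' Specify a simulated analyte
#'
#' @param target A `target_compound`.
#' @param concentration Concentration in ng/uL (>= 0).
#' @param expected_rt Elution apex in minutes; defaults to the target's
#'   expected RT (1.3 min when the target has none).
#' @param rt_jitter_sd SD of run-to-run apex jitter, minutes.
#' @param peak_width_sigma Gaussian chromatographic sigma in minutes
#'   (default 0.03, a ~4 s FWHM peak typical of UHPLC).
#' @param response_factor Integrated precursor area per ng/uL.
#' @param fragment_yields Per-fragment MS2 intensity relative to the
#'   precursor trace, in `[0, 1]`; recycled to the target's fragment
#'   count.
#' @return A list of class `analyte_spec`.
#' @export
analyte_spec <- function(target, concentration, expected_rt = NULL,
                         rt_jitter_sd = 0.01, peak_width_sigma = 0.03,
                         response_factor = 1e6,
                         fragment_yields = 0.2) {
  stopifnot(inherits(target, "target_compound"), concentration >= 0,
            peak_width_sigma > 0, response_factor > 0)
  if (is.null(expected_rt)) {
    expected_rt <- if (is.na(target$expected_rt)) 1.3 else target$expected_rt
  }
  fragment_yields <- rep_len(fragment_yields, length(target$fragments))
  if (any(fragment_yields < 0 | fragment_yields > 1)) {
    stop("fragment yields must lie in [0, 1]")
  }
  structure(list(target = target, concentration = concentration,
                 expected_rt = expected_rt, rt_jitter_sd = rt_jitter_sd,
                 peak_width_sigma = peak_width_sigma,
                 response_factor = response_factor,
                 fragment_yields = fragment_yields),
            class = "analyte_spec")
}

#' Specify matrix background for the simulator
#'
#' Models what a biological matrix contributes inside the SIM windows:
#' discrete interfering compounds with their own Gaussian elution
#' profiles, plus sporadic noise peaks.
#'
#' @param interference data.frame with columns `mz`, `intensity`
#'   (apex), `rt`, `sigma` (minutes); may have zero rows.
#' @param baseline Mean intensity of sporadic noise peaks; 0 disables
#'   noise entirely.
#' @param noise_peaks_per_scan Expected count (Poisson) of noise peaks
#'   per SIM scan.
#' @return A list of class `matrix_spec`.
#' @export
matrix_spec <- function(interference = NULL, baseline = 0,
                        noise_peaks_per_scan = 2) {
  if (is.null(interference)) {
    interference <- data.frame(mz = numeric(0), intensity = numeric(0),
                               rt = numeric(0), sigma = numeric(0))
  }
  stopifnot(all(c("mz", "intensity", "rt", "sigma") %in% names(interference)),
            all(interference$intensity >= 0), baseline >= 0)
  structure(list(interference = interference, baseline = baseline,
                 noise_peaks_per_scan = noise_peaks_per_scan),
            class = "matrix_spec")
}

#' Simulate one tSIM-ddMS2 run
#'
#' Builds an MS1 SIM scan per target per duty cycle containing each
#' in-window analyte's deprotonated isotope envelope (base peak
#' normalized) scaled by its Gaussian elution profile, plus matrix
#' interference and noise; and emits data-dependent MS2 scans carrying
#' the fingerprint fragments at their configured yields whenever a
#' precursor trace exceeds the trigger threshold. All m/z values carry
#' Gaussian ppm-scale error. The Gaussian amplitude is set so the
#' integrated precursor (monoisotopic) trace equals
#' `concentration x response_factor`, which the manifest records as the
#' true area.
#'
#' @param analytes List of `analyte_spec` objects.
#' @param matrix A `matrix_spec` (default: clean, noiseless).
#' @param targets Named list of `target_compound` defining the inclusion
#'   list (default: targets of the analytes themselves).
#' @param acq Acquisition parameters from [acquisition_params()].
#' @param seed Integer seed; identical inputs and seed give an
#'   identical run.
#' @param sample_id Sample identifier stored in the run.
#' @return A list with elements `run` (a `tq_run`) and `manifest` (a
#'   data.frame of per-analyte ground truth: `compound`,
#'   `concentration`, `true_area`, `apex_rt`, `response_factor`).
#' @export
simulate_run <- function(analytes, matrix = matrix_spec(), targets = NULL,
                         acq = acquisition_params(), seed = 1L,
                         sample_id = "sim") {
  stopifnot(all(vapply(analytes, inherits, TRUE, "analyte_spec")))
  if (is.null(targets)) {
    targets <- lapply(analytes, `[[`, "target")
    names(targets) <- vapply(targets, `[[`, "", "name")
  }
  tnames <- vapply(targets, `[[`, "", "name")
  # every analyte must fall in some target's SIM window
  for (a in analytes) {
    hit <- any(vapply(targets, function(tg)
      in_window(a$target$precursor_mz, tg$sim_window), TRUE))
    if (!hit) stop("analyte ", a$target$name,
                   " has no covering SIM window in the inclusion list")
  }
  set.seed(seed)
  times <- seq(acq$rt_min, acq$rt_max, by = acq$cycle_time)
  ppm_jit <- function(mz) mz * (1 + stats::rnorm(length(mz), 0, acq$mz_sd_ppm * 1e-6))

  # per-analyte precomputation
  ana <- lapply(analytes, function(a) {
    apex <- a$expected_rt + stats::rnorm(1, 0, a$rt_jitter_sd)
    amp <- a$concentration * a$response_factor /
      (a$peak_width_sigma * sqrt(2 * pi))
    env <- isotope_pattern(a$target$composition, adduct = "[M-H]-")
    rel <- env$abundance / max(env$abundance)
    trace <- amp * exp(-(times - apex)^2 / (2 * a$peak_width_sigma^2))
    trace[trace < amp * 1e-6] <- 0
    list(spec = a, apex = apex, amp = amp, env_mz = env$mz, env_rel = rel,
         trace = trace)
  })
  manifest <- data.frame(
    compound = vapply(analytes, function(a) a$target$name, ""),
    concentration = vapply(analytes, `[[`, 0, "concentration"),
    true_area = vapply(analytes, function(a) a$concentration * a$response_factor, 0),
    apex_rt = vapply(ana, `[[`, 0, "apex"),
    response_factor = vapply(analytes, `[[`, 0, "response_factor"),
    stringsAsFactors = FALSE)

  intf <- matrix$interference
  nslots <- length(targets) + acq$loop_count
  dt <- acq$cycle_time / (nslots + 1)
  spectra <- vector("list", length(times) * nslots)
  ns <- 0L
  for (ci in seq_along(times)) {
    t <- times[ci]
    slot <- 0L
    prec_now <- numeric(length(targets))
    for (ti in seq_along(targets)) {
      tg <- targets[[ti]]
      w <- tg$sim_window
      mzs <- numeric(0); its <- numeric(0)
      for (aa in ana) {
        if (aa$trace[ci] <= 0) next
        if (!in_window(aa$spec$target$precursor_mz, w)) next
        keep <- in_window(aa$env_mz, w)
        if (!any(keep)) next
        mzs <- c(mzs, ppm_jit(aa$env_mz[keep]))
        its <- c(its, aa$env_rel[keep] * aa$trace[ci])
        if (aa$spec$target$name == tg$name) prec_now[ti] <- aa$trace[ci]
      }
      if (nrow(intf)) {
        keep <- in_window(intf$mz, w)
        if (any(keep)) {
          ii <- intf[keep, , drop = FALSE]
          y <- ii$intensity * exp(-(t - ii$rt)^2 / (2 * ii$sigma^2))
          on <- y > 0
          mzs <- c(mzs, ppm_jit(ii$mz[on])); its <- c(its, y[on])
        }
      }
      if (matrix$baseline > 0) {
        its <- its + stats::rnorm(length(its), 0, matrix$baseline * 0.05)
        k <- stats::rpois(1, matrix$noise_peaks_per_scan)
        if (k > 0) {
          mzs <- c(mzs, stats::runif(k, w[[1]], w[[2]]))
          its <- c(its, stats::rexp(k, 1 / matrix$baseline))
        }
      }
      pk <- .merge_centroids(mzs, its)
      slot <- slot + 1L; ns <- ns + 1L
      spectra[[ns]] <- ms_spectrum(1L, t + slot * dt, pk$mz, pk$intensity,
                                   sim_window = w)
    }
    # data-dependent MS2: top loop_count precursors above threshold
    cand <- which(prec_now > acq$trigger_threshold)
    cand <- cand[order(prec_now[cand], decreasing = TRUE)]
    cand <- utils::head(cand, acq$loop_count)
    for (ti in cand) {
      tg <- targets[[ti]]
      aa <- ana[[match(tg$name, vapply(ana, function(x) x$spec$target$name, ""))]]
      if (is.null(aa) || !length(tg$fragments)) next
      fmz <- ppm_jit(tg$fragments)
      fit <- aa$spec$fragment_yields * aa$trace[ci]
      if (matrix$baseline > 0) {
        fit <- pmax(fit + stats::rnorm(length(fit), 0, matrix$baseline * 0.05), 0)
      }
      pk <- .merge_centroids(fmz, fit)
      if (!length(pk$mz)) next
      slot <- slot + 1L; ns <- ns + 1L
      spectra[[ns]] <- ms_spectrum(2L, t + slot * dt, pk$mz, pk$intensity,
                                   precursor = tg$precursor_mz,
                                   collision = paste0("HCD", acq$nce))
    }
  }
  run <- ms_run(spectra[seq_len(ns)], sample_id = sample_id,
                metadata = list(seed = seed, cycle_time = acq$cycle_time,
                                isolation_width = acq$isolation_width,
                                mz_table = attr(isotope_table(), "version")))
  list(run = run, manifest = manifest)
}

.merge_centroids <- function(mz, intensity) {
  keep <- intensity > 0
  mz <- mz[keep]; intensity <- intensity[keep]
  if (!length(mz)) return(list(mz = numeric(0), intensity = numeric(0)))
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  if (length(mz) > 1L && any(diff(mz) <= 1e-7)) {
    grp <- cumsum(c(TRUE, diff(mz) > 1e-7))
    w <- as.numeric(rowsum(intensity, grp))
    m <- as.numeric(rowsum(mz * intensity, grp)) / w
    mz <- m; intensity <- w
  }
  list(mz = mz, intensity = intensity)
}

#' Study design for the simulator
#'
#' Describes the full acquisition campaign the simulator emulates:
#' two cell-line groups (parental and drug-resistant) sampled with
#' biological replicates under treatment and untreated control, a
#' serial-dilution calibrant series, a per-replicate-batch QC reference
#' standard, and a blank. Drug-derived analytes appear only in treated
#' runs; the endogenous nucleotides appear in every biological run.
#'
#' @param n_replicates Biological replicates per group (default 10).
#' @param parental_means Named vector of mean concentrations (ng/uL) per
#'   compound in the parental treated group. Compounds at 0 emulate
#'   species below the detection limit.
#' @param fold_changes Named vector of resistant/parental concentration
#'   ratios; compounds not listed default to 1.
#' @param cv Log-normal biological coefficient of variation (default
#'   0.2).
#' @param endogenous Compounds present regardless of treatment.
#' @param dilution_series Calibrant concentrations in ng/uL (default a
#'   2-fold series from 100 down to 0.195).
#' @param calibration_compound Compound used for the calibrant and QC
#'   runs (default `"FdUMP"`).
#' @param qc_concentration QC reference standard concentration (default
#'   0.780 ng/uL).
#' @param matrix_type Sample matrix label (`"lysate"` or `"media"`).
#' @param include_calibrants,include_qc,include_untreated,include_blank
#'   Toggles for the auxiliary runs.
#' @return A named list of class `study_design`.
#' @export
study_design <- function(n_replicates = 10L,
                         parental_means = c("5-FU" = 5, FdUMP = 2, FURD = 1.5,
                                            FdURD = 1, dUMP = 3, TMP = 3,
                                            FUTP = 0, FdUTP = 0),
                         fold_changes = c(FdUMP = 0.4, FURD = 0.4, FdURD = 0.5),
                         cv = 0.2,
                         endogenous = c("dUMP", "TMP"),
                         dilution_series = 100 / 2^(0:9),
                         calibration_compound = "FdUMP",
                         qc_concentration = 0.780,
                         matrix_type = "lysate",
                         include_calibrants = TRUE, include_qc = TRUE,
                         include_untreated = TRUE, include_blank = TRUE) {
  stopifnot(n_replicates >= 1, cv >= 0, all(parental_means >= 0))
  structure(list(groups = c("parental", "resistant"),
                 n_replicates = as.integer(n_replicates),
                 parental_means = parental_means, fold_changes = fold_changes,
                 cv = cv, endogenous = endogenous,
                 dilution_series = dilution_series,
                 calibration_compound = calibration_compound,
                 qc_concentration = qc_concentration,
                 matrix_type = matrix_type,
                 include_calibrants = include_calibrants,
                 include_qc = include_qc,
                 include_untreated = include_untreated,
                 include_blank = include_blank),
            class = "study_design")
}

#' Simulate a full study
#'
#' Generates every run of a study design with one master seed: test runs
#' whose per-replicate concentrations follow log-normal biological
#' scatter around the group means, untreated controls carrying only the
#' endogenous compounds, the calibrant dilution series, per-replicate
#' QC standards and a blank. Returns the runs, the sample sheet keying
#' them, and the combined ground-truth manifest.
#'
#' @param design A `study_design`.
#' @param targets Named list of `target_compound` (default the bundled
#'   panel).
#' @param matrix A `matrix_spec` applied to biological runs.
#' @param acq Acquisition parameters.
#' @param seed Master integer seed.
#' @param response_factor Area per ng/uL shared by all analytes.
#' @return List with `runs` (named list of `tq_run`), `sample_sheet`
#'   (data.frame) and `manifest` (data.frame with `sample_id` column
#'   added).
#' @export
simulate_study <- function(design = study_design(), targets = fu_panel(),
                           matrix = matrix_spec(baseline = 200),
                           acq = acquisition_params(), seed = 1L,
                           response_factor = 1e6) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed)
  run_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)

  comp_names <- names(design$parental_means)
  miss <- setdiff(comp_names, names(targets))
  if (length(miss)) stop("design names compounds absent from the panel: ",
                         paste(miss, collapse = ", "))
  fold <- stats::setNames(rep(1, length(comp_names)), comp_names)
  fold[names(design$fold_changes)] <- design$fold_changes

  runs <- list()
  sheet <- list()
  manifest <- list()
  sdlog <- sqrt(log(1 + design$cv^2))

  make_analytes <- function(concs) {
    specs <- lapply(names(concs), function(nm)
      analyte_spec(targets[[nm]], concs[[nm]],
                   response_factor = response_factor))
    specs
  }
  emit <- function(id, analytes, group, treatment, role, rep,
                   cal_conc = NA_real_, mx = matrix) {
    sim <- simulate_run(analytes, matrix = mx, targets = targets, acq = acq,
                        seed = run_seed(), sample_id = id)
    runs[[id]] <<- sim$run
    man <- sim$manifest
    man$sample_id <- if (nrow(man)) id else character(0)
    manifest[[id]] <<- man
    sheet[[id]] <<- data.frame(sample_id = id, group = group,
                               treatment = treatment,
                               matrix = design$matrix_type,
                               replicate = rep, role = role,
                               calibrant_concentration = cal_conc,
                               stringsAsFactors = FALSE)
  }

  if (design$include_calibrants) {
    for (k in seq_along(design$dilution_series)) {
      conc <- design$dilution_series[k]
      emit(sprintf("cal_%02d", k),
           make_analytes(stats::setNames(conc, design$calibration_compound)),
           group = "none", treatment = "untreated", role = "calibrant",
           rep = 1L, cal_conc = conc)
    }
  }
  if (design$include_blank) {
    emit("blank_01", list(), group = "none", treatment = "untreated",
         role = "blank", rep = 1L)
  }
  for (r in seq_len(design$n_replicates)) {
    if (design$include_qc) {
      emit(sprintf("qc_r%02d", r),
           make_analytes(stats::setNames(design$qc_concentration,
                                         design$calibration_compound)),
           group = "none", treatment = "untreated", role = "qc", rep = r)
    }
    for (g in design$groups) {
      mult <- if (g == "resistant") fold else fold^0
      means <- design$parental_means * mult
      scatter <- stats::rlnorm(length(means), -sdlog^2 / 2, sdlog)
      concs <- means * scatter
      emit(sprintf("%s_treated_r%02d", g, r), make_analytes(concs),
           group = g, treatment = "treated", role = "test", rep = r)
      if (design$include_untreated) {
        endo <- intersect(design$endogenous, comp_names)
        econc <- means[endo] *
          stats::rlnorm(length(endo), -sdlog^2 / 2, sdlog)
        emit(sprintf("%s_untreated_r%02d", g, r), make_analytes(econc),
             group = g, treatment = "untreated", role = "test", rep = r)
      }
    }
  }
  list(runs = runs,
       sample_sheet = validate_sample_sheet(do.call(rbind, sheet)),
       manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))))
}
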