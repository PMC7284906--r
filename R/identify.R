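#' Detection parameters
#'
#' @param mz_tol Precursor/fragment m/z tolerance in ppm (default 5, the
#'   pipeline's matching gate).
#' @param rt_tol Fragment co-elution tolerance in minutes.
#' @param min_snr Minimum precursor peak signal-to-noise.
#' @param min_fragments Minimum co-eluting fingerprint fragments for a
#'   positive call (default 1; raise towards the full fingerprint for
#'   stricter identity).
#' @param veto_fraction An analyte is vetoed when the untreated
#'   control's area in the same window and RT bounds reaches this
#'   fraction of the treated area (default 0.1; a hard zero is not
#'   testable under noise).
#' @return Named list.
#' @export
detection_params <- function(mz_tol = 5, rt_tol = 0.1, min_snr = 3,
                             min_fragments = 1L, veto_fraction = 0.1) {
  list(mz_tol = mz_tol, rt_tol = rt_tol, min_snr = min_snr,
       min_fragments = as.integer(min_fragments),
       veto_fraction = veto_fraction)
}

# best precursor peak: nearest expected RT when known, else largest area
.choose_peak <- function(peaks, expected_rt) {
  if (nrow(peaks) == 0L) return(peaks)
  if (!is.null(expected_rt) && length(expected_rt) == 1L && is.finite(expected_rt)) {
    peaks[which.min(abs(peaks$apex_rt - expected_rt)), , drop = FALSE]
  } else {
    peaks[1L, , drop = FALSE]  # already ranked by area
  }
}

#' Decide detection of a target compound in a treated run
#'
#' A compound is called detected when (i) a precursor peak is found in
#' the 5 ppm MS1 chromatogram, (ii) at least `min_fragments` fingerprint
#' fragments co-elute with it in precursor-filtered MS2, and (iii) when
#' an untreated control run is supplied, the control shows no matching
#' signal: its area in the same m/z window over the same RT bounds must
#' stay below `veto_fraction` of the treated area, otherwise the call is
#' vetoed (the signal is not treatment-derived).
#'
#' @param treated A `tq_run` from a treated sample.
#' @param control Optional `tq_run` from the paired untreated sample.
#' @param target A `target_compound`.
#' @param params From [detection_params()].
#' @return A list of class `detection_decision`: `compound`,
#'   `sample_id`, `detected`, `precursor` (one-row peak table or NULL),
#'   `fragments` (evidence table), `n_fragments_present`, `control_veto`,
#'   `control_area`, `total_area` (precursor + fragment areas, the
#'   quantity used for quantification).
#' @export
detect_compound <- function(treated, control = NULL, target,
                            params = detection_params()) {
  stopifnot(inherits(treated, "tq_run"), inherits(target, "target_compound"))
  w <- ppm_window(target$precursor_mz, params$mz_tol)
  xic <- extract_xic(treated, w, ms_level = 1L)
  peaks <- detect_peaks(xic, min_snr = params$min_snr)
  peak <- .choose_peak(peaks, target$expected_rt)
  decision <- list(compound = target$name, sample_id = treated$sample_id,
                   detected = FALSE, precursor = NULL,
                   fragments = NULL, n_fragments_present = 0L,
                   control_veto = FALSE, control_area = NA_real_,
                   total_area = 0)
  class(decision) <- "detection_decision"
  if (nrow(peak) == 0L) return(decision)
  decision$precursor <- peak
  frag <- collect_fragment_evidence(treated, target, peak,
                                    rt_tol = params$rt_tol,
                                    mz_tol = params$mz_tol)
  decision$fragments <- frag
  decision$n_fragments_present <- sum(frag$present)
  decision$total_area <- peak$area + sum(frag$area[frag$present])
  if (!is.null(control)) {
    cx <- extract_xic(control, w, ms_level = 1L)
    b <- c(max(peak$rt_start, min(cx$rt, Inf)),
           min(peak$rt_end, max(cx$rt, -Inf)))
    ca <- if (nrow(cx) >= 2L && b[1] < b[2]) integrate_peak(cx, b) else 0
    decision$control_area <- ca
    decision$control_veto <- ca >= params$veto_fraction * peak$area
  }
  decision$detected <- decision$n_fragments_present >= params$min_fragments &&
    !decision$control_veto
  decision
}

#' @export
print.detection_decision <- function(x, ...) {
  cat(sprintf("<detection> %s in %s: %s (%d fragment%s%s)\n", x$compound,
              x$sample_id, if (x$detected) "DETECTED" else "not detected",
              x$n_fragments_present,
              if (x$n_fragments_present == 1L) "" else "s",
              if (x$control_veto) ", control veto" else ""))
  invisible(x)
}

#' Score agreement of a measured isotope envelope with theory
#'
#' Matches measured envelope peaks to the theoretical isotope pattern
#' within a ppm tolerance and scores the base-peak-normalized intensity
#' agreement: `100 * (1 - L1 / sum(theory))` where L1 is the summed
#' absolute difference between the normalized theoretical and matched
#' measured intensities (unmatched theoretical peaks contribute their
#' full normalized intensity). A missing monoisotopic peak scores 0.
#' The score is an analogue of isotope-pattern identification scores
#' produced by formula-identification tools (higher is better); the
#' exact formula is this package's own.
#'
#' @param measured data.frame or matrix with columns `mz`, `intensity`.
#' @param theoretical An `isotope_pattern`.
#' @param mz_tol Match tolerance in ppm (default 5).
#' @return Score in `[0, 100]`.
#' @export
isotope_pattern_score <- function(measured, theoretical, mz_tol = 5) {
  measured <- as.data.frame(measured)
  stopifnot(nrow(measured) > 0, all(c("mz", "intensity") %in% names(measured)))
  th_rel <- theoretical$abundance / max(theoretical$abundance)
  matched <- vapply(theoretical$mz, function(m) {
    d <- abs(ppm_error(measured$mz, m))
    i <- which.min(d)
    if (d[i] <= mz_tol) measured$intensity[i] else NA_real_
  }, 0)
  if (is.na(matched[1])) return(0)  # monoisotopic peak unmatched
  ms_rel <- matched / max(matched, na.rm = TRUE)
  ms_rel[is.na(ms_rel)] <- 0
  l1 <- sum(abs(th_rel - ms_rel))
  max(0, 100 * (1 - l1 / sum(th_rel)))
}

#' Validate fingerprint fragments by subformula explanation
#'
#' Each observed fragment m/z is explained when at least one elemental
#' sub-multiset of the deprotonated precursor composition has an anion
#' m/z within `tol` ppm ([enumerate_subformulas()]). Reports the
#' fraction explained as a 0-100 score and the median signed ppm
#' deviation between each explained fragment and its best subformula.
#'
#' @param target A `target_compound`.
#' @param observed_mz Numeric vector of observed fragment m/z (may be
#'   empty).
#' @param tol Mass tolerance in ppm (default 10).
#' @return A list of class `validation_score`: `compound`,
#'   `n_observed`, `n_explained`, `fragment_score` (0-100),
#'   `median_ppm` (NA when nothing is explained), `explanations` (list
#'   of best subformula per fragment, NULL where unexplained), and
#'   `pass_5ppm` (median deviation within the 5 ppm acceptance gate).
#' @export
validate_fragments <- function(target, observed_mz, tol = 10) {
  stopifnot(inherits(target, "target_compound"))
  parent <- deprotonated_composition(target$composition)
  observed_mz <- as.numeric(observed_mz)
  expl <- lapply(observed_mz, function(mz) {
    subs <- enumerate_subformulas(parent, mz, tol = tol)
    if (length(subs)) subs[[1]] else NULL
  })
  ok <- !vapply(expl, is.null, TRUE)
  dev <- vapply(expl[ok], function(s) attr(s, "ppm"), 0)
  score <- if (length(observed_mz)) 100 * sum(ok) / length(observed_mz) else 0
  med <- if (any(ok)) stats::median(dev) else NA_real_
  structure(list(compound = target$name, n_observed = length(observed_mz),
                 n_explained = sum(ok), fragment_score = score,
                 median_ppm = med, explanations = expl,
                 pass_5ppm = is.finite(med) && abs(med) <= 5),
            class = "validation_score")
}

#' @export
print.validation_score <- function(x, ...) {
  cat(sprintf("<validation> %s: %d/%d fragments explained (score %.1f)",
              x$compound, x$n_explained, x$n_observed, x$fragment_score))
  if (is.finite(x$median_ppm)) {
    cat(sprintf(", median deviation %.2f ppm", x$median_ppm))
  }
  cat("\n")
  invisible(x)
}
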