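# End-to-end orchestration over a set of runs keyed by a sample sheet.

.measure_area <- function(run, target, params) {
  d <- detect_compound(run, control = NULL, target = target, params = params)
  d$total_area
}

#' Fit the calibration curve from a study's calibrant runs
#'
#' Measures the total (precursor + fragment) area of the calibration
#' compound in every calibrant run and regresses area on the
#' concentrations recorded in the sample sheet.
#'
#' @param runs Named list of `tq_run` keyed by sample id.
#' @param sample_sheet Sample sheet data.frame.
#' @param target `target_compound` of the calibration standard.
#' @param params Detection parameters.
#' @return A `calibration_curve`.
#' @export
calibrate_study <- function(runs, sample_sheet, target,
                            params = detection_params()) {
  sheet <- validate_sample_sheet(sample_sheet)
  cal <- sheet[sheet$role == "calibrant", , drop = FALSE]
  if (nrow(cal) == 0L) stop("sample sheet contains no calibrant runs")
  areas <- vapply(cal$sample_id, function(id) {
    if (is.null(runs[[id]])) stop("missing calibrant run: ", id)
    .measure_area(runs[[id]], target, params)
  }, 0)
  fit_calibration(data.frame(concentration = cal$calibrant_concentration,
                             area = areas),
                  compound = target$name)
}

#' Measure QC reference areas per replicate batch
#'
#' @inheritParams calibrate_study
#' @return Named numeric vector of reference areas keyed by replicate
#'   number (as character).
#' @export
qc_reference_areas <- function(runs, sample_sheet, target,
                               params = detection_params()) {
  sheet <- validate_sample_sheet(sample_sheet)
  qc <- sheet[sheet$role == "qc", , drop = FALSE]
  if (nrow(qc) == 0L) stop("sample sheet contains no QC runs")
  areas <- vapply(qc$sample_id, function(id) {
    if (is.null(runs[[id]])) stop("missing QC run: ", id)
    .measure_area(runs[[id]], target, params)
  }, 0)
  stats::setNames(areas, as.character(qc$replicate))
}

#' Detect and quantify every target in every treated test run
#'
#' For each treated test sample, pairs it with the untreated control of
#' the same group and replicate (when present), runs the
#' detection decision for every target, and normalizes total areas to
#' the QC reference area of the sample's replicate batch.
#'
#' @inheritParams calibrate_study
#' @param targets Named list of `target_compound`.
#' @param reference_areas From [qc_reference_areas()]; NULL skips
#'   normalization (ratios reported as NA).
#' @param control_exempt Compound names for which the untreated control
#'   is not consulted. The control-exclusion rule validates
#'   treatment-derived analytes; endogenous compounds are expected in
#'   untreated samples too and would be vetoed spuriously.
#' @return data.frame with one row per sample x compound: `sample_id`,
#'   `compound`, `detected`, `n_fragments`, `control_veto`,
#'   `total_area`, `ratio`.
#' @export
quantify_study <- function(runs, sample_sheet, targets,
                           reference_areas = NULL,
                           params = detection_params(),
                           control_exempt = character(0)) {
  sheet <- validate_sample_sheet(sample_sheet)
  treated <- sheet[sheet$role == "test" & sheet$treatment == "treated", ,
                   drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(treated))) {
    id <- treated$sample_id[i]
    run <- runs[[id]]
    if (is.null(run)) stop("missing test run: ", id)
    ctrl_sel <- sheet$role == "test" & sheet$treatment == "untreated" &
      sheet$group == treated$group[i] & sheet$replicate == treated$replicate[i]
    ctrl <- if (any(ctrl_sel)) runs[[sheet$sample_id[which(ctrl_sel)[1]]]] else NULL
    ref <- NA_real_
    if (!is.null(reference_areas)) {
      key <- as.character(treated$replicate[i])
      if (!key %in% names(reference_areas)) {
        stop("no QC reference area for replicate batch ", key)
      }
      ref <- reference_areas[[key]]
    }
    for (tg in targets) {
      ctl <- if (tg$name %in% control_exempt) NULL else ctrl
      d <- detect_compound(run, control = ctl, target = tg, params = params)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = id, compound = tg$name, detected = d$detected,
        n_fragments = d$n_fragments_present, control_veto = d$control_veto,
        total_area = d$total_area,
        ratio = if (d$detected && is.finite(ref))
          normalize_to_reference(d$total_area, ref) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the complete pipeline on a simulated or loaded study
#'
#' Convenience wrapper: calibration (when calibrant runs exist), QC
#' reference areas, per-sample detection/quantification, and the group
#' comparison table.
#'
#' @inheritParams quantify_study
#' @param reference_compound Name of the QC/calibration compound
#'   (default `"FdUMP"`).
#' @param control_exempt Endogenous compounds quantified without the
#'   untreated-control veto (default the two endogenous nucleotides of
#'   the bundled panel).
#' @param alpha,p_adjust Passed to [summarize_study()].
#' @return List with `calibration` (or NULL), `reference_areas`,
#'   `measurements`, `summary`.
#' @export
analyze_study <- function(runs, sample_sheet, targets = fu_panel(),
                          reference_compound = "FdUMP",
                          control_exempt = c("dUMP", "TMP"),
                          params = detection_params(), alpha = 0.05,
                          p_adjust = "none") {
  sheet <- validate_sample_sheet(sample_sheet)
  ref_target <- targets[[reference_compound]]
  if (is.null(ref_target)) stop("reference compound not in panel: ",
                                reference_compound)
  calib <- NULL
  if (any(sheet$role == "calibrant")) {
    calib <- calibrate_study(runs, sheet, ref_target, params)
  }
  refs <- NULL
  if (any(sheet$role == "qc")) {
    refs <- qc_reference_areas(runs, sheet, ref_target, params)
  }
  meas <- quantify_study(runs, sheet, targets, reference_areas = refs,
                         params = params, control_exempt = control_exempt)
  summ <- summarize_study(meas, sheet, alpha = alpha, p_adjust = p_adjust)
  list(calibration = calib, reference_areas = refs, measurements = meas,
       summary = summ)
}
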