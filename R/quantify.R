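#' Fit a calibration curve with LOD and LOQ
#'
#' Ordinary least-squares regression of peak area on concentration over
#' a dilution series. The limit of detection is `3 x SD` and the limit
#' of quantification `10 x SD`, where SD is by default the residual
#' standard deviation of the fit converted to concentration units
#' (divided by the slope); a blank-derived SD can be supplied instead.
#' A perfect straight line therefore gives LOD = LOQ = 0 and R-squared
#' of 1, and LOQ/LOD is 10/3 for every fit.
#'
#' @param points data.frame with columns `concentration` (ng/uL, > 0)
#'   and `area`; at least 3 distinct concentrations.
#' @param compound Compound label carried in the result.
#' @param sd_source `"residual"` (default) or `"blank"`.
#' @param blank_sd Blank-area SD, required when `sd_source = "blank"`;
#'   converted to concentration units via the slope.
#' @return A list of class `calibration_curve`: `compound`, `points`,
#'   `slope`, `intercept`, `r_squared`, `sd_conc`, `lod`, `loq`, `fit`.
#' @export
#' @examples
#' fit_calibration(data.frame(concentration = c(1, 2, 4),
#'                            area = c(10, 20, 40)))
fit_calibration <- function(points, compound = "analyte",
                            sd_source = c("residual", "blank"),
                            blank_sd = NULL) {
  sd_source <- match.arg(sd_source)
  stopifnot(all(c("concentration", "area") %in% names(points)))
  if (any(points$concentration <= 0)) stop("calibrant concentrations must be > 0")
  if (length(unique(points$concentration)) < 3L) {
    stop("calibration requires at least 3 distinct concentrations")
  }
  fit <- stats::lm(area ~ concentration, data = points)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope is not positive; check the dilution series")
  }
  # summary.lm warns on an exactly collinear (noise-free) series; that
  # case is legitimate here and yields LOD ~ 0
  sfit <- suppressWarnings(summary(fit))
  resid_sd <- sfit$sigma
  sd_conc <- switch(sd_source,
    residual = resid_sd / slope,
    blank = {
      if (is.null(blank_sd)) stop("blank_sd required when sd_source = 'blank'")
      blank_sd / slope
    })
  structure(list(compound = compound, points = points, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sfit$r.squared,
                 sd_conc = sd_conc, lod = 3 * sd_conc, loq = 10 * sd_conc,
                 sd_source = sd_source, fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(paste0("<calibration '%s'> %d points, slope %.4g, R2 %.4f,\n",
                     "  LOD %.4g ng/uL, LOQ %.4g ng/uL (%s SD)\n"),
              x$compound, nrow(x$points), x$slope, x$r_squared,
              x$lod, x$loq, x$sd_source))
  invisible(x)
}

#' Normalize an area to the batch reference standard
#'
#' Relative quantification divides each compound's total peak area by
#' the peak area of the QC reference standard (0.780 ng/uL FdUMP)
#' acquired with the same replicate batch.
#'
#' @param area Total peak area (precursor + products).
#' @param reference_area QC standard area for the batch; must be > 0.
#' @return Unitless ratio.
#' @export
normalize_to_reference <- function(area, reference_area) {
  if (any(!is.finite(reference_area)) || any(reference_area <= 0)) {
    stop("reference area must be positive")
  }
  area / reference_area
}

#' Compare two groups of normalized ratios
#'
#' Two-sample Student's t-test (equal variance by default; Welch by
#' flag), reporting group means with standard errors. Degenerate input
#' with zero variance in both groups and equal means yields t = 0,
#' p = 1 rather than an error.
#'
#' @param ratios_a,ratios_b Numeric vectors, each of length >= 2.
#' @param var_equal Pooled-variance Student's t-test when TRUE
#'   (default); Welch otherwise.
#' @return A list of class `group_comparison`: `mean_a`, `sem_a`, `n_a`,
#'   `mean_b`, `sem_b`, `n_b`, `t`, `df`, `p_value`, `fold_change`
#'   (b/a).
#' @export
compare_groups <- function(ratios_a, ratios_b, var_equal = TRUE) {
  stopifnot(length(ratios_a) >= 2L, length(ratios_b) >= 2L)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  if (stats::sd(ratios_a) == 0 && stats::sd(ratios_b) == 0) {
    same <- isTRUE(all.equal(mean(ratios_a), mean(ratios_b)))
    t <- if (same) 0 else sign(mean(ratios_b) - mean(ratios_a)) * Inf
    p <- if (same) 1 else 0
    df <- length(ratios_a) + length(ratios_b) - 2L
  } else {
    ht <- stats::t.test(ratios_a, ratios_b, var.equal = var_equal)
    t <- unname(ht$statistic); p <- ht$p.value; df <- unname(ht$parameter)
  }
  structure(list(mean_a = mean(ratios_a), sem_a = sem(ratios_a),
                 n_a = length(ratios_a),
                 mean_b = mean(ratios_b), sem_b = sem(ratios_b),
                 n_b = length(ratios_b),
                 t = t, df = df, p_value = p,
                 fold_change = mean(ratios_b) / mean(ratios_a)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<comparison> %.3g +/- %.2g (n=%d) vs %.3g +/- %.2g (n=%d): t=%.3g, p=%.3g\n",
              x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b,
              x$t, x$p_value))
  invisible(x)
}

#' Summarize a study into a per-compound comparison table
#'
#' Joins detection decisions and normalized measurements with the
#' sample sheet, then per compound (and matrix) compares the parental
#' and resistant treated groups by Student's t-test on the normalized
#' ratios. Compounds detected in no test sample are flagged
#' `below detection` and excluded from testing; within a tested
#' compound, non-detected replicates are dropped rather than imputed as
#' zero.
#'
#' @param measurements data.frame with columns `sample_id`, `compound`,
#'   `detected`, `ratio` (normalized area; NA when not detected).
#' @param sample_sheet Sample sheet data.frame.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` by default (matching the panel-sized
#'   analysis this reproduces), `"BH"` available.
#' @param var_equal Passed to [compare_groups()].
#' @return data.frame with one row per compound x matrix: group means
#'   +/- sem, n, t, p, `significant`, `status`
#'   (`"quantified"`/`"below detection"`).
#' @export
summarize_study <- function(measurements, sample_sheet, alpha = 0.05,
                            p_adjust = "none", var_equal = TRUE) {
  sheet <- validate_sample_sheet(sample_sheet)
  test_ids <- sheet$sample_id[sheet$role == "test" & sheet$treatment == "treated"]
  m <- merge(measurements, sheet, by = "sample_id")
  m <- m[m$sample_id %in% test_ids, , drop = FALSE]
  rows <- list()
  for (mx in unique(m$matrix)) {
    for (cp in unique(m$compound)) {
      d <- m[m$compound == cp & m$matrix == mx, , drop = FALSE]
      det <- d[d$detected & is.finite(d$ratio), , drop = FALSE]
      a <- det$ratio[det$group == "parental"]
      b <- det$ratio[det$group == "resistant"]
      if (nrow(det) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          compound = cp, matrix = mx, status = "below detection",
          mean_parental = NA_real_, sem_parental = NA_real_, n_parental = 0L,
          mean_resistant = NA_real_, sem_resistant = NA_real_, n_resistant = 0L,
          fold_change = NA_real_, t = NA_real_, p_value = NA_real_,
          significant = NA, stringsAsFactors = FALSE)
        next
      }
      if (length(a) >= 2L && length(b) >= 2L) {
        cmpr <- compare_groups(a, b, var_equal = var_equal)
        rows[[length(rows) + 1L]] <- data.frame(
          compound = cp, matrix = mx, status = "quantified",
          mean_parental = cmpr$mean_a, sem_parental = cmpr$sem_a,
          n_parental = cmpr$n_a,
          mean_resistant = cmpr$mean_b, sem_resistant = cmpr$sem_b,
          n_resistant = cmpr$n_b,
          fold_change = cmpr$fold_change, t = cmpr$t, p_value = cmpr$p_value,
          significant = NA, stringsAsFactors = FALSE)
      } else {
        sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          compound = cp, matrix = mx, status = "quantified",
          mean_parental = mean(a), sem_parental = sem(a), n_parental = length(a),
          mean_resistant = mean(b), sem_resistant = sem(b), n_resistant = length(b),
          fold_change = mean(b) / mean(a), t = NA_real_, p_value = NA_real_,
          significant = NA, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  tested <- is.finite(out$p_value)
  out$p_adjusted <- NA_real_
  out$p_adjusted[tested] <- stats::p.adjust(out$p_value[tested], method = p_adjust)
  out$significant[tested] <- out$p_adjusted[tested] < alpha
  rownames(out) <- NULL
  out
}
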