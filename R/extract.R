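#' Extract an ion chromatogram
#'
#' Sums centroid intensity inside a fixed m/z window across the
#' qualifying spectra of a run: MS1 extraction visits every MS1 scan
#' whose SIM range covers the window center (or every MS1 scan when the
#' run has no SIM metadata); MS2 extraction is restricted to fragment
#' scans whose precursor target matches `precursor_filter` within 5 ppm.
#'
#' @param run A `tq_run`.
#' @param window An `mz_window` (e.g. from [ppm_window()]).
#' @param ms_level 1 or 2.
#' @param precursor_filter Precursor target m/z for MS2 extraction.
#' @return A data.frame of class `tq_xic` with columns `rt` (minutes,
#'   increasing) and `intensity`; one point per qualifying spectrum.
#' @export
extract_xic <- function(run, window, ms_level = 1L, precursor_filter = NULL) {
  stopifnot(inherits(run, "tq_run"), inherits(window, "mz_window"))
  center <- mean(as.numeric(window))
  rt <- numeric(0); it <- numeric(0)
  for (sp in run$spectra) {
    if (sp$ms_level != ms_level) next
    if (ms_level == 2L) {
      if (is.null(precursor_filter)) next
      if (is.null(sp$precursor)) next
      if (abs(ppm_error(sp$precursor, precursor_filter)) > 5) next
    } else if (!is.null(sp$sim_window)) {
      # a SIM scan only sees its own isolation range
      if (!in_window(center, sp$sim_window)) next
    }
    rt <- c(rt, sp$rt)
    it <- c(it, sum(sp$intensity[in_window(sp$mz, window)]))
  }
  xic <- data.frame(rt = rt, intensity = it)
  xic <- xic[order(xic$rt), , drop = FALSE]
  rownames(xic) <- NULL
  attr(xic, "window") <- window
  attr(xic, "ms_level") <- as.integer(ms_level)
  class(xic) <- c("tq_xic", "data.frame")
  xic
}

# Robust noise level of a chromatogram: MAD of its lowest quartile.
# Parameter-free and insensitive to the peaks themselves.
xic_noise <- function(intensity) {
  if (length(intensity) < 4L) return(0)
  q <- stats::quantile(intensity, 0.25, names = FALSE)
  low <- intensity[intensity <= q]
  stats::mad(low, center = stats::median(low))
}

#' Detect chromatographic peaks
#'
#' Finds local maxima whose height exceeds `min_snr` times a robust
#' noise estimate (median absolute deviation of the lowest intensity
#' quartile), then extends each peak's bounds to the nearest flanking
#' valley or baseline return. Peaks spanning fewer than `min_points`
#' samples are discarded. Results are ranked by area, descending.
#'
#' @param xic A `tq_xic`.
#' @param min_snr Minimum apex signal-to-noise (default 3).
#' @param min_points Minimum samples across a peak (default 3, the
#'   smallest value accepted).
#' @return A data.frame of class `tq_peaks` with columns `apex_rt`,
#'   `rt_start`, `rt_end`, `area`, `height`, `snr`.
#' @export
detect_peaks <- function(xic, min_snr = 3, min_points = 3L) {
  stopifnot(min_points >= 3L)
  n <- nrow(xic)
  empty <- data.frame(apex_rt = numeric(0), rt_start = numeric(0),
                      rt_end = numeric(0), area = numeric(0),
                      height = numeric(0), snr = numeric(0))
  class(empty) <- c("tq_peaks", "data.frame")
  if (n < min_points) return(empty)
  y <- xic$intensity
  noise <- xic_noise(y)
  floor_level <- max(noise, max(y) * 1e-9)
  apexes <- which(diff(sign(diff(y))) < 0) + 1L
  apexes <- apexes[y[apexes] > min_snr * noise & y[apexes] > 0]
  if (!length(apexes)) return(empty)
  rows <- lapply(apexes, function(a) {
    i <- a
    while (i > 1L && y[i - 1L] < y[i] && y[i - 1L] > floor_level) i <- i - 1L
    if (i > 1L && y[i - 1L] <= floor_level) i <- i - 1L
    j <- a
    while (j < n && y[j + 1L] < y[j] && y[j + 1L] > floor_level) j <- j + 1L
    if (j < n && y[j + 1L] <= floor_level) j <- j + 1L
    if (j - i + 1L < min_points) return(NULL)
    area <- integrate_peak(xic, c(xic$rt[i], xic$rt[j]))
    data.frame(apex_rt = xic$rt[a], rt_start = xic$rt[i], rt_end = xic$rt[j],
               area = area, height = y[a],
               snr = if (noise > 0) y[a] / noise else Inf)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$area, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tq_peaks", "data.frame")
  out
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal integral of intensity over retention time between two
#' bounds, after subtracting a linear baseline drawn between the
#' endpoint intensities (floored at zero so baseline overshoot cannot
#' produce negative area).
#'
#' @param xic A `tq_xic`.
#' @param bounds Numeric `c(rt_start, rt_end)`, inside the chromatogram
#'   RT range, `rt_start < rt_end`.
#' @return Area in intensity x minutes.
#' @export
integrate_peak <- function(xic, bounds) {
  stopifnot(length(bounds) == 2L)
  if (bounds[1] >= bounds[2]) stop("inverted integration bounds")
  if (nrow(xic) == 0L) return(0)
  if (bounds[1] < min(xic$rt) - 1e-9 || bounds[2] > max(xic$rt) + 1e-9) {
    stop("integration bounds outside the chromatogram RT range")
  }
  sel <- xic$rt >= bounds[1] & xic$rt <= bounds[2]
  rt <- xic$rt[sel]; y <- xic$intensity[sel]
  if (length(rt) < 2L) return(0)
  base <- y[1] + (y[length(y)] - y[1]) * (rt - rt[1]) / (rt[length(rt)] - rt[1])
  corr <- pmax(y - base, 0)
  sum(diff(rt) * (utils::head(corr, -1) + utils::tail(corr, -1)) / 2)
}

#' Collect co-eluting MS2 fragment evidence for a precursor peak
#'
#' For each fingerprint fragment of a target, extracts a
#' precursor-filtered MS2 chromatogram in a ppm window around the
#' fragment m/z and integrates it over the precursor peak's RT bounds
#' (shared bounds, so the total precursor-plus-products area is well
#' defined). A fragment counts as present when its apex inside the
#' bounds lies within `rt_tol` of the precursor apex and rises above the
#' fragment chromatogram's noise level.
#'
#' @param run A `tq_run`.
#' @param target A `target_compound`.
#' @param precursor_peak One row of a `tq_peaks` table for this target's
#'   precursor.
#' @param rt_tol Apex co-elution tolerance in minutes (default 0.1).
#' @param mz_tol Fragment m/z tolerance in ppm (default 5).
#' @return A data.frame with one row per fingerprint fragment: columns
#'   `fragment_mz`, `present`, `apex_rt`, `area`, `height`.
#' @export
collect_fragment_evidence <- function(run, target, precursor_peak,
                                      rt_tol = 0.1, mz_tol = 5) {
  stopifnot(inherits(target, "target_compound"), nrow(precursor_peak) == 1L)
  bounds <- c(precursor_peak$rt_start, precursor_peak$rt_end)
  if (!length(target$fragments)) {
    return(data.frame(fragment_mz = numeric(0), present = logical(0),
                      apex_rt = numeric(0), area = numeric(0),
                      height = numeric(0)))
  }
  rows <- lapply(target$fragments, function(fmz) {
    fx <- extract_xic(run, ppm_window(fmz, mz_tol), ms_level = 2L,
                      precursor_filter = target$precursor_mz)
    sel <- fx$rt >= bounds[1] & fx$rt <= bounds[2]
    if (!any(sel)) {
      return(data.frame(fragment_mz = fmz, present = FALSE,
                        apex_rt = NA_real_, area = 0, height = 0))
    }
    inb <- fx[sel, , drop = FALSE]
    apex <- inb$rt[which.max(inb$intensity)]
    height <- max(inb$intensity)
    noise <- xic_noise(fx$intensity)
    # clamp to the fragment trace's own RT coverage
    b <- c(max(bounds[1], min(fx$rt)), min(bounds[2], max(fx$rt)))
    area <- if (b[1] < b[2]) integrate_peak(fx, b) else 0
    present <- height > max(3 * noise, 0) &&
      abs(apex - precursor_peak$apex_rt) <= rt_tol
    data.frame(fragment_mz = fmz, present = present, apex_rt = apex,
               area = area, height = height)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
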