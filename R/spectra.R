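#' A centroided mass spectrum
#'
#' One scan of a tSIM-ddMS2 acquisition: either an MS1 SIM scan
#' restricted to a narrow isolation window, or a data-dependent MS2
#' fragment scan tied to a precursor target.
#'
#' @param ms_level 1 or 2.
#' @param rt Retention time in minutes.
#' @param mz Numeric vector of centroid m/z values, strictly increasing.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param sim_window Optional `mz_window` recording the SIM isolation
#'   range of an MS1 scan.
#' @param precursor Precursor target m/z; required when `ms_level == 2`.
#' @param collision Free-text collision label (e.g. `"HCD25"`).
#' @return A list of class `tq_spectrum`.
#' @export
ms_spectrum <- function(ms_level, rt, mz, intensity, sim_window = NULL,
                        precursor = NULL, collision = NULL) {
  stopifnot(ms_level %in% c(1L, 2L), is.numeric(rt), length(rt) == 1L)
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity arrays must have equal length")
  }
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    stop("mz array must be strictly increasing")
  }
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (ms_level == 2L && is.null(precursor)) {
    stop("MS2 spectrum requires a precursor target m/z")
  }
  structure(list(ms_level = as.integer(ms_level), rt = as.numeric(rt),
                 mz = mz, intensity = intensity,
                 sim_window = sim_window, precursor = precursor,
                 collision = collision),
            class = "tq_spectrum")
}

#' @export
print.tq_spectrum <- function(x, ...) {
  cat(sprintf("<MS%d spectrum> rt %.3f min, %d peaks", x$ms_level, x$rt,
              length(x$mz)))
  if (!is.null(x$sim_window)) {
    cat(sprintf(", SIM %.4f-%.4f", x$sim_window[[1]], x$sim_window[[2]]))
  }
  if (!is.null(x$precursor)) cat(sprintf(", precursor %.4f", x$precursor))
  cat("\n")
  invisible(x)
}

#' An LC-MS run
#'
#' @param spectra List of `tq_spectrum`, ordered by retention time
#'   (non-decreasing; reordered if needed).
#' @param sample_id Sample identifier.
#' @param metadata Named list of acquisition parameters.
#' @return A list of class `tq_run`.
#' @export
ms_run <- function(spectra, sample_id = "run", metadata = list()) {
  stopifnot(is.list(spectra))
  if (length(spectra)) {
    stopifnot(all(vapply(spectra, inherits, TRUE, "tq_spectrum")))
    rts <- vapply(spectra, `[[`, 0, "rt")
    if (is.unsorted(rts)) spectra <- spectra[order(rts)]
  }
  structure(list(spectra = spectra, sample_id = sample_id,
                 metadata = metadata),
            class = "tq_run")
}

#' @export
print.tq_run <- function(x, ...) {
  lv <- vapply(x$spectra, `[[`, 0L, "ms_level")
  cat(sprintf("<LC-MS run '%s'> %d spectra (%d MS1, %d MS2)\n",
              x$sample_id, length(x$spectra), sum(lv == 1L), sum(lv == 2L)))
  invisible(x)
}

#' @export
length.tq_run <- function(x) length(x$spectra)

.num <- function(x) sprintf("%.17g", x)

#' Write a run to disk
#'
#' Two formats are supported: the package's lossless line-delimited text
#' fixture format (one record per spectrum, full double precision), and
#' standard indexed centroided mzML via the `mzR` package. SIM windows
#' travel through mzML scan-window metadata; the fixture format stores
#' all spectrum fields verbatim.
#'
#' @param run A `tq_run`.
#' @param path Output file path.
#' @param format `"fixture"` or `"mzML"`.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path, format = c("fixture", "mzML")) {
  format <- match.arg(format)
  stopifnot(inherits(run, "tq_run"))
  if (format == "fixture") .write_fixture(run, path) else .write_mzml(run, path)
  invisible(path)
}

.write_fixture <- function(run, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#tsimquant-run\t1", con)
  writeLines(paste0("#sample_id\t", run$sample_id), con)
  for (k in names(run$metadata)) {
    writeLines(paste0("#meta\t", k, "\t", as.character(run$metadata[[k]])), con)
  }
  for (sp in run$spectra) {
    sw <- if (is.null(sp$sim_window)) c("NA", "NA") else .num(as.numeric(sp$sim_window))
    pc <- if (is.null(sp$precursor)) "NA" else .num(sp$precursor)
    cl <- if (is.null(sp$collision)) "NA" else sp$collision
    mzs <- if (length(sp$mz)) paste(.num(sp$mz), collapse = ",") else "-"
    its <- if (length(sp$intensity)) paste(.num(sp$intensity), collapse = ",") else "-"
    writeLines(paste(sp$ms_level, .num(sp$rt), sw[1], sw[2], pc, cl,
                     mzs, its, sep = "\t"), con)
  }
}

#' Read a run from disk
#'
#' Auto-detects the fixture format by its header line; anything else is
#' read as mzML through `mzR`. Retention times are normalized to
#' minutes (mzML stores seconds).
#'
#' @param path File path.
#' @return A `tq_run`.
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(first, "#tsimquant-run")) {
    .read_fixture(path)
  } else {
    .read_mzml(path)
  }
}

.read_fixture <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sample_id <- "run"
  metadata <- list()
  spectra <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (startsWith(ln, "#")) {
      if (f[1] == "#sample_id") sample_id <- f[2]
      if (f[1] == "#meta") metadata[[f[2]]] <- f[3]
      next
    }
    if (length(f) != 8L) {
      stop("malformed fixture record at line ", i, " of ", path)
    }
    mz <- if (f[7] != "-") as.numeric(strsplit(f[7], ",", fixed = TRUE)[[1]]) else numeric(0)
    it <- if (f[8] != "-") as.numeric(strsplit(f[8], ",", fixed = TRUE)[[1]]) else numeric(0)
    sw <- if (f[3] == "NA") NULL else mz_window(as.numeric(f[3]), as.numeric(f[4]))
    spectra[[length(spectra) + 1L]] <- ms_spectrum(
      ms_level = as.integer(f[1]), rt = as.numeric(f[2]),
      mz = mz, intensity = it, sim_window = sw,
      precursor = if (f[5] == "NA") NULL else as.numeric(f[5]),
      collision = if (f[6] == "NA") NULL else f[6])
  }
  ms_run(spectra, sample_id = sample_id, metadata = metadata)
}

.write_mzml <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML output requires the mzR package")
  }
  n <- length(run$spectra)
  if (n == 0L) stop("mzML writer requires at least one spectrum")
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = vapply(run$spectra, `[[`, 0L, "ms_level"),
    polarity = 0L,
    peaksCount = vapply(run$spectra, function(s) length(s$mz), 0L),
    totIonCurrent = vapply(run$spectra, function(s) sum(s$intensity), 0),
    retentionTime = vapply(run$spectra, `[[`, 0, "rt") * 60,
    basePeakMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, 0),
    basePeakIntensity = vapply(run$spectra, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, 0),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$spectra, function(s) if (length(s$mz)) min(s$mz) else 0, 0),
    highMZ = vapply(run$spectra, function(s) if (length(s$mz)) max(s$mz) else 0, 0),
    precursorScanNum = 0L,
    precursorMZ = vapply(run$spectra, function(s)
      if (is.null(s$precursor)) 0 else s$precursor, 0),
    precursorCharge = vapply(run$spectra, function(s)
      if (is.null(s$precursor)) 0L else -1L, 0L),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0,
    filterString = vapply(run$spectra, function(s)
      if (is.null(s$collision)) "" else s$collision, ""),
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = vapply(run$spectra, function(s) {
      if (!is.null(s$precursor)) s$precursor
      else if (!is.null(s$sim_window)) mean(as.numeric(s$sim_window))
      else NA_real_
    }, 0),
    isolationWindowLowerOffset = NA_real_, isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = vapply(run$spectra, function(s)
      if (is.null(s$sim_window)) NA_real_ else s$sim_window[[1]], 0),
    scanWindowUpperLimit = vapply(run$spectra, function(s)
      if (is.null(s$sim_window)) NA_real_ else s$sim_window[[2]], 0),
    stringsAsFactors = FALSE)
  pks <- lapply(run$spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(pks, path, header = hdr, outformat = "mzml")
}

.read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package")
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  if (any(!is.na(hdr$centroided) & !hdr$centroided)) {
    stop("profile-mode spectra are not supported; centroid the data first")
  }
  spectra <- vector("list", nrow(hdr))
  for (i in seq_len(nrow(hdr))) {
    pk <- mzR::peaks(fh, i)
    sw <- NULL
    lo <- hdr$scanWindowLowerLimit[i]; hi <- hdr$scanWindowUpperLimit[i]
    if (hdr$msLevel[i] == 1L && !is.na(lo) && !is.na(hi) && lo < hi) {
      sw <- mz_window(lo, hi)
    }
    prec <- NULL
    if (hdr$msLevel[i] == 2L) {
      prec <- hdr$precursorMZ[i]
      if (is.na(prec) || prec <= 0) {
        stop("MS2 spectrum ", i, " lacks a precursor target")
      }
    }
    ord <- order(pk[, 1])
    spectra[[i]] <- ms_spectrum(
      ms_level = hdr$msLevel[i], rt = hdr$retentionTime[i] / 60,
      mz = pk[ord, 1], intensity = pk[ord, 2],
      sim_window = sw, precursor = prec,
      collision = if (nzchar(hdr$filterString[i])) hdr$filterString[i] else NULL)
  }
  ms_run(spectra, sample_id = sub("\\.[^.]+$", "", basename(path)))
}

#' Read a sample sheet
#'
#' The sample sheet is a CSV keying each acquisition: columns
#' `sample_id`, `group` (parental/resistant), `treatment`
#' (treated/untreated), `matrix` (lysate/media), `replicate`, `role`
#' (test/calibrant/qc/blank) and `calibrant_concentration` (ng/uL;
#' required for calibrant rows, empty otherwise).
#'
#' @param path CSV file path.
#' @return A data.frame with validated columns.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet A data.frame to validate in place.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "group", "treatment", "matrix", "replicate", "role",
           "calibrant_concentration")
  miss <- setdiff(req, names(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sample sheet")
  if (any(sheet$replicate < 1, na.rm = TRUE)) stop("replicate must be >= 1")
  cal <- sheet$role == "calibrant"
  if (any(cal & !is.finite(sheet$calibrant_concentration))) {
    stop("calibrant rows must carry a concentration")
  }
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(validate_sample_sheet(sheet), path, row.names = FALSE)
  invisible(path)
}
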