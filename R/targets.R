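#' Define a target compound
#'
#' A target is the per-analyte identification fingerprint: neutral
#' formula, deprotonated precursor m/z, fragment m/z list, expected
#' retention time and the SIM isolation window used to acquire it.
#'
#' @param name Compound name, unique within a panel.
#' @param formula Neutral molecular formula (Hill notation).
#' @param fragments Numeric vector of fingerprint fragment m/z values.
#' @param precursor_mz Optional published precursor m/z; must agree with
#'   the value computed from `formula` within `check_ppm`. When omitted
#'   the computed `[M-H]-` m/z is used.
#' @param expected_rt Expected retention time in minutes, or `NA`.
#' @param isolation_width SIM isolation window width in m/z (default
#'   4.0).
#' @param adduct Only `"[M-H]-"` is supported.
#' @param check_ppm Tolerance for the published-vs-computed precursor
#'   check (default 5 ppm).
#' @return A list of class `target_compound`.
#' @export
#' @examples
#' target_compound("5-FU", "C4H3FN2O2", fragments = 58.993,
#'                 precursor_mz = 129.0109, expected_rt = 1.6)
target_compound <- function(name, formula, fragments = numeric(0),
                            precursor_mz = NULL, expected_rt = NA_real_,
                            isolation_width = 4.0, adduct = "[M-H]-",
                            check_ppm = 5) {
  stopifnot(adduct == "[M-H]-")
  comp <- as_composition(formula)
  computed <- mz_deprotonated(comp)
  if (is.null(precursor_mz) || is.na(precursor_mz)) {
    precursor_mz <- computed
  } else if (abs(ppm_error(precursor_mz, computed)) > check_ppm) {
    stop(sprintf("%s: stated precursor %.4f deviates %.1f ppm from computed %.4f",
                 name, precursor_mz, ppm_error(precursor_mz, computed), computed))
  }
  fragments <- as.numeric(fragments)
  if (any(fragments >= precursor_mz + 0.5)) {
    stop(name, ": fragment m/z above the precursor")
  }
  structure(list(name = name, composition = comp, adduct = adduct,
                 precursor_mz = precursor_mz, computed_mz = computed,
                 fragments = fragments, expected_rt = as.numeric(expected_rt),
                 sim_window = sim_window(precursor_mz, isolation_width)),
            class = "target_compound")
}

#' @export
print.target_compound <- function(x, ...) {
  cat(sprintf("<target '%s'> %s, [M-H]- %.4f, %d fragments, rt %s min\n",
              x$name, format_formula(x$composition), x$precursor_mz,
              length(x$fragments),
              if (is.na(x$expected_rt)) "?" else sprintf("%.1f", x$expected_rt)))
  invisible(x)
}

#' Read a fingerprint table
#'
#' Reads a TSV of targets with columns `compound`, `formula`,
#' `precursor_mz`, `rt_min` and `fragments` (semicolon-separated m/z
#' list); extra columns are ignored.
#'
#' @param path TSV file path.
#' @param isolation_width SIM window width passed to each target.
#' @return Named list of `target_compound` objects.
#' @export
read_fingerprint_table <- function(path, isolation_width = 4.0) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("compound", "formula", "precursor_mz", "rt_min", "fragments")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("fingerprint table missing column(s): ",
                         paste(miss, collapse = ", "))
  targets <- lapply(seq_len(nrow(tab)), function(i) {
    frags <- as.numeric(strsplit(tab$fragments[i], ";", fixed = TRUE)[[1]])
    target_compound(tab$compound[i], tab$formula[i], fragments = frags,
                    precursor_mz = tab$precursor_mz[i],
                    expected_rt = tab$rt_min[i],
                    isolation_width = isolation_width)
  })
  stats::setNames(targets, tab$compound)
}

#' The bundled fluoropyrimidine target panel
#'
#' Eight targets: 5-fluorouracil (5-FU), its metabolites FdUMP, FURD,
#' FdURD, FUTP and FdUTP, and the endogenous nucleotides dUMP and TMP,
#' with their published `[M-H]-` precursor m/z, fragment fingerprints
#' and retention times on a pentafluorophenyl (F5) column.
#'
#' @inheritParams read_fingerprint_table
#' @return Named list of `target_compound` objects.
#' @export
#' @examples
#' panel <- fu_panel()
#' panel[["FdUMP"]]
fu_panel <- function(isolation_width = 4.0) {
  read_fingerprint_table(
    system.file("extdata", "target_panel.tsv", package = "tsimquant"),
    isolation_width = isolation_width)
}

#' Build a tSIM inclusion list
#'
#' One row per target with its precursor m/z and SIM isolation window,
#' formatted the way instrument scan filters print them
#' (`low-high` to four decimals).
#'
#' @param targets List of `target_compound` objects.
#' @param isolation_width SIM window width in m/z.
#' @return A data.frame with columns `name`, `precursor_mz`,
#'   `window_low`, `window_high`, `scan_filter`.
#' @export
#' @examples
#' build_inclusion_list(fu_panel())
build_inclusion_list <- function(targets, isolation_width = 4.0) {
  stopifnot(length(targets) > 0)
  nms <- vapply(targets, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate target names in inclusion list")
  mz <- vapply(targets, `[[`, 0, "precursor_mz")
  lo <- mz - isolation_width / 2
  hi <- mz + isolation_width / 2
  data.frame(name = nms, precursor_mz = mz,
             window_low = lo, window_high = hi,
             scan_filter = sprintf("%.4f-%.4f", lo, hi),
             row.names = NULL, stringsAsFactors = FALSE)
}
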