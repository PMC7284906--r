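# Physical constants (CODATA 2018), in Da.
.ELECTRON_MASS <- 0.000548579909065
.PROTON_MASS <- 1.00727646627

.tq_env <- new.env(parent = emptyenv())

#' Pinned isotope mass and abundance table
#'
#' Returns the package's pinned table of isotopic masses and natural
#' abundances used for all mass arithmetic and isotope-envelope
#' simulation. Masses follow the AME2020 atomic mass evaluation,
#' abundances the CIAAW 2021 representative values; the table is shipped
#' as plain text so every computed m/z is reproducible from the
#' repository alone.
#'
#' @return A data.frame with columns `element`, `mass_number`, `mass`
#'   (Da) and `abundance`, carrying a `version` attribute identifying
#'   the source tables.
#' @export
#' @examples
#' head(isotope_table())
isotope_table <- function() {
  if (is.null(.tq_env$isotopes)) {
    path <- system.file("extdata", "isotope_masses.tsv", package = "tsimquant")
    tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    attr(tab, "version") <- "AME2020 masses / CIAAW 2021 abundances"
    .tq_env$isotopes <- tab
  }
  .tq_env$isotopes
}

.monoisotopic_masses <- function() {
  if (is.null(.tq_env$mono)) {
    tab <- isotope_table()
    # most abundant isotope per element defines the monoisotopic mass
    sp <- split(tab, tab$element)
    .tq_env$mono <- vapply(sp, function(d) d$mass[which.max(d$abundance)], 0)
  }
  .tq_env$mono
}

#' Parse a molecular formula
#'
#' Parses a Hill-notation molecular formula (element symbols each
#' followed by an optional positive count, no parentheses or isotope
#' labels) into an elemental composition: a named integer vector of
#' element counts.
#'
#' @param text Formula string, e.g. `"C4H3FN2O2"` (5-fluorouracil).
#' @return A named integer vector of class `elemental_composition`, in
#'   canonical Hill order (C, H, then remaining elements alphabetically).
#' @export
#' @examples
#' parse_formula("C4H3FN2O2")
#' parse_formula("H2O")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula")
  if (grepl("[^A-Za-z0-9]", text)) {
    stop("formula may contain only element symbols and counts: ", text)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("unparseable formula: ", text)
  }
  known <- unique(isotope_table()$element)
  counts <- integer(0)
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% known) stop("unknown element symbol '", sym, "' in ", text)
    if (is.na(n) || n < 1L) stop("invalid count for ", sym, " in ", text)
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  elemental_composition(counts)
}

#' Construct an elemental composition
#'
#' @param counts Named non-negative integer vector of element counts;
#'   zero counts are dropped. At least one element must be present.
#' @return Named integer vector of class `elemental_composition` in Hill
#'   order.
#' @export
elemental_composition <- function(counts) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers")
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("composition must contain at least one atom")
  known <- unique(isotope_table()$element)
  bad <- setdiff(names(counts), known)
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  # Hill order: C first, H second (when C present), rest alphabetical;
  # without C, all alphabetical.
  v <- stats::setNames(as.integer(counts), names(counts))
  syms <- names(v)
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    ord <- c("C", intersect("H", syms), rest)
  } else {
    ord <- sort(syms)
  }
  out <- v[ord]
  class(out) <- "elemental_composition"
  out
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<elemental composition> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Format a composition as a Hill-notation formula
#'
#' @param comp An `elemental_composition`.
#' @return A single string, e.g. `"C9H12FN2O8P"`.
#' @export
format_formula <- function(comp) {
  comp <- as_composition(comp)
  paste0(names(comp), ifelse(comp > 1L, comp, ""), collapse = "")
}

as_composition <- function(x) {
  if (inherits(x, "elemental_composition")) return(x)
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) return(elemental_composition(x))
  stop("cannot interpret object as an elemental composition")
}

#' Monoisotopic mass of a composition
#'
#' Sum over elements of count times the exact mass of the element's most
#' abundant isotope, from the pinned mass table.
#'
#' @param comp An `elemental_composition`, a formula string, or a named
#'   count vector.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O")   # 18.0106
monoisotopic_mass <- function(comp) {
  comp <- as_composition(comp)
  mono <- .monoisotopic_masses()
  sum(comp * mono[names(comp)])
}

#' m/z of the deprotonated ion [M-H]-
#'
#' The singly charged anion observed in negative-mode electrospray: the
#' neutral monoisotopic mass minus the mass of a proton (the electron is
#' retained by the anion, which matters at the sub-mDa level probed by a
#' 5 ppm gate on small ions).
#'
#' @inheritParams monoisotopic_mass
#' @return m/z in Da of the singly charged `[M-H]-` species.
#' @export
#' @examples
#' mz_deprotonated("C4H3FN2O2")  # 5-fluorouracil, ~129.0106
mz_deprotonated <- function(comp) {
  comp <- as_composition(comp)
  if (!"H" %in% names(comp) || comp[["H"]] < 1L) {
    stop("[M-H]- requires at least one hydrogen in the neutral formula")
  }
  monoisotopic_mass(comp) - .PROTON_MASS
}

#' Parts-per-million deviation between two m/z values
#'
#' @param observed,expected m/z values in Da.
#' @return Signed deviation in ppm, `(observed - expected) / expected * 1e6`.
#' @export
ppm_error <- function(observed, expected) {
  (observed - expected) / expected * 1e6
}

#' Symmetric ppm mass window
#'
#' @param mz Center m/z (Da), positive.
#' @param tol Tolerance in ppm, positive.
#' @return An `mz_window`: numeric `c(low, high)` with `low < high`.
#' @export
#' @examples
#' ppm_window(129.0109, 5)
ppm_window <- function(mz, tol) {
  stopifnot(mz > 0, tol > 0)
  mz_window(mz * (1 - tol * 1e-6), mz * (1 + tol * 1e-6))
}

#' Isolation (SIM) window around a target m/z
#'
#' The quadrupole isolation window used for targeted single ion
#' monitoring: the target plus/minus half the isolation width.
#'
#' @param target_mz Target m/z (Da).
#' @param isolation_width Full window width in m/z (default 4.0, the
#'   tSIM isolation window of the acquisition scheme).
#' @return An `mz_window`.
#' @export
#' @examples
#' sim_window(325.024, 4.0)  # 323.024-327.024
sim_window <- function(target_mz, isolation_width = 4.0) {
  stopifnot(isolation_width > 0)
  mz_window(target_mz - isolation_width / 2, target_mz + isolation_width / 2)
}

#' m/z interval
#'
#' @param low,high Interval bounds in Da, `low < high`.
#' @return Numeric vector `c(low, high)` of class `mz_window`.
#' @export
mz_window <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L, low < high)
  structure(c(low = low, high = high), class = "mz_window")
}

#' @export
print.mz_window <- function(x, ...) {
  cat(sprintf("<m/z window> %.4f-%.4f\n", x[[1]], x[[2]]))
  invisible(x)
}

in_window <- function(mz, window) {
  mz >= window[[1]] & mz <= window[[2]]
}
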