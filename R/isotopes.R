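# Isotope envelope simulation by sparse per-element convolution.
#
# Peaks are tracked as (neutron shift k, probability, centroid mass):
# isotopologues sharing the same nominal mass shift are merged into one
# centroid with abundance-weighted mean mass, which is what a centroided
# high-resolution spectrum shows for small molecules (isotope fine
# structure is out of scope).

# distribution of one element with n atoms: list(shift, prob, mass)
.element_pattern <- function(element, n, prune = 1e-12) {
  iso <- isotope_table()
  iso <- iso[iso$element == element, , drop = FALSE]
  base <- which.max(iso$abundance)
  shifts <- iso$mass_number - iso$mass_number[base]
  one <- list(shift = shifts, prob = iso$abundance, mass = iso$mass)
  acc <- list(shift = 0L, prob = 1, mass = 0)
  # binary exponentiation over convolution keeps large counts cheap
  pow <- one
  m <- n
  while (m > 0) {
    if (m %% 2 == 1) acc <- .convolve_patterns(acc, pow, prune)
    m <- m %/% 2
    if (m > 0) pow <- .convolve_patterns(pow, pow, prune)
  }
  acc
}

.convolve_patterns <- function(a, b, prune = 1e-12) {
  shift <- outer(a$shift, b$shift, `+`)
  prob <- outer(a$prob, b$prob, `*`)
  mass <- outer(a$mass, b$mass, `+`)
  k <- as.vector(shift)
  p <- as.vector(prob)
  mm <- as.vector(mass)
  ps <- rowsum(p, k)
  ms <- rowsum(p * mm, k) / ps
  keys <- as.integer(rownames(ps))
  keep <- ps[, 1] >= prune * max(ps)
  ord <- order(keys[keep])
  list(shift = keys[keep][ord], prob = ps[keep, 1][ord], mass = ms[keep, 1][ord])
}

#' Theoretical isotope pattern of a molecule or its [M-H]- ion
#'
#' Computes the isotopologue envelope of a composition by iterated
#' convolution of per-element isotope distributions from the pinned
#' table, aggregating isotopologues by nominal neutron shift into
#' abundance-weighted centroids. For the `"[M-H]-"` adduct the envelope
#' is that of the composition minus one hydrogen, with each peak shifted
#' up by one electron mass.
#'
#' @param comp Composition (object, formula string, or named counts).
#' @param adduct `"none"` for the neutral molecule or `"[M-H]-"` for the
#'   deprotonated anion.
#' @param truncation Relative-abundance threshold, in (0, 0.01]: peaks
#'   below `truncation` times the base peak are dropped (default 1e-3).
#' @return A data.frame of class `isotope_pattern` with columns `mz`
#'   (strictly increasing; the first row is the monoisotopic peak) and
#'   `abundance` (absolute isotopologue probabilities summing to at most
#'   1).
#' @export
#' @examples
#' isotope_pattern("C4H3FN2O2", adduct = "[M-H]-")
isotope_pattern <- function(comp, adduct = c("none", "[M-H]-"),
                            truncation = 1e-3) {
  adduct <- match.arg(adduct)
  stopifnot(truncation > 0, truncation <= 0.01)
  comp <- as_composition(comp)
  shift_mz <- 0
  if (adduct == "[M-H]-") {
    if (!"H" %in% names(comp) || comp[["H"]] < 1L) {
      stop("[M-H]- requires at least one hydrogen")
    }
    counts <- unclass(comp)
    counts[["H"]] <- counts[["H"]] - 1L
    counts <- counts[counts > 0]
    comp <- elemental_composition(counts)
    shift_mz <- .ELECTRON_MASS
  }
  acc <- list(shift = 0L, prob = 1, mass = 0)
  for (el in names(comp)) {
    acc <- .convolve_patterns(acc, .element_pattern(el, comp[[el]]), 1e-12)
  }
  keep <- acc$prob >= truncation * max(acc$prob)
  out <- data.frame(mz = acc$mass[keep] + shift_mz,
                    abundance = acc$prob[keep])
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truncation") <- truncation
  attr(out, "adduct") <- adduct
  class(out) <- c("isotope_pattern", "data.frame")
  out
}

#' Enumerate subformulas explaining a fragment m/z
#'
#' Finds every elemental sub-multiset of a parent composition whose
#' singly charged anion m/z (monoisotopic mass plus one electron mass)
#' lies within a ppm tolerance of an observed fragment m/z. This is the
#' fragment-explanation primitive used to validate MS2 fingerprints:
#' a fragment anion of a deprotonated precursor must be composed of a
#' subset of the precursor's atoms.
#'
#' The search is a bounded depth-first enumeration over element counts
#' with mass-remaining pruning; candidates are ranked by absolute ppm
#' deviation, ties broken by fewer heteroatoms (atoms other than C and
#' H).
#'
#' @param parent Parent composition (typically the deprotonated
#'   precursor composition, i.e. the neutral formula minus one H).
#' @param observed_mz Observed fragment m/z (Da), positive.
#' @param tol Mass tolerance in ppm.
#' @return A list of `elemental_composition` objects sorted by absolute
#'   ppm deviation, each carrying attributes `mz` (theoretical anion
#'   m/z) and `ppm` (signed deviation observed vs theoretical). Empty
#'   list when no subformula explains the mass.
#' @export
#' @examples
#' parent <- parse_formula("C9H12FN2O8P")  # FdUMP, neutral
#' enumerate_subformulas(deprotonated_composition(parent), 96.969, tol = 10)
enumerate_subformulas <- function(parent, observed_mz, tol = 10) {
  parent <- as_composition(parent)
  stopifnot(observed_mz > 0, tol > 0)
  mono <- .monoisotopic_masses()
  syms <- names(parent)
  masses <- mono[syms]
  lo <- observed_mz * (1 - tol * 1e-6) - .ELECTRON_MASS
  hi <- observed_mz * (1 + tol * 1e-6) - .ELECTRON_MASS
  nmax <- as.integer(parent)
  # heaviest elements first tightens the mass-remaining bound
  ord <- order(masses, decreasing = TRUE)
  syms <- syms[ord]; masses <- masses[ord]; nmax <- nmax[ord]
  # max mass attainable from elements i..k
  tail_max <- rev(cumsum(rev(masses * nmax)))
  hits <- list()
  recurse <- function(i, counts, mass) {
    if (mass > hi) return()
    if (i > length(syms)) {
      if (mass >= lo && mass > 0) {
        hits[[length(hits) + 1L]] <<- counts
      }
      return()
    }
    if (mass + tail_max[i] < lo) return()
    for (n in 0:nmax[i]) {
      counts[i] <- n
      recurse(i + 1L, counts, mass + n * masses[i])
    }
  }
  recurse(1L, integer(length(syms)), 0)
  if (length(hits) == 0L) return(list())
  out <- lapply(hits, function(cnt) {
    names(cnt) <- syms
    comp <- elemental_composition(cnt)
    mz <- monoisotopic_mass(comp) + .ELECTRON_MASS
    attr(comp, "mz") <- mz
    attr(comp, "ppm") <- ppm_error(observed_mz, mz)
    comp
  })
  dev <- vapply(out, function(x) abs(attr(x, "ppm")), 0)
  hetero <- vapply(out, function(x) sum(x[!names(x) %in% c("C", "H")]), 0L)
  out[order(dev, hetero)]
}

#' Deprotonated composition of a neutral molecule
#'
#' The elemental composition of the `[M-H]-` anion: the neutral formula
#' with one hydrogen removed. Fragment subformula explanation runs
#' against this composition, since fragments of a deprotonated precursor
#' draw from its atoms.
#'
#' @inheritParams monoisotopic_mass
#' @return An `elemental_composition` with one H fewer.
#' @export
deprotonated_composition <- function(comp) {
  comp <- as_composition(comp)
  if (!"H" %in% names(comp) || comp[["H"]] < 1L) {
    stop("[M-H]- requires at least one hydrogen")
  }
  counts <- unclass(comp)
  counts[["H"]] <- counts[["H"]] - 1L
  elemental_composition(counts[counts > 0])
}
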