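# Independent brute-force oracles, deliberately naive: they enumerate
# rather than convolve/search, so they share no code path with the
# implementation they check.

# Exhaustive isotopologue enumeration: every per-atom isotope choice,
# aggregated by nominal neutron shift into probability-weighted
# centroids. Only feasible for small formulas.
oracle_isotope_pattern <- function(formula) {
  comp <- parse_formula(formula)
  stopifnot(sum(comp) <= 12)
  iso <- isotope_table()
  atoms <- list()
  for (el in names(comp)) {
    sub <- iso[iso$element == el, , drop = FALSE]
    base <- which.max(sub$abundance)
    tab <- data.frame(shift = sub$mass_number - sub$mass_number[base],
                      mass = sub$mass, prob = sub$abundance)
    atoms <- c(atoms, rep(list(tab), comp[[el]]))
  }
  idx <- expand.grid(lapply(atoms, function(a) seq_len(nrow(a))))
  shift <- rowSums(cbind(mapply(function(a, i) a$shift[i], atoms, idx)))
  mass <- rowSums(cbind(mapply(function(a, i) a$mass[i], atoms, idx)))
  prob <- apply(cbind(mapply(function(a, i) a$prob[i], atoms, idx)), 1, prod)
  agg_p <- tapply(prob, shift, sum)
  agg_m <- tapply(prob * mass, shift, sum) / agg_p
  ord <- order(as.integer(names(agg_p)))
  data.frame(mz = as.numeric(agg_m[ord]), abundance = as.numeric(agg_p[ord]))
}

# Exhaustive sub-multiset enumeration via expand.grid; anion m/z is
# monoisotopic mass + one electron mass.
oracle_subformulas <- function(parent_formula, observed_mz, tol_ppm) {
  comp <- parse_formula(parent_formula)
  iso <- isotope_table()
  mono <- sapply(split(iso, iso$element),
                 function(d) d$mass[which.max(d$abundance)])
  grid <- expand.grid(lapply(as.integer(comp), function(n) 0:n))
  names(grid) <- names(comp)
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  masses <- as.matrix(grid) %*% mono[names(comp)] + 0.000548579909065
  hit <- abs((observed_mz - masses) / masses * 1e6) <= tol_ppm
  out <- grid[hit, , drop = FALSE]
  if (nrow(out) == 0L) return(character(0))
  apply(out, 1, function(cnt) {
    cnt <- cnt[cnt > 0]
    cnt <- cnt[order(names(cnt))]
    paste0(names(cnt), ifelse(cnt > 1, cnt, ""), collapse = "|")
  })
}

# canonical key for comparing composition sets
comp_key <- function(comp) {
  cnt <- sort(unclass(comp)[unclass(comp) > 0])
  cnt <- cnt[order(names(cnt))]
  paste0(names(cnt), ifelse(cnt > 1, cnt, ""), collapse = "|")
}

# small helper: a clean Gaussian chromatogram as a tq_xic
gaussian_xic <- function(amp, mu, sigma, rt = seq(0, 3, by = 0.01),
                         baseline = 0) {
  xic <- data.frame(rt = rt,
                    intensity = amp * exp(-(rt - mu)^2 / (2 * sigma^2)) + baseline)
  attr(xic, "window") <- ppm_window(100, 5)
  attr(xic, "ms_level") <- 1L
  class(xic) <- c("tq_xic", "data.frame")
  xic
}
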