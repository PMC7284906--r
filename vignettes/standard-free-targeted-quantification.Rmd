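---
title: "Standard-free targeted quantification of a fluoropyrimidine metabolite panel"
author: "tsimquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standard-free targeted quantification of a fluoropyrimidine metabolite panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsimquant)
```

## The problem this package addresses

5-fluorouracil (5-FU) is only cytotoxic after intracellular conversion to
active metabolites (FdUMP, FURD, FdURD, FUTP, FdUTP), and a blunted
conversion is one route to chemoresistance. Measuring those metabolites is
awkward because authentic standards are not commercially available for most
of them, which rules out classical triple-quadrupole assays that calibrate
against a standard per analyte. The alternative implemented here leans on
high-resolution mass spectrometry: compute each analyte's deprotonated
precursor m/z and isotope envelope directly from its molecular formula,
acquire with targeted single ion monitoring plus data-dependent MS2
(tSIM-ddMS2) on the computed inclusion list, and accept an identification
only when the accurate precursor mass, its isotope pattern, co-eluting
fingerprint fragments, and absence from an untreated control all agree.
Quantification is then *relative*: every compound's total (precursor +
product) peak area is normalized to the area of a single mid-range QC
standard (0.780 ng/µL FdUMP) acquired with each replicate batch.

`tsimquant` implements that whole workflow, plus a seeded simulator of
tSIM-ddMS2 acquisitions so the pipeline can be validated end to end with
known ground truth.

## Mass arithmetic and its conventions

All mass math derives from one pinned plain-text table of isotope masses
(AME2020) and abundances (CIAAW 2021), shipped in `inst/extdata` and
reported by `isotope_table()`. Reproducibility of every computed m/z from
the repository alone is the reason the table is pinned rather than taken
from whichever library happens to be installed.

The deprotonated ion's m/z is computed as the neutral monoisotopic mass
minus the mass of a *proton*, i.e. the electron stays with the anion:

$$ m/z_{[M-H]^-} = M_{mono} - m_p $$

The distinction from subtracting a neutral hydrogen atom is about 0.55 mDa
— roughly 4 ppm at m/z 129 — so at the pipeline's 5 ppm matching gate the
convention is not cosmetic. With it, all eight panel precursors match the
published fingerprint values within 5 ppm (the worst case, FdURD, is
3.8 ppm; see `fu_panel()`).

Two published inclusion-list entries (FdUMP 325.0211, FdURD 245.0605)
disagree both with exact-mass computation and with their own published scan
filter centers (325.0240, 245.0570); the bundled panel treats them as
typographical and records the alternates in its `alt_mz` column.

## Isotope envelopes

`isotope_pattern()` convolves per-element isotope distributions (binary
exponentiation over sparse convolution, pruning at $10^{-12}$ absolute
probability) and aggregates isotopologues by nominal neutron shift into
abundance-weighted centroids — what a centroided Orbitrap spectrum shows
for small molecules; isotope fine structure is deliberately out of scope.
Peaks below $10^{-3}$ of the base peak are dropped by default (`truncation`
accepts anything in $(0, 0.01]$). The test suite checks the convolution
peak-by-peak against an exhaustive isotopologue enumeration oracle on
formulas of up to 12 atoms, at $10^{-6}$ relative-abundance tolerance.

## Fragment explanation by subformula enumeration

A fragment anion of a deprotonated precursor must be an elemental
sub-multiset of the precursor's atoms. `enumerate_subformulas()` finds
every sub-multiset whose anion mass (monoisotopic mass + one electron) lies
within a ppm tolerance of the observed fragment, by depth-first search over
element counts with a mass-remaining bound, heaviest elements first.
Candidates are ranked by absolute ppm deviation, ties broken by fewer
heteroatoms. One caveat the tests make explicit: published fragment masses
are rounded to 2–3 decimals, so the top-ranked candidate by pure mass
deviation is occasionally an isobaric alternative to the chemically
expected subformula; the expected subformula is always in the returned set
at 10 ppm. Mass alone cannot adjudicate rounded values, and this package
does not pretend otherwise.

The identity-validation scores reported by `validate_fragments()` and
`isotope_pattern_score()` are this package's own analogues of the scores
that formula-identification tools print: they preserve the semantics
(higher is better, a ±5 ppm median-deviation gate) but are not numerically
comparable to any external tool's proprietary scoring.

## The acquisition simulator and what it does (not) emulate

`simulate_run()` models the instrument duty cycle directly: per cycle
(default 0.01 min), one MS1 SIM scan per inclusion-list target over a
4.0 m/z isolation window, then data-dependent MS2 for up to `loop_count`
(4) targets whose precursor trace exceeds the trigger threshold. Analytes
elute as Gaussians; the amplitude is set so the integrated monoisotopic
trace equals `concentration × response_factor`, which the manifest records
as the exact truth downstream code must recover. Fragments appear in MS2 at
configurable yields relative to the precursor trace. All m/z values carry
Gaussian error with SD 1 ppm, inside the < 2 ppm accuracy class of the
emulated instrument.

`simulate_study()` reproduces the study design: two groups
(parental/resistant) × treated/untreated with 10 biological replicates by
default, a 2-fold calibrant dilution series from 100 down to 0.195 ng/µL
(10 runs), one 0.780 ng/µL FdUMP QC run per replicate batch, and a blank.
Treatment-derived analytes appear only in treated runs; the endogenous
nucleotides dUMP and TMP appear in every biological run; FUTP and FdUTP
default to concentration zero, emulating species below the detection
limit. Biological scatter is log-normal with 20% CV — chosen once as a
realistic spread for replicate cell-culture metabolite levels, with the
mean-preserving parameterization $\mu = -\sigma_{\log}^2/2$ so configured
group means are unbiased. Retention times default to the published panel
values (1.4–2.1 min on an F5 column).

What the simulator does *not* emulate: ion suppression and other matrix
effects on response, retention drift between runs, exponentially modified
(tailing) peak shapes, profile-mode data, and real biological matrix
complexity beyond configurable discrete interferences plus noise peaks.
Passing tests therefore demonstrate that the pipeline's logic and
arithmetic are correct under its stated assumptions — not that the assay
performs identically on real lysates, where matrix effects dominate
calibration transferability.

## Extraction, peak picking and integration

Chromatograms are extracted by summing centroid intensity inside a fixed
m/z window per qualifying scan; MS1 SIM scans contribute only to windows
they actually isolate, and MS2 extraction is restricted to scans whose
precursor target matches within 5 ppm. Peak picking takes local maxima
above `min_snr` (3) times a robust noise level — the MAD of the lowest
intensity quartile, chosen because it is parameter-free and ignores the
peaks themselves — and extends bounds to the flanking valley or baseline
return, requiring at least 3 points. Integration is trapezoidal with a
linear baseline between the bound endpoints, floored at zero. When several
candidate peaks survive, the one nearest the expected retention time is
used if an expected RT is known, otherwise the largest; this mirrors how an
analyst resolves a crowded extracted chromatogram. Fragments are
integrated over the *precursor's* bounds so the "total area including
precursor and products" is well defined.

## Detection decisions

A compound is detected in a treated sample when a precursor peak is found,
at least `min_fragments` (default 1) fingerprint fragments co-elute with it
(apex within 0.1 min), and the paired untreated control shows no matching
signal. The control rule needs two numeric choices the source procedure
states only qualitatively: "absence" in the control is implemented as
control area below `veto_fraction` (0.1) of the treated area, because a
hard zero is untestable under noise; and the co-elution tolerance of
0.1 min puts "same retention time" at about two peak widths. Both are
configurable. The veto is only applied to treatment-derived analytes:
endogenous nucleotides are expected in untreated samples too, so
`analyze_study()` exempts them (`control_exempt`, default dUMP and TMP) —
otherwise the rule would veto exactly the compounds it is meant to leave
alone.

## Calibration, normalization and statistics

`fit_calibration()` is ordinary least squares of area on concentration;
LOD = 3 × SD and LOQ = 10 × SD with SD the residual standard deviation in
concentration units (residual SD over slope). The source defines the
limits only as "3×SD"/"10×SD"; the residual-based reading is the default
because it needs no extra measurements, and a blank-based SD is available
via `sd_source = "blank"`. LOQ/LOD = 10/3 identically, and a noise-free
series yields LOD = 0 and $R^2 = 1$ — both are test invariants.

Group comparison uses the pooled-variance Student's t-test by default
(Welch by flag), reporting mean ± SEM with n per group, matching the
"mean ± s.e.m., Student's t-test (n = 10)" analysis convention.
Non-detected replicates are excluded from the test and flagged rather than
imputed as zero, so a compound below the detection limit is reported as
"below detection", not as a zero level. No multiple-testing correction is
applied by default across the 8-compound panel (Benjamini–Hochberg is one
flag away), matching the original analysis scale.

## Numerical choices and degenerate inputs

* Zero-variance groups with equal means return t = 0, p = 1 instead of
  erroring; unequal means with zero variance return p = 0.
* Empty chromatograms, empty runs and zero-length spectra are legal values
  throughout, not errors.
* Fixture files store doubles at full precision (`%.17g`), so the internal
  format round-trips bit-exactly; mzML interchange via `mzR` round-trips
  to $10^{-6}$.
* Simulated spectra merge centroids closer than $10^{-7}$ m/z to keep the
  strictly-increasing m/z invariant under jitter.

## Problem sizes used by the test suite

The suite validates the statistical claims at deliberately desk-scale
sizes, chosen as the smallest designs that still measure the property:
detection is checked over 50 seeded single-replicate studies; fold-change
recovery over 6 seeded studies per configured fold (0.25, 0.5, 1, 2) at
n = 10 replicates, asserting the mean estimate within 10% of truth; and
type-I error over 1000 two-group draws from the study's own scatter model
at n = 10 per group, asserting the 0.05 ± 0.02 band.

## Known limitations

* Only the `[M-H]⁻` adduct and singly charged species are supported;
  positive-ion adducts, multiple charging and isotope fine structure are
  out of scope.
* Identity scores are package-defined analogues, not reproductions of any
  external tool's scoring.
* Quantification is strictly relative to the QC reference; absolute
  concentrations are only meaningful for compounds with their own
  calibration series.
* Peak boundaries are this package's valley/baseline rule; no claim is
  made of matching any particular vendor integrator.
* No cross-run retention-time alignment is performed; runs are assumed
  RT-comparable, as is reasonable for a short isocratic-start gradient.
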