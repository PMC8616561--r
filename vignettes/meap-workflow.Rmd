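---
title: "Identifying native protein complexes from ME-AP and complexome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying native protein complexes from ME-AP and complexome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mecap)
```

## The problem

Affinity purification of a low-abundance membrane protein recovers, besides
the bait and its true partners, hundreds of background proteins that bind
beads, antibodies or detergent micelles. Deciding which co-purified
proteins are genuine subunits of the native complex requires (i) accurate
label-free quantification at the MS1 level, (ii) stringent negative
controls, and (iii) cross-validation across independent purifications.
`mecap` implements that decision chain — *multi-epitope* affinity
purification (ME-AP) scoring — together with a second, orthogonal view of
the same question: complexome profiling of a blue-native gel lane, which
asks how large the intact complex actually is compared to the mass computed
from its subunit sequence.

This vignette explains the models and the choices behind each stage;
everything stated here is computed by the package's tests or acceptance
script, not asserted from outside data.

## MS1 quantification model

A run is a table of identified MS1 features: peptide, charge, theoretical
and observed m/z, elution time, and peak volume (PV) — the integrated
intensity that serves as the label-free quantification unit.

**m/z recalibration.** Instrument calibration drifts by a few ppm and is
nearly constant within a run. We estimate each run's offset as the *median*
signed ppm error over all features matched within a wide 50 ppm window and
divide observed m/z by `1 + offset*1e-6`. The median is robust to the small
fraction of mismatches the wide window admits; after correction the
residual offset on simulated runs is below 0.1 ppm.

**Retention-time alignment.** Runs drift non-linearly in elution time. For
each peptide (by sequence and charge) the *reference time* is the median of
its elution times across runs; each run is then warped onto the reference
by LOESS regression (degree 2, tricube weights, robustified by two
reweighting passes). Because "dynamically calculated" references depend on
the warps and vice versa, the two steps alternate; two rounds suffice on
smooth monotone drifts — per-run residual MAD is non-increasing across
rounds in the diagnostics, and further rounds change warps by far less
than the assignment window. The fitted curve is passed through an isotonic
repair (`isoreg`) so the warp can never reverse elution order; between
anchor points it is evaluated by linear interpolation and extended with
unit slope outside the anchored range. Defaults: `span = 0.3` (smooth
enough for minutes-scale drift over a ~100 min gradient, local enough to
track curvature), `iterations = 2`, a floor of 30 anchors per run.

**Peak-volume assignment.** A feature is assigned to an identified peptide
when it agrees within ±1 min of aligned elution time and ±3 ppm of m/z —
the match window is deliberately asymmetric in information: m/z is several
orders of magnitude more discriminating than RT at these tolerances, so
ambiguities are resolved by smallest |ppm| first, then smallest |RT|
difference, then lexicographic peptide order (a pure determinism
tie-break). Each feature is assigned at most once, so total assigned PV
never exceeds total feature PV; PVs of features assigned to the same
(peptide, charge) are summed.

## Protein abundance and the abundance-norm

Per protein and run we sum the PVs of its *specific* peptides (peptides
mapping to more than one protein are ignored) and discard proteins
quantified by fewer than two specific peptides — the standard one-hit-wonder
filter. Summed PV grows with protein size, so for molar comparisons it is
divided by the number of *MS-accessible* peptides: distinct fully tryptic
peptides (cleavage after K/R, never before P, up to one missed cleavage)
whose monoisotopic mass lies in 700–3500 Da. The exact accessible-peptide
definition in the literature varies with instrument setup; the one used
here (window and missed-cleavage count are both configurable) is a declared
convention, and the package treats a digest yielding zero accessible
peptides as "norm undefined" rather than an arithmetic error. Protein
grouping is by exact accession; collapsing homolog/subset groups to a
predominant member is out of scope.

## Specificity, consistency, and abundance classes

For every protein quantified in at least one target purification:

* `target_value` — median abundance-norm over the target purifications in
  which it appears;
* `control_value` — the *maximum* abundance-norm over all negative-control
  runs (target-unrelated antibodies and knockout purifications): a
  worst-case, maximally stringent comparison;
* if the protein never appears in any control, the ratio denominator is a
  pseudo-floor of half the smallest positive control abundance-norm, and
  the record keeps `control_detected = FALSE` so "absent from all
  controls" remains a distinguishable, stronger statement than any finite
  ratio.

A purification is *specific* for a protein when its abundance-norm exceeds
`specificity_fold` times the control value (default 10) or the protein is
control-free. The default fold is a package choice: it cleanly separates
planted truth from background across the synthetic designs and is exposed
in `call_config()` — raising it (or `min_antibodies`) provably never
enlarges the called set. A protein is a *high-confidence partner* when
specific with ≥ 2 distinct antibodies under the same detergent; requiring
agreement within one solubilisation condition avoids calling proteins
whose apparent enrichment is condition-specific noise, and can be relaxed
with `require_same_detergent = FALSE`.

Prey-to-bait molar ratios (median over specific purifications, per
detergent) are binned into `=` (0.33–3.3-fold of the bait), `<`
(0.033–0.33), `<<` (0.0033–0.033) and `<<<` (< 0.0033). Bounds are taken
lower-inclusive; the parity class is closed at 3.3, and ratios above 3.3
also report `=` with a warning since no super-stoichiometric class is
defined. Whether ratio-to-bait should aggregate by median or mean is not
settled usage; the median was chosen for robustness to a single outlier
purification.

## Complexome profiling

Gel slices are numbered from the top (slice 1 = largest mass). Profiles
are smoothed by a centred sliding average over 5 slices; at the edges the
window truncates to the available slices, which preserves profile length
and avoids padding artefacts, and smoothing can never exceed the input
envelope. Marker complexes of known mass anchor the slice→mass map, fitted
as a four-parameter logistic in `log10(mass)`:

`log10(M) = d + (a − d) / (1 + exp((s − s0)/b))`

"Sigmoidal" does not pin down a functional form; the 4-parameter logistic
is the standard choice, is analytically invertible, and recovers noiseless
logistic markers to 1e-4 relative accuracy in the tests. The fit is
rejected unless strictly monotone (mass decreasing with slice) over the
marker range; marker tables whose masses do not decrease with slice are a
data error naming the offenders. Slices outside the marker-anchored range
convert with an extrapolation warning.

The apparent complex mass is read at the smoothed profile maximum (ties
resolve to the smaller slice, i.e. the larger mass, with a multi-peak
warning) and the reported mass range spans the outermost slices at ≥ 50%
of the maximum. A half-maximum rule is a declared convention — published
mass ranges rarely state their extent rule — and is the natural analogue of
peak width at half height. Comparing the apparent mass against
`oligomer_mass(sequence, n)` (n × average — not monoisotopic — subunit
mass, matching the gel-scale mass convention) asks whether the native
complex carries mass beyond the bare n-mer.

## What the synthetic generators emulate

`simulate_apms_study()` plants a bait, true partners at configured molar
ratios, and background proteins in a multi-run design: target antibodies ×
detergents, five target-unrelated-control purifications, and knockout
controls lacking bait and partners. Peptides come from real in-silico
digests of generated sequences, so m/z and ppm arithmetic is physically
meaningful; runs carry smooth strictly increasing cubic RT warps (≤ 2 min),
constant per-run ppm offsets (±8 ppm), log-normal PV noise (σ = 0.25 on
the natural-log scale), 10% feature dropout, and a background spanning
four orders of magnitude of abundance — the stated dynamic range of the
quantification. Partners appear in controls at `1/enrichment_fold` of
their target abundance (default fold 100); `enrichment_fold = Inf`
reproduces the strict "never detected in any control" regime. Both regimes
are exercised in the tests.

`simulate_complexome()` plants Gaussian migration peaks (default width 3–4
slices) over 192 slices through a true logistic calibration, with seven
marker complexes spanning 130–2800 kDa — mitochondrial-style respiratory
complexes and supercomplexes — and multiplicative log-normal noise
(σ = 0.1). The true calibration places every marker inside the resolved
gel region, away from the edge slices where a truncated peak would bias
its detected maximum.

What the generators do **not** emulate: correlated (batch-like) intensity
noise, intensity-dependent dropout, co-eluting near-isobaric interference,
chimeric identifications, off-target TUC antibody binding with structure
beyond flat background, and overlapping complexes in the gel dimension.
Passing the planted-truth benchmarks therefore demonstrates that the
decision chain is implemented correctly and is well-conditioned at
realistic noise levels — not that it would survive every pathology of real
data.

## Problem sizes and reference values

The study designs used by the tests and acceptance script are the
package's defaults: 500 background proteins, 5 partners, 4 target
antibodies × 2 detergents, 5 TUC and 8 knockout control runs (≈ 64,000
features over 26 runs) for the end-to-end partner-recovery benchmark; a
reduced 60-background design for module-level properties; 192-slice
profiles for the gel arm; and a 5-decade design for the dynamic-range
check, where the contiguous span with median |log2(recovered/true)| ≤ 1
must cover at least four orders of magnitude.

The tetramer reference check uses
`inst/extdata/trpm7_mouse_tetramer_reference_synthetic.fasta` — a
**synthetic surrogate** subunit, not a database sequence: it has the
canonical length of the channel subunit it stands in for (1863 aa) and a
residue composition adjusted until an independent mass calculator
(pyteomics) reported the published ~212.4 kDa monomer average mass, so
four subunits weigh ~850 kDa. The check thus validates the package's
residue-mass arithmetic against an independent implementation at protein
scale; it does not re-derive the subunit mass from the canonical database
entry.

## Known limitations

* Protein inference is accession-exact; shared-peptide parsimony grouping
  is not implemented.
* Assignment transfers identifications only through the (m/z, RT) window —
  there is no FDR model for match-between-runs transfers.
* The abundance-norm denominator is a declared stand-in for lab-specific
  observable-peptide counting rules.
* Cross-run intensity normalisation beyond the abundance-norm (e.g.
  iBAQ/LFQ-style) is out of scope.
* The complexome arm reports one peak per protein; overlapping complexes
  are reported as a single peak with a multi-peak warning where detectable.
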