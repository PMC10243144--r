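---
title: "Protein Score Chromatograms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein Score Chromatograms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venompsc)
```

## The data and the representation

High-resolution nanofractionation venomics separates a crude snake venom by
reversed-phase LC, splits the effluent between intact-mass MS/UV detection
and a fraction collector that deposits 6 s or 12 s slices of the gradient
into consecutive wells of a 384-well plate, digests each well with trypsin,
and identifies the digests by fast nanoLC–MS/MS plus database searching.
Because a toxin elutes over several consecutive fractions, its per-well
search scores, plotted against the retention time of each well, trace out a
chromatogram-like curve: the **Protein Score Chromatogram (PSC)**. The PSC
is this package's central object. Summing all proteins' scores per fraction
gives the **Total Protein Chromatogram (TPC)**; substituting percent
sequence coverage for score gives the **Sequence Coverage Chromatogram
(SCC)**.

A protein search score is not a concentration. It grows with the amount of
digested protein in a well (more peptide-spectrum matches, better spectra)
but saturates, depends on sequence, and carries run-to-run noise. The
package therefore treats PSC peak areas as *semiquantitative*: reliable for
ranking toxins and for family-level composition, not for absolute amounts.
Absolute quantitation requires internal standards and is explicitly out of
scope.

## Plate geometry and retention-time reconstruction

Fractions are collected column by column in a serpentine path. Two
conventions are not fixed by the collection hardware description and are
therefore explicit, configurable choices:

* **Start corner and direction.** Collection is taken to begin at A1
  moving down column 1, then up column 2, alternating — the conventional
  reading order of a serpentine fill. `plate_layout()` records the
  convention; `serpentine_sequence()` and `well_to_fraction()` are exact
  inverses under it.
* **Retention time of a well.** A well integrates a finite time slice; we
  assign the *midpoint* of its collection window
  (`start + (i - 1/2) · resolution/60` minutes). The midpoint minimises
  systematic offset between a PSC apex and the underlying elution apex; a
  `start`-of-window convention is available via `fraction_schedule()`.

The default collection window is 2208 s, chosen so that 6 s fractions fill
368 wells (one run per plate) and 12 s fractions fill 184 wells (two runs
per plate, the second run continuing the same serpentine path). Dead time
between injection and the first collected fraction is zero by default and
configurable (`collection_start_min`). A 12 s plate holds two runs; traces
are always built per run and never span runs.

## From search exports to the merged table

Per-well search exports arrive as CSV in a canonical dialect (`accession`,
`score`, `coverage_pct`, `mass_da`, `description`, `species`, `sequence`,
`peptides`, `link`); a header-alias map adapts real export headers. Rows
with no accession or a non-numeric score are dropped and counted. A
duplicated accession within one well keeps only its highest-scoring record:
scores are not additive evidence, and duplicates indicate a malformed
export rather than two observations. No protein inference or homologue
grouping is attempted — the search engine has already collapsed peptides to
their closest database homologue, and second-guessing it here would blur
the provenance of every downstream number.

`merge_wells()` produces the venom's single merged table (one row per
well × protein, sorted by retention time, then accession for
determinism), realized as plain CSV — diffable, locale-safe (UTF-8, `.`
decimal), and byte-identical under any input permutation.

## Building PSCs

`build_psc()` places scores on the full fraction grid and **zero-fills**
wells where the protein was not reported. Zero-filling, rather than leaving
gaps, makes the trace a proper baseline-returning chromatogram and gives
peak detection a well-defined notion of "run of detection". No smoothing or
interpolation is ever applied to PSC values: each point is a raw
measurement of one well, and with only a handful of points per peak any
filter would manufacture shape.

## Peak detection and integration

The PSC peak model is deliberately simple, because a peak spans few
fractions:

* A **peak** is a maximal run of nonzero fractions, tolerating up to
  `gap_tolerance` consecutive zero fractions inside it (default 1 — a
  single dropout well, e.g. a failed digest or injection, should not split
  a toxin in two).
* A run containing two local maxima is **split** at the interior valley
  when the valley value is below `split_ratio` (default 0.5) times the
  smaller of the two maxima. The split test applies only to *strictly
  positive* valleys: a zero-valued valley is a dropout and is governed
  solely by `gap_tolerance` — otherwise any bridged gap would immediately
  re-split the run it just joined. The valley fraction itself is assigned
  to the earlier peak (an arbitrary but fixed tie-break; with 6 s fractions
  it moves at most `apex_value·resolution/120` of area between neighbours).
* **Integration** is the trapezoidal rule over the points inside the peak
  bounds, closed by zero-valued anchors one fraction interval outside each
  bound. The anchors treat wells as point samples of a continuous elution
  profile returning to baseline; they also give a single-fraction peak the
  triangular area `value × fraction_width` instead of zero, which keeps
  rare, sharply eluting toxins in the composition. Areas are in
  score · minutes so that 6 s and 12 s runs are directly comparable.

Both knobs are exposed and recorded in the pipeline report. Scaling a trace
scales every area linearly (the split criterion is a ratio, hence
scale-free), and detected peaks partition the nonzero fractions disjointly;
both properties are enforced by tests.

## Semiquantitation and family composition

Two modes are computed side by side, as the workflow's own comparison did:
**peak areas** (the default, more robust to a single saturated well) and
**summed scores** (the sum of a protein's scores over all wells, equal to
its PSC column total). Toxins are assigned to families (SVMP, SVSP, PLA2,
CTL, LAAO, 3FTx, CRISP, VKTI/Kunitz, disintegrin) by an ordered,
case-insensitive keyword table over the protein description — curated
databases encode the family in the protein name, and the order matters:
"metalloproteinase/disintegrin" is an SVMP domain architecture, so the SVMP
rule precedes the disintegrin rule. The table is an editable tibble, not
hard-coded logic. Family totals are normalized to fractions (the pie-chart
numbers); all-zero totals yield an empty result with a warning rather than
0/0.

UV cross-checking (`match_uv_peaks()`) integrates, for each PSC peak, the
220 nm UV peak whose apex lies within `rt_tolerance_min` (default 0.1 min);
UV peak bounds are the flanking local minima, cut off below 5 % of apex
height. Co-eluting toxins claiming one UV peak are flagged `ambiguous`
rather than apportioned — splitting a UV peak between proteins would
require assumptions (equal response per amide bond, no overlap error) that
the data cannot support.

## Correlating PSCs with intact-mass XICs

A multi-peak PSC for a single accession is either one protein with
different post-translational modifications, several near-identical isoforms
whose conserved tryptic peptides are credited to one database homologue, or
both. The intact-mass dimension disambiguates. For each PSC peak, each XIC
is tested on two axes:

* **Retention time**: the XIC apex (its global maximum within the peak
  window widened by the tolerance, ties resolved toward the smaller
  offset) must lie within `rt_tolerance_min` (default 0.1 min) of the PSC
  apex. Note that with 6 s fractions the PSC apex is quantized to 0.1 min,
  so a one-fraction apex shift from score noise can push a true match just
  outside the default tolerance; widen the tolerance to trade recall
  against co-elution confusion.
* **Shape**: Pearson correlation between the PSC and the XIC resampled
  (linearly) onto the PSC grid over the peak window ± one fraction must
  reach `min_similarity` (default 0.7). Pearson is scale- and
  offset-invariant, which is exactly the equivalence class "same peak
  shape"; a constant window has no shape and yields `NA`, never a match.

Verdicts per accession: ≥ 2 peaks with distinct matched masses (different
by more than `mass_tol_da`, default 1 Da) →
`multiple_masses_candidate_PTM_or_isoform`, with all pairwise mass deltas
reported; multiple peaks sharing one mass (or carrying none) →
`shared_peptide_artifact_suspected`; a lone peak → `single_form`. The mass
deltas are descriptive — no PTM dictionary is consulted, though the deltas
are exactly what one would look up against glycan or phosphate masses.

## The synthetic venom

`simulate_venom()` exists so that every downstream claim can be tested
against known truth. It emulates:

* Gaussian elution: toxin amount per fraction is the Gaussian probability
  mass of the fraction's time window (`fraction_amounts()`), conserving
  abundance up to tail truncation.
* A **linear score response** with multiplicative lognormal noise of unit
  mean and CV `noise_cv` (default 0.2), and a detection floor below which
  a well reports nothing. Linearity is the weakest assumption under which
  semiquantitation is meaningful at all; saturation or other
  nonlinearities can be emulated by editing the toxin table.
* Matched intact-mass XICs (one scaled Gaussian per toxin, labelled with
  its mass) and a UV trace (sum of all toxin Gaussians) on a 0.01 min
  grid.

The stock `default_venom_spec()` fixes the validation conditions: 12 toxins
in 4 families (SVMP/PLA2/SVSP/3FTx), abundances 100 down to 5 with ~1.2×
adjacent ratios (so ranks are meaningful but not trivially separated),
apexes spread over 5.8–32.8 min of the 36.8 min window and separated by at
least four peak widths, elution sigmas of 0.15–0.30 min (1.5–3 fraction
widths at 6 s), score response 50 per unit, and a detection floor at 1 % of
the venom's largest expected well score. Under these conditions the
pipeline recovers abundance ranks with Spearman ρ ≳ 0.99 and family
fractions within ~3 percentage points across seeds.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: chromatographic tailing and fronting, co-eluting
toxins sharing wells, score saturation at high load, cross-well
carry-over, wrong or missing database entries (every simulated search is
"correct"), and shared-peptide leakage between homologues. The recovery
numbers above are therefore an upper bound on real-data performance; the
isoform logic in particular is validated on constructed cases, not
simulated biology.

## Numerical conventions and degenerate inputs

* All-zero traces yield zero peaks, not errors; empty export directories
  yield a valid empty bundle with a warning.
* Grids are validated as uniform to 1e-9 relative before peak detection;
  trace combination requires grids identical to 1e-9 min.
* Apex ties within a peak take the earliest fraction; XIC apex ties take
  the smaller retention-time offset; combined-table column ties order
  lexicographically by accession. Every output is thereby a pure function
  of the input set, independent of input order.
* The simulator scopes its RNG with `withr::with_seed`: identical spec and
  seed give byte-identical exports, and the caller's RNG stream is
  untouched.

## Problem sizes in the test suite

Unit and property tests run on 10–20-fraction toy schedules plus the full
368-fraction default venom; the integration oracle is checked against a
brute-force trapezoid on 200 randomly generated traces; mapping round-trips
are exhaustive over both 6 s and 12 s runs. The full suite completes in
well under a minute.

## Known limitations

* Family classification is keyword-based; descriptions in transcriptome
  databases are often uninformative IDs, for which the rule table falls
  back to "other" (matching the practical need to search a curated
  database when family labels matter).
* Peak areas compare toxins *within* one run; between runs or instruments
  the score scale may differ (shorter gradients systematically deflate
  scores).
* The UV and XIC matching assumes the detectors' retention axes are
  already aligned with the fractionation axis; no warping is estimated.
* One run = one venom: multi-plate studies are processed run by run.
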