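# venompsc

Post-processing toolkit for **high-resolution nanofractionation
venomics** — the workflow in which a crude snake venom is separated by
reversed-phase LC, the effluent is split between intact-mass MS/UV
detection and a fraction collector filling a 384-well plate in 6 s or 12 s
serpentine fractions, each well is trypsin-digested, and the digests are
identified by fast nanoLC–MS/MS with database searching.

The package turns the resulting pile of per-well search exports into
interpretable, semiquantitative venom proteomes:

* **Plate mapping** — serpentine fraction ↔ well ↔ retention-time
  reconstruction and capacity planning (`plate_layout()`,
  `fraction_schedule()`, `well_map()`).
* **Merging** — per-well search exports + a job→well map become one
  retention-time-sorted result table (`read_search_dir()`,
  `merge_wells()`).
* **Protein Score Chromatograms** — for each toxin *t*, the trace
  `PSC_t(rt_i) = score(t, well_i)` over the fraction grid, zero-filled
  where the toxin was not found (`build_psc()`); also sequence-coverage
  (SCC) and summed (TPC) variants.
* **Semiquantitation** — peak detection on each PSC (maximal nonzero runs
  with a gap tolerance and a valley-split rule) and trapezoidal
  integration with baseline anchors; toxin-family composition as
  normalized peak-area (or summed-score) fractions — the venom pie chart
  (`detect_peaks()`, `family_abundance()`).
* **Correlation** — PSC peaks matched to intact-mass XIC peaks by apex
  retention time and Pearson peak-shape similarity; multi-peak accessions
  annotated as PTM/isoform candidates (distinct masses, with mass deltas)
  or suspected shared-peptide artifacts (one mass)
  (`match_psc_xic()`, `annotate_isoforms()`, `match_uv_peaks()`).
* **Simulation** — a ground-truthed synthetic venom (Gaussian elution,
  linear score response with lognormal noise, detection floor, matched
  XIC/UV traces) that closes the loop for validation
  (`simulate_venom()`).
* **Pipeline** — one call (or the `inst/scripts/venompsc` command line)
  from an exports directory to a result bundle with merged table, traces,
  peaks, family summary, matches, figures and a JSON report
  (`run_pipeline()`).

See the vignette `vignettes/psc-methods.Rmd` for the model, parameter
meanings and design rationale.

## Worked example

Simulate the stock 12-toxin, 4-family venom (20 % score noise, detection
floor at 1 % of the largest expected well score), merge, build PSCs,
integrate, and summarize:

```r
library(venompsc)

spec   <- default_venom_spec(seed = 1)
sim    <- simulate_venom(spec)
merged <- merge_wells(sim$hits, spec$schedule)
merged[1:4, c("rt_min", "well_id", "accession", "score", "coverage_pct")]
#>   rt_min well_id accession score coverage_pct
#> 1   5.45 J4      3FTX_D01   27.1         20.3
#> 2   5.55 I4      3FTX_D01  149.          48
#> 3   5.65 H4      3FTX_D01  361.          68.5
#> 4   5.75 G4      3FTX_D01  465.          76.9
```

Each row is one protein hit in one well; `rt_min` is the midpoint of the
well's 6 s collection window, and consecutive fractions sit in adjacent
wells of column 4 because the plate was filled serpentine-wise.

```r
traces <- build_all_psc(merged, spec$schedule)
peaks  <- dplyr::bind_rows(lapply(traces, detect_peaks))
peaks[peaks$accession == "PLA2_B01",
      c("rt_start", "rt_end", "apex_rt", "apex_value", "area")]
#>   rt_start rt_end apex_rt apex_value  area
#> 1     11.8   12.8    12.4      1385.  442.
```

The acidic PLA2 elutes over 11 fractions around its true 12.4 min apex;
`area` is in score·minutes (trapezoid with zero anchors one fraction
outside the bounds).

```r
peaks$family <- classify_family(
  merged$description[match(peaks$accession, merged$accession)])
family_abundance(peaks, "area")
#>   family total fraction
#> 1 SVMP    791.    0.368
#> 2 PLA2    620.    0.289
#> 3 SVSP    436.    0.203
#> 4 3FTx    300.    0.140
```

The recovered composition (36.8 / 28.9 / 20.3 / 14.0 %) sits within one
percentage point of the simulated ground truth
(37.7 / 28.1 / 20.9 / 13.2 %).

The same chain, from files on disk and including XIC/UV correlation and
figures, is one call:

```r
simulate_venom(spec, "demo")
run_pipeline(run_config(
  output_dir = "demo/results",
  exports_dir = "demo/exports", job_map = "demo/job_well_map.csv",
  xic = "demo/xic.csv", uv = "demo/uv.csv"))
```

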