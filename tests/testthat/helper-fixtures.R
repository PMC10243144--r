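# Shared fixture builders; everything is generated in code.

# trace on a uniform dt grid starting at dt/2 (fraction midpoints)
make_trace <- function(values, dt = 0.1, accession = "X",
                       value_kind = "score") {
  new_psc_trace(seq(dt / 2, by = dt, length.out = length(values)), values,
                accession = accession, value_kind = value_kind)
}

# tiny 10-fraction schedule (6 s fractions over 60 s)
tiny_schedule <- function(resolution_s = 6, window_s = 60) {
  fraction_schedule(resolution_s, window_s)
}

# minimal per-well hit rows in the canonical dialect
make_hits <- function(well_id, accession, score, coverage_pct = 50,
                      mass_da = 14000, description = "Phospholipase A2") {
  tibble::tibble(
    well_id = well_id, accession = accession, score = score,
    coverage_pct = coverage_pct, mass_da = mass_da,
    description = description, species = "Test venom",
    sequence = NA_character_, peptides = "PEPTIDEK;VENOMK",
    link = NA_character_
  )
}

# brute-force trapezoid oracle: accumulate segment by segment in a loop,
# independently of the package's vectorized integration
oracle_peak_area <- function(trace, peak) {
  dt <- diff(trace$rt_min)[1]
  sel <- which(trace$rt_min >= peak$rt_start - 1e-9 &
               trace$rt_min <= peak$rt_end + 1e-9)
  x <- c(trace$rt_min[min(sel)] - dt, trace$rt_min[sel],
         trace$rt_min[max(sel)] + dt)
  y <- c(0, trace$value[sel], 0)
  area <- 0
  for (i in seq_len(length(x) - 1)) {
    area <- area + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  area
}

# random sparse chromatogram-like trace (mix of peaks and dropouts)
random_trace <- function(n = 60, dt = 0.1) {
  v <- numeric(n)
  n_peaks <- sample(1:4, 1)
  for (k in seq_len(n_peaks)) {
    centre <- runif(1, 5, n - 5)
    sigma <- runif(1, 0.8, 3)
    height <- runif(1, 50, 1000)
    v <- v + height * exp(-((seq_len(n) - centre)^2) / (2 * sigma^2))
  }
  v[v < runif(1, 1, 20)] <- 0          # detection floor with dropouts
  v[sample(n, size = sample(0:5, 1))] <- 0  # random missing wells
  make_trace(v, dt = dt)
}

# two-peak single-accession merged fixture for isoform logic: peaks at
# 0.55 and 1.45 min on a 20-fraction 6 s grid
isoform_fixture <- function() {
  schedule <- fraction_schedule(6, 120)
  layout <- plate_layout()
  v <- numeric(20)
  v[4:8] <- c(10, 80, 200, 80, 10)
  v[13:17] <- c(10, 70, 180, 70, 10)
  wells <- serpentine_sequence(layout, 20)
  idx <- which(v > 0)
  hits <- make_hits(wells[idx], "PA2_X", v[idx])
  merged <- merge_wells(hits, schedule, layout)
  trace <- build_psc(merged, "PA2_X", schedule)
  fine <- seq(0, 2, by = 0.01)
  xic_two <- dplyr::bind_rows(
    tibble::tibble(label = "13958.3", rt_min = fine,
                   intensity = 1e4 * dnorm(fine, 0.55, 0.1)),
    tibble::tibble(label = "14000.1", rt_min = fine,
                   intensity = 1e4 * dnorm(fine, 1.45, 0.1))
  )
  xic_one <- tibble::tibble(
    label = "13958.3", rt_min = fine,
    intensity = 1e4 * (dnorm(fine, 0.55, 0.1) + dnorm(fine, 1.45, 0.1))
  )
  list(schedule = schedule, merged = merged, trace = trace,
       xic_two_masses = xic_two, xic_one_mass = xic_one)
}
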