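# Synthetic venom simulator: toxins elute as Gaussian peaks, are
# fractionated into wells, and yield noisy per-well search exports plus
# matched XIC and UV traces, with full ground truth for recovery tests.

#' Define a synthetic toxin
#'
#' One toxin elutes as a Gaussian concentration profile with apex
#' `apex_rt_min` and width `sigma_min`; the amount landing in a well is the
#' Gaussian probability mass of that well's collection window times
#' `abundance`. The search score reported for a well is linear in the
#' digested amount (`score_per_unit`), with multiplicative lognormal noise
#' applied by [simulate_venom()], and is suppressed below
#' `detection_floor`.
#'
#' @param accession Unique protein accession.
#' @param description Free text; should carry the family keyword so that
#'   [classify_family()] can recover the family.
#' @param family Ground-truth toxin family label.
#' @param apex_rt_min,sigma_min Elution apex and standard deviation, min.
#' @param abundance Relative amount, arbitrary units.
#' @param intact_mass_da Intact (undigested) mass, Da, used for the XIC
#'   label.
#' @param score_per_unit Search score per unit of digested amount.
#' @param detection_floor Score below which a well reports no hit.
#' @return A one-row tibble.
#' @export
synthetic_toxin <- function(accession, description, family, apex_rt_min,
                            sigma_min, abundance, intact_mass_da,
                            score_per_unit = 50, detection_floor = 0) {
  if (sigma_min <= 0) vp_abort("sigma_min must be > 0", "venompsc_spec_error")
  if (abundance < 0) vp_abort("abundance must be >= 0", "venompsc_spec_error")
  if (score_per_unit <= 0)
    vp_abort("score_per_unit must be > 0", "venompsc_spec_error")
  tibble::tibble(accession = accession, description = description,
                 family = family, apex_rt_min = apex_rt_min,
                 sigma_min = sigma_min, abundance = abundance,
                 intact_mass_da = intact_mass_da,
                 score_per_unit = score_per_unit,
                 detection_floor = detection_floor)
}

#' Assemble a synthetic venom specification
#'
#' @param toxins Tibble of toxins ([synthetic_toxin()] rows).
#' @param schedule A [fraction_schedule()].
#' @param layout A [plate_layout()].
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   score noise (default 0.2).
#' @param seed Integer seed; the same spec and seed reproduce identical
#'   exports byte for byte.
#' @return An object of class `venom_spec`.
#' @export
venom_spec <- function(toxins, schedule = fraction_schedule(6),
                       layout = plate_layout(), noise_cv = 0.2, seed = 1L) {
  if (any(duplicated(toxins$accession)))
    vp_abort(sprintf("duplicated accession(s) in spec: %s",
                     paste(unique(toxins$accession[duplicated(toxins$accession)]),
                           collapse = ", ")),
             "venompsc_spec_error")
  if (noise_cv < 0) vp_abort("noise_cv must be >= 0", "venompsc_spec_error")
  structure(list(toxins = toxins, schedule = schedule, layout = layout,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "venom_spec")
}

#' Default 12-toxin, 4-family synthetic venom
#'
#' The stock validation venom: 12 toxins across SVMP, PLA2, SVSP and 3FTx
#' with distinct abundances spanning 100 down to 5 (adjacent ratios around
#' 1.2), apexes spread over 5.8-32.8 min of the 36.8 min collection window
#' and separated by at least four peak widths, elution sigmas of
#' 0.15-0.30 min (1.5-3 fraction widths at 6 s), score response 50 per
#' unit, 20 % multiplicative score noise, and a detection floor at 1 % of
#' the venom's largest expected well score.
#'
#' @param seed Seed stored in the spec (default 1).
#' @param resolution_s Fraction resolution, 6 (default) or 12 s.
#' @param noise_cv Score noise CV (default 0.2).
#' @return A `venom_spec`.
#' @export
default_venom_spec <- function(seed = 1L, resolution_s = 6, noise_cv = 0.2) {
  toxins <- tibble::tribble(
    ~accession, ~description, ~family, ~apex_rt_min, ~sigma_min,
      ~abundance, ~intact_mass_da,
    "SVMP_A01", "Zinc metalloproteinase homolog A01", "SVMP", 24.0, 0.25,
      100, 46230.5,
    "SVMP_A02", "Zinc metalloproteinase/disintegrin A02", "SVMP", 27.2, 0.30,
      45, 23115.2,
    "SVMP_A03", "Zinc metalloproteinase homolog A03", "SVMP", 30.5, 0.28,
      12, 35480.8,
    "PLA2_B01", "Phospholipase A2, acidic, B01", "PLA2", 12.4, 0.18,
      80, 13958.3,
    "PLA2_B02", "Phospholipase A2, basic, B02", "PLA2", 14.6, 0.20,
      28, 13812.6,
    "PLA2_B03", "Phospholipase A2 homolog B03", "PLA2", 16.9, 0.20,
      9, 14102.4,
    "SVSP_C01", "Snake venom serine protease C01", "SVSP", 20.1, 0.22,
      60, 26244.1,
    "SVSP_C02", "Thrombin-like serine protease C02", "SVSP", 22.3, 0.25,
      20, 27051.7,
    "SVSP_C03", "Snake venom serine protease C03", "SVSP", 32.8, 0.26,
      7, 25913.9,
    "3FTX_D01", "Three-finger toxin D01", "3FTx", 5.8, 0.15,
      35, 6845.2,
    "3FTX_D02", "Three-finger toxin, cytotoxin, D02", "3FTx", 7.9, 0.16,
      15, 7012.9,
    "3FTX_D03", "Three-finger toxin, alpha-neurotoxin, D03", "3FTx", 9.8, 0.15,
      5, 6791.4
  )
  toxins$score_per_unit <- 50
  toxins$detection_floor <- 0
  schedule <- fraction_schedule(resolution_s)
  # floor at 1 % of the venom's largest expected (noise-free) well score
  max_score <- max(vapply(seq_len(nrow(toxins)), function(i) {
    max(fraction_amounts(toxins[i, ], schedule)) * toxins$score_per_unit[i]
  }, 0))
  toxins$detection_floor <- 0.01 * max_score
  venom_spec(toxins, schedule = schedule, noise_cv = noise_cv, seed = seed)
}

#' Amount of a toxin collected per fraction
#'
#' Fraction i spans a known time window; the amount collected is the
#' toxin's abundance times the Gaussian probability mass of that window, so
#' window totals conserve abundance up to truncation of the tails outside
#' the collection window.
#'
#' @param toxin One toxin row.
#' @param schedule A [fraction_schedule()].
#' @return Numeric vector, one amount per fraction of the run.
#' @export
fraction_amounts <- function(toxin, schedule) {
  i <- seq_len(schedule$wells_per_run)
  res_min <- schedule$resolution_s / 60
  lo <- schedule$collection_start_min + (i - 1) * res_min
  hi <- lo + res_min
  toxin$abundance * (stats::pnorm(hi, toxin$apex_rt_min, toxin$sigma_min) -
                     stats::pnorm(lo, toxin$apex_rt_min, toxin$sigma_min))
}

# deterministic saturating sequence-coverage model: coverage rises with the
# digested amount and plateaus below 95 %
coverage_model <- function(amount, max_amount) {
  ifelse(amount > 0, pmin(95, 100 * amount / (amount + 0.3 * max_amount)), 0)
}

#' Simulate a venom into search exports, XIC and UV traces
#'
#' Runs the generative chain: Gaussian elution -> fractionation ->
#' score = `score_per_unit * amount * lognormal noise` (unit mean,
#' CV `noise_cv`), reported only at or above the toxin's detection floor.
#' The parallel intact-mass data are emulated as one XIC per toxin (scaled
#' Gaussian on a 0.01 min grid, labelled with the intact mass) and the UV
#' trace as the sum of all toxin Gaussians. Outputs land in exactly the
#' formats the ingestion and correlation functions consume, closing the
#' loop without any real data.
#'
#' @param spec A [venom_spec()].
#' @param dir Optional directory; when given, writes `exports/<job>.csv`
#'   (wells with hits only), `job_well_map.csv`, `xic.csv`, `uv.csv` and
#'   `ground_truth.csv`.
#' @return Invisibly (visibly when `dir` is `NULL`) a list with `hits`
#'   (long tibble), `job_map`, `xic`, `uv`, `truth`, `expected` (noise-free
#'   score matrix, fractions x toxins) and `spec`.
#' @export
simulate_venom <- function(spec, dir = NULL) {
  tox <- spec$toxins
  if (any(duplicated(tox$accession)))
    vp_abort("duplicated accessions in spec", "venompsc_spec_error")
  schedule <- spec$schedule
  n_frac <- schedule$wells_per_run
  grid <- rt_grid(schedule)
  wells <- serpentine_sequence(spec$layout, n_frac)

  amounts <- vapply(seq_len(nrow(tox)),
                    function(i) fraction_amounts(tox[i, ], schedule),
                    numeric(n_frac))
  expected <- sweep(amounts, 2, tox$score_per_unit, `*`)

  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  noisy <- withr::with_seed(spec$seed, {
    if (sdlog > 0) {
      expected * matrix(stats::rlnorm(length(expected), -sdlog^2 / 2, sdlog),
                        nrow = n_frac)
    } else {
      expected
    }
  })

  hit_rows <- list(empty_hits())
  for (j in seq_len(nrow(tox))) {
    score <- noisy[, j]
    keep <- which(score > 0 & score >= tox$detection_floor[j])
    if (length(keep) == 0) next
    hit_rows[[j + 1]] <- tibble::tibble(
      well_id = wells[keep],
      accession = tox$accession[j],
      score = score[keep],
      coverage_pct = round(coverage_model(amounts[keep, j],
                                          max(amounts[, j])), 1),
      mass_da = tox$intact_mass_da[j],
      description = tox$description[j],
      species = "Synthetic venom (simulated)",
      sequence = NA_character_,
      peptides = NA_character_,
      link = NA_character_
    )
  }
  hits <- dplyr::bind_rows(hit_rows)
  hits <- hits[order(match(hits$well_id, wells), hits$accession), ,
               drop = FALSE]

  job_map <- tibble::tibble(job_id = as.character(1000L + seq_len(n_frac)),
                            well_id = wells)

  fine <- seq(0, schedule$collection_window_s / 60, by = 0.01)
  xic <- dplyr::bind_rows(lapply(seq_len(nrow(tox)), function(j) {
    tibble::tibble(label = sprintf("%.1f", tox$intact_mass_da[j]),
                   rt_min = fine,
                   intensity = 1e4 * tox$abundance[j] *
                     stats::dnorm(fine, tox$apex_rt_min[j], tox$sigma_min[j]))
  }))
  uv_y <- Reduce(`+`, lapply(seq_len(nrow(tox)), function(j) {
    tox$abundance[j] * stats::dnorm(fine, tox$apex_rt_min[j], tox$sigma_min[j])
  }))
  uv <- tibble::tibble(rt_min = fine, absorbance = 0.01 * uv_y)

  truth <- tox
  truth$true_fraction <- tox$abundance / sum(tox$abundance)
  # retention window over which the noise-free score clears the floor
  truth$rt_lo <- NA_real_
  truth$rt_hi <- NA_real_
  for (j in seq_len(nrow(tox))) {
    up <- which(expected[, j] >= max(tox$detection_floor[j], 1e-12))
    if (length(up) > 0) {
      truth$rt_lo[j] <- grid[min(up)]
      truth$rt_hi[j] <- grid[max(up)]
    }
  }

  sim <- list(hits = hits, job_map = job_map, xic = xic, uv = uv,
              truth = truth, expected = expected, spec = spec)

  if (!is.null(dir)) {
    exp_dir <- file.path(dir, "exports")
    dir.create(exp_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(job_map))) {
      wh <- hits[hits$well_id == job_map$well_id[i],
                 setdiff(names(hits), "well_id"), drop = FALSE]
      if (nrow(wh) == 0) next
      readr::write_csv(wh, file.path(exp_dir,
                                     paste0(job_map$job_id[i], ".csv")),
                       na = "")
    }
    readr::write_csv(job_map, file.path(dir, "job_well_map.csv"))
    readr::write_csv(xic, file.path(dir, "xic.csv"))
    readr::write_csv(uv, file.path(dir, "uv.csv"))
    readr::write_csv(truth, file.path(dir, "ground_truth.csv"), na = "")
    return(invisible(sim))
  }
  sim
}
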