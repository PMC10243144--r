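# Correlating PSC peaks with intact-mass XIC traces and flagging
# isoform / post-translational-modification candidates.
#
# A protein whose PSC shows several peaks may be one protein carrying
# different PTMs, or several near-identical isoforms whose shared tryptic
# peptides are credited to the closest database homologue. The parallel
# intact-mass run disambiguates: distinct accurate masses under the
# different PSC peaks point to PTM/isoform variants, while one shared mass
# suggests a shared-peptide artifact.

#' Resample a trace onto a retention-time grid
#'
#' Linear interpolation; grid points outside the trace's retention-time
#' range get value 0 (baseline convention).
#'
#' @param trace A tibble with `rt_min` and a value column (second column
#'   used), e.g. an XIC or UV trace.
#' @param grid Numeric retention-time grid (minutes).
#' @return Numeric vector of interpolated values, one per grid point.
#' @export
resample_to_grid <- function(trace, grid) {
  if (is.null(trace) || nrow(trace) < 2)
    vp_abort("cannot resample a trace with fewer than two points",
             "venompsc_degenerate_trace_error")
  out <- stats::approx(trace$rt_min, trace[[2]], xout = grid,
                       method = "linear", rule = 1)$y
  out[is.na(out)] <- 0
  out
}

#' Peak-shape similarity of two windowed series
#'
#' Pearson correlation of two traces resampled onto one grid and restricted
#' to a retention-time window. Symmetric, bounded in [-1, 1], and equal to
#' 1 for any positive affine transform of the same shape. A window in which
#' either series is constant has no defined shape; the similarity is then
#' `NA`.
#'
#' @param a,b Tibbles with `rt_min` and a value column.
#' @param window Length-2 numeric `c(rt_lo, rt_hi)` in minutes, or `NULL`
#'   for the overlap of the two traces.
#' @param grid Evaluation grid; defaults to `a`'s points inside the window.
#' @return A number in [-1, 1], or `NA` if either windowed series has zero
#'   variance.
#' @export
shape_similarity <- function(a, b, window = NULL, grid = NULL) {
  if (is.null(grid)) grid <- a$rt_min
  if (!is.null(window)) grid <- grid[grid >= window[1] & grid <= window[2]]
  if (length(grid) < 3) return(NA_real_)
  ya <- resample_to_grid(a, grid)
  yb <- resample_to_grid(b, grid)
  if (stats::sd(ya) == 0 || stats::sd(yb) == 0) return(NA_real_)
  stats::cor(ya, yb)
}

# normalize XIC input: long tibble (label, rt_min, intensity) or named list
# of tibbles -> named list of (rt_min, intensity) tibbles
as_xic_list <- function(xic_traces) {
  if (is.data.frame(xic_traces)) {
    if (!all(c("label", "rt_min") %in% names(xic_traces)))
      vp_abort("long XIC input needs columns label, rt_min, intensity",
               "venompsc_format_error")
    val <- setdiff(names(xic_traces), c("label", "rt_min"))[1]
    split_df <- split(xic_traces[c("rt_min", val)], xic_traces$label)
    return(lapply(split_df, tibble::as_tibble))
  }
  xic_traces
}

#' Match PSC peaks to intact-mass XIC peaks
#'
#' For each PSC peak, every XIC is examined: the XIC apex is the global
#' maximum of the XIC within the peak window widened by the tolerance, and
#' the XIC matches when that apex lies within `rt_tolerance_min` of the PSC
#' apex and the peak-shape similarity (Pearson, over the peak window +/- one
#' fraction) reaches `min_similarity`. A peak may match several XICs;
#' matches are ranked by similarity.
#'
#' @param psc_peaks Peak table from [detect_peaks()].
#' @param psc_traces Named list of `psc_trace` objects (names = accessions)
#'   the peaks came from, or a single trace.
#' @param xic_traces Long tibble with columns `label` (accurate mass, Da,
#'   as text), `rt_min`, `intensity`, or a named list of such traces.
#' @param rt_tolerance_min Apex tolerance, minutes (default 0.1).
#' @param min_similarity Minimum shape similarity (default 0.7).
#' @return A tibble `accession`, `peak_id`, `apex_rt`, `xic_label`,
#'   `xic_apex_rt`, `rt_delta_min`, `shape_similarity`, `rank` (per peak,
#'   by descending similarity). No matches gives zero rows.
#' @export
match_psc_xic <- function(psc_peaks, psc_traces, xic_traces,
                          rt_tolerance_min = 0.1, min_similarity = 0.7) {
  xics <- as_xic_list(xic_traces)
  if (inherits(psc_traces, "psc_trace")) {
    psc_traces <- stats::setNames(list(psc_traces),
                                  trace_accession(psc_traces))
  }
  empty <- tibble::tibble(accession = character(0), peak_id = integer(0),
                          apex_rt = numeric(0), xic_label = character(0),
                          xic_apex_rt = numeric(0), rt_delta_min = numeric(0),
                          shape_similarity = numeric(0), rank = integer(0))
  if (nrow(psc_peaks) == 0 || length(xics) == 0) return(empty)
  rows <- list(empty)
  for (i in seq_len(nrow(psc_peaks))) {
    pk <- psc_peaks[i, ]
    trace <- psc_traces[[pk$accession]]
    if (is.null(trace)) {
      vp_abort(sprintf("no PSC trace supplied for accession %s", pk$accession),
               "venompsc_format_error")
    }
    dt <- trace_dt(trace)
    window <- c(pk$rt_start - dt, pk$rt_end + dt)
    cand <- list()
    for (lab in names(xics)) {
      x <- xics[[lab]]
      sel <- x$rt_min >= window[1] - rt_tolerance_min &
             x$rt_min <= window[2] + rt_tolerance_min
      if (!any(sel)) next
      xw <- x[sel, , drop = FALSE]
      apex_idx <- which.max(xw[[2]])
      # ties on the maximum resolve toward the smaller |rt delta|
      mx <- max(xw[[2]])
      tied <- which(xw[[2]] == mx)
      if (length(tied) > 1)
        apex_idx <- tied[which.min(abs(xw$rt_min[tied] - pk$apex_rt))]
      xic_apex <- xw$rt_min[apex_idx]
      delta <- xic_apex - pk$apex_rt
      if (abs(delta) > rt_tolerance_min) next
      sim <- shape_similarity(trace, x, window = window)
      if (is.na(sim) || sim < min_similarity) next
      cand[[length(cand) + 1]] <- tibble::tibble(
        accession = pk$accession, peak_id = pk$peak_id, apex_rt = pk$apex_rt,
        xic_label = lab, xic_apex_rt = xic_apex, rt_delta_min = delta,
        shape_similarity = sim, rank = NA_integer_
      )
    }
    if (length(cand) > 0) {
      cd <- dplyr::bind_rows(cand)
      cd <- cd[order(-cd$shape_similarity, abs(cd$rt_delta_min)), ,
               drop = FALSE]
      cd$rank <- seq_len(nrow(cd))
      rows[[length(rows) + 1]] <- cd
    }
  }
  dplyr::bind_rows(rows)
}

parse_mass <- function(label) {
  suppressWarnings(as.numeric(sub("^[^0-9]*([0-9]+\\.?[0-9]*).*$", "\\1",
                                  label)))
}

#' Annotate multi-peak accessions as isoform/PTM candidates
#'
#' Per accession, each PSC peak is assigned the accurate mass of its
#' top-ranked XIC match. Verdicts: `multiple_masses_candidate_PTM_or_isoform`
#' when at least two peaks carry distinct masses (all pairwise mass deltas
#' are reported - glycosylation and other PTMs shift the intact mass);
#' `shared_peptide_artifact_suspected` when several peaks share one mass
#' (or carry no mass at all), consistent with conserved tryptic peptides of
#' related isoforms being credited to one homologue; `single_form` for a
#' lone peak. Mass deltas are descriptive; no modification dictionary is
#' consulted.
#'
#' @param peaks Peak table from [detect_peaks()] (may span accessions).
#' @param matches Match table from [match_psc_xic()].
#' @param mass_tol_da Masses closer than this are considered the same
#'   molecular species (default 1 Da).
#' @return A tibble with one row per accession: `accession`, `n_peaks`,
#'   `n_masses`, `masses` and `mass_deltas_da` (list columns), `verdict`.
#' @export
annotate_isoforms <- function(peaks, matches, mass_tol_da = 1) {
  accs <- sort(unique(peaks$accession))
  rows <- lapply(accs, function(acc) {
    pk <- peaks[peaks$accession == acc, , drop = FALSE]
    mm <- matches[matches$accession == acc, , drop = FALSE]
    peak_mass <- rep(NA_real_, nrow(pk))
    for (i in seq_len(nrow(pk))) {
      mi <- mm[mm$peak_id == pk$peak_id[i], , drop = FALSE]
      if (nrow(mi) > 0)
        peak_mass[i] <- parse_mass(mi$xic_label[which.min(mi$rank)])
    }
    masses <- sort(unique(peak_mass[!is.na(peak_mass)]))
    # collapse masses within tolerance
    if (length(masses) > 1) {
      grp <- cumsum(c(TRUE, diff(masses) > mass_tol_da))
      masses <- as.numeric(tapply(masses, grp, mean))
    }
    deltas <- if (length(masses) >= 2) {
      as.numeric(dist(masses))
    } else {
      numeric(0)
    }
    verdict <- if (nrow(pk) <= 1) {
      "single_form"
    } else if (length(masses) >= 2) {
      "multiple_masses_candidate_PTM_or_isoform"
    } else {
      "shared_peptide_artifact_suspected"
    }
    tibble::tibble(accession = acc, n_peaks = nrow(pk),
                   n_masses = length(masses), masses = list(masses),
                   mass_deltas_da = list(deltas), verdict = verdict)
  })
  dplyr::bind_rows(rows)
}

#' Read XIC / UV trace CSVs
#'
#' XIC input is long-format CSV with columns `label` (accurate mass, Da, as
#' text), `rt_min`, `intensity`; UV input has columns `rt_min`,
#' `absorbance`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_xic <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    label = readr::col_character(), rt_min = readr::col_double(),
    intensity = readr::col_double()
  ), progress = FALSE)
  if (!all(c("label", "rt_min", "intensity") %in% names(df)))
    vp_abort("XIC CSV needs columns label, rt_min, intensity",
             "venompsc_format_error")
  df
}

#' @rdname read_xic
#' @export
read_uv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  if (!"rt_min" %in% names(df) || ncol(df) < 2)
    vp_abort("UV CSV needs columns rt_min, absorbance",
             "venompsc_format_error")
  df
}
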