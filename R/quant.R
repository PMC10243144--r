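# PSC peak detection, trapezoidal integration, score summing, toxin-family
# classification, and relative-abundance summaries.

empty_peaks <- function() {
  tibble::tibble(accession = character(0), peak_id = integer(0),
                 rt_start = numeric(0), rt_end = numeric(0),
                 apex_rt = numeric(0), apex_value = numeric(0),
                 area = numeric(0), n_fractions = integer(0))
}

trace_dt <- function(trace) {
  rt <- trace$rt_min
  if (length(rt) < 2)
    vp_abort("trace needs at least two grid points", "venompsc_grid_error")
  d <- diff(rt)
  if (max(abs(d - d[1])) > 1e-9 * max(d[1], 1))
    vp_abort("trace grid is not uniform", "venompsc_grid_error")
  d[1]
}

# trapezoidal rule; x strictly increasing
trapz_area <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# local maxima positions of v (>= on the left, > on the right, so a plateau
# yields a single maximum); endpoints qualify
local_maxima <- function(v) {
  n <- length(v)
  if (n == 1) return(1L)
  left <- c(TRUE, v[-1] >= v[-n])
  right <- c(v[-n] > v[-1], TRUE)
  which(left & right & v > 0)
}

# split a run [lo, hi] (absolute indices into v) at valleys between local
# maxima; a split happens when a strictly positive interior minimum is below
# split_ratio times the smaller flanking maximum. Zero-valued valleys are
# dropout wells and are governed by gap_tolerance alone, never by the split
# rule. The valley fraction stays with the left peak.
split_run <- function(v, lo, hi, split_ratio) {
  vs <- v[lo:hi]
  maxima <- local_maxima(vs)
  cuts <- integer(0)
  if (length(maxima) >= 2) {
    for (k in seq_len(length(maxima) - 1)) {
      a <- maxima[k]; b <- maxima[k + 1]
      if (b - a < 2) next
      interior <- vs[(a + 1):(b - 1)]
      m <- min(interior)
      if (m > 0 && m < split_ratio * min(vs[a], vs[b]))
        cuts <- c(cuts, a + which.min(interior))
    }
  }
  starts <- c(lo, lo + cuts)
  ends <- c(lo + cuts - 1L, hi)
  Map(c, starts, ends)
}

#' Detect peaks in a PSC trace
#'
#' A peak is a maximal run of nonzero fractions, tolerating up to
#' `gap_tolerance` consecutive zero fractions inside it (absorbing single
#' dropout wells, the default). A run containing two local maxima is split
#' at the interior valley when the valley value is below
#' `split_ratio` times the smaller maximum; the valley fraction is assigned
#' to the earlier peak. Peak areas use the trapezoid convention of
#' [integrate_peak()].
#'
#' @param trace A `psc_trace` on a uniform retention-time grid.
#' @param gap_tolerance Maximum number of interior zero fractions bridged
#'   within one peak (default 1).
#' @param split_ratio Valley-to-smaller-maximum ratio below which a run is
#'   split into two peaks (default 0.5).
#' @return A tibble with one row per peak: `accession`, `peak_id`,
#'   `rt_start`, `rt_end` (inclusive fraction midpoints), `apex_rt`,
#'   `apex_value`, `area` (score x minutes), `n_fractions`. Peaks are
#'   disjoint and ordered by `rt_start`; an all-zero trace yields no rows.
#' @export
detect_peaks <- function(trace, gap_tolerance = 1L, split_ratio = 0.5) {
  v <- trace$value
  if (length(v) == 0 || all(v <= 0)) return(empty_peaks())
  trace_dt(trace)  # uniform-grid check
  idx <- which(v > 0)
  run_id <- cumsum(c(0L, diff(idx) > gap_tolerance + 1L))
  segs <- list()
  for (r in split(idx, run_id)) {
    segs <- c(segs, split_run(v, min(r), max(r), split_ratio))
  }
  peaks <- lapply(segs, function(seg) {
    lo <- seg[1]; hi <- seg[2]
    # trim zero edges that a split can leave behind
    while (lo < hi && v[lo] == 0) lo <- lo + 1L
    while (hi > lo && v[hi] == 0) hi <- hi - 1L
    vv <- v[lo:hi]
    apex <- lo + which.max(vv) - 1L
    tibble::tibble(
      accession = trace_accession(trace), peak_id = NA_integer_,
      rt_start = trace$rt_min[lo], rt_end = trace$rt_min[hi],
      apex_rt = trace$rt_min[apex], apex_value = v[apex],
      area = NA_real_, n_fractions = hi - lo + 1L
    )
  })
  out <- dplyr::bind_rows(peaks)
  out <- out[order(out$rt_start), , drop = FALSE]
  out$peak_id <- seq_len(nrow(out))
  out$area <- vapply(seq_len(nrow(out)),
                     function(i) integrate_peak(trace, out[i, ]), 0)
  out
}

#' Integrate one PSC peak
#'
#' Trapezoidal rule over the (retention time, value) points inside the peak
#' bounds, with zero-valued anchor points one fraction interval outside each
#' bound. Wells are point samples of an elution profile; the anchors close
#' the trapezoid back to baseline, so even a single-fraction peak gets a
#' nonzero (triangular) area of `value * fraction_width`.
#'
#' @param trace The `psc_trace` the peak was detected in.
#' @param peak One row of the [detect_peaks()] table (or any list with
#'   `rt_start` and `rt_end`).
#' @return The peak area in score x minutes.
#' @export
integrate_peak <- function(trace, peak) {
  dt <- trace_dt(trace)
  eps <- dt * 1e-6
  sel <- which(trace$rt_min >= peak$rt_start - eps &
               trace$rt_min <= peak$rt_end + eps)
  if (length(sel) == 0)
    vp_abort("peak bounds outside the trace grid", "venompsc_range_error")
  x <- c(trace$rt_min[sel[1]] - dt, trace$rt_min[sel],
         trace$rt_min[sel[length(sel)]] + dt)
  y <- c(0, trace$value[sel], 0)
  trapz_area(x, y)
}

#' Sum all protein scores of an accession
#'
#' The score-summing alternative to peak-area semiquantitation: the total of
#' an accession's scores over all wells, which equals the column total of
#' its PSC trace.
#'
#' @param table A `merged_results` table.
#' @param accession One accession, or `NULL` for a per-accession table.
#' @return A number, or (for `NULL`) a tibble `accession`, `summed_score`.
#' @export
summed_score <- function(table, accession = NULL) {
  if (!is.null(accession)) {
    return(sum(table$score[!is.na(table$accession) &
                           table$accession == accession]))
  }
  out <- dplyr::summarise(dplyr::group_by(table, accession),
                          summed_score = sum(score), .groups = "drop")
  dplyr::arrange(out, dplyr::desc(summed_score), accession)
}

#' Default toxin-family keyword rules
#'
#' Ordered (regular expression, family) pairs matched case-insensitively
#' against protein descriptions; the first match wins, so
#' "metalloproteinase/disintegrin" domains classify as SVMP, not
#' disintegrin. Families cover the majors seen across viperid and elapid
#' venoms: SVMP, SVSP, PLA2, CTL, LAAO, 3FTx, CRISP, Kunitz-type inhibitors
#' and disintegrins. Edit or extend the table to adapt the nomenclature of
#' a particular database.
#'
#' @return A tibble with columns `pattern`, `family`.
#' @export
default_family_rules <- function() {
  tibble::tribble(
    ~pattern, ~family,
    "metalloprotein", "SVMP",
    "serine protease|serine-protease|thrombin-like", "SVSP",
    "phospholipase a2|phospholipase a\\(2\\)|\\bpla2\\b", "PLA2",
    "c-type lectin|snaclec", "CTL",
    "amino[- ]acid oxidase|amine oxidase|\\blaao\\b", "LAAO",
    "three[- ]finger|\\b3ftx\\b|cytotoxin|cardiotoxin|neurotoxin", "3FTx",
    "cysteine-rich secretory|\\bcrisp\\b", "CRISP",
    "kunitz|protease inhibitor", "VKTI/Kunitz",
    "disintegrin", "disintegrin"
  )
}

#' Classify a protein description into a toxin family
#'
#' @param description Character vector of protein descriptions.
#' @param accession Optional accession(s), carried for interface symmetry;
#'   classification is description-driven because curated databases encode
#'   the family in the protein name.
#' @param rules Ordered rule table, see [default_family_rules()].
#' @return Character vector of family labels; `"other"` when no rule hits.
#' @export
classify_family <- function(description, accession = NULL,
                            rules = default_family_rules()) {
  out <- rep("other", length(description))
  decided <- is.na(description)
  for (i in seq_len(nrow(rules))) {
    hit <- !decided & grepl(rules$pattern[i], description, ignore.case = TRUE)
    out[hit] <- rules$family[i]
    decided <- decided | hit
  }
  out
}

#' Relative abundance per toxin family
#'
#' Sums a per-toxin quantity (PSC peak area, or summed score) within each
#' family and normalizes to fractions - the numbers behind a venom
#' composition pie chart. Fractions sum to 1 whenever any total is
#' positive.
#'
#' @param x A tibble with a `family` column and a quantity column.
#' @param value Name of the quantity column (default `"area"`).
#' @return A tibble `family`, `total`, `fraction`, sorted by descending
#'   total. All-zero input yields an empty result with a warning.
#' @export
family_abundance <- function(x, value = "area") {
  if (!all(c("family", value) %in% names(x)))
    vp_abort(sprintf("need columns 'family' and '%s'", value),
             "venompsc_format_error")
  v <- x[[value]]
  totals <- tapply(v, x$family, sum)
  if (length(totals) == 0 || sum(totals) <= 0) {
    warning("all family totals are zero; no composition to report")
    return(tibble::tibble(family = character(0), total = numeric(0),
                          fraction = numeric(0)))
  }
  out <- tibble::tibble(family = names(totals), total = as.numeric(totals))
  out$fraction <- out$total / sum(out$total)
  dplyr::arrange(out, dplyr::desc(total), family)
}

# UV peak around a local-maximum index: descend both flanks while values
# decrease, stopping at a flanking local minimum or once below
# bound_frac * apex height.
uv_peak_bounds <- function(y, apex, bound_frac = 0.05) {
  lo <- apex
  while (lo > 1 && y[lo - 1] <= y[lo] && y[lo] >= bound_frac * y[apex])
    lo <- lo - 1
  hi <- apex
  n <- length(y)
  while (hi < n && y[hi + 1] <= y[hi] && y[hi] >= bound_frac * y[apex])
    hi <- hi + 1
  c(lo, hi)
}

#' Match PSC peaks to UV peaks and integrate them
#'
#' Overlays detected PSC peaks on the LC-UV trace (typically 220 nm): for
#' each PSC peak, the UV local maximum whose apex lies within
#' `rt_tolerance_min` of the PSC apex is taken as the corresponding UV peak
#' and integrated by the trapezoid rule between its flanking local minima
#' (bounded below at `bound_frac` of apex height). PSC peaks with no UV
#' apex in tolerance are flagged unmatched; a UV peak claimed by more than
#' one PSC peak (co-eluting toxins) is flagged ambiguous for both.
#'
#' @param psc_peaks Peak table from [detect_peaks()] (any accession mix).
#' @param uv_trace A tibble with `rt_min` and an intensity column (second
#'   column used), on its own - typically finer - grid.
#' @param rt_tolerance_min Apex matching tolerance, minutes (default 0.1).
#' @param bound_frac UV peak bound threshold as a fraction of apex height
#'   (default 0.05).
#' @return The peak table plus `uv_apex_rt`, `uv_area`, `rt_delta_min`,
#'   `matched`, `ambiguous`.
#' @export
match_uv_peaks <- function(psc_peaks, uv_trace, rt_tolerance_min = 0.1,
                           bound_frac = 0.05) {
  out <- tibble::as_tibble(psc_peaks)
  out$uv_apex_rt <- NA_real_
  out$uv_area <- NA_real_
  out$rt_delta_min <- NA_real_
  out$matched <- FALSE
  out$ambiguous <- FALSE
  if (nrow(out) == 0) return(out)
  if (is.null(uv_trace) || nrow(uv_trace) < 3) return(out)
  rt <- uv_trace$rt_min
  y <- uv_trace[[2]]
  apexes <- local_maxima(y)
  if (length(apexes) == 0) return(out)
  claim <- integer(nrow(out))
  for (i in seq_len(nrow(out))) {
    deltas <- abs(rt[apexes] - out$apex_rt[i])
    j <- which.min(deltas)
    if (deltas[j] <= rt_tolerance_min) {
      ap <- apexes[j]
      b <- uv_peak_bounds(y, ap, bound_frac)
      out$uv_apex_rt[i] <- rt[ap]
      out$rt_delta_min[i] <- rt[ap] - out$apex_rt[i]
      out$uv_area[i] <- trapz_area(rt[b[1]:b[2]], y[b[1]:b[2]])
      out$matched[i] <- TRUE
      claim[i] <- ap
    }
  }
  shared <- claim[claim > 0][duplicated(claim[claim > 0])]
  out$ambiguous <- claim > 0 & claim %in% shared
  out
}
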