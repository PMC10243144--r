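# Protein Score Chromatograms (PSCs), Sequence Coverage Chromatograms, the
# Total Protein Chromatogram, and the combined wide trace table.
#
# A PSC plots one protein's search score per fraction against that
# fraction's retention time; a venom's set of PSCs is its proteome rendered
# as a chromatogram. Wells where a protein was not found are zero-filled so
# traces return to baseline like ordinary chromatograms.

#' Construct a PSC trace
#'
#' Low-level constructor used by the `build_*` functions and by tests; the
#' trace is a tibble of (rt_min, value) points on the full fraction grid of
#' one run, carrying its accession and value kind as attributes.
#'
#' @param rt_min Retention-time grid (minutes), strictly increasing.
#' @param value Nonnegative values, one per grid point.
#' @param accession Protein accession (NA for aggregate traces).
#' @param description Free-text protein description.
#' @param value_kind `"score"` or `"coverage"`.
#' @return A tibble of class `psc_trace`.
#' @export
new_psc_trace <- function(rt_min, value, accession = NA_character_,
                          description = NA_character_,
                          value_kind = c("score", "coverage")) {
  value_kind <- match.arg(value_kind)
  if (length(rt_min) != length(value))
    vp_abort("rt_min and value must have equal length", "venompsc_grid_error")
  if (length(rt_min) > 1 && any(diff(rt_min) <= 0))
    vp_abort("rt_min must be strictly increasing", "venompsc_grid_error")
  if (any(value < 0))
    vp_abort("trace values must be nonnegative", "venompsc_grid_error")
  out <- tibble::tibble(rt_min = as.numeric(rt_min), value = as.numeric(value))
  attr(out, "accession") <- accession
  attr(out, "description") <- description
  attr(out, "value_kind") <- value_kind
  class(out) <- c("psc_trace", class(out))
  out
}

trace_accession <- function(trace) attr(trace, "accession")

# map merged-table retention times back to grid indices
rt_to_index <- function(schedule, rt_min) {
  res_min <- schedule$resolution_s / 60
  offset <- if (schedule$rt_convention == "midpoint") 0.5 else 1
  i <- as.integer(round((rt_min - schedule$collection_start_min) / res_min + offset))
  if (any(i < 1L) || any(i > schedule$wells_per_run))
    vp_abort("retention time outside the run's fraction grid",
             "venompsc_range_error")
  i
}

build_trace <- function(table, accession, schedule, column, value_kind) {
  grid <- rt_grid(schedule)
  value <- numeric(length(grid))
  rows <- table[!is.na(table$accession) & table$accession == accession, ,
                drop = FALSE]
  desc <- NA_character_
  if (nrow(rows) > 0) {
    idx <- rt_to_index(schedule, rows$rt_min)
    v <- rows[[column]]
    v[is.na(v)] <- 0
    value[idx] <- v
    desc <- rows$description[[1]]
  }
  new_psc_trace(grid, value, accession = accession, description = desc,
                value_kind = value_kind)
}

#' Build a Protein Score Chromatogram
#'
#' Places one accession's protein scores from the merged table onto the
#' run's full retention-time grid; fractions where the protein was not
#' identified are zero. An accession absent from the table yields an
#' all-zero trace. No smoothing or interpolation is applied: the trace is
#' the raw score per well.
#'
#' @param table A `merged_results` table from [merge_wells()] (one run).
#' @param accession Protein accession.
#' @param schedule The run's [fraction_schedule()].
#' @return A `psc_trace` with `value_kind = "score"`.
#' @export
build_psc <- function(table, accession, schedule) {
  build_trace(table, accession, schedule, "score", "score")
}

#' Build a Sequence Coverage Chromatogram
#'
#' As [build_psc()] but the trace carries percent sequence coverage.
#'
#' @inheritParams build_psc
#' @return A `psc_trace` with `value_kind = "coverage"`.
#' @export
build_scc <- function(table, accession, schedule) {
  build_trace(table, accession, schedule, "coverage_pct", "coverage")
}

#' Build the Total Protein Chromatogram
#'
#' The TPC is the sum of all proteins' scores per fraction - the proteomics
#' analogue of a total ion chromatogram. It equals the column-wise sum of
#' all individual PSCs, and its grand total equals the score total of the
#' merged table exactly.
#'
#' @inheritParams build_psc
#' @return A `psc_trace` (accession `NA`).
#' @export
build_tpc <- function(table, schedule) {
  grid <- rt_grid(schedule)
  value <- numeric(length(grid))
  if (nrow(table) > 0) {
    idx <- rt_to_index(schedule, table$rt_min)
    sums <- tapply(table$score, idx, sum)
    value[as.integer(names(sums))] <- as.numeric(sums)
  }
  new_psc_trace(grid, value, accession = NA_character_,
                description = "total protein chromatogram",
                value_kind = "score")
}

#' Build PSCs for every accession in a merged table
#'
#' @inheritParams build_psc
#' @return A named list of `psc_trace` objects, one per accession.
#' @export
build_all_psc <- function(table, schedule) {
  accs <- sort(unique(table$accession))
  traces <- lapply(accs, function(a) build_psc(table, a, schedule))
  stats::setNames(traces, accs)
}

#' Combine traces into one wide table
#'
#' One shared retention-time grid, one value column per accession, ordered
#' by descending total score (ties broken by accession, lexicographic) so
#' the most abundant traces plot first. Every input trace is recoverable as
#' a column.
#'
#' @param traces A list of `psc_trace` objects sharing one grid.
#' @param schedule Optional [fraction_schedule()] supplying the grid when
#'   `traces` is empty.
#' @return A tibble with `rt_min` and one column per accession.
#' @export
combine_traces <- function(traces, schedule = NULL) {
  if (length(traces) == 0) {
    grid <- if (is.null(schedule)) numeric(0) else rt_grid(schedule)
    return(tibble::tibble(rt_min = grid))
  }
  grid <- traces[[1]]$rt_min
  for (tr in traces) {
    if (length(tr$rt_min) != length(grid) ||
        max(abs(tr$rt_min - grid)) > 1e-9)
      vp_abort("traces do not share one retention-time grid",
               "venompsc_grid_error")
  }
  accs <- vapply(traces, trace_accession, "")
  totals <- vapply(traces, function(tr) sum(tr$value), 0)
  ord <- order(-totals, accs)
  out <- tibble::tibble(rt_min = grid)
  for (k in ord) out[[accs[k]]] <- traces[[k]]$value
  out
}

#' Long-format export of a set of traces
#'
#' @param traces A list of `psc_trace` objects.
#' @return A tibble with columns `accession`, `rt_min`, `value`,
#'   `value_kind`, suitable for CSV export.
#' @export
traces_long <- function(traces) {
  dplyr::bind_rows(lapply(traces, function(tr) {
    tibble::tibble(accession = trace_accession(tr), rt_min = tr$rt_min,
                   value = tr$value, value_kind = attr(tr, "value_kind"))
  }))
}
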