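# Well-plate geometry and fraction <-> well <-> retention-time mapping for
# serpentine nanofractionation collection.

vp_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "venompsc_error")))
}

#' Well-plate layout for serpentine fraction collection
#'
#' Nanofractionation sprays the post-column LC effluent into consecutive
#' wells of a microtitre plate, filling it column by column in a serpentine
#' path so that consecutive fractions always occupy adjacent wells.
#' Collection starts at the top-left well (A1) moving down column 1, then
#' up column 2, alternating direction each column.
#'
#' @param n_rows Number of rows, labelled `A` upwards (max 26). Default 16.
#' @param n_cols Number of columns, numbered from 1. Default 24, giving the
#'   standard 384-well plate.
#' @param start_corner Corner receiving fraction 1. Only `"top_left"`.
#' @param fill_axis Fill order. Only `"column_major"`.
#' @return An object of class `plate_layout` with fields `n_rows`, `n_cols`,
#'   `row_labels`, `capacity`.
#' @examples
#' plate_layout()
#' serpentine_sequence(plate_layout(), 3)
#' @export
plate_layout <- function(n_rows = 16L, n_cols = 24L,
                         start_corner = "top_left",
                         fill_axis = "column_major") {
  start_corner <- match.arg(start_corner, "top_left")
  fill_axis <- match.arg(fill_axis, "column_major")
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || n_rows < 1L || n_rows > 26L)
    vp_abort("n_rows must be an integer in [1, 26]", "venompsc_layout_error")
  if (is.na(n_cols) || n_cols < 1L)
    vp_abort("n_cols must be a positive integer", "venompsc_layout_error")
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         row_labels = LETTERS[seq_len(n_rows)],
         start_corner = start_corner, fill_axis = fill_axis,
         capacity = n_rows * n_cols),
    class = "plate_layout"
  )
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d x %d (%d wells), serpentine column-major from %s\n",
              x$n_rows, x$n_cols, x$capacity, x$start_corner))
  invisible(x)
}

#' Serpentine collection order of wells
#'
#' Returns the well identifiers visited by the fraction collector, in
#' collection order: down column 1 (A1..P1 on a 384 plate), up column 2
#' (P2..A2), and so on.
#'
#' @param layout A [plate_layout()].
#' @param n Number of fractions (1 to plate capacity).
#' @return Character vector of `n` unique well IDs such as `"P2"`.
#' @export
serpentine_sequence <- function(layout, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    vp_abort("n must be a positive integer", "venompsc_capacity_error")
  if (n > layout$capacity)
    vp_abort(sprintf("n = %d exceeds plate capacity %d", n, layout$capacity),
             "venompsc_capacity_error")
  fraction_to_well(layout, seq_len(n))
}

#' Map plate fraction indices to well IDs (and back)
#'
#' `fraction_to_well()` and `well_to_fraction()` are exact inverses over the
#' plate; fraction indices count from 1 along the serpentine path.
#'
#' @param layout A [plate_layout()].
#' @param fraction_index Integer vector of plate fraction indices (1-based).
#' @return Character vector of well IDs.
#' @export
fraction_to_well <- function(layout, fraction_index) {
  p <- as.integer(fraction_index)
  if (any(is.na(p)) || any(p < 1L) || any(p > layout$capacity))
    vp_abort("fraction_index out of [1, capacity]", "venompsc_capacity_error")
  col <- (p - 1L) %/% layout$n_rows + 1L
  pos <- (p - 1L) %% layout$n_rows + 1L
  row <- ifelse(col %% 2L == 1L, pos, layout$n_rows + 1L - pos)
  paste0(layout$row_labels[row], col)
}

#' @param well_id Character vector of well IDs (row letter + column number).
#' @rdname fraction_to_well
#' @export
well_to_fraction <- function(layout, well_id) {
  m <- regmatches(well_id, regexec("^([A-Z])([0-9]+)$", well_id))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    vp_abort(sprintf("malformed well ID(s): %s",
                     paste(well_id[bad], collapse = ", ")),
             "venompsc_layout_error")
  row <- match(vapply(m, `[`, "", 2L), layout$row_labels)
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(is.na(row)) || any(col < 1L) || any(col > layout$n_cols))
    vp_abort(sprintf("well ID(s) outside a %dx%d plate: %s",
                     layout$n_rows, layout$n_cols,
                     paste(well_id[is.na(row) | col < 1L | col > layout$n_cols],
                           collapse = ", ")),
             "venompsc_layout_error")
  pos <- ifelse(col %% 2L == 1L, row, layout$n_rows + 1L - row)
  (col - 1L) * layout$n_rows + pos
}

#' Fraction-collection schedule
#'
#' Describes the timing of one collection run: seconds per fraction and the
#' total collected effluent window. The default window of 2208 s gives 368
#' wells per run at 6 s resolution (one run per 384-well plate) and 184
#' wells per run at 12 s (two runs per plate).
#'
#' @param resolution_s Seconds of effluent per well, typically 6 or 12.
#' @param collection_window_s Total collected duration, seconds; must be
#'   divisible by `resolution_s`. Default 2208.
#' @param collection_start_min LC time (minutes) at which fraction 1 begins.
#'   Default 0; set this if there is dead time between injection and the
#'   first collected fraction.
#' @param rt_convention Retention time assigned to a well: `"midpoint"`
#'   (default; centre of its collection window) or `"start"`.
#' @param layout A [plate_layout()] used to derive `runs_per_plate`.
#' @return An object of class `fraction_schedule` with `wells_per_run` and
#'   `runs_per_plate`.
#' @examples
#' fraction_schedule(6)$wells_per_run    # 368
#' fraction_schedule(12)$wells_per_run   # 184
#' @export
fraction_schedule <- function(resolution_s = 6, collection_window_s = 2208,
                              collection_start_min = 0,
                              rt_convention = c("midpoint", "start"),
                              layout = plate_layout()) {
  rt_convention <- match.arg(rt_convention)
  if (!is.numeric(resolution_s) || resolution_s <= 0)
    vp_abort("resolution_s must be positive", "venompsc_schedule_error")
  if (!is.numeric(collection_window_s) || collection_window_s <= 0)
    vp_abort("collection_window_s must be positive", "venompsc_schedule_error")
  if (collection_window_s %% resolution_s != 0)
    vp_abort(sprintf("collection_window_s (%g) is not divisible by resolution_s (%g)",
                     collection_window_s, resolution_s),
             "venompsc_schedule_error")
  wells_per_run <- as.integer(collection_window_s / resolution_s)
  if (wells_per_run > layout$capacity)
    vp_abort(sprintf("one run needs %d wells but the plate holds %d",
                     wells_per_run, layout$capacity),
             "venompsc_layout_error")
  structure(
    list(resolution_s = resolution_s,
         collection_window_s = collection_window_s,
         collection_start_min = collection_start_min,
         rt_convention = rt_convention,
         wells_per_run = wells_per_run,
         runs_per_plate = layout$capacity %/% wells_per_run),
    class = "fraction_schedule"
  )
}

#' @export
print.fraction_schedule <- function(x, ...) {
  cat(sprintf("<fraction_schedule> %gs fractions, %gs window: %d wells/run, %d run(s)/plate\n",
              x$resolution_s, x$collection_window_s, x$wells_per_run,
              x$runs_per_plate))
  invisible(x)
}

#' Retention time of a fraction
#'
#' Under the default midpoint convention, fraction i spans
#' `[(i-1) r, i r]` seconds after `collection_start_min` and is assigned the
#' centre of that window, `start + (i - 1/2) r / 60` minutes; the midpoint
#' minimises the systematic offset against peak apex positions.
#'
#' @param schedule A [fraction_schedule()].
#' @param fraction_index Integer vector of within-run fraction indices.
#' @return Retention times in minutes.
#' @examples
#' fraction_to_rt(fraction_schedule(6), 1)    # 0.05
#' fraction_to_rt(fraction_schedule(12), 1)   # 0.10
#' @export
fraction_to_rt <- function(schedule, fraction_index) {
  i <- as.numeric(fraction_index)
  if (any(is.na(i)) || any(i < 1))
    vp_abort("fraction_index must be >= 1", "venompsc_range_error")
  if (any(i > schedule$wells_per_run))
    vp_abort(sprintf("fraction_index beyond wells_per_run (%d)",
                     schedule$wells_per_run),
             "venompsc_range_error")
  offset <- if (schedule$rt_convention == "midpoint") 0.5 else 1
  schedule$collection_start_min + (i - offset) * schedule$resolution_s / 60
}

#' Retention-time grid of a full run
#'
#' @param schedule A [fraction_schedule()].
#' @return Numeric vector of length `wells_per_run`.
#' @export
rt_grid <- function(schedule) {
  fraction_to_rt(schedule, seq_len(schedule$wells_per_run))
}

#' Capacity planning for a fractionation sequence
#'
#' One venom occupies one chromatographic run; a sequence of `n_plates`
#' plates therefore accommodates `n_plates * runs_per_plate` venoms
#' (4 at 6 s resolution or 8 at 12 s on four 384-well plates with the
#' default window).
#'
#' @param layout A [plate_layout()].
#' @param schedule A [fraction_schedule()].
#' @param n_plates Number of plates in the sequence.
#' @return A list with `wells_per_run`, `runs_per_plate`,
#'   `venoms_per_sequence`.
#' @export
plan_plate <- function(layout, schedule, n_plates) {
  n_plates <- as.integer(n_plates)
  if (is.na(n_plates) || n_plates < 0L)
    vp_abort("n_plates must be a nonnegative integer", "venompsc_layout_error")
  if (schedule$wells_per_run > layout$capacity)
    vp_abort("schedule run does not fit on one plate", "venompsc_layout_error")
  list(wells_per_run = schedule$wells_per_run,
       runs_per_plate = schedule$runs_per_plate,
       venoms_per_sequence = n_plates * schedule$runs_per_plate)
}

#' Analytical runs per day at a given gradient runtime
#'
#' @param runtime_min Run-to-run time in minutes (default 14.4, the fast
#'   digest gradient, giving 100 runs per day).
#' @return Whole runs per 24 h.
#' @export
runs_per_day <- function(runtime_min = 14.4) {
  if (!is.numeric(runtime_min) || runtime_min <= 0)
    vp_abort("runtime_min must be positive", "venompsc_range_error")
  floor(24 * 60 / runtime_min)
}

#' Full plate/run/well map
#'
#' Enumerates every collected fraction of a sequence: which plate and run it
#' belongs to, its within-run fraction index, its well, and its retention
#' time. A second run on a plate continues the same serpentine path where
#' the first run stopped (injection sequences follow the identical
#' serpentine order).
#'
#' @param layout A [plate_layout()].
#' @param schedule A [fraction_schedule()].
#' @param n_plates Number of plates (default 1).
#' @return A tibble with columns `plate_index`, `run_index`,
#'   `fraction_index`, `well_id`, `rt_min`.
#' @export
well_map <- function(layout, schedule, n_plates = 1L) {
  n_plates <- as.integer(n_plates)
  per_plate <- schedule$runs_per_plate * schedule$wells_per_run
  one_plate <- tibble::tibble(
    run_index = rep(seq_len(schedule$runs_per_plate),
                    each = schedule$wells_per_run),
    fraction_index = rep(seq_len(schedule$wells_per_run),
                         times = schedule$runs_per_plate),
    well_id = fraction_to_well(layout, seq_len(per_plate)),
    rt_min = rep(rt_grid(schedule), times = schedule$runs_per_plate)
  )
  out <- dplyr::bind_rows(lapply(seq_len(n_plates), function(p) {
    dplyr::mutate(one_plate, plate_index = p, .before = 1L)
  }))
  if (n_plates == 0L) {
    out <- dplyr::mutate(one_plate[0, ], plate_index = integer(0), .before = 1L)
  }
  out
}

# Within-run fraction index of a well under a schedule; errors if the well
# lies outside the requested run.
well_to_run_fraction <- function(layout, schedule, well_id, run_index = 1L) {
  pf <- well_to_fraction(layout, well_id)
  rf <- pf - (as.integer(run_index) - 1L) * schedule$wells_per_run
  bad <- rf < 1L | rf > schedule$wells_per_run
  if (any(bad))
    vp_abort(sprintf("well(s) outside run %d of the schedule: %s", run_index,
                     paste(unique(well_id[bad]), collapse = ", ")),
             "venompsc_range_error")
  rf
}

#' Read a flat key-value plate/schedule configuration
#'
#' The config is a two-column CSV with header `key,value` and keys
#' `n_rows`, `n_cols`, `resolution_s`, `collection_window_s`,
#' `collection_start_min`, `n_plates` (missing keys fall back to defaults).
#'
#' @param path Path to the CSV config.
#' @return A list with `layout`, `schedule`, `n_plates`.
#' @export
read_platemap_config <- function(path) {
  kv <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("key", "value") %in% names(kv)))
    vp_abort("platemap config must have columns key,value",
             "venompsc_format_error")
  get <- function(key, default) {
    v <- kv$value[kv$key == key]
    if (length(v) == 0) default else as.numeric(v[[1]])
  }
  layout <- plate_layout(n_rows = get("n_rows", 16), n_cols = get("n_cols", 24))
  schedule <- fraction_schedule(
    resolution_s = get("resolution_s", 6),
    collection_window_s = get("collection_window_s", 2208),
    collection_start_min = get("collection_start_min", 0),
    layout = layout
  )
  list(layout = layout, schedule = schedule,
       n_plates = as.integer(get("n_plates", 1)))
}
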