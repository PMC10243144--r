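# Ingest per-well protein search-result exports and merge them into a single
# retention-time-sorted result table (the workflow's "one sheet per venom").

# Canonical per-well export dialect. `accession` and `score` are required;
# the rest are carried through untouched.
CANONICAL_EXPORT_COLS <- c("accession", "score", "coverage_pct", "mass_da",
                           "description", "species", "sequence", "peptides",
                           "link")
REQUIRED_EXPORT_COLS <- c("accession", "score")

MERGED_COLS <- c("rt_min", "well_id", CANONICAL_EXPORT_COLS)

empty_hits <- function() {
  tibble::tibble(
    well_id = character(0), accession = character(0), score = numeric(0),
    coverage_pct = numeric(0), mass_da = numeric(0),
    description = character(0), species = character(0),
    sequence = character(0), peptides = character(0), link = character(0)
  )
}

#' Read a search-job to well mapping
#'
#' Bottom-up searches of the digested wells are submitted as numbered jobs;
#' this two-column table (`job_id`, `well_id`) records which job belongs to
#' which well so that per-well exports can be placed on the plate.
#'
#' @param x Path to a CSV with columns `job_id`, `well_id`, or a data frame.
#' @param layout A [plate_layout()] used to validate well IDs.
#' @return A tibble with character columns `job_id`, `well_id`.
#' @export
read_job_well_map <- function(x, layout = plate_layout()) {
  df <- if (is.character(x)) {
    readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    tibble::as_tibble(x)
  }
  if (!all(c("job_id", "well_id") %in% names(df)))
    vp_abort("job/well map must have columns job_id, well_id",
             "venompsc_format_error")
  df <- tibble::tibble(job_id = as.character(df$job_id),
                       well_id = as.character(df$well_id))
  if (nrow(df) == 0) {
    warning("empty job/well map")
    return(df)
  }
  dup <- unique(df$job_id[duplicated(df$job_id)])
  if (length(dup) > 0)
    vp_abort(sprintf("duplicate job id(s): %s", paste(dup, collapse = ", ")),
             "venompsc_format_error")
  well_to_fraction(layout, df$well_id)  # errors on wells not on the plate
  df
}

#' Parse one per-well search-result export
#'
#' Reads the canonical export dialect (columns `accession`, `score`,
#' `coverage_pct`, `mass_da`, `description`, `species`, `sequence`,
#' `peptides`, `link`; header required) into one hit per protein record.
#' Real search-engine export headers can be adapted with `aliases`. Records
#' with a missing accession or a non-numeric score are dropped and counted
#' in the `n_dropped` attribute. A duplicated accession within one well is
#' collapsed to its single highest-scoring record: protein scores are not
#' additive evidence, and duplicates only arise from malformed exports.
#'
#' @param x Path to a CSV export, or a data frame. A blank well may be an
#'   export with zero rows.
#' @param well_id Well the export belongs to.
#' @param aliases Optional named character vector mapping export headers to
#'   canonical names, e.g. `c(prot_acc = "accession", prot_score = "score")`.
#' @return A tibble of hits with a `well_id` column and the canonical
#'   columns, attribute `n_dropped`.
#' @export
parse_search_export <- function(x, well_id, aliases = NULL) {
  df <- if (is.character(x)) {
    readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    tibble::as_tibble(x)
  }
  if (!is.null(aliases)) {
    hit <- names(df) %in% names(aliases)
    names(df)[hit] <- unname(aliases[names(df)[hit]])
  }
  missing <- setdiff(REQUIRED_EXPORT_COLS, names(df))
  if (length(missing) > 0)
    vp_abort(sprintf("export for well %s lacks required column(s): %s",
                     well_id, paste(missing, collapse = ", ")),
             "venompsc_format_error")
  for (col in setdiff(CANONICAL_EXPORT_COLS, names(df))) df[[col]] <- NA
  df <- df[CANONICAL_EXPORT_COLS]
  df$accession <- as.character(df$accession)
  suppressWarnings({
    df$score <- as.numeric(df$score)
    df$coverage_pct <- as.numeric(df$coverage_pct)
    df$mass_da <- as.numeric(df$mass_da)
  })
  for (col in c("description", "species", "sequence", "peptides", "link"))
    df[[col]] <- as.character(df[[col]])
  keep <- !is.na(df$accession) & nzchar(df$accession) & !is.na(df$score)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (any(df$score < 0))
    vp_abort(sprintf("negative protein score in well %s", well_id),
             "venompsc_format_error")
  if (any(!is.na(df$coverage_pct) &
          (df$coverage_pct < 0 | df$coverage_pct > 100)))
    vp_abort(sprintf("sequence coverage outside [0, 100] in well %s", well_id),
             "venompsc_format_error")
  # max-score de-duplication per accession (ties: first record)
  if (nrow(df) > 0) {
    ord <- order(df$accession, -df$score)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df$accession), , drop = FALSE]
  }
  out <- tibble::as_tibble(df)
  out <- tibble::add_column(out, well_id = rep(as.character(well_id), nrow(out)),
                            .before = 1L)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read a directory of per-well exports via a job map
#'
#' Export files are named `<job_id>.csv`. Jobs whose file is absent are
#' treated as blank wells (many wells contain no toxin) and reported in the
#' `missing_jobs` attribute.
#'
#' @param dir Directory containing the export CSVs.
#' @param job_map Tibble from [read_job_well_map()].
#' @param aliases Passed to [parse_search_export()].
#' @return A single tibble of hits across all wells.
#' @export
read_search_dir <- function(dir, job_map, aliases = NULL) {
  if (!dir.exists(dir))
    vp_abort(sprintf("exports directory not found: %s", dir),
             "venompsc_format_error")
  pieces <- vector("list", nrow(job_map))
  missing_jobs <- character(0)
  for (i in seq_len(nrow(job_map))) {
    path <- file.path(dir, paste0(job_map$job_id[i], ".csv"))
    if (!file.exists(path)) {
      missing_jobs <- c(missing_jobs, job_map$job_id[i])
      next
    }
    pieces[[i]] <- parse_search_export(path, job_map$well_id[i],
                                       aliases = aliases)
  }
  out <- dplyr::bind_rows(c(list(empty_hits()), pieces))
  attr(out, "missing_jobs") <- missing_jobs
  out
}

#' Merge per-well hits into a retention-time-sorted result table
#'
#' Builds the venom's single merged table: one row per (well, protein hit),
#' sorted by fractionation retention time, with the retention time of each
#' row derived from its well under the collection schedule. When several
#' proteins are found in one well each gets its own row sharing that well's
#' retention time. Wells without hits contribute no rows; they remain on
#' the retention-time axis when chromatogram traces are built.
#'
#' @param per_well_hits A tibble of hits with a `well_id` column (e.g. from
#'   [read_search_dir()]), or a list of such tibbles.
#' @param schedule A [fraction_schedule()].
#' @param layout A [plate_layout()].
#' @param run_index Which run of the plate these wells belong to (a 12 s
#'   plate holds two runs). Hits in wells outside this run are an error.
#' @return A tibble of class `merged_results` with columns `rt_min`,
#'   `well_id`, then the canonical hit columns; sorted by `rt_min` and
#'   accession, no duplicated (well, accession) pairs.
#' @export
merge_wells <- function(per_well_hits, schedule, layout = plate_layout(),
                        run_index = 1L) {
  hits <- if (is.data.frame(per_well_hits)) {
    tibble::as_tibble(per_well_hits)
  } else {
    dplyr::bind_rows(c(list(empty_hits()), per_well_hits))
  }
  if (nrow(hits) == 0) {
    out <- tibble::add_column(empty_hits(), rt_min = numeric(0), .before = 1L)
    class(out) <- c("merged_results", class(out))
    return(out)
  }
  if (!"well_id" %in% names(hits))
    vp_abort("hits must carry a well_id column", "venompsc_format_error")
  attr(hits, "missing_jobs") <- NULL
  attr(hits, "n_dropped") <- NULL
  rf <- well_to_run_fraction(layout, schedule, hits$well_id, run_index)
  hits$rt_min <- fraction_to_rt(schedule, rf)
  # collapse any duplicated (well, accession) pairs to the top-scoring record
  ord <- order(hits$well_id, hits$accession, -hits$score)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits[c("well_id", "accession")]), , drop = FALSE]
  hits <- hits[order(hits$rt_min, hits$accession), MERGED_COLS]
  out <- tibble::as_tibble(hits)
  class(out) <- c("merged_results", class(out))
  out
}

#' Write / read a merged result table
#'
#' The merged table is serialized as plain CSV (UTF-8, `.` decimal point),
#' the canonical diffable realization of the workflow's single sheet.
#' `read_merged()` validates the column set and sort order on the way in.
#'
#' @param table A `merged_results` tibble from [merge_wells()].
#' @param path File path.
#' @return `read_merged()` returns a `merged_results` tibble.
#' @export
write_merged <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @rdname write_merged
#' @export
read_merged <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    rt_min = readr::col_double(), well_id = readr::col_character(),
    accession = readr::col_character(), score = readr::col_double(),
    coverage_pct = readr::col_double(), mass_da = readr::col_double(),
    .default = readr::col_character()
  ), na = "", progress = FALSE)
  missing <- setdiff(MERGED_COLS, names(df))
  if (length(missing) > 0)
    vp_abort(sprintf("merged table lacks column(s): %s",
                     paste(missing, collapse = ", ")),
             "venompsc_format_error")
  df <- df[MERGED_COLS]
  if (is.unsorted(df$rt_min))
    vp_abort("merged table is not sorted by rt_min", "venompsc_format_error")
  class(df) <- c("merged_results", class(df))
  df
}
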