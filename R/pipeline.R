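# End-to-end orchestration: exports (or a synthetic spec) -> merged table
# -> PSC traces -> peaks -> family composition -> XIC/UV correlation ->
# report bundle.

#' Assemble a pipeline run configuration
#'
#' @param output_dir Directory for the result bundle (created if needed).
#' @param exports_dir Directory of per-well export CSVs (`<job_id>.csv`),
#'   or `NULL` when only simulating.
#' @param job_map Path to the job/well map CSV.
#' @param xic,uv Optional paths to XIC / UV trace CSVs.
#' @param n_rows,n_cols Plate geometry (default 16 x 24).
#' @param resolution_s,collection_window_s,collection_start_min Schedule
#'   keys, see [fraction_schedule()].
#' @param run_index Which run of the plate to process (default 1).
#' @param gap_tolerance,split_ratio Peak detection knobs, see
#'   [detect_peaks()].
#' @param quant_mode `"area"` (PSC peak areas; default) or `"score_sum"`
#'   for the family composition written to `family_summary.csv`. Both modes
#'   are always computed and reported side by side in the JSON report.
#' @param rt_tolerance_min,min_similarity XIC matching knobs, see
#'   [match_psc_xic()].
#' @param aliases Optional export header aliases, see
#'   [parse_search_export()].
#' @param figures Write figure files (default TRUE; failures to open a
#'   graphics device degrade to a warning).
#' @param seed Seed recorded in the report.
#' @return A list of class `run_config`.
#' @export
run_config <- function(output_dir, exports_dir = NULL, job_map = NULL,
                       xic = NULL, uv = NULL, n_rows = 16, n_cols = 24,
                       resolution_s = 6, collection_window_s = 2208,
                       collection_start_min = 0, run_index = 1,
                       gap_tolerance = 1, split_ratio = 0.5,
                       quant_mode = c("area", "score_sum"),
                       rt_tolerance_min = 0.1, min_similarity = 0.7,
                       aliases = NULL, figures = TRUE, seed = 1L) {
  structure(list(
    output_dir = output_dir, exports_dir = exports_dir, job_map = job_map,
    xic = xic, uv = uv, n_rows = n_rows, n_cols = n_cols,
    resolution_s = resolution_s, collection_window_s = collection_window_s,
    collection_start_min = collection_start_min, run_index = run_index,
    gap_tolerance = gap_tolerance, split_ratio = split_ratio,
    quant_mode = match.arg(quant_mode), rt_tolerance_min = rt_tolerance_min,
    min_similarity = min_similarity, aliases = aliases, figures = figures,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' @param config A [run_config()].
#' @return A tibble of findings with columns `level` (`error`, `warning`,
#'   `info`), `field`, `message`. Errors block [run_pipeline()].
#' @export
validate_config <- function(config) {
  f <- list()
  add <- function(level, field, message) {
    f[[length(f) + 1]] <<- tibble::tibble(level = level, field = field,
                                          message = message)
  }
  if (is.null(config$output_dir) || !nzchar(config$output_dir))
    add("error", "output_dir", "output_dir is required")
  if (!is.null(config$exports_dir)) {
    if (!dir.exists(config$exports_dir))
      add("error", "exports_dir",
          sprintf("exports_dir not found: %s", config$exports_dir))
    if (is.null(config$job_map))
      add("error", "job_map", "job_map is required when exports_dir is set")
    else if (!file.exists(config$job_map))
      add("error", "job_map", sprintf("job map not found: %s", config$job_map))
  }
  for (key in c("xic", "uv")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      add("error", key, sprintf("%s file not found: %s", key, config[[key]]))
  }
  sched_err <- tryCatch({
    fraction_schedule(config$resolution_s, config$collection_window_s,
                      config$collection_start_min,
                      layout = plate_layout(config$n_rows, config$n_cols))
    NULL
  }, venompsc_error = function(e) conditionMessage(e))
  if (!is.null(sched_err)) add("error", "schedule", sched_err)
  if (config$rt_tolerance_min <= 0)
    add("warning", "rt_tolerance_min",
        "tolerance of 0 disables XIC/UV matching")
  if (config$split_ratio < 0 || config$split_ratio > 1)
    add("warning", "split_ratio", "split_ratio is usually within [0, 1]")
  if (length(f) == 0)
    return(tibble::tibble(level = character(0), field = character(0),
                          message = character(0)))
  dplyr::bind_rows(f)
}

write_manifest <- function(dir, stages) {
  writeLines(stages, file.path(dir, "MANIFEST"))
}

save_figure <- function(plot, path, width = 8, height = 5) {
  tryCatch(
    suppressMessages(ggplot2::ggsave(path, plot, width = width,
                                     height = height, dpi = 150)),
    error = function(e) warning(sprintf("could not write figure %s: %s",
                                        path, conditionMessage(e)))
  )
}

#' Run the full post-processing pipeline
#'
#' Stages: ingest (job map + per-well exports), merge, psc (traces),
#' quant (peaks, family composition, pie figure), correlate (optional
#' XIC/UV), report. Each stage's outputs are written to `output_dir` as it
#' completes and recorded in a `MANIFEST`; a stage failure stops the run
#' with the stage named, retaining completed outputs. Rerunning on the same
#' inputs overwrites the bundle deterministically.
#'
#' @param config A [run_config()].
#' @return Invisibly, the report list (also written to `report.json`):
#'   counts of wells with hits, accessions, peaks, families, both
#'   quantitation modes, and all effective parameters.
#' @export
run_pipeline <- function(config) {
  findings <- validate_config(config)
  errs <- findings[findings$level == "error", , drop = FALSE]
  if (nrow(errs) > 0)
    vp_abort(paste0("invalid configuration: ",
                    paste(sprintf("[%s] %s", errs$field, errs$message),
                          collapse = "; ")),
             "venompsc_config_error")
  for (w in findings$message[findings$level == "warning"]) warning(w)

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  done <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      write_manifest(config$output_dir, done)
      vp_abort(sprintf("pipeline failed at stage '%s': %s", name,
                       conditionMessage(e)),
               "venompsc_stage_error")
    })
    done <<- c(done, name)
    write_manifest(config$output_dir, done)
    res
  }

  layout <- plate_layout(config$n_rows, config$n_cols)
  schedule <- fraction_schedule(config$resolution_s,
                                config$collection_window_s,
                                config$collection_start_min, layout = layout)

  hits <- stage("ingest", {
    if (is.null(config$exports_dir)) {
      empty_hits()
    } else {
      jm <- read_job_well_map(config$job_map, layout)
      read_search_dir(config$exports_dir, jm, aliases = config$aliases)
    }
  })
  if (nrow(hits) == 0)
    warning("no protein hits found; producing an empty bundle")

  merged <- stage("merge", {
    m <- merge_wells(hits, schedule, layout, run_index = config$run_index)
    write_merged(m, file.path(config$output_dir, "merged.csv"))
    m
  })

  traces <- stage("psc", {
    tr <- build_all_psc(merged, schedule)
    tpc <- build_tpc(merged, schedule)
    readr::write_csv(traces_long(c(tr, list(tpc))),
                     file.path(config$output_dir, "traces_long.csv"), na = "")
    readr::write_csv(combine_traces(tr, schedule),
                     file.path(config$output_dir, "combined_traces.csv"))
    tr
  })

  quant <- stage("quant", {
    peaks <- dplyr::bind_rows(c(list(empty_peaks()),
      lapply(traces, detect_peaks, gap_tolerance = config$gap_tolerance,
             split_ratio = config$split_ratio)))
    desc <- merged$description[match(peaks$accession, merged$accession)]
    peaks$family <- classify_family(desc, peaks$accession)
    readr::write_csv(peaks, file.path(config$output_dir, "peaks.csv"))
    fam_area <- if (nrow(peaks) > 0) {
      family_abundance(peaks, "area")
    } else {
      family_abundance(tibble::tibble(family = character(0),
                                      area = numeric(0)))
    }
    ss <- summed_score(merged)
    ss$family <- classify_family(
      merged$description[match(ss$accession, merged$accession)])
    fam_score <- if (nrow(ss) > 0 && sum(ss$summed_score) > 0) {
      family_abundance(ss, "summed_score")
    } else {
      tibble::tibble(family = character(0), total = numeric(0),
                     fraction = numeric(0))
    }
    fam_main <- if (config$quant_mode == "area") fam_area else fam_score
    readr::write_csv(fam_main,
                     file.path(config$output_dir, "family_summary.csv"))
    if (config$figures && nrow(fam_main) > 0)
      save_figure(plot_family_pie(fam_main),
                  file.path(config$output_dir, "family_pie.png"),
                  width = 6, height = 5)
    if (config$figures && length(traces) > 0)
      save_figure(plot_traces(traces),
                  file.path(config$output_dir, "psc_overlay.png"))
    list(peaks = peaks, fam_area = fam_area, fam_score = fam_score)
  })

  correl <- stage("correlate", {
    out <- list(matches = NULL, annotations = NULL, uv_matches = NULL)
    if (!is.null(config$xic) && nrow(quant$peaks) > 0 &&
        config$rt_tolerance_min > 0) {
      xic <- read_xic(config$xic)
      out$matches <- match_psc_xic(quant$peaks, traces, xic,
                                   rt_tolerance_min = config$rt_tolerance_min,
                                   min_similarity = config$min_similarity)
      out$annotations <- annotate_isoforms(quant$peaks, out$matches)
      readr::write_csv(out$matches,
                       file.path(config$output_dir, "xic_matches.csv"))
      ann <- out$annotations
      jsonlite::write_json(
        lapply(seq_len(nrow(ann)), function(i) list(
          accession = ann$accession[i], n_peaks = ann$n_peaks[i],
          n_masses = ann$n_masses[i], masses = ann$masses[[i]],
          mass_deltas_da = ann$mass_deltas_da[[i]], verdict = ann$verdict[i]
        )),
        file.path(config$output_dir, "isoform_annotations.json"),
        auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(config$uv) && nrow(quant$peaks) > 0 &&
        config$rt_tolerance_min > 0) {
      uv <- read_uv(config$uv)
      out$uv_matches <- match_uv_peaks(quant$peaks, uv,
                                       rt_tolerance_min = config$rt_tolerance_min)
      readr::write_csv(out$uv_matches,
                       file.path(config$output_dir, "uv_matches.csv"))
    }
    out
  })

  report <- stage("report", {
    rep <- list(
      counts = list(
        wells_with_hits = length(unique(merged$well_id)),
        accessions = length(unique(merged$accession)),
        hits = nrow(merged),
        peaks = nrow(quant$peaks),
        families = nrow(quant$fam_area),
        xic_matches = if (is.null(correl$matches)) 0L
                      else nrow(correl$matches)
      ),
      family_composition = list(
        area_mode = as.list(stats::setNames(quant$fam_area$fraction,
                                            quant$fam_area$family)),
        score_sum_mode = as.list(stats::setNames(quant$fam_score$fraction,
                                                 quant$fam_score$family))
      ),
      parameters = config[setdiff(names(config), "aliases")]
    )
    jsonlite::write_json(rep, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    rep
  })

  invisible(report)
}
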