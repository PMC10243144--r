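test_that("job/well map reads, validates wells and rejects duplicates", {
  jm <- read_job_well_map(data.frame(job_id = c(101, 102),
                                     well_id = c("A1", "B1")))
  expect_equal(nrow(jm), 2)
  expect_equal(jm$well_id, c("A1", "B1"))
  expect_error(
    read_job_well_map(data.frame(job_id = c(101, 101),
                                 well_id = c("A1", "C1"))),
    class = "venompsc_format_error")
  expect_warning(
    empty <- read_job_well_map(data.frame(job_id = character(0),
                                          well_id = character(0))),
    "empty")
  expect_equal(nrow(empty), 0)
  expect_error(
    read_job_well_map(data.frame(job_id = 1, well_id = "Z99")),
    class = "venompsc_layout_error")
})

test_that("per-well exports parse, drop bad rows and de-duplicate by score", {
  hits3 <- parse_search_export(make_hits("A1", c("P1", "P2", "P3"),
                                         c(100, 50, 20)), "A1")
  expect_equal(nrow(hits3), 3)
  blank <- parse_search_export(make_hits(character(0), character(0),
                                         numeric(0)), "B1")
  expect_equal(nrow(blank), 0)
  # duplicated accession keeps the single highest-scoring record
  dup <- parse_search_export(make_hits("A1", c("P1", "P1"), c(80, 120)), "A1")
  expect_equal(nrow(dup), 1)
  expect_equal(dup$score, 120)
  # missing accession / non-numeric score rows are dropped and counted
  raw <- data.frame(accession = c("P1", "", NA, "P2"),
                    score = c("100", "50", "30", "n/a"))
  ok <- parse_search_export(raw, "A1")
  expect_equal(ok$accession, "P1")
  expect_equal(attr(ok, "n_dropped"), 3)
  expect_error(parse_search_export(data.frame(protein = "P1"), "A1"),
               "accession", class = "venompsc_format_error")
  expect_error(parse_search_export(make_hits("A1", "P1", -5), "A1"),
               class = "venompsc_format_error")
  expect_error(parse_search_export(make_hits("A1", "P1", 10,
                                             coverage_pct = 120), "A1"),
               class = "venompsc_format_error")
})

test_that("header aliases adapt real export dialects", {
  raw <- data.frame(prot_acc = "P63", prot_score = 321, prot_cover = 44)
  hits <- parse_search_export(raw, "C2",
                              aliases = c(prot_acc = "accession",
                                          prot_score = "score",
                                          prot_cover = "coverage_pct"))
  expect_equal(hits$accession, "P63")
  expect_equal(hits$score, 321)
  expect_equal(hits$coverage_pct, 44)
})

test_that("merging sorts by retention time and shares rt within a well", {
  s <- tiny_schedule()
  l <- plate_layout()
  wells <- serpentine_sequence(l, 10)
  hits <- make_hits(wells[c(3, 1, 2)], c("P3", "P1", "P2"), c(30, 10, 20))
  m <- merge_wells(hits, s, l)
  expect_s3_class(m, "merged_results")
  expect_equal(m$accession, c("P1", "P2", "P3"))   # fraction order 1,2,3
  expect_equal(m$rt_min, fraction_to_rt(s, 1:3))
  # two accessions in one well: two rows, same retention time
  m2 <- merge_wells(make_hits(wells[c(5, 5)], c("PB", "PA"), c(50, 100)), s, l)
  expect_equal(nrow(m2), 2)
  expect_equal(m2$rt_min[1], m2$rt_min[2])
  expect_equal(m2$accession, c("PA", "PB"))
  # empty input gives an empty table with a valid header
  m0 <- merge_wells(list(), s, l)
  expect_equal(nrow(m0), 0)
  expect_true(all(c("rt_min", "well_id", "accession", "score") %in% names(m0)))
})

test_that("hits outside the schedule's run are a range error", {
  s12 <- fraction_schedule(12)
  l <- plate_layout()
  run2_well <- fraction_to_well(l, 200)  # plate fraction 200 lives in run 2
  expect_error(merge_wells(make_hits(run2_well, "P1", 10), s12, l,
                           run_index = 1),
               class = "venompsc_range_error")
  m <- merge_wells(make_hits(run2_well, "P1", 10), s12, l, run_index = 2)
  expect_equal(m$rt_min, fraction_to_rt(s12, 200 - 184))
})

test_that("merging is permutation-invariant and row counts add up", {
  s <- tiny_schedule()
  l <- plate_layout()
  wells <- serpentine_sequence(l, 10)
  hits <- make_hits(wells[c(1, 1, 4, 7, 9)],
                    c("PB", "PA", "PA", "PC", "PA"),
                    c(10, 20, 30, 40, 50))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  set.seed(7)
  write_merged(merge_wells(hits, s, l), f1)
  write_merged(merge_wells(hits[sample(nrow(hits)), ], s, l), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(nrow(merge_wells(hits, s, l)), 5)  # no duplicates to collapse
})

test_that("merged tables round-trip through CSV unchanged", {
  s <- tiny_schedule()
  l <- plate_layout()
  wells <- serpentine_sequence(l, 10)
  m <- merge_wells(make_hits(wells[c(2, 5, 8)], c("PA", "PB", "PC"),
                             c(123.456, 0.1, 1e4)), s, l)
  path <- withr::local_tempfile(fileext = ".csv")
  write_merged(m, path)
  back <- read_merged(path)
  expect_equal(as.data.frame(back), as.data.frame(m))
})
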