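test_that("serpentine collection starts at A1 and turns at column ends", {
  l <- plate_layout()
  expect_equal(serpentine_sequence(l, 1), "A1")
  seq17 <- serpentine_sequence(l, 17)
  expect_equal(seq17[17], "P2")           # 16 rows down col 1, turn into col 2
  seq368 <- serpentine_sequence(l, 368)
  expect_equal(seq368[368], "P23")        # 368 = 16 x 23, odd column ends at P
  expect_equal(anyDuplicated(seq368), 0L)
  expect_error(serpentine_sequence(l, 385), class = "venompsc_capacity_error")
})

test_that("consecutive serpentine wells are plate-adjacent", {
  l <- plate_layout()
  ids <- serpentine_sequence(l, l$capacity)
  row <- match(substr(ids, 1, 1), l$row_labels)
  col <- as.integer(substring(ids, 2))
  same_col_step <- diff(col) == 0 & abs(diff(row)) == 1
  col_turn <- diff(col) == 1 & diff(row) == 0 & (row[-length(row)] %in% c(1, l$n_rows))
  expect_true(all(same_col_step | col_turn))
})

test_that("fraction midpoint retention times follow the schedule", {
  s6 <- fraction_schedule(6)
  s12 <- fraction_schedule(12)
  expect_equal(fraction_to_rt(s6, 1), 0.05)
  expect_equal(fraction_to_rt(s6, 100), 9.95)
  expect_equal(fraction_to_rt(s12, 1), 0.10)
  expect_error(fraction_to_rt(s6, 369), class = "venompsc_range_error")
  expect_error(fraction_to_rt(s6, 0), class = "venompsc_range_error")
  # strictly monotone with uniform spacing of resolution/60 everywhere
  g <- rt_grid(s6)
  expect_true(all(diff(g) > 0))
  expect_equal(diff(g), rep(0.1, 367))
  expect_equal(diff(rt_grid(s12)), rep(0.2, 183))
  # start-of-window convention shifts the whole grid back half a fraction
  s_start <- fraction_schedule(6, rt_convention = "start")
  expect_equal(fraction_to_rt(s_start, 1), 0)
})

test_that("capacity planning reproduces the printed plate arithmetic", {
  l <- plate_layout()
  p6 <- plan_plate(l, fraction_schedule(6), 4)
  expect_equal(p6$wells_per_run, 368)
  expect_equal(p6$runs_per_plate, 1)
  expect_equal(p6$venoms_per_sequence, 4)
  p12 <- plan_plate(l, fraction_schedule(12), 4)
  expect_equal(p12$wells_per_run, 184)
  expect_equal(p12$runs_per_plate, 2)
  expect_equal(p12$venoms_per_sequence, 8)
  expect_equal(plan_plate(l, fraction_schedule(6), 0)$venoms_per_sequence, 0)
  # a run that does not fit on one plate is rejected at schedule time
  expect_error(fraction_schedule(6, 2400), class = "venompsc_layout_error")
  # window must divide evenly into fractions
  expect_error(fraction_schedule(7, 2208), class = "venompsc_schedule_error")
  expect_equal(runs_per_day(14.4), 100)
})

test_that("fraction <-> well <-> rt mapping round-trips exhaustively", {
  l <- plate_layout()
  for (res in c(6, 12)) {
    s <- fraction_schedule(res)
    i <- seq_len(s$wells_per_run)
    ids <- fraction_to_well(l, i)
    expect_equal(well_to_fraction(l, ids), i)
    expect_equal(fraction_to_well(l, well_to_fraction(l, ids)), ids)
  }
  expect_error(well_to_fraction(l, "Q1"), class = "venompsc_layout_error")
  expect_error(well_to_fraction(l, "A25"), class = "venompsc_layout_error")
  expect_error(well_to_fraction(l, "foo"), class = "venompsc_layout_error")
})

test_that("halving the resolution halves wells per run and doubles runs", {
  s6 <- fraction_schedule(6)
  s12 <- fraction_schedule(12)
  expect_equal(s12$wells_per_run * 2, s6$wells_per_run)
  expect_equal(s12$runs_per_plate, 2 * s6$runs_per_plate)
})

test_that("well map enumerates disjoint runs continuing one serpentine", {
  l <- plate_layout()
  s12 <- fraction_schedule(12)
  wm <- well_map(l, s12, n_plates = 2)
  expect_named(wm, c("plate_index", "run_index", "fraction_index",
                     "well_id", "rt_min"))
  expect_equal(nrow(wm), 2 * 2 * 184)
  p1 <- wm[wm$plate_index == 1, ]
  expect_equal(length(intersect(p1$well_id[p1$run_index == 1],
                                p1$well_id[p1$run_index == 2])), 0)
  # run 2 continues the serpentine where run 1 stopped
  expect_equal(p1$well_id[p1$run_index == 2][1],
               fraction_to_well(l, 185))
  expect_equal(p1$rt_min[p1$run_index == 1], p1$rt_min[p1$run_index == 2])
})

test_that("flat key-value config reproduces layout and schedule", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("key,value", "n_rows,16", "n_cols,24", "resolution_s,12",
               "collection_window_s,2208", "collection_start_min,0.5",
               "n_plates,4"), path)
  cfg <- read_platemap_config(path)
  expect_equal(cfg$schedule$wells_per_run, 184)
  expect_equal(cfg$schedule$collection_start_min, 0.5)
  expect_equal(cfg$n_plates, 4L)
  expect_equal(cfg$layout$capacity, 384)
})
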