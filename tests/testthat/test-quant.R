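test_that("peak detection finds runs, bridges small gaps and splits valleys", {
  # unimodal run: one peak with the apex at the middle fraction
  p1 <- detect_peaks(make_trace(c(0, 100, 200, 100, 0)))
  expect_equal(nrow(p1), 1)
  expect_equal(p1$apex_rt, 0.25)
  expect_equal(p1$apex_value, 200)
  expect_equal(p1$n_fractions, 3)
  # a gap of two zero fractions exceeds tolerance 1: two peaks
  p2 <- detect_peaks(make_trace(c(0, 100, 0, 0, 100, 0)), gap_tolerance = 1)
  expect_equal(nrow(p2), 2)
  # a single dropout well is absorbed
  p3 <- detect_peaks(make_trace(c(0, 100, 0, 100, 0)), gap_tolerance = 1)
  expect_equal(nrow(p3), 1)
  # valley below split_ratio x smaller maximum splits the run
  p4 <- detect_peaks(make_trace(c(0, 200, 40, 180, 0)), split_ratio = 0.5)
  expect_equal(nrow(p4), 2)
  expect_equal(p4$apex_value, c(200, 180))
  # valley at exactly the ratio does not split
  p5 <- detect_peaks(make_trace(c(0, 200, 90, 180, 0)), split_ratio = 0.5)
  expect_equal(nrow(p5), 1)
  expect_equal(detect_peaks(make_trace(rep(0, 6))), detect_peaks(make_trace(numeric(0) )))
  expect_equal(nrow(detect_peaks(make_trace(rep(0, 6)))), 0)
})

test_that("peaks partition the nonzero fractions disjointly", {
  set.seed(402)
  for (k in 1:25) {
    tr <- random_trace()
    pk <- detect_peaks(tr)
    if (nrow(pk) == 0) next
    expect_true(all(pk$rt_start <= pk$apex_rt & pk$apex_rt <= pk$rt_end))
    expect_true(all(diff(pk$rt_start) > 0))
    expect_true(all(pk$rt_end[-nrow(pk)] < pk$rt_start[-1]))
    expect_true(all(pk$area > 0))
    # every nonzero fraction belongs to at most one peak; apex is the max
    for (i in seq_len(nrow(pk))) {
      inside <- tr$rt_min >= pk$rt_start[i] & tr$rt_min <= pk$rt_end[i]
      expect_equal(max(tr$value[inside]), pk$apex_value[i])
    }
  }
})

test_that("trapezoid integration with zero anchors matches hand values", {
  tr <- make_trace(c(0, 100, 200, 100, 0))
  pk <- detect_peaks(tr)
  expect_equal(pk$area, 40)              # 0.1 * (50 + 150 + 150 + 50)
  # degenerate single-fraction peak: two triangles, not zero
  tr1 <- make_trace(c(0, 0, 100, 0, 0))
  expect_equal(detect_peaks(tr1)$area, 10)
  # and against the independent trapezoid in pracma
  expect_equal(pk$area,
               pracma::trapz(c(0.05, 0.15, 0.25, 0.35, 0.45),
                             c(0, 100, 200, 100, 0)))
})

test_that("peak areas agree with a brute-force oracle on random traces", {
  set.seed(517)
  for (k in 1:40) {
    tr <- random_trace()
    pk <- detect_peaks(tr)
    for (i in seq_len(nrow(pk))) {
      expect_equal(pk$area[i], oracle_peak_area(tr, pk[i, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("integration is linear in the trace scale", {
  set.seed(88)
  for (k in 1:10) {
    tr <- random_trace()
    pk <- detect_peaks(tr)
    if (nrow(pk) == 0) next
    tr_scaled <- make_trace(tr$value * 3.7)
    pk_scaled <- detect_peaks(tr_scaled)
    expect_equal(nrow(pk_scaled), nrow(pk))  # split ratios are scale-free
    expect_equal(pk_scaled$area, pk$area * 3.7)
  }
})

test_that("summed scores total an accession's wells", {
  s <- tiny_schedule()
  l <- plate_layout()
  wells <- serpentine_sequence(l, 10)
  m <- merge_wells(make_hits(wells[c(1, 3, 5, 7)], c("PA", "PA", "PA", "PB"),
                             c(100, 300, 150, 40)), s, l)
  expect_equal(summed_score(m, "PA"), 550)
  expect_equal(summed_score(m, "NOPE"), 0)
  # equals the total of its PSC trace
  expect_equal(summed_score(m, "PA"), sum(build_psc(m, "PA", s)$value))
  tab <- summed_score(m)
  expect_equal(tab$summed_score[tab$accession == "PB"], 40)
})

test_that("toxin families classify by first matching keyword", {
  expect_equal(classify_family("Zinc metalloproteinase/disintegrin"), "SVMP")
  expect_equal(classify_family("Phospholipase A2"), "PLA2")
  expect_equal(classify_family("hypothetical protein"), "other")
  expect_equal(
    classify_family(c("Snake venom serine protease", "C-type lectin 2",
                      "L-amino-acid oxidase", "Three-finger toxin",
                      "Cysteine-rich secretory protein",
                      "Kunitz-type protease inhibitor", "Disintegrin rhodo")),
    c("SVSP", "CTL", "LAAO", "3FTx", "CRISP", "VKTI/Kunitz", "disintegrin"))
  expect_equal(classify_family(NA_character_), "other")
  # custom rule table takes precedence in its own order
  rules <- tibble::tibble(pattern = c("disintegrin", "metalloprotein"),
                          family = c("DIS", "SVMP"))
  expect_equal(classify_family("metalloproteinase/disintegrin",
                               rules = rules), "DIS")
})

test_that("family abundances normalize to 1 and rank by total", {
  x <- tibble::tibble(family = c("SVMP", "PLA2", "SVMP"),
                      area = c(200, 100, 100))
  fa <- family_abundance(x)
  expect_equal(fa$family, c("SVMP", "PLA2"))
  expect_equal(fa$fraction, c(0.75, 0.25))
  expect_equal(sum(fa$fraction), 1)
  expect_equal(family_abundance(tibble::tibble(family = "PLA2",
                                               area = 5))$fraction, 1)
  expect_warning(
    out <- family_abundance(tibble::tibble(family = "PLA2", area = 0)),
    "zero")
  expect_equal(nrow(out), 0)
  # score-sum mode runs through the same normalization
  fs <- family_abundance(tibble::tibble(family = c("A", "B"),
                                        summed_score = c(30, 10)),
                         "summed_score")
  expect_equal(fs$fraction, c(0.75, 0.25))
})

test_that("UV peaks match PSC apexes within tolerance, flag co-elution", {
  fine <- seq(0, 21, by = 0.005)
  uv <- tibble::tibble(rt_min = fine,
                       absorbance = dnorm(fine, 10.03, 0.15) +
                                    0.5 * dnorm(fine, 15.0, 0.15))
  peaks <- tibble::tibble(accession = c("PA", "PB"), peak_id = c(1L, 1L),
                          rt_start = c(9.75, 19.75), rt_end = c(10.25, 20.25),
                          apex_rt = c(10.0, 20.0), apex_value = c(100, 80),
                          area = c(10, 8), n_fractions = c(5L, 5L))
  res <- match_uv_peaks(peaks, uv, rt_tolerance_min = 0.1)
  expect_true(res$matched[1])                    # 10.03 within 0.1 of 10.0
  expect_equal(res$uv_apex_rt[1], 10.03, tolerance = 1e-6)
  expect_false(res$matched[2])                   # nearest UV apex 5 min away
  expect_true(res$uv_area[1] > 0.9 && res$uv_area[1] < 1.1)  # unit Gaussian
  # two PSC peaks near one UV apex: both flagged ambiguous
  peaks2 <- peaks
  peaks2$apex_rt <- c(10.0, 10.05)
  peaks2$rt_start <- c(9.75, 9.8)
  peaks2$rt_end <- c(10.25, 10.3)
  res2 <- match_uv_peaks(peaks2, uv, rt_tolerance_min = 0.1)
  expect_true(all(res2$matched))
  expect_true(all(res2$ambiguous))
  # empty UV trace: everything unmatched
  res3 <- match_uv_peaks(peaks, uv[0, ], rt_tolerance_min = 0.1)
  expect_false(any(res3$matched))
})
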