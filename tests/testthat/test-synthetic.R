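test_that("cohort generation is deterministic and calibrated to cell means", {
  spec <- small_spec(seed = 101)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)

  # TE-male cell at its study size: sample mean within 3 SEs of the cell mean
  cells <- default_cells()
  spec_te <- cohort_spec(seed = 202,
                         cells = cells[cells$sex == "male" & cells$group == "TE", ],
                         n_fail_scores = 0L, n_fail_downstream = 0L)
  ch <- generate_cohort(spec_te)
  expect_equal(nrow(ch$participants), 62)
  se3 <- 3 * 9.4 / sqrt(62)
  expect_lt(abs(mean(ch$participants$weight_kg) - 82.6), se3)
  # composition identity holds exactly by construction
  expect_equal(ch$participants$ffm_kg + ch$participants$bfm_kg,
               ch$participants$weight_kg)
})

test_that("degenerate cells with zero SDs collapse to the cell means", {
  cells <- default_cells()[1, ]
  cells[grep("_sd$", names(cells))] <- 0
  ch <- generate_cohort(cohort_spec(seed = 1, cells = cells,
                                    n_fail_scores = 0L, n_fail_downstream = 0L))
  expect_equal(unique(ch$participants$weight_kg), cells$weight_mean)
  expect_equal(unique(ch$participants$height_cm), cells$height_mean)
  expect_equal(unique(ch$truth$duration_min), round(cells$extime_mean * 3) / 3)
})

test_that("generated score vectors reproduce the intended exclusion split", {
  spec <- small_spec(seed = 303, n = 10L, n_fail_scores = 12L,
                     n_fail_downstream = 0L)
  ch <- generate_cohort(spec)
  cls <- classify_sasang(ch$participants$score_te, ch$participants$score_se,
                         ch$participants$score_sy)
  fails <- cls %in% c("low_top_score", "ambiguous_margin")
  expect_equal(sum(fails), 12)
  expect_equal(sum(!fails), 60)
  # passing subjects are classified as their generating group
  pass <- ch$truth$fail_mode == "none"
  expect_equal(cls[pass], ch$truth$true_group[pass])
})

test_that("breath traces follow the kinetic forward model", {
  subj <- list(weight_kg = 70, peak_vo2_ml_kg = 45, duration_min = 11)
  tr <- generate_breath_trace(subj, trace_spec(), seed = 5)
  expect_equal(sum(tr$t > 0), 33)
  expect_equal(sum(tr$t <= 0), 3)

  # zero noise: the trace is the deterministic curve, twice the same
  ts0 <- trace_spec(vo2_noise_sd = 0, rq_noise_sd = 0)
  d1 <- generate_breath_trace(subj, ts0, seed = 1)
  d2 <- generate_breath_trace(subj, ts0, seed = 99)
  expect_equal(d1$vo2, d2$vo2)
  expect_true(all(diff(d1$vo2[d1$t > 0]) > -1e-9)) # monotone rise to peak

  # the generator's peak parameter is recovered through ingest
  subj12 <- list(weight_kg = 70, peak_vo2_ml_kg = 45, duration_min = 12)
  d3 <- generate_breath_trace(subj12, ts0)
  m <- aggregate_per_minute(d3, c("vo2", "rq"))
  expect_equal(max_oxygen_uptake(m, 70), 45, tolerance = 0.02)
})

test_that("sweat traces are piecewise-linear ramps with group-ordered slopes", {
  subj <- list(duration_min = 10, true_group = "SY", fail_mode = "none")
  ts0 <- trace_spec(lsr_noise_sd = 0)
  tr <- generate_sweat_trace(subj, ts0)
  chest <- tr[tr$site == "chest", ]
  expect_true(all(chest$lsr[chest$t <= ts0$onset_chest_min * 60] == 0))
  k <- chest$t / 60 - ts0$onset_chest_min
  expect_equal(chest$lsr, ts0$lsr_slope * 1.0 * pmax(k, 0))

  flat <- trace_spec(lsr_noise_sd = 0, lsr_slope = 0)
  tr0 <- generate_sweat_trace(subj, flat)
  expect_true(all(tr0$lsr == 0))

  mult <- trace_spec()$slope_multiplier
  expect_true(mult[["TE"]] > mult[["SY"]] && mult[["SY"]] > mult[["SE"]])
})

test_that("study bundles are byte-identical under a fixed seed and round-trip", {
  spec <- small_spec(seed = 404, n = 4L, n_fail_scores = 3L,
                     n_fail_downstream = 2L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_study(spec, d1)
  generate_study(spec, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # bundle is directly consumable by the pipeline with zero validation errors
  rep <- run_pipeline(d1)
  expect_equal(nrow(rep$included), 24)
  expect_equal(sort(unique(rep$exclusions$reason)),
               sort(unique(c("low_top_score", "ambiguous_margin",
                             "unusual_sweat", "missing_vo2"))))
})
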