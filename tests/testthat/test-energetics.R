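test_that("vertical displacement and external workload follow their definitions", {
  expect_equal(vertical_displacement(0.10, 45.6, 70), 319.2)
  expect_equal(vertical_displacement(0, 50, 70), 0)
  expect_equal(vertical_displacement(0.12, 67.1, 70), 563.64)
  expect_equal(external_workload(612), 100.0)
  expect_equal(external_workload(0), 0)
  expect_equal(external_workload(319.2), 319.2 / 6.12)
  expect_error(external_workload(-1), ">= 0")
})

test_that("metabolic energy reproduces the pure-substrate endpoints", {
  # carbohydrate-only limit: 21.13 kJ/L scaled by 16.67
  expect_equal(metabolic_energy(1.0, 1.0), 21.13 * 16.67)
  # fat-only limit: 19.62 kJ/L
  expect_equal(metabolic_energy(1.0, 0.7), 19.62 * 16.67)
  expect_equal(metabolic_energy(0, 0.85), 0)
  expect_error(metabolic_energy(-0.1, 0.85), ">= 0")
})

test_that("metabolic energy is affine in RQ and linear in VO2", {
  rq <- seq(0.7, 1.0, by = 0.05)
  e <- metabolic_energy(1.0, rq)
  expect_equal(diff(e, differences = 2), rep(0, length(rq) - 2))
  vo2 <- c(0.5, 1, 2, 3.3)
  expect_equal(metabolic_energy(vo2, 0.85), vo2 * metabolic_energy(1, 0.85))
})

test_that("RQ above 1 is clamped by default and extrapolated on request", {
  expect_equal(metabolic_energy(1, 1.1), metabolic_energy(1, 1.0))
  expect_equal(metabolic_energy(1, 0.6), metabolic_energy(1, 0.7))
  expect_gt(metabolic_energy(1, 1.1, clamp_rq = FALSE), metabolic_energy(1, 1.0))
})

test_that("heat production, efficiency and temperature increment compose", {
  expect_equal(heat_production(352.24, 52.16), 300.08)
  expect_equal(heat_production(120, 0), 120)
  expect_equal(heat_production(100, 100), 0)
  expect_warning(h <- heat_production(90, 100), "over 100")
  expect_equal(h, -10)
  expect_equal(metabolic_efficiency(25, 100), 25.0)
  expect_equal(metabolic_efficiency(0, 100), 0)
  expect_true(is.na(metabolic_efficiency(0, 0)))
  expect_equal(metabolic_efficiency(52.16, 352.24), 14.81, tolerance = 1e-3)

  # definitional unit case: one kcal per kg of water raises it 1 degree C
  bw <- 45.1; rest <- 83.6
  expect_equal(temperature_increment(rest + 69.78 * bw, rest, bw), 1.0)
  expect_equal(temperature_increment(rest, rest, bw), 0)
  expect_equal(temperature_increment(300.08, 83.6, 45.1), 0.0688,
               tolerance = 1e-3)
  # negative increments floor at zero unless asked not to
  expect_equal(temperature_increment(50, 83.6, 45.1), 0)
  expect_lt(temperature_increment(50, 83.6, 45.1, floor_at_zero = FALSE), 0)
  expect_error(temperature_increment(100, 80, 0), "body water")
})

test_that("temperature increment is additive when a minute is split in half", {
  h <- 300; rest <- 84; bw <- 42
  whole <- temperature_increment(h, rest, bw, floor_at_zero = FALSE)
  halves <- 2 * temperature_increment(h / 2, rest / 2, bw, floor_at_zero = FALSE)
  expect_equal(whole, halves)
})

test_that("protocol stages map onto exercise minutes", {
  expect_equal(stage_for_minute(1:9), rep(1:3, each = 3))
  expect_equal(stage_for_minute(21), 7L)
  expect_error(stage_for_minute(22), "schedule-exhausted")
  p <- bruce_protocol()
  expect_equal(p$speed_m_min[1], 1.7 * 26.8224)
  expect_equal(p$grade, seq(0.10, 0.22, by = 0.02))
})

test_that("the per-minute energetics series composes the unit examples", {
  bm <- tibble::tibble(minute = 0:1, vo2 = c(0.3, 1.0), rq = c(0.8, 1.0))
  en <- build_energetics_series(bm, weight_kg = 70, body_water_kg = 45.1)
  p <- bruce_protocol()
  w_e_exp <- 0.10 * p$speed_m_min[1] * 70 / 6.12
  expect_equal(en$minutes$w_e, w_e_exp)
  expect_equal(en$minutes$m_ee, 21.13 * 16.67)
  expect_equal(en$minutes$h_prod, 21.13 * 16.67 - w_e_exp)
  expect_equal(w_e_exp, 52.16, tolerance = 2e-4)
  expect_equal(en$minutes$h_prod, 300.08, tolerance = 1e-4)
})

test_that("flat-grade minutes yield zero workload and H_prod = M_ee", {
  flat <- tibble::tibble(stage = 1L, speed_m_min = 50, grade = 1e-9,
                         duration_min = 10)
  bm <- tibble::tibble(minute = 0:3, vo2 = c(0.3, 1, 1, 1), rq = 0.85)
  en <- build_energetics_series(bm, protocol = flat, weight_kg = 70,
                                body_water_kg = 40)
  expect_equal(en$minutes$w_e, rep(0, 3), tolerance = 1e-6)
  expect_equal(en$minutes$h_prod, en$minutes$m_ee, tolerance = 1e-6)
  expect_equal(en$minutes$efficiency_pct, rep(0, 3), tolerance = 1e-4)
})

test_that("totals conserve energy and the series needs a resting record", {
  set.seed(5)
  bm <- tibble::tibble(minute = 0:11,
                       vo2 = c(0.3, seq(0.8, 3, length.out = 11)),
                       rq = c(0.8, seq(0.82, 1.0, length.out = 11)))
  en <- build_energetics_series(bm, weight_kg = 80, body_water_kg = 44)
  expect_equal(en$totals$total_h_prod,
               en$totals$total_m_ee - en$totals$total_w_e)
  expect_equal(en$totals$total_w_e, sum(en$minutes$w_e))
  expect_equal(en$minutes$t_inc_cum, cumsum(en$minutes$t_inc_step))
  expect_true(all(diff(en$minutes$t_inc_cum) >= 0))
  expect_error(build_energetics_series(bm[-1, ], weight_kg = 80,
                                       body_water_kg = 44), "minute-0")
})

test_that("the printed energy constants match their physical derivations", {
  expect_equal(energy_constants()$kcal_watt_min, 4186.8 / 60)
  expect_equal(round(60 / 9.80665, 2), energy_constants()$workload_divisor)
})
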