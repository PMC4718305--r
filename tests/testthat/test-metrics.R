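# Expected crossing times frozen from an independent high-accuracy oracle:
# deSolve::lsoda (rtol 1e-12) + uniroot on the resulting concentration,
# run on the same scenarios outside the package.
ORACLE <- list(
  group_a_ce_cross = 13.95876,   # abs time, 50 ug bolus at t = -10
  group_a_cp_cross = 3.965611,
  group_a_ce_peak = 0.4669857,
  group_a_ce_peak_t = -4.729131,
  group_b_ce_cross = 39.41442,
  group_b_ce_at_60 = 0.2234494
)

test_that("a series that never leaves the window reports full compliance", {
  # a large constant infusion keeps ce far above the MEC over [30, 120]
  r <- regimen("high", list(bolus_event(0, 100), infusion_segment(0, 200, 60)))
  ser <- simulate_regimen(r, t_start = 0, t_end = 200, grid_step = 0.5)
  m <- window_metrics(ser, therapeutic_window(), 30, 120)
  expect_true(is.na(m$first_below_mec))
  expect_equal(m$time_below_mec, 0)
  expect_equal(nrow(m$undertreated_intervals), 0)
})

test_that("a series entirely below the MEC is undertreated throughout", {
  ser <- simulate_regimen(regimen("empty"), t_start = 0, t_end = 60, grid_step = 1)
  m <- window_metrics(ser, therapeutic_window(), 0, 60)
  expect_equal(m$time_below_mec, 60)
  expect_equal(m$undertreated_intervals, data.frame(start = 0, end = 60))
  expect_true(is.na(m$first_below_mec))  # never crossed downward
})

test_that("the demand-only scenario crosses the MEC where the oracle says", {
  ser <- simulate_regimen(scenario_regimen("group_a"), t_end = 240)
  m <- window_metrics(ser, therapeutic_window(), 0, 240)
  expect_equal(m$first_below_mec, ORACLE$group_a_ce_cross, tolerance = 1e-4)
  expect_equal(m$first_below_mec_rel, ORACLE$group_a_ce_cross + 10, tolerance = 1e-4)

  mp <- window_metrics(ser, therapeutic_window(reference = "plasma"), 0, 240)
  expect_equal(mp$first_below_mec, ORACLE$group_a_cp_cross, tolerance = 1e-4)

  # peaks, evaluated over a window that includes the preoperative bolus
  mf <- window_metrics(ser, therapeutic_window(), -10, 240)
  expect_equal(mf$c_max, ORACLE$group_a_ce_peak, tolerance = 1e-5)
  expect_equal(mf$t_cmax, ORACLE$group_a_ce_peak_t, tolerance = 1e-3)
  mpf <- window_metrics(ser, therapeutic_window(reference = "plasma"), -10, 240)
  # the peak plasma concentration sits at the bolus instant
  expect_equal(mpf$c_max, 50 / 26.6, tolerance = 1e-9)
  expect_equal(mpf$t_cmax, -10)
})

test_that("the model-based scenario crosses the MEC where the oracle says", {
  ser <- simulate_regimen(scenario_regimen("group_b"), t_end = 240)
  m <- window_metrics(ser, therapeutic_window(), 0, 240)
  expect_equal(m$first_below_mec, ORACLE$group_b_ce_cross, tolerance = 1e-4)
  expect_equal(concentration_at(ser, 60, "effect_site"),
               ORACLE$group_b_ce_at_60, tolerance = 1e-6)
})

test_that("crossing times do not depend on the simulation grid", {
  for (step in c(0.05, 0.3, 1)) {
    ser <- simulate_regimen(scenario_regimen("group_b"), t_end = 120, grid_step = step)
    m <- window_metrics(ser, therapeutic_window(), 0, 120)
    expect_equal(m$first_below_mec, ORACLE$group_b_ce_cross, tolerance = 1e-4)
  }
})

test_that("undertreated intervals partition the time below the MEC", {
  # a bolus regimen that dips below the MEC and is pushed back above by a
  # later bolus produces two disjoint undertreated intervals
  r <- regimen("two_dips", list(bolus_event(0, 50), bolus_event(40, 50)))
  ser <- simulate_regimen(r, t_start = 0, t_end = 120, grid_step = 0.5)
  m <- window_metrics(ser, therapeutic_window(), 0, 120)
  ui <- m$undertreated_intervals
  expect_gte(nrow(ui), 2)
  expect_true(all(diff(as.vector(t(ui[, c("start", "end")]))) >= 0)) # sorted, disjoint
  expect_equal(sum(ui$end - ui$start), m$time_below_mec, tolerance = 1e-6)
})

test_that("adding dose never increases the time below the MEC", {
  base <- scenario_regimen("group_a")
  m0 <- window_metrics(simulate_regimen(base, t_end = 240),
                       therapeutic_window(), 0, 240)
  set.seed(5)
  for (i in 1:5) {
    extra <- bolus_event(runif(1, 0, 200), runif(1, 5, 50))
    r2 <- regimen("plus", c(base$preop_events, list(extra)), pca = base$pca)
    m2 <- window_metrics(simulate_regimen(r2, t_end = 240),
                         therapeutic_window(), 0, 240)
    expect_lte(m2$time_below_mec, m0$time_below_mec + 1e-6)
  }
})

test_that("an excursion above the upper bound is measured", {
  # stack boluses to push ce beyond 2 ng/mL
  r <- regimen("stacked", list(bolus_event(0, 100), bolus_event(5, 100),
                               bolus_event(10, 100)))
  ser <- simulate_regimen(r, t_start = 0, t_end = 120, grid_step = 0.5)
  m <- window_metrics(ser, therapeutic_window(), 0, 120)
  expect_gt(m$c_max, 2)
  expect_gt(m$time_above_upper, 0)
})

test_that("degenerate evaluation intervals are rejected", {
  ser <- simulate_regimen(scenario_regimen("group_a"), t_end = 60)
  expect_error(window_metrics(ser, therapeutic_window(), 30, 30), "degenerate")
  expect_error(window_metrics(ser, therapeutic_window(), 0, 600), "range")
})
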