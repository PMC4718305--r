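test_that("an empty regimen stays at zero concentration", {
  ser <- simulate_regimen(regimen("empty"), t_start = 0, t_end = 60, grid_step = 1)
  expect_true(all(ser$cp == 0))
  expect_true(all(ser$ce == 0))
  expect_true(all(ser$cumulative_dose == 0))
})

test_that("the demand-only scenario jumps to dose/V at the preoperative bolus", {
  ser <- simulate_regimen(scenario_regimen("group_a"), t_end = 120)
  expect_equal(ser$times[1], -10)
  expect_equal(ser$cp[1], 50 / 26.6, tolerance = 1e-12) # post-bolus right limit
  expect_equal(ser$ce[1], 0)
  expect_true(all(diff(ser$cumulative_dose) >= 0))
})

test_that("results are independent of the output grid (exact propagation)", {
  for (name in scenario_names()) {
    coarse <- simulate_regimen(scenario_regimen(name), t_end = 120, grid_step = 0.8)
    fine <- simulate_regimen(scenario_regimen(name), t_end = 120, grid_step = 0.4)
    shared <- intersect(round(coarse$times, 9), round(fine$times, 9))
    ic <- match(shared, round(coarse$times, 9))
    if_ <- match(shared, round(fine$times, 9))
    expect_equal(coarse$cp[ic], fine$cp[if_], tolerance = 1e-12)
    expect_equal(coarse$ce[ic], fine$ce[if_], tolerance = 1e-12)
  }
})

test_that("ce is continuous at boluses while cp jumps", {
  r <- regimen("mid_bolus", preop_events = list(bolus_event(0, 50), bolus_event(30, 25)))
  ser <- simulate_regimen(r, t_start = 0, t_end = 60, grid_step = 0.5)
  eps <- 1e-7
  ce_before <- concentration_at(ser, 30 - eps, "effect_site")
  i30 <- which(abs(ser$times - 30) < 1e-9)
  expect_equal(ser$ce[i30], ce_before, tolerance = 1e-6)
  cp_before <- concentration_at(ser, 30 - eps, "plasma")
  expect_equal(ser$cp[i30] - cp_before, 25 / 26.6, tolerance = 1e-6)
})

test_that("cumulative dose accounts for boluses plus infused volume", {
  ser <- simulate_regimen(scenario_regimen("group_b"), t_end = 2880)
  i60 <- which(abs(ser$times - 60) < 1e-9)
  expect_equal(ser$cumulative_dose[i60], 70)
  # 50 loading + 20 ug/h * 1 h + 10 ug/h * 47 h
  expect_equal(max(ser$cumulative_dose), 50 + 20 + 10 * 47)
})

test_that("simulation is additive across superposed regimens", {
  r1 <- regimen("bolus_only", list(bolus_event(-10, 50)))
  r2 <- regimen("infusion_only", list(infusion_segment(0, 60, 20),
                                      infusion_segment(60, 120, 10)))
  r12 <- regimen("both", c(r1$preop_events, r2$preop_events))
  s1 <- simulate_regimen(r1, t_end = 120, grid_step = 1)
  s2 <- simulate_regimen(r2, t_end = 120, grid_step = 1)
  s12 <- simulate_regimen(r12, t_end = 120, grid_step = 1)
  expect_equal(s12$cp, s1$cp + s2$cp, tolerance = 1e-9)
  expect_equal(s12$ce, s1$ce + s2$ce, tolerance = 1e-9)
})

test_that("concentration_at recomputes exactly between breakpoints", {
  ser <- simulate_regimen(scenario_regimen("group_b"), t_end = 120, grid_step = 2)
  fine <- simulate_regimen(scenario_regimen("group_b"), t_end = 120, grid_step = 0.25)
  # stored value at a grid point
  i <- which(abs(ser$times - 30) < 1e-9)
  expect_identical(concentration_at(ser, 30, "effect_site"), ser$ce[i])
  # off-grid values match a finer simulation's stored values
  for (t in c(15.25, 59.75, 60.25, 99.5)) {
    j <- which(abs(fine$times - t) < 1e-9)
    expect_equal(concentration_at(ser, t, "effect_site"), fine$ce[j], tolerance = 1e-10)
    expect_equal(concentration_at(ser, t, "plasma"), fine$cp[j], tolerance = 1e-10)
  }
  expect_error(concentration_at(ser, 500), "range")
})

test_that("series round-trip through the fixed CSV layout", {
  ser <- simulate_regimen(scenario_regimen("group_a"), t_end = 30, grid_step = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(ser, path)
  df <- utils::read.csv(path)
  expect_named(df, c("time_min", "cp_ng_ml", "ce_ng_ml", "cumulative_dose_ug"))
  expect_equal(df$cp_ng_ml, ser$cp, tolerance = 1e-12)
})

test_that("events outside the simulation window are rejected", {
  expect_error(simulate_regimen(regimen("early", list(bolus_event(-30, 10))),
                                t_start = -10, t_end = 60),
               "start")
  expect_error(simulate_regimen(regimen("late", list(bolus_event(500, 10))),
                                t_start = -10, t_end = 60),
               "horizon")
})
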