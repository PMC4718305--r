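test_that("rate matrix encodes the mammillary model with effect site", {
  p <- pk_parameters()
  A <- rate_matrix(p)
  expect_equal(dim(A), c(4L, 4L))
  expect_equal(A["a1", "a1"], -0.3362)
  expect_equal(A["a2", ], c(a1 = p$k12, a2 = -p$k21, a3 = 0, ce = 0))
  expect_equal(A["a3", ], c(a1 = p$k13, a2 = 0, a3 = -p$k31, ce = 0))
  expect_equal(A["ce", ], c(a1 = p$ke0 / p$v_central, a2 = 0, a3 = 0, ce = -p$ke0))

  # mass balance of the amount block: column sums (-k10, 0, 0), for arbitrary
  # positive parameters
  set.seed(11)
  for (i in 1:20) {
    pr <- random_params()
    expect_equal(unname(colSums(rate_matrix(pr)[1:3, 1:3])),
                 c(-pr$k10, 0, 0), tolerance = 1e-12)
  }

  expect_error(pk_parameters(k10 = 0), "positive")
  expect_error(pk_parameters(v_central = -1), "positive")
})

test_that("propagation reduces to the mono-exponential when peripheral transfer is off", {
  p <- pk_parameters(k12 = 1e-300, k13 = 1e-300) # effectively decoupled
  s <- propagate(system_state(a1 = 50), p, dt = 1 / p$k10)
  expect_equal(s$a1, 50 * exp(-1), tolerance = 1e-9)
  expect_equal(s$a2, 0, tolerance = 1e-12)
  expect_equal(s$a3, 0, tolerance = 1e-12)
})

test_that("propagate handles the identity and validation cases", {
  p <- pk_parameters()
  s <- apply_bolus(system_state(), 50)
  expect_identical(propagate(s, p, dt = 0), s)
  expect_error(propagate(s, p, dt = -1), "non-negative")
  expect_error(propagate(s, p, infusion_rate = -0.1, dt = 1), "non-negative")
})

test_that("a constant infusion approaches cp = rate / (k10 * v_central)", {
  p <- pk_parameters()
  rate <- 20 / 60 # 20 ug/h in ug/min
  # exact propagation allows one very long step
  s <- propagate(system_state(), p, infusion_rate = rate, dt = 5e4)
  cp_ss <- rate / (p$k10 * p$v_central)
  expect_equal(plasma_conc(s, p), cp_ss, tolerance = 1e-6)
  expect_equal(cp_ss, 0.37746, tolerance = 1e-4)
  # at steady state the effect site has equilibrated with plasma
  expect_equal(s$ce, plasma_conc(s, p), tolerance = 1e-6)
})

test_that("boluses are instantaneous, additive and validated", {
  p <- pk_parameters()
  s0 <- system_state()
  s <- apply_bolus(s0, 50)
  expect_equal(plasma_conc(s, p), 50 / 26.6)
  expect_equal(plasma_conc(s, p), 1.8797, tolerance = 1e-4)
  expect_equal(s$ce, 0)
  expect_identical(apply_bolus(s0, 0), s0)
  expect_identical(apply_bolus(apply_bolus(s0, 30), 30), apply_bolus(s0, 60))
  expect_error(apply_bolus(s0, -5), "non-negative")
})

test_that("the propagator is linear in dose and rate", {
  set.seed(42)
  for (i in 1:10) {
    p <- random_params()
    d <- runif(1, 1, 100)
    r <- runif(1, 0, 2)
    dt <- runif(1, 0.5, 120)
    s1 <- propagate(apply_bolus(system_state(), d), p, r, dt)
    s3 <- propagate(apply_bolus(system_state(), 3 * d), p, 3 * r, dt)
    for (f in c("a1", "a2", "a3", "ce"))
      expect_equal(s3[[f]], 3 * s1[[f]], tolerance = 1e-9)
  }
})

test_that("states stay non-negative under non-negative dosing", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_params()
    s <- apply_bolus(system_state(), runif(1, 0, 100))
    for (dt in runif(5, 0.01, 300)) {
      s <- propagate(s, p, infusion_rate = runif(1, 0, 1), dt = dt)
      expect_true(all(c(s$a1, s$a2, s$a3, s$ce) >= 0))
    }
  }
})

test_that("the effect site lags the plasma after a bolus", {
  p <- pk_parameters()
  ser <- simulate_regimen(regimen("bolus", list(bolus_event(0, 50))),
                          p, t_start = 0, t_end = 240, grid_step = 0.1)
  expect_lt(max(ser$ce), max(ser$cp))
  expect_gt(ser$times[which.max(ser$ce)], ser$times[which.max(ser$cp)])
})

test_that("matrix-exponential propagation matches the adaptive ODE oracle", {
  skip_if_not_installed("deSolve")
  set.seed(101)
  for (i in 1:10) {
    p <- random_params()
    reg <- random_regimen()
    ser <- simulate_regimen(reg, p, t_start = 0, t_end = 120, grid_step = 5)
    tab <- series_event_tables(ser)
    ref <- ode_oracle(p, ser$times, tab$boluses, tab$rate_steps)
    scale <- max(ref, 1e-8)
    expect_lt(max(abs(ser$states - ref)) / scale, 1e-6)
  }
})

test_that("mass is conserved up to first-order elimination", {
  p <- pk_parameters()
  reg <- scenario_regimen("group_b")
  ser <- simulate_regimen(reg, p, t_start = -10, t_end = 2880, grid_step = 0.1)
  administered <- max(ser$cumulative_dose)
  # eliminated mass k10 * integral of a1 dt by trapezoidal quadrature
  a1 <- ser$states[, "a1"]
  eliminated <- p$k10 * sum(diff(ser$times) * (utils::head(a1, -1) + utils::tail(a1, -1)) / 2)
  in_body <- sum(ser$states[nrow(ser$states), c("a1", "a2", "a3")])
  expect_equal(eliminated + in_body, administered, tolerance = 1e-3)
})
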