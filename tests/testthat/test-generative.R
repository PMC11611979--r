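test_that("rest is a fixed point of the neuronal and hemodynamic equations", {
  p <- gen_params()
  expect_equal(unname(neural_derivative(rep(0, 6), p, 0, 0)), rep(0, 6))
  expect_equal(hemodynamic_derivative(c(0, 1, 1, 1), 0), rep(0, 4))
})

test_that("the driving term is linear in C", {
  B <- matrix(0, 3, 3)
  p1 <- dcm_parameters(B = B, C = c(0, 0.3, 0.5))
  p2 <- dcm_parameters(B = B, C = 2 * c(0, 0.3, 0.5))
  x <- c(0.1, -0.2, 0.05, 0.02, 0, -0.01)
  d0 <- neural_derivative(x, p1, 0, 0)
  d1 <- neural_derivative(x, p1, 1, 0)
  d2 <- neural_derivative(x, p2, 1, 0)
  expect_equal(d2 - d0, 2 * (d1 - d0), tolerance = 1e-12)
})

test_that("non-finite states or parameters are rejected", {
  p <- gen_params()
  expect_error(neural_derivative(c(NA, rep(0, 5)), p, 0, 0), "finite")
  expect_error(dcm_parameters(A = matrix(Inf, 3, 3)), "finite")
  expect_error(hemodynamic_derivative(c(0, 1, -1, 1), 0), "physical")
})

test_that("the compiled integrator matches an adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  # single region, constant driving input; compare full BOLD trajectories
  A <- matrix(0, 1, 1); B <- matrix(0, 1, 1)
  p <- dcm_parameters(A = A, B = B, C = 1, log_tau = 0)
  cst <- p$constants
  dt <- 0.01; T_end <- 60
  n <- T_end / dt + 1
  inp <- structure(list(u = cbind(drive = rep(1, n), mod = rep(0, n)),
                        dt = dt, run_starts = 1L, n_per_run = as.integer(n)),
                   class = "input_set")
  bs <- simulate_bold(p, inp, tr = 1, n_volumes = T_end, snr = Inf)

  deriv <- function(t, y, parms) {
    nd <- neural_derivative(y[1:2], p, 1, 0)
    hd <- hemodynamic_derivative(y[3:6], y[1], cst)
    list(c(nd, hd))
  }
  y0 <- c(0, 0, 0, 1, 1, 1)
  times <- seq(0, T_end - 1, by = 1)
  sol <- deSolve::lsoda(y0, times, deriv, NULL, rtol = 1e-12, atol = 1e-12)
  bold_ref <- bold_signal(sol[, 6], sol[, 7], cst)
  expect_lt(max(abs(bs$y[, 1] - bold_ref)), 1e-6)
})

test_that("a brief neural impulse yields a BOLD peak 4-6 s later", {
  A <- matrix(0, 1, 1); B <- matrix(0, 1, 1)
  p <- dcm_parameters(A = A, B = B, C = 1, log_tau = 0)
  dt <- 0.05; T_end <- 30
  n <- T_end / dt + 1
  tgrid <- seq(0, T_end, by = dt)
  drive <- as.numeric(tgrid < 0.5)
  inp <- structure(list(u = cbind(drive = drive, mod = 0), dt = dt,
                        run_starts = 1L, n_per_run = as.integer(n)),
                   class = "input_set")
  bs <- simulate_bold(p, inp, tr = 0.25, n_volumes = T_end * 4, snr = Inf)
  t_peak <- (which.max(bs$y[, 1]) - 1) * 0.25
  expect_gte(t_peak, 4); expect_lte(t_peak, 6)
})

test_that("flow reaches the closed-form steady state under constant drive", {
  skip_if_not_installed("deSolve")
  cst <- twostate_constants()
  xE <- 0.3
  deriv <- function(t, y, parms)
    list(hemodynamic_derivative(y, xE, cst))
  sol <- deSolve::lsoda(c(0, 1, 1, 1), seq(0, 120, 1), deriv, NULL,
                        rtol = 1e-10, atol = 1e-10)
  f_end <- unname(sol[nrow(sol), 3])
  expect_equal(f_end, 1 + xE / cst$gamma, tolerance = 1e-6)
})

test_that("simulation is deterministic given the seed and flat without input", {
  p <- gen_params()
  b1 <- simulate_bold(p, fix_inputs_run1, snr = 1, seed = 5)
  b2 <- simulate_bold(p, fix_inputs_run1, snr = 1, seed = 5)
  expect_identical(b1$y, b2$y)
  b3 <- simulate_bold(p, fix_inputs_run1, snr = 1, seed = 6)
  expect_false(identical(b3$y, b1$y))
  # no path from input to the network: output stays at baseline
  p0 <- dcm_parameters()
  expect_true(all(simulate_bold(p0, fix_inputs_run1, snr = Inf)$y == 0))
})

test_that("halving the integration step changes noise-free BOLD by < 0.1 % of range", {
  p <- gen_params()
  # degenerate 2.5 s jitter aligns every event edge on both microtime
  # grids, so the comparison isolates pure integration error
  cfg32 <- design_config(dt = 2.5 / 32, jitter = c(2.5, 2.5))
  sch <- build_trial_schedule(cfg32, seed = 7)
  inp32 <- dcm_inputs(sch, dt = 2.5 / 32)
  inp16 <- dcm_inputs(sch, dt = 2.5 / 16)
  y16 <- simulate_bold(p, inp16, snr = Inf)$y
  y32 <- simulate_bold(p, inp32, snr = Inf)$y
  expect_lt(max(abs(y16 - y32)), 0.001 * diff(range(y16)))
})

test_that("simulations stay bounded over 900 s across the prior range", {
  set.seed(21)
  for (i in 1:20) {
    A <- matrix(rnorm(9, 0, 0.25), 3, 3)
    B <- matrix(rnorm(9, 0, 0.5), 3, 3)
    p <- dcm_parameters(A = A, B = B, C = runif(3, 0, 0.6),
                        log_tau = rnorm(3, 0, 0.25))
    y <- simulate_bold(p, fix_inputs_run1, snr = Inf)$y
    expect_true(all(is.finite(y)))
    expect_lt(max(abs(y)), 50)
  }
})

test_that("the effective self-connection is negative for every parameter value", {
  for (theta in seq(-3, 3, by = 0.5))
    for (ub in seq(-3, 3, by = 0.5))
      expect_lt(effective_self_rate(theta, 1, ub), 0)
})

test_that("releasing self-inhibition monotonically increases the BOLD response", {
  totals <- vapply(c(0, -0.2, -0.4, -0.6), function(bs) {
    y <- simulate_bold(gen_params(b_self = bs), fix_inputs_run1,
                       snr = Inf)$y
    sum(y[, "SM1"])
  }, 0)
  expect_true(all(diff(totals) > 0))
})
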