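test_that("priors implement mask semantics", {
  null_spec <- model_spec(character(0), "PMd")
  pr <- default_priors(null_spec)
  tm <- pr$template
  sm1_b <- tm[tm$block == "B" &
                grepl("SM1", tm$connection) & !tm$enabled, ]
  expect_true(all(sm1_b$prior_var == 0))
  expect_true(all(tm$prior_mean[tm$block == "B"] == 0))
  # enabling a parameter strictly enlarges the prior support dimension
  bigger <- default_priors(model_spec("SMA->SM1", "PMd"))$template
  expect_equal(sum(bigger$enabled), sum(tm$enabled) + 1)
})

test_that("noise-free data generated at the prior mean is recovered exactly there", {
  p0 <- dcm_parameters()  # all parameters at their prior mean of 0
  bs <- simulate_bold(p0, fix_inputs_run1, snr = Inf)
  fit <- invert(bs, fix_inputs_run1, gen_spec, settings = st_fast)
  expect_lt(max(abs(fit$map_enabled)), 1e-3)
})

test_that("free energy equals the closed-form evidence for a linear-Gaussian model", {
  set.seed(1)
  n <- 50; p <- 4
  G <- matrix(rnorm(n * p), n, p)
  sigma2 <- 0.5
  y <- G %*% c(0.5, -0.3, 0.2, 0) + rnorm(n, 0, sqrt(sigma2))
  pm <- stats::setNames(rep(0, p), paste0("b", 1:p))
  pv <- stats::setNames(rep(1, p), paste0("b", 1:p))
  st <- invert_settings(estimate_noise = FALSE, lambda0 = log(1 / sigma2),
                        decimate = 1)
  fit <- invert_vl(matrix(y, ncol = 1), function(th) G %*% th, pm, pv, st)
  Sy <- G %*% diag(pv) %*% t(G) + diag(sigma2, n)
  exact <- -0.5 * (n * log(2 * pi) +
                     as.numeric(determinant(Sy)$modulus) +
                     drop(t(y) %*% solve(Sy, y)))
  expect_equal(fit$free_energy, exact, tolerance = 1e-3)
  # and the MAP equals the conjugate posterior mean
  post_mean <- solve(crossprod(G) / sigma2 + diag(1, p),
                     crossprod(G, y) / sigma2)
  expect_equal(unname(fit$map), drop(post_mean), tolerance = 1e-6)
})

test_that("accepted free energy is non-decreasing and inversion is deterministic", {
  bs <- gen_series()
  f1 <- invert(bs, fix_inputs_run1, gen_spec, settings = st_fast)
  f2 <- invert(bs, fix_inputs_run1, gen_spec, settings = st_fast)
  expect_true(all(diff(f1$F_trace) >= -1e-9))
  expect_identical(f1$map, f2$map)
  expect_identical(f1$free_energy, f2$free_energy)
})

test_that("strong negative SM1 self-modulation is recovered with the right sign", {
  signs <- vapply(1:3, function(r) {
    bs <- gen_series(snr = 1, seed = 100 + r)
    fit <- invert(bs, fix_inputs_run1, gen_spec, settings = st_fast)
    sign(fit$map[["B:self-SM1"]])
  }, 0)
  expect_true(all(signs == -1))
})

test_that("the generating model beats the null model in evidence", {
  # strong SM1-coupled modulations: the evidence margin comes from the
  # modulatory effects alone, since the null model shares A and C
  Bs <- matrix(0, 3, 3)
  Bs[1, 1] <- -0.6; Bs[1, 3] <- 0.5; Bs[3, 1] <- 0.4; Bs[3, 3] <- 0.1
  strong <- dcm_parameters(B = Bs, C = c(0, 0.4, 0.4))
  wins <- vapply(1:20, function(r) {
    bs <- gen_series(snr = 1, seed = 200 + r, params = strong)
    f_gen <- invert(bs, fix_inputs_run1, gen_spec, settings = st_fast)
    f_null <- invert(bs, fix_inputs_run1, model_spec(character(0), c("PMd", "SMA")),
                     settings = st_fast)
    f_gen$free_energy > f_null$free_energy
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("an irrelevant extra connection cannot inflate the evidence", {
  aug_spec <- model_spec(c(gen_spec$b_mask, "SMA->PMd", "PMd->SMA"),
                         gen_spec$c_mask)
  diffs <- vapply(1:5, function(r) {
    bs <- gen_series(snr = 1, seed = 300 + r)
    f_true <- invert(bs, fix_inputs_run1, gen_spec, settings = st_fast)
    f_aug <- invert(bs, fix_inputs_run1, aug_spec, settings = st_fast)
    f_aug$free_energy - f_true$free_energy
  }, 0)
  expect_true(all(diffs < 3))
})

test_that("variance explained follows its definition", {
  bs <- gen_series(snr = Inf)
  expect_equal(variance_explained(bs$y, bs), 100)
  flat <- matrix(mean(bs$y), nrow(bs$y), ncol(bs$y))
  expect_equal(variance_explained(flat, bs), 0)
  expect_error(variance_explained(flat, structure(list(y = flat, tr = 2.5),
                                                  class = "bold_series")),
               "zero-variance")
})

test_that("variance explained by the generating model is plausible at SNR 1", {
  ve <- vapply(1:3, function(r) {
    bs <- gen_series(snr = 1, seed = 400 + r)
    fit <- invert(bs, fix_inputs_run1, gen_spec, settings = st_fast)
    variance_explained(fit, bs)
  }, 0)
  expect_true(all(ve >= 20 & ve <= 60))
})
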