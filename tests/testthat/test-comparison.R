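# Cheap synthetic posteriors: only map + free_energy are consumed downstream.
fake_post <- function(map_vals, F) {
  nm <- paste0("B:", c("SMA->SM1", "self-SM1"))
  list(map = stats::setNames(map_vals, nm), free_energy = F)
}

test_that("uniform evidence gives equal family exceedance summing to one", {
  space <- enumerate_model_space()
  ev <- matrix(0, 6, 180)
  colnames(ev) <- vapply(space, `[[`, character(1), "id")
  res <- rfx_bms(ev, space, level = "family", n_draws = 1e6, seed = 1)
  expect_equal(sum(res$exceedance), 1, tolerance = 1e-6)
  expect_true(all(abs(res$exceedance - 1 / 8) < 0.02))
  expect_equal(sum(res$expected_family_prob), 1, tolerance = 1e-6)
  # prior counts corrected for family size: uniform prior over families
  expect_true(all(abs(res$expected_family_prob - 1 / 8) < 1e-6))
})

test_that("degenerate evidence inputs are rejected", {
  ev <- matrix(0, 1, 8)
  expect_error(rfx_bms(ev, level = "model"), "2 subjects")
  ev2 <- matrix(c(NA, rep(0, 15)), 2, 8)
  expect_error(rfx_bms(ev2, level = "model"), "finite")
})

test_that("BMS is invariant to per-subject evidence shifts", {
  set.seed(4)
  ev <- matrix(rnorm(5 * 8, sd = 2), 5, 8)
  colnames(ev) <- paste0("m", 1:8)
  r1 <- rfx_bms(ev, level = "model", n_draws = 1e4, seed = 9)
  ev2 <- ev; ev2[3, ] <- ev2[3, ] + 50
  r2 <- rfx_bms(ev2, level = "model", n_draws = 1e4, seed = 9)
  expect_equal(r1$alpha, r2$alpha, tolerance = 1e-8)
  expect_equal(r1$exceedance, r2$exceedance)
})

test_that("overwhelming evidence concentrates family exceedance", {
  space <- reduced_model_space()
  win <- which(vapply(space, `[[`, character(1), "family_label") ==
                 "top_down+selfSM1")
  xp_at <- function(n_subj) {
    ev <- matrix(0, n_subj, 8)
    colnames(ev) <- vapply(space, `[[`, character(1), "id")
    ev[, win] <- 1000
    res <- rfx_bms(ev, space, level = "family", n_draws = 1e5, seed = 2)
    res$exceedance[["top_down+selfSM1"]]
  }
  # approaches 1 as the cohort grows
  expect_gt(xp_at(24), 0.99)
  expect_gt(xp_at(24), xp_at(6))
})

test_that("the decisiveness threshold is strict at 0.95", {
  mk <- function(top) {
    xp <- c(a = top, b = 1 - top)
    structure(list(exceedance = xp), class = "bms_result")
  }
  expect_false(decisive(mk(0.94))$decisive)
  expect_true(is.na(decisive(mk(0.94))$winner))
  d <- decisive(mk(0.96))
  expect_true(d$decisive)
  expect_equal(d$winner, "a")
})

test_that("BMA reduces to the winning model and to simple averages", {
  # one model carries all posterior probability
  posts <- list(list(fake_post(c(0.5, -0.3), 0),
                     fake_post(c(9, 9), -1000)))
  posts <- rep(posts, 2)
  ev <- matrix(c(0, -1000, 0, -1000), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("m1", "m2")))
  res <- bma(posts, ev, occam = 0.05)
  expect_equal(res$window, "m1")
  expect_equal(unname(res$subject_maps[1, ]), c(0.5, -0.3))
  # two models with equal weights average exactly
  posts2 <- rep(list(list(fake_post(c(1, 0), 0), fake_post(c(3, 2), 0))), 2)
  ev2 <- matrix(0, 2, 2, dimnames = list(NULL, c("m1", "m2")))
  res2 <- bma(posts2, ev2, occam = 0.05)
  expect_equal(unname(res2$subject_maps[1, ]), c(2, 1))
  expect_equal(rowSums(res2$weights), c(1, 1))
})

test_that("deterministic BMA equals the brute-force weighted mean", {
  set.seed(11)
  n_s <- 3; n_m <- 5
  ev <- matrix(rnorm(n_s * n_m), n_s, n_m,
               dimnames = list(NULL, paste0("m", 1:n_m)))
  maps <- array(rnorm(n_s * n_m * 2), c(n_s, n_m, 2))
  posts <- lapply(1:n_s, function(s)
    lapply(1:n_m, function(m) fake_post(maps[s, m, ], ev[s, m])))
  res <- bma(posts, ev, occam = 1e-9)  # window includes everything
  # oracle: direct softmax weights and weighted mean per subject
  for (s in 1:n_s) {
    w <- exp(ev[s, ] - max(ev[s, ])); w <- w / sum(w)
    expect_equal(unname(res$subject_maps[s, ]),
                 c(sum(w * maps[s, , 1]), sum(w * maps[s, , 2])),
                 tolerance = 1e-12)
  }
})

test_that("shrinking the Occam window only removes models", {
  set.seed(12)
  ev <- matrix(rnorm(4 * 6, sd = 1.5), 4, 6,
               dimnames = list(NULL, paste0("m", 1:6)))
  posts <- lapply(1:4, function(s)
    lapply(1:6, function(m) fake_post(rnorm(2), ev[s, m])))
  wins <- lapply(c(0.01, 0.05, 0.2, 0.8), function(oc)
    bma(posts, ev, occam = oc)$window)
  for (i in 2:length(wins))
    expect_true(all(wins[[i]] %in% wins[[i - 1]]))
})

test_that("averaged parameters stay within the hull of included models", {
  set.seed(13)
  ev <- matrix(rnorm(3 * 4), 3, 4, dimnames = list(NULL, paste0("m", 1:4)))
  posts <- lapply(1:3, function(s)
    lapply(1:4, function(m) fake_post(rnorm(2), ev[s, m])))
  res <- bma(posts, ev, occam = 1e-9)
  for (s in 1:3) {
    all_maps <- vapply(posts[[s]], `[[`, numeric(2), "map")
    expect_true(all(res$subject_maps[s, ] <= apply(all_maps, 1, max) + 1e-12))
    expect_true(all(res$subject_maps[s, ] >= apply(all_maps, 1, min) - 1e-12))
  }
})

test_that("sampling mode is seeded and approaches the deterministic mean", {
  set.seed(14)
  ev <- matrix(rnorm(3 * 4), 3, 4, dimnames = list(NULL, paste0("m", 1:4)))
  posts <- lapply(1:3, function(s)
    lapply(1:4, function(m) fake_post(rnorm(2), ev[s, m])))
  s1 <- bma(posts, ev, mode = "sampling", n_draws = 4000, seed = 7)
  s2 <- bma(posts, ev, mode = "sampling", n_draws = 4000, seed = 7)
  expect_identical(s1$subject_maps, s2$subject_maps)
  d <- bma(posts, ev)
  expect_equal(s1$subject_maps, d$subject_maps, tolerance = 0.1)
})
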