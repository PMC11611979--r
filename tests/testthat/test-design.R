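test_that("schedules satisfy every paradigm invariant across many seeds", {
  for (seed in 1:100) {
    first <- if (seed %% 2) "slowing" else "control"
    sch <- build_trial_schedule(first_condition = first, seed = seed)
    expect_silent(validate_schedule(sch))
    ev <- sch$events
    expect_lte(max(ev$onset + ev$duration), 900)
  }
})

test_that("a subject gets 16 trials per condition over two counterbalanced runs", {
  taps <- do.call(rbind, lapply(fix_schedules, function(s)
    s$events[s$events$event_type == "tap", ]))
  counts <- table(taps$condition)
  expect_equal(unname(counts[["slowing"]]), 16)
  expect_equal(unname(counts[["control"]]), 16)
  expect_equal(fix_schedules[[1]]$first_condition, "slowing")
  expect_equal(fix_schedules[[2]]$first_condition, "control")
})

test_that("degenerate jitter bounds give exact cue durations", {
  cfg <- design_config(jitter = c(2.5, 2.5))
  sch <- build_trial_schedule(cfg, seed = 3)
  cues <- sch$events[sch$events$event_type == "cue", ]
  expect_true(all(abs(cues$duration - 2.5) < 1e-12))
})

test_that("infeasible designs raise an explicit error", {
  cfg <- design_config(tap_slowing = 120)
  expect_error(build_trial_schedule(cfg, seed = 1), "infeasible")
})

test_that("canonical HRF is zero at onset, peaks near 5 s, and is resolution-stable", {
  expect_equal(canonical_hrf(0.1)[1], 0)
  h <- canonical_hrf(0.01)
  t <- seq(0, 32, by = 0.01)
  expect_equal(t[which.max(h)], 5, tolerance = 0.02)
  expect_true(all(is.finite(h)))
  # resampling oracle: coarse kernel equals fine kernel at shared points
  h1 <- canonical_hrf(0.1)
  h2 <- canonical_hrf(0.05)
  expect_lt(max(abs(h1 - h2[seq(1, length(h2), by = 2)])), 1e-3)
  expect_error(canonical_hrf(0), "dt")
})

test_that("orthogonalization matches the closed-form projection and is idempotent", {
  expect_equal(orthogonalize(c(1, 1), c(1, 0)), c(0, 1))
  v <- c(3, -2, 5)
  expect_equal(orthogonalize(v, v), rep(0, 3))
  expect_equal(orthogonalize(rep(0, 3), v), rep(0, 3))
  expect_error(orthogonalize(v, rep(0, 3)), "zero")
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    o1 <- orthogonalize(a, b)
    expect_equal(orthogonalize(o1, b), o1, tolerance = 1e-12)
    expect_lt(abs(sum(o1 * b)), 1e-10)
  }
})

test_that("parametric modulators have 6 (slowing) and 2 (control) staircase levels", {
  reg <- build_regressors(fix_schedule)
  ev <- fix_schedule$events
  grid <- reg$grid
  for (cond in c("slowing", "control")) {
    taps <- ev[ev$event_type == "tap" & ev$condition == cond, ]
    sel <- grid >= taps$onset[1] & grid < taps$onset[1] + taps$duration[1]
    lv <- unique(reg$microtime$tap_modulation[sel])
    expect_equal(length(lv), if (cond == "slowing") 6 else 2)
    expect_true(all(diff(reg$microtime$tap_modulation[sel]) >= 0))
  }
  # modulators are zero outside their parent epochs before convolution
  off <- reg$microtime$tapping == 0
  expect_true(all(reg$microtime$tap_modulation[off] == 0))
})

test_that("final modulator columns are orthogonal to their parents", {
  reg <- build_regressors(fix_schedule)
  r <- reg$regressors
  expect_equal(nrow(r), 360)
  expect_named(r, c("tapping", "tap_modulation", "recovery",
                    "recovery_modulation", "get_ready"))
  expect_lt(abs(sum(r$tap_modulation * r$tapping)), 1e-10)
  expect_lt(abs(sum(r$recovery_modulation * r$recovery)), 1e-10)
})

test_that("the staircase is identical across subjects (performance-independent)", {
  r1 <- build_regressors(build_trial_schedule(seed = 11))
  r2 <- build_regressors(build_trial_schedule(seed = 99))
  on1 <- r1$microtime$tap_modulation[r1$microtime$tap_modulation > 0]
  on2 <- r2$microtime$tap_modulation[r2$microtime$tap_modulation > 0]
  expect_equal(sort(unique(on1)), sort(unique(on2)))
})

test_that("driving input is a tapping boxcar totalling 640 s over two runs", {
  u <- fix_inputs$u
  expect_equal(sum(u[, "drive"]) * fix_inputs$dt, 640, tolerance = 1e-6)
  # zero outside tapping epochs; modulator maximal in the last 5 s bin
  expect_true(all(u[u[, "drive"] == 0, "mod"] == 0))
  ev <- fix_schedule$events
  tap1 <- ev[ev$event_type == "tap" & ev$condition == "slowing", ][1, ]
  grid <- seq(0, fix_schedule$run_duration - fix_inputs$dt / 2,
              by = fix_inputs$dt)
  sel <- grid >= tap1$onset & grid < tap1$onset + 30
  m <- fix_inputs$u[seq_along(grid), "mod"][sel]
  peak_times <- grid[sel][m == max(m)] - tap1$onset
  expect_true(all(peak_times >= 25))
})

test_that("speed binning and normalization follow the control-referenced rule", {
  rec <- expand.grid(subject = 1:2, trial = 1:4, bin = 1:3)
  rec$condition <- "slowing"
  ctrl <- expand.grid(subject = 1:2, trial = 5:8, bin = 1)
  ctrl$condition <- "control"
  rec <- rbind(rec, ctrl)
  rec$speed <- 4  # constant tapping
  out <- bin_and_normalize_speed(rec)
  expect_true(all(out$normalized_speed == 1))
  # per-subject control grand mean is 1 by construction
  for (s in 1:2)
    expect_equal(mean(out$normalized_speed[out$subject == s &
                                             out$condition == "control"]), 1)
  # linear 10 %/bin decline shows up as 1.0/0.9/0.8 relative to control
  dec <- rec
  dec$speed <- ifelse(dec$condition == "slowing",
                      4 * (1 - 0.1 * (dec$bin - 1)), 4)
  nd <- bin_and_normalize_speed(dec)
  means <- tapply(nd$normalized_speed[nd$condition == "slowing"],
                  nd$bin[nd$condition == "slowing"], mean)
  expect_equal(as.numeric(means), c(1, 0.9, 0.8), tolerance = 1e-12)
  # zero control tapping cannot be normalized
  bad <- rec; bad$speed[bad$condition == "control" & bad$subject == 1] <- 0
  expect_error(bin_and_normalize_speed(bad), "control")
  # a 30 s trial has exactly 3 bins, no more
  wrong <- rec; wrong$bin[1] <- 4
  expect_error(bin_and_normalize_speed(wrong), "bins")
})

test_that("the mixed model recovers a known slowing slope", {
  make_cohort <- function(slope, n = 24, seed = 1) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(n), function(s) {
      d <- expand.grid(trial = 1:16, bin = 1:3)
      d$subject <- s
      d$condition <- "slowing"
      subj_slope <- slope + rnorm(1, 0, 0.02)
      d$normalized_speed <- 1 + subj_slope * (d$bin - 1) + rnorm(nrow(d), 0, 0.1)
      d
    }))
  }
  fits <- lapply(1:10, function(r)
    fit_slowing_lmm(make_cohort(-0.1, seed = r)))
  slopes <- vapply(fits, `[[`, 0, "slope")
  expect_true(all(slopes > -0.13 & slopes < -0.07))
  expect_true(all(vapply(fits, `[[`, 0, "p") < 0.05))
  expect_true(all(vapply(fits, `[[`, TRUE, "slowing")))
})

test_that("the slowing test holds its size under the null", {
  set.seed(99)
  rejections <- vapply(1:120, function(r) {
    d <- do.call(rbind, lapply(1:12, function(s) {
      x <- expand.grid(trial = 1:8, bin = 1:3)
      x$subject <- s
      x$condition <- "slowing"
      x$normalized_speed <- 1 + rnorm(1, 0, 0.05) + rnorm(nrow(x), 0, 0.1)
      x
    }))
    fit <- suppressMessages(fit_slowing_lmm(d))
    fit$p < 0.05
  }, TRUE)
  expect_lt(abs(mean(rejections) - 0.05), 0.05)
})

test_that("a single subject degenerates to the OLS slope", {
  d <- expand.grid(trial = 1:4, bin = 1:3)
  d$subject <- 1
  d$condition <- "slowing"
  d$normalized_speed <- 1 - 0.1 * (d$bin - 1)
  # exactly linear data: lm warns about the perfect fit, which is intended
  fit <- suppressWarnings(fit_slowing_lmm(d))
  expect_equal(fit$slope, -0.1, tolerance = 1e-12)
  expect_true(fit$singular)
})
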