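#' Design constants for the tapping paradigm
#'
#' Returns the default experimental design configuration: two fMRI runs of
#' 360 volumes at TR = 2.5 s, each containing two blocks of 4 slowing
#' trials (30 s tapping) and 4 control trials (10 s tapping), every trial
#' preceded by a visual get-ready cue jittered uniformly between 2 and 3 s
#' and followed by a 30 s break, with a 20 s implicit baseline after each
#' block.
#'
#' @param tr repetition time in seconds.
#' @param n_volumes volumes acquired per run.
#' @param n_runs number of runs per subject.
#' @param tap_slowing,tap_control tapping durations (s) for the slowing and
#'   control conditions.
#' @param break_duration rest after every trial (s).
#' @param baseline_duration implicit baseline after each block (s).
#' @param jitter lower/upper bound (s) of the uniform get-ready jitter.
#' @param trials_per_condition_block trials of each condition within a block.
#' @param blocks_per_run condition blocks per run.
#' @param dt microtime resolution (s) used for regressor and input
#'   construction; must divide `tr`.
#' @return a list of class `design_config`.
#' @export
design_config <- function(tr = 2.5, n_volumes = 360, n_runs = 2,
                          tap_slowing = 30, tap_control = 10,
                          break_duration = 30, baseline_duration = 20,
                          jitter = c(2, 3),
                          trials_per_condition_block = 4,
                          blocks_per_run = 2,
                          dt = tr / 16) {
  stopifnot(tr > 0, dt > 0, n_volumes > 0, n_runs >= 1)
  if (abs(tr / dt - round(tr / dt)) > 1e-9)
    stop("dt must divide the TR")
  if (length(jitter) != 2L || jitter[1] > jitter[2] || jitter[1] < 0)
    stop("jitter must be c(lower, upper) with 0 <= lower <= upper")
  structure(list(tr = tr, n_volumes = n_volumes, n_runs = n_runs,
                 tap_slowing = tap_slowing, tap_control = tap_control,
                 break_duration = break_duration,
                 baseline_duration = baseline_duration,
                 jitter = jitter,
                 trials_per_condition_block = trials_per_condition_block,
                 blocks_per_run = blocks_per_run,
                 dt = dt),
            class = "design_config")
}

#' Build the trial schedule for one run
#'
#' Lays out get-ready cues, tapping epochs, breaks and block baselines on a
#' continuous timeline.  A block is 4 trials of one condition followed by 4
#' of the other; `first_condition` fixes which condition opens the first
#' block, and the second block within the run starts with the opposite
#' condition.
#'
#' @param config a [design_config()].
#' @param first_condition `"slowing"` or `"control"`.
#' @param run_index run number (recorded in the output).
#' @param seed integer seed for the cue jitter.
#' @return an object of class `trial_schedule`: a list with an `events`
#'   data frame (onset, duration, event_type, condition, trial, block),
#'   the run index, and the design constants.
#' @export
build_trial_schedule <- function(config = design_config(),
                                 first_condition = "slowing",
                                 run_index = 1L, seed = 1L) {
  stopifnot(inherits(config, "design_config"))
  first_condition <- match.arg(first_condition, c("slowing", "control"))
  run_duration <- config$n_volumes * config$tr

  n_per_block <- 2L * config$trials_per_condition_block
  n_trials <- n_per_block * config$blocks_per_run
  set.seed(as.integer(seed))
  jit <- stats::runif(n_trials, config$jitter[1], config$jitter[2])

  rows <- list()
  t <- 0
  trial <- 0L
  other <- function(cond) if (cond == "slowing") "control" else "slowing"
  for (block in seq_len(config$blocks_per_run)) {
    block_start <- if (block %% 2L == 1L) first_condition else other(first_condition)
    conds <- rep(c(block_start, other(block_start)),
                 each = config$trials_per_condition_block)
    for (cond in conds) {
      trial <- trial + 1L
      tap_dur <- if (cond == "slowing") config$tap_slowing else config$tap_control
      rows[[length(rows) + 1L]] <- data.frame(
        onset = t, duration = jit[trial], event_type = "cue",
        condition = cond, trial = trial, block = block)
      t <- t + jit[trial]
      rows[[length(rows) + 1L]] <- data.frame(
        onset = t, duration = tap_dur, event_type = "tap",
        condition = cond, trial = trial, block = block)
      t <- t + tap_dur
      rows[[length(rows) + 1L]] <- data.frame(
        onset = t, duration = config$break_duration, event_type = "break",
        condition = cond, trial = trial, block = block)
      t <- t + config$break_duration
    }
    rows[[length(rows) + 1L]] <- data.frame(
      onset = t, duration = config$baseline_duration, event_type = "baseline",
      condition = NA_character_, trial = NA_integer_, block = block)
    t <- t + config$baseline_duration
  }
  events <- do.call(rbind, rows)
  if (t > run_duration)
    stop(sprintf(
      "infeasible schedule: events end at %.1f s but the run is %.0f s",
      t, run_duration))
  out <- structure(list(events = events, run_index = as.integer(run_index),
                        tr = config$tr, n_volumes = config$n_volumes,
                        dt = config$dt, run_duration = run_duration,
                        first_condition = first_condition, seed = seed),
                   class = "trial_schedule")
  validate_schedule(out)
  out
}

#' Validate a trial schedule against the paradigm's invariants
#'
#' Checks non-overlap, strictly increasing onsets, condition-specific
#' tapping durations, the 30 s break after every trial, cue durations
#' within the jitter bounds, the 4+4 block structure, the 20 s baseline
#' after each block, and that the last event ends within the run.
#'
#' @param schedule a `trial_schedule`.
#' @return the schedule, invisibly; errors describe the violated invariant.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  ev <- schedule$events
  if (any(diff(ev$onset) <= 0)) stop("event onsets must be strictly increasing")
  if (any(abs(ev$onset[-1] - (ev$onset[-nrow(ev)] + ev$duration[-nrow(ev)])) > 1e-9))
    stop("events overlap or leave gaps")
  taps <- ev[ev$event_type == "tap", ]
  ok_dur <- ifelse(taps$condition == "slowing", 30, 10)
  if (any(abs(taps$duration - ok_dur) > 1e-9))
    stop("tapping durations must be 30 s (slowing) / 10 s (control)")
  cues <- ev[ev$event_type == "cue", ]
  if (any(cues$duration < 2 - 1e-9 | cues$duration > 3 + 1e-9))
    stop("cue durations must lie in [2, 3] s")
  brk <- ev[ev$event_type == "break", ]
  if (nrow(brk) != nrow(taps) || any(abs(brk$duration - 30) > 1e-9))
    stop("every trial must be followed by a 30 s break")
  bas <- ev[ev$event_type == "baseline", ]
  if (any(abs(bas$duration - 20) > 1e-9))
    stop("each block must be followed by a 20 s baseline")
  for (b in unique(taps$block)) {
    tb <- taps[taps$block == b, ]
    counts <- table(tb$condition)
    if (!(length(counts) == 2L && all(counts == 4L)))
      stop("each block must contain 4 slowing + 4 control trials")
    r <- rle(tb$condition)$lengths
    if (!identical(as.integer(r), c(4L, 4L)))
      stop("within a block the two conditions must form contiguous 4-trial sets")
  }
  last_end <- ev$onset[nrow(ev)] + ev$duration[nrow(ev)]
  if (last_end > schedule$run_duration + 1e-9)
    stop("schedule exceeds the run duration")
  invisible(schedule)
}

#' Build both runs of a subject's schedule
#'
#' Run 1 starts with `first_condition`; run 2 is counterbalanced (starts
#' with the opposite condition), matching the alternating/counterbalanced
#' assignment across subjects.
#'
#' @inheritParams build_trial_schedule
#' @return list of `trial_schedule`, one per run.
#' @export
build_subject_schedule <- function(config = design_config(),
                                   first_condition = "slowing", seed = 1L) {
  other <- if (first_condition == "slowing") "control" else "slowing"
  firsts <- rep(c(first_condition, other), length.out = config$n_runs)
  lapply(seq_len(config$n_runs), function(r)
    build_trial_schedule(config, firsts[r], run_index = r,
                         seed = as.integer(seed) + 1000L * r))
}

#' Canonical double-gamma hemodynamic response function
#'
#' The widely used canonical parameterization: response gamma density with
#' shape 6 and rate 1 (peak at about 5 s), minus an undershoot gamma
#' density with shape 16 and rate 1 scaled by 1/6, evaluated on a grid of
#' step `dt` over `duration` seconds.  The kernel is zero at t = 0.
#'
#' @param dt sampling step in seconds (> 0).
#' @param duration kernel length in seconds (default 32).
#' @param peak_delay,undershoot_delay gamma shape parameters (dispersion
#'   fixed at 1 s).
#' @param ratio peak:undershoot amplitude ratio.
#' @return numeric vector of kernel values.
#' @export
canonical_hrf <- function(dt, duration = 32, peak_delay = 6,
                          undershoot_delay = 16, ratio = 6) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be > 0")
  if (duration < 32) stop("kernel length must be at least 32 s")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    stats::dgamma(t, shape = undershoot_delay, rate = 1) / ratio
  h
}

#' Residualize one regressor against another
#'
#' Removes from `target` its least-squares projection onto `base`, so the
#' result is orthogonal to `base`.  This is the serial orthogonalization
#' applied to parametric modulators with respect to their parent regressor.
#'
#' @param target,base numeric vectors of equal length; `base` must not be
#'   all zero.
#' @return `target - base * <target, base> / <base, base>`.
#' @export
orthogonalize <- function(target, base) {
  if (length(target) != length(base)) stop("vectors must have equal length")
  bb <- sum(base^2)
  if (bb == 0) stop("cannot orthogonalize against an all-zero base")
  target - base * (sum(target * base) / bb)
}

## Microtime indicator/staircase helpers.  The parametric staircase rises in
## 5 s bins; levels are bin / 6 so the slowing condition spans {1/6, ..., 1}
## (6 levels) and the control condition {1/6, 2/6} (2 levels) with the same
## slope per bin.  The increase is identical for all subjects by design.
.microtime_grid <- function(schedule) {
  seq(0, schedule$run_duration - schedule$dt / 2, by = schedule$dt)
}

.boxcar <- function(grid, onsets, durations) {
  x <- numeric(length(grid))
  for (i in seq_along(onsets))
    x[grid >= onsets[i] - 1e-9 & grid < onsets[i] + durations[i] - 1e-9] <- 1
  x
}

.staircase <- function(grid, onsets, durations, bin_width = 5, denom = 6) {
  x <- numeric(length(grid))
  for (i in seq_along(onsets)) {
    sel <- grid >= onsets[i] - 1e-9 & grid < onsets[i] + durations[i] - 1e-9
    bin <- floor((grid[sel] - onsets[i]) / bin_width) + 1
    x[sel] <- bin / denom
  }
  x
}

#' GLM-style regressors for one run
#'
#' Builds the four regressors of interest (tapping, parametric modulation
#' of tapping, recovery, parametric modulation of recovery) plus the
#' get-ready regressor: microtime boxcars/staircases, convolution with the
#' canonical HRF, and down-sampling to one value per volume.  The
#' parametric modulators are residualized against their parent regressor;
#' by default this happens after convolution on the TR grid (so the final
#' design columns are exactly orthogonal), `ortho = "microtime"` applies it
#' to the raw staircase before convolution instead, and `ortho = "none"`
#' skips it.
#'
#' @param schedule a `trial_schedule`.
#' @param dt microtime resolution; defaults to the schedule's.
#' @param ortho orthogonalization stage: `"convolved"` (default),
#'   `"microtime"` or `"none"`.
#' @return an object of class `regressor_set`: `regressors` (360-row data
#'   frame), `microtime` (raw pre-convolution columns), `dt`, `tr`.
#' @export
build_regressors <- function(schedule, dt = schedule$dt,
                             ortho = c("convolved", "microtime", "none")) {
  validate_schedule(schedule)
  ortho <- match.arg(ortho)
  sch <- schedule
  sch$dt <- dt
  grid <- .microtime_grid(sch)
  ev <- schedule$events
  taps <- ev[ev$event_type == "tap", ]
  brks <- ev[ev$event_type == "break", ]
  cues <- ev[ev$event_type == "cue", ]
  slow_breaks <- brks[brks$condition == "slowing", ]

  raw <- data.frame(
    tapping = .boxcar(grid, taps$onset, taps$duration),
    tap_modulation = .staircase(grid, taps$onset, taps$duration),
    recovery = .boxcar(grid, brks$onset, brks$duration),
    recovery_modulation = .staircase(grid, slow_breaks$onset,
                                     slow_breaks$duration),
    get_ready = .boxcar(grid, cues$onset, cues$duration))

  if (ortho == "microtime") {
    raw_o <- raw
    raw_o$tap_modulation <- orthogonalize(raw$tap_modulation, raw$tapping)
    raw_o$recovery_modulation <- orthogonalize(raw$recovery_modulation,
                                               raw$recovery)
  } else raw_o <- raw

  h <- canonical_hrf(dt)
  conv_one <- function(x) {
    y <- stats::convolve(x, rev(h), type = "open")[seq_along(x)] * dt
    y
  }
  conv <- as.data.frame(lapply(raw_o, conv_one))
  vol_idx <- round(seq(0, schedule$n_volumes - 1) * schedule$tr / dt) + 1L
  reg <- conv[vol_idx, , drop = FALSE]
  rownames(reg) <- NULL

  if (ortho == "convolved") {
    reg$tap_modulation <- orthogonalize(reg$tap_modulation, reg$tapping)
    reg$recovery_modulation <- orthogonalize(reg$recovery_modulation,
                                             reg$recovery)
  }
  structure(list(regressors = reg, microtime = raw, grid = grid,
                 dt = dt, tr = schedule$tr, ortho = ortho),
            class = "regressor_set")
}

#' Driving and modulatory DCM inputs
#'
#' The driving input is an unconvolved boxcar spanning every tapping epoch
#' (the constant input from upstream areas, on during task and off at
#' rest).  The modulatory input encodes motor slowing as the same
#' within-epoch linear staircase used for the parametric tapping modulator
#' (not orthogonalized, not mean-centred unless requested).
#'
#' @param schedules a `trial_schedule` or list of them (runs are
#'   concatenated; state resets at run boundaries are handled downstream).
#' @param dt microtime resolution.
#' @param centre_modulation subtract the within-task mean from the
#'   modulatory input (default FALSE, preserving the linear-increase
#'   semantics).
#' @param session_constant_drive if TRUE the driving input is 1 throughout
#'   the session instead of a tapping-epoch boxcar.
#' @return an object of class `input_set`: matrix `u` (microtime x 2, columns
#'   `drive`, `mod`), `dt`, `run_starts` (row indices), `n_per_run`.
#' @export
dcm_inputs <- function(schedules, dt = NULL, centre_modulation = FALSE,
                       session_constant_drive = FALSE) {
  if (inherits(schedules, "trial_schedule")) schedules <- list(schedules)
  if (is.null(dt)) dt <- schedules[[1]]$dt
  per_run <- lapply(schedules, function(schedule) {
    validate_schedule(schedule)
    sch <- schedule; sch$dt <- dt
    grid <- .microtime_grid(sch)
    ev <- schedule$events
    taps <- ev[ev$event_type == "tap", ]
    drive <- if (session_constant_drive) rep(1, length(grid))
             else .boxcar(grid, taps$onset, taps$duration)
    mod <- .staircase(grid, taps$onset, taps$duration)
    cbind(drive = drive, mod = mod)
  })
  n_per_run <- vapply(per_run, nrow, integer(1))
  u <- do.call(rbind, per_run)
  if (centre_modulation) {
    on <- u[, "mod"] > 0
    u[on, "mod"] <- u[on, "mod"] - mean(u[on, "mod"])
  }
  structure(list(u = u, dt = dt,
                 run_starts = cumsum(c(1L, n_per_run[-length(n_per_run)])),
                 n_per_run = n_per_run),
            class = "input_set")
}

#' Bin tapping data and normalize speed to the control condition
#'
#' Tapping intervals are divided into 10 s bins (3 per slowing trial, 1 per
#' control trial) and each subject's bin speeds are divided by that
#' subject's own control-condition mean, so the normalized control grand
#' mean is 1 per subject by construction.
#'
#' @param record data frame with columns `subject`, `trial`, `condition`
#'   (`"slowing"`/`"control"`), `bin` (1-based 10 s bin index within the
#'   trial) and either `n_taps` (taps in that bin) or `speed` (taps/s).
#' @return data frame `subject, trial, condition, bin, speed,
#'   normalized_speed`.
#' @export
bin_and_normalize_speed <- function(record) {
  need <- c("subject", "trial", "condition", "bin")
  if (!all(need %in% names(record)))
    stop("record needs columns subject, trial, condition, bin")
  if (!("speed" %in% names(record))) {
    if (!("n_taps" %in% names(record)))
      stop("record needs a speed or n_taps column")
    record$speed <- record$n_taps / 10
  }
  bad_bins <- (record$condition == "slowing" & !(record$bin %in% 1:3)) |
    (record$condition == "control" & record$bin != 1L)
  if (any(bad_bins))
    stop("slowing trials have 3 bins of 10 s, control trials 1")
  out <- do.call(rbind, lapply(split(record, record$subject), function(d) {
    ctrl <- d$speed[d$condition == "control"]
    if (length(ctrl) == 0 || mean(ctrl) <= 0)
      stop(sprintf("subject %s has no control-condition tapping to normalize by",
                   d$subject[1]))
    d$normalized_speed <- d$speed / mean(ctrl)
    d
  }))
  rownames(out) <- NULL
  out
}

#' Linear mixed-effects test for motor slowing
#'
#' Fits normalized speed in the slowing condition against time bin with a
#' random intercept per participant (REML), and reports the fixed-effect
#' slope for time with its standard error and p-value.  Motor slowing is a
#' significantly negative time effect.  With a single subject the random
#' effect is degenerate and an ordinary least-squares fit is returned.
#'
#' @param normalized output of [bin_and_normalize_speed()].
#' @param condition which condition's bins enter the model.
#' @return list with `slope`, `se`, `p`, `df`, `singular`, `slowing`
#'   (logical: significant negative slope at 0.05) and the fitted `model`.
#' @export
fit_slowing_lmm <- function(normalized, condition = "slowing") {
  d <- normalized[normalized$condition == condition, ]
  if (length(unique(d$bin)) < 2) stop("need at least 2 time bins")
  d$subject <- factor(d$subject)
  if (nlevels(d$subject) < 2) {
    fit <- stats::lm(normalized_speed ~ bin, data = d)
    co <- summary(fit)$coefficients
    return(list(slope = co["bin", 1], se = co["bin", 2], p = co["bin", 4],
                df = fit$df.residual, singular = TRUE,
                slowing = co["bin", 1] < 0 && co["bin", 4] < 0.05,
                model = fit))
  }
  fit <- lmerTest::lmer(normalized_speed ~ bin + (1 | subject), data = d,
                        REML = TRUE)
  co <- stats::coef(summary(fit))
  list(slope = co["bin", "Estimate"], se = co["bin", "Std. Error"],
       p = co["bin", "Pr(>|t|)"], df = co["bin", "df"],
       singular = lme4::isSingular(fit),
       slowing = co["bin", "Estimate"] < 0 && co["bin", "Pr(>|t|)"] < 0.05,
       model = fit)
}
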