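#' Ground-truth configuration for a synthetic cohort
#'
#' Defines the generating model and population distributions from which
#' synthetic subjects are drawn.  Defaults emulate the study conditions:
#' 24 subjects, 2 runs of 360 volumes at TR 2.5 s, SNR 1, a generating
#' model from the top-down family with SM1 self-modulation (driving input
#' to both premotor areas), a negative SM1 self-modulation of -0.4 (self-
#' inhibition is released as slowing builds up), and tapping speeds whose
#' within-trial decline is linearly linked to the subject's true
#' modulatory parameters.
#'
#' @param spec generating `model_spec`.
#' @param b_true,c_true named true population means for the enabled
#'   modulatory and driving parameters.
#' @param a_true 3x3 endogenous log-scaling means (default 0).
#' @param sd_between between-subject SD applied to every A/B/C parameter.
#' @param snr signal-to-noise ratio of the measurement noise.
#' @param n_subjects cohort size.
#' @param design a [design_config()].
#' @param control_speed_mean,control_speed_sd population distribution of
#'   control-condition tapping speed (taps/s).
#' @param link_intercept,link_weights,slope_noise_sd behavioural link: the
#'   per-subject normalized slowing slope per 10 s bin is
#'   `link_intercept + sum(link_weights * true B) + noise`.  The default
#'   weight of 0.25 on `B:self-SM1` gives a population-mean slope of
#'   -0.1 per bin.
#' @param bin_noise_sd within-subject tapping noise per bin (taps/s).
#' @param seed master seed; everything else derives from it.
#' @return list of class `ground_truth_config`.
#' @export
ground_truth_config <- function(
    spec = model_spec(c("SMA->SM1", "PMd->SM1", "self-SM1"),
                      c("PMd", "SMA")),
    b_true = c("B:SMA->SM1" = 0.3, "B:PMd->SM1" = 0.3, "B:self-SM1" = -0.4),
    c_true = c("C:PMd" = 0.4, "C:SMA" = 0.4),
    a_true = matrix(0, 3, 3),
    sd_between = 0.1, snr = 1, n_subjects = 24,
    design = design_config(),
    control_speed_mean = 5, control_speed_sd = 0.5,
    link_intercept = 0,
    link_weights = c("B:self-SM1" = 0.25),
    slope_noise_sd = 0.02, bin_noise_sd = 0.15,
    seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), n_subjects >= 2, snr > 0)
  miss_b <- setdiff(paste0("B:", spec$b_mask), names(b_true))
  if (length(miss_b))
    stop("b_true missing entries for: ", paste(miss_b, collapse = ", "))
  structure(list(spec = spec, b_true = b_true, c_true = c_true,
                 a_true = a_true, sd_between = sd_between, snr = snr,
                 n_subjects = n_subjects, design = design,
                 control_speed_mean = control_speed_mean,
                 control_speed_sd = control_speed_sd,
                 link_intercept = link_intercept,
                 link_weights = link_weights,
                 slope_noise_sd = slope_noise_sd,
                 bin_noise_sd = bin_noise_sd, seed = as.integer(seed)),
            class = "ground_truth_config")
}

#' Generate a complete synthetic cohort
#'
#' Per subject: draw A/B/C parameters from the configured population
#' distributions, build a seeded trial schedule (starting condition
#' alternating across subjects, second run counterbalanced), integrate the
#' two-state model to region BOLD at the scan TR with measurement noise at
#' the configured SNR, and produce per-trial, per-bin tapping speeds whose
#' within-trial decline follows the behavioural link.  Fully reproducible
#' from the master seed.
#'
#' @param config a [ground_truth_config()].
#' @return object of class `synthetic_cohort`: `config` and a list
#'   `subjects`, each with `id`, `schedules`, `inputs`, `bold`,
#'   `behaviour` (trial/bin speed table), `true_params` (named vector) and
#'   `true_slope`.
#' @export
generate_cohort <- function(config = ground_truth_config()) {
  stopifnot(inherits(config, "ground_truth_config"))
  template <- spec_param_template(config$spec)
  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    seed_s <- config$seed + 7919L * s
    set.seed(seed_s)
    truth <- stats::setNames(numeric(nrow(template)), template$name)
    for (k in seq_len(nrow(template))) {
      nm <- template$name[k]
      blk <- template$block[k]
      if (blk == "tau") next
      mu <- if (nm %in% names(config$b_true)) config$b_true[[nm]]
        else if (nm %in% names(config$c_true)) config$c_true[[nm]]
        else if (blk == "A") {
          ij <- .connection_index(template$connection[k])
          config$a_true[ij[1], ij[2]]
        } else 0
      enabled <- template$enabled[k] || blk == "A"
      truth[nm] <- if (enabled) stats::rnorm(1, mu, config$sd_between) else 0
    }
    ctrl_speed <- abs(stats::rnorm(1, config$control_speed_mean,
                                   config$control_speed_sd))
    lw <- config$link_weights
    slope <- config$link_intercept +
      sum(lw * truth[names(lw)]) +
      stats::rnorm(1, 0, config$slope_noise_sd)

    first <- if (s %% 2L == 1L) "slowing" else "control"
    schedules <- build_subject_schedule(config$design, first, seed = seed_s)
    inputs <- dcm_inputs(schedules)
    params <- .theta_to_params(truth[template$name], template,
                               twostate_constants())
    bold <- simulate_bold(params, inputs, tr = config$design$tr,
                          n_volumes = config$design$n_volumes,
                          snr = config$snr, seed = seed_s + 1L)

    beh <- list()
    for (r in seq_along(schedules)) {
      ev <- schedules[[r]]$events
      taps <- ev[ev$event_type == "tap", ]
      for (i in seq_len(nrow(taps))) {
        nb <- if (taps$condition[i] == "slowing") 3L else 1L
        for (b in seq_len(nb)) {
          mu_b <- if (taps$condition[i] == "slowing")
            ctrl_speed * (1 + slope * (b - 1)) else ctrl_speed
          beh[[length(beh) + 1L]] <- data.frame(
            subject = s, run = r, trial = taps$trial[i],
            condition = taps$condition[i], bin = b,
            speed = max(0, mu_b + stats::rnorm(1, 0, config$bin_noise_sd)))
        }
      }
    }
    subjects[[s]] <- list(id = s, schedules = schedules, inputs = inputs,
                          bold = bold, behaviour = do.call(rbind, beh),
                          true_params = truth, true_slope = slope,
                          seed = seed_s)
  }
  structure(list(config = config, subjects = subjects),
            class = "synthetic_cohort")
}

#' Combined behavioural table of a cohort
#'
#' @param cohort a `synthetic_cohort`.
#' @return one data frame over all subjects (columns as in each subject's
#'   `behaviour`).
#' @export
cohort_behaviour <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, `[[`, "behaviour"))
}

#' Per-subject behavioural slowing scores
#'
#' The per-subject OLS slope of normalized speed over 10 s bins within the
#' slowing condition — the scalar behavioural summary entering the
#' brain-behaviour regression.
#'
#' @param normalized output of [bin_and_normalize_speed()].
#' @return named numeric vector, one slope per subject.
#' @export
slowing_scores <- function(normalized) {
  d <- normalized[normalized$condition == "slowing", ]
  vapply(split(d, d$subject), function(x)
    unname(stats::coef(stats::lm(normalized_speed ~ bin, data = x))["bin"]),
    0)
}

#' True-versus-recovered parameter report
#'
#' Per-parameter recovery summary after running the pipeline on a
#' synthetic cohort: bias, RMSE, and — for parameters whose true magnitude
#' is at least `sign_threshold` — the sign-agreement rate.
#'
#' @param cohort a `synthetic_cohort`.
#' @param recovered subjects x parameters matrix of recovered estimates
#'   (e.g. `bma_result$subject_maps`), columns named like the parameter
#'   template.
#' @param sign_threshold minimum |truth| for a sign-agreement claim.
#' @return data frame: parameter, mean truth, bias, RMSE, sign agreement
#'   (NA below threshold).
#' @export
ground_truth_report <- function(cohort, recovered, sign_threshold = 0.2) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  recovered <- as.matrix(recovered)
  truth <- t(vapply(cohort$subjects, `[[`,
                    cohort$subjects[[1]]$true_params, "true_params"))
  common <- intersect(colnames(truth), colnames(recovered))
  if (length(common) == 0) stop("no common parameters between truth and recovery")
  if (nrow(recovered) != nrow(truth))
    stop("recovered matrix must have one row per subject")
  rows <- lapply(common, function(pn) {
    tr <- truth[, pn]; rc <- recovered[, pn]
    err <- rc - tr
    strong <- abs(tr) >= sign_threshold
    data.frame(parameter = pn, true_mean = mean(tr), bias = mean(err),
               rmse = sqrt(mean(err^2)),
               sign_agreement = if (any(strong))
                 mean(sign(rc[strong]) == sign(tr[strong])) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
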