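#' Write/read a trial schedule as a BIDS-style events table
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type` (the event
#' type), `condition`, `trial`, `block`; header line included.
#'
#' @param schedule a `trial_schedule`.
#' @param path file path (.tsv).
#' @return the path, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  ev <- schedule$events
  out <- data.frame(onset = ev$onset, duration = ev$duration,
                    trial_type = ev$event_type, condition = ev$condition,
                    trial = ev$trial, block = ev$block)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @param tr,n_volumes,run_index scan constants to attach on read.
#' @export
read_events_tsv <- function(path, tr = 2.5, n_volumes = 360, run_index = 1L) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(ev)[names(ev) == "trial_type"] <- "event_type"
  structure(list(events = ev, run_index = run_index, tr = tr,
                 n_volumes = n_volumes, dt = tr / 16,
                 run_duration = n_volumes * tr,
                 first_condition = ev$condition[1], seed = NA),
            class = "trial_schedule")
}

#' Write/read region BOLD series as TSV with a JSON sidecar
#'
#' One column per region, one row per volume (runs stacked); the sidecar
#' records TR, volumes per run, run count, SNR and seed so the series can
#' be regenerated or re-aligned exactly.
#'
#' @param series a `bold_series`.
#' @param path file path (.tsv); the sidecar is written at `path` with
#'   extension replaced by `.json`.
#' @return the path, invisibly.
#' @export
write_series_tsv <- function(series, path) {
  utils::write.table(as.data.frame(series$y), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(list(tr = series$tr, n_volumes = series$n_volumes,
                            n_runs = series$n_runs, snr = series$snr,
                            seed = series$seed),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  y <- as.matrix(utils::read.delim(path, check.names = FALSE))
  side <- sub("\\.tsv$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  structure(list(y = y, tr = meta$tr, n_volumes = meta$n_volumes,
                 n_runs = meta$n_runs,
                 run_starts = seq(1L, by = meta$n_volumes,
                                  length.out = meta$n_runs),
                 snr = meta$snr, seed = meta$seed),
            class = "bold_series")
}

#' Write/read a subjects x models evidence matrix as TSV
#'
#' @param evidence matrix with model-id column names.
#' @param path file path.
#' @return the path (write) or the matrix (read).
#' @export
write_evidence_tsv <- function(evidence, path) {
  utils::write.table(as.data.frame(evidence, check.names = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evidence_tsv
#' @export
read_evidence_tsv <- function(path) {
  as.matrix(utils::read.delim(path, check.names = FALSE))
}

#' Reduced representative model space
#'
#' One model per family (8 models): the two-connection top-down and
#' bottom-up cores, the SM1<->SMA selective core, and the null core, each
#' with driving input to both premotor areas and no premotor-interaction
#' modulation, crossed with the SM1 self-modulation factor.  Used to keep
#' recovery studies tractable while spanning every family.
#'
#' @return list of 8 `model_spec`.
#' @export
reduced_model_space <- function() {
  cores <- list(top_down = c("SMA->SM1", "PMd->SM1"),
                bottom_up = c("SM1->SMA", "SM1->PMd"),
                selective = c("SMA->SM1", "SM1->SMA", "self-SMA"),
                null = character(0))
  out <- list()
  for (cn in names(cores))
    for (self in c(FALSE, TRUE))
      out[[length(out) + 1L]] <-
        model_spec(c(cores[[cn]], if (self) "self-SM1"), c("PMd", "SMA"))
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis; writable to and
#' readable from YAML.
#'
#' @param out_dir output directory, or `NULL` to keep results in memory.
#' @param n_subjects cohort size.
#' @param snr measurement SNR of the synthetic cohort.
#' @param space `"full"` (180 models), `"reduced"` (8 representatives) or
#'   a list of `model_spec`.
#' @param seed master seed.
#' @param threshold family decisiveness threshold on the exceedance
#'   probability.
#' @param occam Occam's-window posterior-odds cutoff.
#' @param n_draws Monte-Carlo draws for exceedance probabilities.
#' @param max_iter,tol inversion settings.
#' @param p_enter,p_remove stepwise-regression thresholds.
#' @param design a [design_config()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = NULL, n_subjects = 24, snr = 1,
                            space = "full", seed = 1L,
                            threshold = 0.95, occam = 0.05, n_draws = 1e6,
                            max_iter = 64, tol = 0.01,
                            p_enter = 0.05, p_remove = 0.10,
                            design = design_config()) {
  for (v in c(threshold, occam))
    if (v <= 0 || v >= 1) stop("thresholds must lie in (0, 1)")
  structure(list(out_dir = out_dir, n_subjects = n_subjects, snr = snr,
                 space = space, seed = as.integer(seed),
                 threshold = threshold, occam = occam, n_draws = n_draws,
                 max_iter = max_iter, tol = tol,
                 p_enter = p_enter, p_remove = p_remove, design = design),
            class = "pipeline_config")
}

#' Write/read a pipeline configuration as YAML
#'
#' The model space is stored by name (`"full"`/`"reduced"`) or as
#' b/c-mask lists.
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return the path (write) / the config (read).
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  x$design <- unclass(x$design)
  if (is.list(x$space))
    x$space <- lapply(x$space, function(m)
      list(b_mask = m$b_mask, c_mask = m$c_mask))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.list(x$space))
    x$space <- lapply(x$space, function(m) model_spec(m$b_mask, m$c_mask))
  x$design <- do.call(design_config, x$design[setdiff(names(x$design),
                                                      NULL)])
  do.call(pipeline_config, x)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in order: cohort generation, behavioural binning /
#' normalization and the mixed-model slowing test, Bayesian inversion of
#' every model for every subject, family-level random-effects BMS, the
#' decisiveness check, Bayesian model averaging (over the whole space when
#' no family is decisive — over the winning family otherwise),
#' Bonferroni-corrected group t-tests on the averaged modulatory
#' parameters, and the stepwise brain-behaviour regression.  When
#' `config$out_dir` is set, every stage's outputs are written (TSV/JSON)
#' and a manifest with per-file MD5 hashes, seeds and the branch taken is
#' saved; reruns with the same config reproduce identical hashes.
#'
#' @param config a [pipeline_config()].
#' @return list (class `pipeline_result`) with `cohort`, `behaviour`
#'   (normalized table, LMM fit, slowing scores), `space`, `posteriors`,
#'   `evidence`, `bms`, `decision`, `bma`, `ttests`, `stepwise`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  space <- if (is.character(config$space)) {
    switch(config$space,
           full = enumerate_model_space(),
           reduced = reduced_model_space(),
           stop("unknown space name: ", config$space))
  } else config$space

  gt <- ground_truth_config(n_subjects = config$n_subjects,
                            snr = config$snr, design = config$design,
                            seed = config$seed)
  cohort <- generate_cohort(gt)

  norm <- bin_and_normalize_speed(cohort_behaviour(cohort))
  lmm <- fit_slowing_lmm(norm)
  scores <- slowing_scores(norm)

  settings <- invert_settings(max_iter = config$max_iter, tol = config$tol)
  posteriors <- lapply(cohort$subjects, function(subj)
    lapply(space, function(m)
      invert(subj$bold, subj$inputs, m, settings = settings)))

  evidence <- evidence_matrix(posteriors, space)
  bms_fam <- rfx_bms(evidence, space, level = "family",
                     n_draws = config$n_draws, seed = config$seed)
  dec <- decisive(bms_fam, config$threshold)

  if (dec$decisive) {
    fam <- vapply(space, `[[`, character(1), "family_label")
    keep <- which(fam == dec$winner)
    branch <- sprintf("BMA within winning family (%s)", dec$winner)
    bma_res <- bma(lapply(posteriors, `[`, keep),
                   evidence[, keep, drop = FALSE],
                   bms = NULL, occam = config$occam, seed = config$seed)
  } else {
    branch <- "BMA over whole space"
    bma_res <- bma(posteriors, evidence, bms = bms_fam,
                   occam = config$occam, seed = config$seed)
  }

  tt <- map_group_ttests(bma_res)
  sel_cols <- tt$parameter
  sw <- stepwise_regression(scores, bma_res$subject_maps[, sel_cols,
                                                         drop = FALSE],
                            p_enter = config$p_enter,
                            p_remove = config$p_remove)

  manifest <- list(seed = config$seed, n_subjects = config$n_subjects,
                   n_models = length(space), branch = branch,
                   slowing_slope = lmm$slope, slowing_p = lmm$p)
  res <- structure(list(cohort = cohort,
                        behaviour = list(normalized = norm, lmm = lmm,
                                         scores = scores),
                        space = space, posteriors = posteriors,
                        evidence = evidence, bms = bms_fam, decision = dec,
                        bma = bma_res, ttests = tt, stepwise = sw,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) res$manifest <- .write_pipeline(res, config)
  res
}

.write_pipeline <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir
  paths <- character(0)
  for (subj in res$cohort$subjects) {
    for (r in seq_along(subj$schedules))
      paths <- c(paths, write_events_tsv(
        subj$schedules[[r]],
        file.path(od, sprintf("sub-%02d_run-%d_events.tsv", subj$id, r))))
    p <- file.path(od, sprintf("sub-%02d_bold.tsv", subj$id))
    write_series_tsv(subj$bold, p)
    paths <- c(paths, p, sub("\\.tsv$", ".json", p))
  }
  bp <- file.path(od, "behaviour.tsv")
  utils::write.table(res$behaviour$normalized, bp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ep <- file.path(od, "evidence.tsv")
  write_evidence_tsv(res$evidence, ep)
  rp <- file.path(od, "results.json")
  jsonlite::write_json(list(
    exceedance = as.list(res$bms$exceedance),
    expected_family_prob = as.list(res$bms$expected_family_prob),
    decisive = res$decision$decisive, winner = res$decision$winner,
    bma_window = res$bma$window,
    ttests = res$ttests,
    stepwise_selected = res$stepwise$selected,
    stepwise_adj_r2 = res$stepwise$adj_r_squared,
    slowing_slope = res$behaviour$lmm$slope,
    slowing_p = res$behaviour$lmm$p),
    rp, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, bp, ep, rp)
  manifest <- c(res$manifest,
                list(files = as.list(tools::md5sum(sort(paths)))))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
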