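#' Collect an evidence matrix from per-subject inversions
#'
#' @param posteriors list over subjects, each a list over models of
#'   `dcm_posterior` objects (aligned with `space`).
#' @param space list of `model_spec` giving column order and ids.
#' @return subjects x models matrix of free energies with model ids as
#'   column names.
#' @export
evidence_matrix <- function(posteriors, space) {
  ids <- vapply(space, `[[`, character(1), "id")
  ev <- t(vapply(posteriors, function(subj)
    vapply(subj, `[[`, numeric(1), "free_energy"), numeric(length(ids))))
  colnames(ev) <- ids
  ev
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet scheme over subject-specific model frequencies:
#' the model (or family) identity is treated as a random effect across
#' subjects and a Dirichlet posterior over frequencies is fitted from the
#' free-energy evidence matrix.  At the family level, each subject's
#' per-family evidence is first pooled over member models under a uniform
#' within-family prior (a log-mean-exp, i.e. the per-model prior mass is
#' inversely proportional to family size so that unequal sizes — 36/36/12/6
#' per SM1-self level — cannot bias the comparison), and the Dirichlet is
#' fitted over the 8 families.  Exceedance probabilities (the probability
#' that a model/family is the most frequent in the population) are
#' estimated by seeded Monte-Carlo sampling from the fitted Dirichlet.
#'
#' @param evidence subjects x models matrix of free energies (finite),
#'   columns named by model id.
#' @param space list of `model_spec` aligned with the columns (needed for
#'   `level = "family"`).
#' @param level `"family"` (default) or `"model"`.
#' @param n_draws Monte-Carlo draws for exceedance probabilities.
#' @param seed seed for the draws.
#' @param prior_alpha per-model prior counts; default 1 at model level,
#'   `1/family size` at family level.
#' @return object of class `bms_result`: Dirichlet `alpha` per model,
#'   `alpha_family`, expected probabilities, exceedance probabilities,
#'   subject responsibilities `g`, and the settings used.
#' @export
rfx_bms <- function(evidence, space = NULL,
                    level = c("family", "model"),
                    n_draws = 1e6, seed = 1L, prior_alpha = NULL) {
  level <- match.arg(level)
  evidence <- as.matrix(evidence)
  n <- nrow(evidence); K <- ncol(evidence)
  if (n < 2) stop("random-effects BMS needs at least 2 subjects")
  if (!all(is.finite(evidence))) stop("evidence matrix contains non-finite values")

  vb_dirichlet <- function(ev, a0) {
    alpha <- a0
    g <- NULL
    for (it in 1:500) {
      lg <- sweep(ev, 2, digamma(alpha) - digamma(sum(alpha)), "+")
      lg <- lg - apply(lg, 1, max)
      g <- exp(lg)
      g <- g / rowSums(g)
      alpha_new <- a0 + colSums(g)
      if (max(abs(alpha_new - alpha)) < 1e-8) { alpha <- alpha_new; break }
      alpha <- alpha_new
    }
    list(alpha = alpha, g = g)
  }

  set.seed(as.integer(seed))
  if (level == "family") {
    if (is.null(space)) stop("family-level BMS needs the model space")
    fam <- vapply(space, `[[`, character(1), "family_label")
    if (length(fam) != K) stop("space and evidence disagree")
    fams <- sort(unique(fam))
    ## per-subject family evidence: log-mean-exp over member models
    ## (uniform within-family prior corrects for unequal family sizes)
    fev <- vapply(fams, function(f) {
      sub <- evidence[, fam == f, drop = FALSE]
      mx <- apply(sub, 1, max)
      mx + log(rowMeans(exp(sub - mx)))
    }, numeric(n))
    fit <- vb_dirichlet(fev, rep(if (is.null(prior_alpha)) 1 else
      prior_alpha, length.out = length(fams)))
    alpha_family <- stats::setNames(fit$alpha, fams)
    g_family <- fit$g
    colnames(g_family) <- fams
    ## subject-model responsibilities: family responsibility times the
    ## within-family posterior over member models
    g <- matrix(0, n, K, dimnames = list(NULL, colnames(evidence)))
    for (f in fams) {
      sel <- fam == f
      sub <- evidence[, sel, drop = FALSE]
      wm <- exp(sub - apply(sub, 1, max))
      wm <- wm / rowSums(wm)
      g[, sel] <- wm * g_family[, f]
    }
    xp <- .dirichlet_exceedance(alpha_family, n_draws)
    res <- list(level = level, alpha = NULL, alpha_family = alpha_family,
                expected_model_prob = colMeans(g),
                expected_family_prob = alpha_family / sum(alpha_family),
                exceedance = xp, family = fam, g = g,
                g_family = g_family, n_draws = n_draws, seed = seed)
  } else {
    fit <- vb_dirichlet(evidence,
                        rep(if (is.null(prior_alpha)) 1 else prior_alpha,
                            length.out = K))
    alpha <- stats::setNames(fit$alpha, colnames(evidence))
    xp <- .dirichlet_exceedance(alpha, n_draws)
    res <- list(level = level, alpha = alpha, alpha_family = NULL,
                expected_model_prob = alpha / sum(alpha),
                expected_family_prob = NULL,
                exceedance = xp, family = NULL, g = fit$g,
                g_family = NULL, n_draws = n_draws, seed = seed)
  }
  structure(res, class = "bms_result")
}

## P(r_k > r_j for all j) under Dirichlet(alpha), by chunked gamma sampling.
.dirichlet_exceedance <- function(alpha, n_draws) {
  K <- length(alpha)
  counts <- numeric(K)
  left <- as.integer(n_draws)
  chunk <- as.integer(min(left, max(1, floor(2e6 / K))))
  while (left > 0) {
    nd <- min(chunk, left)
    draws <- matrix(stats::rgamma(nd * K, shape = rep(alpha, each = nd)),
                    nd, K)
    win <- max.col(draws, ties.method = "first")
    counts <- counts + tabulate(win, K)
    left <- left - nd
  }
  stats::setNames(counts / n_draws, names(alpha))
}

#' Decisiveness check on a family-level BMS result
#'
#' Returns the family whose exceedance probability strictly exceeds the
#' threshold, or `NA` if no family is decisive — in which case the
#' pipeline proceeds to Bayesian model averaging over the whole model
#' space.
#'
#' @param result a `bms_result`.
#' @param threshold decisiveness threshold on the exceedance probability.
#' @return list with `decisive` (logical) and `winner` (family label or
#'   `NA_character_`).
#' @export
decisive <- function(result, threshold = 0.95) {
  stopifnot(inherits(result, "bms_result"))
  xp <- result$exceedance
  if (max(xp) > threshold)
    list(decisive = TRUE, winner = names(xp)[which.max(xp)])
  else list(decisive = FALSE, winner = NA_character_)
}

#' Bayesian model averaging with an Occam's window
#'
#' Models whose posterior model probability relative to the best model is
#' at least `occam` enter the window; within it, each subject's parameter
#' estimates are averaged over models.  Subject-level model probabilities
#' are the random-effects responsibilities when a `bms_result` is supplied
#' (or can be requested as fixed-effects softmax weights of each subject's
#' own evidences).  In `"deterministic"` mode the average is the exact
#' probability-weighted mean; in `"sampling"` mode the model identity is
#' drawn per subject from those probabilities (seeded) and draws are
#' averaged.  Parameters absent from a model contribute their prior mean
#' of zero, so averaged estimates are shrunk by model uncertainty.
#'
#' @param posteriors list over subjects of lists over models of
#'   `dcm_posterior` (full `map` vectors are averaged).
#' @param evidence subjects x models free-energy matrix.
#' @param bms optional `bms_result` at model level or family level
#'   providing responsibilities; if `NULL`, fixed-effects weights
#'   `softmax(F_n)` per subject are used.
#' @param occam Occam's window as a posterior-odds cutoff relative to the
#'   best model.
#' @param mode `"deterministic"` or `"sampling"`.
#' @param n_draws draws per subject in sampling mode.
#' @param seed seed for sampling mode.
#' @return object of class `bma_result`: `subject_maps` (subjects x
#'   parameters), `window` (model ids), `weights` (subjects x window
#'   models, rows sum to 1), `group_model_prob`.
#' @export
bma <- function(posteriors, evidence, bms = NULL, occam = 0.05,
                mode = c("deterministic", "sampling"),
                n_draws = 1000, seed = 1L) {
  mode <- match.arg(mode)
  evidence <- as.matrix(evidence)
  n <- nrow(evidence); K <- ncol(evidence)
  stopifnot(length(posteriors) == n,
            all(vapply(posteriors, length, 0L) == K))
  ## subject-level model probabilities
  w <- if (!is.null(bms)) bms$g else {
    lw <- evidence - apply(evidence, 1, max)
    ew <- exp(lw)
    ew / rowSums(ew)
  }
  group_p <- colMeans(w)
  keep <- which(group_p / max(group_p) >= occam)
  if (length(keep) == 0) stop("empty Occam's window")
  wk <- w[, keep, drop = FALSE]
  wk <- wk / rowSums(wk)

  par_names <- names(posteriors[[1]][[1]]$map)
  maps <- lapply(seq_len(n), function(s)
    vapply(posteriors[[s]][keep],
           function(p) p$map[par_names], numeric(length(par_names))))

  subject_maps <- matrix(0, n, length(par_names),
                         dimnames = list(NULL, par_names))
  if (mode == "deterministic") {
    for (s in seq_len(n))
      subject_maps[s, ] <- as.vector(maps[[s]] %*% wk[s, ])
  } else {
    set.seed(as.integer(seed))
    for (s in seq_len(n)) {
      draws <- sample.int(length(keep), n_draws, replace = TRUE,
                          prob = wk[s, ])
      subject_maps[s, ] <- rowMeans(maps[[s]][, draws, drop = FALSE])
    }
  }
  structure(list(subject_maps = subject_maps,
                 window = colnames(evidence)[keep],
                 weights = wk, group_model_prob = group_p,
                 occam = occam, mode = mode, seed = seed),
            class = "bma_result")
}
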