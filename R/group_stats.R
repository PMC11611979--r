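#' Group-level one-sample t-tests on averaged connectivity parameters
#'
#' Tests each modulated connection's per-subject (BMA-averaged) MAP
#' estimates against zero with one-sample t-tests and Bonferroni
#' correction over the tested set.  By default the tested set is every
#' modulatory (B) parameter with non-zero variance across subjects, i.e.
#' every connection modulated in at least one window model.
#'
#' @param bma a `bma_result` or a subjects x parameters matrix.
#' @param parameters parameter names to test; default all `B:` columns
#'   with across-subject variance.
#' @param alpha significance level applied to corrected p-values.
#' @return data frame (class `group_stats`) with per connection: mean MAP,
#'   t, df, raw and Bonferroni-corrected p (capped at 1), significance
#'   flag; sorted by |t|, largest first.
#' @export
map_group_ttests <- function(bma, parameters = NULL, alpha = 0.05) {
  X <- if (inherits(bma, "bma_result")) bma$subject_maps else as.matrix(bma)
  if (nrow(X) < 2) stop("group t-tests need at least 2 subjects")
  if (is.null(parameters)) {
    bcols <- grep("^B:", colnames(X), value = TRUE)
    vv <- apply(X[, bcols, drop = FALSE], 2, stats::var)
    parameters <- bcols[vv > 0]
  }
  for (pn in parameters)
    if (stats::var(X[, pn]) == 0)
      stop(sprintf("parameter %s has zero across-subject variance", pn))
  m <- length(parameters)
  rows <- lapply(parameters, function(pn) {
    tt <- stats::t.test(X[, pn], mu = 0)
    p_raw <- tt$p.value
    data.frame(parameter = pn, mean = unname(tt$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = p_raw, p_bonferroni = min(1, m * p_raw),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_bonferroni < alpha
  out <- out[order(-abs(out$t)), ]
  rownames(out) <- NULL
  class(out) <- c("group_stats", "data.frame")
  out
}

#' Forward-backward stepwise regression of slowing on connectivity
#'
#' Ordinary least-squares stepwise selection relating each subject's
#' behavioural slowing score to the averaged modulatory parameter
#' estimates: at each step the candidate with the smallest partial
#' p-value below `p_enter` is added, then included predictors whose
#' p-value has risen above `p_remove` are dropped, until no change.
#' Candidates that are collinear with the current model are skipped with a
#' warning.  Leverage and Cook's-distance diagnostics are always returned
#' (associations can be driven by outlying subjects).
#'
#' @param slowing numeric vector, one behavioural slowing score per
#'   subject (e.g. the fitted per-subject speed decline per bin).
#' @param maps subjects x predictors matrix (columns named).
#' @param p_enter,p_remove entry and removal thresholds.
#' @return list with `selected`, `model` (the final `lm` or `NULL`),
#'   `coefficients`, `adj_r_squared`, `p_overall`, `cooks_distance`,
#'   `leverage`, `influential` (Cook's distance > 4/n).
#' @export
stepwise_regression <- function(slowing, maps, p_enter = 0.05,
                                p_remove = 0.10) {
  maps <- as.matrix(maps)
  n <- length(slowing)
  stopifnot(nrow(maps) == n)
  candidates <- colnames(maps)
  if (is.null(candidates)) stop("maps must have column names")
  d <- data.frame(.y = slowing, maps, check.names = FALSE)
  selected <- character(0)
  repeat {
    changed <- FALSE
    ## forward step
    pool <- setdiff(candidates, selected)
    if (length(pool) > 0 && n > length(selected) + 2) {
      pvals <- vapply(pool, function(v) {
        fml <- stats::reformulate(sprintf("`%s`", c(selected, v)),
                                  response = ".y")
        fit <- stats::lm(fml, data = d)
        co <- summary(fit)$coefficients
        rn <- sprintf("`%s`", v)
        if (!(rn %in% rownames(co)) && !(v %in% rownames(co))) {
          warning(sprintf("predictor %s collinear with current model; skipped", v))
          return(NA_real_)
        }
        co[if (rn %in% rownames(co)) rn else v, 4]
      }, 0)
      if (any(!is.na(pvals)) && min(pvals, na.rm = TRUE) < p_enter) {
        selected <- c(selected, pool[which.min(pvals)])
        changed <- TRUE
      }
    }
    ## backward step
    if (length(selected) > 0) {
      fml <- stats::reformulate(sprintf("`%s`", selected), response = ".y")
      fit <- stats::lm(fml, data = d)
      co <- summary(fit)$coefficients
      rn <- setdiff(rownames(co), "(Intercept)")
      pv <- co[rn, 4]
      if (length(pv) && max(pv) > p_remove) {
        worst <- rn[which.max(pv)]
        worst <- gsub("^`|`$", "", worst)
        selected <- setdiff(selected, worst)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(selected) == 0)
    return(list(selected = character(0), model = NULL, coefficients = NULL,
                adj_r_squared = 0, p_overall = NA_real_,
                cooks_distance = NULL, leverage = NULL,
                influential = integer(0)))
  fml <- stats::reformulate(sprintf("`%s`", selected), response = ".y")
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p_overall <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  cd <- stats::cooks.distance(fit)
  list(selected = selected, model = fit,
       coefficients = stats::coef(fit),
       adj_r_squared = sm$adj.r.squared,
       p_overall = unname(p_overall),
       cooks_distance = cd, leverage = stats::hatvalues(fit),
       influential = which(cd > 4 / n))
}
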