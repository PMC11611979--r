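#' Parameter template for a model specification
#'
#' Expands a `model_spec` into the full named parameter vector of the
#' two-state DCM: the six endogenous between-region log-scalings and three
#' self-inhibition parameters (always present), the modulatory weights and
#' driving weights switched on by the spec's masks, and the per-region
#' hemodynamic transit-time log-scalings.  Masked-out parameters are kept
#' in the template with zero prior variance, pinning them to their prior
#' mean.
#'
#' @param spec a `model_spec`.
#' @param prior_var_a,prior_var_b,prior_var_c,prior_var_tau prior variances
#'   per parameter block.
#' @return data frame with columns `name`, `block`, `connection`,
#'   `prior_mean`, `prior_var`, `enabled`.
#' @keywords internal
spec_param_template <- function(spec,
                                prior_var_a = 1 / 16, prior_var_b = 1 / 4,
                                prior_var_c = 1 / 4, prior_var_tau = 1 / 16) {
  stopifnot(inherits(spec, "model_spec"))
  between <- c("SMA->SM1", "SM1->SMA", "PMd->SM1", "SM1->PMd",
               "SMA->PMd", "PMd->SMA")
  selfs <- paste0("self-", REGIONS)
  rows <- list()
  add <- function(name, block, connection, var, enabled)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, block = block, connection = connection,
      prior_mean = 0, prior_var = if (enabled) var else 0,
      enabled = enabled, stringsAsFactors = FALSE)
  for (cn in between) add(paste0("A:", cn), "A", cn, prior_var_a, TRUE)
  for (cn in selfs) add(paste0("A:", cn), "A", cn, prior_var_a, TRUE)
  for (cn in c(between, selfs))
    add(paste0("B:", cn), "B", cn, prior_var_b, cn %in% spec$b_mask)
  for (rg in c("PMd", "SMA"))
    add(paste0("C:", rg), "C", rg, prior_var_c, rg %in% spec$c_mask)
  for (rg in REGIONS) add(paste0("tau:", rg), "tau", rg, prior_var_tau, TRUE)
  out <- do.call(rbind, rows)
  rownames(out) <- out$name
  out
}

#' Default shrinkage priors for a model
#'
#' Zero-mean Gaussian priors on every enabled parameter: variance 1/16 on
#' the endogenous couplings, self-inhibition and transit-time log-scalings
#' (mild deviations about the fixed rates keep the network in its stable
#' regime), 1/4 on the modulatory and driving weights switched on by the
#' model.  Disabled parameters have zero prior variance.  The observation
#' noise log-precisions carry a broad Gaussian hyperprior (mean 0,
#' variance 16), one per region.
#'
#' @param spec a `model_spec`.
#' @return object of class `prior_spec`: the parameter `template` plus
#'   `hyper_mean`, `hyper_var`.
#' @export
default_priors <- function(spec) {
  structure(list(template = spec_param_template(spec),
                 hyper_mean = 0, hyper_var = 16),
            class = "prior_spec")
}

## Assemble dcm_parameters from the enabled-parameter vector theta.
.theta_to_params <- function(theta, template, constants) {
  full <- stats::setNames(template$prior_mean, template$name)
  full[names(theta)] <- theta
  A <- B <- matrix(0, 3, 3, dimnames = list(REGIONS, REGIONS))
  for (k in seq_len(nrow(template))) {
    blk <- template$block[k]; cn <- template$connection[k]
    v <- full[template$name[k]]
    if (blk %in% c("A", "B")) {
      ij <- .connection_index(cn)
      if (blk == "A") A[ij[1], ij[2]] <- v else B[ij[1], ij[2]] <- v
    }
  }
  C <- stats::setNames(numeric(3), REGIONS)
  for (rg in c("PMd", "SMA")) {
    nm <- paste0("C:", rg)
    if (nm %in% template$name) C[rg] <- full[nm]
  }
  log_tau <- vapply(REGIONS, function(rg) full[paste0("tau:", rg)], 0)
  dcm_parameters(A = A, B = B, C = C, log_tau = log_tau,
                 constants = constants)
}

## Decimate a microtime input set to a coarser integration step.
.decimate_inputs <- function(inputs, factor) {
  if (factor == 1L) return(inputs)
  idx <- unlist(lapply(seq_along(inputs$n_per_run), function(r) {
    start <- inputs$run_starts[r]
    seq(start, start + inputs$n_per_run[r] - 1L, by = factor)
  }))
  n_per_run <- vapply(seq_along(inputs$n_per_run), function(r)
    length(seq(1L, inputs$n_per_run[r], by = factor)), integer(1))
  structure(list(u = inputs$u[idx, , drop = FALSE], dt = inputs$dt * factor,
                 run_starts = cumsum(c(1L, n_per_run[-length(n_per_run)])),
                 n_per_run = n_per_run),
            class = "input_set")
}

#' Inversion settings
#'
#' @param max_iter Gauss-Newton iteration cap.
#' @param tol convergence tolerance on the free-energy increase (nats).
#' @param fd_step finite-difference step for the prediction Jacobian.
#' @param estimate_noise estimate per-region noise log-precisions (TRUE) or
#'   hold them at `lambda0`.
#' @param lambda0 initial (or fixed) noise log-precisions; `NULL` =
#'   initialize from the residuals at the prior mean.
#' @param decimate integer factor by which the microtime inputs are
#'   thinned for integration during inversion (default 2: TR/8 when the
#'   inputs are built at TR/16).
#' @param max_halvings step halvings per iteration before giving up.
#' @return list of settings.
#' @export
invert_settings <- function(max_iter = 128, tol = 0.01, fd_step = 1e-3,
                            estimate_noise = TRUE, lambda0 = NULL,
                            decimate = 2L, max_halvings = 4L) {
  list(max_iter = max_iter, tol = tol, fd_step = fd_step,
       estimate_noise = estimate_noise, lambda0 = lambda0,
       decimate = as.integer(decimate), max_halvings = as.integer(max_halvings))
}

#' Variational-Laplace inversion of a nonlinear Gaussian model
#'
#' Gauss-Newton ascent on the variational free energy under the Laplace
#' approximation, for a model `y = forward(theta) + noise` with Gaussian
#' shrinkage priors on `theta` and independent Gaussian noise whose
#' log-precision (one per data column) is optimized alongside under a
#' Gaussian hyperprior.  Steps that fail to increase the free energy are
#' halved and, if still failing, rejected, so the accepted free-energy
#' trajectory is non-decreasing.  For a linear `forward` and fixed noise
#' precision the converged free energy equals the exact log model
#' evidence.
#'
#' @param y data matrix (n x m columns, e.g. regions).
#' @param forward function mapping a named parameter vector to an n x m
#'   prediction matrix.
#' @param prior_mean,prior_var named vectors over the free parameters
#'   (`prior_var` > 0).
#' @param settings from [invert_settings()].
#' @param hyper_mean,hyper_var Gaussian hyperprior on the noise
#'   log-precisions.
#' @return list with `map` (named), `Sigma`, `free_energy`, `lambda`,
#'   `prediction`, `F_trace`, `iterations`, `converged`.
#' @export
invert_vl <- function(y, forward, prior_mean, prior_var,
                      settings = invert_settings(),
                      hyper_mean = 0, hyper_var = 16) {
  y <- as.matrix(y)
  n <- nrow(y); m <- ncol(y); N <- n * m
  stopifnot(length(prior_mean) == length(prior_var), all(prior_var > 0))
  p <- length(prior_mean)
  col_of <- rep(seq_len(m), each = n)
  yv <- as.vector(y)
  P0 <- diag(1 / prior_var, p)
  ld_P0 <- sum(log(1 / prior_var))

  theta <- prior_mean
  g <- forward(theta)
  if (!all(is.finite(g))) stop("forward model non-finite at the prior mean")
  ev <- yv - as.vector(g)
  if (is.null(settings$lambda0)) {
    v0 <- vapply(seq_len(m), function(r) stats::var(ev[col_of == r]), 0)
    lambda <- -log(pmax(v0, 1e-8))
  } else lambda <- rep_len(settings$lambda0, m)

  Fe <- function(ev, theta, lambda, ld_Sp, ld_Sl) {
    w <- exp(lambda)[col_of]
    Fl <- -0.5 * sum(w * ev^2) + 0.5 * sum(n * lambda) - N / 2 * log(2 * pi)
    d0 <- theta - prior_mean
    Fp <- -0.5 * sum(d0^2 / prior_var) + 0.5 * ld_P0 + 0.5 * ld_Sp
    Fh <- if (settings$estimate_noise)
      -0.5 * sum((lambda - hyper_mean)^2) / hyper_var -
        0.5 * m * log(hyper_var) + 0.5 * ld_Sl
    else 0
    Fl + Fp + Fh
  }

  jac <- function(theta, g0) {
    J <- matrix(0, N, p)
    for (k in seq_len(p)) {
      tk <- theta
      tk[k] <- tk[k] + settings$fd_step
      J[, k] <- (as.vector(forward(tk)) - as.vector(g0)) / settings$fd_step
    }
    J
  }

  update_lambda <- function(lambda, ev, J, Sp) {
    if (!settings$estimate_noise) return(lambda)
    for (it in 1:8) {
      grad <- numeric(m); hess <- numeric(m)
      for (r in seq_len(m)) {
        sel <- col_of == r
        Jr <- J[sel, , drop = FALSE]
        tr_r <- sum((Jr %*% Sp) * Jr)
        s2 <- sum(ev[sel]^2) + tr_r
        wr <- exp(lambda[r])
        grad[r] <- -0.5 * wr * s2 + n / 2 - (lambda[r] - hyper_mean) / hyper_var
        hess[r] <- -0.5 * wr * s2 - 1 / hyper_var
      }
      step <- -grad / hess
      step <- pmin(pmax(step, -2), 2)
      lambda <- lambda + step
      if (max(abs(step)) < 1e-4) break
    }
    lambda
  }

  F_trace <- numeric(0)
  Sp <- diag(prior_var, p)
  ld_Sp <- sum(log(prior_var))
  ld_Sl <- 0
  F_cur <- Fe(ev, theta, lambda, ld_Sp, ld_Sl)
  converged <- FALSE
  iter_done <- 0
  Sigma <- Sp
  for (iter in seq_len(settings$max_iter)) {
    iter_done <- iter
    J <- jac(theta, g)
    w <- exp(lambda)[col_of]
    H <- crossprod(J, J * w) + P0
    Hc <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(Hc)) {
      H <- H + diag(1e-6 * max(diag(H)), p)
      Hc <- chol(H)
      warning("singular curvature regularized")
    }
    Sp_new <- chol2inv(Hc)
    grad <- crossprod(J, w * ev) - (theta - prior_mean) / prior_var
    delta <- as.vector(Sp_new %*% grad)

    lambda_try <- update_lambda(lambda, ev, J, Sp_new)
    ld_Sp_new <- -2 * sum(log(diag(Hc)))
    ld_Sl_new <- if (settings$estimate_noise) {
      s <- vapply(seq_len(m), function(r) {
        sel <- col_of == r
        Jr <- J[sel, , drop = FALSE]
        s2 <- sum(ev[sel]^2) + sum((Jr %*% Sp_new) * Jr)
        -1 / (-0.5 * exp(lambda_try[r]) * s2 - 1 / hyper_var)
      }, 0)
      sum(log(s))
    } else 0

    step <- 1
    accepted <- FALSE
    for (h in 0:settings$max_halvings) {
      theta_try <- theta + step * delta
      g_try <- tryCatch(forward(theta_try), error = function(e) NULL)
      if (!is.null(g_try) && all(is.finite(g_try))) {
        ev_try <- yv - as.vector(g_try)
        F_try <- Fe(ev_try, theta_try, lambda_try, ld_Sp_new, ld_Sl_new)
        if (F_try >= F_cur - 1e-12) {
          dF <- F_try - F_cur
          theta <- theta_try; g <- g_try; ev <- ev_try
          lambda <- lambda_try; Sigma <- Sp_new
          ld_Sp <- ld_Sp_new; ld_Sl <- ld_Sl_new
          F_cur <- F_try
          accepted <- TRUE
          break
        }
      }
      step <- step / 2
    }
    F_trace <- c(F_trace, F_cur)
    if (accepted && iter > 1 && dF < settings$tol) {
      converged <- TRUE
      break
    }
    if (!accepted) {
      ## no uphill step found: treat as converged at the current optimum
      converged <- TRUE
      break
    }
  }
  dimnames(Sigma) <- list(names(prior_mean), names(prior_mean))
  list(map = theta, Sigma = Sigma, free_energy = F_cur, lambda = lambda,
       prediction = g, F_trace = F_trace, iterations = iter_done,
       converged = converged)
}

#' Bayesian inversion of one DCM for one subject
#'
#' Variational-Laplace inversion of the two-state DCM: the forward model
#' integrates the neuronal and hemodynamic dynamics for the parameters
#' enabled by `spec`, and [invert_vl()] performs Gauss-Newton ascent on
#' the free energy.  Returns MAP estimates (masked parameters stay at
#' their prior mean of 0), the posterior covariance over enabled
#' parameters, the free-energy approximation to log model evidence, and
#' diagnostics.  Deterministic given identical inputs and settings.
#'
#' @param series a `bold_series` (or volumes x regions matrix).
#' @param inputs the `input_set` used to generate/invert the data.
#' @param spec a `model_spec`.
#' @param priors a `prior_spec`; default [default_priors()].
#' @param settings from [invert_settings()].
#' @param constants two-state constants.
#' @return object of class `dcm_posterior`.
#' @export
invert <- function(series, inputs, spec, priors = default_priors(spec),
                   settings = invert_settings(),
                   constants = twostate_constants()) {
  y <- if (inherits(series, "bold_series")) series$y else as.matrix(series)
  tr <- if (inherits(series, "bold_series")) series$tr else 2.5
  n_volumes <- nrow(y) / length(inputs$n_per_run)
  stopifnot(n_volumes == round(n_volumes))
  template <- priors$template
  en <- template[template$enabled & template$prior_var > 0, ]
  prior_mean <- stats::setNames(en$prior_mean, en$name)
  prior_var <- stats::setNames(en$prior_var, en$name)

  inp <- .decimate_inputs(inputs, settings$decimate)
  spv <- tr / inp$dt
  if (abs(spv - round(spv)) > 1e-9)
    stop("decimated input dt must divide the TR")
  forward <- function(theta) {
    par <- .theta_to_params(theta, template, constants)
    tau <- constants$tau0 * exp(par$log_tau)
    .dcm_simulate_cpp(par$A, par$B, as.numeric(par$C), tau, inp$u, inp$dt,
                      as.integer(inp$n_per_run), as.integer(round(spv)),
                      as.integer(n_volumes), constants)
  }
  fit <- invert_vl(y, forward, prior_mean, prior_var, settings,
                   hyper_mean = priors$hyper_mean,
                   hyper_var = priors$hyper_var)
  map_full <- stats::setNames(template$prior_mean, template$name)
  map_full[names(fit$map)] <- fit$map
  structure(list(map = map_full, map_enabled = fit$map, Sigma = fit$Sigma,
                 free_energy = fit$free_energy, lambda = fit$lambda,
                 prediction = fit$prediction, F_trace = fit$F_trace,
                 iterations = fit$iterations, converged = fit$converged,
                 spec = spec, template = template),
            class = "dcm_posterior")
}

#' Percent variance explained by a posterior prediction
#'
#' `100 * (1 - RSS / TSS)` where RSS is the residual sum of squares of the
#' posterior-mean prediction and TSS the total sum of squares of the data
#' about its mean.
#'
#' @param posterior a `dcm_posterior` (or a prediction matrix).
#' @param series the data the model was fitted to.
#' @return percent (can be negative for predictions worse than the mean).
#' @export
variance_explained <- function(posterior, series) {
  y <- if (inherits(series, "bold_series")) series$y else as.matrix(series)
  pred <- if (inherits(posterior, "dcm_posterior")) posterior$prediction
          else as.matrix(posterior)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("zero-variance data: variance explained undefined")
  100 * (1 - sum((y - pred)^2) / tss)
}
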