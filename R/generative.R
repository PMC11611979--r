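#' Fixed constants of the two-state neuronal and balloon models
#'
#' The two-state model places one excitatory (E) and one inhibitory (I)
#' population in each region.  Between-region connections couple E
#' populations and are strictly excitatory; within each region the I
#' population is driven by its E population and inhibits it, so
#' self-connections are strictly inhibitory for every value of the
#' (log-scale) self parameters.  Units are Hz.
#'
#' * `sigma_E`, `sigma_I`: passive decay rates of the E (1 Hz) and I
#'   (0.5 Hz) populations; the faster E decay keeps the network stable
#'   over the whole prior range of the coupling log-scalings.
#' * `g_EI`: local E->I drive (0.5 Hz).
#' * `g_IE`: I->E inhibitory gain at self parameter 0 (1 Hz); the
#'   effective gain is `g_IE * exp(theta_self + u_mod * b_self)`.
#' * `a0`: between-region excitatory rate at connection parameter 0
#'   (0.2 Hz); the effective rate is `a0 * exp(A_ij + u_mod * B_ij)`.
#' * Balloon model: signal decay `kappa` = 0.64/s, flow feedback `gamma` =
#'   0.32/s, reference transit time `tau0` = 2 s (per-region transit is
#'   `tau0 * exp(log_tau_i)` and estimable), vessel stiffness `alpha` =
#'   0.32, resting oxygen extraction `E0` = 0.4, resting blood volume
#'   fraction `V0` = 0.04.
#'
#' @param ... overrides for individual constants.
#' @return named list of constants.
#' @export
twostate_constants <- function(...) {
  cst <- list(sigma_E = 1.0, sigma_I = 0.5, g_EI = 0.5, g_IE = 1.0,
              a0 = 0.2,
              kappa = 0.64, gamma = 0.32, tau0 = 2.0, alpha = 0.32,
              E0 = 0.4, V0 = 0.04)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cst))
  if (length(bad)) stop("unknown constants: ", paste(bad, collapse = ", "))
  cst[names(dots)] <- dots
  cst
}

#' DCM parameters for one subject-model
#'
#' Numerical parameters of the two-state model.  `A` holds the endogenous
#' log-scaling of between-region excitatory rates (off-diagonal) and the
#' self-inhibition log-scaling parameters (diagonal).  `B` holds the
#' modulatory log-scaling weights applied per unit of the slowing input,
#' with the diagonal modulating self-inhibition (a negative diagonal entry
#' means self-inhibition is released as slowing builds up).  `C` holds the
#' driving-input weights, and `log_tau` per-region log-scaling of the
#' hemodynamic transit time.
#'
#' @param A,B 3x3 matrices (rows = targets, columns = sources).
#' @param C length-3 driving weights (SM1, PMd, SMA).
#' @param log_tau length-3 log transit-time scaling.
#' @param constants output of [twostate_constants()].
#' @return object of class `dcm_parameters`.
#' @export
dcm_parameters <- function(A = matrix(0, 3, 3), B = matrix(0, 3, 3),
                           C = numeric(3), log_tau = numeric(3),
                           constants = twostate_constants()) {
  A <- as.matrix(A); B <- as.matrix(B)
  R <- nrow(A)
  stopifnot(ncol(A) == R, all(dim(B) == R), length(C) == R,
            length(log_tau) == R)
  if (!all(is.finite(A)) || !all(is.finite(B)) || !all(is.finite(C)) ||
      !all(is.finite(log_tau)))
    stop("non-finite parameter values")
  dimnames(A) <- dimnames(B) <- list(REGIONS[seq_len(R)], REGIONS[seq_len(R)])
  structure(list(A = A, B = B, C = stats::setNames(C, REGIONS[seq_len(R)]),
                 log_tau = log_tau, constants = constants),
            class = "dcm_parameters")
}

#' Effective self-connection rate
#'
#' The inhibitory gain a region's I population exerts on its E population:
#' `-g_IE * exp(theta + u_mod * b_self)`.  Strictly negative for every
#' real-valued parameter, so self-connections can never turn excitatory;
#' a negative modulatory weight `b_self` under a positive slowing input
#' reduces the magnitude of inhibition (disinhibition).
#'
#' @param theta self-inhibition log-scaling parameter.
#' @param u_mod current value of the modulatory input.
#' @param b_self modulatory weight on the self-connection.
#' @param constants model constants.
#' @return negative scalar (Hz).
#' @export
effective_self_rate <- function(theta, u_mod = 0, b_self = 0,
                                constants = twostate_constants()) {
  -constants$g_IE * exp(theta + u_mod * b_self)
}

#' Neuronal state derivative of the two-state model
#'
#' Pure-R reference implementation of the bilinear state equation
#' `xdot = (A + u B) x + C u` in its two-state form: E populations receive
#' between-region excitation with effective rates
#' `a0 exp(A_ij + u_mod B_ij)`, driving input through `C u_drive`, and
#' local inhibition `g_IE exp(A_ii + u_mod B_ii) xI`; I populations
#' integrate local E activity.  The compiled integrator uses the identical
#' vector field; this function exists for inspection and as the basis of
#' independent adaptive-integrator checks.
#'
#' @param state numeric vector `c(xE, xI)` of length 2R.
#' @param params a `dcm_parameters`.
#' @param u_drive_t,u_mod_t scalar input values at the current time.
#' @return derivative vector of length 2R.
#' @export
neural_derivative <- function(state, params, u_drive_t, u_mod_t) {
  cst <- params$constants
  R <- nrow(params$A)
  if (length(state) != 2 * R) stop("state must have length 2R")
  if (!all(is.finite(state)) || !is.finite(u_drive_t) || !is.finite(u_mod_t))
    stop("non-finite state or input")
  xE <- state[seq_len(R)]
  xI <- state[R + seq_len(R)]
  Aeff <- cst$a0 * exp(params$A + u_mod_t * params$B)
  diag(Aeff) <- 0
  self_gain <- cst$g_IE * exp(diag(params$A) + u_mod_t * diag(params$B))
  dxE <- -cst$sigma_E * xE + as.vector(Aeff %*% xE) - self_gain * xI +
    params$C * u_drive_t
  dxI <- cst$g_EI * xE - cst$sigma_I * xI
  c(dxE, dxI)
}

#' Balloon-model state derivative
#'
#' Standard balloon-Windkessel stage for one region: vasodilatory signal
#' `s`, normalized blood flow `f`, volume `v` and deoxyhemoglobin `q`,
#' driven by excitatory activity `xE`.
#'
#' @param hstate numeric vector `c(s, f, v, q)` (natural units; `f`, `v`,
#'   `q` are 1 at rest).
#' @param xE excitatory activity of the region.
#' @param constants model constants; `tau` may be supplied to override the
#'   region's transit time (seconds), else `tau0` is used.
#' @param tau transit time in seconds.
#' @return derivative vector `c(ds, df, dv, dq)`.
#' @export
hemodynamic_derivative <- function(hstate, xE, constants = twostate_constants(),
                                   tau = constants$tau0) {
  s <- hstate[1]; f <- hstate[2]; v <- hstate[3]; q <- hstate[4]
  if (v <= 0 || f <= 0) stop("non-physical hemodynamic state (f, v must be > 0)")
  Ef <- 1 - (1 - constants$E0)^(1 / f)
  c(xE - constants$kappa * s - constants$gamma * (f - 1),
    s,
    (f - v^(1 / constants$alpha)) / tau,
    (f * Ef / constants$E0 - v^(1 / constants$alpha) * q / v) / tau)
}

#' BOLD read-out from hemodynamic states
#'
#' @param v,q normalized volume and deoxyhemoglobin.
#' @param constants model constants.
#' @return percent signal change.
#' @export
bold_signal <- function(v, q, constants = twostate_constants()) {
  k1 <- 7 * constants$E0; k2 <- 2; k3 <- 2 * constants$E0 - 0.2
  100 * constants$V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

#' Simulate region BOLD time series from a parameterized model
#'
#' Integrates the two-state neuronal model coupled to the balloon model
#' with fixed-step RK4 at the input's microtime resolution, samples at the
#' TR, and optionally adds white measurement noise at a given SNR (noise
#' SD = noise-free signal SD / SNR, per region).  States reset to rest at
#' every run boundary.  Deterministic given the seed.
#'
#' @param params a `dcm_parameters`.
#' @param inputs an `input_set` from [dcm_inputs()].
#' @param tr repetition time (s).
#' @param n_volumes volumes per run.
#' @param snr signal-to-noise ratio; `Inf` (or `NULL`) for noise-free.
#' @param seed integer seed for the measurement noise.
#' @return object of class `bold_series`: matrix `y` (volumes x regions,
#'   runs stacked), `tr`, `n_volumes`, `n_runs`, `snr`, `seed`.
#' @export
simulate_bold <- function(params, inputs, tr = 2.5, n_volumes = 360,
                          snr = Inf, seed = 1L) {
  stopifnot(inherits(params, "dcm_parameters"), inherits(inputs, "input_set"))
  spv <- tr / inputs$dt
  if (abs(spv - round(spv)) > 1e-9) stop("input dt must divide the TR")
  cst <- params$constants
  tau <- cst$tau0 * exp(params$log_tau)
  y <- .dcm_simulate_cpp(params$A, params$B, as.numeric(params$C), tau,
                         inputs$u, inputs$dt,
                         as.integer(inputs$n_per_run), as.integer(round(spv)),
                         as.integer(n_volumes),
                         cst)
  colnames(y) <- rownames(params$A)
  n_runs <- length(inputs$n_per_run)
  if (!is.null(snr) && is.finite(snr)) {
    if (snr <= 0) stop("snr must be positive")
    set.seed(as.integer(seed))
    sds <- apply(y, 2, stats::sd)
    noise <- sapply(seq_along(sds), function(j)
      stats::rnorm(nrow(y), 0, sds[j] / snr))
    y <- y + noise
  }
  structure(list(y = y, tr = tr, n_volumes = n_volumes, n_runs = n_runs,
                 run_starts = seq(1L, by = n_volumes, length.out = n_runs),
                 snr = snr, seed = seed),
            class = "bold_series")
}
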