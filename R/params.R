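#' Neuron and integration parameters
#'
#' Parameters of the lumped RC membrane model shared by the input (S),
#' excitatory (E) and inhibitory (I) populations.  Each membrane leaks with
#' time constant `tau_m` and receives one unit of drive per integration
#' step: in Euler mode `v(t+1) = alpha_m v(t) + I(t) + eps(t)` with
#' `alpha_m = 1 - h/tau_m`, where `I` is the fan-in-averaged synaptic drive
#' (plus the external stimulus for S units).  Firing rates follow the
#' sigmoid [firing_rate()].  Uniform i.i.d. noise `eps` on
#' `[-noise_amp, noise_amp]` is added to every membrane potential at every
#' step, outside the deterministic update.
#'
#' @param tau_m membrane time constant in seconds.
#' @param h integration step in seconds (1 ms); must satisfy `h < tau_m`.
#' @param beta_m sigmoid gain of the rate function.
#' @param noise_amp half-width of the additive membrane noise; set to 0 for
#'   deterministic runs.
#' @param mode integration scheme: `"rk4"` (default; classical Runge--Kutta on
#'   the membrane relaxation, drive held fixed over each step) or `"euler"`
#'   (the forward-Euler map `v(t+1) = (1 - h/tau_m) v(t) + (h/tau_m) I`).
#' @return Object of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 0.025, h = 0.001, beta_m = 4.0,
                          noise_amp = 0.01, mode = c("rk4", "euler")) {
  mode <- match.arg(mode)
  if (h <= 0) stop("integration step h must be positive")
  if (tau_m <= h) stop("tau_m must exceed the integration step h")
  if (noise_amp < 0) stop("noise_amp must be nonnegative")
  structure(list(tau_m = tau_m, h = h, beta_m = beta_m,
                 noise_amp = noise_amp, mode = mode),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(
    "Neuron params: tau_m=%g s, h=%g s (alpha_m=%g), beta_m=%g, noise=%s%g, %s\n",
    x$tau_m, x$h, 1 - x$h / x$tau_m, x$beta_m, "±", x$noise_amp, x$mode))
  invisible(x)
}

#' Synaptic plasticity parameters
#'
#' All four connection types adapt under the same covariance rule
#' `w(t+1) = alpha_w w(t) + beta_w r_post(t) r_pre(t)` applied at every
#' integration step while plasticity is gated on, with `alpha_w = 1 - h/tau_w`
#' and `tau_w = 100 tau_m` by default.  The adaptation step decays once per
#' completed stimulation cycle, `beta_w(T+1) = alpha_beta beta_w(T)`.  At the
#' end of every plasticity-on trial each cell's incoming weights of each type
#' are rescaled multiplicatively so that their mean equals the type's resource
#' level: inputs to excitatory cells (ES, EE, EI) carry resource 2.0 and
#' inputs to inhibitory cells (IE) carry resource 1.0.  This per-postsynaptic-
#' cell budget is what makes the learning competitive, and the E/I asymmetry
#' (inhibitory drive on E cells commanding the same resource as the lateral
#' excitatory drive) is what lets the network return to its resting state
#' after every stimulus.
#'
#' @param beta_w0 initial adaptation step size.
#' @param alpha_beta per-cycle decay factor of the adaptation step.
#' @param tau_w weight decay time constant in seconds.
#' @param resources named numeric vector of per-type resource levels, in
#'   order `ES`, `EE`, `EI`, `IE`.
#' @param beta_reset if `TRUE` (default) the adaptation step is reset to
#'   `beta_w0` at the start of each experimental phase; if `FALSE` it
#'   continues to decay across phases.
#' @return Object of class `plasticity_params`.
#' @export
plasticity_params <- function(beta_w0 = 0.00025, alpha_beta = 0.99,
                              tau_w = 2.5,
                              resources = c(ES = 2.0, EE = 2.0,
                                            EI = 2.0, IE = 1.0),
                              beta_reset = TRUE) {
  if (beta_w0 <= 0) stop("beta_w0 must be positive")
  if (alpha_beta <= 0 || alpha_beta > 1) stop("alpha_beta must be in (0, 1]")
  if (tau_w <= 0) stop("tau_w must be positive")
  resources <- resources[CONN_TYPES]
  if (anyNA(resources))
    stop("resources must be named with all of: ", paste(CONN_TYPES, collapse = ", "))
  if (any(resources <= 0)) stop("resource levels must be positive")
  structure(list(beta_w0 = beta_w0, alpha_beta = alpha_beta, tau_w = tau_w,
                 resources = resources, beta_reset = beta_reset),
            class = "plasticity_params")
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat(sprintf("Plasticity: beta_w0=%g (x%g/cycle), tau_w=%g s, resources %s\n",
              x$beta_w0, x$alpha_beta, x$tau_w,
              paste(names(x$resources), x$resources, sep = "=",
                    collapse = " ")))
  invisible(x)
}

#' Trial timing and stimulus magnitude
#'
#' A trial lasts `total_ms`; the stimulus is on for `stim_ms` following a
#' `prestim_ms` pre-stimulus period, and the remainder of the trial lets the
#' network relax back to rest.  For patch trials the per-node ON drive is
#' scaled so the drive vector over the patch has Euclidean norm `stim_mag`
#' (4.0: each node of a 7 x 7 patch receives 4/7).  Receptive-field probe
#' trials drive a single node at magnitude 1.0 with no renormalization.
#'
#' @param total_ms,prestim_ms,stim_ms trial timing in milliseconds.
#' @param stim_mag target Euclidean norm of the patch drive vector.
#' @param settle_ms relaxation run (no stimulus, no plasticity) from the
#'   zero state to the network's resting state before the first trial of a
#'   block; within a block trials then run back-to-back, so every
#'   pre-stimulus window reflects genuine resting activity.
#' @return Object of class `trial_spec`.
#' @export
trial_spec <- function(total_ms = 350, prestim_ms = 100, stim_ms = 50,
                       stim_mag = 4.0, settle_ms = 500) {
  if (prestim_ms + stim_ms > total_ms)
    stop("trial timing inconsistent: prestim_ms + stim_ms exceeds total_ms")
  if (min(total_ms, prestim_ms, stim_ms, settle_ms) < 0 || stim_mag <= 0)
    stop("trial parameters must be nonnegative and stim_mag positive")
  structure(list(total_ms = total_ms, prestim_ms = prestim_ms,
                 stim_ms = stim_ms, stim_mag = stim_mag,
                 settle_ms = settle_ms),
            class = "trial_spec")
}

#' Sigmoidal firing-rate function
#'
#' The rate is `g(v) = (1 + tanh(beta_m (v - 1/2))) / 2`: strictly increasing,
#' bounded in (0, 1), with `g(1/2) = 1/2`.
#'
#' @param v membrane potential (vectorized).
#' @param beta_m sigmoid gain.
#' @return Firing rate(s) in (0, 1).
#' @examples
#' firing_rate(0.5)  # 0.5
#' firing_rate(0)    # ~0.018
#' @export
firing_rate <- function(v, beta_m = 4.0) {
  0.5 * (1 + tanh(beta_m * (v - 0.5)))
}

#' Per-cycle decay of the adaptation step
#'
#' @param beta_w current adaptation step.
#' @param k number of completed cycles to decay over.
#' @param alpha_beta per-cycle decay factor.
#' @return `beta_w * alpha_beta^k`.
#' @export
decay_beta <- function(beta_w, k = 1L, alpha_beta = 0.99) {
  if (k < 0) stop("k must be nonnegative")
  beta_w * alpha_beta^k
}

#' One covariance adaptation step
#'
#' The elementwise update `w' = alpha_w w + beta_w r_post r_pre` applied to
#' existing connections only; a reference implementation of the rule the
#' compiled kernel applies at every gated step.
#'
#' @param w weight (vectorized).
#' @param r_pre,r_post pre- and postsynaptic firing rates in `[0, 1]`.
#' @param beta_w adaptation step size.
#' @param alpha_w per-step decay factor `1 - h/tau_w`.
#' @return Updated weight(s).
#' @export
adapt_step <- function(w, r_pre, r_post, beta_w, alpha_w = 1 - 0.001 / 2.5) {
  alpha_w * w + beta_w * r_post * r_pre
}
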