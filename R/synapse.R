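# Tsodyks-Markram short-term synaptic plasticity: exponential relaxation,
# spike-triggered jumps, the closed-form periodic-drive steady state, and
# weighted PSC aggregation.

#' Relax Tsodyks-Markram state variables over one time step
#'
#' Exact exponential relaxation (no spike effects): the utilization `u`
#' decays towards 0 with time constant `tau_f`, the available resources
#' `x` recover towards 1 with `tau_d`, and the postsynaptic current
#' `I_psc` decays towards 0 with `tau_s`. Exact (rather than Euler)
#' relaxation is unconditionally stable and testable against the
#' analytic exponential.
#'
#' @param state List with numeric vectors `u`, `x`, `I_psc`.
#' @param params List with `tau_f`, `tau_d`, `tau_s` (ms).
#' @param dt Time step (ms).
#' @return Updated state list.
#' @export
tm_decay <- function(state, params, dt) {
  if (dt <= 0) stop("dt must be > 0")
  state$u <- state$u * exp(-dt / params$tau_f)
  state$x <- 1 - (1 - state$x) * exp(-dt / params$tau_d)
  state$I_psc <- state$I_psc * exp(-dt / params$tau_s)
  state
}

#' Apply spike-triggered Tsodyks-Markram jumps
#'
#' For every synapse flagged by `spike_mask` (presynaptic spikes arriving
#' this step, already delay-shifted by the caller), the jump rules are
#' applied in the standard order: first the utilization increases,
#' `u+ = u- + U (1 - u-)`; the released current uses the post-jump
#' utilization and pre-jump resources, `dI = A u+ x-`; then the resources
#' deplete, `x+ = x- - u+ x-`. Unflagged entries are untouched.
#'
#' @param state List with numeric vectors `u`, `x`, `I_psc`.
#' @param params List with `U` (utilization increment) and `A` (absolute
#'   synaptic response, signed by the presynaptic type).
#' @param spike_mask Logical vector, one entry per synapse state.
#' @return Updated state list.
#' @export
tm_spike_update <- function(state, params, spike_mask) {
  if (!any(spike_mask)) return(state)
  u0 <- state$u[spike_mask]
  x0 <- state$x[spike_mask]
  u1 <- u0 + params$U * (1 - u0)
  state$I_psc[spike_mask] <- state$I_psc[spike_mask] + params$A * u1 * x0
  state$u[spike_mask] <- u1
  state$x[spike_mask] <- x0 - u1 * x0
  state
}

#' Steady state of a periodically driven Tsodyks-Markram synapse
#'
#' Closed-form fixed point of the spike-to-spike map under periodic
#' presynaptic firing at `rate_hz` (inter-spike interval
#' `T = 1000 / rate_hz` ms). With `eF = exp(-T/tau_f)` and
#' `eD = exp(-T/tau_d)`:
#' `u_ss = U / (1 - (1 - U) eF)` (evaluated just after the jump),
#' `x_ss = (1 - eD) / (1 - (1 - u_ss) eD)` (just before the jump), and
#' the steady-state PSC jump amplitude is `A u_ss x_ss`. For depressing
#' parameters the amplitude decreases with rate — the synaptic
#' suppression mechanism by which high-frequency stimulation throttles
#' transmission.
#'
#' @param params List with `U`, `tau_f`, `tau_d`, `A`.
#' @param rate_hz Presynaptic firing rate (Hz), > 0.
#' @return List with `u_ss`, `x_ss`, `amplitude_ss`.
#' @examples
#' dep <- list(U = 0.5, tau_f = 17, tau_d = 671, A = 1)
#' tm_steady_state(dep, 130)$amplitude_ss < tm_steady_state(dep, 20)$amplitude_ss
#' @export
tm_steady_state <- function(params, rate_hz) {
  if (!is.numeric(rate_hz) || any(rate_hz <= 0))
    stop("rate_hz must be > 0")
  T_ms <- 1000 / rate_hz
  eF <- exp(-T_ms / params$tau_f)
  eD <- exp(-T_ms / params$tau_d)
  u_ss <- params$U / (1 - (1 - params$U) * eF)
  x_ss <- (1 - eD) / (1 - (1 - u_ss) * eD)
  list(u_ss = u_ss, x_ss = x_ss, amplitude_ss = params$A * u_ss * x_ss)
}

#' Aggregate presynaptic PSCs into per-neuron input currents
#'
#' The synaptic input of each postsynaptic neuron is the weight-matrix
#' product of the (delay-shifted) presynaptic PSC vector: a linear map in
#' both arguments. `weights` has one row per postsynaptic neuron and one
#' column per presynaptic neuron.
#'
#' @param weights Numeric matrix (n_post x n_pre).
#' @param class_psc Numeric vector of presynaptic PSC values (length n_pre).
#' @return Numeric vector of per-neuron synaptic input (length n_post).
#' @export
aggregate_psc <- function(weights, class_psc) {
  if (!is.matrix(weights)) weights <- matrix(weights, nrow = 1)
  if (ncol(weights) != length(class_psc))
    stop("weight matrix has ", ncol(weights),
         " columns but PSC vector has length ", length(class_psc))
  as.numeric(weights %*% class_psc)
}
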