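# Izhikevich neuron dynamics: drift, noisy Euler stepping with reset, and
# population realization with per-neuron heterogeneity.

#' Izhikevich membrane drift
#'
#' Right-hand side of the two-variable Izhikevich model:
#' `dv/dt = 0.04 v^2 + 5 v - u + 140 + I` and `du/dt = a (b v - u)`.
#' A pure function of the current state; no reset logic, no noise.
#'
#' @param v Membrane voltage vector (mV).
#' @param u Recovery variable vector.
#' @param I_total Total input current per neuron (bias + synaptic +
#'   background + DBS), same length as `v`.
#' @param params List with numeric vectors (or scalars) `a` and `b`.
#' @return List with components `dv_dt` and `du_dt`.
#' @examples
#' izhikevich_drift(-70, -14, 0, list(a = 0.02, b = 0.2))  # rest fixed point
#' @export
izhikevich_drift <- function(v, u, I_total, params) {
  n <- length(v)
  if (length(u) != n || length(I_total) != n)
    stop("v, u and I_total must have the same length")
  list(
    dv_dt = 0.04 * v^2 + 5 * v - u + 140 + I_total,
    du_dt = params$a * (params$b * v - u)
  )
}

#' Advance a population of Izhikevich neurons by one time step
#'
#' Explicit Euler step of the membrane and recovery equations with
#' Gaussian membrane noise added to `v` and noisy spike-threshold
#' detection. A neuron spikes when `v >= v_peak + zeta`, with `zeta`
#' drawn fresh per neuron per step from `N(0, threshold_noise_std)`;
#' spiking neurons are reset (`v -> c`, `u -> u + d`) and their recorded
#' voltage for the spike step is clamped to `v_peak`.
#'
#' Two noise conventions are supported. `per_step` adds
#' `N(0, membrane_noise_std)` once per step regardless of `dt` (the noise
#' term is deliberately not multiplied by the time step). `sqrt_dt` adds
#' `membrane_noise_std * sqrt(dt) * N(0,1)`, the stochastic-Euler form
#' whose ensemble variance grows as `sigma^2 * t` independently of `dt`;
#' the two coincide at `dt = 1` ms. Noise draws use R's RNG; seed the
#' stream before calling for reproducibility.
#'
#' @param state List with numeric vectors `v` and `u`.
#' @param I_total Total input current per neuron.
#' @param params List of per-neuron parameter vectors `a`, `b`, `c`, `d`,
#'   `v_peak` (scalars are recycled).
#' @param noise List with `membrane_noise_std`, `threshold_noise_std` and
#'   `noise_mode` (`"per_step"` or `"sqrt_dt"`).
#' @param dt Time step in ms.
#' @param drift If `FALSE`, the deterministic drift is suppressed and only
#'   noise acts on `v` (used to validate the noise integrator against the
#'   analytic Wiener-process variance).
#' @param xi,zeta Optional pre-drawn noise vectors (one value per neuron)
#'   overriding the internal draws; used for cross-engine equivalence
#'   checks. `xi` is on the standard-normal scale and is scaled by the
#'   configured standard deviation internally; `zeta` likewise.
#' @return List with `state` (updated `v`, `u`), `spiked` (logical mask)
#'   and `v_record` (voltage to record for this step, clamped to
#'   `v_peak` on spike steps).
#' @export
step_neurons <- function(state, I_total, params, noise, dt,
                         drift = TRUE, xi = NULL, zeta = NULL) {
  v <- state$v
  u <- state$u
  n <- length(v)
  if (n == 0L)
    return(list(state = state, spiked = logical(0), v_record = numeric(0)))

  if (drift) {
    dd <- izhikevich_drift(v, u, I_total, params)
    v <- v + dt * dd$dv_dt
    u <- u + dt * dd$du_dt
  }

  sd_xi <- noise$membrane_noise_std
  if (sd_xi > 0 || !is.null(xi)) {
    if (is.null(xi)) xi <- stats::rnorm(n)
    scale <- if (identical(noise$noise_mode, "per_step")) sd_xi
             else sd_xi * sqrt(dt)
    v <- v + scale * xi
  }

  if (any(!is.finite(v)) || any(!is.finite(u)))
    stop("numerical blow-up: non-finite membrane state after update ",
         "(reduce dt_ms or input current)")

  sd_zeta <- noise$threshold_noise_std
  thr <- params$v_peak
  if (sd_zeta > 0 || !is.null(zeta)) {
    if (is.null(zeta)) zeta <- stats::rnorm(n)
    thr <- thr + sd_zeta * zeta
  }
  spiked <- v >= thr

  v_record <- v
  if (any(spiked)) {
    v_record[spiked] <- rep_len(params$v_peak, n)[spiked]
    v[spiked] <- rep_len(params$c, n)[spiked]
    u[spiked] <- u[spiked] + rep_len(params$d, n)[spiked]
  }

  list(state = list(v = v, u = u), spiked = spiked, v_record = v_record)
}

#' Realize a neuron population from its specification
#'
#' Draws per-neuron Izhikevich parameters around the archetype values and
#' returns the parameter arrays together with the initial state. The
#' heterogeneity scheme is the canonical Izhikevich randomization scaled
#' by `heterogeneity_scale` (h): for excitatory populations
#' `c = c0 + 15 h r^2`, `d = d0 - 6 h r^2`; for inhibitory populations
#' `a` and `b` are perturbed by `0.08 h r` and `0.05 h r` along the
#' fast-spiking / low-threshold-spiking continuum (a in [0.02, 0.1],
#' b in [0.2, 0.25]), directed away from the archetype's own end so the
#' perturbed values stay inside the canonical range. One `r ~ U(0,1)` is
#' drawn per neuron. With `h = 0` all neurons are identical. Initial conditions are
#' `v0 = c` (the post-heterogeneity reset value) and `u0 = b * v0`.
#'
#' @param spec A population specification (one element of
#'   `cfg$populations`, with `n_neurons`, `excitatory`, `bias_current`).
#' @param archetype_params Archetype parameter list (`a`, `b`, `c`, `d`,
#'   `v_peak`, `heterogeneity_scale`).
#' @param heterogeneity_scale Overrides the archetype's scale if not `NULL`.
#' @return List with per-neuron vectors `a`, `b`, `c`, `d`, `v_peak`,
#'   `bias`, and `state` (initial `v`, `u`). All vectors have length
#'   `spec$n_neurons` (possibly 0).
#' @export
make_population <- function(spec, archetype_params,
                            heterogeneity_scale = NULL) {
  n <- spec$n_neurons
  ap <- archetype_params
  if (is.null(ap)) stop("unknown neuron archetype: ", spec$neuron_archetype)
  h <- heterogeneity_scale %||% ap$heterogeneity_scale
  a <- rep(ap$a, n); b <- rep(ap$b, n)
  c_ <- rep(ap$c, n); d <- rep(ap$d, n)
  if (n > 0 && h > 0) {
    r <- stats::runif(n)
    if (isTRUE(spec$excitatory)) {
      c_ <- c_ + 15 * h * r^2
      d <- d - 6 * h * r^2
    } else {
      dir_a <- if (ap$a < 0.06) 1 else -1   # away from the archetype's end
      dir_b <- if (ap$b < 0.225) 1 else -1
      a <- a + dir_a * 0.08 * h * r
      b <- b + dir_b * 0.05 * h * r
    }
  }
  v0 <- c_
  list(a = a, b = b, c = c_, d = d,
       v_peak = rep(ap$v_peak, n),
       bias = rep(spec$bias_current, n),
       state = list(v = v0, u = b * v0))
}
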