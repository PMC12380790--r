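# Simulation engine: per-step update (delayed PSC aggregation, neuron
# stepping, TM synapse updates, DBS injection, background events) and the
# top-level simulate() driver.
#
# Three interchangeable engines implement the identical per-step
# algorithm:
#   "cpp"       compiled vectorized loop (default; used for full runs),
#   "r"         vectorized R loop built from the exported module
#               operations (update_time_step),
#   "reference" naive scalar loops over neurons and synapses
#               (simulate_reference; the validation oracle).
#
# Step s (time t = (s-1)*dt) executes, in this fixed order:
#   1. read the delay-shifted presynaptic PSC of every projection and
#      aggregate it into per-neuron synaptic currents;
#   2. add bias, background events (if enabled) and the DBS current
#      (target structure only);
#   3. Euler-step all neurons with membrane noise, detect spikes against
#      the noisy threshold, reset;
#   4. relax all TM synapse states (tm_decay), then apply the
#      spike-triggered jumps for this step's presynaptic spikes
#      (tm_spike_update);
#   5. push the new per-class PSC values into the delay buffers;
#   6. record spikes at time s*dt.
# Conduction delays act at delivery (step 1): a presynaptic spike at
# step s first reaches its targets at step s + delay_steps. The minimum
# latency is one step. The sign of each connection is applied exactly
# once, through the weight matrix; the TM state tracks the unsigned PSC
# magnitude (|A|).

# Build the mutable engine state for a network.
init_engine_state <- function(net) {
  sn <- .structure_names
  pops <- net$populations
  n_per <- net$n_per

  glue <- function(field) unlist(lapply(pops, function(p) p[[field]]),
                                 use.names = FALSE)
  params <- list(a = glue("a"), b = glue("b"), c = glue("c"), d = glue("d"),
                 v_peak = glue("v_peak"))
  bias <- glue("bias")
  v <- unlist(lapply(pops, function(p) p$state$v), use.names = FALSE)
  u <- unlist(lapply(pops, function(p) p$state$u), use.names = FALSE)

  # projections with a realized weight matrix
  proj <- list()
  for (tj in 1:6) for (sj in 1:6) {
    if (!is.null(net$weights[[tj]][[sj]]))
      proj[[length(proj) + 1L]] <- list(tj = tj, sj = sj,
                                        k = net$delays_steps[tj, sj])
  }
  max_k <- if (length(proj)) max(vapply(proj, `[[`, numeric(1), "k")) else 1
  n_hist <- as.integer(max_k + 1)

  tm <- lapply(stats::setNames(sn, sn), function(s) {
    n <- n_per[[s]]
    lapply(stats::setNames(.synapse_classes, .synapse_classes), function(cl)
      list(u = numeric(n), x = rep(1, n), I_psc = numeric(n)))
  })
  buf <- lapply(stats::setNames(sn, sn), function(s)
    lapply(stats::setNames(.synapse_classes, .synapse_classes), function(cl)
      matrix(0, n_hist, n_per[[s]])))

  list(v = v, u = u, params = params, bias = bias,
       tm = tm, buf = buf, n_hist = n_hist, proj = proj)
}

.buf_row <- function(step, n_hist) ((step - 1L) %% n_hist) + 1L

#' Execute one time step of the full network update
#'
#' Advances the engine state by one step of the fixed per-step algorithm
#' (delayed PSC aggregation, current summation, noisy neuron stepping,
#' TM relaxation and spike jumps, delay-buffer push). This is the
#' vectorized R implementation; [simulate()] wraps it in a loop when
#' `engine = "r"` and runs a compiled equivalent when `engine = "cpp"`.
#'
#' @param net A `tcm_network`.
#' @param state Engine state from the previous step (created internally
#'   by [simulate()]).
#' @param step Step index (1-based).
#' @param cfg The simulation configuration.
#' @param dbs_value DBS current for this step (scalar).
#' @param xi,zeta Optional pre-drawn standard-normal noise vectors
#'   (length = live neuron count).
#' @param background Optional per-neuron background current for this step.
#' @return List with `state` (advanced), `spiked` (logical per neuron),
#'   `I_syn` (per-neuron synaptic input used this step) and `v_record`.
#' @export
update_time_step <- function(net, state, step, cfg, dbs_value = 0,
                             xi = NULL, zeta = NULL, background = NULL) {
  n <- net$n_total
  I_syn <- numeric(n)
  mix <- net$synapse_mix
  for (p in state$proj) {
    tj <- p$tj; sj <- p$sj
    row <- .buf_row(step - p$k, state$n_hist)
    eff <- numeric(net$n_per[[sj]])
    for (cl in .synapse_classes) {
      f <- mix[[cl]][tj, sj]
      if (f > 0) eff <- eff + f * state$buf[[sj]][[cl]][row, ]
    }
    idx <- (net$offsets[[tj]] + 1):(net$offsets[[tj]] + net$n_per[[tj]])
    I_syn[idx] <- I_syn[idx] + aggregate_psc(net$weights[[tj]][[sj]], eff)
  }

  I_total <- state$bias + I_syn
  if (!is.null(background)) I_total <- I_total + background
  if (dbs_value != 0) {
    tgt <- cfg$dbs$target_structure
    nm <- .structure_names[tgt]
    if (net$n_per[[nm]] > 0) {
      idx <- (net$offsets[[nm]] + 1):(net$offsets[[nm]] + net$n_per[[nm]])
      I_total[idx] <- I_total[idx] + dbs_value
    }
  }

  stepped <- step_neurons(list(v = state$v, u = state$u), I_total,
                          state$params, cfg$noise, cfg$dt_ms,
                          xi = xi, zeta = zeta)
  state$v <- stepped$state$v
  state$u <- stepped$state$u
  spiked <- stepped$spiked

  row_now <- .buf_row(step, state$n_hist)
  for (s in .structure_names) {
    ns <- net$n_per[[s]]
    if (ns == 0) next
    idx <- (net$offsets[[s]] + 1):(net$offsets[[s]] + ns)
    mask <- spiked[idx]
    for (cl in .synapse_classes) {
      prm <- net$tm_params[[s]][[cl]]
      prm_abs <- list(U = prm$U, tau_f = prm$tau_f, tau_d = prm$tau_d,
                      tau_s = prm$tau_s, A = abs(prm$A))
      st <- tm_decay(state$tm[[s]][[cl]], prm_abs, cfg$dt_ms)
      st <- tm_spike_update(st, prm_abs, mask)
      # flush to the no-activity fixed point below 1e-12 (identical rule
      # in all engines): avoids decay into slow subnormal arithmetic
      st$u[st$u < 1e-12] <- 0
      st$x[st$x > 1 - 1e-12] <- 1
      st$I_psc[st$I_psc < 1e-12 & st$I_psc > -1e-12] <- 0
      state$tm[[s]][[cl]] <- st
      state$buf[[s]][[cl]][row_now, ] <- st$I_psc
    }
  }

  list(state = state, spiked = spiked, I_syn = I_syn,
       v_record = stepped$v_record)
}

#' Sample Poissonian background events for one step
#'
#' Each neuron independently receives an event with probability
#' `rate * dt / 1000` in the step; an event contributes the background
#' amplitude to that neuron's input current for the step.
#'
#' @param noise The `noise` component of a configuration
#'   (`background_rate_hz` and `background_amplitude` may be scalars or
#'   one value per structure; per-structure values are expanded by the
#'   caller).
#' @param n_neurons Number of neurons to sample for.
#' @param dt Time step (ms).
#' @param rate_hz,amplitude Optional per-neuron overrides of the noise
#'   fields (vectors recycled to `n_neurons`).
#' @return Numeric vector of per-neuron event amplitudes (0 where no
#'   event occurred).
#' @export
sample_background_events <- function(noise, n_neurons, dt,
                                     rate_hz = NULL, amplitude = NULL) {
  rate <- rep_len(rate_hz %||% noise$background_rate_hz, n_neurons)
  amp <- rep_len(amplitude %||% noise$background_amplitude, n_neurons)
  p <- rate * dt / 1000
  amp * (stats::runif(n_neurons) < p)
}

# Expand per-structure background fields to per-neuron vectors.
.background_per_neuron <- function(cfg, net) {
  expand <- function(x) {
    x <- rep_len(x, 6)
    unlist(lapply(seq_along(.structure_names), function(j)
      rep(x[j], net$n_per[[j]])), use.names = FALSE)
  }
  list(rate = expand(cfg$noise$background_rate_hz),
       amp = expand(cfg$noise$background_amplitude))
}

#' Run a full network simulation
#'
#' Builds the network from the configuration, runs
#' `duration_s * 1000 / dt_ms` steps of the per-step update, and returns
#' the spike record plus metadata. Fully deterministic under a fixed
#' `cfg$seed` (per engine): the master seed is split into named
#' substreams (weights, heterogeneity, membrane noise, threshold noise,
#' background), so in the compiled engine toggling one noise source does
#' not shift the draws of the others.
#'
#' @param cfg A valid `tcm_config`.
#' @param engine `"cpp"` (compiled, default), `"r"` (vectorized R), or
#'   `"reference"` (naive scalar loops; see [simulate_reference()]).
#'   All three implement the identical algorithm and agree exactly when
#'   fed the same noise draws.
#' @param record_traces Record per-structure mean membrane voltage
#'   (defaults to `cfg$record_traces`).
#' @param noise_streams Optional list with matrices `xi` and/or `zeta`
#'   (`n_steps` x `n_neurons`, standard-normal) replacing the internal
#'   noise generation; used by cross-engine equivalence tests.
#' @return Object of class `tcm_result`: `spikes` (data frame with
#'   `neuron_id`, `structure`, `time_ms`, sorted by time), `traces`
#'   (NULL or list with `time_ms` and `mean_v`, one column per
#'   structure), `n_per`, `seed`, `dt_ms`, `duration_s`,
#'   `config_fingerprint`, `engine`.
#' @examples
#' \donttest{
#' cfg <- default_config(duration_s = 2)
#' cfg$dbs$onset_s <- 1
#' res <- simulate(cfg)
#' head(res$spikes)
#' }
#' @export
simulate <- function(cfg, engine = c("cpp", "r", "reference"),
                     record_traces = NULL, noise_streams = NULL) {
  engine <- match.arg(engine)
  record_traces <- record_traces %||% isTRUE(cfg$record_traces)
  net <- build_network(cfg)
  n_steps <- as.integer(round(cfg$duration_s * 1000 / cfg$dt_ms))
  dbs_wave <- dbs_waveform(cfg$dbs, cfg$duration_s, cfg$dt_ms)

  if (engine == "cpp") {
    raw <- .simulate_cpp(cfg, net, n_steps, dbs_wave, record_traces,
                         noise_streams)
  } else if (engine == "r") {
    raw <- .simulate_r(cfg, net, n_steps, dbs_wave, record_traces,
                       noise_streams)
  } else {
    raw <- .simulate_scalar(cfg, net, n_steps, dbs_wave, record_traces,
                            noise_streams)
  }

  spikes <- data.frame(
    neuron_id = raw$spike_id,
    structure = net$neuron_index$structure[raw$spike_id],
    time_ms = raw$spike_step * cfg$dt_ms,
    stringsAsFactors = FALSE
  )
  ord <- order(spikes$time_ms, spikes$neuron_id)
  spikes <- spikes[ord, , drop = FALSE]
  rownames(spikes) <- NULL

  traces <- NULL
  if (record_traces && !is.null(raw$mean_v)) {
    colnames(raw$mean_v) <- .structure_names
    traces <- list(time_ms = seq_len(n_steps) * cfg$dt_ms,
                   mean_v = raw$mean_v)
  }

  res <- list(spikes = spikes, traces = traces,
              n_per = net$n_per, n_total = net$n_total,
              seed = cfg$seed, dt_ms = cfg$dt_ms,
              duration_s = cfg$duration_s,
              dbs = cfg$dbs,
              config_fingerprint = object_fingerprint(unclass(cfg)),
              engine = engine)
  class(res) <- "tcm_result"
  res
}

# Vectorized R engine: a loop over update_time_step under a single seeded
# stream (membrane and threshold draws interleaved per step).
.simulate_r <- function(cfg, net, n_steps, dbs_wave, record_traces,
                        noise_streams) {
  state <- init_engine_state(net)
  n <- net$n_total
  spike_id <- integer(0); spike_step <- integer(0)
  mean_v <- if (record_traces) matrix(NA_real_, n_steps, 6) else NULL
  bg <- if (isTRUE(cfg$noise$background_enabled))
    .background_per_neuron(cfg, net) else NULL

  set.seed(substream_seed(cfg$seed, "membrane"))
  use_xi <- cfg$noise$membrane_noise_std > 0
  use_zeta <- cfg$noise$threshold_noise_std > 0
  for (s in seq_len(n_steps)) {
    xi <- if (!is.null(noise_streams$xi)) noise_streams$xi[s, ]
          else if (use_xi && n > 0) stats::rnorm(n) else NULL
    zeta <- if (!is.null(noise_streams$zeta)) noise_streams$zeta[s, ]
            else if (use_zeta && n > 0) stats::rnorm(n) else NULL
    background <- if (!is.null(bg))
      sample_background_events(cfg$noise, n, cfg$dt_ms,
                               rate_hz = bg$rate, amplitude = bg$amp)
      else NULL
    upd <- update_time_step(net, state, s, cfg, dbs_wave[s],
                            xi = xi, zeta = zeta, background = background)
    state <- upd$state
    if (any(upd$spiked)) {
      ids <- which(upd$spiked)
      spike_id <- c(spike_id, ids)
      spike_step <- c(spike_step, rep.int(s, length(ids)))
    }
    if (record_traces) {
      for (j in 1:6) {
        nj <- net$n_per[[j]]
        if (nj > 0)
          mean_v[s, j] <- mean(upd$v_record[(net$offsets[[j]] + 1):(net$offsets[[j]] + nj)])
      }
    }
  }
  list(spike_id = spike_id, spike_step = spike_step, mean_v = mean_v)
}

# Compiled engine: marshal the network into flat structures and call the
# C++ core. Noise is generated inside from named substream seeds.
.simulate_cpp <- function(cfg, net, n_steps, dbs_wave, record_traces,
                          noise_streams) {
  proj <- list()
  for (tj in 1:6) for (sj in 1:6) {
    if (is.null(net$weights[[tj]][[sj]])) next
    proj[[length(proj) + 1L]] <- list(
      tj = tj - 1L, sj = sj - 1L,
      W = net$weights[[tj]][[sj]],
      k = as.integer(net$delays_steps[tj, sj]),
      mix = vapply(.synapse_classes, function(cl)
        net$synapse_mix[[cl]][tj, sj], numeric(1))
    )
  }
  tm_par <- lapply(1:6, function(sj) {
    lapply(.synapse_classes, function(cl) {
      p <- net$tm_params[[sj]][[cl]]
      c(U = p$U, tau_f = p$tau_f, tau_d = p$tau_d, tau_s = p$tau_s,
        A = abs(p$A))
    })
  })
  glue <- function(field) unlist(lapply(net$populations, `[[`, field),
                                 use.names = FALSE)
  bg <- .background_per_neuron(cfg, net)
  st <- init_engine_state(net)
  run_tcm_cpp(
    n_steps = n_steps, dt = cfg$dt_ms,
    n_per = as.integer(net$n_per), offsets = as.integer(net$offsets),
    a = st$params$a, b = st$params$b, c_ = st$params$c, d = st$params$d,
    v_peak = st$params$v_peak, bias = st$bias,
    v0 = st$v, u0 = st$u,
    proj = proj, tm_par = tm_par, n_hist = st$n_hist,
    dbs_wave = dbs_wave, dbs_target = as.integer(cfg$dbs$target_structure) - 1L,
    sigma_xi = cfg$noise$membrane_noise_std,
    sigma_zeta = cfg$noise$threshold_noise_std,
    per_step = identical(cfg$noise$noise_mode, "per_step"),
    bg_enabled = isTRUE(cfg$noise$background_enabled),
    bg_rate = bg$rate, bg_amp = bg$amp,
    seed_membrane = substream_seed(cfg$seed, "membrane"),
    seed_threshold = substream_seed(cfg$seed, "threshold"),
    seed_background = substream_seed(cfg$seed, "background"),
    record_traces = record_traces,
    xi_stream = noise_streams$xi %||% matrix(0, 0, 0),
    zeta_stream = noise_streams$zeta %||% matrix(0, 0, 0)
  )
}

#' @export
print.tcm_result <- function(x, ...) {
  cat("Simulation result:", nrow(x$spikes), "spikes from", x$n_total,
      "neurons over", x$duration_s, "s (dt", x$dt_ms, "ms, seed",
      x$seed, ", engine", x$engine, ")\n")
  if (nrow(x$spikes)) {
    tab <- table(factor(x$spikes$structure, levels = .structure_names))
    cat("  spikes per structure:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write a spike record to CSV
#'
#' @param result A `tcm_result` (or its `spikes` data frame).
#' @param path Output path; columns `neuron_id,structure,time_ms`.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(result, path) {
  spikes <- if (inherits(result, "tcm_result")) result$spikes else result
  utils::write.csv(spikes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spike record written by [write_spikes()]
#'
#' @param path CSV path.
#' @return Data frame with `neuron_id`, `structure`, `time_ms`.
#' @export
read_spikes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(neuron_id = "integer",
                                 structure = "character",
                                 time_ms = "numeric"))
}
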