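# Shared fixtures: small deterministic networks and hand-built results.

# Three-population toy (S, M excitatory + CI inhibitory, n neurons each),
# suprathreshold bias so it spikes without noise; noise off by default.
toy_config <- function(n = 10, duration_s = 1, seed = 1,
                       noise = FALSE, bias = c(6, 5.5, 5)) {
  cfg <- default_config(duration_s = duration_s, seed = seed)
  for (nm in c("D", "TRN", "TCR")) cfg <- deactivate_population(cfg, nm)
  for (nm in c("S", "M", "CI")) cfg$populations[[nm]]$n_neurons <- as.integer(n)
  cfg$populations$S$bias_current <- bias[1]
  cfg$populations$M$bias_current <- bias[2]
  cfg$populations$CI$bias_current <- bias[3]
  if (!noise) {
    cfg$noise$membrane_noise_std <- 0
    cfg$noise$threshold_noise_std <- 0
  }
  cfg$dbs$amplitude <- 0
  cfg
}

# Standard-normal noise stream matrices shared across engines.
make_streams <- function(n_steps, n_neurons, seed = 99) {
  set.seed(seed)
  list(xi = matrix(rnorm(n_steps * n_neurons), n_steps, n_neurons),
       zeta = matrix(rnorm(n_steps * n_neurons), n_steps, n_neurons))
}

# Hand-built minimal result object for analysis tests.
make_result <- function(spikes, n_per = c(S = 100, M = 0, D = 0, CI = 0,
                                          TRN = 0, TCR = 0),
                        duration_s = 12, dt_ms = 0.1,
                        dbs = list(frequency_hz = 130, amplitude = 100,
                                   onset_s = 6, offset_s = 12,
                                   target_structure = 3)) {
  res <- list(spikes = spikes, traces = NULL, n_per = n_per,
              n_total = sum(n_per), seed = 1L, dt_ms = dt_ms,
              duration_s = duration_s, dbs = dbs,
              config_fingerprint = "test", engine = "synthetic")
  class(res) <- "tcm_result"
  res
}

spike_df <- function(neuron_id, structure, time_ms) {
  data.frame(neuron_id = as.integer(neuron_id), structure = structure,
             time_ms = time_ms, stringsAsFactors = FALSE)
}

# Step a single Izhikevich neuron population for n_steps under constant
# input; returns total spike count. Used for archetype-level properties.
count_spikes <- function(params_list, I, n_steps, dt = 0.1, n = 1,
                         noise = list(membrane_noise_std = 0,
                                      threshold_noise_std = 0,
                                      noise_mode = "sqrt_dt")) {
  state <- list(v = rep(params_list$c, n),
                u = rep(params_list$b * params_list$c, n))
  total <- 0L
  for (s in seq_len(n_steps)) {
    out <- step_neurons(state, rep(I, n), params_list, noise, dt)
    state <- out$state
    total <- total + sum(out$spiked)
  }
  total
}
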