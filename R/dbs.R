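# DBS pulse-train generation and targeted injection.

#' DBS pulse train definition
#'
#' Computes the pulse onset times of a DBS protocol over a simulation of
#' given length. Pulses start at `onset_s` and repeat with period
#' `1000 / frequency_hz` ms; a pulse whose onset falls at or beyond
#' `offset_s` (or the end of the simulation) is dropped, and a pulse
#' straddling the offset is clipped by the waveform sampler.
#'
#' @param protocol The `dbs` component of a `tcm_config`.
#' @param duration_s Simulation length (s).
#' @param dt_ms Time step (ms).
#' @return List with `pulse_onsets_ms` (sorted, strictly increasing),
#'   `width_ms`, `amplitude`, `n_steps`, `dt_ms`.
#' @export
make_pulse_train <- function(protocol, duration_s, dt_ms) {
  n_steps <- round(duration_s * 1000 / dt_ms)
  if (protocol$frequency_hz <= 0 || protocol$amplitude == 0) {
    return(list(pulse_onsets_ms = numeric(0), width_ms = protocol$pulse_width_ms,
                amplitude = protocol$amplitude, n_steps = n_steps, dt_ms = dt_ms))
  }
  period_ms <- 1000 / protocol$frequency_hz
  if (protocol$pulse_width_ms >= period_ms)
    stop("pulse width (", protocol$pulse_width_ms,
         " ms) must be smaller than the pulse period (", period_ms, " ms)")
  t_end <- min(protocol$offset_s, duration_s) * 1000
  onset <- protocol$onset_s * 1000
  if (onset >= t_end)
    return(list(pulse_onsets_ms = numeric(0), width_ms = protocol$pulse_width_ms,
                amplitude = protocol$amplitude, n_steps = n_steps, dt_ms = dt_ms))
  k_max <- ceiling((t_end - onset) / period_ms) + 1
  onsets <- onset + period_ms * (0:k_max)
  onsets <- onsets[onsets < t_end - 1e-9]
  list(pulse_onsets_ms = onsets, width_ms = protocol$pulse_width_ms,
       amplitude = protocol$amplitude, n_steps = n_steps, dt_ms = dt_ms)
}

#' Sample the DBS current waveform
#'
#' Returns the per-step DBS current: monophasic rectangular pulses of the
#' protocol's amplitude and width at exact period `1000/frequency_hz` ms,
#' zero before onset and after offset. Sample `s` (at time
#' `t = (s-1) * dt_ms`) carries the pulse amplitude iff `t` lies in
#' `[pulse_onset, pulse_onset + width)`. With `biphasic = TRUE` each
#' pulse is followed immediately by an equal-width pulse of opposite
#' sign (charge-balanced stimulation).
#'
#' @param protocol The `dbs` component of a `tcm_config`.
#' @param duration_s Simulation length (s).
#' @param dt_ms Time step (ms).
#' @param biphasic Use charge-balanced biphasic pulses (default FALSE).
#' @return Numeric vector of length `duration_s * 1000 / dt_ms`.
#' @examples
#' cfg <- default_config()
#' w <- dbs_waveform(cfg$dbs, cfg$duration_s, cfg$dt_ms)
#' sum(diff(w > 0) == 1)  # number of pulses
#' @export
dbs_waveform <- function(protocol, duration_s, dt_ms, biphasic = FALSE) {
  train <- make_pulse_train(protocol, duration_s, dt_ms)
  wave <- numeric(train$n_steps)
  t <- (seq_len(train$n_steps) - 1) * dt_ms
  t_end <- min(protocol$offset_s, duration_s) * 1000
  for (on in train$pulse_onsets_ms) {
    idx <- which(t >= on - 1e-9 & t < on + train$width_ms - 1e-9 &
                 t < t_end - 1e-9)
    wave[idx] <- wave[idx] + train$amplitude
    if (biphasic) {
      idx2 <- which(t >= on + train$width_ms - 1e-9 &
                    t < on + 2 * train$width_ms - 1e-9 & t < t_end - 1e-9)
      wave[idx2] <- wave[idx2] - train$amplitude
    }
  }
  wave
}

#' Distribute one step's DBS current over the network
#'
#' Every neuron of the target structure receives the step's DBS current
#' value; all other neurons receive exactly zero (Kronecker-delta
#' targeting, by default the deep cortical layer D). A deactivated target
#' yields an all-zero increment.
#'
#' @param step_value DBS current at this step (scalar).
#' @param network A `tcm_network`.
#' @param target_structure Structure id in 1..6 (default 3 = D).
#' @return Numeric vector with one entry per live neuron.
#' @export
apply_dbs <- function(step_value, network, target_structure = 3L) {
  out <- numeric(network$n_total)
  nm <- .structure_names[target_structure]
  n <- network$n_per[[nm]]
  if (n > 0 && step_value != 0) {
    i0 <- network$offsets[[nm]]
    out[(i0 + 1):(i0 + n)] <- step_value
  }
  out
}

#' Write a DBS waveform to CSV
#'
#' @param wave Waveform vector from [dbs_waveform()].
#' @param dt_ms Time step (ms).
#' @param path Output CSV path (columns `time_ms`, `current`).
#' @return `path`, invisibly.
#' @export
write_dbs_waveform <- function(wave, dt_ms, path) {
  utils::write.csv(
    data.frame(time_ms = (seq_along(wave) - 1) * dt_ms, current = wave),
    path, row.names = FALSE)
  invisible(path)
}
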