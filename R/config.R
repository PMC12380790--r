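# Model configuration: defaults, validation, YAML (de)serialization.
#
# Units convention (used throughout the package): membrane voltage in mV,
# time in ms, currents on the dimensionless Izhikevich current scale.
# Structures are indexed j = 1..6 in the fixed order S, M, D, CI, TRN, TCR.

.structure_names <- c("S", "M", "D", "CI", "TRN", "TCR")
.synapse_classes <- c("F", "D", "P")
.config_schema_version <- 1L

#' Structure names of the thalamo-cortical model
#'
#' The six populations in their canonical index order: the supragranular
#' (S), middle (M) and deep (D) excitatory cortical layers, the shared
#' cortical interneurons (CI), the thalamic reticular nucleus (TRN) and
#' the thalamocortical relay nucleus (TCR).
#'
#' @return Character vector of length 6.
#' @export
structure_names <- function() .structure_names

#' Default simulation configuration
#'
#' Returns the reference configuration of the model: 540 neurons across
#' six populations (S, M, D, CI = 100 each, TRN = 40, TCR = 100), a 12 s
#' simulation at dt = 0.1 ms, Gaussian membrane noise with standard
#' deviation 0.5 and threshold noise with standard deviation 0.1,
#' Poissonian background input disabled, and a 130 Hz DBS pulse train
#' injected into the deep cortical layer (D) from second 6 to the end of
#' the run.
#'
#' Neuron archetypes, Tsodyks-Markram synapse classes, coupling gains and
#' conduction delays ship as documented, fully overridable defaults: the
#' archetypes are canonical Izhikevich parameter sets (regular spiking for
#' the excitatory populations, fast spiking for CI, low-threshold spiking
#' for TRN), the synapse classes are canonical facilitating / depressing /
#' pseudo-linear triplets, and the gain magnitudes are tuned only to
#' reproduce the qualitative network states (synchronized beta-band
#' activity at rest and under 20 Hz DBS, desynchronization under 130 Hz
#' DBS). See the package vignette for the rationale behind each value.
#'
#' @param duration_s Simulation length in seconds (default 12).
#' @param seed Master seed for all random number streams (default 1).
#' @return An object of class `tcm_config` (a nested named list).
#' @examples
#' cfg <- default_config()
#' sum(vapply(cfg$populations, function(p) p$n_neurons, numeric(1)))
#' @export
default_config <- function(duration_s = 12, seed = 1L) {
  pop <- function(id, n, exc, arch, bias) {
    list(structure_id = id, n_neurons = n, excitatory = exc,
         neuron_archetype = arch, bias_current = bias)
  }
  # Bias currents sit just below each archetype's rheobase (4.0 for the
  # RS cells at b = 0.2), so firing is noise-driven; CI and TRN are
  # driven mainly by their synaptic input.
  populations <- list(
    S   = pop(1L, 100L, TRUE,  "RS",  3.9),
    M   = pop(2L, 100L, TRUE,  "RS",  3.9),
    D   = pop(3L, 100L, TRUE,  "RS",  3.9),
    CI  = pop(4L, 100L, FALSE, "FS",  0.8),
    TRN = pop(5L,  40L, FALSE, "LTS", 0.8),
    TCR = pop(6L, 100L, TRUE,  "RS",  3.2)
  )

  neuron_params <- list(
    RS  = list(a = 0.02, b = 0.2,  c = -65, d = 8, v_peak = 30,
               heterogeneity_scale = 1),
    FS  = list(a = 0.1,  b = 0.2,  c = -65, d = 2, v_peak = 30,
               heterogeneity_scale = 1),
    LTS = list(a = 0.02, b = 0.25, c = -65, d = 2, v_peak = 30,
               heterogeneity_scale = 1)
  )

  # Canonical short-term plasticity triplets for facilitating (F),
  # depressing (D) and pseudo-linear (P) synapses, split by presynaptic
  # type. A carries the sign of the presynaptic population; its magnitude
  # scales the PSC jump.
  synapse_params <- list(
    exc = list(
      F = list(U = 0.09, tau_f = 670, tau_d = 138, tau_s = 3, A = 1),
      D = list(U = 0.5,  tau_f = 17,  tau_d = 671, tau_s = 3, A = 1),
      P = list(U = 0.29, tau_f = 326, tau_d = 329, tau_s = 3, A = 1)
    ),
    inh = list(
      F = list(U = 0.016, tau_f = 376, tau_d = 45,  tau_s = 11, A = -1),
      D = list(U = 0.25,  tau_f = 21,  tau_d = 706, tau_s = 11, A = -1),
      P = list(U = 0.32,  tau_f = 62,  tau_d = 144, tau_s = 11, A = -1)
    )
  )

  # Gain magnitudes are tuned to place the unstimulated network in a
  # parkinsonian-like state: synchronized population bursts with elevated
  # beta-band power, sustained by strong recurrent cortical excitation
  # and paced by interneuron feedback and spike-frequency adaptation.
  sn <- .structure_names
  gain <- matrix(0, 6, 6, dimnames = list(target = sn, source = sn))
  # Excitatory cortical layers project to each other and to CI.
  gain[c("S", "M", "D", "CI"), "S"] <- c(10, 10, 10, 8)
  gain[c("S", "M", "D", "CI"), "M"] <- c(10, 10, 10, 8)
  gain[c("S", "M", "D", "CI"), "D"] <- c(10, 10, 10, 8)
  # D is the cortical output layer: drives thalamus.
  gain[c("TRN", "TCR"), "D"] <- c(2, 3)
  # CI inhibits the cortical populations.
  gain[c("S", "M", "D", "CI"), "CI"] <- c(-8, -8, -8, -4)
  # Thalamic loop: TCR excites cortex and TRN; TRN inhibits TCR.
  gain[c("S", "M", "D", "CI", "TRN"), "TCR"] <- c(3, 3, 3, 2, 3)
  gain[c("TRN", "TCR"), "TRN"] <- c(-2, -6)

  delay <- matrix(8, 6, 6, dimnames = list(target = sn, source = sn))
  ctx <- c("S", "M", "D", "CI"); thal <- c("TRN", "TCR")
  delay[ctx, ctx] <- 1
  delay[thal, thal] <- 1

  # F/D/P fractions per (target, source) pair; defaults depend on the
  # source type only and are depression-dominant.
  mix_exc <- c(F = 0.2, D = 0.65, P = 0.15)
  mix_inh <- c(F = 0.1, D = 0.7,  P = 0.2)
  synapse_mix <- lapply(stats::setNames(.synapse_classes, .synapse_classes),
    function(cl) {
      m <- matrix(0, 6, 6, dimnames = list(target = sn, source = sn))
      for (s in sn) {
        frac <- if (populations[[s]]$excitatory) mix_exc else mix_inh
        m[, s] <- frac[[cl]]
      }
      m
    })

  cfg <- list(
    schema_version = .config_schema_version,
    duration_s = duration_s,
    dt_ms = 0.1,
    seed = as.integer(seed),
    record_traces = FALSE,
    populations = populations,
    neuron_params = neuron_params,
    synapse_params = synapse_params,
    connectivity = list(
      weight_gain = gain,
      delay_ms = delay,
      weight_jitter = 0.1,
      synapse_mix = synapse_mix
    ),
    noise = list(
      membrane_noise_std = 0.5,
      threshold_noise_std = 0.1,
      noise_mode = "sqrt_dt",
      background_rate_hz = 10,
      background_amplitude = 5,
      background_enabled = FALSE
    ),
    dbs = list(
      frequency_hz = 130,
      amplitude = 120,
      pulse_width_ms = 0.3,
      onset_s = 6,
      offset_s = max(duration_s, 6),
      target_structure = 3L
    )
  )
  class(cfg) <- "tcm_config"
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant of the configuration and returns all
#' violations at once; the configuration is never modified. An empty
#' character vector means the configuration is valid.
#'
#' @param cfg A `tcm_config` object (or a compatible nested list).
#' @return Character vector of violation messages (empty if valid).
#' @examples
#' validate_config(default_config())
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config is not a list; cannot validate")
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)

  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

  if (!num1(cfg$duration_s) || cfg$duration_s <= 0)
    note("duration_s must be a positive number")
  if (!num1(cfg$dt_ms) || cfg$dt_ms <= 0)
    note("dt_ms must be a positive number")
  if (num1(cfg$duration_s) && num1(cfg$dt_ms) && cfg$dt_ms > 0) {
    n_steps <- cfg$duration_s * 1000 / cfg$dt_ms
    if (abs(n_steps - round(n_steps)) > 1e-6)
      note("duration_s / dt_ms must give an integer step count")
    if (cfg$dt_ms > 0.5)
      warning("dt_ms > 0.5 ms: the quadratic membrane term can make the ",
              "explicit Euler update unstable at this step size")
  }

  pops <- cfg$populations
  if (!is.list(pops) || !identical(sort(names(pops)), sort(.structure_names))) {
    note("populations must contain exactly S, M, D, CI, TRN, TCR")
    pops <- NULL
  }
  exc_default <- c(S = TRUE, M = TRUE, D = TRUE, CI = FALSE,
                   TRN = FALSE, TCR = TRUE)
  for (nm in names(pops)) {
    p <- pops[[nm]]
    if (!num1(p$n_neurons) || p$n_neurons < 0 ||
        p$n_neurons != round(p$n_neurons))
      note(sprintf("populations$%s$n_neurons must be a non-negative integer", nm))
    if (!isTRUE(p$excitatory == exc_default[[nm]]))
      note(sprintf("populations$%s$excitatory must be %s", nm,
                   exc_default[[nm]]))
    if (!is.character(p$neuron_archetype) ||
        !(p$neuron_archetype %in% names(cfg$neuron_params)))
      note(sprintf("populations$%s$neuron_archetype is not a defined archetype", nm))
    if (!num1(p$bias_current))
      note(sprintf("populations$%s$bias_current must be a finite number", nm))
  }

  for (arch in names(cfg$neuron_params)) {
    np <- cfg$neuron_params[[arch]]
    for (f in c("a", "b", "c", "d", "v_peak", "heterogeneity_scale"))
      if (!num1(np[[f]]))
        note(sprintf("neuron_params$%s$%s must be a finite number", arch, f))
    if (num1(np$a) && np$a <= 0)
      note(sprintf("neuron_params$%s$a must be > 0", arch))
    if (num1(np$v_peak) && num1(np$c) && np$v_peak <= np$c)
      note(sprintf("neuron_params$%s$v_peak must exceed the reset value c", arch))
    if (num1(np$heterogeneity_scale) && np$heterogeneity_scale < 0)
      note(sprintf("neuron_params$%s$heterogeneity_scale must be >= 0", arch))
  }

  for (side in c("exc", "inh")) {
    for (cl in .synapse_classes) {
      sp <- cfg$synapse_params[[side]][[cl]]
      if (is.null(sp)) { note(sprintf("synapse_params$%s$%s is missing", side, cl)); next }
      if (!num1(sp$U) || sp$U <= 0 || sp$U > 1)
        note(sprintf("synapse_params$%s$%s$U must be in (0, 1]", side, cl))
      for (f in c("tau_f", "tau_d", "tau_s"))
        if (!num1(sp[[f]]) || sp[[f]] <= 0)
          note(sprintf("synapse_params$%s$%s$%s must be > 0", side, cl, f))
      if (num1(sp$A)) {
        if (side == "exc" && sp$A < 0)
          note(sprintf("synapse_params$exc$%s$A must be >= 0 (excitatory source)", cl))
        if (side == "inh" && sp$A > 0)
          note(sprintf("synapse_params$inh$%s$A must be <= 0 (inhibitory source)", cl))
      } else note(sprintf("synapse_params$%s$%s$A must be a finite number", side, cl))
    }
  }

  conn <- cfg$connectivity
  is_mat6 <- function(m) is.matrix(m) && all(dim(m) == c(6, 6)) &&
    is.numeric(m) && all(is.finite(m))
  if (!is_mat6(conn$weight_gain)) {
    note("connectivity$weight_gain must be a finite 6x6 numeric matrix")
  } else if (!is.null(pops)) {
    for (s in .structure_names) {
      col <- conn$weight_gain[, match(s, .structure_names)]
      if (exc_default[[s]] && any(col < 0))
        note(sprintf("connectivity$weight_gain: gains from excitatory source %s must be >= 0", s))
      if (!exc_default[[s]] && any(col > 0))
        note(sprintf("connectivity$weight_gain: gains from inhibitory source %s must be <= 0", s))
    }
  }
  if (!is_mat6(conn$delay_ms)) {
    note("connectivity$delay_ms must be a finite 6x6 numeric matrix")
  } else {
    if (any(conn$delay_ms < 0))
      note("connectivity$delay_ms: all delays must be >= 0")
  }
  if (!num1(conn$weight_jitter) || conn$weight_jitter < 0 ||
      conn$weight_jitter >= 1)
    note("connectivity$weight_jitter must be in [0, 1)")
  mx <- conn$synapse_mix
  if (!is.list(mx) || !identical(sort(names(mx)), sort(.synapse_classes))) {
    note("connectivity$synapse_mix must have components F, D, P")
  } else if (all(vapply(mx, is_mat6, logical(1)))) {
    tot <- mx$F + mx$D + mx$P
    off <- which(abs(tot - 1) > 1e-12, arr.ind = TRUE)
    for (k in seq_len(nrow(off)))
      note(sprintf(
        "connectivity$synapse_mix fractions for target %s, source %s sum to %.6g (must be 1)",
        .structure_names[off[k, 1]], .structure_names[off[k, 2]],
        tot[off[k, 1], off[k, 2]]))
    if (any(unlist(mx) < 0))
      note("connectivity$synapse_mix fractions must be >= 0")
  } else note("connectivity$synapse_mix components must be 6x6 numeric matrices")

  nz <- cfg$noise
  if (!num1(nz$membrane_noise_std) || nz$membrane_noise_std < 0)
    note("noise$membrane_noise_std must be >= 0")
  if (!num1(nz$threshold_noise_std) || nz$threshold_noise_std < 0)
    note("noise$threshold_noise_std must be >= 0")
  if (!is.character(nz$noise_mode) ||
      !(nz$noise_mode %in% c("per_step", "sqrt_dt")))
    note("noise$noise_mode must be 'per_step' or 'sqrt_dt'")
  if (!is.numeric(nz$background_rate_hz) ||
      !(length(nz$background_rate_hz) %in% c(1L, 6L)) ||
      any(nz$background_rate_hz < 0))
    note("noise$background_rate_hz must be >= 0 (scalar or one value per structure)")
  if (!is.numeric(nz$background_amplitude) ||
      !(length(nz$background_amplitude) %in% c(1L, 6L)))
    note("noise$background_amplitude must be numeric (scalar or one value per structure)")
  if (!is.logical(nz$background_enabled) || length(nz$background_enabled) != 1)
    note("noise$background_enabled must be TRUE or FALSE")

  dbs <- cfg$dbs
  if (!num1(dbs$frequency_hz) || dbs$frequency_hz < 0)
    note("dbs$frequency_hz must be >= 0")
  if (!num1(dbs$amplitude))
    note("dbs$amplitude must be a finite number")
  if (!num1(dbs$pulse_width_ms) || dbs$pulse_width_ms <= 0)
    note("dbs$pulse_width_ms must be > 0")
  if (num1(dbs$frequency_hz) && dbs$frequency_hz > 0 &&
      num1(dbs$pulse_width_ms) &&
      dbs$pulse_width_ms >= 1000 / dbs$frequency_hz)
    note("dbs$pulse_width_ms must be smaller than the pulse period 1000/frequency_hz")
  if (!num1(dbs$onset_s) || dbs$onset_s < 0)
    note("dbs$onset_s must be >= 0")
  if (!num1(dbs$offset_s) || (num1(dbs$onset_s) && dbs$offset_s < dbs$onset_s))
    note("dbs$offset_s must be >= onset_s")
  if (!num1(dbs$target_structure) || !(dbs$target_structure %in% 1:6))
    note("dbs$target_structure must be a structure id in 1..6")

  bad
}

# Recursively list nested key paths of a config-shaped list (matrices and
# atomic leaves stop the recursion).
.key_paths <- function(x, prefix = "") {
  if (!is.list(x) || is.null(names(x))) return(prefix)
  unlist(lapply(names(x), function(nm) {
    p <- if (prefix == "") nm else paste(prefix, nm, sep = "$")
    v <- x[[nm]]
    if (is.list(v) && !is.null(names(v))) c(p, .key_paths(v, p)) else p
  }))
}

#' Save a configuration to a YAML file
#'
#' @param cfg A `tcm_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_config()]
#' @export
save_config <- function(cfg, path) {
  ser <- unclass(cfg)
  ser$connectivity$weight_gain <- .mat_to_rows(ser$connectivity$weight_gain)
  ser$connectivity$delay_ms <- .mat_to_rows(ser$connectivity$delay_ms)
  ser$connectivity$synapse_mix <- lapply(ser$connectivity$synapse_mix,
                                         .mat_to_rows)
  yaml::write_yaml(ser, path, precision = 15L)
  invisible(path)
}

.mat_to_rows <- function(m) {
  stats::setNames(lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])),
                  rownames(m))
}

.rows_to_mat <- function(rows, what) {
  if (!is.list(rows) || length(rows) != 6 ||
      !all(lengths(rows) == 6))
    stop("config field ", what, " must be a 6x6 matrix (six rows of six numbers)")
  m <- do.call(rbind, lapply(rows, as.numeric))
  dimnames(m) <- list(target = .structure_names, source = .structure_names)
  m
}

#' Load a configuration from a YAML file
#'
#' The file must carry the expected `schema_version` and may not contain
#' unknown keys; a missing required field or an unrecognized key is
#' reported by name. `load_config(save_config(cfg, f))` reproduces `cfg`
#' field for field.
#'
#' @param path Path to a YAML configuration written by [save_config()].
#' @return A `tcm_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("config file is not parseable YAML: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(raw)) stop("config file is not a YAML mapping")
  if (is.null(raw$schema_version))
    stop("config file is missing required field: schema_version")
  if (raw$schema_version != .config_schema_version)
    stop("unsupported config schema_version: ", raw$schema_version)

  template <- default_config()
  tser <- unclass(template)
  # Compare key paths against the reference schema.
  known <- .key_paths(tser)
  # synapse params / neuron params allow user-defined archetype names, so
  # wildcard their second level.
  canon <- function(paths) {
    paths <- sub("^neuron_params\\$[^$]+", "neuron_params$*", paths)
    paths <- sub("^(synapse_params\\$(exc|inh))\\$[^$]+", "\\1$*", paths)
    # matrix-valued fields serialize as one named row per structure
    paths <- sub("^(connectivity\\$(weight_gain|delay_ms))\\$[^$]+", "\\1", paths)
    paths <- sub("^(connectivity\\$synapse_mix\\$[FDP])\\$[^$]+", "\\1", paths)
    unique(paths)
  }
  got <- .key_paths(raw)
  unknown <- setdiff(canon(got), canon(known))
  if (length(unknown))
    stop("config file contains unknown key(s): ",
         paste(unknown, collapse = ", "))
  required <- setdiff(canon(known), canon(got))
  if (length(required))
    stop("config file is missing required field(s): ",
         paste(unique(required), collapse = ", "))

  cfg <- raw
  cfg$schema_version <- as.integer(cfg$schema_version)
  cfg$seed <- as.integer(cfg$seed)
  cfg$record_traces <- isTRUE(cfg$record_traces)
  for (nm in names(cfg$populations)) {
    cfg$populations[[nm]]$structure_id <-
      as.integer(cfg$populations[[nm]]$structure_id)
    cfg$populations[[nm]]$n_neurons <-
      as.integer(cfg$populations[[nm]]$n_neurons)
  }
  cfg$connectivity$weight_gain <-
    .rows_to_mat(cfg$connectivity$weight_gain, "connectivity$weight_gain")
  cfg$connectivity$delay_ms <-
    .rows_to_mat(cfg$connectivity$delay_ms, "connectivity$delay_ms")
  cfg$connectivity$synapse_mix <-
    lapply(cfg$connectivity$synapse_mix, .rows_to_mat, what = "connectivity$synapse_mix")
  cfg$dbs$target_structure <- as.integer(cfg$dbs$target_structure)
  class(cfg) <- "tcm_config"
  cfg
}

#' @export
print.tcm_config <- function(x, ...) {
  n <- vapply(x$populations, function(p) p$n_neurons, numeric(1))
  cat("Thalamo-cortical model configuration (schema v", x$schema_version,
      ")\n", sep = "")
  cat("  populations:",
      paste(sprintf("%s=%d", names(n), as.integer(n)), collapse = ", "),
      sprintf("(total %d)\n", as.integer(sum(n))))
  cat(sprintf("  duration %.3g s at dt %.3g ms, seed %d\n",
              x$duration_s, x$dt_ms, x$seed))
  cat(sprintf("  noise: membrane sd %.3g (%s), threshold sd %.3g, background %s\n",
              x$noise$membrane_noise_std, x$noise$noise_mode,
              x$noise$threshold_noise_std,
              if (isTRUE(x$noise$background_enabled)) "on" else "off"))
  cat(sprintf("  DBS: %.5g Hz, amplitude %.4g, %.3g-%.3g s, target %s\n",
              x$dbs$frequency_hz, x$dbs$amplitude, x$dbs$onset_s,
              x$dbs$offset_s, .structure_names[x$dbs$target_structure]))
  invisible(x)
}
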