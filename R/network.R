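# Network assembly: realized populations, signed jittered weight matrices
# with per-source normalization, integer-step delays, synapse-class mixes,
# and population deactivation.

#' Build a network instance from a configuration
#'
#' Realizes the six populations (drawing per-neuron heterogeneity),
#' constructs dense all-to-all weight matrices for every ordered structure
#' pair with a non-zero gain, converts conduction delays to integer step
#' counts, and prepares the per-class Tsodyks-Markram parameter sets.
#'
#' Individual weights are `gain(target, source) / N_source * (1 + jitter * eta)`
#' with `eta ~ U(-1, 1)` drawn per element; the division by the live
#' presynaptic count keeps the total input to a neuron invariant under
#' population resizing. The sign of each weight is the sign of the gain
#' (excitatory sources >= 0, inhibitory <= 0; `weight_jitter < 1`
#' guarantees the jitter never flips it). Neuron self-connections are
#' excluded; all other pairs, including pairs within a structure, are
#' connected. Weight and heterogeneity draws use dedicated RNG substreams
#' derived from `cfg$seed`, so rebuilding with the same seed gives
#' identical matrices.
#'
#' @param cfg A valid `tcm_config`.
#' @return An object of class `tcm_network`: realized populations with
#'   parameter arrays, `weights[[target]][[source]]` matrices,
#'   `delays_steps` (6x6 integer, minimum 1 step), the synapse-class
#'   mixes, per-source-class TM parameters, and a global neuron index
#'   (`neuron_index` maps global id to structure and local index).
#' @export
build_network <- function(cfg) {
  bad <- validate_config(cfg)
  if (length(bad))
    stop("invalid config:\n  ", paste(bad, collapse = "\n  "))

  sn <- .structure_names
  pops <- with_substream(cfg$seed, "heterogeneity", {
    lapply(sn, function(nm) {
      spec <- cfg$populations[[nm]]
      p <- make_population(spec, cfg$neuron_params[[spec$neuron_archetype]])
      p$name <- nm
      p$structure_id <- spec$structure_id
      p$excitatory <- isTRUE(spec$excitatory)
      p$n <- spec$n_neurons
      p
    })
  })
  names(pops) <- sn
  n_per <- vapply(pops, function(p) p$n, numeric(1))
  n_total <- sum(n_per)
  offsets <- cumsum(c(0, n_per))[1:6]
  names(offsets) <- sn

  neuron_index <- data.frame(
    global_id = seq_len(n_total),
    structure = rep(sn, times = n_per),
    local_index = unlist(lapply(n_per, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE
  )

  dt <- cfg$dt_ms
  delay_raw <- cfg$connectivity$delay_ms / dt
  delays_steps <- matrix(pmax(1L, as.integer(round(delay_raw))), 6, 6,
                         dimnames = dimnames(cfg$connectivity$delay_ms))
  err <- abs(delay_raw - round(delay_raw))
  if (any(err > 0.1))
    warning("some conduction delays are not multiples of dt_ms; ",
            "rounded to the nearest step (max error ",
            sprintf("%.3g", max(err) * dt), " ms)")

  gain <- cfg$connectivity$weight_gain
  jit <- cfg$connectivity$weight_jitter
  weights <- with_substream(cfg$seed, "weights", {
    w <- vector("list", 6); names(w) <- sn
    for (tj in 1:6) {
      w[[tj]] <- vector("list", 6); names(w[[tj]]) <- sn
      for (sj in 1:6) {
        nt <- n_per[tj]; ns <- n_per[sj]
        if (nt == 0 || ns == 0 || gain[tj, sj] == 0) next
        base <- gain[tj, sj] / ns
        m <- matrix(base, nt, ns)
        if (jit > 0)
          m <- m * (1 + jit * matrix(stats::runif(nt * ns, -1, 1), nt, ns))
        if (tj == sj) diag(m) <- 0  # no neuron self-loops
        w[[tj]][[sj]] <- m
      }
    }
    w
  })

  tm_params <- lapply(stats::setNames(sn, sn), function(s) {
    side <- if (pops[[s]]$excitatory) "exc" else "inh"
    cfg$synapse_params[[side]]
  })

  net <- list(
    populations = pops,
    n_per = n_per,
    n_total = n_total,
    offsets = offsets,
    neuron_index = neuron_index,
    weights = weights,
    delays_steps = delays_steps,
    synapse_mix = cfg$connectivity$synapse_mix,
    tm_params = tm_params,
    dt_ms = dt,
    seed = cfg$seed
  )
  class(net) <- "tcm_network"
  net
}

#' Deactivate one population
#'
#' Returns a copy of the configuration with the named population's size
#' set to zero. The resulting network contains no neurons, weights or
#' synapse states for that structure, and simulations run without error
#' (an all-deactivated network yields an empty spike record).
#'
#' @param cfg A `tcm_config`.
#' @param name One of `"S"`, `"M"`, `"D"`, `"CI"`, `"TRN"`, `"TCR"`.
#' @return The modified configuration.
#' @export
deactivate_population <- function(cfg, name) {
  if (!name %in% .structure_names)
    stop("unknown population: ", name,
         " (expected one of ", paste(.structure_names, collapse = ", "), ")")
  cfg$populations[[name]]$n_neurons <- 0L
  cfg
}

#' @export
print.tcm_network <- function(x, ...) {
  cat("Thalamo-cortical network:", x$n_total, "neurons\n")
  cat(" ", paste(sprintf("%s=%d", names(x$n_per), as.integer(x$n_per)),
                 collapse = ", "), "\n")
  live <- names(x$n_per)[x$n_per > 0]
  np <- sum(vapply(x$weights, function(row)
    sum(vapply(row, function(m) !is.null(m), logical(1))), numeric(1)))
  cat("  ", np, "active projections, dt =", x$dt_ms, "ms, seed", x$seed, "\n")
  invisible(x)
}

#' Summarize a network instance for provenance
#'
#' @param object A `tcm_network`.
#' @param ... Unused.
#' @return A data frame with one row per active projection: target,
#'   source, mean weight, weight sign, delay in steps and in ms.
#' @export
summary.tcm_network <- function(object, ...) {
  rows <- list()
  for (tj in .structure_names) for (sj in .structure_names) {
    m <- object$weights[[tj]][[sj]]
    if (is.null(m)) next
    rows[[length(rows) + 1L]] <- data.frame(
      target = tj, source = sj,
      n_target = nrow(m), n_source = ncol(m),
      mean_weight = mean(m),
      delay_steps = object$delays_steps[match(tj, .structure_names),
                                        match(sj, .structure_names)],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$delay_ms <- out$delay_steps * object$dt_ms
  out
}
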