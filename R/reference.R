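# Naive scalar reference engine: the same per-step algorithm as the
# vectorized engines, written as explicit loops over neurons, synapse
# states and weight-matrix entries. Slow by design; it exists to validate
# the vectorized engines step-for-step on small networks. Arithmetic is
# ordered identically to the compiled engine (per-target accumulation
# over ascending source indices, projections visited target-major), so
# the two agree bit-for-bit when fed the same noise draws.

#' Run a simulation with the naive scalar reference engine
#'
#' Equivalent to `simulate(cfg, engine = "reference")`. Every operation
#' is an explicit scalar loop: per-neuron Euler updates, per-synapse
#' Tsodyks-Markram updates, and a double loop over (source neuron,
#' target neuron) for the weighted PSC aggregation. Use only on small
#' networks.
#'
#' @inheritParams simulate
#' @return A `tcm_result`.
#' @export
simulate_reference <- function(cfg, record_traces = NULL,
                               noise_streams = NULL) {
  simulate(cfg, engine = "reference", record_traces = record_traces,
           noise_streams = noise_streams)
}

.simulate_scalar <- function(cfg, net, n_steps, dbs_wave, record_traces,
                             noise_streams) {
  n <- net$n_total
  dt <- cfg$dt_ms
  st <- init_engine_state(net)
  v <- st$v; u <- st$u
  a <- st$params$a; b <- st$params$b; c_ <- st$params$c; d <- st$params$d
  vp <- st$params$v_peak; bias <- st$bias
  n_hist <- st$n_hist

  # per-structure, per-class scalar TM state and decay factors
  tm_u <- st$tm; buf <- st$buf
  eF <- eD <- eS <- Uj <- Aj <- vector("list", 6)
  for (sj in 1:6) {
    eF[[sj]] <- eD[[sj]] <- eS[[sj]] <- Uj[[sj]] <- Aj[[sj]] <- numeric(3)
    for (ci in 1:3) {
      p <- net$tm_params[[sj]][[.synapse_classes[ci]]]
      eF[[sj]][ci] <- exp(-dt / p$tau_f)
      eD[[sj]][ci] <- exp(-dt / p$tau_d)
      eS[[sj]][ci] <- exp(-dt / p$tau_s)
      Uj[[sj]][ci] <- p$U
      Aj[[sj]][ci] <- abs(p$A)
    }
  }

  sigma_xi <- cfg$noise$membrane_noise_std
  sigma_zeta <- cfg$noise$threshold_noise_std
  per_step_mode <- identical(cfg$noise$noise_mode, "per_step")
  xi_scale <- if (per_step_mode) sigma_xi else sigma_xi * sqrt(dt)
  tgt <- cfg$dbs$target_structure
  bg_on <- isTRUE(cfg$noise$background_enabled)
  bgpn <- if (bg_on) .background_per_neuron(cfg, net) else NULL

  spike_id <- integer(0); spike_step <- integer(0)
  mean_v <- if (record_traces) matrix(NA_real_, n_steps, 6) else NULL

  set.seed(substream_seed(cfg$seed, "membrane"))
  for (s in seq_len(n_steps)) {
    xi <- if (!is.null(noise_streams$xi)) noise_streams$xi[s, ]
          else if (sigma_xi > 0 && n > 0) stats::rnorm(n) else NULL
    zeta <- if (!is.null(noise_streams$zeta)) noise_streams$zeta[s, ]
            else if (sigma_zeta > 0 && n > 0) stats::rnorm(n) else NULL
    bg <- if (bg_on && n > 0)
      sample_background_events(cfg$noise, n, dt,
                               rate_hz = bgpn$rate, amplitude = bgpn$amp)
      else NULL

    # (1) delayed PSC aggregation: explicit double loop over (i', j')
    I_syn <- numeric(n)
    for (p in st$proj) {
      tj <- p$tj; sj <- p$sj
      W <- net$weights[[tj]][[sj]]
      row <- .buf_row(s - p$k, n_hist)
      ns_src <- net$n_per[[sj]]
      eff <- numeric(ns_src)
      for (is in seq_len(ns_src)) {
        acc <- 0
        for (ci in 1:3) {
          f <- net$synapse_mix[[.synapse_classes[ci]]][tj, sj]
          if (f > 0) acc <- acc + f * buf[[sj]][[ci]][row, is]
        }
        eff[is] <- acc
      }
      off_t <- net$offsets[[tj]]
      for (it in seq_len(net$n_per[[tj]])) {
        acc <- 0
        for (is in seq_len(ns_src)) acc <- acc + W[it, is] * eff[is]
        I_syn[off_t + it] <- I_syn[off_t + it] + acc
      }
    }

    # (2)-(3) per-neuron current summation, Euler step, spike detection
    dbs_val <- dbs_wave[s]
    spiked <- logical(n)
    vrec <- if (record_traces) numeric(n) else NULL
    tgt_lo <- net$offsets[[tgt]] + 1
    tgt_hi <- net$offsets[[tgt]] + net$n_per[[tgt]]
    for (i in seq_len(n)) {
      I <- bias[i] + I_syn[i]
      if (!is.null(bg)) I <- I + bg[i]
      if (dbs_val != 0 && i >= tgt_lo && i <= tgt_hi) I <- I + dbs_val
      dv <- 0.04 * v[i]^2 + 5 * v[i] - u[i] + 140 + I
      du <- a[i] * (b[i] * v[i] - u[i])
      vi <- v[i] + dt * dv
      ui <- u[i] + dt * du
      if (!is.null(xi)) vi <- vi + xi_scale * xi[i]
      if (!is.finite(vi) || !is.finite(ui))
        stop("numerical blow-up at step ", s, ", neuron ", i)
      thr <- vp[i]
      if (!is.null(zeta)) thr <- thr + sigma_zeta * zeta[i]
      if (vi >= thr) {
        spiked[i] <- TRUE
        if (record_traces) vrec[i] <- vp[i]
        vi <- c_[i]
        ui <- ui + d[i]
      } else if (record_traces) vrec[i] <- vi
      v[i] <- vi
      u[i] <- ui
    }

    # (4)-(5) scalar TM updates and buffer push
    row_now <- .buf_row(s, n_hist)
    for (sj in 1:6) {
      ns_src <- net$n_per[[sj]]
      if (ns_src == 0) next
      off_s <- net$offsets[[sj]]
      for (ci in 1:3) {
        stc <- tm_u[[sj]][[ci]]
        for (is in seq_len(ns_src)) {
          uu <- stc$u[is] * eF[[sj]][ci]
          xx <- 1 - (1 - stc$x[is]) * eD[[sj]][ci]
          II <- stc$I_psc[is] * eS[[sj]][ci]
          if (spiked[off_s + is]) {
            u1 <- uu + Uj[[sj]][ci] * (1 - uu)
            II <- II + Aj[[sj]][ci] * u1 * xx
            xx <- xx - u1 * xx
            uu <- u1
          }
          # flush to the no-activity fixed point (see engine contract)
          if (uu < 1e-12) uu <- 0
          if (xx > 1 - 1e-12) xx <- 1
          if (II < 1e-12 && II > -1e-12) II <- 0
          stc$u[is] <- uu; stc$x[is] <- xx; stc$I_psc[is] <- II
          buf[[sj]][[ci]][row_now, is] <- II
        }
        tm_u[[sj]][[ci]] <- stc
      }
    }

    if (any(spiked)) {
      ids <- which(spiked)
      spike_id <- c(spike_id, ids)
      spike_step <- c(spike_step, rep.int(s, length(ids)))
    }
    if (record_traces) {
      for (j in 1:6) {
        nj <- net$n_per[[j]]
        if (nj > 0)
          mean_v[s, j] <- mean(vrec[(net$offsets[[j]] + 1):(net$offsets[[j]] + nj)])
      }
    }
  }
  list(spike_id = spike_id, spike_step = spike_step, mean_v = mean_v)
}
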