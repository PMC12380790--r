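# Analysis of simulation results: LFP proxy, Golomb-Hansel population
# synchrony, Welch beta-band power, pre/post-DBS epoch comparison, and
# raster plots.

#' Population activity proxy (LFP surrogate)
#'
#' Binned population spike count of one structure (default bin 1 ms),
#' mean-subtracted; or, when membrane traces were recorded, the
#' population-mean membrane voltage. A structure with no spikes yields a
#' (mean-subtracted) zero series; a deactivated structure is an error.
#'
#' @param result A `tcm_result`.
#' @param structure Structure name ("S", "M", "D", "CI", "TRN", "TCR").
#' @param bin_ms Bin width in ms (ignored for `source = "traces"`).
#' @param source `"spikes"` (binned counts) or `"traces"` (mean voltage).
#' @param t_range Optional `c(start_ms, end_ms)` restriction.
#' @return List with `series` (mean-subtracted), `dt_ms` (sample
#'   interval) and `time_ms` (bin left edges).
#' @export
lfp_proxy <- function(result, structure, bin_ms = 1,
                      source = c("spikes", "traces"), t_range = NULL) {
  source <- match.arg(source)
  if (!structure %in% .structure_names)
    stop("unknown structure: ", structure)
  if (result$n_per[[structure]] == 0)
    stop("structure ", structure, " is deactivated (no neurons)")
  t0 <- if (is.null(t_range)) 0 else t_range[1]
  t1 <- if (is.null(t_range)) result$duration_s * 1000 else t_range[2]

  if (source == "traces") {
    if (is.null(result$traces))
      stop("no traces recorded; run simulate() with record_traces = TRUE")
    sel <- result$traces$time_ms > t0 & result$traces$time_ms <= t1
    x <- result$traces$mean_v[sel, structure]
    return(list(series = x - mean(x), dt_ms = result$dt_ms,
                time_ms = result$traces$time_ms[sel]))
  }

  edges <- seq(t0, t1, by = bin_ms)
  n_bins <- length(edges) - 1
  sp <- result$spikes
  tms <- sp$time_ms[sp$structure == structure]
  tms <- tms[tms > t0 & tms <= t1]
  counts <- if (length(tms))
    tabulate(pmin(n_bins, ceiling((tms - t0) / bin_ms)), nbins = n_bins)
    else numeric(n_bins)
  list(series = counts - mean(counts), dt_ms = bin_ms,
       time_ms = edges[-length(edges)])
}

# Gaussian smoothing of columns of a (time x neuron) matrix; sd in samples.
.smooth_columns <- function(m, sd_samples) {
  if (sd_samples <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_samples))
  k <- stats::dnorm(seq(-half, half), sd = sd_samples)
  k <- k / sum(k)
  apply(m, 2, function(x) {
    y <- stats::convolve(c(numeric(half), x, numeric(half)), rev(k),
                         type = "open")
    # trim to the central, fully overlapped part
    y[(2 * half + 1):(2 * half + length(x))]
  })
}

#' Per-neuron smoothed spike signals of one structure
#'
#' Bins each neuron's spike train (default 1 ms bins) over an epoch and
#' smooths it with a Gaussian kernel (default sd 5 ms). This is the
#' signal matrix on which the synchrony index is defined.
#'
#' @param result A `tcm_result`.
#' @param structure Structure name.
#' @param epoch `c(start_ms, end_ms)`.
#' @param bin_ms Bin width (ms).
#' @param smooth_ms Gaussian kernel standard deviation (ms); 0 disables
#'   smoothing.
#' @return Numeric matrix, one column per neuron of the structure.
#' @export
spike_signals <- function(result, structure, epoch, bin_ms = 1,
                          smooth_ms = 5) {
  if (!structure %in% .structure_names)
    stop("unknown structure: ", structure)
  n_nrn <- result$n_per[[structure]]
  if (n_nrn < 2) stop("need at least 2 neurons in ", structure)
  if (diff(epoch) < 500)
    stop("epoch must be at least 500 ms long")
  n_bins <- floor(diff(epoch) / bin_ms)
  sp <- result$spikes
  sel <- sp$structure == structure & sp$time_ms > epoch[1] &
    sp$time_ms <= epoch[1] + n_bins * bin_ms
  m <- matrix(0, n_bins, n_nrn)
  if (any(sel)) {
    loc <- sp$neuron_id[sel] - .structure_offset(result, structure)
    bin <- pmin(n_bins, ceiling((sp$time_ms[sel] - epoch[1]) / bin_ms))
    for (k in seq_along(loc)) m[bin[k], loc[k]] <- m[bin[k], loc[k]] + 1
  }
  .smooth_columns(m, smooth_ms / bin_ms)
}

# global-id offset of a structure within a result
.structure_offset <- function(result, structure) {
  j <- match(structure, .structure_names)
  if (j == 1) return(0L)
  as.integer(sum(unlist(result$n_per[1:(j - 1)])))
}

#' Golomb-Hansel population synchrony index
#'
#' The coherence measure
#' `chi = sqrt( Var_t[ mean_i s_i(t) ] / mean_i Var_t[ s_i(t) ] )`
#' over per-neuron signals `s_i` (columns of `signals`): 1 for perfectly
#' identical signals, approaching 0 for independent ones as the
#' population grows. Invariant to uniform amplitude scaling. Returns
#' `NA` when all signals are constant (no variance to compare).
#'
#' @param signals Numeric matrix, time samples in rows, neurons in
#'   columns (e.g. from [spike_signals()] or recorded voltage traces).
#' @return Scalar synchrony index.
#' @examples
#' s <- matrix(sin(seq(0, 20 * pi, length.out = 1000)), 1000, 20)
#' synchrony_index(s)  # identical signals -> 1
#' @export
synchrony_index <- function(signals) {
  if (!is.matrix(signals) || ncol(signals) < 2)
    stop("signals must be a matrix with at least 2 columns (neurons)")
  denom <- mean(apply(signals, 2, stats::var))
  if (denom == 0) return(NA_real_)
  num <- stats::var(rowMeans(signals))
  sqrt(num / denom)
}

#' Band power and total power of a series (Welch estimate)
#'
#' Averaged periodogram with Hann-windowed segments (default 2 s) at 50%
#' overlap, one-sided density normalization. `band_power` integrates the
#' spectral density over the requested band (default beta, 13-30 Hz);
#' `total_power` integrates over [1, Nyquist] Hz.
#'
#' @param series Numeric vector (uniformly sampled; at least one full
#'   window of samples).
#' @param dt_ms Sample interval in ms.
#' @param band `c(low_hz, high_hz)`; must lie below the Nyquist
#'   frequency.
#' @param window_s Segment length in seconds (default 2).
#' @return List with `band_power`, `total_power`, and the density
#'   (`freq_hz`, `psd`) it integrated.
#' @export
band_power <- function(series, dt_ms, band = c(13, 30), window_s = 2) {
  fs <- 1000 / dt_ms
  nyq <- fs / 2
  if (band[2] > nyq || band[1] < 0 || band[1] >= band[2])
    stop("band must lie within (0, ", nyq, ") Hz")
  L <- round(window_s * fs)
  if (length(series) < L)
    stop("series too short: need at least ", window_s,
         " s of samples for the Welch window")
  hop <- floor(L / 2)
  starts <- seq(1, length(series) - L + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann
  scale <- 1 / (fs * sum(w^2))
  n_freq <- floor(L / 2) + 1
  acc <- numeric(n_freq)
  for (s0 in starts) {
    seg <- series[s0:(s0 + L - 1)]
    seg <- (seg - mean(seg)) * w
    p <- abs(stats::fft(seg))^2 * scale
    p <- p[seq_len(n_freq)]
    # one-sided: double everything except DC (and Nyquist if L even)
    dbl <- rep(2, n_freq); dbl[1] <- 1
    if (L %% 2 == 0) dbl[n_freq] <- 1
    acc <- acc + p * dbl
  }
  psd <- acc / length(starts)
  freq <- (seq_len(n_freq) - 1) * fs / L
  df <- fs / L
  in_band <- freq >= band[1] & freq <= band[2]
  in_total <- freq >= 1 & freq <= nyq
  list(band_power = sum(psd[in_band]) * df,
       total_power = sum(psd[in_total]) * df,
       freq_hz = freq, psd = psd)
}

#' Compare network activity across epochs
#'
#' Computes, per epoch and per live structure with at least 2 neurons:
#' the Golomb-Hansel synchrony index (on 1 ms-binned, 5 ms-smoothed
#' per-neuron spike signals), the mean firing rate, and the beta-band
#' (13-30 Hz) and total power of the population LFP proxy. Also returns
#' the ratio (each later epoch / first epoch) of synchrony and beta
#' power per structure.
#'
#' Default epochs follow the stimulation protocol in the result: a
#' pre-DBS epoch from 1 s to the DBS onset and a DBS epoch from 1 s
#' after onset to the end of the run (the first second of each epoch is
#' a settle-in margin and is excluded).
#'
#' @param result A `tcm_result`.
#' @param epochs Named list of `c(start_ms, end_ms)` pairs; the first is
#'   the baseline. Must be non-overlapping and within the simulation.
#' @param structures Structures to analyze (default: all live with >= 2
#'   neurons).
#' @param beta_band `c(low_hz, high_hz)`, default 13-30.
#' @return Object of class `tcm_epoch_metrics`: list with `metrics` (one
#'   row per epoch x structure: `epoch`, `t_start_ms`, `t_end_ms`,
#'   `structure`, `chi`, `rate_hz`, `beta_power`, `total_power`) and
#'   `ratios` (per structure and non-baseline epoch: `chi_ratio`,
#'   `beta_ratio` relative to the baseline epoch).
#' @export
compare_epochs <- function(result, epochs = NULL, structures = NULL,
                           beta_band = c(13, 30)) {
  dur_ms <- result$duration_s * 1000
  if (is.null(epochs)) {
    onset_ms <- result$dbs$onset_s * 1000
    epochs <- list(pre = c(1000, onset_ms),
                   dbs = c(onset_ms + 1000, dur_ms))
  }
  if (is.null(names(epochs)) || any(names(epochs) == ""))
    stop("epochs must be a named list")
  for (e in epochs)
    if (e[1] < 0 || e[2] > dur_ms + 1e-9 || e[1] >= e[2])
      stop("epoch out of range [0, ", dur_ms, "] ms or empty")
  if (length(epochs) > 1) {
    iv <- do.call(rbind, epochs)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2] - 1e-9))
      stop("epochs overlap")
  }
  structures <- structures %||%
    .structure_names[unlist(result$n_per) >= 2]

  rows <- list()
  for (en in names(epochs)) {
    ep <- epochs[[en]]
    win_s <- min(2, floor(diff(ep)) / 1000)
    for (st in structures) {
      sig <- spike_signals(result, st, ep)
      chi <- synchrony_index(sig)
      n_sp <- sum(result$spikes$structure == st &
                    result$spikes$time_ms > ep[1] &
                    result$spikes$time_ms <= ep[2])
      rate <- n_sp / result$n_per[[st]] / (diff(ep) / 1000)
      proxy <- lfp_proxy(result, st, t_range = ep)
      bp <- band_power(proxy$series, proxy$dt_ms, band = beta_band,
                       window_s = win_s)
      rows[[length(rows) + 1L]] <- data.frame(
        epoch = en, t_start_ms = ep[1], t_end_ms = ep[2], structure = st,
        chi = chi, rate_hz = rate, beta_power = bp$band_power,
        total_power = bp$total_power, stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)

  base <- names(epochs)[1]
  ratios <- NULL
  if (length(epochs) > 1) {
    rr <- list()
    for (en in names(epochs)[-1]) for (st in structures) {
      m0 <- metrics[metrics$epoch == base & metrics$structure == st, ]
      m1 <- metrics[metrics$epoch == en & metrics$structure == st, ]
      rr[[length(rr) + 1L]] <- data.frame(
        epoch = en, structure = st,
        chi_ratio = m1$chi / m0$chi,
        beta_ratio = m1$beta_power / m0$beta_power,
        stringsAsFactors = FALSE)
    }
    ratios <- do.call(rbind, rr)
  }
  out <- list(metrics = metrics, ratios = ratios, baseline = base)
  class(out) <- "tcm_epoch_metrics"
  out
}

#' @export
print.tcm_epoch_metrics <- function(x, ...) {
  cat("Epoch metrics (baseline:", x$baseline, ")\n")
  print(x$metrics, digits = 4, row.names = FALSE)
  if (!is.null(x$ratios)) {
    cat("Ratios vs baseline:\n")
    print(x$ratios, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Write epoch metrics to CSV
#'
#' @param em A `tcm_epoch_metrics`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(em, path) {
  utils::write.csv(em$metrics, path, row.names = FALSE)
  invisible(path)
}

#' Raster plot of a simulation
#'
#' One panel: spike times on the x-axis, neurons grouped by structure on
#' the y-axis in the order S, M, D, CI, TRN, TCR (bottom to top), with
#' the DBS onset marked by a vertical line. The output format follows
#' the file extension (`.png` or `.pdf`). An empty spike record draws
#' blank axes.
#'
#' @param result A `tcm_result`.
#' @param path Output image path.
#' @param point_cex Point size for spikes.
#' @return `path`, invisibly.
#' @export
raster_plot <- function(result, path, point_cex = 0.15) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    grDevices::png(path, width = 1400, height = 900, res = 140)
  } else if (ext == "pdf") {
    grDevices::pdf(path, width = 10, height = 6.5)
  } else stop("unsupported image format: .", ext, " (use .png or .pdf)")
  on.exit(grDevices::dev.off())

  n_per <- unlist(result$n_per)
  n_tot <- sum(n_per)
  offs <- cumsum(c(0, n_per))[1:6]
  graphics::par(mar = c(4, 4.5, 2.5, 1))
  graphics::plot(NULL, xlim = c(0, result$duration_s * 1000),
                 ylim = c(0, max(1, n_tot)),
                 xlab = "time (ms)", ylab = "", yaxt = "n",
                 main = sprintf("%g Hz DBS from %g s (seed %d)",
                                result$dbs$frequency_hz,
                                result$dbs$onset_s, result$seed))
  if (nrow(result$spikes))
    graphics::points(result$spikes$time_ms, result$spikes$neuron_id,
                     pch = ".", cex = point_cex * 10)
  for (j in 1:6) {
    if (n_per[j] == 0) next
    graphics::abline(h = offs[j], col = "grey70", lwd = 0.5)
    graphics::axis(2, at = offs[j] + n_per[j] / 2,
                   labels = .structure_names[j], las = 1, tick = FALSE)
  }
  if (result$dbs$frequency_hz > 0 && result$dbs$amplitude != 0)
    graphics::abline(v = result$dbs$onset_s * 1000, col = "red3",
                     lwd = 1.2, lty = 2)
  invisible(path)
}
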