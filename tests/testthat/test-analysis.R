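# Analysis utilities: LFP proxy, synchrony index, band power, epoch
# comparison, raster output.

test_that("the LFP proxy bins, demeans, and is linear in spike counts", {
  res0 <- make_result(spike_df(integer(0), character(0), numeric(0)))
  p0 <- lfp_proxy(res0, "S")
  expect_true(all(p0$series == 0))
  expect_equal(p0$dt_ms, 1)

  # one neuron spiking every 50 ms: the proxy has a 20 Hz fundamental
  tms <- seq(50, 12000, by = 50)
  res <- make_result(spike_df(rep(1L, length(tms)), "S", tms))
  p <- lfp_proxy(res, "S")
  expect_equal(mean(p$series), 0, tolerance = 1e-12)
  bp <- band_power(p$series, p$dt_ms, band = c(13, 30))
  peak <- bp$freq_hz[-1][which.max(bp$psd[-1])]
  expect_equal(peak, 20, tolerance = 0.3)

  # doubling every spike doubles the counts (and their mean), so the
  # demeaned proxy doubles too
  res2 <- make_result(rbind(res$spikes, res$spikes))
  p2 <- lfp_proxy(res2, "S")
  expect_equal(p2$series, 2 * p$series, tolerance = 1e-12)

  expect_error(lfp_proxy(res, "M"), "deactivated")
  expect_error(lfp_proxy(res, "Q"), "unknown structure")
})

test_that("synchrony index is 1 for identical signals and low for independent ones", {
  tpl <- sin(seq(0, 40 * pi, length.out = 2000))
  ident <- matrix(tpl, 2000, 50)
  expect_equal(synchrony_index(ident), 1, tolerance = 1e-12)

  chis <- vapply(1:5, function(seed) {
    set.seed(seed)
    # 100 independent Poisson trains at 10 Hz, 5 s, 1 ms bins, 5 ms kernel
    m <- matrix(rbinom(5000 * 100, 1, 0.01), 5000, 100)
    synchrony_index(tcmdbs:::.smooth_columns(m, 5))
  }, numeric(1))
  expect_true(all(chis < 0.3))

  # ordering holds for all tested population sizes
  set.seed(6)
  for (n in c(10, 50, 100)) {
    m <- matrix(rbinom(3000 * n, 1, 0.01), 3000, n)
    indep <- synchrony_index(tcmdbs:::.smooth_columns(m, 5))
    sync <- synchrony_index(matrix(tcmdbs:::.smooth_columns(m[, 1, drop = FALSE], 5),
                                   3000, n))
    expect_gt(sync, indep)
  }
})

test_that("synchrony index is scale invariant and NA for flat signals", {
  set.seed(8)
  m <- matrix(rnorm(1000 * 20), 1000, 20)
  expect_equal(synchrony_index(m), synchrony_index(3.7 * m),
               tolerance = 1e-12)
  expect_true(is.na(synchrony_index(matrix(1, 100, 5))))
  expect_error(synchrony_index(matrix(0, 10, 1)), "2 columns")
})

test_that("band power separates in-band from out-of-band sinusoids", {
  t <- seq(0, 20, by = 1e-3)[-1]          # 20 s at 1 kHz
  s20 <- sin(2 * pi * 20 * t)
  bp <- band_power(s20, 1, band = c(13, 30))
  expect_gte(bp$band_power / bp$total_power, 0.9)

  s50 <- sin(2 * pi * 50 * t)
  bp50 <- band_power(s50, 1, band = c(13, 30))
  expect_lt(bp50$band_power / bp50$total_power, 0.05)

  expect_error(band_power(s20, 1, band = c(13, 600)), "band")
  expect_error(band_power(s20[1:100], 1), "too short")
})

test_that("white noise carries beta power in proportion to bandwidth", {
  fracs <- vapply(1:10, function(seed) {
    set.seed(seed)
    x <- rnorm(20000)
    bp <- band_power(x, 1, band = c(13, 30))
    bp$band_power / bp$total_power
  }, numeric(1))
  expect_equal(mean(fracs), (30 - 13) / (500 - 1), tolerance = 0.1)
})

test_that("band power is non-negative and additive over disjoint bands", {
  set.seed(9)
  x <- rnorm(10000) + sin(2 * pi * 18 * seq_len(10000) / 1000)
  b1 <- band_power(x, 1, band = c(5.2, 15.3))$band_power
  b2 <- band_power(x, 1, band = c(15.7, 25.3))$band_power
  btot <- band_power(x, 1, band = c(5.2, 25.3))$band_power
  expect_gte(b1, 0); expect_gte(b2, 0)
  expect_equal(b1 + b2, btot, tolerance = 0.02)
})

test_that("identical activity in both epochs yields unit ratios", {
  # same periodic pattern in [1,6) and [7,12) s across 20 neurons
  base <- as.vector(outer(seq(0, 4999, by = 40), (1:20) * 0.5, "+"))
  sp <- rbind(
    spike_df(rep(1:20, each = 125), "S", 1000 + base),
    spike_df(rep(1:20, each = 125), "S", 7000 + base)
  )
  res <- make_result(sp[order(sp$time_ms), ], n_per = c(S = 20, M = 0, D = 0,
                                                        CI = 0, TRN = 0, TCR = 0))
  em <- compare_epochs(res, epochs = list(pre = c(1000, 6000),
                                          dbs = c(7000, 12000)),
                       structures = "S")
  expect_equal(em$ratios$chi_ratio, 1, tolerance = 1e-9)
  expect_equal(em$ratios$beta_ratio, 1, tolerance = 1e-9)
})

test_that("epoch validation rejects malformed windows", {
  res <- make_result(spike_df(1L, "S", 100))
  expect_error(compare_epochs(res, epochs = list(a = c(0, 3000),
                                                 b = c(2000, 5000))),
               "overlap")
  expect_error(compare_epochs(res, epochs = list(a = c(-10, 3000))),
               "out of range")
  expect_error(compare_epochs(res, epochs = list(c(0, 1000))), "named")
})

test_that("raster plots are written for full and empty records", {
  cfg <- toy_config(n = 5, duration_s = 0.5, noise = TRUE)
  res <- simulate(cfg)
  f <- withr::local_tempfile(fileext = ".png")
  raster_plot(res, f)
  expect_true(file.exists(f) && file.size(f) > 0)

  res0 <- make_result(spike_df(integer(0), character(0), numeric(0)))
  f2 <- withr::local_tempfile(fileext = ".pdf")
  raster_plot(res0, f2)
  expect_true(file.exists(f2) && file.size(f2) > 0)
  expect_error(raster_plot(res, "x.gif"), "format")
})
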