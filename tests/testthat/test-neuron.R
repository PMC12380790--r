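# Izhikevich drift, noisy Euler stepping, reset semantics, and population
# realization.

test_that("drift vanishes at the analytic rest point and evaluates exactly", {
  # with u = b v, equilibria solve 0.04 v^2 + (5 - b) v + 140 = 0;
  # for b = 0.2 the roots are v = -70 and v = -50
  d <- izhikevich_drift(-70, -14, 0, list(a = 0.02, b = 0.2))
  expect_equal(d$dv_dt, 0, tolerance = 1e-12)
  expect_equal(d$du_dt, 0, tolerance = 1e-12)
  d2 <- izhikevich_drift(-50, -10, 0, list(a = 0.02, b = 0.2))
  expect_equal(d2$dv_dt, 0, tolerance = 1e-12)

  # direct evaluation: 0.04*4225 - 325 + 13 + 140 = -3
  d3 <- izhikevich_drift(-65, -13, 0, list(a = 0.02, b = 0.2))
  expect_equal(d3$dv_dt, -3)

  # additivity of the input current
  v <- c(-72.3, -55, -60.1); u <- c(-10, -14, 3)
  base <- izhikevich_drift(v, u, rep(0, 3), list(a = 0.02, b = 0.2))
  shift <- izhikevich_drift(v, u, rep(2.5, 3), list(a = 0.02, b = 0.2))
  expect_equal(shift$dv_dt - base$dv_dt, rep(2.5, 3))
  expect_equal(shift$du_dt, base$du_dt)

  expect_error(izhikevich_drift(c(1, 2), 1, 0, list(a = 1, b = 1)), "length")
})

test_that("spiking neurons reset to c and increment u by d", {
  p <- list(a = 0.02, b = 0.2, c = -65, d = 8, v_peak = 30)
  nz <- list(membrane_noise_std = 0, threshold_noise_std = 0,
             noise_mode = "sqrt_dt")
  out <- step_neurons(list(v = 29.9, u = -14), I_total = 500, p, nz, dt = 0.1)
  expect_true(out$spiked)
  expect_equal(out$state$v, -65)
  expect_equal(out$v_record, 30)           # clamped to v_peak for recording
  # u was Euler-updated then incremented by d
  du <- 0.02 * (0.2 * 29.9 - (-14))
  expect_equal(out$state$u, -14 + 0.1 * du + 8)
})

test_that("the rest fixed point is stationary for 1e5 noise-free steps", {
  p <- list(a = 0.02, b = 0.2, c = -65, d = 8, v_peak = 30)
  nz <- list(membrane_noise_std = 0, threshold_noise_std = 0,
             noise_mode = "sqrt_dt")
  state <- list(v = -70, u = -14)
  for (s in 1:1e5) state <- step_neurons(state, 0, p, nz, dt = 0.1)$state
  expect_equal(state$v, -70, tolerance = 1e-8)
  expect_equal(state$u, -14, tolerance = 1e-8)
})

test_that("regular-spiking cells are silent at I=0 and fire at I=10", {
  p <- list(a = 0.02, b = 0.2, c = -65, d = 8, v_peak = 30)
  expect_equal(count_spikes(p, 0, 1e4), 0)          # subthreshold at rest
  expect_gt(count_spikes(p, 10, 1e4), 10)           # sustained spiking over 1 s
})

test_that("noise integration reproduces the Wiener-process variance", {
  # drift disabled: v(t) is a pure random walk; in sqrt_dt mode
  # Var[v(t)] = sigma^2 * t independent of dt
  nz <- list(membrane_noise_std = 0.5, threshold_noise_std = 0,
             noise_mode = "sqrt_dt")
  n_rep <- 4000
  set.seed(11)
  state <- list(v = rep(0, n_rep), u = rep(0, n_rep))
  p <- list(a = 0.02, b = 0.2, c = -65, d = 8, v_peak = 1e9)
  for (s in 1:1000)
    state <- step_neurons(state, rep(0, n_rep), p, nz, dt = 0.1,
                          drift = FALSE)$state
  expect_equal(var(state$v), 0.25 * 100, tolerance = 0.05)
})

test_that("per_step and sqrt_dt noise modes coincide at dt = 1 ms", {
  p <- list(a = 0.02, b = 0.2, c = -65, d = 8, v_peak = 30)
  xi <- rnorm(50)
  st <- list(v = rep(-70, 50), u = rep(-14, 50))
  a <- step_neurons(st, rep(0, 50), p,
                    list(membrane_noise_std = 0.5, threshold_noise_std = 0,
                         noise_mode = "per_step"), dt = 1, xi = xi)
  b <- step_neurons(st, rep(0, 50), p,
                    list(membrane_noise_std = 0.5, threshold_noise_std = 0,
                         noise_mode = "sqrt_dt"), dt = 1, xi = xi)
  expect_identical(a$state$v, b$state$v)
})

test_that("noise-driven firing rate is non-decreasing in the noise level", {
  p <- list(a = 0.02, b = 0.2, c = -65, d = 8, v_peak = 30)
  rates <- vapply(c(0.5, 1.5, 3), function(sig) {
    mean(vapply(1:5, function(seed) {
      set.seed(seed)
      count_spikes(p, I = 3.5, n_steps = 5e3, n = 20,
                   noise = list(membrane_noise_std = sig,
                                threshold_noise_std = 0.1,
                                noise_mode = "sqrt_dt"))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("population realization honors size, heterogeneity and archetype", {
  arch <- list(a = 0.02, b = 0.2, c = -65, d = 8, v_peak = 30,
               heterogeneity_scale = 1)
  spec <- list(n_neurons = 0L, excitatory = TRUE, bias_current = 3,
               neuron_archetype = "RS")
  p0 <- make_population(spec, arch)
  expect_length(p0$a, 0)
  expect_length(p0$state$v, 0)

  spec$n_neurons <- 10L
  ph <- make_population(spec, arch, heterogeneity_scale = 0)
  expect_equal(ph$c, rep(-65, 10))
  expect_equal(ph$d, rep(8, 10))
  expect_equal(ph$state$u, ph$b * ph$state$v)

  set.seed(3); p1 <- make_population(spec, arch)
  set.seed(3); p2 <- make_population(spec, arch)
  expect_identical(p1, p2)                  # reproducible under a seed
  expect_gt(stats::sd(p1$c), 0)             # non-constant rows
  # excitatory scheme trades reset depth against adaptation increment
  expect_true(all(p1$c >= -65 & p1$c <= -50))
  expect_true(all(p1$d <= 8 & p1$d >= 2))

  spec_in <- list(n_neurons = 50L, excitatory = FALSE, bias_current = 0,
                  neuron_archetype = "FS")
  fs <- list(a = 0.1, b = 0.2, c = -65, d = 2, v_peak = 30,
             heterogeneity_scale = 1)
  set.seed(4); pin <- make_population(spec_in, fs)
  expect_true(all(pin$a >= 0.02 - 1e-12 & pin$a <= 0.1 + 1e-12))
  expect_true(all(pin$b >= 0.2 - 1e-12 & pin$b <= 0.25 + 1e-12))

  expect_error(make_population(spec, NULL), "archetype")
})
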