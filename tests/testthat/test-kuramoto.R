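test_that("uncoupled oscillators advance linearly (Euler exact for constant rate)", {
  cfg <- kuramoto_config(n_oscillators = 3, k = 0, n_samples = 500,
                         burn_in = 0, natural_freqs = c(8, 10, 12),
                         initial_phases = c(0.1, 0.2, 0.3), seed = 1)
  m <- uniform_cmat(3, 0.9)
  traj <- simulate_kuramoto(cfg, m)
  omega <- 2 * pi * c(8, 10, 12) * cfg$time_unit_scale
  for (i in 1:3) {
    expected <- c(0.1, 0.2, 0.3)[i] + omega[i] * cfg$h * seq_len(500)
    expect_equal(traj$phases[, i], expected, tolerance = 1e-10)
  }
})

test_that("a symmetric pair with identical frequencies attracts to synchrony", {
  cfg <- kuramoto_config(n_oscillators = 2, k = 1, n_samples = 4000,
                         burn_in = 0, natural_freqs = c(10, 10),
                         initial_phases = c(0, 2), seed = 1)
  traj <- simulate_kuramoto(cfg, uniform_cmat(2, 1))
  dphi <- traj$phases[, 1] - traj$phases[, 2]
  expect_lt(abs(tail(dphi, 1)), 1e-4)
  expect_gt(tail(traj$r, 1), 1 - 1e-8)
})

test_that("two-oscillator locking matches the closed-form phase difference", {
  # dphi/dt = dOmega - 2ka sin(phi): locked fixed point phi* = asin(ratio)
  k <- 1
  scale <- 0.01
  df <- 1                                  # Hz difference
  d_omega <- 2 * pi * df * scale
  for (ratio in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    a <- d_omega / (2 * k * ratio)
    cfg <- kuramoto_config(n_oscillators = 2, k = k, n_samples = 60000,
                           burn_in = 50000, natural_freqs = c(10 + df, 10),
                           initial_phases = c(0, 0), seed = 1)
    traj <- simulate_kuramoto(cfg, uniform_cmat(2, a))
    phi <- traj$phases[, 1] - traj$phases[, 2]
    phi_wrapped <- atan2(sin(phi), cos(phi))
    expect_equal(mean(tail(phi_wrapped, 1000)), asin(ratio),
                 tolerance = 0.01 * asin(ratio))
  }
  # above threshold (ratio > 1) the pair drifts instead of locking
  a <- d_omega / (2 * k * 1.2)
  cfg <- kuramoto_config(n_oscillators = 2, k = k, n_samples = 60000,
                         burn_in = 0, natural_freqs = c(10 + df, 10),
                         initial_phases = c(0, 0), seed = 1)
  traj <- simulate_kuramoto(cfg, uniform_cmat(2, a))
  phi <- traj$phases[, 1] - traj$phases[, 2]
  expect_gt(abs(tail(phi, 1) - phi[1]), 2 * pi)
})

test_that("order parameter matches its defining cases", {
  expect_identical(order_parameter(matrix(2.2, 1, 21))$r, 1)
  expect_lt(order_parameter(matrix(c(1, 1 + pi), 1, 2))$r, 1e-12)
  set.seed(41)
  r <- order_parameter(matrix(runif(10000 * 21, 0, 2 * pi), 10000, 21))$r
  expect_true(all(r >= 0 & r <= 1))
  # incoherent ensemble: E[r] ~ sqrt(pi / (4 N))
  expect_equal(mean(r), sqrt(pi / (4 * 21)), tolerance = 0.05)
  expect_error(order_parameter(matrix(numeric(0), 0, 0)), "empty")
})

test_that("to_eeg maps phases through sine with labels and group tag", {
  cfg <- kuramoto_config(n_oscillators = 2, k = 0.3, n_samples = 2000,
                         burn_in = 100, seed = 7)
  traj <- simulate_kuramoto(cfg, uniform_cmat(2, 0.5))
  rec <- to_eeg(traj, labels = c("L", "R"), group = "simulated-patient")
  expect_identical(rec$data, sin(traj$phases), ignore_attr = TRUE)
  expect_true(all(rec$data >= -1 & rec$data <= 1))
  expect_identical(rec$channel_labels, c("L", "R"))
  expect_identical(rec$group, "simulated-patient")
  expect_error(to_eeg(traj, labels = c("only-one")), "label count")
  summed <- to_eeg(traj, collapse = TRUE)
  expect_equal(summed$data[, 1], rowSums(sin(traj$phases)))
})

test_that("locked channels peak in cross-correlation at the locked lag", {
  k <- 1
  scale <- 0.01
  d_omega <- 2 * pi * 1 * scale
  ratio <- 0.5
  a <- d_omega / (2 * k * ratio)
  cfg <- kuramoto_config(n_oscillators = 2, k = k, n_samples = 40000,
                         burn_in = 30000, natural_freqs = c(11, 10),
                         initial_phases = c(0, 0), seed = 1)
  traj <- simulate_kuramoto(cfg, uniform_cmat(2, a))
  rec <- to_eeg(traj, labels = c("x", "y"))
  cc <- stats::ccf(rec$data[, 1], rec$data[, 2], lag.max = 60, plot = FALSE)
  best_lag <- cc$lag[which.max(cc$acf)]
  # locked offset asin(ratio) rad; the common instantaneous frequency of the
  # locked pair is the mean of the two natural rates
  omega_bar <- 2 * pi * 10.5 * scale * cfg$h
  expect_equal(best_lag * omega_bar, -asin(ratio), tolerance = 0.25)
})

test_that("ensembles are reproducible and sized by the config", {
  cfg <- kuramoto_config(n_oscillators = 4, n_samples = 1500, burn_in = 500,
                         n_runs = 3, seed = 99)
  m <- uniform_cmat(4, 0.5)
  recs <- run_ensemble(cfg, m)
  expect_length(recs, 3)
  expect_true(all(vapply(recs, n_samples, numeric(1)) == 1000))
  manifest <- attr(recs, "manifest")
  expect_identical(nrow(manifest), 3L)
  recs2 <- run_ensemble(cfg, m)
  for (i in 1:3) expect_identical(recs[[i]]$data, recs2[[i]]$data)
  # distinct runs differ
  expect_false(identical(recs[[1]]$data, recs[[2]]$data))
})

test_that("a global phase rotation leaves r(t) invariant and shifts psi", {
  f <- c(9, 10, 11, 12)
  base <- kuramoto_config(n_oscillators = 4, n_samples = 2000, burn_in = 0,
                          natural_freqs = f,
                          initial_phases = c(0.3, 1.1, 2.9, 4.2))
  rot <- kuramoto_config(n_oscillators = 4, n_samples = 2000, burn_in = 0,
                         natural_freqs = f,
                         initial_phases = c(0.3, 1.1, 2.9, 4.2) + 1.234)
  m <- uniform_cmat(4, 0.6)
  t1 <- simulate_kuramoto(base, m)
  t2 <- simulate_kuramoto(rot, m)
  expect_equal(t2$r, t1$r, tolerance = 1e-9)
  dpsi <- atan2(sin(t2$psi - t1$psi), cos(t2$psi - t1$psi))
  expect_equal(dpsi, rep(1.234, 2000), tolerance = 1e-9)
})

test_that("halving the integration step changes r(t) only slightly when stable", {
  f <- c(9.5, 10, 10.5, 11)
  th0 <- c(0.5, 1.5, 2.5, 3.5)
  m <- uniform_cmat(4, 0.8)
  cfg1 <- kuramoto_config(n_oscillators = 4, h = 0.1, n_samples = 4000,
                          burn_in = 0, natural_freqs = f, initial_phases = th0)
  cfg2 <- kuramoto_config(n_oscillators = 4, h = 0.05, n_samples = 8000,
                          burn_in = 0, natural_freqs = f, initial_phases = th0)
  r1 <- simulate_kuramoto(cfg1, m)$r
  r2 <- simulate_kuramoto(cfg2, m)$r[seq(2, 8000, by = 2)]
  expect_lt(sqrt(mean((r1 - r2)^2)) / sqrt(mean(r1^2)), 0.05)
})

test_that("strong coupling with identical frequencies synchronizes fully", {
  # k = 50 in 1/N-normalized units; the step is reduced so the Euler map
  # stays inside its stability region (h * k * mean degree < 2)
  cfg <- kuramoto_config(n_oscillators = 21, k = 50, n_samples = 3000,
                         burn_in = 0, h = 0.01, normalize_coupling = TRUE,
                         natural_freqs = rep(10, 21), seed = 3)
  traj <- simulate_kuramoto(cfg, uniform_cmat(21, 0.5))
  expect_gt(tail(traj$r, 1), 0.99)
  expect_true(all(traj$r >= 0 & traj$r <= 1))
})

test_that("simulation errors are informative", {
  cfg <- kuramoto_config(n_oscillators = 3, n_samples = 100, burn_in = 10)
  expect_error(simulate_kuramoto(cfg, uniform_cmat(4, 0.5)), "dimension")
  expect_error(kuramoto_config(burn_in = 200, n_samples = 100), "burn_in")
})

test_that("coupling sweep reduces to the pipeline at a single k and falls with synchrony", {
  m <- uniform_cmat(21, 0.5)
  cfg <- kuramoto_config(n_samples = 5000, burn_in = 500, n_runs = 2,
                         seed = 5)
  sweep1 <- coupling_sweep(cfg, m, k_values = 1,
                           params = complexity_params(hfd_kmax = 6))
  recs <- run_ensemble(cfg, m)
  tbl <- score_recordings(recs, complexity_params(hfd_kmax = 6),
                          regions = region_map(paste0("ch", 1:21)))
  expect_equal(sweep1$LZC, mean(tbl$value[tbl$measure == "LZC"]),
               tolerance = 1e-12)
  # LZC declines as coupling drives the network from partial coherence
  # into strong synchrony (scaled mode: transition near k ~ 0.02)
  lzc_by_seed <- sapply(1:6, function(s) {
    cfg_s <- kuramoto_config(n_samples = 5000, burn_in = 500, n_runs = 2,
                             seed = s)
    coupling_sweep(cfg_s, m, k_values = c(0.03, 0.15, 0.75),
                   params = complexity_params(hfd_kmax = 6))$LZC
  })
  trend <- rowMeans(lzc_by_seed)
  expect_true(all(diff(trend) <= 0))
})
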