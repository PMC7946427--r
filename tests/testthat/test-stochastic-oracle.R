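test_that("OU ligand reproduces its stationary moments and memory", {
  sig <- signal_params(1, 0.1, 1)
  o <- simulate_ou_ligand(sig, sim_config(5000, dt = 0.05, seed = 3,
                                          record_every = 1L))
  n_eff <- 5000 / 2      # roughly one independent draw per 2 tau_L
  expect_lt(abs(mean(o$L) - 1), 3 * 0.1 / sqrt(n_eff))
  expect_lt(abs(sd(o$L) - 0.1) / 0.1, 0.05)
  ac <- acf(o$L, lag.max = 21, plot = FALSE)$acf
  expect_lt(abs(ac[21] - exp(-1)), 0.03)
  # small relative noise: no clamping at zero over the whole run
  expect_identical(o$clamped_fraction, 0)
  expect_true(o$valid)
})

test_that("network settles at its mean-field steady state for a static-like input", {
  sys <- make_system(p = 0.3, f = 0.4, tau_r = 0.1, dmu1 = 4, dmu2 = 2,
                     R_T = 200, X_T = 400, tau_c = 0.05, noise = 1e-6)
  b <- simulate_network(sys$receptor, sys$readout, sys$signal,
                        sim_config(400, seed = 5))
  st <- b$state
  se_RL <- sd(b$RL) / sqrt(400 / (2 * 0.05))   # ~independent per 2 tau_c
  se_X <- sd(b$X_star) / sqrt(400 / (2 * 0.1))
  expect_lt(abs(mean(b$RL) - st$p * 200), 3 * se_RL)
  expect_lt(abs(mean(b$X_star) - st$f * 400), 3 * se_X)
  expect_true(all(b$RL >= 0 & b$RL <= 200))
  expect_true(all(b$X_star >= 0 & b$X_star <= 400))
})

test_that("event bookkeeping reproduces the analytic cycle flux", {
  sys <- make_system(p = 0.5, f = 0.5, tau_r = 0.1, dmu1 = 3, dmu2 = 3,
                     R_T = 200, X_T = 500, tau_c = 0.02, noise = 0.05)
  st <- steady_state(sys$receptor, sys$readout, sys$signal)
  b <- simulate_network(sys$receptor, sys$readout, sys$signal,
                        sim_config(500, seed = 9))
  expect_lt(abs(b$net_flux_rate - st$thermo$ndot) / st$thermo$ndot, 0.05)
})

test_that("equilibrium cycles carry no information about the signal", {
  # detailed balance (kf kr = kmf kmr): dmu = 0, q = 0, and the simulated
  # ligand-readout correlation vanishes within error
  p <- 0.5; tau_r <- 0.1; R_T <- 200
  rec <- receptor_rates_from_design(p, 0.01, 1, R_T = R_T)
  k <- 1 / (4 * tau_r)
  rd <- readout_params(X_T = 500, kf = k / (p * R_T), kmf = k / (p * R_T),
                       kr = k, kmr = k)
  sig <- signal_params(1, 0.05, 1)
  expect_equal(sample_quality(0, 0), 0)
  b <- simulate_network(rec, rd, sig, sim_config(500, seed = 7))
  set.seed(1)
  e <- empirical_snr(b)
  expect_lt(abs(e$rho), 3 * e$se_rho)
})

test_that("shuffling the readout trace destroys the correlation", {
  sys <- make_system(tau_r = 0.1, R_T = 200, X_T = 500, tau_c = 0.02)
  b <- simulate_network(sys$receptor, sys$readout, sys$signal,
                        sim_config(300, seed = 13))
  set.seed(2)
  shuffled <- cor(b$L, sample(as.numeric(b$X_star)))
  expect_lt(abs(shuffled), 0.02)
})

test_that("empirical dynamic gain matches the low-pass prediction", {
  sys <- make_system(p = 0.5, f = 0.5, tau_r = 0.2, dmu1 = 10, dmu2 = 10,
                     R_T = 200, X_T = 1000, tau_c = 0.01, noise = 0.05)
  b <- simulate_network(sys$receptor, sys$readout, sys$signal,
                        sim_config(1000, seed = 11))
  g <- empirical_gain(b)
  expect_lt(abs(g$slope / g$dynamic_gain - 1), 0.1)
  # short-memory averaging of a slow signal approaches the static gain
  g_fast <- empirical_gain(b, tau_r = 0.02)
  st <- b$state
  g0 <- static_gain(st$p, 1)
  expect_lt(abs(g_fast$slope / g0 - 1), 0.12)
})

test_that("spectral oracle agrees with the closed form in its regime", {
  # tau_c << tau_r << tau_L, large copy numbers
  for (co in list(list(p = 0.5, tau_r = 0.3, R_T = 300, X_T = 1000),
                  list(p = 0.3, tau_r = 0.2, R_T = 1000, X_T = 3000),
                  list(p = 0.6, tau_r = 0.5, R_T = 300, X_T = 300))) {
    sys <- make_system(p = co$p, tau_r = co$tau_r, R_T = co$R_T,
                       X_T = co$X_T, dmu1 = 2, dmu2 = 2, tau_c = 0.005)
    an <- snr_total(sys$signal, sys$design, sys$tau_c)$snr
    sp <- spectral_snr(sys$receptor, sys$readout, sys$signal)$snr
    expect_lt(abs(an / sp - 1), 0.1)
  }
})

test_that("slow-input limit of the spectral oracle is the static error", {
  sys <- make_system(p = 0.5, tau_r = 0.05, R_T = 200, X_T = 600,
                     dmu1 = 10, dmu2 = 10, tau_c = 0.002, tau_L = 500,
                     noise = 0.05)
  sp <- spectral_snr(sys$receptor, sys$readout, sys$signal)$snr
  b <- snr_total(sys$signal, sys$design, sys$tau_c)
  expect_lt(b$dynamical_error / b$sampling_error, 0.05)
  expect_lt(abs(sp / b$snr - 1), 0.1)
})

test_that("stochastic and spectral oracles agree with each other", {
  sys <- make_system(p = 0.5, tau_r = 0.3, R_T = 300, X_T = 1000,
                     dmu1 = 10, dmu2 = 10, tau_c = 0.01, noise = 0.05)
  b <- simulate_network(sys$receptor, sys$readout, sys$signal,
                        sim_config(1500, seed = 21))
  set.seed(3)
  e <- empirical_snr(b)
  sp <- spectral_snr(sys$receptor, sys$readout, sys$signal)
  expect_lt(abs(e$snr - sp$snr), 3 * e$se_snr)
})

test_that("seeded runs are bit-reproducible and audit clamping", {
  sys <- make_system(tau_r = 0.1, R_T = 100, X_T = 300, tau_c = 0.02)
  b1 <- simulate_network(sys$receptor, sys$readout, sys$signal,
                         sim_config(200, seed = 33))
  b2 <- simulate_network(sys$receptor, sys$readout, sys$signal,
                         sim_config(200, seed = 33))
  expect_identical(b1$L, b2$L)
  expect_identical(b1$X_star, b2$X_star)
  # strongly fluctuating input trips the clamp audit at a strict threshold
  sig_wild <- signal_params(1, 0.6, 1)
  b3 <- simulate_network(sys$receptor, sys$readout, sig_wild,
                         sim_config(200, seed = 33,
                                    clamp_fraction_max = 1e-4))
  expect_gt(b3$clamped_fraction, 1e-4)
  expect_false(b3$valid)
})

test_that("coarse discretizations are rejected", {
  sys <- make_system(tau_r = 0.1, tau_c = 0.02)
  expect_error(simulate_network(sys$receptor, sys$readout, sys$signal,
                                sim_config(200, dt = 0.05, seed = 1)),
               "configuration error")
  expect_error(simulate_network(sys$receptor, sys$readout, sys$signal,
                                sim_config(50, seed = 1)),
               "configuration error")
})
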