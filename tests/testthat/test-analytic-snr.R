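test_that("static gain is the occupancy parabola over the mean input", {
  expect_equal(static_gain(0.5, 100), 0.0025)
  expect_equal(static_gain(0, 10), 0)
  expect_equal(static_gain(1, 10), 0)
  p_grid <- seq(0.05, 0.95, by = 0.05)
  gains <- vapply(p_grid, static_gain, numeric(1), L_mean = 1)
  expect_equal(p_grid[which.max(gains)], 0.5)
})

test_that("dynamic gain is the static gain under low-pass attenuation", {
  expect_equal(dynamic_gain(0.3, 5, 0, 0, 1), static_gain(0.3, 5))
  expect_equal(dynamic_gain(0.3, 5, 1, 1, 1), static_gain(0.3, 5) / 4)
  expect_lt(dynamic_gain(0.3, 5, 0.1, 0.2, 1), static_gain(0.3, 5))
})

test_that("sample quality follows the two-leg driving formula", {
  expect_equal(sample_quality(2, 2), tanh(1), tolerance = 1e-12)
  # weak symmetric driving: q -> dmu / 4
  for (dmu in c(1e-3, 1e-5)) {
    expect_equal(sample_quality(dmu / 2, dmu / 2), dmu / 4,
                 tolerance = 1e-3)
  }
  expect_equal(sample_quality(Inf, Inf), 1)
  expect_equal(sample_quality(50, 50), 1, tolerance = 1e-12)
  expect_equal(sample_quality(0, 3), 0)
  expect_equal(sample_quality(5, 0), 0)
  expect_error(sample_quality(-1, 2), "outside")
})

test_that("sample bookkeeping respects its ordering and limits", {
  d <- design_point(p = 0.4, f = 0.5, tau_r = 0.2, dmu1 = 2, dmu2 = 3,
                    R_T = 200, X_T = 1000)
  sc <- sample_counts(d, tau_c = 0.01)
  expect_lte(sc$n_I, sc$n_eff)
  expect_lte(sc$n_eff, sc$n_bar)
  expect_equal(sc$f_I, sc$n_I / sc$n_eff, tolerance = 1e-12)
  expect_equal(sc$n_eff, sc$q * sc$n_bar, tolerance = 1e-12)

  # sampling interval equal to twice the receptor correlation time
  # halves the independent fraction: f_I = 1/(1 + 2 tau_c / delta)
  expect_equal(1 / (1 + 2 * 0.01 / (2 * 0.01)), 0.5)

  # unbounded readout pool with perfect copies: n_I = R_T tau_r / tau_c
  d_bp <- design_point(p = 0.4, tau_r = 0.2, R_T = 200, xt_infinite = TRUE,
                       q_unity = TRUE)
  expect_identical(sample_counts(d_bp, 0.01)$n_I, 200 * 0.2 / 0.01)

  # the finite-pool formulas approach that limit as X_T grows
  d_big <- design_point(p = 0.4, f = 0.5, tau_r = 0.2, R_T = 200,
                        X_T = 1e12, q_unity = TRUE)
  sc_big <- sample_counts(d_big, 0.01)
  expect_equal(sc_big$n_I, 200 * 0.2 / 0.01, tolerance = 1e-6)
  expect_equal(sc_big$f_I, sc_big$delta / (2 * 0.01), tolerance = 1e-6)

  # zero driving: no samples, not an exception
  d0 <- design_point(p = 0.4, f = 0.5, tau_r = 0.2, dmu1 = 0, dmu2 = 0,
                     R_T = 200, X_T = 1000)
  expect_equal(sample_counts(d0, 0.01)$n_bar, 0)
})

test_that("dynamical error has the stated limits and monotonicity", {
  expect_equal(dynamical_error(0, 1, 1), 1)
  expect_equal(dynamical_error(0, 0, 1), 0)
  expect_equal(dynamical_error(1, 1, 1), 5 / 3, tolerance = 1e-12)
  tr_grid <- seq(0, 2, by = 0.1)
  e_tr <- vapply(tr_grid, function(tr) dynamical_error(0.05, tr, 1),
                 numeric(1))
  expect_true(all(diff(e_tr) >= 0))
  tc_grid <- seq(0, 2, by = 0.1)
  e_tc <- vapply(tc_grid, function(tc) dynamical_error(tc, 0.3, 1),
                 numeric(1))
  expect_true(all(diff(e_tc) >= 0))
  expect_true(all(e_tr >= 0))
})

test_that("SNR matches direct hand substitution in the Berg-Purcell limit", {
  # p = 1/2, tau_c/tau_L = 0.01, tau_r/tau_L = 0.1, R_T = 100, noise 0.1
  sig <- signal_params(1, 0.1, 1)
  d <- design_point(p = 0.5, tau_r = 0.1, R_T = 100, xt_infinite = TRUE,
                    q_unity = TRUE)
  b <- snr_total(sig, d, tau_c = 0.01)
  sampling_hand <- 1.01^2 * 1.1^2 * (1 / 0.1^2) / (0.25 * 100 * 0.1 / 0.01)
  expect_equal(sampling_hand, 1.0201 * 1.21 * 0.4, tolerance = 1e-12)
  dyn_hand <- (1.01 * 1.1) / (1 + 0.01 * 0.1 / (1 * 0.11)) - 1
  expect_equal(b$sampling_error, sampling_hand, tolerance = 1e-12)
  expect_equal(b$dynamical_error, dyn_hand, tolerance = 1e-12)
  expect_equal(b$snr, 1 / (sampling_hand + dyn_hand), tolerance = 1e-12)
  expect_equal(b$mutual_info_nats, 0.5 * log1p(b$snr), tolerance = 1e-12)
  expect_equal(b$snr_run, b$snr / 0.1, tolerance = 1e-12)
})

test_that("slow input removes the dynamical error and the gain attenuation", {
  sig <- signal_params(1, 0.1, 1e9)
  d <- design_point(p = 0.5, tau_r = 0.1, R_T = 100, xt_infinite = TRUE,
                    q_unity = TRUE)
  b <- snr_total(sig, d, tau_c = 0.01)
  expect_lt(b$dynamical_error, 1e-8)
  expect_equal(b$dynamic_gain, b$static_gain, tolerance = 1e-8)
})

test_that("zero driving gives zero SNR without an exception", {
  sig <- signal_params(1, 0.1, 1)
  d0 <- design_point(p = 0.5, f = 0.5, tau_r = 0.1, dmu1 = 0, dmu2 = 0,
                     R_T = 100, X_T = 1000)
  b <- snr_total(sig, d0, 0.01)
  expect_identical(b$snr, 0)
  expect_identical(b$sampling_error, Inf)
})

test_that("SNR depends on concentration units only through relative noise", {
  set.seed(105)
  for (i in 1:10) {
    co <- random_design_coords()
    d <- design_point(p = co$p, f = co$f, tau_r = co$tau_r, dmu1 = co$dmu1,
                      dmu2 = co$dmu2, R_T = co$R_T, X_T = co$X_T)
    scale <- 10^runif(1, -3, 3)
    b1 <- snr_total(signal_params(1, 0.05, 1), d, co$tau_c)
    b2 <- snr_total(signal_params(scale, 0.05 * scale, 1), d, co$tau_c)
    expect_equal(b1$snr, b2$snr, tolerance = 1e-12)
  }
})

test_that("SNR is monotone in receptors, readouts and sample quality", {
  sig <- signal_params(1, 0.05, 1)
  snr_at <- function(R_T = 300, X_T = 1000, dmu = 8)
    snr_total(sig, design_point(p = 0.4, f = 0.5, tau_r = 0.2,
                                dmu1 = dmu / 2, dmu2 = dmu / 2,
                                R_T = R_T, X_T = X_T), 0.01)$snr
  expect_true(all(diff(vapply(c(50, 200, 800, 3200), function(r)
    snr_at(R_T = r), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(100, 400, 1600, 6400), function(x)
    snr_at(X_T = x), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(0.5, 1, 2, 4, 8), function(d)
    snr_at(dmu = d), numeric(1))) > 0))
})

test_that("run-scale SNR rescales by the measurement count per run", {
  expect_equal(snr_run(0.5, tau_r = 0.5, tau_L = 1), 1)
  expect_equal(snr_run(0.37, tau_r = 1, tau_L = 1), 0.37)
})

test_that("power-constrained evaluation implies the matching readout pool", {
  sig <- signal_params(1, 0.05, 1)
  b <- snr_from_power(sig, p = 0.5, tau_r = 0.2, wdot = 500, dmu = 4,
                      R_T = 300, tau_c = 0.01)
  expect_equal(b$samples$ndot, 500 / 4, tolerance = 1e-9)
})
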