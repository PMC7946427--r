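# Stochastic and spectral oracles for the closed-form SNR theory.

#' Simulation configuration
#'
#' Discretization and bookkeeping for the hybrid stochastic simulator.
#' At simulation time the configuration is validated against the model's
#' timescales: `dt <= min(tau_c, tau_r, tau_L) / 20`, burn-in
#' `>= 10 max(tau_c, tau_r, tau_L)`, and every per-step event probability
#' `<= 0.1`.  Leaving `dt`, `t_burnin` or `record_every` `NULL` picks those
#' defaults automatically.
#'
#' @param t_total simulated duration after burn-in (same units as `tau_L`).
#' @param dt time step; default `min(tau_c, tau_r, tau_L) / 20`.
#' @param t_burnin discarded transient; default `10 max(tau_c, tau_r, tau_L)`.
#' @param seed integer seed (applied via `set.seed()` before simulating).
#' @param n_replicates number of independent replicates (seeds are
#'   `seed + 0:(n-1)` so adding replicates never perturbs earlier ones).
#' @param clamp_fraction_max maximum tolerated fraction of steps at which
#'   the Gaussian ligand signal had to be clamped at zero (default 0.01);
#'   beyond it the run is marked invalid (theory regime violated).
#' @param record_every store every k-th step; default keeps the recording
#'   interval near `min(tau_r, tau_L) / 20`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(t_total, dt = NULL, t_burnin = NULL, seed = 1L,
                       n_replicates = 1L, clamp_fraction_max = 0.01,
                       record_every = NULL) {
  check_scalar(t_total, "t_total", lower = 0)
  if (!is.null(dt)) check_scalar(dt, "dt", lower = 0)
  if (!is.null(t_burnin)) check_scalar(t_burnin, "t_burnin", lower = 0,
                                       open_lower = FALSE)
  structure(list(t_total = t_total, dt = dt, t_burnin = t_burnin,
                 seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 clamp_fraction_max = clamp_fraction_max,
                 record_every = record_every),
            class = "sim_config")
}

resolve_config <- function(config, tau_c, tau_r, tau_L) {
  scales <- c(tau_c, tau_r, tau_L)
  scales <- scales[is.finite(scales) & scales > 0]
  if (config$t_total < 200 * tau_L)
    stop_domain("configuration error: t_total must cover at least 200 tau_L")
  dt <- config$dt %||% (min(scales) / 20)
  if (dt > min(scales) / 20 + 1e-12)
    stop_domain("configuration error: dt must be <= min(tau_c, tau_r, tau_L)/20")
  t_burnin <- config$t_burnin %||% (10 * max(scales))
  if (t_burnin < 10 * max(scales) - 1e-9)
    stop_domain("configuration error: burn-in must cover 10 max(tau_c, tau_r, tau_L)")
  record_every <- config$record_every %||%
    max(1L, floor(min(tau_r, tau_L, na.rm = TRUE) / 20 / dt))
  list(dt = dt, n_steps = floor(config$t_total / dt),
       n_burn = ceiling(t_burnin / dt),
       record_every = as.integer(record_every))
}

#' Simulate the Ornstein-Uhlenbeck ligand signal
#'
#' Exact-discretization updates
#' `L(t + dt) = L_mean + (L(t) - L_mean) e^(-dt/tau_L) +
#'  sigma_L sqrt(1 - e^(-2 dt/tau_L)) xi`.  Negative excursions are clamped
#' at zero and audited: the model signal is Gaussian, so clamping is
#' negligible in the small-noise regime the theory assumes.
#'
#' @param signal a [signal_params()] object.
#' @param config a [sim_config()] object.
#' @return A list with `times`, `L`, `clamped_fraction`, `valid`, `config`.
#' @export
simulate_ou_ligand <- function(signal, config) {
  rc <- resolve_config(config, tau_c = signal$tau_L, tau_r = signal$tau_L,
                       tau_L = signal$tau_L)
  set.seed(config$seed)
  out <- .sim_ou_cpp(signal$L_mean, signal$sigma_L, signal$tau_L,
                     rc$dt, rc$n_steps, rc$n_burn, rc$record_every)
  out$valid <- out$clamped_fraction <= config$clamp_fraction_max
  out$dt_rec <- rc$dt * rc$record_every
  out$config <- config
  out
}

#' Simulate the full receptor + push-pull network
#'
#' Hybrid stochastic simulation: the ligand follows its exact OU update;
#' receptor binding/unbinding and the four readout reactions fire as
#' aggregated binomial updates at piecewise-constant rates over `dt`.  The
#' net receptor-catalysed activation flux is accumulated so the stationary
#' cycle flux can be compared with [steady_state()].
#'
#' @param receptor a [receptor_params()] object.
#' @param readout a [readout_params()] object.
#' @param signal a [signal_params()] object.
#' @param config a [sim_config()] object.
#' @return An object of class `trajectory_bundle`: recorded `times`, `L`,
#'   `RL`, `X_star`, the recording interval `dt_rec`, `clamped_fraction`
#'   and `valid` flag, the realized `net_flux_rate`, steady-state echo
#'   `state`, and the seed/config echo.
#' @export
simulate_network <- function(receptor, readout, signal, config) {
  st <- steady_state(receptor, readout, signal)
  rc <- resolve_config(config, st$tau_c, st$tau_r, signal$tau_L)
  # conservative pre-check of per-step event probabilities (3-sigma signal)
  L_hi <- signal$L_mean + 3 * signal$sigma_L
  RL_hi <- min(receptor$R_T,
               st$p * receptor$R_T + 5 * sqrt(receptor$R_T * st$p * (1 - st$p)))
  pmax_est <- 1 - exp(-max(receptor$k1 * L_hi, receptor$k2,
                           readout$kf * RL_hi, readout$kmf * RL_hi,
                           readout$kr, readout$kmr) * rc$dt)
  if (pmax_est > 0.1)
    stop_domain("configuration error: per-step event probability exceeds 0.1; reduce dt")
  set.seed(config$seed)
  out <- .sim_network_cpp(signal$L_mean, signal$sigma_L, signal$tau_L,
                          receptor$R_T, receptor$k1, receptor$k2,
                          readout$X_T, readout$kf, readout$kmf,
                          readout$kr, readout$kmr,
                          rc$dt, rc$n_steps, rc$n_burn, rc$record_every)
  if (out$max_event_prob > 0.1)
    stop_domain("configuration error: realized per-step event probability exceeded 0.1")
  out$valid <- out$clamped_fraction <= config$clamp_fraction_max
  out$dt_rec <- rc$dt * rc$record_every
  out$state <- st
  out$receptor <- receptor
  out$readout <- readout
  out$signal <- signal
  out$config <- config
  class(out) <- "trajectory_bundle"
  out
}

#' @export
print.trajectory_bundle <- function(x, ...) {
  cat("push-pull trajectory:", length(x$times), "recorded points, dt_rec =",
      x$dt_rec, "\n")
  cat("clamped fraction", x$clamped_fraction,
      if (x$valid) "(valid)" else "(INVALID: clamping above threshold)", "\n")
  invisible(x)
}

block_stats <- function(x, y, block_len_pts) {
  n_blocks <- floor(length(x) / block_len_pts)
  if (n_blocks < 5) stop_domain("trajectory too short for block bootstrap")
  n <- n_blocks * block_len_pts
  xm <- matrix(x[seq_len(n)], nrow = block_len_pts)
  ym <- matrix(y[seq_len(n)], nrow = block_len_pts)
  list(n_blocks = n_blocks, m = block_len_pts,
       sx = colSums(xm), sy = colSums(ym),
       sxx = colSums(xm^2), syy = colSums(ym^2), sxy = colSums(xm * ym))
}

rho_from_sums <- function(bs, idx) {
  n <- length(idx) * bs$m
  sx <- sum(bs$sx[idx]); sy <- sum(bs$sy[idx])
  sxx <- sum(bs$sxx[idx]); syy <- sum(bs$syy[idx]); sxy <- sum(bs$sxy[idx])
  vx <- sxx / n - (sx / n)^2
  vy <- syy / n - (sy / n)^2
  cxy <- sxy / n - (sx / n) * (sy / n)
  if (vx <= 0 || vy <= 0) stop_domain("degenerate variance in trajectory")
  cxy / sqrt(vx * vy)
}

#' Empirical SNR and mutual information of a simulated trajectory
#'
#' Stationary Pearson correlation `rho` between the ligand signal and the
#' active readout count, converted through the jointly-Gaussian identities
#' `SNR = rho^2 / (1 - rho^2)` and `I = -log(1 - rho^2) / 2` (nats).
#' Standard errors come from a moving-block bootstrap with block length
#' `10 max(tau_c, tau_r, tau_L)`.
#'
#' @param bundle a [simulate_network()] trajectory.
#' @param n_boot bootstrap replicates (default 200).
#' @param block_len block length in time units; default
#'   `10 max(tau_c, tau_r, tau_L)`.
#' @return A list with `rho`, `snr`, `mutual_info_nats`, bootstrap
#'   standard errors `se_rho`, `se_snr`, and `n_blocks`.
#' @export
empirical_snr <- function(bundle, n_boot = 200, block_len = NULL) {
  st <- bundle$state
  block_len <- block_len %||%
    (10 * max(st$tau_c, st$tau_r, bundle$signal$tau_L))
  blen_pts <- max(2L, ceiling(block_len / bundle$dt_rec))
  bs <- block_stats(bundle$L, as.numeric(bundle$X_star), blen_pts)
  rho <- rho_from_sums(bs, seq_len(bs$n_blocks))
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(bs$n_blocks, bs$n_blocks, replace = TRUE)
    r <- rho_from_sums(bs, idx)
    c(r, r^2 / (1 - r^2))
  }, numeric(2))
  list(rho = rho, snr = rho^2 / (1 - rho^2),
       mutual_info_nats = -0.5 * log1p(-rho^2),
       se_rho = sd(boot[1, ]), se_snr = sd(boot[2, ]),
       n_blocks = bs$n_blocks)
}

#' Empirical dynamic gain from a simulated trajectory
#'
#' The trailing average of the receptor occupancy over the past `tau_r`
#' (exponential kernel, matching the push-pull filter) is regressed on the
#' current ligand concentration; the slope `cov / var` estimates the
#' dynamic gain and is compared against [dynamic_gain()].
#'
#' @param bundle a [simulate_network()] trajectory.
#' @param tau_r averaging timescale; default the network's relaxation time.
#' @return A list with `slope`, its ratio to the static gain
#'   (`attenuation`), and the predicted `dynamic_gain`.
#' @export
empirical_gain <- function(bundle, tau_r = NULL) {
  st <- bundle$state
  tau_r <- tau_r %||% st$tau_r
  a <- exp(-bundle$dt_rec / tau_r)
  occ <- as.numeric(bundle$RL) / bundle$receptor$R_T
  y <- as.numeric(stats::filter((1 - a) * occ, a, method = "recursive"))
  drop <- min(length(y) - 2L, ceiling(10 * tau_r / bundle$dt_rec))
  keep <- seq.int(drop + 1L, length(y))
  L <- bundle$L[keep]; y <- y[keep]
  if (var(L) <= 0) stop_domain("degenerate ligand variance")
  slope <- cov(y, L) / var(L)
  g0 <- static_gain(st$p, bundle$signal$L_mean)
  list(slope = slope, attenuation = slope / g0,
       dynamic_gain = dynamic_gain(st$p, bundle$signal$L_mean, st$tau_c,
                                   tau_r, bundle$signal$tau_L))
}

#' Spectral (linear-noise) SNR of the sensing network
#'
#' Independent frequency-domain oracle: the linearized cascade
#' ligand -> bound receptor -> active readout is a chain of first-order
#' low-pass filters with intrinsic binding and (de)modification shot noise.
#' The stationary covariances are obtained by integrating the Lorentzian
#' spectra over frequency, and the Gaussian identity
#' `SNR = rho^2 / (1 - rho^2)` converts the ligand-readout correlation.
#' Valid in the linearization regime (`sigma_L / L_mean <= ~0.1`).
#'
#' @inheritParams simulate_network
#' @param rel_tol quadrature relative tolerance (default 1e-10).
#' @return A list with `rho`, `snr`, `mutual_info_nats`.
#' @export
spectral_snr <- function(receptor, readout, signal, rel_tol = 1e-10) {
  st <- steady_state(receptor, readout, signal)
  a <- 1 / st$tau_c
  b <- 1 / st$tau_r
  lam <- 1 / signal$tau_L
  nbar <- st$p * receptor$R_T
  g_L <- receptor$k1 * (1 - st$p) * receptor$R_T      # input coupling
  S_n <- 2 * st$p * (1 - st$p) * receptor$R_T / st$tau_c  # receptor shot noise
  G <- readout$kf * st$xbar - readout$kmf * st$xstar  # receptor -> readout
  phi <- (readout$kf * nbar + readout$kmr) * st$xbar  # one-way readout flux
  S_m <- 2 * phi
  S_LL <- function(w) 2 * signal$sigma_L^2 / signal$tau_L / (w^2 + lam^2)

  quad <- function(f) {
    integrate(f, 0, Inf, rel.tol = rel_tol, subdivisions = 2000L,
              stop.on.error = TRUE)$value / pi
  }
  cov_mL <- quad(function(w)
    G * g_L * S_LL(w) * (a * b - w^2) / ((a^2 + w^2) * (b^2 + w^2)))
  var_m <- quad(function(w)
    (G^2 * (g_L^2 * S_LL(w) + S_n) / (a^2 + w^2) + S_m) / (b^2 + w^2))
  if (var_m <= 0) stop_domain("quadrature returned non-positive variance")
  rho <- cov_mL / sqrt(var_m * signal$sigma_L^2)
  list(rho = rho, snr = rho^2 / (1 - rho^2),
       mutual_info_nats = -0.5 * log1p(-rho^2))
}
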