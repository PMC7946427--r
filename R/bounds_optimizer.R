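# Resource bounds, optimal integration time, allocation principle, Pareto
# fronts.  Optimization is deterministic: coarse log grid (64 points per
# decade) followed by golden-section refinement; ties break toward smaller
# tau_r.

# Lean evaluation of 1/SNR from coarse coordinates (hot path for the
# optimizers; snr_total() builds the same quantities as a rich object).
inv_snr_coords <- function(p, f, tau_r, q, R_T, X_T, tau_c, tau_L, noise,
                           xt_infinite = FALSE) {
  pref <- (1 + tau_c / tau_L)^2 * (1 + tau_r / tau_L)^2
  inv2 <- 1 / noise^2
  if (xt_infinite) {
    n_I <- q * R_T * tau_r / tau_c
    samp <- pref * inv2 / (p * (1 - p) * n_I)
  } else {
    n_eff <- f * (1 - f) * X_T * q^2 / p
    if (n_eff <= 0) return(Inf)
    delta <- 2 * tau_r * R_T / n_eff
    n_I <- n_eff / (1 + 2 * tau_c / delta)
    samp <- pref * inv2 * (1 / (p * (1 - p) * n_I) +
                             1 / ((1 - p)^2 * n_eff))
  }
  dyn <- (1 + tau_c / tau_L) * (1 + tau_r / tau_L) /
    (1 + tau_c * tau_r / (tau_L * (tau_c + tau_r))) - 1
  samp + dyn
}

# Deterministic 1-d minimizer: log-spaced grid + golden-section refinement.
# Ties (within numerical equality) go to the smaller abscissa because
# which.min returns the first minimum.
minimize_log_grid <- function(fn, lower, upper, n_per_decade = 64,
                              tol = 1e-12) {
  lo <- log(lower); hi <- log(upper)
  n <- max(8L, ceiling((hi - lo) / log(10) * n_per_decade)) + 1L
  grid <- seq(lo, hi, length.out = n)
  vals <- vapply(grid, function(g) fn(exp(g)), numeric(1))
  i <- which.min(vals)
  a <- grid[max(1L, i - 1L)]
  b <- grid[min(n, i + 1L)]
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- fn(exp(x1)); f2 <- fn(exp(x2))
  while (b - a > tol) {
    if (f1 <= f2) {       # "<=" pushes ties toward smaller tau_r
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- fn(exp(x1))
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- fn(exp(x2))
    }
  }
  x <- exp((a + b) / 2)
  list(x = x, value = fn(x),
       boundary = (i == 1L || i == n))
}

# Golden-section on an occupancy/fraction in (0, 1), linear scale.
minimize_unit_interval <- function(fn, lower = 1e-4, upper = 1 - 1e-4,
                                   tol = 1e-10) {
  gr <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- fn(x1); f2 <- fn(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a); f1 <- fn(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a); f2 <- fn(x2)
    }
  }
  x <- (a + b) / 2
  list(x = x, value = fn(x))
}

#' Fundamental lower bound on the sensing error
#'
#' For an effective number of independent concentration measurements `h`,
#' the inverse SNR obeys
#' `1/SNR >= (1 + tau_r/tau_L)^2 * 4 / (noise^2 * h) + tau_r / tau_L`,
#' where `noise = sigma_L / L_mean` and
#' `h = min(R_T tau_r / tau_c, X_T, wdot * tau_r)` (kT units) when the
#' three resource classes are evaluated jointly.
#'
#' @param h effective measurement count (> 0).
#' @param tau_r integration time.
#' @param tau_L input correlation time.
#' @param noise relative input noise `sigma_L / L_mean`.
#' @return lower bound on `1/SNR`.
#' @export
fundamental_bound <- function(h, tau_r, tau_L, noise) {
  check_scalar(h, "h", lower = 0)
  (1 + tau_r / tau_L)^2 * 4 / (noise^2 * h) + tau_r / tau_L
}

#' Optimal integration time of the sensing network
#'
#' Maximizes the sensing precision over the integration time `tau_r` (and
#' optionally the receptor occupancy `p`) in one of three resource regimes:
#' receptor-limited (`"receptors"`: unbounded readout pool, perfect copies
#' -- the Berg-Purcell limit), readout-limited (`"readouts"`: finite `X_T`,
#' perfect copies) or power-limited (`"power"`: fixed dissipation `wdot` at
#' total drive `dmu`, readout pool implied).  With `objective = "full"` the
#' complete sampling + dynamical error is minimized; with
#' `objective = "bound"` the fundamental resource bound for the regime's
#' `h` is minimized instead (for the receptor regime its minimizer has the
#' closed form `tau_r* = tau_L sqrt(A / (1 + A))`,
#' `A = 4 tau_c / (noise^2 R_T tau_L)`).
#'
#' @param regime which resource is constrained.
#' @param noise relative input noise `sigma_L / L_mean`.
#' @param tau_c receptor correlation time.
#' @param tau_L input correlation time (default 1; all times in its units).
#' @param R_T receptor count (regimes `"receptors"`, `"readouts"`, `"power"`).
#' @param X_T readout count (regime `"readouts"`).
#' @param wdot dissipated power in kT per time (regime `"power"`).
#' @param dmu total drive in kT for the power regime (default 4, the
#'   crossover optimum; see [delta_mu_opt()]).
#' @param objective `"full"` (complete error) or `"bound"` (resource bound).
#' @param optimize_p also optimize the receptor occupancy (default `FALSE`,
#'   `p = 1/2`).
#' @param p,f occupancy and active fraction used when not optimized.
#' @param tau_r_range search interval (default `c(1e-6, 10) * tau_L`);
#'   boundary optima are flagged.
#' @param n_per_decade grid density before golden-section refinement.
#' @return A list with `tau_r_opt`, `snr_max`, `I_max`, `p_opt` and a
#'   `boundary` flag.
#' @examples
#' # receptor-limited bound with A = 1 has tau_r* = tau_L / sqrt(2)
#' opt <- optimal_tau_r("receptors", noise = 0.02, tau_c = 0.01,
#'                      R_T = 100, objective = "bound")
#' opt$tau_r_opt * sqrt(2)
#' @export
optimal_tau_r <- function(regime = c("receptors", "readouts", "power"),
                          noise, tau_c, tau_L = 1,
                          R_T = NULL, X_T = NULL, wdot = NULL, dmu = 4,
                          objective = c("full", "bound"),
                          optimize_p = FALSE, p = 0.5, f = 0.5,
                          tau_r_range = c(1e-6, 10) * tau_L,
                          n_per_decade = 64) {
  regime <- match.arg(regime)
  objective <- match.arg(objective)
  check_scalar(noise, "noise", lower = 0)
  check_scalar(tau_c, "tau_c", lower = 0)
  if (regime %in% c("receptors", "readouts") && is.null(R_T))
    stop_domain("R_T is required in the '", regime, "' regime")
  if (regime == "readouts" && is.null(X_T))
    stop_domain("X_T is required in the 'readouts' regime")
  if (regime == "power" && (is.null(wdot) || is.null(R_T)))
    stop_domain("wdot and R_T are required in the 'power' regime")

  q_dmu <- sample_quality(dmu / 2, dmu / 2)
  inv_snr <- function(tau_r, p_) {
    switch(regime,
      receptors = if (objective == "bound")
        fundamental_bound(R_T * tau_r / tau_c, tau_r, tau_L, noise)
      else
        inv_snr_coords(p_, f, tau_r, q = 1, R_T = R_T, X_T = Inf,
                       tau_c = tau_c, tau_L = tau_L, noise = noise,
                       xt_infinite = TRUE),
      readouts = if (objective == "bound")
        fundamental_bound(X_T, tau_r, tau_L, noise)
      else
        inv_snr_coords(p_, f, tau_r, q = 1, R_T = R_T, X_T = X_T,
                       tau_c = tau_c, tau_L = tau_L, noise = noise),
      power = if (objective == "bound")
        fundamental_bound(wdot * tau_r / max(1, dmu / 4), tau_r, tau_L, noise)
      else
        inv_snr_coords(p_, f, tau_r, q = q_dmu, R_T = R_T,
                       X_T = wdot * tau_r / (dmu * q_dmu * f * (1 - f)),
                       tau_c = tau_c, tau_L = tau_L, noise = noise))
  }

  p_cur <- p
  res <- minimize_log_grid(function(tr) inv_snr(tr, p_cur),
                           tau_r_range[1], tau_r_range[2],
                           n_per_decade = n_per_decade)
  if (optimize_p && objective == "full") {
    for (sweep in 1:3) {
      p_cur <- minimize_unit_interval(function(pp) inv_snr(res$x, pp))$x
      res <- minimize_log_grid(function(tr) inv_snr(tr, p_cur),
                               tau_r_range[1], tau_r_range[2],
                               n_per_decade = n_per_decade)
    }
  }
  snr_max <- 1 / res$value
  list(tau_r_opt = res$x, snr_max = snr_max,
       I_max = mutual_information(snr_max),
       p_opt = p_cur, boundary = res$boundary)
}

# Receptor-limited optimum evaluated through the spectral (linear-noise)
# oracle: abundant readouts (X_T = 1000 R_T) and near-irreversible driving
# stand in for the unbounded-readout, perfect-copy regime, since the
# frequency-domain route needs finite microscopic rates.  p = f = 1/2.
optimal_tau_r_spectral <- function(noise, tau_c, tau_L = 1, R_T,
                                   tau_r_range = c(1e-3, 10) * tau_L,
                                   n_per_decade = 8) {
  sig <- signal_params(1, noise, tau_L)
  rec <- receptor_rates_from_design(0.5, tau_c, 1, R_T = R_T)
  inv_snr <- function(tau_r) {
    rd <- readout_rates_from_design(0.5, tau_r, 13, 13, 0.5, R_T,
                                    X_T = 1000 * R_T)
    1 / spectral_snr(rec, rd, sig, rel_tol = 1e-8)$snr
  }
  res <- minimize_log_grid(inv_snr, tau_r_range[1], tau_r_range[2],
                           n_per_decade = n_per_decade, tol = 1e-6)
  snr_max <- 1 / res$value
  list(tau_r_opt = res$x, snr_max = snr_max,
       I_max = mutual_information(snr_max), p_opt = 0.5,
       boundary = res$boundary)
}

#' Closed-form optimal integration time in the receptor-limited bound
#'
#' Minimizer of the fundamental bound with `h = R_T tau_r / tau_c`:
#' `tau_r* = tau_L sqrt(A / (1 + A))` with
#' `A = 4 tau_c / (noise^2 R_T tau_L)`.
#'
#' @inheritParams optimal_tau_r
#' @return the optimal `tau_r`.
#' @export
tau_r_opt_closed_form <- function(noise, tau_c, tau_L = 1, R_T) {
  A <- 4 * tau_c / (noise^2 * R_T * tau_L)
  tau_L * sqrt(A / (1 + A))
}

#' Readout molecules required to sustain a given power
#'
#' Number of readout molecules consuming energy at rate `wdot` during one
#' integration time.  In the irreversible regime (`q -> 1`)
#' `X_T = wdot tau_r / (dmu f (1 - f))`; in the quasi-equilibrium regime
#' (`q -> dmu / 4`) `X_T = 4 wdot tau_r / (dmu^2 f (1 - f))` (kT units).
#' The two coincide at the crossover `dmu = 4` kT.
#'
#' @param wdot dissipated power (kT per time, > 0).
#' @param tau_r integration time (> 0).
#' @param dmu total free-energy drop (kT, > 0).
#' @param f active readout fraction, strictly inside (0, 1).
#' @param regime `"irr"` (irreversible) or `"qeq"` (quasi-equilibrium).
#' @return readout count (not rounded).
#' @export
xt_required <- function(wdot, tau_r, dmu, f = 0.5,
                        regime = c("irr", "qeq")) {
  regime <- match.arg(regime)
  check_scalar(wdot, "wdot", lower = 0)
  check_scalar(tau_r, "tau_r", lower = 0)
  check_scalar(dmu, "dmu", lower = 0)
  check_scalar(f, "f", lower = 0, upper = 1)
  switch(regime,
         irr = wdot * tau_r / (dmu * f * (1 - f)),
         qeq = 4 * wdot * tau_r / (dmu^2 * f * (1 - f)))
}

#' Optimal free-energy drop of the readout cycle
#'
#' The allocation principle equates the readout pool with the work spent
#' filling it, which fixes the drive via `q(dmu) = 4 / dmu` (kT units,
#' symmetric legs, so `q = tanh(dmu / 4)`).  The root is ~4.8 kT; the
#' crossover between the quasi-equilibrium and irreversible regimes,
#' `dmu = 4` kT where `q = tanh(1) ~ 0.76`, is its standard approximation.
#'
#' @return A list with `dmu_opt` (kT), `q_opt = 4 / dmu_opt`, and
#'   `q_crossover = tanh(1)`, the quality at the 4 kT crossover.
#' @examples
#' delta_mu_opt()$dmu_opt   # ~ 4.80
#' @export
delta_mu_opt <- function() {
  root <- uniroot(function(d) tanh(d / 4) - 4 / d,
                  interval = c(1, 50), tol = 1e-14)$root
  list(dmu_opt = root, q_opt = 4 / root, q_crossover = tanh(1))
}

#' Resource-allocation audit of a design
#'
#' In an optimally designed system the number of independent receptor
#' measurements, the readout pool storing them, and the work spent storing
#' them reliably are matched: `R_T tau_r / tau_c ~ X_T ~ wdot tau_r` (kT
#' units).  Returns the three quantities and their max/min spread ratio;
#' designs on a computed Pareto front satisfy spread <= 3 (order-unity
#' agreement).
#'
#' @param design a [design_point()] object (finite `X_T` and drops).
#' @param tau_c receptor correlation time.
#' @return A list with `measurements`, `readouts`, `work` and `spread`.
#' @export
allocation_gap <- function(design, tau_c) {
  q <- if (design$q_unity) 1 else sample_quality(design$dmu1, design$dmu2)
  dmu <- design$dmu1 + design$dmu2
  triple <- c(measurements = design$R_T * design$tau_r / tau_c,
              readouts = design$X_T,
              work = q * dmu * design$f * (1 - design$f) * design$X_T)
  list(measurements = triple[["measurements"]],
       readouts = triple[["readouts"]],
       work = triple[["work"]],
       spread = max(triple) / min(triple))
}

#' Pareto front of sensing precision versus protein cost
#'
#' For each total protein cost `C = R_T + c_X * X_T`, minimizes the full
#' sensing error over the receptor share, the occupancy `p` and the
#' integration time `tau_r` (active fraction fixed at the symmetric optimum
#' `f = 1/2`; sample quality fixed by `dmu`, default the 4 kT crossover
#' where `q = tanh(1) ~ 0.76`).  Copy numbers are treated as continuous.
#'
#' @param cost vector of protein-cost values (each > 2).
#' @param noise relative input noise (default 0.01).
#' @param tau_c receptor correlation time (default 0.01 `tau_L`).
#' @param tau_L input correlation time (default 1).
#' @param c_X relative cost of a readout versus a receptor (default 1).
#' @param dmu total drive per cycle (kT, default 4).
#' @param optimize_p co-optimize the occupancy (default `TRUE`).
#' @return A data frame with one row per cost: the optimizing design
#'   (`R_T`, `X_T`, `p`, `tau_r`), `snr_max`, `I_max`, and the allocation
#'   triple with its `spread`.
#' @export
pareto_front <- function(cost, noise = 0.01, tau_c = 0.01, tau_L = 1,
                         c_X = 1, dmu = 4, optimize_p = TRUE) {
  check_scalar(c_X, "c_X", lower = 0)
  if (any(cost <= 2)) stop_domain("each cost value must exceed 2 proteins")
  q <- sample_quality(dmu / 2, dmu / 2)
  one <- function(C) {
    obj_s <- function(s) {           # s = receptor share of the cost
      R_T <- s * C
      X_T <- (1 - s) * C / c_X
      inner <- function(p_) {
        minimize_log_grid(function(tr)
          inv_snr_coords(p_, 0.5, tr, q, R_T, X_T, tau_c, tau_L, noise),
          1e-6 * tau_L, 10 * tau_L, n_per_decade = 16)
      }
      p_best <- 0.5
      res <- inner(p_best)
      if (optimize_p) {
        p_best <- minimize_unit_interval(function(pp) inner(pp)$value,
                                         tol = 1e-6)$x
        res <- inner(p_best)
      }
      list(value = res$value, tau_r = res$x, p = p_best)
    }
    s_opt <- minimize_unit_interval(function(s) obj_s(s)$value,
                                    lower = 1e-3, upper = 1 - 1e-3,
                                    tol = 1e-6)
    best <- obj_s(s_opt$x)
    R_T <- s_opt$x * C
    X_T <- (1 - s_opt$x) * C / c_X
    d <- design_point(p = best$p, f = 0.5, tau_r = best$tau_r,
                      dmu1 = dmu / 2, dmu2 = dmu / 2,
                      R_T = R_T, X_T = X_T)
    gap <- allocation_gap(d, tau_c)
    snr <- 1 / best$value
    data.frame(cost = C, R_T = R_T, X_T = X_T, p = best$p,
               tau_r = best$tau_r, snr_max = snr,
               I_max = mutual_information(snr),
               measurements = gap$measurements, readouts = gap$readouts,
               work = gap$work, spread = gap$spread)
  }
  do.call(rbind, lapply(cost, one))
}

#' Resource sweeps of the optimal design
#'
#' Tidy tables of the maximal mutual information and the optimal
#' integration time over sweeps of the resources, each obtained by
#' minimizing the full sensing error over `tau_r` (and `p`).  Scenarios:
#' `"info_vs_copies"` (grid of `R_T` x `X_T`, irreversible copies),
#' `"info_vs_power"` (grid of `R_T` x `wdot` at fixed `dmu`),
#' `"tau_vs_rt"` (optimal `tau_r` versus `R_T`, unbounded readout pool),
#' `"tau_vs_tauc"` (versus the receptor correlation time, same limit),
#' `"tau_vs_xt"` (versus `X_T` for several `R_T`),
#' `"tau_vs_power"` (versus `wdot` at fixed `R_T` and `dmu`).
#' Defaults follow the reference operating point `tau_c/tau_L = 0.01`,
#' `noise = 0.01`.
#'
#' @param scenario which sweep to run.
#' @param noise relative input noise.
#' @param tau_c receptor correlation time.
#' @param tau_L input correlation time.
#' @param R_T,X_T,wdot grids for the swept resources (scenario-dependent
#'   defaults).
#' @param dmu total drive (kT) for the power scenarios.
#' @param optimize_p co-optimize the occupancy (default `TRUE`).
#' @param n_per_decade optimizer grid density (default 32 for sweeps).
#' @param objective for `"tau_vs_tauc"`: `"spectral"` (default) evaluates
#'   the exact linearized model through [spectral_snr()], which captures the
#'   collapse to instantaneous response once the receptor correlation time
#'   approaches the input timescale; `"full"` uses the closed-form error,
#'   whose sample-independence interpolation is only valid for
#'   `tau_r > tau_c` and therefore misses the downturn.
#' @return A data frame, one row per grid point, deterministic row order.
#' @export
scan_resources <- function(scenario = c("info_vs_copies", "info_vs_power",
                                        "tau_vs_rt", "tau_vs_tauc",
                                        "tau_vs_xt", "tau_vs_power"),
                           noise = 0.01, tau_c = 0.01, tau_L = 1,
                           R_T = NULL, X_T = NULL, wdot = NULL, dmu = 4,
                           optimize_p = TRUE, n_per_decade = 32,
                           objective = c("spectral", "full")) {
  scenario <- match.arg(scenario)
  objective <- match.arg(objective)
  grid10 <- function(lo, hi, per_decade = 2)
    10^seq(log10(lo), log10(hi), by = 1 / per_decade)
  rows <- switch(scenario,
    info_vs_copies = {
      R_T <- R_T %||% grid10(10, 1e5, 1)
      X_T <- X_T %||% grid10(10, 1e5, 1)
      do.call(rbind, lapply(R_T, function(rt) do.call(rbind, lapply(X_T,
        function(xt) {
          o <- optimal_tau_r("readouts", noise, tau_c, tau_L, R_T = rt,
                             X_T = xt, optimize_p = optimize_p,
                             n_per_decade = n_per_decade)
          data.frame(R_T = rt, X_T = xt, tau_r_opt = o$tau_r_opt,
                     p_opt = o$p_opt, snr_max = o$snr_max, I_max = o$I_max)
        }))))
    },
    info_vs_power = {
      R_T <- R_T %||% grid10(10, 1e5, 1)
      wdot <- wdot %||% grid10(1, 1e6, 1)
      do.call(rbind, lapply(R_T, function(rt) do.call(rbind, lapply(wdot,
        function(w) {
          o <- optimal_tau_r("power", noise, tau_c, tau_L, R_T = rt,
                             wdot = w, dmu = dmu, optimize_p = optimize_p,
                             n_per_decade = n_per_decade)
          data.frame(R_T = rt, wdot = w, dmu = dmu,
                     tau_r_opt = o$tau_r_opt, p_opt = o$p_opt,
                     snr_max = o$snr_max, I_max = o$I_max)
        }))))
    },
    tau_vs_rt = {
      R_T <- R_T %||% grid10(100, 1e6, 2)
      do.call(rbind, lapply(R_T, function(rt) {
        o <- optimal_tau_r("receptors", noise, tau_c, tau_L, R_T = rt,
                           optimize_p = optimize_p,
                           n_per_decade = n_per_decade)
        data.frame(R_T = rt, tau_r_opt = o$tau_r_opt, p_opt = o$p_opt,
                   snr_max = o$snr_max, I_max = o$I_max)
      }))
    },
    tau_vs_tauc = {
      tau_c_grid <- if (length(tau_c) > 1) tau_c else
        10^seq(-4, 2, by = 0.25) * tau_L
      rt <- (R_T %||% 1e3)[1]
      do.call(rbind, lapply(tau_c_grid, function(tc) {
        o <- if (objective == "spectral")
          optimal_tau_r_spectral(noise, tc, tau_L, R_T = rt,
                                 n_per_decade = max(8, n_per_decade / 4))
        else
          optimal_tau_r("receptors", noise, tc, tau_L, R_T = rt,
                        optimize_p = optimize_p,
                        n_per_decade = n_per_decade)
        data.frame(R_T = rt, tau_c = tc, tau_r_opt = o$tau_r_opt,
                   p_opt = o$p_opt, snr_max = o$snr_max, I_max = o$I_max)
      }))
    },
    tau_vs_xt = {
      R_T <- R_T %||% c(100, 1000)
      X_T <- X_T %||% grid10(10, 1e6, 1)
      do.call(rbind, lapply(R_T, function(rt) do.call(rbind, lapply(X_T,
        function(xt) {
          o <- optimal_tau_r("readouts", noise, tau_c, tau_L, R_T = rt,
                             X_T = xt, optimize_p = optimize_p,
                             n_per_decade = n_per_decade)
          data.frame(R_T = rt, X_T = xt, tau_r_opt = o$tau_r_opt,
                     p_opt = o$p_opt, snr_max = o$snr_max, I_max = o$I_max)
        }))))
    },
    tau_vs_power = {
      rt <- (R_T %||% 1e3)[1]
      wdot <- wdot %||% grid10(0.1, 1e6, 1)
      q <- sample_quality(dmu / 2, dmu / 2)
      do.call(rbind, lapply(wdot, function(w) {
        o <- optimal_tau_r("power", noise, tau_c, tau_L, R_T = rt,
                           wdot = w, dmu = dmu, optimize_p = optimize_p,
                           n_per_decade = n_per_decade)
        data.frame(R_T = rt, wdot = w, dmu = dmu,
                   tau_r_opt = o$tau_r_opt, p_opt = o$p_opt,
                   X_T_opt = w * o$tau_r_opt / (dmu * q * 0.25),
                   snr_max = o$snr_max, I_max = o$I_max)
      }))
    })
  rownames(rows) <- NULL
  rows
}
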