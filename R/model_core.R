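#' @useDynLib pushpull, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats integrate uniroot var cov cor sd coef lm quantile rnorm runif
#' @importFrom utils write.table read.table packageVersion
NULL

# Energies are in units of kT throughout (beta = 1).

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = TRUE, open_upper = TRUE,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_domain(sprintf("'%s' must be a single finite number", name))
  if (!allow_inf && !is.finite(x))
    stop_domain(sprintf("'%s' must be finite", name))
  if (allow_inf && is.infinite(x) && x > lower) return(x)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_domain(sprintf("'%s' = %g is outside its admissible range", name, x))
  x
}

#' Statistics of the fluctuating ligand input
#'
#' The ligand concentration is modelled as a stationary Gaussian Markov
#' (Ornstein-Uhlenbeck) signal with mean `L_mean`, standard deviation
#' `sigma_L` and correlation time `tau_L`.  The linearized theory assumes
#' small relative fluctuations; when `sigma_L / L_mean > 0.3` the object is
#' flagged (`linear_regime = FALSE`) and downstream consumers warn but
#' proceed.
#'
#' @param L_mean mean ligand concentration (arbitrary units, > 0).  All
#'   exported statistics depend on it only through `sigma_L / L_mean`.
#' @param sigma_L standard deviation of the concentration (same units, > 0).
#' @param tau_L correlation time of the input fluctuations (seconds, > 0).
#' @return An object of class `signal_params`.
#' @examples
#' sig <- signal_params(L_mean = 100, sigma_L = 10, tau_L = 1)
#' sig$sigma_L / sig$L_mean
#' @export
signal_params <- function(L_mean, sigma_L, tau_L) {
  check_scalar(L_mean, "L_mean", lower = 0)
  check_scalar(sigma_L, "sigma_L", lower = 0)
  check_scalar(tau_L, "tau_L", lower = 0)
  structure(list(L_mean = L_mean, sigma_L = sigma_L, tau_L = tau_L,
                 linear_regime = (sigma_L / L_mean) <= 0.3),
            class = "signal_params")
}

#' @export
print.signal_params <- function(x, ...) {
  cat("OU ligand input: mean", x$L_mean, " sd", x$sigma_L,
      " tau_L", x$tau_L, "s\n")
  cat("relative noise sigma_L/L_mean =", x$sigma_L / x$L_mean,
      if (x$linear_regime) "(linear regime)" else "(OUTSIDE linear regime)",
      "\n")
  invisible(x)
}

#' Receptor-ligand binding parameters
#'
#' `R_T` receptors bind ligand independently with association rate `k1`
#' (per concentration per time) and dissociation rate `k2` (per time).  At
#' mean concentration `L` the occupancy is `p = k1 L / (k1 L + k2)` and the
#' correlation time of the receptor state is `tau_c = 1 / (k1 L + k2)`.
#'
#' @param R_T total receptor count (positive integer).
#' @param k1 association rate constant (> 0).
#' @param k2 dissociation rate (> 0).
#' @return An object of class `receptor_params`.
#' @seealso [receptor_occupancy()], [receptor_corr_time()],
#'   [receptor_rates_from_design()]
#' @export
receptor_params <- function(R_T, k1, k2) {
  check_scalar(R_T, "R_T", lower = 0)
  if (R_T != round(R_T)) stop_domain("'R_T' must be an integer count")
  check_scalar(k1, "k1", lower = 0)
  check_scalar(k2, "k2", lower = 0)
  structure(list(R_T = as.integer(R_T), k1 = k1, k2 = k2),
            class = "receptor_params")
}

#' Receptor occupancy at a given mean concentration
#' @param receptor a [receptor_params()] object.
#' @param L_mean mean ligand concentration.
#' @return occupancy `p` in (0, 1).
#' @export
receptor_occupancy <- function(receptor, L_mean) {
  with(receptor, k1 * L_mean / (k1 * L_mean + k2))
}

#' Receptor correlation time at a given mean concentration
#' @inheritParams receptor_occupancy
#' @return `tau_c = 1 / (k1 L_mean + k2)`.
#' @export
receptor_corr_time <- function(receptor, L_mean) {
  with(receptor, 1 / (k1 * L_mean + k2))
}

#' Push-pull readout parameters
#'
#' The ligand-bound receptor catalyses activation of a readout molecule
#' (`x -> x*`, rate `kf` per bound receptor) with microscopic reverse `kmf`;
#' deactivation is spontaneous (`x* -> x`, rate `kr`) with microscopic
#' reverse `kmr`.  Fuel species (ATP/ADP/Pi) are absorbed into the rates.
#' Zero reverse rates are only admitted under the explicit irreversible
#' limit (see `q_unity` in [design_point()]).
#'
#' @param X_T total readout count (positive integer).
#' @param kf activation rate per ligand-bound receptor (> 0).
#' @param kmf microscopic reverse of `kf` (>= 0).
#' @param kr deactivation rate (> 0).
#' @param kmr microscopic reverse of `kr` (>= 0).
#' @return An object of class `readout_params`.
#' @export
readout_params <- function(X_T, kf, kmf, kr, kmr) {
  check_scalar(X_T, "X_T", lower = 0)
  if (X_T != round(X_T)) stop_domain("'X_T' must be an integer count")
  check_scalar(kf, "kf", lower = 0)
  check_scalar(kr, "kr", lower = 0)
  check_scalar(kmf, "kmf", lower = 0, open_lower = FALSE)
  check_scalar(kmr, "kmr", lower = 0, open_lower = FALSE)
  structure(list(X_T = as.integer(X_T), kf = kf, kmf = kmf, kr = kr, kmr = kmr),
            class = "readout_params")
}

#' Coarse design coordinates of the sensing system
#'
#' The coordinates in which the theory is optimized: receptor occupancy `p`,
#' active readout fraction `f`, integration time `tau_r`, the free-energy
#' drops `dmu1` (activation leg) and `dmu2` (deactivation leg) in units of
#' kT, and the copy numbers `R_T`, `X_T`.  Two limit flags replace infinite
#' parameters: `xt_infinite` (readout pool unbounded, suppresses the
#' finite-storage error terms) and `q_unity` (irreversible driving,
#' `dmu -> Inf`, perfect sample quality).
#'
#' @param p mean receptor occupancy, in (0, 1).
#' @param f mean active readout fraction, in (0, 1).
#' @param tau_r integration (readout relaxation) time (> 0).
#' @param dmu1,dmu2 free-energy drops over the activation and deactivation
#'   reactions (kT, >= 0).  Ignored when `q_unity = TRUE`.
#' @param R_T receptor count.
#' @param X_T readout count; may be `NULL`/`Inf` when `xt_infinite = TRUE`.
#' @param xt_infinite logical flag for the unbounded-readout limit.
#' @param q_unity logical flag for the irreversible (perfect-copy) limit.
#' @return An object of class `design_point`.
#' @examples
#' design_point(p = 0.5, f = 0.5, tau_r = 0.1, dmu1 = 2, dmu2 = 2,
#'              R_T = 100, X_T = 1000)
#' @export
design_point <- function(p, f = 0.5, tau_r, dmu1 = Inf, dmu2 = Inf,
                         R_T, X_T = Inf,
                         xt_infinite = !is.finite(X_T),
                         q_unity = !is.finite(dmu1) && !is.finite(dmu2)) {
  check_scalar(p, "p", lower = 0, upper = 1)
  check_scalar(f, "f", lower = 0, upper = 1)
  check_scalar(tau_r, "tau_r", lower = 0)
  check_scalar(R_T, "R_T", lower = 0)
  if (!q_unity) {
    check_scalar(dmu1, "dmu1", lower = 0, open_lower = FALSE, allow_inf = TRUE)
    check_scalar(dmu2, "dmu2", lower = 0, open_lower = FALSE, allow_inf = TRUE)
  }
  if (!xt_infinite) check_scalar(X_T, "X_T", lower = 0)
  structure(list(p = p, f = f, tau_r = tau_r, dmu1 = dmu1, dmu2 = dmu2,
                 R_T = R_T, X_T = if (xt_infinite) Inf else X_T,
                 xt_infinite = isTRUE(xt_infinite),
                 q_unity = isTRUE(q_unity)),
            class = "design_point")
}

#' Microscopic receptor rates from design coordinates
#'
#' Inverts `tau_c = 1/(k1 L_mean + k2)` and `p = k1 L_mean/(k1 L_mean + k2)`:
#' `k1 = p/(tau_c L_mean)`, `k2 = (1 - p)/tau_c`.  Recomputing `p`, `tau_c`
#' from the returned rates reproduces the inputs exactly.
#'
#' @param p receptor occupancy, in (0, 1).
#' @param tau_c receptor correlation time (> 0).
#' @param L_mean mean ligand concentration (> 0).
#' @param R_T receptor count carried into the returned object (default 1).
#' @return A [receptor_params()] object.
#' @export
receptor_rates_from_design <- function(p, tau_c, L_mean, R_T = 1L) {
  check_scalar(p, "p", lower = 0, upper = 1)
  check_scalar(tau_c, "tau_c", lower = 0)
  check_scalar(L_mean, "L_mean", lower = 0)
  receptor_params(R_T = R_T, k1 = p / (tau_c * L_mean), k2 = (1 - p) / tau_c)
}

#' Microscopic readout rates from design coordinates
#'
#' Solves for `(kf, kmf, kr, kmr)` such that the steady-state active
#' fraction, relaxation time and free-energy drops of the resulting cycle
#' reproduce `(f, tau_r, dmu1, dmu2)`, with the ligand-bound receptor count
#' entering in mean field as `p * R_T`.  Writing `a = kf p R_T`, `c = kr`,
#' detailed bookkeeping of the stationary cycle gives the linear system
#' `a (1 - f) (1 - exp(-dmu1)) = c f (1 - exp(-dmu2))` together with the
#' rate-sum constraint `a + a' + c + c' = 1/tau_r` (primes denote the
#' microscopic reverses).
#'
#' @param f active readout fraction, in (0, 1).
#' @param tau_r relaxation time (> 0).
#' @param dmu1,dmu2 free-energy drops (kT, > 0, finite; the irreversible
#'   limit is a [design_point()] flag, not a job for this map).
#' @param p receptor occupancy.
#' @param R_T receptor count.
#' @param X_T readout count carried into the returned object (default 1).
#' @return A [readout_params()] object.
#' @export
readout_rates_from_design <- function(f, tau_r, dmu1, dmu2, p, R_T, X_T = 1L) {
  check_scalar(f, "f", lower = 0, upper = 1)
  check_scalar(tau_r, "tau_r", lower = 0)
  check_scalar(dmu1, "dmu1", lower = 0)
  check_scalar(dmu2, "dmu2", lower = 0)
  check_scalar(p, "p", lower = 0, upper = 1)
  check_scalar(R_T, "R_T", lower = 0)
  # am = a (1-f) / (f e^{dmu1});  cm = c f e^{-dmu2} / (1-f)
  # flux balance  => c = a (1-f)(1 - e^{-dmu1}) / (f (1 - e^{-dmu2}))
  # rate sum      => a [1 + (1-f)/(f e^{dmu1})] + c [1 + f e^{-dmu2}/(1-f)] = 1/tau_r
  ratio <- (1 - f) * (1 - exp(-dmu1)) / (f * (1 - exp(-dmu2)))
  coef_a <- 1 + (1 - f) / (f * exp(dmu1))
  coef_c <- 1 + f * exp(-dmu2) / (1 - f)
  a <- (1 / tau_r) / (coef_a + ratio * coef_c)
  c_ <- a * ratio
  am <- a * (1 - f) / (f * exp(dmu1))
  cm <- c_ * f * exp(-dmu2) / (1 - f)
  if (!all(is.finite(c(a, am, c_, cm))) || a <= 0 || c_ <= 0)
    stop_domain("no positive rate solution for the requested (f, tau_r, dmu1, dmu2)")
  readout_params(X_T = X_T, kf = a / (p * R_T), kmf = am / (p * R_T),
                 kr = c_, kmr = cm)
}

#' Thermodynamic state of the readout cycle
#'
#' Bundles the free-energy drops, the net cycle flux and the dissipated
#' power of a push-pull cycle at steady state.  `dmu = dmu1 + dmu2 =
#' log(kf kr / (kmf kmr))` is independent of the steady state; `ndot = 0`
#' exactly at detailed balance (`dmu = 0`) and `wdot = ndot * dmu >= 0`.
#'
#' @param dmu1,dmu2 free-energy drops (kT).
#' @param ndot net activation flux around the cycle (events per time).
#' @param tau_r relaxation time used to convert power to work.
#' @return An object of class `thermo_state` with fields `dmu1`, `dmu2`,
#'   `dmu`, `ndot`, `wdot`, `work` (all energies in kT).
#' @export
thermo_state <- function(dmu1, dmu2, ndot, tau_r) {
  dmu <- dmu1 + dmu2
  wdot <- if (ndot == 0 && !is.finite(dmu)) 0 else ndot * dmu
  structure(list(dmu1 = dmu1, dmu2 = dmu2, dmu = dmu,
                 ndot = ndot, wdot = wdot, work = wdot * tau_r),
            class = "thermo_state")
}

#' Steady state of the full receptor + push-pull network
#'
#' Mean-field steady state: occupancy `p` and correlation time `tau_c` from
#' the receptor rates at the mean concentration; active fraction `f` from
#' the balance of activation and deactivation fluxes with the bound-receptor
#' count at its mean `p * R_T`; relaxation time
#' `tau_r = 1/((kf + kmf) p R_T + kr + kmr)`; net flux
#' `ndot = kf p R_T xbar - kmf p R_T xstar` with `xbar = (1 - f) X_T`,
#' `xstar = f X_T`; power `wdot = ndot * dmu` (kT per time).
#'
#' @param receptor a [receptor_params()] object.
#' @param readout a [readout_params()] object.
#' @param signal a [signal_params()] object (only `L_mean` is used here).
#' @return A list with `p`, `f`, `tau_c`, `tau_r`, `xbar`, `xstar` and a
#'   `thermo` field of class [thermo_state()].
#' @examples
#' sig <- signal_params(100, 5, 1)
#' rec <- receptor_rates_from_design(p = 0.5, tau_c = 0.01, L_mean = 100, R_T = 100)
#' rd  <- readout_rates_from_design(f = 0.5, tau_r = 0.1, dmu1 = 2, dmu2 = 2,
#'                                  p = 0.5, R_T = 100, X_T = 500)
#' st <- steady_state(rec, rd, sig)
#' st$thermo$dmu   # = 4 kT
#' @export
steady_state <- function(receptor, readout, signal) {
  p <- receptor_occupancy(receptor, signal$L_mean)
  tau_c <- receptor_corr_time(receptor, signal$L_mean)
  nbar <- p * receptor$R_T
  act <- readout$kf * nbar + readout$kmr     # x  -> x*, per molecule
  dea <- readout$kmf * nbar + readout$kr     # x* -> x,  per molecule
  f <- act / (act + dea)
  tau_r <- 1 / (act + dea)
  xstar <- f * readout$X_T
  xbar <- (1 - f) * readout$X_T
  ndot <- readout$kf * nbar * xbar - readout$kmf * nbar * xstar
  dmu1 <- if (readout$kmf == 0) Inf else
    log(readout$kf * xbar / (readout$kmf * xstar))
  dmu2 <- if (readout$kmr == 0) Inf else
    log(readout$kr * xstar / (readout$kmr * xbar))
  list(p = p, f = f, tau_c = tau_c, tau_r = tau_r,
       xbar = xbar, xstar = xstar,
       thermo = thermo_state(dmu1, dmu2, ndot, tau_r))
}

#' Design coordinates of a microscopic parameter set
#'
#' Forward map from microscopic rates to the coarse coordinates used by the
#' optimizers; inverse of [receptor_rates_from_design()] and
#' [readout_rates_from_design()].
#'
#' @inheritParams steady_state
#' @return A [design_point()] object.
#' @export
design_from_rates <- function(receptor, readout, signal) {
  st <- steady_state(receptor, readout, signal)
  design_point(p = st$p, f = st$f, tau_r = st$tau_r,
               dmu1 = st$thermo$dmu1, dmu2 = st$thermo$dmu2,
               R_T = receptor$R_T, X_T = readout$X_T,
               xt_infinite = FALSE,
               q_unity = !is.finite(st$thermo$dmu))
}
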