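# Closed-form SNR of the push-pull sensing network.
# All energies in kT (beta = 1); concentrations enter only via sigma_L/L_mean.

#' Static gain of the receptor
#'
#' Slope of the static input-output relation at the mean concentration:
#' `g = p (1 - p) / L_mean`.  Maximal at `p = 1/2`.
#'
#' @param p receptor occupancy in (0, 1) (boundaries allowed; gain 0 there).
#' @param L_mean mean ligand concentration (> 0).
#' @return gain (occupancy per concentration).
#' @export
static_gain <- function(p, L_mean) {
  check_scalar(p, "p", lower = 0, upper = 1, open_lower = FALSE,
               open_upper = FALSE)
  check_scalar(L_mean, "L_mean", lower = 0)
  p * (1 - p) / L_mean
}

#' Dynamic gain of the receptor + readout cascade
#'
#' Slope of the dynamic input-output relation: the static gain attenuated by
#' the low-pass action of receptor binding and readout relaxation,
#' `g_dyn = g_static / ((1 + tau_c/tau_L) (1 + tau_r/tau_L))`.  Equals the
#' static gain only in the instantaneous limit `tau_c = tau_r = 0`.
#'
#' @inheritParams static_gain
#' @param tau_c receptor correlation time (>= 0).
#' @param tau_r integration time (>= 0).
#' @param tau_L input correlation time (> 0).
#' @return gain (occupancy per concentration).
#' @export
dynamic_gain <- function(p, L_mean, tau_c, tau_r, tau_L) {
  check_scalar(tau_c, "tau_c", lower = 0, open_lower = FALSE)
  check_scalar(tau_r, "tau_r", lower = 0, open_lower = FALSE)
  check_scalar(tau_L, "tau_L", lower = 0)
  static_gain(p, L_mean) / ((1 + tau_c / tau_L) * (1 + tau_r / tau_L))
}

#' Sample quality of the receptor-readout copy process
#'
#' Each readout-receptor interaction copies the ligand-binding state of the
#' receptor into the readout with quality
#' `q = (e^dmu1 - 1)(e^dmu2 - 1) / (e^(dmu1 + dmu2) - 1)`,
#' set by the free-energy drops over the two legs of the cycle (kT units).
#' `q = 0` at detailed balance (either drop zero), `q -> 1` under strong
#' driving, and for symmetric legs `dmu1 = dmu2 = dmu/2`,
#' `q = tanh(dmu/4)` (so `q -> dmu/4` for weak driving).
#'
#' @param dmu1,dmu2 free-energy drops (kT, >= 0; `Inf` allowed).
#' @return quality `q` in \[0, 1\].
#' @examples
#' sample_quality(2, 2)   # tanh(1) ~ 0.76
#' @export
sample_quality <- function(dmu1, dmu2) {
  check_scalar(dmu1, "dmu1", lower = 0, open_lower = FALSE, allow_inf = TRUE)
  check_scalar(dmu2, "dmu2", lower = 0, open_lower = FALSE, allow_inf = TRUE)
  if (dmu1 == 0 || dmu2 == 0) return(0)
  if (!is.finite(dmu1) && !is.finite(dmu2)) return(1)
  if (!is.finite(dmu1)) return(1 - exp(-dmu2))
  if (!is.finite(dmu2)) return(1 - exp(-dmu1))
  # expm1 keeps the weak-driving limit q -> dmu1 dmu2 / (dmu1 + dmu2) accurate
  expm1(dmu1) * expm1(dmu2) / expm1(dmu1 + dmu2)
}

#' Receptor-sample bookkeeping of the readout pool
#'
#' Decomposes the readout activity into receptor samples: the total number
#' of samples taken during one integration time, `n_bar = (ndot / p) tau_r`
#' (with `ndot` the net cycle flux, identically equal to
#' `f (1 - f) X_T q / tau_r`); the effective (reliable) number
#' `n_eff = q n_bar`; the receptor sampling interval
#' `delta = 2 tau_r R_T / n_eff`; the independent fraction
#' `f_I = 1 / (1 + 2 tau_c / delta)`; and the independent count
#' `n_I = f_I n_eff`.  Under the unbounded-readout flag the independent
#' count saturates at `R_T tau_r / tau_c`.
#'
#' @param design a [design_point()] object.
#' @param tau_c receptor correlation time (> 0).
#' @return An object of class `sample_counts` with fields `n_bar`, `n_eff`,
#'   `n_I`, `f_I`, `q`, `delta`, `ndot`.
#' @export
sample_counts <- function(design, tau_c) {
  check_scalar(tau_c, "tau_c", lower = 0)
  q <- if (design$q_unity) 1 else sample_quality(design$dmu1, design$dmu2)
  if (design$xt_infinite) {
    n_I <- q * design$R_T * design$tau_r / tau_c
    out <- list(n_bar = Inf, n_eff = Inf, n_I = n_I, f_I = 0, q = q,
                delta = 0, ndot = Inf)
    return(structure(out, class = "sample_counts"))
  }
  ndot <- design$f * (1 - design$f) * design$X_T * q / design$tau_r
  n_bar <- ndot * design$tau_r / design$p
  n_eff <- q * n_bar
  if (n_eff == 0) {
    out <- list(n_bar = n_bar, n_eff = 0, n_I = 0, f_I = 1, q = q,
                delta = Inf, ndot = ndot)
    return(structure(out, class = "sample_counts"))
  }
  delta <- 2 * design$tau_r * design$R_T / n_eff
  f_I <- 1 / (1 + 2 * tau_c / delta)
  structure(list(n_bar = n_bar, n_eff = n_eff, n_I = f_I * n_eff,
                 f_I = f_I, q = q, delta = delta, ndot = ndot),
            class = "sample_counts")
}

#' Dynamical error of time-integrated sensing
#'
#' Systematic contribution to `1/SNR` from estimating the current
#' concentration via the receptor history over the past `tau_r`:
#' `E_dyn = (1 + tau_c/tau_L)(1 + tau_r/tau_L) /
#'          (1 + tau_c tau_r / (tau_L (tau_c + tau_r))) - 1`.
#' Vanishes as `tau_c, tau_r -> 0` and reduces to `tau_r / tau_L` when
#' `tau_c -> 0`.  Cannot be reduced by taking more receptor samples.
#'
#' @param tau_c,tau_r times (>= 0); the doubly-instantaneous case returns 0
#'   by continuity.
#' @param tau_L input correlation time (> 0).
#' @return nonnegative dimensionless error.
#' @export
dynamical_error <- function(tau_c, tau_r, tau_L) {
  check_scalar(tau_c, "tau_c", lower = 0, open_lower = FALSE)
  check_scalar(tau_r, "tau_r", lower = 0, open_lower = FALSE)
  check_scalar(tau_L, "tau_L", lower = 0)
  if (tau_c + tau_r == 0) return(0)
  (1 + tau_c / tau_L) * (1 + tau_r / tau_L) /
    (1 + tau_c * tau_r / (tau_L * (tau_c + tau_r))) - 1
}

#' Signal-to-noise ratio of the push-pull sensing network
#'
#' Central closed form: the inverse SNR of the instantaneous concentration
#' estimate decomposes into a sampling error,
#' `(1 + tau_c/tau_L)^2 (1 + tau_r/tau_L)^2 *
#'  ((L/sigma)^2 / (p (1-p) n_I) + (L/sigma)^2 / ((1-p)^2 n_eff))`,
#' and the [dynamical_error()].  Also reports the mutual information
#' `I = log(1 + SNR) / 2` (nats) and the run-scale SNR
#' `SNR * tau_L / tau_r`.  Zero flux (e.g. `q = 0`) gives `snr = 0` with an
#' infinite sampling error, not an error condition.
#'
#' @param signal a [signal_params()] object.
#' @param design a [design_point()] object.
#' @param tau_c receptor correlation time (> 0).
#' @return An object of class `snr_breakdown` with fields `static_gain`,
#'   `dynamic_gain`, `sampling_error`, `dynamical_error`, `snr`,
#'   `mutual_info_nats`, `snr_run` and `samples` (a [sample_counts()]).
#' @examples
#' sig <- signal_params(100, 10, 1)
#' d <- design_point(p = 0.5, tau_r = 0.1, R_T = 100, xt_infinite = TRUE,
#'                   q_unity = TRUE)
#' snr_total(sig, d, tau_c = 0.01)$snr
#' @export
snr_total <- function(signal, design, tau_c) {
  if (!signal$linear_regime)
    warning("sigma_L/L_mean > 0.3: outside the linearized-theory regime",
            call. = FALSE)
  sc <- sample_counts(design, tau_c)
  tau_L <- signal$tau_L
  pref <- (1 + tau_c / tau_L)^2 * (1 + design$tau_r / tau_L)^2
  inv_noise2 <- (signal$L_mean / signal$sigma_L)^2
  term_indep <- if (sc$n_I > 0)
    inv_noise2 / (design$p * (1 - design$p) * sc$n_I) else Inf
  term_store <- if (design$xt_infinite) 0 else if (sc$n_eff > 0)
    inv_noise2 / ((1 - design$p)^2 * sc$n_eff) else Inf
  sampling <- pref * (term_indep + term_store)
  dyn <- dynamical_error(tau_c, design$tau_r, tau_L)
  snr <- if (is.finite(sampling)) 1 / (sampling + dyn) else 0
  structure(list(
    static_gain = static_gain(design$p, signal$L_mean),
    dynamic_gain = dynamic_gain(design$p, signal$L_mean, tau_c,
                                design$tau_r, tau_L),
    sampling_error = sampling,
    dynamical_error = dyn,
    snr = snr,
    mutual_info_nats = mutual_information(snr),
    snr_run = snr_run(snr, design$tau_r, tau_L),
    samples = sc), class = "snr_breakdown")
}

#' @export
print.snr_breakdown <- function(x, ...) {
  cat("push-pull SNR breakdown\n")
  cat(sprintf("  sampling error : %g\n", x$sampling_error))
  cat(sprintf("  dynamical error: %g\n", x$dynamical_error))
  cat(sprintf("  SNR            : %g\n", x$snr))
  cat(sprintf("  mutual info    : %g nats\n", x$mutual_info_nats))
  cat(sprintf("  run-scale SNR  : %g\n", x$snr_run))
  invisible(x)
}

#' Run-scale signal-to-noise ratio
#'
#' The instantaneous SNR multiplied by the number of independent
#' measurements `tau_L / tau_r` performed during one input correlation time
#' (one run, for a swimming bacterium).
#'
#' @param snr instantaneous SNR (>= 0).
#' @param tau_r integration time (> 0).
#' @param tau_L input correlation time (> 0).
#' @return `snr * tau_L / tau_r`.
#' @export
snr_run <- function(snr, tau_r, tau_L) {
  snr * tau_L / tau_r
}

#' Mutual information of the Gaussian sensing channel
#'
#' @param snr signal-to-noise ratio (>= 0).
#' @param bits report in bits instead of nats (default `FALSE`).
#' @return `log(1 + snr)/2`, nats by default.
#' @export
mutual_information <- function(snr, bits = FALSE) {
  i <- 0.5 * log1p(snr)
  if (bits) i / log(2) else i
}

#' SNR from design coordinates under a power constraint
#'
#' Evaluates [snr_total()] for a system dissipating power `wdot` (kT per
#' time) at total drive `dmu` split symmetrically over the two legs: the
#' implied readout pool is `X_T = wdot tau_r / (dmu q f (1 - f))`.
#'
#' @inheritParams snr_total
#' @param p receptor occupancy.
#' @param f active fraction (default 1/2, the symmetric optimum).
#' @param tau_r integration time.
#' @param wdot dissipated power (kT per time, > 0).
#' @param dmu total free-energy drop per cycle (kT, > 0).
#' @param R_T receptor count.
#' @return An `snr_breakdown` (its `samples$ndot` equals `wdot / dmu`).
#' @export
snr_from_power <- function(signal, p, tau_r, wdot, dmu, R_T, tau_c, f = 0.5) {
  check_scalar(wdot, "wdot", lower = 0)
  check_scalar(dmu, "dmu", lower = 0)
  q <- sample_quality(dmu / 2, dmu / 2)
  X_T <- wdot * tau_r / (dmu * q * f * (1 - f))
  d <- design_point(p = p, f = f, tau_r = tau_r, dmu1 = dmu / 2,
                    dmu2 = dmu / 2, R_T = R_T, X_T = X_T)
  snr_total(signal, d, tau_c)
}
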