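# Application to E. coli chemotactic gradient sensing.  A cell running at
# speed v through an exponential attractant profile L(x) = L0 exp(x / x0)
# experiences relative concentration fluctuations sigma_L/L_mean = l / x0
# over a run of length l; the input correlation time tau_L is the run
# duration (~1 s) and the receptor correlation time tau_c ~ 10 ms.

#' Relative input noise experienced in an exponential gradient
#'
#' For an exponential concentration profile with length scale `x0`, the
#' relative change of the signal over one run of length `l` is `l / x0`.
#'
#' @param l run length (micrometres, > 0; default 50).
#' @param x0 gradient length scale (micrometres, > 0).
#' @return `sigma_L / L_mean = l / x0` (dimensionless).
#' @examples
#' gradient_noise(50, 25000)   # 2e-3, a very shallow gradient
#' @export
gradient_noise <- function(l = 50, x0) {
  check_scalar(l, "l", lower = 0)
  check_scalar(x0, "x0", lower = 0)
  l / x0
}

#' Optimal integration time for the chemotaxis network
#'
#' Numerically minimizes the receptor-limited sensing bound
#' (`h = R_T tau_r / tau_c`, the Berg-Purcell limit: perfect copies,
#' unbounded readout pool, `p = 1/2`) over the integration time.  The
#' minimizer admits the closed form `tau_L sqrt(A / (1 + A))` with
#' `A = 4 tau_c / (noise^2 R_T tau_L)` (see [tau_r_opt_closed_form()]),
#' which the numerical optimum matches to high accuracy.
#'
#' @param R_T receptor (receptor-kinase complex) count.
#' @param noise relative input noise `sigma_L / L_mean` (= `l / x0` in an
#'   exponential gradient).
#' @param tau_c receptor correlation time (s, default 0.01).
#' @param tau_L input (run) correlation time (s, default 1).
#' @return the optimal integration time (s).
#' @export
optimal_tau_r_ecoli <- function(R_T, noise, tau_c = 0.01, tau_L = 1) {
  optimal_tau_r("receptors", noise = noise, tau_c = tau_c, tau_L = tau_L,
                R_T = R_T, objective = "bound")$tau_r_opt
}

# Run-scale SNR maximized over the integration time, receptor-limited
# bound.  SNR_run(tau) = 1 / (A (1 + tau)^2 + tau^2) with tau = tau_r/tau_L
# is monotone decreasing, so the supremum is its tau -> 0 limit 1/A.
sup_snr_run_bp <- function(R_T, noise, tau_c, tau_L) {
  A <- 4 * tau_c / (noise^2 * R_T * tau_L)
  1 / A
}

#' Shallowest gradient detectable by an optimal receptor-limited sensor
#'
#' Finds, by bisection, the relative input noise at which the run-scale SNR
#' of the optimal system drops to 1 -- the detection threshold.  The
#' run-scale SNR is maximized over the integration time in the
#' receptor-limited (Berg-Purcell) bound; the supremum is attained as
#' `tau_r -> 0` and is evaluated by its analytic limit, giving the closed
#' form `noise* = 2 sqrt(tau_c / (R_T tau_L))` as a cross-check.  The
#' corresponding exponential-gradient length scale is `x0* = l / noise*`.
#'
#' @inheritParams optimal_tau_r_ecoli
#' @param l run length (micrometres, default 50).
#' @return A list with `noise_star` (threshold `sigma_L / L_mean`),
#'   `x0_star` (micrometres), and `closed_form` (the analytic `noise*`).
#' @examples
#' shallowest_gradient(R_T = 1e4)$x0_star   # ~ 25000 um
#' @export
shallowest_gradient <- function(R_T, tau_c = 0.01, tau_L = 1, l = 50) {
  f <- function(nu) sup_snr_run_bp(R_T, nu, tau_c, tau_L) - 1
  lo <- 1e-6; hi <- 1
  if (f(lo) > 0 || f(hi) < 0)
    stop_domain("detection threshold outside the bracket [1e-6, 1]")
  nu_star <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  list(noise_star = nu_star,
       x0_star = l / nu_star,
       closed_form = 2 * sqrt(tau_c / (R_T * tau_L)))
}

#' Gradient-sensing tables for the chemotaxis network
#'
#' For each receptor count and each relative noise level (gradient
#' steepness `l / x0`), tabulates the optimal integration time (numerical
#' minimizer of the receptor-limited bound) and the run-scale SNR at the
#' detection-relevant supremum over the integration time.  The run-scale
#' SNR crosses 1 exactly at the [shallowest_gradient()] threshold.
#'
#' @param R_T vector of receptor counts (default `c(1e3, 1e4)`).
#' @param noise vector of relative noise values (default 25 log-spaced
#'   points in `[1e-3, 1]`).
#' @inheritParams shallowest_gradient
#' @return A data frame with columns `R_T`, `noise`, `x0` (micrometres),
#'   `tau_r_opt`, `tau_r_opt_over_tau_L`, `snr_run`.
#' @export
chemotaxis_tables <- function(R_T = c(1e3, 1e4),
                              noise = 10^seq(-3, 0, length.out = 25),
                              tau_c = 0.01, tau_L = 1, l = 50) {
  rows <- do.call(rbind, lapply(R_T, function(rt) do.call(rbind, lapply(
    noise, function(nu) {
      tr <- optimal_tau_r_ecoli(rt, nu, tau_c, tau_L)
      data.frame(R_T = rt, noise = nu, x0 = l / nu,
                 tau_r_opt = tr, tau_r_opt_over_tau_L = tr / tau_L,
                 snr_run = sup_snr_run_bp(rt, nu, tau_c, tau_L))
    }))))
  rownames(rows) <- NULL
  rows
}
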