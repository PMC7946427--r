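# Shared builders for parameterised tests.  All fixtures are generated in
# code; draws use a fixed seed per test.

# a consistent (receptor, readout, signal, design) quadruple from coarse
# coordinates, concentration units fixed by L_mean
make_system <- function(p = 0.5, f = 0.5, tau_r = 0.3, dmu1 = 10, dmu2 = 10,
                        R_T = 300, X_T = 1000, tau_c = 0.01,
                        L_mean = 1, noise = 0.05, tau_L = 1) {
  sig <- signal_params(L_mean, noise * L_mean, tau_L)
  rec <- receptor_rates_from_design(p, tau_c, L_mean, R_T = R_T)
  rd <- readout_rates_from_design(f, tau_r, dmu1, dmu2, p, R_T, X_T = X_T)
  des <- design_point(p = p, f = f, tau_r = tau_r, dmu1 = dmu1, dmu2 = dmu2,
                      R_T = R_T, X_T = X_T)
  list(signal = sig, receptor = rec, readout = rd, design = des,
       tau_c = tau_c)
}

# random coarse coordinates inside the theory's comfortable regime
random_design_coords <- function() {
  list(p = runif(1, 0.1, 0.9), f = runif(1, 0.2, 0.8),
       tau_r = 10^runif(1, -2, 0.5), dmu1 = runif(1, 0.5, 8),
       dmu2 = runif(1, 0.5, 8), R_T = round(10^runif(1, 1.5, 4)),
       X_T = round(10^runif(1, 2, 4)), tau_c = 10^runif(1, -3, -1.5))
}
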