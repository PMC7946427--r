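# pushpull

Precision limits of cellular sensing of *time-varying* chemical
concentrations through the canonical receptor + push–pull readout motif
(GTPase cycles, phosphorylation cycles, two-component systems such as the
*E. coli* chemotaxis network).

A cell cannot read a fluctuating ligand concentration `L(t)` directly: it
samples the binding state of `R_T` receptors through a cycle of covalent
activation and deactivation of `X_T` readout molecules, which acts as an
exponential low-pass filter with integration time `tau_r`. Each
receptor–readout encounter copies one receptor state into one readout
molecule, at a fidelity set by how far the cycle is driven out of
equilibrium. This package implements the closed-form theory of that
process and everything needed to check and exploit it:

- **SNR decomposition** (`snr_total()`): the inverse signal-to-noise ratio
  of the concentration estimate splits into a *sampling error* — set by
  the number of receptor samples `N̄ = (ṅ/p) τr`, their fidelity
  `q = (e^{Δμ1}−1)(e^{Δμ2}−1)/(e^{Δμ}−1)` and their independence
  `f_I = 1/(1 + 2τc/Δ)` — and a *dynamical error* set purely by the
  timescales `τc`, `τr`, `τL` (all energies in kT).
- **Fundamental resource bounds** (`fundamental_bound()`):
  `SNR⁻¹ ≥ (1+τr/τL)² · 4(L̄/σL)²/h + τr/τL` with
  `h = min(R_T τr/τc, X_T, β ẇ τr)` — receptors, readout molecules and
  power each limit sensing and cannot compensate one another.
- **Optimal design** (`optimal_tau_r()`, `delta_mu_opt()`,
  `xt_required()`, `allocation_gap()`, `pareto_front()`,
  `scan_resources()`): the optimal integration time
  (`τr* = τL √(A/(1+A))`, `A = 4τc(L̄/σL)²/(R_T τL)` in the
  receptor-limited regime), the ~4 kT optimal drive, and the resource
  allocation principle `R_T τr/τc ≈ X_T ≈ β ẇ τr`.
- **Independent oracles** (`simulate_network()`, `empirical_snr()`,
  `empirical_gain()`, `spectral_snr()`): a seeded stochastic simulator of
  the full network driven by an Ornstein–Uhlenbeck signal (Rcpp), and a
  deterministic linear-noise spectral calculation, both used to verify the
  closed forms and map their regime of validity.
- **Chemotaxis application** (`gradient_noise()`, `optimal_tau_r_ecoli()`,
  `shallowest_gradient()`, `chemotaxis_tables()`): parameter-free
  predictions for *E. coli* gradient sensing.

## Worked example

```r
library(pushpull)

sig <- signal_params(L_mean = 100, sigma_L = 10, tau_L = 1)   # 10% input noise
d <- design_point(p = 0.5, f = 0.5, tau_r = 0.1, dmu1 = 2, dmu2 = 2,
                  R_T = 1000, X_T = 10000)
snr_total(sig, d, tau_c = 0.01)
#> push-pull SNR breakdown
#>   sampling error : 0.38986
#>   dynamical error: 0.100991
#>   SNR            : 2.03728
#>   mutual info    : 0.555481 nats
#>   run-scale SNR  : 20.3728
```

At a total drive of 4 kT each copy succeeds with quality
`q = tanh(1) ≈ 0.76`; of the `N̄ ≈ 3808` receptor samples taken during one
integration time, `N̄eff ≈ 2900` are reliable and `N̄I ≈ 2248` independent.
The resulting SNR of 2.04 means the cell resolves about
`sqrt(1 + SNR) ≈ 1.7` distinct concentration levels instantaneously
(0.56 nats of mutual information), and about 20 levels-worth of signal
energy over one input correlation time.

The optimal integration time trades sample number against signal
distortion:

```r
optimal_tau_r("receptors", noise = 0.1, tau_c = 0.01, R_T = 1000)[1:3]
#> $tau_r_opt [1] 0.06432059
#> $snr_max   [1] 7.267331
#> $I_max     [1] 1.056156
```

For *E. coli* (`τc = 10 ms`, `τL = 1 s`, run length 50 µm), the shallowest
exponential gradient a receptor-limited sensor can resolve (run-scale
SNR = 1):

```r
shallowest_gradient(R_T = 1e4)[c("noise_star", "x0_star")]
#> $noise_star [1] 0.002
#> $x0_star    [1] 25000
```

i.e. a relative signal change of 2×10⁻³ per run, a gradient length scale
of 2.5 cm; with `R_T = 1e3` the threshold is `x0 ≈ 7.9e3` µm. Gradients
this shallow are at the edge of what has been measured behaviorally,
which is what makes the 50–500 ms measured integration time look not just
sufficient but necessary.

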