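# lipkin

Membrane lipid composition regulates the ER-associated degradation (ERAD)
ubiquitination cascade at the level of its membrane-anchored E2 enzyme:
bilayers rich in unsaturated acyl chains expose lipid-packing defects that
trap the catalytic (UBC) domain in an inactive, membrane-bound
conformation, while saturated, tightly packed bilayers leave it free to be
charged with ubiquitin by E1. `lipkin` is an R package for scientists
analysing this system quantitatively — kinetic time courses from
reconstituted liposomes, contact statistics from membrane simulations, and
the supporting composition and spectroscopy arithmetic.

It provides:

* **Two-state loading kinetics.** The enzyme interconverts between active
  (A) and inactive (B) conformations with rates k1, k2; only A is loaded
  (to C) at rate k3:

  dA/dt = −k3·A − k1·A + k2·B, dB/dt = k1·A − k2·B, dC/dt = k3·A,

  starting from the conformational equilibrium B0/A0 = k1/k2 with
  A0 + B0 = T, the loadable fraction (fixed at 0.75). `loaded_fraction()`
  is the closed-form eigen-decomposition solution,
  `integrate_two_state_ode()` an independent stiff-solver cross-check, and
  `fit_global_two_state()` fits several membrane conditions jointly with
  per-condition (k1, k2) and a shared k3 (multi-start Levenberg–Marquardt
  on log rates). `steady_state_loaded_fraction()` gives the loaded steady
  state C* = (k3/kd) / (1 + k1/k2 + k3/kd) under continuous
  loading/discharge cycling.
* **Poisson-mixture contact analysis.** `fit_poisson_mixture_em()` fits
  K-component Poisson mixtures to per-frame protein–membrane contact
  counts by EM; `select_component_count()` chooses K by BIC;
  `bound_fraction()` reports the membrane-bound population under an
  explicit classification policy; `residue_contact_frequency()` summarizes
  per-residue contacts.
* **Membrane composition arithmetic.** `sfa_chain_fraction()` computes the
  saturated-fatty-acid chain percentage of a liposome mix (saturated
  phospholipid chains over all phospholipid chains, sterols excluded);
  eleven standard compositions ship with the package
  (`builtin_compositions()`).
* **Assay formulas.** C-Laurdan generalized polarization
  (`generalized_polarization()`), FRET acceptor/donor ratios
  (`fret_ratio()`), gel-lane modified fractions
  (`lane_modified_fraction()`).
* **Seeded synthetic-data generators** for every input
  (`simulate_loading_timecourse()`, `simulate_contact_counts()`,
  `simulate_emission_spectrum()`, `write_fixture_set()`), so the whole
  pipeline is testable without any external data.

## Worked example

```r
library(lipkin)

# SFA content of an ER-like liposome (60% POPC, 20% DOPE, 10% DOPS,
# 10% cholesterol): 60 saturated chains of 180 phospholipid chains
sfa_chain_fraction(composition_by_label("33% SFA (ER-like)"))
#> [1] 33.33333

# simulate biphasic loading in two membrane conditions and fit globally
sim <- simulate_loading_timecourse(noise_sd = 0.02, replicates = 10, seed = 11)
fit_global_two_state(sim, n_starts = 8, seed = 1)
#> Global two-state loading fit
#>   shared k3 = 30.3 /s (se 0.81), total fixed at 0.75
#>   RSS = 0.1317 over 400 observations; converged: TRUE
#>  condition        k1         k2      k1_se      k2_se
#>    10% SFA 2.2909755 0.01843781 0.84771594 0.00062692
#>    60% SFA 0.4540629 1.84562649 0.06666066 0.18188778

# contact-count mixture: unbound / loosely bound / bound / tightly bound
x <- simulate_contact_counts(50000, seed = 1)
fit <- fit_poisson_mixture_em(x, K = 4, restarts = 20, seed = 1)
fit
#> Poisson mixture fit: K = 4, n = 50000, logL = -161652.17, BIC = 323380.08
#>  component    mean weight
#>          1  0.2005 0.3995
#>          2  8.0260 0.1005
#>          3 30.0100 0.3494
#>          4 49.9000 0.1506
bound_fraction(fit)                     # tight components only: 0.50
bound_fraction(fit, "all_but_unbound")  # adds the loose component: 0.60
```

The mixture recovers the generating means (0.2, 8, 30, 50 contacts); the
global fit recovers the shared loading rate k3 = 30 s⁻¹ within a few
percent, with the expected large uncertainty on k1 in the strongly
inactivated condition (only k1/k2 and the slow relaxation rate are well
identified there).

The vignette (`vignettes/membrane-regulated-loading.Rmd`) documents the
models, their assumptions, the numerical choices and what the synthetic
generators do and do not emulate.

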