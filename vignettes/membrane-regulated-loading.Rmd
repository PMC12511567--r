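---
title: "Modeling membrane-regulated ubiquitin loading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling membrane-regulated ubiquitin loading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipkin)
```

## The biological setting

ER-associated degradation depends on membrane-embedded ubiquitination
machinery. UBE2J2 is a tail-anchored E2 ubiquitin-conjugating enzyme whose
catalytic UBC domain sits just above the cytosolic face of the ER membrane.
Its activity — the rate at which E1 charges it with ubiquitin — depends
strongly on the lipid environment: bilayers rich in unsaturated acyl chains
expose packing defects that sequester the UBC domain in an inactive,
membrane-associated conformation, while tightly packed (more saturated)
bilayers leave it free to react. `lipkin` implements the quantitative
machinery needed to analyse this system: the kinetic model of loading, the
mixture analysis of simulated membrane contacts, the lipid-composition
arithmetic that labels experimental conditions, and the spectroscopic
quantification formulas.

## The two-state loading model

The enzyme interconverts between an active conformation $A$ and an inactive
one $B$, and only $A$ is loaded (to $C$) by E1:

$$\frac{dA}{dt} = -k_3 A - k_1 A + k_2 B, \qquad
  \frac{dB}{dt} = k_1 A - k_2 B, \qquad
  \frac{dC}{dt} = k_3 A.$$

Before E1 is added the enzyme is equilibrated, so $B_0/A_0 = k_1/k_2$ and
$A_0 + B_0 = T$, the loadable fraction of the total enzyme ($T = 0.75$ by
default: a quarter of reconstituted enzyme is typically refractory to
loading regardless of condition, and fixing $T$ removes a degeneracy with
the per-condition rates). The $(A,B)$ subsystem is linear with relaxation
eigenvalues

$$r_{1,2} = \frac{-(k_1+k_2+k_3) \pm
  \sqrt{(k_1+k_2+k_3)^2 - 4k_2k_3}}{2},$$

both real and non-positive (the discriminant is at least $(k_2-k_3)^2$). The
loaded fraction is obtained from the eigen-decomposition as
$C(t) = k_3 \int_0^t A(s)\,ds$, giving a biexponential approach to $T$: a
fast phase loading the pre-existing active pool and a slow phase limited by
reactivation of the inactive pool.

Closed forms of this model quoted in the literature sometimes carry
typographical errors; ours is validated against two analytic limits —
$C(t) = T(1-e^{-k_3 t})$ when $k_1 = 0$, and $C(\infty) = T$ by mass
conservation — and against stiff numerical integration
(`integrate_two_state_ode()`, built on `deSolve`), which the test suite
checks to $10^{-8}$ over randomized parameter sweeps. A repeated eigenvalue
($|r_1 - r_2| < 10^{-10}|r_1 + r_2|$) switches to the confluent
$t\,e^{rt}$ branch, and the $(e^{rt}-1)/r$ terms use `expm1` with series
limits so the $k_3 \to 0$ and $r \to 0$ edges stay accurate.

```{r}
p <- kinetic_params(k1 = 0.5, k2 = 2, k3 = 30)
loaded_fraction(p, c(0.01, 0.1, 1, 60))$C
```

### Global fitting

Loading time courses from several membrane conditions are fitted jointly:
each condition has its own conformational rates $(k_1, k_2)$ — membrane
composition shifts the conformational equilibrium — while the loading rate
$k_3$ is shared, because the chemistry of the active conformation does not
depend on the membrane. Residuals are unweighted squared differences on the
fraction scale with replicates entered individually (no weighting scheme is
assumed; optional $1/\sigma$ weights are exposed). Rates are optimized on
the log scale with Levenberg–Marquardt (`minpack.lm::nls.lm`) inside bounds
$[10^{-6}, 10^4]\,\mathrm{s^{-1}}$, restarted from seeded log-uniform
starting points (8 by default, drawn from $[10^{-2}, 10^2]$ where realistic
rates live); the best solution by residual sum of squares is kept. Standard
errors come from the Gauss–Newton Hessian via the delta method. Note an
intrinsic identifiability limit: when $k_1 \gg k_2$ the active pool is tiny
and only the ratio $k_1/k_2$ and the slow relaxation rate are well
determined, so individual $k_1$ estimates in strongly inactivating membranes
carry large uncertainty — the shared $k_3$ and the equilibrium ratio remain
precise.

Quenched-flow instruments resolve the millisecond regime; manual sampling
covers later times. `assemble_loading_dataset()` merges the two, keeping
manual records inside a closed 30 s – 600 s window by default (early manual
points are unreliable on the fast phase; beyond ten minutes discharge, which
the loading model neglects, starts to matter).

### Steady-state cycling

In a cell E1 is always present and loaded enzyme is continuously discharged,
so the relevant quantity is the steady state of the cycle
$A \rightleftharpoons B$, $A \to C$ ($k_3$), $C \to A$ ($k_d$):

$$C^\ast = \frac{k_3/k_d}{1 + k_1/k_2 + k_3/k_d}.$$

This three-state cycle is this package's own minimal formalization of the
idea that cycling frequency gates the impact of the conformational
equilibrium; its numbers are qualitative. As $k_d \to 0$ the loaded state
absorbs everything regardless of conformational rates, while for fast
cycling the ratio of loaded fractions between a weakly and a strongly
inactivated condition approaches $(1 + q_{high})/(1 + q_{low})$ with
$q = k_1/k_2$ — so membrane composition controls steady-state ubiquitination
capacity exactly when loading/discharge turnover is fast, as expected in
vivo. The test suite verifies the closed form against long-time numerical
integration of the cycle and the monotonicity of the sensitivity in $k_d$.

## Poisson-mixture contact analysis

Coarse-grained simulations of the enzyme on different bilayers yield, per
trajectory frame, the number of contacts between the UBC domain (residues
1–168) and the membrane. The empirical count distribution has a peak at zero
(unbound) and structure at higher counts; we model it as a $K$-component
Poisson mixture fitted by expectation–maximization, the standard estimator
for count mixtures. The M-step is closed-form; means are floored at
$10^{-6}$ so the unbound near-zero component remains a proper Poisson (a
zero-inflated variant with a structural zero component is available but not
the default, since the unbound state still makes occasional grazing
contacts). Initialization uses k-quantile means with uniform weights plus
seeded randomized restarts (20 by default); components are reported sorted
by mean, making the fit invariant to initialization order. Internally
counts are tabulated to their unique values, which makes each EM sweep exact
and effectively independent of trajectory length. The component count is
chosen by BIC ($-2\log L + (2K-1)\log n$); on data generated from the
four-state mixture below, BIC selects $K = 4$ in at least 18 of 20 seeded
replicates.

```{r}
x <- simulate_contact_counts(50000, seed = 1)
fit <- fit_poisson_mixture_em(x, K = 4, restarts = 20, seed = 1)
fit
```

The components are read as conformational states: unbound (mean near 0),
loosely bound (~8 contacts), bound (~30) and tightly bound (~50). The
membrane-bound population is the summed weight of the bound components, but
whether the loosely bound state counts as "bound" is a reporting choice:
`bound_fraction()` therefore implements two explicit policies — a
mean-contact threshold (default 15, between the loose and tight peaks) and
"all but the lowest component" — and records the policy with the number.

## Membrane composition arithmetic

Liposome conditions are labelled by their saturated-fatty-acid chain
content: the percentage of phospholipid acyl chains with zero double bonds,
counting two chains per phospholipid and excluding sterols entirely. An
ER-like mix of 60% POPC, 20% DOPE, 10% DOPS, 10% cholesterol has 60
saturated chains (one palmitoyl per POPC) out of 180 phospholipid chains:
33% SFA. The eleven built-in compositions ship as a plain CSV; chain
annotations for the common lipids (POPC, DOPC, DPPC, DOPE, POPE, DOPS,
16:1 PC/PE, cholesterol) are built in, and unknown species require explicit
annotation. Two conventions to note: the "+cholesterol" mixes keep the
label of their parent phospholipid mixture (the label is metadata — chain
arithmetic on the 35%-SFA-plus-cholesterol mix gives ~37% because
cholesterol displaces mostly unsaturated lipid); and the flattened source
table admits only one reading of the "35% SFA" column consistent with its
label (POPC 70 / DOPC 10 / DOPE 20), which is the one shipped. Mol-percent
sums are validated to 100 within ±0.5 to accommodate one-decimal rounding
(e.g. 66.7 + 6.7 + 16.7 + 10 = 100.1).

## Spectroscopy and gel quantification

C-Laurdan generalized polarization summarizes lipid packing from a two-band
emission spectrum: $GP = (I_{p1} - I_{p2})/(I_{p1} + I_{p2})$ with
$I_{p1}$ the summed intensity over 402–460 nm and $I_{p2}$ over 470–530 nm.
Band sums are raw sums over recorded samples on closed intervals — the
convention matches instruments reporting fixed wavelength steps; whether the
band endpoints are inclusive is not standardized, and we chose inclusive
(a trapezoidal mode is available for non-uniform grids). The FRET ratio is
the intensity at the acceptor emission wavelength over that at the donor
wavelength (defaults 614/516 nm, an Alexa 488/594 pair), read from the
nearest recorded sample rather than interpolated, since plate readers report
discrete 2 nm steps. Gel lanes are quantified as the modified-band intensity
over the total lane intensity.

## What the synthetic generators emulate — and what they do not

All parameter-recovery claims in the tests rest on the package's own
generators, which are deterministic given a seed:

* `simulate_loading_timecourse()` draws the forward two-state curve on a
  20-point log-spaced grid from 5 ms to 600 s (the span of quenched-flow
  plus manual sampling) and adds i.i.d. Gaussian noise (SD 0.02 on the
  fraction scale, a typical gel-densitometry error), clipping to [0, 1].
  The default conditions are a loosely packed membrane with the enzyme
  mostly inactivated ($k_1 = 5$, $k_2 = 0.02\,\mathrm{s^{-1}}$) and a
  tightly packed one mostly active ($k_1 = 0.5$, $k_2 = 2$), sharing
  $k_3 = 30\,\mathrm{s^{-1}}$ — invented magnitudes chosen so that the fast
  phase completes within tens of milliseconds and the slow phase runs on
  the minute scale, the qualitative behaviour of the real system. They are
  synthetic defaults, not measured rates.
* `simulate_contact_counts()` draws from the four-component mixture
  (means 0.2/8/30/50, weights 0.40/0.10/0.35/0.15 — the weights are
  invented; real occupancies vary with membrane composition). The `markov`
  mode threads a hidden-state chain with geometric dwell times and the
  mixture weights as stationary distribution, emulating reversible
  association while preserving the marginal distribution.
* `simulate_emission_spectrum()` sums Gaussian bands on a 2 nm grid.

What passing these tests shows is that the estimators are correct and well
calibrated *under their own model assumptions*. Real data violate them in
known ways the generators do not emulate: loading noise is
heteroscedastic and correlated within gels; contact counts from a
trajectory are autocorrelated (the `markov` mode exists precisely to check
that marginal-mixture estimates survive this, but EM standard errors would
not); real emission spectra have asymmetric bands and baselines. Parameter
recovery here is therefore a necessary, not sufficient, validation for any
particular dataset.

## Problem sizes and numerical choices

Defaults used throughout the package and its tests: mixture fits use 50,000
frames (a typical pooled trajectory length after striding), 20 EM restarts,
tolerance $10^{-8}$ on the relative log-likelihood, 500 iterations maximum;
replicated sweeps in the test suite use 8 restarts (recovery) and 4–5
restarts (BIC scans) per replicate, which the restart-invariance test shows
to be ample for this mixture. Kinetic recovery sweeps use two conditions,
20 time points, 10 replicates, noise SD 0.02, and 4–8 optimizer starts.
Tie-breaks and degenerate inputs: mixture components with weight below
$10^{-6}$ are flagged rather than deleted; BIC scans drop K values with
fewer than $10K$ observations with a warning; the discharge fit profiles
out the amplitude analytically and returns $k_d = 0$ for trendless data;
compositions of only sterols raise an error rather than 0/0.

## Known limitations

The package deliberately stops short of: extracting contacts from
trajectories (a contact distance cutoff would have to be chosen; the module
consumes precomputed counts), modeling E1/E3 chemistry or the
lipid-dependence of rates mechanistically (rates are free per-condition
parameters), predicting GP or packing from composition, and any wet-lab
image processing. The steady-state cycling model is a minimal stand-in
whose value is qualitative.
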