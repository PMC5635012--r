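---
title: "Anchor-mediated trapping in biogels: model, assumptions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-mediated trapping in biogels: model, assumptions and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchortrap)
```

## The trapping problem

A nanoparticulate smaller than the mesh spacing of a biogel diffuses freely
through the gel's pores unless adhesive interactions stop it. Molecular
anchors — IgG antibodies are the canonical example — bind both the particle
and the matrix, so a particle can be immobilized through
matrix–anchor–particle crosslinks even when the gel itself has no affinity
for it. The central question this package addresses is counterintuitive:
what anchor–matrix binding kinetics maximize trapping? Long-lived,
high-affinity bonds are *not* optimal; anchors that exchange with the matrix
rapidly accumulate on the particle via fast free-solution encounters and
then rebind the matrix almost instantly, so that at least one crosslink is
essentially always engaged.

## State space and dynamics

One particle with `N` binding sites is described by `(n, s)`:
`n` anchors bound to the particle, `s ≤ n` of them simultaneously bound to
the matrix. The six transition channels are

| transition | rate | meaning |
|---|---|---|
| `(n,s) → (n+1,s)` | `(N−n) k_on` | free anchor binds particle |
| `(n,0) → (n+1,1)` | `(N−n) k'_on` | matrix-bound anchor captures particle |
| `(n,s) → (n−1,s)` | `(n−s) k_off` | non-crosslinking anchor released |
| `(n,s) → (n−1,s−1)` | `s k_off` | crosslinking anchor released |
| `(n,s) → (n,s+1)` | `g(s)(n−s) a_on` | anchor in complex binds matrix |
| `(n,s) → (n,s−1)` | `s a_off` | anchor–matrix bond breaks |

with `g(0) = D_P/D_A` and `g(s ≥ 1) = C` (default `C = 1`). Two gating
choices deserve comment, because both are forced by the physics and are
verified against the exact chain in the test suite:

* The matrix-capture channel `k'_on` operates only from `s = 0`. A
  crosslinked particle is immobile, and with an immobile matrix
  (`D_M ≈ 0`) the Smoluchowski encounter rate between two immobile partners
  vanishes. Free-anchor binding (`k_on`) is *not* gated: free anchors
  diffuse to the particle whether or not it is crosslinked, at a rate
  dominated by `D_A ≫ D_P`.
* The first crosslink of a free complex forms at `g(0) = D_P/D_A` times the
  intra-complex rate, because the entire complex must diffuse to the matrix.

The particle diffuses with `D_P` only while `s = 0`; its long-run free-time
fraction therefore equals `D_eff/D_P`.

The release channels deserve one more note: total anchor release from a
particle in state `(n, s)` is always `n k_off`, split as `(n−s) k_off`
(release of a non-crosslinking anchor, `s` unchanged) plus `s k_off`
(release of a crosslinking anchor, `s` decremented). Bonds are independent,
so no other split is consistent.

## Validity conditions

`regime_report()` evaluates the six conditions under which the reduction
below is derived, each with a numeric ratio and a configurable separation
factor (default 10, applied to the strict `≫` conditions; the plain
inequalities C4 and C5 use factor 1):

* C1 `τ_AM ≪ τ_AP`: matrix exchange much faster than particle exchange;
* C2 `N ≫ 1`: multiple binding sites;
* C3 `D_A ≫ D_P`: anchors much more mobile than the particle;
* C4 `τ_AP < τ_L = L²/(2 D_P)`: anchors accumulate within the passage time;
* C5 matrix-bound anchors do not saturate the matrix, `[A](1−φ) < [M]`;
* C6 at most one anchor per particle volume, `[A] ≪ 1/V_P`.

## Quasi-steady-state reduction

With `τ_AM ≪ τ_AP` the crosslink number `s` equilibrates at fixed `n`:

```
ρ(0|n) = D_A C αⁿ / ((D_A C − D_P) αⁿ + D_P),   α = a_off/(C a_on + a_off)
ρ(s|n) = D_P C(n,s) (1−α)^s α^(n−s) / ((D_A C − D_P) αⁿ + D_P),  s ≥ 1
```

Averaging the `n`-transitions over `ρ(s|n)` gives a birth–death process with
per-site gain `κ(n) = k_on + ρ(0|n) k'_on` — only the gated matrix-capture
channel picks up the factor `ρ(0|n)` — and per-anchor loss `k_off`, whose
stationary law is `ρ(n) ∝ C(N,n) ∏_{j<n} κ(j) / k_off^n`. Finally

```
D_eff/D_P = Σ_n ρ(0|n) ρ(n).
```

The test suite checks this closed form against the exact stationary
distribution of the full chain (dense null-space solve) across randomized
parameters: agreement is within 1% whenever `τ_AP/τ_AM ≥ 10³`, and already
excellent at ratio 20 for well-separated points. Note that weighting `k_on`
by `ρ(0|n)` instead — a tempting but incorrect averaging — produces values
up to two orders of magnitude away from the exact chain; the package's form
is the one the chain converges to.

## Parameters, units, and scales

All concentrations are number densities (1/µm³), diffusivities µm²/s,
lengths µm, times s. The dimensionless knobs the model is naturally swept
over are `D_A/D_P`, `N`, `τ_AP/τ_AM`, the concentration scale
`[A](D_P+D_A)R0/k_off`, `φ`, and `C`. Conversions:

* `from_dimensionless()` fixes `k_off = 1 s⁻¹` and `D_P = 1 µm²/s` by
  default; every reported model quantity (`D_eff/D_P`, reductions,
  penetration at stated `L`, `T`) is invariant to these scales or carries
  them explicitly.
* The concentration axis is `[A](D_P+D_A)R0/k_off`, deliberately
  φ-independent (the φ-dependent `k_on` would make the `φ = 0` column of a
  sweep degenerate). One consequence worth knowing: at *fixed* dimensionless
  concentration, raising `D_A/D_P` dilutes the physical anchor
  concentration (`[A]R0 = conc·k_off/(D_P+D_A)`), and `D_eff` can *rise*
  with anchor mobility. At fixed physical `[A]R0`, trapping strengthens
  monotonically with `D_A`. `sensitivity(..., conc_held =)` exposes both
  conventions and the tests pin both signs.
* `R0` is a lumped encounter parameter (µm) absorbing the geometric 4π
  factor, so `rate = D·[A]·R0` is 1/s.
* For dimensional penetration questions the default particle diffusivity is
  `D_P = 2 µm²/s`, the Stokes–Einstein order of magnitude for a ~200-nm
  particle in watery gel pores at 37 °C; it is always recorded in outputs.
* Mass-concentration helpers assume a molar mass in kDa (150 for IgG);
  `anchor_spacing()`/`conc_for_spacing()` are exact inverses.

## Gel-layer transport

The absorption probability treats the gel as a 1-D slab `[0, L]`: the
particle starts at the entry face `x = 0` (deposition on the outer surface),
reflects there, and is absorbed at `x = L`. The eigenfunction series

```
P(T) = 1 − Σ_{k≥0} 4(−1)^k/((2k+1)π) · exp(−D_eff (2k+1)² π² T / (4L²))
```

is truncated when the next term falls below 1e-12; probabilities are
reported only to that floor (differences below ~1e-12 are truncation noise).
The spatial Monte-Carlo (`simulate_spatial()`) makes no homogenization
assumption: it alternates exact exponential chain dwells with Brownian
sub-steps of at most `τ_L/10⁴` during free intervals, reflecting at 0 and
absorbing at `L`. Sub-stepping bounds the bias from undetected
boundary crossings inside a step; with step standard deviation
`≈ L/√(2·10⁴)` the residual bias is well below the Monte-Carlo error at the
particle counts used. The two routes agree within 3 Monte-Carlo standard
errors whenever `τ_AM, τ_AP ≪ τ_L`, which the tests verify on a 3×3 grid of
diffusivities and thicknesses.

## Stochastic simulation

`gillespie()` is an exact SSA on the `(n, s)` chain starting from `(0, 0)` —
a bare particle entering the gel. The estimator `D_P · t_free/t_total` uses
no burn-in: it is a long-run time average and the chain mixes quickly
relative to run lengths; the initial-state bias is O(mixing time / run
time). Standard errors come from batch means with 20 equal transition-count
batches; they are approximate (batches are weakly correlated), so the tests
allow occasional 3-sigma excursions across 20 randomized parameter sets.
All randomness flows through R's RNG (`set.seed`), so identical seeds give
bit-identical runs, and every stochastic result records its seed.

## Matrix saturation and many anchor species

With `m` anchor species of identical kinetics and equal per-species
concentration, the total pool `[A_T] = m[A]` competes for matrix sites. The
fraction of unoccupied sites is `ξ = a_off/(([A_T]/[M]) a_on + a_off)`, and
every anchor-to-matrix binding rate is scaled by `ξ`. The package applies
this exact occupancy form smoothly at all `[A_T]` rather than switching
between an unsaturated and a saturated branch at `[A_T] = [M]`: the smooth
form recovers the unmodified model exactly as `[A_T]/[M] → 0` and the
asymptotic substitutions (`φ → 1 − [M]/[A_T]`, `α → 1 − C[M]/[A_T]`,
`τ_AM → 1/a_off`) as `[A_T]/[M] → ∞`, whereas a hard switch makes
`D_eff(m)` discontinuous. The asymptotic quantities themselves are exposed
by `saturated_regime()`. The balance `u = ξ a_on/a_off =
(1−φ)/(r(1−φ)+φ)` (with `r = [A_T]/[M]`) is evaluated in a form that stays
defined in the permanent-bond limit `φ = 0`. One caveat: the occupancy form
is a kinetic mean field; for `φ → 0` at `[A_T] < [M]` it overstates
competition slightly (a mass balance would leave sites free until
`[A_T] = [M]`), which matters only in that extreme corner.

`species_capacity()` evaluates the focal species' `D_eff/D_P` against `m`
with the exact chain by default — essential, because the closed-form
reduction depends on the anchor–matrix rates only through `φ` and `α` and is
therefore blind to the timescale ratio that distinguishes slow from fast
anchor exchange. Two capacity summaries are provided
(`species_capacity_limit()`):

* *relative*: the largest `m` with `D_eff(m) ≤ 2 · D_eff(1)`. This is
  sensitive to how deep the single-species optimum is — a system that traps
  10⁵-fold has its value "doubled" by an inconsequential absolute change —
  and under it, fast and slow anchor designs have capacities within a small
  factor of each other.
* *absolute*: the largest `m` with `D_eff(m)` below a potency ceiling (for
  example 0.05, a 95% mobility reduction). This tracks whether the marginal
  species is still effectively immobilized, and under it rapidly exchanging
  anchors sustain an order of magnitude (and more) greater species counts
  than slow, tight-binding anchors — the mechanistic reason being that
  tight binders monopolize matrix sites (`ξ` collapses at
  `[A_T]/[M] ≈ φ/(1−φ)`, which is small precisely when trapping requires
  small `φ`). The test suite computes both.

The multi-species defaults emulate a 2% w/v gel with 10 anchor-binding
sites per 500-kDa matrix molecule (`[M] = 10⁵ µm⁻³`) and a per-species
anchor density of 4 µm⁻³ (≈1 µg/mL of a 150-kDa IgG), with `R0` set so the
single-species dimensionless concentration is 10 — a trapping-effective
operating point. These are design choices where no measured values exist;
they are configurable.

## Sensitivity analysis

`sensitivity()` differentiates `log(D_eff/D_P)` by central finite
differences with adaptive step halving (relative start 1e-3, stop when
successive estimates agree within 1%); the integer site count `N` uses a
centered unit difference. The exact chain is the default engine — required
for the `τ_AP/τ_AM` axis, along which the closed form is constant by
construction. Both absolute-step and relative-step normalizations are
reported, since the choice is conventional. At the reference point
(`D_A/D_P = 20`, `N = 20`, `τ_AP/τ_AM = 20`, concentration 2) the timescale
ratio, concentration and valency all have non-positive sensitivities, and
the timescale ratio dominates everything at its low end.

## Particle-tracking pipeline and the synthetic generator

The analysis follows standard multiple-particle-tracking practice:
time-averaged MSD per track, `D_eff = MSD(τ)/(4τ)` at the reference lag
`τ = 0.2667 s` (4 frames at 66.7 ms, implying a 5-frame minimum usable
track), a log–log least-squares fit of `MSD = 4 D_0 τ^α` for the diffusive
exponent, geometric (log-mean) ensemble averaging with zero/low MSDs floored
at the localization noise floor `4σ²`, and a mobile classification at
`D_eff ≥ 10^−1.5 µm²/s` (boundary inclusive, compared against the constant
computed once). The per-track `D_eff` is the single-lag estimator at the
reference lag; fitting instead of single-lag evaluation is a known
alternative and would change individual values slightly but not the
classification logic.

`generate_tracks()` emulates the imaging experiment: the binding chain runs
in continuous time, frame displacements are Gaussian with variance
`2 D_P t_free` per axis (`t_free` the within-frame free time), and i.i.d.
Gaussian localization noise (σ = 10 nm) is added per coordinate per frame.
Defaults: 300 frames (20 s), 66.7-ms frames. What the generator does *not*
emulate — and hence what passing pipeline tests do and do not show about
real data: gel heterogeneity and pore-scale obstruction, hydrodynamic
coupling, motion blur within exposures, correlated/static localization
errors, depth-dependent aberrations, track splitting/linking errors, and
photobleaching-limited track lengths. Pipeline closure on synthetic data
validates the estimators, not the microscopy.

## Numerical choices and degenerate inputs

* `ρ(n)` products and binomials are evaluated in log space (`lchoose`,
  log-sum-exp), so `N` in the hundreds poses no overflow risk.
* The stationary distribution solves the augmented system `[Qᵀ; 1] π = [0; 1]`
  by dense QR least squares — state counts are `(N+1)(N+2)/2` (136 at
  `N = 15`), far below where sparse machinery would pay off. Tiny negative
  entries from roundoff (≥ −1e-12) are clamped to zero.
* `k_off = 0` makes high-`n` states absorbing; `stationary()` then reports
  the absorbing structure explicitly and returns the long-run `s`-law of the
  terminal level instead of a meaningless global stationary vector.
* `α = 0` and `α = 1` in `ρ(s|n)` are handled as exact limits rather than
  through `0·log(0)`.
* `φ = 1` and zero concentration yield `D_eff/D_P = 1` exactly; the φ-grid
  minimizer reports degenerate (flat) profiles rather than an arbitrary
  argmin.
* YAML configuration keys `N` and `T` are restored after YAML 1.1's
  boolean coercion.

## Problem sizes in the test suite

The suite runs in well under a minute: exact-chain cross-checks use
`N ≤ 15` (≤136 states) over 20 randomized draws; Gillespie consistency uses
10⁶ transitions per draw; the spatial-vs-series comparison uses 200
particles per cell on a 3×3 grid; tracking closure uses 100–250 tracks of
300 frames. These sizes were chosen so Monte-Carlo error bars are tight
enough for 3-sigma checks to be informative.

## Known limitations

The gel is spatially homogeneous with a single matrix-site species; anchor
concentration is held constant (no depletion by binding); anchor–anchor
interactions and correlated bonds are excluded; the spatial model is 1-D
through the layer thickness; multi-species theory assumes identical kinetics
across species; and no fitting of rates to binding-sensor data is provided —
rates are inputs.
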