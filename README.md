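# anchortrap

Biopolymer gels such as mucus, basement membranes and reconstituted matrices
rarely bind invading nanoparticulates (viruses, nanoparticles) directly.
Instead, "third-party" molecular anchors — most prominently IgG antibodies —
can crosslink a particle to the matrix even when each individual
anchor–matrix bond is weak and short-lived. `anchortrap` implements the
stochastic theory of this mechanism for researchers studying mucosal
immunology, antibody engineering and barrier transport: it answers how anchor
kinetics, affinity, concentration and valency should be tuned to immobilize
particles most effectively, and it provides the particle-tracking analysis
used to connect the model to microscopy experiments.

## The model

Three species interact: anchors **A** (diffusivity `D_A`, concentration
`[A]`), nanoparticulates **P** (diffusivity `D_P`, `N` binding sites), and
immobile matrix sites **M**. Anchors exchange with the matrix at rates
`a_on`/`a_off` (free fraction `φ = a_off/(a_on + a_off)`) and bind the
particle at Smoluchowski encounter rates

    k_on  = (D_P + D_A) φ [A] R0        (free anchors)
    k'_on = (D_P + D_M) (1 − φ) [A] R0  (matrix-bound anchors, D_M ≈ 0)

The state of one particle is `(n, s)`: `n` anchors bound to the particle, of
which `s` simultaneously crosslink it to the matrix. The six reaction
channels form a continuous-time Markov chain; the particle diffuses only
while `s = 0`, so its long-run free-time fraction *is* the relative
effective diffusivity `D_eff/D_P`. When anchor–matrix kinetics are much
faster than anchor–particle kinetics (`τ_AM ≪ τ_AP`), the chain reduces in
closed form:

    ρ(s|n): quasi-stationary crosslink distribution at fixed n
    ρ(n) ∝ C(N,n) ∏_{j<n} κ(j) / k_off^n,  κ(n) = k_on + ρ(0|n) k'_on
    D_eff = D_P Σ_n ρ(0|n) ρ(n)

The package computes this reduction, the exact chain stationary law (the
brute-force reference), a Gillespie simulation with the time-fraction
estimator `D_eff ≈ D_P t_free/t_total`, first-passage ("absorption")
probabilities across a gel layer, matrix-saturation theory for many
coexisting anchor species, finite-difference sensitivities of
`log(D_eff/D_P)`, and a multiple-particle-tracking MSD pipeline with a
synthetic switching-diffusion trajectory generator (66.7-ms frames, 20-s
videos, 10-nm localization noise).

## Worked example

Fifteen binding sites per particle, anchors 20-fold more mobile than the
particle, fast matrix exchange (`τ_AP/τ_AM = 20`), 30% of anchors free, a
moderate dimensionless anchor concentration of 2:

```r
library(anchortrap)

dp <- dimensionless_params(d_ratio = 20, N = 15, tau_ratio = 20,
                           conc = 2, phi = 0.3)
d_eff_qss(dp)
#> [1] 0.08945967

p <- from_dimensionless(dp)          # physical rates with k_off = 1, D_P = 1
stationary(build_chain(p))
#> Stationary distribution over 136 states
#>   P[s = 0] = D_eff/D_P = 0.0910216

gillespie(p, max_transitions = 1e6, seed = 1)
#> Gillespie run: 1e+06 transitions, 6916 s simulated
#>   D_eff_hat = 0.0881806 (SE 0.0023), D_eff/D_P = 0.0881806
```

All three engines agree: weak, rapidly exchanging anchors cut particle
mobility by about 91% at this operating point. The consequence for barrier
function, for a 200-nm particle (`D_P = 2 µm²/s`) facing a 50-µm gel layer
over 2 h:

```r
penetration_probability(2 * d_eff_qss(dp), L = 50, T = 7200)
#> Absorption probability: P = 0.642947 (D_eff = 0.178919 um^2/s, ...)
penetration_probability(2, L = 50, T = 7200)$probability  # anchor-free gel
#> [1] 0.9999991
```

At a higher anchor concentration (dimensionless 10) the reduction exceeds
99.9% and penetration is essentially abolished, with the optimum free
fraction at `phi_minimizer(N = 15, tau_ratio = 20, conc = 10)$phi_opt`
= 0.22 — weak anchor–matrix bonds outperform permanent ones whenever the
particle carries multiple binding sites.

The tracking pipeline closes the loop on synthetic microscopy data:

```r
ts <- generate_tracks(p, n_tracks = 100, seed = 2)
analyze_tracks(ts)
#> MSD analysis: 100 tracks (0 excluded as too short)
#>   geometric <D_eff> = ... um^2/s at tau = 0.2668 s; ...
#>   mobile fraction = ... (cutoff 0.03162 um^2/s)
```

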