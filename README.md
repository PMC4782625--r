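# fondaka

An electrostatic model of how a spherical cationic polymer antidote
associates with the anticoagulant **fondaparinux**, for *in silico*
screening of antidote candidates.

Fondaparinux is a synthetic pentasaccharide with a net charge of −10 at
physiological pH and no clinical antidote. One proposed reversal agent is a
polymer: a roughly spherical core grafted with small cationic oligoamine
*binding groups* (R1-1 … R6-1). Because these polymers cannot be
crystallized and are expensive to synthesize, candidate structures are
screened computationally. `fondaka` implements that screen at desk scale —
no molecular-dynamics engine, no force field — for researchers in polymer
therapeutics and molecular modelling.

## The model

The association rate constant is diffusion-limited and electrostatically
steered (Schreiber relation over a sphere–rod Smoluchowski basal rate):

    ln k_a = ln k_a0 − ΔU / (k_B T (1 + κa))
    k_a0   = 4π N_A (D_A + D_B) R_x,   R_x = l / ln(2l/w),   D = k_B T / (6π η r′)
    κ      = sqrt(2 F² I / (ε₀ ε_r R T))
    U      = ½ Σ_{i≠j} q_i q_j e^{−κ(r_ij − a)} / (4π ε₀ ε_r r_ij (1 + κa))

with `a` the minimal approach distance (8.5 Å refined / 6 Å simplified
binding criterion), `ΔU` the screened interaction energy between the charge
sets, and physiological defaults I = 150 mM, T = 298.15 K,
η = 0.90×10⁻³ kg s⁻¹ m⁻¹, ε_r = 80.

Polymers are built by Monte Carlo: binding groups placed uniformly on the
sphere under a minimum separation r_min = 9.16 Å, binding sites identified
as ≥ 3 groups within a capture radius of a seed group, fondaparinux bound
sequentially with full charge bookkeeping (lumped site charges under the
refined criterion). Each condition is summarized over 1,000 polymers:
geometric-mean k_a (non-binders count as exactly 1) and arithmetic-mean
bound count, with 95% confidence intervals.

A companion PMF toolkit plans restrained-window protocols (21.5 → 1.5 Å at
0.5 Å, 60 ps per window), integrates free-energy profiles from per-window
mean restraint forces (trapezoid quadrature plus the −2k_BT ln(R/R₀′)
Jacobian term), aggregates replicates with Student-t intervals, extracts
binding free energies from well depths, and synthesizes window data from
analytic potentials for testing.

## Worked example

```r
library(fondaka)

cond <- solution_conditions()
cond
#> Solution conditions
#>   ionic strength : 150 mM
#>   temperature    : 298.15 K
#>   viscosity      : 0.0009 kg/s/m
#>   dielectric     : 80
#>   Debye parameter: 0.12612 1/Angstrom

# one polymer: 12 R4-1 groups on a 4 nm core
sc    <- place_groups(n = 12, r_H = 40, r_min = 9.16, seed = 7)
sites <- find_binding_sites(sc)
state <- bind_sequential(sc, sites, variant = "refined", cond = cond)
length(sites); state$events$dU[1]; polymer_ka(state, cond)
#> [1] 1
#> [1] -8.440271        # kcal/mol, first binding event
#> [1] 2.498e+12        # 1/(M s)

# a 1,000-polymer ensemble under the same condition
run_ensemble(ensemble_config(n_polymers = 1000, n_groups = 12, seed = 1))
#> ensemble (refined, 12 x R4-1 groups = 12, r_H = 4 nm, n = 1000)
#>   geometric mean k_a : 1.376e+12 [1.09e+12, 1.736e+12] 1/(M s)
#>   mean bound count   : 1.869 [1.826, 1.912]
```

The single polymer here forms one binding site; the favourable −8.4 kcal/mol
screened interaction energy boosts its association rate three orders of
magnitude above the ~2.6×10⁹ M⁻¹s⁻¹ diffusion limit. Across the ensemble,
polymers that fail to form a site contribute the sentinel k_a = 1, pulling
the geometric mean below the best performers — which is exactly how sparse
binding-site formation shows up in this model.

Sweeps over group number, polymer radius, effective charge and group
identity, and the refined-vs-simplified criterion comparison, are available
as `sweep_ensemble()` and `compare_variants()`, or from the shell via the
`inst/cli/fondaka` script (`simulate`, `sweep`, `compare-variants`,
`pmf plan|synth|integrate`, `constants`).

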