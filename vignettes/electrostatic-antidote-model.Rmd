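---
title: "An electrostatic model for polymer antidote association with fondaparinux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An electrostatic model for polymer antidote association with fondaparinux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fondaka)
```

## The problem

Fondaparinux is a synthetic pentasaccharide anticoagulant carrying a net
charge of −10 at physiological pH. It has no clinical antidote: protamine,
which reverses heparin, does not bind it. One design strategy is a polymer
antidote — a roughly spherical polymer core grafted with small cationic
oligoamine *binding groups* (named R1-1 … R6-1 by nitrogen count and linker)
that captures fondaparinux electrostatically. Because such polymers resist
crystallography and are arduous to synthesize, candidate screening has to be
done *in silico*.

`fondaka` implements the desk-scale electrostatic model used for that
screening, together with the potential-of-mean-force (PMF) machinery used to
choose binding groups. It deliberately contains **no molecular dynamics**:
MD enters only as per-window mean restraint forces that the PMF toolkit can
also synthesize from known analytic potentials for testing.

## The rate model

Association of a polymer (sphere, hydrodynamic radius $r_H$) with
fondaparinux (rod, semiaxes $l \ge w$) is taken to be diffusion-limited and
electrostatically steered. The basal Smoluchowski rate for the sphere–rod
pair is

$$k_a^\circ = 4 \pi N_A (D_A + D_B) R_x, \qquad
R_x = \frac{l}{\ln(2l/w)}, \qquad
D = \frac{k_B T}{6 \pi \eta r'},$$

converted to $\mathrm{M^{-1} s^{-1}}$. Long-range electrostatics modulate it
through the Schreiber relation

$$\ln k_a = \ln k_a^\circ - \frac{\Delta U}{k_B T}\,\frac{1}{1 + \kappa a},$$

where $a$ is the minimal approach distance, $\kappa$ the Debye–Hückel
parameter

$$\kappa = \sqrt{\frac{2 F^2 I}{\varepsilon_0 \varepsilon_r R T}},$$

and $\Delta U$ the screened interaction energy between the two charge sets,

$$U = \tfrac{1}{2}\sum_{i \ne j}
\frac{q_i q_j}{4\pi \varepsilon_0 \varepsilon_r r_{ij}}
\frac{e^{-\kappa (r_{ij} - a)}}{1 + \kappa a}, \qquad
\Delta U = U_{AB} - U_A - U_B .$$

The symbol multiplying $a$ in the $(1+\kappa a)$ factors is the Debye
parameter, not a rate constant; this is the only dimensionally consistent
reading. Internally everything is SI with charges in elementary units at the
interface; energies are reported in kcal mol⁻¹ and all unit conversions are
centralized and covered by hand-computed oracle tests (e.g. two +1 charges
at 7.13 Å in $\varepsilon_r = 80$ give 0.582 kcal mol⁻¹ unscreened; the
physiological $\kappa$ is 0.1261 Å⁻¹).

Default solution conditions are physiological: $I = 150$ mM, $T = 298.15$ K,
$\eta = 0.90\times10^{-3}$ kg s⁻¹ m⁻¹, $\varepsilon_r = 80$.

## The stochastic polymer model

A polymer is `n` binding groups placed uniformly at random on the sphere
surface subject to a minimum pairwise distance $r_\mathrm{min} = 9.16$ Å
(standing in for inter-group repulsion and sterics; it exceeds the group
radii of R4-1, 6.61 Å, and R6-1, 7.10 Å). Placement is rejection sampling
with a fail-fast spherical-cap packing bound, a budget of $10^4$ attempts
per group and up to 100 restarts; everything is reproducible under a fixed
seed.

A *binding site* is three or more groups close enough together that one
fondaparinux can engage all of them. We realize this as greedy disjoint
clustering in placement order: an unassigned group seeds a candidate made of
all unassigned groups within a Euclidean *capture radius* of it; candidates
with ≥ 3 members become sites. The capture radius defaults to the rod length
$2l = 30$ Å — a rod contacting every member bounds their spread by its own
length. The exact geometric construction behind "close enough" is a declared
approximation; the ball rule is simple, testable and order-deterministic.

Binding proceeds site by site in seed order. Per event, a fondaparinux
(default: one −10 point charge; a 10 × (−1) rod layout is available) is
placed at distance $a$ radially above the seed group, $\Delta U$ is computed
against the **current** polymer charge state (remaining free groups plus
previously lumped sites), and the event's $k_a$ follows from the Schreiber
relation. Two binding criteria are provided:

* **refined** ($a = 8.5$ Å, the centroid–centroid distance at binding seen
  in the PMF wells of the strong binders): every site binds, and the site is
  replaced by a single lumped charge $-10 + \sum q_\mathrm{eff}$ at the seed
  location. Unneutralized fondaparinux charge thus stays in the system
  ("system neutralization").
* **simplified** ($a = 6$ Å, the classic best-fit contact distance for
  protein pairs): a site binds only if its member charges sum to at least
  +9 — almost complete neutralization of the −10 — and the neutralized
  complex is removed. The +9 threshold is configurable; it is not stated
  anywhere and +9 is the natural reading of "almost complete".

The per-polymer $k_a$ is the **first** binding event's value; a polymer with
no event returns exactly 1, the no-binding sentinel that keeps geometric
means over mixed ensembles well defined. A consequence worth knowing:
because the refined criterion is purely geometric, bound counts are exactly
independent of the effective charge at a fixed seed, while $k_a$ is strictly
increasing in it.

## Ensembles and sweeps

A condition is summarized over 1,000 independently constructed polymers
(configurable): geometric mean of $k_a$ (computed in log space; sentinels
included, with an exclusion flag for sensitivity analysis) and arithmetic
mean of the bound count, each with a two-sided Student-t 95% CI (on the log
scale for $k_a$). Per-polymer seeds are derived from the master seed and the
polymer index, and every grid point of a sweep reuses the master seed, so
comparisons across effective charges, radii or group identities are matched
polymer-by-polymer.

`compare_variants()` runs the same group-number grid under both criteria and
reports each variant's $k_a$ *span* — the ratio of the largest to the
smallest per-condition geometric mean, excluding conditions stuck exactly on
the sentinel — plus the log₁₀ simplified-to-refined span ratio. Because
"range" can also be read as overall magnitude, the log₁₀ ratio of the two
maxima is reported alongside.

## The PMF toolkit

The free-energy profile along the centroid–centroid distance $R$ is
reconstructed from per-window mean restraint forces
$\langle K^r (R(t) - R_o) \rangle$ (default $K^r = 100$ kcal mol⁻¹ Å⁻²):

$$F(R') = -\int_{R_o'}^{R'} \langle f \rangle \, dR''
\;-\; 2 k_B T \ln\frac{R'}{R_o'} \;+\; F(R_o'),$$

with the outermost window as reference ($F = 0$ there by default) and the
logarithmic Jacobian term, which corrects for the growth of configurational
space with separation, exposed as a flag. The default window protocol runs
from 21.5 Å to 1.5 Å in 0.5 Å steps — 41 windows of 10 ps equilibration +
50 ps production, 2.46 ns in total.

Numerical choices: the quadrature is the composite trapezoid rule on the
window grid (matched to the equally spaced protocol; its second-order
convergence is asserted against a 100× finer-grid oracle), and the sign
convention is fixed so attractive mean forces produce negative wells
(asserted via a harmonic-well oracle: at restrained equilibrium the mean
restraint force equals $-dV/dR$).

Binding free energies are extracted as
$\Delta G = F(\text{minimum}) - \overline{F}(\text{plateau})$ with the
plateau defined as all points at $R \ge 17.5$ Å (configurable; profiles of
the strong binders flatten around there). The well width is the contiguous
span around the minimum where $F$ stays below the plateau mean, and a
no-well flag is raised when $\Delta G \ge 0$.

`synth_window_forces()` emulates the restrained protocol for known analytic
potentials (harmonic, Gaussian well, flat): mean forces are $-dV/dR$ at the
window centers plus Gaussian noise. It reproduces what matters for testing
the estimator — grid, noise, replicate structure — and nothing else: no
force field, no time correlation within a window, no equilibration
transients. Passing tests therefore validate the *estimator*, not any claim
about real MD data.

## Parameters that are model defaults, not measurements

The fondaparinux rod dimensions ($l = 15$ Å, $w = 5$ Å) and hydrodynamic
radius (7 Å), the R6-1 theoretical charge (+4), and the radii of R1-1, R3-1
and R4-2 are plausible, documented defaults chosen once — nothing in the
package depends on them being exact, and all are configurable. Effective
charges default to the theoretical protonation charges; in reality they are
shielded and generally unknown, which is why every sweep exposes them.

## Problem sizes

The test suite exercises ensembles of 20–1,000 polymers; the headline
refined-vs-simplified comparison uses the full grid of 18 group numbers ×
2 criteria × 1,000 polymers (36,000 polymer constructions), which runs in
about two minutes on one core. PMF coverage checks use 100 Monte-Carlo
trials of 7 replicates × 41 windows.

## Known limitations

* No polymer conformational dynamics, no excluded volume beyond
  $r_\mathrm{min}$, no bridging-induced structural change, no atomistic
  fondaparinux — the model is strictly the screened point-charge picture.
* No Poisson–Boltzmann solver, explicit ions or dielectric boundaries; the
  Debye–Hückel closed forms are the physics, by design.
* The simplified binding criterion is a reconstruction from a textual
  description of an earlier model; its contact bookkeeping is the least
  constrained part of the package and the main driver of disagreement in
  refined-vs-simplified span comparisons.
* MD-derived quantities (the −2.394 / −2.768 kcal mol⁻¹ well depths of the
  R4-1/R6-1 groups) require a commercial force field and are used here only
  as fixture-extraction examples for the PMF machinery, never as physics the
  package claims to recompute.
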