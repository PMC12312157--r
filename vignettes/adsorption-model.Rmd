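---
title: "Modelling dynamic surface tension of an adsorbing chaperone protein"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dynamic surface tension of an adsorbing chaperone protein}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensiokin)
```

## The system and the model

tensiokin models the dynamic surface tension $\gamma(t)$ of a protein
solution in a hanging-drop tensiometer. The motivating system is the
human molecular chaperone DNAJB6b (27 kg/mol, diffusion coefficient
about 45 µm²/s) adsorbing to the air–water interface of a pendant drop
(approximated for transport purposes as a sphere of radius $R$ = 2.1 mm),
but every physical parameter is configurable.

Measured traces show three kinetic regimes: an induction period at the
buffer tension $\gamma_0$ = 72.0 mJ/m², a rapid fall, and a semistable
tail. The model reproduces this with three coupled ingredients:

1. **Transport.** Protein diffuses inside the drop,
   $\partial_t c = D(\tfrac{2}{r}\partial_r c + \partial_r^2 c)$, with a
   symmetry condition at the centre and an adsorbing boundary at the
   surface, $d\Gamma/dt = -D\,\partial_r c|_{r=R}$. For a perfect sink
   the adsorbed amount has the closed series solution
   $$\Gamma_\mathrm{diff}(t) = \frac{c_\mathrm{int} R}{3}\Bigl(1 -
   \frac{6}{\pi^2}\sum_{z\ge1} \frac{e^{-D z^2 \pi^2 t/R^2}}{z^2}\Bigr),$$
   which also defines the diffusion-limited induction time (the time to
   reach a critical coverage $\Gamma_0$). The finite drop volume makes
   bulk depletion explicit: at $\Gamma_0 = 24\times10^3$ µm⁻² a
   50 mm²/40 µL drop loses about 0.05 µM from its bulk.

2. **Surface equation of state.** Below the critical coverage
   $\Gamma_0$ the adsorbed film is in a two-phase (gas + condensed)
   region and the surface pressure $\Pi = \gamma_0 - \gamma$ is zero —
   this *is* the induction plateau. Above $\Gamma_0$ the package uses the
   saturating-exponential family
   $$\Pi(\Gamma) = \Pi_\mathrm{max}\Bigl(1 -
   e^{-(E_0/\Pi_\mathrm{max})(\Gamma/\Gamma_0 - 1)}\Bigr),$$
   chosen because exactly three constraints are available: onset at
   $\Gamma_0$, a 2D bulk elastic modulus
   $\Gamma\,d\Pi/d\Gamma = E_0 = 15$ mJ/m² at onset, and saturation at
   $\Pi_\mathrm{max} = 22$ mJ/m². Any monotone $C^1$ family satisfying
   the same anchors could be substituted behind `pi_of_excess()` /
   `excess_of_pi()`. The collapse coverage
   $\Gamma_\mathrm{collapse} = 3.5\,\Gamma_0$ (12 nm² per molecule) is
   carried as an annotation; the model treats $\Pi$ as saturating rather
   than enforcing a mechanical collapse.

3. **Adsorption barrier.** Once a condensed film exists, an arriving
   molecule must cavitate a hole against the film pressure
   ($\Delta G_\mathrm{cav} = \Pi\,a(\Pi)$, with $a(\Pi)$ the current
   area per molecule — the cavity shrinks as the film compresses) and be
   compressed from its uncompressed footprint $a_0$ to $a(\Pi)$
   ($\Delta G_\mathrm{comp} = \int_{a(\Pi)}^{a_0}\Pi(a')\,da'$, an
   isothermal work along the equation of state). The rate law is
   $$\frac{d\Gamma}{dt} = B\,
   e^{-q\,(\Delta G_\mathrm{comp}+\Delta G_\mathrm{cav})/k_BT}\,
   \frac{c(R)}{c_\mathrm{ref}},$$
   with fitted constants $B = 70\times10^3$ µm⁻²s⁻¹ and $q = 0.15$, and
   adsorption fully irreversible. The chemical-potential factor
   $e^{(\mu-\mu^\circ)/k_BT}$ reduces to the relative concentration in
   the ideal-dilute approximation; the standard state is fixed at
   $c_\mathrm{ref}$ = 1 molecule/µm³ so that $B$ carries the published
   units.

With clustering enabled, an isodesmic equilibrium (single association
constant $K$; default $5\times10^{-3}$ µm³, i.e. 3 µM⁻¹) sets a
geometric cluster size distribution, frozen during a run because cluster
interconversion is slow on the experimental timescale. A cluster of $n$
monomers adsorbs $n$ monomers at once with the barrier scaled by the
very weak factor $n^{1/20}$; each size class diffuses with the monomer
$D$ by default (a $D_1 n^{-1/3}$ mode exists but changes the
diffusion-limited flux only as $n^{-1/6}$, see
`cluster_flux_scaling()`).

## Functional-form choices worth knowing about

**The split of the barrier is not monotone; the total is.** With the
saturating-exponential equation of state the coverage grows
logarithmically as $\Pi \to \Pi_\mathrm{max}$, so the cavity area
$a(\Pi)$ shrinks fast enough that $\Delta G_\mathrm{cav} = \Pi a(\Pi)$
peaks (near $\Pi \approx 14$ mJ/m²) and then declines, while
$\Delta G_\mathrm{comp}$ keeps growing and overtakes it above
$\Pi \approx 12$ mJ/m². The physically meaningful combination is the
sum, and that is rigorously monotone for *any* monotone equation of
state: $d(\Delta G_\mathrm{cav}+\Delta G_\mathrm{comp})/d\Pi = a(\Pi) > 0$.
The adsorption rate therefore decreases strictly with coverage, which
is the property the tests assert.

**Exact barrier forms are a model definition.** Only the conceptual
content of the cavitation and compression steps is fixed by the
physical picture; the package's $\Pi a(\Pi)$ and
$\int \Pi\,da$ expressions are its own concrete definitions, isolated
behind `delta_g_cav()` and `delta_g_comp()` so they can be swapped.
Quantitative values of $B$ absorb any residual standard-state
ambiguity, which is why curve-level reproduction is semiquantitative by
construction and the package's validation is anchor- and
property-based.

## Numerics

* **Spatial discretisation.** Finite volumes on a geometrically graded
  spherical mesh (default 150 cells, finest cell 1 µm at the surface,
  which resolves the boundary layer $\sqrt{Dt}\approx 67$ µm at
  $t = 100$ s; the near-surface spacing is kept at or below 2 µm). The
  flux form conserves bulk + surface material exactly in the
  semi-discrete system; runs track the drift and abort if it exceeds
  0.1%. The centre singularity never enters because the $r = 0$ face
  has zero area.
* **Time integration.** deSolve's `lsoda` (adaptive, implicit when
  stiff), switching to the sparse `lsodes` when cluster size classes
  push the state dimension past ~600. The boundary rate at
  $B = 70\times10^3$ µm⁻²s⁻¹ makes the pre-onset regime a stiff,
  nearly-perfect sink; the implicit integrator handles it without
  step-size collapse, reproducing the closed series to better than
  0.2% over $t \in [1, 10^4]$ s.
* **Series evaluation.** The spherical series is truncated adaptively
  (next term below $10^{-12}$ of the partial sum) and switched to the
  planar Ward–Tordai form $2c\sqrt{Dt/\pi}$ when
  $\sqrt{Dt}/R < 10^{-3}$, where the series converges slowly and the
  planar form is accurate to well under 0.1%.
* **Barrier evaluation.** $\Delta G(\Pi)$ is precomputed once per
  simulation on a 400-knot monotone spline; the compression integral
  itself uses adaptive quadrature at relative tolerance $10^{-8}$
  (validated against a Riemann-sum oracle in the tests).
* **Cluster binning.** The isodesmic distribution (truncated at 99.9%
  retained mass, hard cap $n = 10^4$) is binned to at most ~24 species
  classes — exact sizes up to 8, geometric bins beyond — preserving
  cluster number and monomer mass per bin exactly; the $n^{1/20}$
  factor varies negligibly within a bin.
* **Degenerate inputs.** Zero concentration gives a flat trace at
  $\gamma_0$; $\Pi \ge \Pi_\mathrm{max}$ has no finite coverage and is
  rejected; induction targets above the drop's total content
  ($\Gamma_0 \ge cR/3$) raise "insufficient total protein".

## Experiment protocols

* **Bulk exchange** is an instantaneous uniform reset of the bulk
  profile at the exchange time with the surface excess retained (the
  real coaxial-capillary exchange takes minutes; the reset is a
  deliberate idealisation). Exchange to buffer freezes $\gamma$
  exactly; exchange to a higher concentration resumes the decrease. One
  subtlety follows from the idealisation: exchanging with the *same*
  nominal concentration refreshes the diffusion-depleted boundary
  layer, so the trace afterwards runs slightly below an uninterrupted
  run (about 1 mJ/m² at 0.44 µM) rather than coinciding with it.
* **Area steps** are instantaneous: $\Gamma \mapsto \Gamma/f$ for an
  area factor $f$ (irreversible layer, coverage inversely proportional
  to area), the drop resphered at $R\sqrt{f}$, and the bulk profile
  carried over preserving depth below the surface (liquid enters and
  leaves at the centre through the capillary). The experimentally
  observed viscoelastic relaxation after a step is deliberately not
  modelled mechanistically — the synthetic-data generator adds it as an
  exponential nuisance transient instead.
* **Master curve.** Area-step experiments are merged into a single
  $\gamma(\Gamma)$ curve by alternating an isotonic (monotone
  non-increasing) regression with per-experiment refits of the scale
  $\alpha_x$ in $\Gamma = \alpha_x/A_r$. The absolute scale is fixed by
  anchoring the curve's departure from $\gamma_0$ at $\Gamma_0$ — a
  package decision, since only relative scales are identifiable from
  overlap. The onset locator crosses the fitted curve at
  $\gamma_0 - 0.75$ mJ/m² and backtracks to the plateau; experiments
  with disjoint tension ranges are rejected as unidentifiable.

## Fitting

`fit_gamma0()` minimises log-time residuals of the series-implied
induction time against measured induction times (log residuals because
the times span orders of magnitude across a concentration ladder), over
the single bounded parameter $\Gamma_0 \in (0, \min_i c_i R/3)$.
`fit_barrier_params()` compares whole simulated $\gamma(t)$ curves to
the data (trapezoid-weighted on each trace's grid) over
$(\log B, q)$, $q \in [0,1]$, with a derivative-free Nelder–Mead search
restarted from three points; features alone (induction time, semistable
value) would leave $(B, q)$ weakly identified, and a single-
concentration data set triggers an explicit warning. Failed candidate
simulations are penalised rather than fatal. A `fix_q` argument
profiles the 1D $B$ direction.

## The synthetic-data generator

The generator is the package's stand-in for instrument data and defines
the conditions under which everything is tested: forward-model traces
plus Gaussian noise (default $\sigma$ = 0.2 mJ/m²) and optional linear
drift; induction-time datasets with multiplicative lognormal noise
(median 1, positivity preserved); and area-step tables with an
exponentially decaying post-contraction overshoot (amplitude 2 mJ/m²,
timescale 100 s) as the viscoelastic nuisance. All generators are pure
functions of (parameters, seed). What passing tests show is therefore
internal consistency — parameter recovery, oracle agreement,
conservation, and the qualitative regime structure — not agreement with
any particular instrument's noise spectrum, drift behaviour, or surface
rheology; those are explicitly not emulated.

## Problem sizes used in validation

The validation suite runs the radial solver at 70–150 cells (surface
cell 1–2 µm), trace output every 10–30 s over 2-hour simulated runs, a
five-point concentration ladder (0.2–5 µM) with and without clustering,
100-seed Monte Carlo studies for the noisy recovery checks, and a
three-trace $(B, q)$ recovery at 0.2/0.44/1.0 µM. Grid-refinement
checks (halving the surface cell) bound the discretisation error of
$\Gamma(t)$ at 0.2%.

## Known limitations

* The equation-of-state family above collapse is an extrapolation; the
  data cannot distinguish pressure saturation from mechanical collapse
  at nearly constant $\Pi$.
* No desorption, surface diffusion, rearrangement kinetics, Marangoni
  convection, evaporation, or drop-shape (Young–Laplace) coupling.
* Cluster size distributions are frozen equilibrium snapshots; no
  association/dissociation kinetics.
* The $n^{1/20}$ barrier scaling is phenomenological (consistent with
  clusters shedding one monomer at a time at the interface, but not
  derived from a mechanism).
* QCM-D support is limited to the Sauerbrey mass conversion at the
  fundamental; overtones and viscoelastic corrections are out of scope.

## A short worked example

```{r example, eval = FALSE}
cfg <- simulation_config(c_bulk_uM = 0.44, t_end_s = 3600, dt_out_s = 10)
trace <- simulate_adsorption(cfg)
extract_induction_time(trace)      # ~190 s at 0.44 uM
extract_semistable_gamma(trace)    # ~57 mJ/m^2

data <- generate_induction_dataset(c(0.15, 0.2, 0.3, 0.44, 0.7, 1.0),
                                   Gamma0_um2 = 24e3, noise_fraction = 0)
fit_gamma0(data)                   # recovers Gamma0 = 24e3
```
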