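---
title: "Modeling centrosome size control: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling centrosome size control: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Before mitosis the two centrosomes of a cell grow many-fold by accumulating
pericentriolar material (PCM) from shared, finite cytoplasmic pools, and
they normally end up the same size. Because both centrosomes draw on the
same pools, any *private* positive feedback — an assembly rate that grows
with a centrosome's own size — lets an initially larger centrosome
outcompete its sibling. `centrosim` implements three quantitative model
families for a centrosome pair and the statistics used to compare them:

* **Autocatalytic growth.** Each centrosome with `n_i` incorporated
  subunits obeys
  `dn_i/dt = (k0+ + k1+ n_i) rho(t) - k- n_i`, with
  `rho = (N - n1 - n2)/Vc` the free subunit concentration. `k0+` is
  centriole activity (size-independent), `k1+` the cooperative,
  size-proportional term. Linearizing about the symmetric steady state
  gives the size-equality condition `2 k0+ + k- Vc > k1+ N`
  (`equality_condition_holds()`): outside it, initial differences are
  amplified.

* **Catalytic growth in a shared enzyme pool.** Assembly itself is
  size-independent (centriole-localized, rates `k+` for inactive and `k*`
  for activated subunits), while the positive feedback runs through a
  *shared* cytoplasmic loop: PCM activates enzyme at rate `kE* Sn [E]`
  (size-proportional), activated enzyme converts free subunits to an
  activated form (`k1* [S1][E*]`), and the activated subunits assemble
  anywhere. Turnover `k- Sn` is distributed. Both pools are limiting:
  `S1 = N - Sn,1 - Sn,2 - S1*` and `E = N_E - E* - S1*` (an activated
  subunit carries one enzyme; incorporation returns it inactive). An
  unlimited-enzyme variant clamps `[E]`. The single-centrosome steady
  state has the closed form implemented in `steady_state_volume()`.

* **Two-scaffold-component growth.** Scaffold former a (Spd-2-like) seeds
  the PCM and activates the enzyme; scaffold former b (Cnn-like) binds in
  an a-dependent intermediate form and is stably incorporated only via the
  activated enzyme; b dominates the mature scaffold. The enzyme is either
  *shared* (released to the cytoplasm after activation and after each
  catalytic cycle) or *localized* (anchored: enzyme captured by a
  centrosome keeps catalyzing only that centrosome).

All three families are expressed as reaction networks over integer
molecule counts and run through the same two engines: an exact Gillespie
direct-method simulation (compiled core) and its deterministic mass-action
twin (`deSolve::lsoda`). Identical `(network, seed)` pairs give
bit-identical stochastic trajectories.

# Units and the count convention

Rate constants are quoted in the field's bulk units (uM^-1 s^-1 for
bimolecular steps, s^-1 otherwise) while the dynamics run on molecule
counts; every bimolecular propensity is normalized by `c * Vc` with `c`
the count factor of the selected `unit_system()`:

* `"avogadro"` (`c = 602.214` molecules per uM per um^3) — physical
  counts. This convention is pinned for deterministic quantities because
  it is the one that reproduces the calibrated behavior of the published
  parameter sets: steady-state volumes land at the few-um^3 scale with
  growth timescales of a few hundred seconds, and the analytic
  size-equality boundary separates the weakly from the strongly
  cooperative example regimes (under `c = 1` the same parameter sets land
  at millicubic-micron sizes and the boundary misclassifies the strongly
  cooperative regime).
* `"unity"` (`c = 1`, i.e. `N = rho0 * Vc` "molecules") — a reduced count
  scale used for stochastic ensemble statistics. Concentration dynamics
  are identical across conventions; only the count scale (and hence the
  relative fluctuation size and simulation cost) changes. The reduced
  scale keeps thousand-run ensembles at desk scale and produces relative
  size fluctuations of the few-percent magnitude that the robustness
  analyses discuss.

Each analysis states its convention; mixed use is intentional and
documented per scenario.

# Fixed parameters

| symbol | meaning | default |
|---|---|---|
| `delta_v` | effective subunit volume | 2e-4 um^3 |
| `V0` | initial centrosome volume | 5e-3 um^3 (25 subunits) |
| `k-` | disassembly rate constant | 5e-3 s^-1 |
| `Vc` | cell volume | 5000 um^3 |

The subunit volume is treated as a fixed constant rather than re-derived
from scaffold-protein mass estimates, whose printed intermediate
arithmetic is not internally consistent; only the final value is used.

# Initial-condition protocols

`initial_counts()` converts `(V0, dV0)` into seed subunit counts under
three protocols: `symmetric_split` (difference split about `V0`; used for
robustness scans), `deficit_on_first` (the higher-activity centrosome
starts smaller; the differential-growth protocol), and `excess_on_first`
(one centrosome larger by the full `dV0`). The third protocol exists
because the robustness-map protocol imposes `dV0 = 0.1 um^3` on seeds of
`V0 = 5e-3 um^3`, which no split-about-`V0` assignment can represent.
Fractional counts round half-to-even and seeds are clamped to >= 1
subunit (a centrosome must exist to grow).

# Stochastic engine

The Gillespie direct method is implemented exactly as the two-variate
scheme: waiting time `tau = log(1/r1) / sum(a_j)`, reaction selection by
first index whose cumulative propensity share exceeds `r2` (half-open
intervals, ties resolved by first index). Propensities of the model
networks all belong to a restricted family `k/div * F1 * F2` with affine
factors, evaluated in compiled code; arbitrary R-function propensities run
on a reference R loop that consumes the identical RNG stream (the two
engines produce identical event sequences and are cross-checked in the
tests). The engine masks any reaction whose firing would drive a species
negative — for well-formed mass-action networks the mask never binds, but
it is what keeps the literal size-independent disassembly variant
(`off_literal = TRUE`, provided for comparison because the stochastic
off-step is sometimes written without the `n_i` factor) inside the
non-negative orthant. Disassembly defaults to the per-subunit form
`k- n_i`, whose mean field recovers the deterministic growth law.

Recording defaults to a uniform 500-interval grid (left-held states) to
bound memory; `every_event` recording is available and is used by the
conservation and determinism tests. Ensembles use consecutive seeds
`base_seed + 0..n-1`.

Two further unit normalizations are isolated in one place each and kept
deliberately simple:

* the enzyme-activation constant `kE*` is tabulated in s^-1 but couples
  PCM size to enzyme concentration bimolecularly; its propensity is
  `kE* * Sn * [E]` with the numeric value read as per-uM per-second
  (equivalently, normalized at the 1 uM reference concentration);
* the two-component incorporation constant `kb1+` is tabulated in
  uM^-1 s^-1 but the step is unimolecular; it is normalized by the same
  1 uM reference to a pseudo-first-order rate.

# Two-component model: resolved design choices

The published reaction topology fixes which species interact but not
every propensity form. The choices here, and why:

* **a-assembly has two channels.** A centriole-anchored, size-independent
  channel `ka+ (s0 c) [A]` (with `s0` in subunit-equivalents of
  1 uM x um^3, about 600 molecular sites at physical counts — a
  centriole-scale number) plus a weak PCM-distributed channel
  `ka1+ [A](Sa_i + Sb_i)` carrying the size-dependent positive feedback.
  A single multiplicative channel `ka+ [A](Sa_i + Sb_i + 1)` was
  implemented first and rejected: the linearized difference dynamics of
  the centrosome pair are then *exactly marginal* (the stabilizing
  turnover term is cancelled structurally by the allocation of b-influx,
  which is proportional to `Sa_i` through every linear route), so the
  shared-enzyme mode never relaxes size differences and the a pool
  depletes completely, compressing the a/b radial-spread ratio. With the
  split channels the shared mode is strictly stable for both tabulated
  scenarios and the a pool remains partially undepleted, which is what
  places the b spread near twice the a spread. `ka1+ = 3e-3 uM^-1 s^-1`
  was fixed once, inside the shared-mode stability region of both
  tabulated parameter rows, and is not scenario-tuned.
* **Localized mode = anchored enzyme.** Activation still consumes the
  shared inactive pool, but the activated enzyme enters a
  centrosome-local pool and each catalytic cycle returns it to that local
  pool (the anchored-kinase picture). The only difference between modes
  is enzyme sharing, keeping the comparison clean. With the tabulated
  rates the localized mode expresses its failure of size control as
  *permanent retention and mild amplification* of initial size
  differences (plus visibly larger stochastic size scatter), not as
  exponential runaway: b-scaffold influx is limited by the strongly
  depleted shared b pool, which caps how fast private feedback can
  compound. The shared mode, by contrast, forgets initial differences
  exponentially. The dichotomy is asserted in exactly that form in the
  tests.
* **Enzyme fate at incorporation (shared mode)** is inactive release,
  forced by the enzyme conservation law, mirroring the single-component
  model; disassembly returns inactive subunits; there is no spontaneous
  E* deactivation. Both scaffold species occupy the same `delta_v`.

# Analysis conventions

* **Hill fits** use `V(t) = A t^alpha / (B^alpha + t^alpha)` with
  deterministic initialization (`A0 = max V`, `B0 =` time of half-max,
  `alpha0 = 2`) and Levenberg-Marquardt least squares; `alpha >= 2` is
  the sigmoidality threshold. `B` (half-rise time) is reported as the
  characteristic growth timescale; the 90%-rise time is also computed
  where a plateau-approach time is wanted.
* **Steady-state readout** is the first time the deterministic twin's
  total volume changes by less than 0.1% per 100 s; stochastic finals are
  read at the same time.
* **Robustness** is summarized by the per-grid-point ensemble mean
  `|V1 - V2| / <V>`, the Pearson correlation (two-sided) between per-run
  initial and signed final differences pooled across the grid, and the
  regression slope of the per-run relative difference on `dV0` with its
  95% CI. No multiple-testing correction is applied: each figure-level
  analysis is a single planned comparison.
* **Activation pulses** are quantified as global maximum (amplitude),
  argmax (peak time) and full width at half maximum (lifetime); a series
  whose maximum sits at a boundary, or which is monotone, counts as "no
  pulse". The FWHM definition is a package choice; the underlying
  timescale claim is qualitative.
* **Asymmetry efficiency** counts the fraction of runs in which the
  higher-activity centrosome (which starts *smaller* under the deficit
  protocol) ends larger; exact ties count one half; a Wilson 95% interval
  accompanies the point estimate.
* **Size scaling** sweeps `Vc` at fixed concentrations (`N = rho0 c Vc`),
  reads the deterministic steady state per cell volume, and reports
  `dV/dVc` (central differences; also in `delta_v` units) next to the
  residual cytoplasmic subunit fraction.
* **Transport estimates** use `D = 30 (30/M)^{1/3}` um^2/s (GFP-anchored
  Stokes-Einstein mass scaling) and `tau_D = L^2 / (6D)`.

# What the scenario registry emulates — and what it does not

`list_scenarios()` enumerates named bindings of model family, rate
constants, pool concentrations, initial protocol and ensemble settings
reproducing the published figure protocols; rates quoted as multiples of
600 uM^-1 s^-1 are stored as (multiplier, base) pairs. Scenario-to-panel
bindings that the source table leaves ambiguous are marked "best guess"
in the provenance strings. The registry defines the *study conditions*:
simulated cells are well-mixed (reaction-limited — justified by the
diffusion-time estimates above), contain exactly two centrosomes, and
conserve their pools exactly. Real centrosomes experience spatial
gradients, cell-cycle-dependent enzyme activity, many additional PCM
clients, and measurement noise; none of these are modeled, so passing
tests here validate the *mechanistic logic* of shared-versus-private
feedback, not quantitative agreement with any particular embryo. Fitting
model parameters to experimental growth curves is deliberately out of
scope; the fitted parameter row is shipped as a named scenario instead.

# Problem sizes and numerical choices

Deterministic integrations use `lsoda` with `rtol = atol = 1e-8` on
500-interval output grids. Stochastic ensemble sizes in the tests and in
the acceptance script are chosen so each check's statistical resolution
comfortably exceeds its assertion: 400-500 runs for mean-field and
robustness comparisons at the reduced count scale, 1000 runs for the
linear-death calibration, 5-8 runs per cell for the 4x4 equality-boundary
map (classification only), and about two dozen runs for
physical-count mean-field checks, where per-run fluctuations are already
far below the tolerance band. The robustness ensembles read finals at the
deterministic readout time (about 1500 s for the headline catalytic
scenario). Root-finding for the self-consistent activated-enzyme
abundance brackets `[0, N_E]` and treats a non-positive balance at zero
as "no activation".

# Known limitations

* The spatially extended (diffusion-coupled) variants are not
  implemented; the models are reaction-limited by construction.
* Tau-leaping is not provided; pools beyond ~10^6 molecules make
  ensembles expensive (single trajectories remain fast).
* The two-component propensity forms beyond the published topology are
  package choices (documented above); alternative resolutions would shift
  quantitative outputs such as the radial-spread ratio.
* The catalytic model's cytosolic activation pulse is not a model of the
  centriolar Polo pulse; the correspondence is qualitative.
* In the two-component model the cytoplasmic activated-enzyme series rises
  and saturates near the total enzyme pool instead of pulsing: with the
  tabulated fast activation rate the enzyme's inactive and complexed
  shares are negligible at steady state, so a transient interior maximum
  cannot occur. The activation pulse is a robust prediction of the
  single-component catalytic model only.
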