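# centrosim

Stochastic and deterministic models of centrosome size control.

Before cell division, the two centrosomes of a cell mature by accumulating
pericentriolar material (PCM) from shared, limiting cytoplasmic pools — and
they normally reach equal sizes, which matters for symmetric spindle
formation. Whether size equality is robust depends on where the positive
feedback in PCM assembly lives. `centrosim` implements and compares three
growth mechanisms for a centrosome pair:

* **autocatalytic** — per-centrosome feedback,
  `dn_i/dt = (k0+ + k1+ n_i) rho - k- n_i` with a shared free-subunit
  concentration `rho = (N - n1 - n2)/Vc`; equality holds only inside the
  analytic region `2 k0+ + k- Vc > k1+ N`;
* **catalytic, shared enzyme pool** — centriole-localized assembly of
  inactive (`k+`) and enzyme-activated (`k*`) subunits, size-proportional
  enzyme activation `kE* Sn [E]`, cytoplasmic subunit activation
  `k1* [S1][E*]`, distributed turnover `k- Sn`; the feedback is shared, so
  pairs equalize robustly while growing sigmoidally;
* **two scaffold components** (Spd-2-like a, Cnn-like b, Polo-like enzyme
  E) with shared versus centrosome-anchored ("localized") enzyme — the
  mechanistic test of why enzyme sharing matters.

Every model runs both as an exact Gillespie (direct-method) simulation over
integer molecule counts and as its deterministic mass-action twin, with
exact pool conservation, reproducible seeding, and a registry of named
parameter scenarios (`list_scenarios()`) reproducing the published figure
protocols. Analysis tools cover Hill-coefficient cooperativity of growth
curves, robustness of size equality to initial differences, differential
centriole-activity efficiency, centrosome-size scaling with cell volume,
and Stokes-Einstein transport estimates.

## Worked example

Grow a catalytic centrosome pair from a 10% initial size difference and
check that the pair forgets it:

```r
library(centrosim)

sc  <- load_scenario("fig3c")          # published catalytic parameter row
net <- scenario_network(sc, dV0 = 0.1 * sc$initial$V0)
tr  <- simulate_ssa(net, t_max = 3000, seed = 1)
ode <- simulate_ode(net, t_max = 3000)

tail(as.data.frame(ode), 1)[, c("time", "V1", "V2")]
#>     time     V1     V2
#> 501 3000 3.9929 3.9929

fit_hill(ode$times, as.data.frame(ode)$V1)
#> <hill_fit: A = 4.002 um^3, B = 449.9 s, alpha = 4.08 (sigmoidal)>

pulse_metrics(ode, "Es")$peak_time    # early activation pulse (s)
#> [1] 318
```

Each centrosome plateaus near 4 um^3 — the deterministic pair forgets the
imposed initial difference entirely — the growth curve is sigmoidal (Hill
coefficient alpha about 4, half-rise time about 450 s), and the
cytoplasmic activated-enzyme series shows the characteristic transient
pulse at growth onset. The same network run with
`autocatalytic_params(600, 0.6, rho0 = 0.033)` instead amplifies the
initial difference (`equality_condition_holds()` returns `FALSE` for that
parameter set).

A thin command-line front end is included at `inst/cli/centrosim`
(`centrosim list-scenarios`, `centrosim simulate --scenario fig3c ...`).

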