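---
title: "A two-reserve Dynamic Energy Budget model of bacterial batch growth"
author: "debatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-reserve Dynamic Energy Budget model of bacterial batch growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(debatch)
```

## The model

`debatch` describes a bacterial population in a stirred batch reactor as a
single V1-morph organism: surface area stays proportional to volume as the
culture grows by division, so all specific rates are size-independent.
Biomass is split into one **structure** (fixed composition
CH~1.96~O~0.45~N~0.22~, maintained at a cost) and two **reserves** with no
maintenance cost of their own: a carbon reserve fed by glucose and a
nitrogen reserve fed by ammonium, reflecting the essentially independent C
and N assimilation pathways of enteric bacteria.  Reserve amounts are
carried as densities $m_{E_i}$ (C-mol or mol per C-mol of structure); under
the strong-homeostasis assumption every composition change of total biomass
is a change of these two densities.

Per C-mol of structure, with $i \in \{C, N\}$:

* **Assimilation** $j_{E_iA} = j_{E_iAm}\, S_i/(K_i + S_i)$, shut off when
  $S_i \le 0$.  The half-saturation constants are fixed at $10^{-6}$
  mol/L, far below working concentrations, so uptake runs at its maximum
  until a substrate is nearly gone.
* **Mobilization** $j_{E_iC} = m_{E_i}(\dot k_E - \dot r)$ — first-order
  turnover of the reserve, corrected for growth dilution.
* **Maintenance** $j_{E_iM}$ is paid from mobilization with priority;
  the remainder $j_{E_iG} = j_{E_iC} - j_{E_iM}$ is offered to growth.
* **Synthesizing unit.** The two growth fluxes are complementary: with
  scaled inputs $a = j_{E_CG}/y_{E_CV}$ and $b = j_{E_NG}/y_{E_NV}$,

  $$j_G = \left[\,j_P^{-1} + a^{-1} + b^{-1} - (a+b)^{-1}\right]^{-1},$$

  and the $j_P^{-1}$ product term is dropped in the default configuration
  (product formation much faster than reserve delivery).  The SU output
  is strictly below $\min(a, b)$ and vanishes if either input does:
  structure needs both elements.
* **Rejection.** The flux each reserve offered but the SU could not use,
  $j_{E_iR} = j_{E_iG} - y_{E_iV} j_G$, is recycled to its reserve with
  fraction $\kappa_{E_i} = 0.9$; of the excreted remainder a fraction
  $\kappa_{S_i} = 1$ reappears in the medium as substrate.
* **Switch-model maintenance.** Maintenance not covered by mobilization
  could in principle be paid from structure,
  $j_{VM_i} = (j_{E_iM} - \min(j_{E_iC}, j_{E_iM}))/y_{E_iV}$.  The
  package computes and reports this flux but never feeds it into the
  dynamics ($j_{VM} = 0$): instead, the culture **dies** at the first
  instant either reserve's mobilization falls below its maintenance
  demand, after which every flux is zero and the state is frozen —
  consistent with intact, assayable, but inactive cells.

The growth rate is implicit: mobilization needs $\dot r$ while
$\dot r = j_G$ is built from mobilization.  $g(r) - r$ is strictly
decreasing on $[0, \dot k_E]$ with $g(\dot k_E) = 0$, so the fixed point
is unique; both the R reference implementation and the compiled
right-hand side solve it by bracketed bisection to $10^{-14}\dot k_E$ at
every evaluation.

Mass balances (volume $V$, structural mass $M_V$):

$$\frac{dS_i}{dt} = \left[-j_{E_iA} + \kappa_{S_i}(1-\kappa_{E_i})\,j_{E_iR}\right] y_{SE_i}\frac{M_V}{V} \;\left(+\tfrac{\dot J_{NH_3}}{V}\ \text{for } S_N\right)$$
$$\frac{dm_{E_i}}{dt} = j_{E_iA} - j_{E_iC} + \kappa_{E_i} j_{E_iR} - \dot r\, m_{E_i},
\qquad \frac{dM_V}{dt} = \dot r\, M_V$$

Ammonia is also a metabolite: the overheads of N assimilation
($y_{SE_N}-1$ per unit assimilated), of growth ($y_{E_NV}-n_{NV}$ per
unit structure) and the maintenance-consumed N are excreted, and
`nh3_closure_flux()` collects exactly these terms.  Two cumulative
dissipation pools absorb every other element flow, so along any
trajectory total carbon and total nitrogen are conserved to the
integration tolerance (the tests require $10^{-6}$ relative; typical
values are $10^{-9}$).

One bookkeeping subtlety is inherited from the model topology: the
excreted part of a rejected flux is converted back to substrate at the
substrate-to-reserve yield $y_{SE_i} > 1$, i.e. slightly more substrate
reappears than reserve was discarded.  The dissipation pools close the
balance exactly either way (the corresponding closure term is negative);
with $\kappa_{E} = 0.9$ the term is small, and it vanishes for
$\kappa_E = 1$.

### Death, exhaustion and integration

The equations are integrated with `deSolve::lsodar` (stiff-capable,
adaptive) with the right-hand side compiled in C, relative tolerance
$10^{-8}$ and absolute tolerance $10^{-12}$.  Substrate exhaustion needs
no event handling of its own: the Monod factor takes assimilation to
zero smoothly as $S_i \to 0$ (the corner at $S_i \sim K_i = 10^{-6}$ is
merely stiff), and a clamp guards round-off excursions below zero.  The
death condition *is* a root event: $\min_i (j_{E_iC} - j_{E_iM})$
crossing zero from above stops the integrator at the crossing, the
remaining sampling grid is filled with the frozen state, and the death
time is reported as a trajectory attribute.  A state that cannot pay
maintenance at $t = 0$ is dead from the start.

### The Monod baseline

For comparison, the classical unstructured model is included with the
same scenario interface: $\mu = \mu_{max}\,\frac{S_C}{K_C+S_C}\frac{S_N}{K_N+S_N}$,
$dX/dt = \mu X$, $dS_i/dt = -\mu X / Y_{XS_i}$, with constant yields.
Growth simply stalls as a substrate runs out; there are no reserves, no
composition dynamics and no death event.  Its yield identities
($\Delta X = Y_{XS_C}\Delta S_C = Y_{XS_N}\Delta S_N$) hold to
$10^{-8}$ and serve as an integration oracle.

## Parameters

Defaults are the calibrated values for aerobic *E. coli* on glucose and
ammonium (rates per hour, amounts per C-mol of structure):

| symbol | meaning | default | unit |
|---|---|---|---|
| `jEcAm` | max C assimilation | 1.7396 | C-mol C-mol^-1^ h^-1^ |
| `jEnAm` | max N assimilation | 0.2405 | mol C-mol^-1^ h^-1^ |
| `KC`, `KN` | half-saturation | 1e-6 | (C-)mol L^-1^ |
| `kE` | reserve turnover | 5.3 | h^-1^ |
| `jEcM`, `jEnM` | maintenance from C / N reserve | 0.6104 / 0.0010 | as assimilation |
| `yEcV`, `yEnV` | reserve → structure yield | 1.1 / 0.23 | — |
| `ySEc`, `ySEn` | substrate → reserve yield | 1.1 / 1.05 | — |
| `kappaEc`, `kappaEn` | rejected flux recycled | 0.9 | — |
| `kappaSc`, `kappaSn` | excretion returned as substrate | 1 | — |
| Monod: `mu_max`; `YXSC`, `YXSN` | max growth rate; yields | 0.51; 0.45, 4.74 | h^-1^; — |

The yields exceed the corresponding elemental indices of structure (1
for C, 0.22 for N), so every synthesis step dissipates a non-negative
element overhead — this is enforced at construction.

## The scenario library and its calibration choices

`limitation_scenarios()` encodes the six-flask limitation design the
package emulates, plus the pre-culture for the shock-transfer
experiment: carbon limitation at glucose 1, 2, 3 g/L (25–75 % of the
basic 4 g/L) with ammonium chloride at 150 % of basic, and nitrogen
limitation at NH~4~Cl 0.075, 0.125, 0.25 g/L (15–50 % of basic) with
glucose raised 50 % to 6 g/L; hourly sampling in triplicate over 12 h;
the basic-medium pre-culture (4 g/L glucose, 0.5 g/L NH~4~Cl) runs 4 h
with 30-minute sampling.  Internal consistency of the design fixes the
basic ammonium chloride concentration at 0.5 g/L — the percentage
specifications of the nitrogen-limited media and the 0.75 g/L of the
carbon-limited composition assay only agree on that value, and with the
calibrated yields a lower value would silently turn the "carbon-limited"
media nitrogen-limited.

Three quantities the design does not print had to be chosen once:

* **Initial reserve densities.** Inocula come from exponential
  pre-cultures, so reserves start at their balanced-growth values —
  the joint steady state of both reserve balances including rejected-flux
  recycling, solved by `balanced_reserves()` (for a reserve whose
  rejected flux vanishes this reduces to the textbook closed form
  $m_{E_i}^* = j_{E_iAm}/\dot k_E$; with both reserves active the
  recycling raises the densities above that value, e.g. $m_{E_C}^* =
  0.370$ vs $1.7396/5.3 = 0.328$).  Scenario definitions may override.
* **Inoculum size.** The observed arrest window pins it: with total
  inoculum biomass $4\times10^{-5}$ C-mol/L ($\approx$ 1.2 mg/L dry
  mass, a plausible 1:100 transfer of an exponential pre-culture) the
  three carbon-limited cultures arrest at 8.4, 9.3 and 9.8 h — inside
  the observed 8–10 h window and ordered by initial glucose.
* **Assay noise.** The synthetic-observation generator draws
  truncated-Gaussian replicates with CVs of 5 % (optical-density-derived
  biomass), 3 % (enzymatic glucose) and 5 % (colorimetric ammonium),
  plus small additive floors near the assays' detection limits
  (~0.6 mg/L biomass, ~0.01 g/L glucose, ~0.5 mg/L NH~4~Cl).  No
  measurement-error magnitudes are printed anywhere; these affect test
  tolerances only, never the model itself.

## What a simulation shows

```{r c-limitation}
p <- deb_params()
scns <- limitation_scenarios()
tr <- deb_simulate(p, scenario = scns$C1)
attr(tr, "death_time")
tail(composition_trajectory(tr)[c("time_h", "C_pct", "N_pct", "mEc", "mEn")], 3)
```

Under carbon limitation, glucose exhausts first; the C reserve then
drains with time constant $1/\dot k_E \approx 11$ min until it cannot
cover maintenance and the culture dies — "growth stops when the glucose
is used up", about 0.2 h after exhaustion.  Meanwhile the nitrogen
reserve keeps filling, so the nitrogen mass fraction of total biomass
*rises* toward stationary phase; the converse happens under nitrogen
limitation.  The simulated shift (9.6 % → 12.6 % N with the default
carbohydrate-like CH~2~O and ammonia-like NH~3~ reserve formulas) is
directionally the measured one but larger in magnitude: the measured
shift is about 10.6 % → 11.2 %, and the exact reserve formulas behind
those measurements are not public, so the composition bookkeeping should
be read as mechanistic, not assay-calibrated.

In the shock-limitation experiment the pre-culture is transferred to a
glucose-free medium: the C reserve is spent in minutes,

```{r shock}
sh <- shock_experiment(p, remove = "C")
60 * sh$death_after_transfer  # minutes to the death condition
```

and biomass and the remaining substrate stay constant for the rest of
the 6.5 h observation window.  The ammonium-free transfer behaves
asymmetrically.  The N reserve drains fast — 88 % gone at 30 min, ~99 %
at 1 h — but not at pure turnover speed, because carbon is still the
SU-limiting input at first, so the N reserve is rejected and 90 %
recycled.  The growth rate collapses from 0.75 to 0.015 h^-1^ within the
first hour; the residual density then creeps down toward the maintenance
threshold $j_{E_NM}/\dot k_E = 1.9\times10^{-4}$, and the *formal* death
crossing $j_{E_NC} < j_{E_NM}$ fires only around 5.3 h, the N
maintenance demand being ~600-fold smaller than the C one.  One
consequence of taking the recycling topology literally
($\kappa_{S_N} = 1$: excreted reserve N reappears as ammonium) is that
the model builds roughly 3× more structure in the first post-transfer
hour from recycled reserve nitrogen, whereas the experiment saw no
biomass change after the transfer — a genuine tension between this
model topology and the shock data, and a reason the recycling fractions
deserve scrutiny if such experiments are to be fitted.

## Parameter estimation

`deb_fit()` fits either model simultaneously to all scenarios by
weighted nonlinear least squares.  The loss is the weighted sum of
squared errors: per scenario and variable, the squared deviations
between the simulated curve at the observation times and the replicate
means, weighted by the reciprocal of the mean replicate variance
(`compute_weights()`); a config switch fits individual replicates
instead.  Free parameters default to the two maximum assimilation rates
and the two maintenance coefficients (DEB), or the maximum growth rate
and both yields (Monod); half-saturation constants stay fixed, and the
reserve turnover rate is either fixed or pre-estimated per limitation
group and fixed at the mean of the two (`kE_mode = "two_stage"`).

Minimization runs in log-parameter space (positivity without bounds)
with the Nelder–Mead simplex, restarted once at its own optimum, and
simulation failures at a trial point map to `+Inf` rather than raising —
a simplex tolerates infinite vertices, which keeps the search alive near
death-event discontinuities.  A Levenberg–Marquardt engine
(`method = "lm"`, via minpack.lm on the $\sqrt{w}$-scaled residual
vector, finite-difference step $10^{-3}$ in log space) is offered as a
faster alternative; it is markedly better conditioned on the smooth part
of the problem.

Identifiability is not uniform.  On noiseless synthetic data the
assimilation rates and the C maintenance coefficient recover to well
under 1 % from a 2× starting error, and to a few percent under 5 % CV
triplicate noise.  The N maintenance coefficient `jEnM` does not: its
entire signature in hourly batch data is at the $10^{-3}$ relative level
of the other parameters' effects and is compensated almost exactly by
~0.1 % shifts of the assimilation rates, so its loss valley is flat over
decades (and kinked where the death event crosses a sampling time).  No
standard optimizer pins it from a 2× start, and the package reports it
as estimated-but-unreliable rather than pretending otherwise — a
maintenance flux this small is simply below the resolution of the
experimental design, which is consistent with the suspiciously round
published value.

Goodness of fit is reported as a pooled adjusted $R^2$ and RMSE on the
weighted scale (all variables and scenarios in one residual vector —
one number per model), plus per-variable $R^2$ diagnostics.  The
pooling convention is a package choice; published single-number
$R^2_{adj}$ values from other conventions are not comparable.

Nonsimultaneous 95 % prediction bands are pointwise t-intervals, fitted
curve ± $t_{0.975,\,n-k} \cdot s_{pred}$, with $s_{pred}$ the
per-variable pooled residual SD scaled back to single-observation units
when the fit used replicate means.  Parameter uncertainty is not
propagated, and the band is constant-width within a variable: under
strictly proportional noise it over-covers small values and
under-covers large ones (empirically ~82 % average coverage), while
under additive noise it covers at the nominal rate — the coverage test
uses the latter regime deliberately.

## What the synthetic generator does and does not emulate

The generator reproduces the design's structure — six media, hourly
triplicates, a transferred pre-culture — and a plausible noise model.
It does not emulate OD-to-biomass calibration error, instrument drift,
plate effects, sampling-volume depletion, or any model-misspecification
gap between a real culture and the DEB equations.  Green recovery tests
therefore demonstrate that the pipeline is self-consistent and that the
data carry enough information for the identifiable parameters; they do
not certify the model against real cultures.

## Numerical choices, in one place

* ODE: `lsodar`, rtol $10^{-8}$, atol $10^{-12}$; death located by root
  finding; post-death state frozen exactly.
* Growth-rate fixed point: bisection on $[0, \dot k_E]$, tolerance
  $10^{-14}\dot k_E$; mobilization floored at zero (the fixed point
  cannot exceed $\dot k_E$).
* Balanced reserves: per-reserve steady densities are closed-form in
  $r$; the scalar consistency equation is solved by `uniroot` to
  $10^{-12}$.
* Fitting: log-space; Nelder–Mead maxit 2000, reltol $10^{-10}$, one
  restart; LM ftol $10^{-15}$, ptol $10^{-12}$, epsfcn $10^{-6}$.
  Monte-Carlo recovery studies in the tests use 20 seeds at the default
  noise model; the interval-coverage study uses 25 seeds on the Monod
  model (sub-second fits) — sizes chosen to keep the default suite
  comfortably reproducible on a laptop.
* Units: molar internally (C-mol, mol, h, L); grams only at the
  scenario/report boundary (glucose 30.026 g/C-mol, NH~4~Cl 53.491
  g/mol, structure 29.76, whole biomass 30.00 — the latter two measured
  values exceed their CHON-computed masses because of residual S/ash,
  and the measured values are used wherever mass matters).

## Known limitations

* Structure is never mobilized ("shrinking" is off, $j_{VM} = 0$);
  maturation and reproduction machinery are absent by design.
* The composition targets are mechanistic, not assay-calibrated (reserve
  formulas are package defaults; see above).
* `jEnM` is reported but effectively unidentifiable from this design.
* Two reserves, one structure, batch only; no pH/O~2~/temperature
  effects; the transfer event is the only feed-like operation.
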