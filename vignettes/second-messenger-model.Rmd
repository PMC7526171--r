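---
title: "Modelling cdG and (p)ppGpp coupling to the nitrogen PTS in Caulobacter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cdG and (p)ppGpp coupling to the nitrogen PTS in Caulobacter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdgpp)
```

## The biological problem

*Caulobacter crescentus* runs a fixed developmental program: a motile
swarmer cell differentiates into a sessile stalked cell before replicating,
on a roughly 150-min cycle. Two guanine-based second messengers gate this
program antagonistically. A pulse of cyclic di-GMP (cdG) at the
swarmer-to-stalked transition licenses proteolysis of the master regulator
CtrA and entry into S phase; the alarmone (p)ppGpp accumulates under
starvation and arrests the cycle. Both are drawn from the same guanine
nucleotide pool, so the cell's nutrient state — sensed as intracellular
glutamine by the nitrogen phosphotransferase system (PTS^Ntr^) — propagates
through SpoT into every pool at once. This package implements that coupling
as a quantitative, testable dynamical model.

## Model structure and assumptions

The state has seven variables, all in µM: cdG, GTP, (p)ppGpp, GMP,
EI∼P~tot~, NPr∼P and EIIA∼P. The main simplifications, each inherited from
the biology:

* **Lumped nucleotide pools.** GTP and GDP interconvert rapidly and their
  SpoT products (pppGpp, ppGpp) behave alike, so each pair is one variable.
* **cdG enzymology.** Diguanylate cyclases (DgcB, PleD) are dimers whose
  I-site binds two cdG molecules; product inhibition is therefore a Hill
  function with exponent 2. Phosphodiesterase output is counted directly as
  2 GMP — the pGpG intermediate is assumed to hydrolyse fast and is not
  modelled. PDE activity is treated as substrate-saturated in GTP, and the
  reported (p)ppGpp inhibition of GMP salvage enzymes is ignored.
* **SpoT partition.** SpoT is bifunctional. NPr∼P activates synthesis
  (indirectly) and EIIA∼P inhibits hydrolysis, folded into one
  synthetase:hydrolase ratio
  $\alpha = K_\mathrm{SpoT}\frac{[\mathrm{NPr\sim P}]}{[\mathrm{NPr\sim P}]+K_2}
  \cdot \frac{[\mathrm{EIIA\sim P}]+K_3}{K_3}$.
* **Relay kinetics.** PEP/pyruvate binding to EI is far faster than
  phosphotransfer, so the EI·PEP and EI∼P·Pyr complexes are algebraic
  functions of the totals (`partition_EI()`). Both EI and EI·PEP accept the
  phosphoryl group back from NPr∼P. Forward and back rate constants of the
  two transfer steps are equal (one constant per step). There is no
  terminal phosphate sink beyond EIIA∼P. Enzyme totals (EI 10, NPr 30,
  EIIA 30 µM) are constant.
* **Conservation.** The nutrient signals exchange phosphoryl groups only,
  so total guanine $2[\mathrm{cdG}]+[\mathrm{GTP}]+[\mathrm{GMP}]+
  [\mathrm{(p)ppGpp}]$ is exactly conserved — 1420.6 µM with the standard
  initial condition. This is the model's sharpest internal check and is
  enforced at run time.

Glutamine enters once, scaling EI autophosphorylation by
$(K_4+\varepsilon[\mathrm{Gln}])/(K_4+[\mathrm{Gln}])$: a smooth decrease
from 1 to the residual floor $\varepsilon = 0.1$, half-way at
$K_4 = 75.63$ µM.

## Parameters that matter

All defaults are returned by `default_params()` (µM and minutes). The ones
worth knowing when exploring:

* `k_s_cdG = 33.5`/min, `k_d_cdG = 100`/min, `K1 = 0.5` µM, `Km2 = 0.06` µM
  — set the height and sharpness of the cdG pulse.
* `k_s_ppGpp = 170`, `k_d_ppGpp = 160` µM/min with `Km3 = 1000`,
  `Km4 = 2000` µM — the SpoT tug-of-war; the steady (p)ppGpp:GTP ratio
  moves from ~0.1 (rich) to ~2.1 (starved) across the glutamine range.
* `K_SpoT = 4`, `K2 = 75`, `K3 = 10` µM — how strongly relay
  phosphorylation tips SpoT.
* `Kd1 = 350`, `Kd2 = 670` µM — the PEP/Pyr binding steps that make relay
  phosphorylation a nonlinear function of the PEP:Pyr ratio.

The phosphotransfer constants (`k2 = 1.2e4`, `k3 = 3.7e3` /(min·µM)) are
three to four orders faster than the nucleotide rates. That rate separation
is what makes the system stiff, and also why the relay is effectively
slaved to the signals: it equilibrates within milliseconds of simulated
time.

## Enzyme abundance forcing and the fitting utility

Total DGC is constant DgcB (0.7) plus the PleD time course; total PDE is a
basal level (0.2) plus the PdeA course. Both courses are sinusoids with
shared angular frequency $\pi/75$ rad/min (150-min period, $t=0$ at swarmer
birth):

* PleD: $0.1834\,\sin(\pi t/75 + 0.5587) + 0.7579$ (`pled_profile()`);
* PdeA: $-0.3605\,\sin(\pi t/75 + 0.1767) + 0.361$ (`pdea_profile()`).

These printed functions are used directly by the simulations;
`fit_sinusoid()` is a utility for re-deriving such curves from abundance
points, not a pipeline dependency — the underlying measurements are
digitized western/immunoblots that are not tabulated anywhere. Design
choices in the fitter:

* The frequency is **fixed at $\pi/75$ by default**. With ≤ 9 points per
  course a free frequency is poorly identifiable; fixing it makes the
  problem linear in $(A\sin\phi, A\cos\phi, c)$ and exactly solvable by
  least squares. A free-frequency mode (Levenberg–Marquardt, initialized at
  $\pi/75$) exists for denser data.
* Fits are canonicalized to $A \ge 0$, $\phi \in [0, 2\pi)$ using
  $A\sin x = -A\sin(x+\pi)$.
* **Outlier handling is manual.** The PleD course has one time point widely
  judged aberrant on biological grounds (the pulse must precede the G1→S
  transition); that is a curation judgment, so the fitter exposes a `mask`
  argument instead of automating rejection. `pled_profile(refit = FALSE)`
  keeps the all-points fit for comparison.

`synth_profile_points()` generates the fixtures for testing the fitter:
evenly spaced samples over one period plus i.i.d. Gaussian noise, seeded
and RNG-restoring. It emulates blot quantification noise only — it does not
emulate the uneven sampling, baseline drift or censoring of real blot
series, so a passing recovery test says the estimator is correct, not that
real courses are this clean.

## Numerics

* **Integration**: `deSolve::ode(method = "lsoda")` with `rtol = 1e-8`,
  `atol = 1e-10` µM. The tolerances are sized to the conservation budget:
  total guanine must drift < 1e-4 relative over any run (it typically stays
  below 1e-10), and `integrate_model()` errors if it does not. Schedules
  restart the solver at every breakpoint so signal steps are never smoothed;
  a breakpoint row in the output belongs to the incoming segment.
* **Steady states** (`steady_state()`): settle by integration until
  $\max_i |\dot x_i|/(|x_i| + 1\,\mu M) < 10^{-9}$/min, then polish with a
  damped Newton iteration in which the GMP equation is replaced by the
  guanine-conservation constraint. The substitution removes the Jacobian's
  conserved null direction, and anchoring the constraint to the *initial*
  total (conservation is exact in the continuous system) keeps accumulated
  solver drift out of the answer.
* **Closed-form oracle** (`equilibrium_state()`): the relay steady state
  has one shared phosphorylated:unphosphorylated ratio
  $r = k_1\,\mathrm{gf}\,f_\mathrm{PEP}/(k_{-1} f_\mathrm{Pyr})$ because
  the transfer steps are symmetric; the nucleotide balance is a bracketed
  1-D root in GTP. One subtlety: at the fixed point cdG turns over at
  $v_\mathrm{cdG} \approx 19$ µM/min, a steady GTP → cdG → GMP cycle, so
  the GMP balance is $[\mathrm{GMP}] = (k_\mathrm{d.GTP}[\mathrm{GTP}] +
  2v_\mathrm{cdG})/k_\mathrm{s.GTP}$ — without the cycle term the "oracle"
  misses the true fixed point by ~3·10⁻⁴ relative. cdG's small contribution
  to the guanine balance is handled by two fixed-point refinement passes
  (cdG = 0 solve → cdG root → re-solve); remaining error is below 1e-8.
  Oracle and integrator agree to ~1e-10 relative across randomized signals.
* **Degenerate inputs**: `Pyr = 0` leaves no dephosphorylation route and is
  returned as the fully phosphorylated limit; `PEP = Pyr = 0` makes the
  relay level undetermined (error); a pure-synthetase SpoT split has no
  finite (p)ppGpp equilibrium (error). State validation tolerates
  excursions above −10⁻⁸ µM (clipped as solver round-off) and rejects
  anything worse.

## Design decisions in open territory

* **Condition-table convention.** The non-cdG pools vary by well under 1%
  over the forcing cycle, so the nutrient-grid tables report
  constant-enzyme steady states at the cycle-mean DGC (0.7 + 0.7579) and
  PDE (0.2 + 0.361) levels; only the cdG range row uses the oscillating
  profiles. Either convention matches at the 2–3 printed digits.
* **cdG ranges** are extracted from the final 150-min window after a
  600-min (four-cycle) transient; ranges are insensitive (±1 in the last
  digit) to halving tolerances or output resolution.
* **Calibration glutamine.** The PTS calibration against carbon-PTS
  titration data (PEP = 160 µM, Pyr = 48.5 µM) reproduces the published
  simulation column only with the glutamine factor at its nutrient-rich
  floor (~0.107, i.e. Gln = 10000 µM), although the accompanying text
  describes setting glutamine to zero — with gf = 1 the predicted sums are
  ~2.8-fold larger and the Pyr estimate is no longer self-consistent.
  `pts_phospho_sum()` therefore defaults to `Gln = 10000` and exposes the
  level as an argument.
* **Carbon-limited preset.** "Limited glutamine" is a 1000–2000 µM band;
  the preset pins 1000 µM (the emphasised grid column) and the value is a
  plain argument everywhere.
* **Initial cdG** (0.3 µM) slightly exceeds the oscillation peak (0.28);
  it is treated as a legitimate transient start, not clamped.

## Problem sizes

The bundled tests and the acceptance script run entirely at desk scale:
steady states converge in well under a second; each oscillation range is a
single 750-min stiff integration (~1 s); the full 12-condition grid with
ranges takes under half a minute; the oracle-equivalence property uses 50
randomized signals. The full suite completes in about twenty seconds on one
CPU.

## Limitations

The model stops at the second-messenger pools: no CtrA/DnaA targets, no
division event or cell-cycle phase map (the 150-min forcing is imposed, not
emergent), no carbon-PTS cross-talk, no pGpG, and the enzyme profiles stand
in for *active* PleD with *total* PleD abundance. Steady-state uniqueness
holds in every regime explored here but is assumed, not proven — there is
no continuation analysis.
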