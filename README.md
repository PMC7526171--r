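# cdgpp

Kinetic simulator of the guanine-nucleotide second-messenger network of
*Caulobacter crescentus*, coupling cyclic di-GMP (cdG) and the alarmone
(p)ppGpp to nutrient status through the nitrogen phosphotransferase system
(PTS<sup>Ntr</sup>).

*C. crescentus* divides asymmetrically on a ~150-min cycle, and the
swarmer-to-stalked (G1→S) transition is driven by a cdG pulse, while
(p)ppGpp accumulation under starvation arrests the cycle. Both messengers
are made from the same GTP pool, so nutrient signals that shift SpoT between
its (p)ppGpp-synthetase and hydrolase activities also reshape the GTP and
cdG pools. The package is for systems biologists who want to simulate,
perturb and extend this coupling quantitatively.

## The model

Seven stiff ODEs over state (cdG, GTP, (p)ppGpp, GMP, EI∼P<sub>tot</sub>,
NPr∼P, EIIA∼P), all in µM, time in minutes:

- **cdG**: synthesis `k_s·[DGC]·K₁²/(K₁²+cdG²)·GTP²/(GTP²+K_m1²)`
  (diguanylate cyclases are product-inhibited at the I-site with Hill
  exponent 2 and consume 2 GTP) minus phosphodiesterase degradation
  `k_d·[PDE]·cdG/(cdG+K_m2)`, which yields 2 GMP.
- **(p)ppGpp**: SpoT synthetase/hydrolase fluxes, Michaelis–Menten in GTP
  and (p)ppGpp, weighted by the partition
  `α = K_SpoT · NPr∼P/(NPr∼P+K₂) · (EIIA∼P+K₃)/K₃`,
  synthetase fraction `α/(1+α)`.
- **GTP/GMP**: first-order interconversion plus the fluxes above; the total
  guanine `2·cdG + GTP + GMP + (p)ppGpp` is exactly conserved.
- **PTS<sup>Ntr</sup> relay**: PEP-driven EI autophosphorylation, inhibited
  by glutamine via `(K₄+ε·Gln)/(K₄+Gln)`, reversible transfer
  EI∼P → NPr → EIIA<sup>Ntr</sup>, with fast PEP/pyruvate binding resolved
  algebraically (quasi-steady state).

Total DGC = DgcB + PleD(t) and total PDE = basal + PdeA(t), where PleD and
PdeA follow 150-min sinusoids fitted to immunoblot time courses; that
periodic forcing produces the cell-cycle cdG oscillation.

A closed-form steady-state solution (common phosphorelay ratio
`r = k₁·gf·fPEP/(k₋₁·fPyr)`, plus a 1-D root for the nucleotide balance)
is implemented independently of the integrator and used as its oracle.

## Worked example

```r
library(cdgpp)

# steady state under "ammonia with high carbon"
eq <- equilibrium_state(nutrient_signal(Gln = 10000, PEP = 300, Pyr = 1500))
round(eq, 3)
#>      cdG      GTP    ppGpp      GMP  EIP_tot     NPrP    EIIAP
#>    0.032 1220.908  118.209   81.420    0.527    1.580    1.580

# cdG oscillation over one settled cell cycle with periodic DGC/PDE forcing
rng <- periodic_range("cdG", nutrient_signal(10000, 300, 1500))
sprintf("cdG range over one settled cycle: [%.3f, %.3f] uM", rng$min, rng$max)
#> "cdG range over one settled cycle: [0.014, 0.281] uM"
```

Under rich conditions GTP sits near 1221 µM with a (p)ppGpp:GTP ratio of
about 0.1, and cdG pulses to ~0.28 µM at the G1→S transition. Dropping
glutamine to 1 µM (nitrogen starvation) drives the relay to high
phosphorylation, tips SpoT toward synthesis, and collapses the cdG pulse to
~0.02 µM — cell-cycle arrest. `run_nutrient_grid()`,
`run_pts_calibration()`, `run_cell_cycle()` and `run_nitrogen_shift()`
reproduce the full condition tables and shift protocols; a command-line
front end lives at `inst/scripts/cdgpp-cli.R`.

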