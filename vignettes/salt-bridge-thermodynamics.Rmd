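---
title: "Activation thermodynamics of an active-site salt-bridge: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activation thermodynamics of an active-site salt-bridge: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acptherm)
```

## The scientific problem

Thermophilic enzymes are usually less active than their mesophilic
homologues at low temperature. One mechanistic proposal is that extra
stabilizing interactions rigidify the active site: pinning a catalytic
residue costs nothing at the transition state (where it must be ordered
anyway) but removes conformational freedom from the ground state, so the
activation entropy becomes *less negative*. The price is a compensating
increase in activation enthalpy, which steepens the temperature dependence
of $k_{cat}$ — favouring activity at high temperature and penalizing it at
low temperature.

Acylphosphatases are a clean model system: their invariant active-site
arginine forms a salt-bridge with the C-terminal carboxylate in
thermophilic family members only. The bridge can be removed from the
thermophilic enzyme (PhWT to PhG91A) and installed in the mesophilic
homologue (HuA99/HuWT to HuG99), giving matched with/without pairs.
`acptherm` implements the full quantitative chain for this analysis:
kinetics, transition-state decomposition, binding calorimetry, equilibrium
stability, and side-chain flexibility statistics, plus generators that
produce synthetic versions of every input with known ground truth.

## Transition-state decomposition

With a transmission coefficient of 1, transition-state theory links a
turnover number to an activation free energy,

$$\Delta G^\# = RT\left(\ln\frac{k_B T}{h} - \ln k_{cat}\right),
\qquad \Delta H^\# = E_a - RT, \qquad T\Delta S^\# = \Delta H^\# - \Delta G^\#,$$

where $E_a$ is the Arrhenius activation energy. `eyring_decompose()`
evaluates these at a reference temperature of exactly 298 K. We use
298.00 K rather than 298.15 K because the source measurements are quoted
"at 298 K" and the distinction moves $\Delta G^\#$ by under 0.05 kJ/mol,
below the reported rounding. Constants are CODATA 2018
(`physical_constants()`).

Uncertainty propagation is first-order with independent errors:
$\mathrm{se}(\Delta G^\#) = RT\,\mathrm{se}(k_{cat})/k_{cat}$,
$\mathrm{se}(\Delta H^\#) = \mathrm{se}(E_a)$, and quadrature for sums.
Quadrature also reproduces the published paired-difference errors (e.g.
$\sqrt{1.4^2 + 1.7^2} = 2.2$ for the thermophilic
$\Delta\Delta H^\#$). The published $\Delta G^\#$ uncertainties
(±0.02–0.04 kJ/mol) are smaller than what propagation of the quoted
$k_{cat}$ errors gives (±0.16 for PhWT); the derivation of those printed
errors is not stated, so the package reports the propagated value and
treats the printed one as informational only.

```{r}
wt <- eyring_decompose(c(228, 15), c(49.1, 1.4))
mut <- eyring_decompose(c(211, 25), c(32.1, 1.7))
delta_delta(mut, wt, "PhG91A", "PhWT")
```

`delta_delta()` uses the convention *first argument = variant without the
bridge*, so negative $\Delta\Delta H^\#$ and $T\Delta\Delta S^\#$ mean the
bridge removal lowered both. `compensation_curve()` propagates a pair
difference across temperature assuming temperature-independent
$\Delta\Delta H$ and $\Delta\Delta S$ (the Arrhenius plots are straight,
so this is the appropriate level of theory); its crossing temperature
$T_c = \Delta\Delta H / \Delta\Delta S$ is where the two variants are
equally active. `entropic_fold_change()` converts an entropic term into
the rate ratio it implies at constant enthalpy,
$\exp(T\Delta\Delta S^\#/RT)$ — about 3200-fold for 20 kJ/mol at 298 K.

## Kinetics

`fit_michaelis_menten()` fits $v = k_{cat} E_0 S/(K_m + S)$ by
Levenberg–Marquardt (through `minpack.lm`), with starting values read off
the data (max rate over enzyme concentration; substrate at half-max).
Enzyme concentrations are supplied in nM and converted internally, so
$k_{cat}$ comes out in s$^{-1}$. The assay design emulated throughout is
an 8-level substrate series from 0.05 to 2.0 mM in triplicate, with
$K_m \approx 0.10$ mM; a pooled $K_m$ (median across temperatures) is the
single-number summary.

`fit_arrhenius()` is ordinary least squares of $\ln k_{cat}$ on $1/T$,
unweighted by default because per-point errors are typically available
only at the reference temperature; a `weights` argument exists. The
reported $k_{cat}$ at 298 K comes from the per-temperature fit at 298 K
(with its own standard error), not from the regression line.
`extrapolate_kcat()` carries the full (intercept, slope) covariance into
prediction errors, and `crossover_temperature()` solves the two-line
intersection
$T^* = (E_{a,1}-E_{a,2})/(R\,(\ln A_1 - \ln A_2))$, returning `NA` for
parallel lines. Default temperature grids mirror the assay protocol:
283–303 K in 5 K steps for the mesophilic enzymes, extended to 318 K for
the thermophilic ones (the substrate is too labile above that).

Whether a per-temperature $k_{cat}$ should come from a full
Michaelis–Menten fit or a single saturating-substrate rate is left open
by the source protocol; the package supports both and defaults to the
full fit (`kcat_series()`).

## Binding calorimetry

`simulate_injection_heats()` implements the single-site (Wiseman)
isotherm for a displacement cell: each injection expels `dV/V0` of the
instantly mixed cell contents, so both species are diluted
multiplicatively while titrant accumulates; the cumulative heat follows
the closed-form quadratic solution of the 1:1 binding polynomial, and the
per-injection heat applies the standard displaced-volume correction
$q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2}$. The
forward model is verified in the tests against an independent bisection
solver of the binding equilibrium to 1e-8 across $K_a$ from $10^2$ to
$10^7$ M$^{-1}$.

The default protocol is 25 injections of 4 µl of 30 mM titrant into
1.5 mM protein in a 1 ml cell at 298 K, giving a Wiseman parameter
$c = n K_a M_0 \approx 10$ for the acylphosphatase presets — comfortably
inside the fittable window. `fit_single_site()` floats
$(\ln K_a, \Delta H_b, n)$ (log-affinity for conditioning), warns when
$c$ leaves $[1, 1000]$, and can fix $n = 1$ or drop a spoiled first
injection; both options are off by default since the source analysis does
not state either choice. `binding_decompose()` applies
$\Delta G_b = -RT\ln K_a$ and $T\Delta S_b = \Delta H_b - \Delta G_b$.
Heats are in µJ throughout.

## Equilibrium stability

`lem_model()`/`fit_lem()` implement the two-state linear extrapolation
model with sloped native and unfolded baselines (six parameters; sloped
baselines are standard practice even though the source analysis is silent
on them). The midpoint is reported as $C_m = \Delta G_u/m$ with its error
from the full $(\Delta G_u, m)$ covariance. The fit is observable-
agnostic — any signal linear in the folded fraction works — and warns when
fewer than three points fall inside the transition. Thermal unfolding is
deliberately not modelled: the melting of these proteins is irreversible,
so only apparent $T_m$ values are carried as metadata in
`stability_presets()`.

## Flexibility statistics

`classify_rotamer()` bins $\chi_1$–$\chi_3$ into the p/t/m wells (modal
values 60/180/300°) and $\chi_4$ into the guanido descriptors 85/180/−85.
Bins are half-open 120°-wide intervals with boundaries at 0/120/240°,
the natural symmetric choice around the modal values; only the 180°
$\chi_4$ bin occurs in the arginine data considered here.
`rotamer_statistics()` reports occupancies, transition counts and dwell
lengths; `salt_bridge_occupancy()` scores a donor–acceptor distance trace
against a 4 Å contact cutoff (an intact bridge sits below 4 Å, a broken
one near 6 Å).

`kabsch_superpose()` is the SVD solution of the rigid superposition
problem with the determinant sign corrected to exclude reflections;
collinear point sets are rejected. `rmsd_series()` scores each frame
against a reference (flagging trajectories that stay under 1.5 Å, the
usual stability criterion), and `rmsf_per_atom()` uses two passes of
alignment to the evolving mean structure. Inputs are plain tables and
multi-frame XYZ text — the package deliberately consumes
trajectory-derived tables rather than binary MD formats, and running the
simulations themselves is out of scope.

## Synthetic data: what it emulates and what it does not

Each generator is a pure function of its parameters and a seed, and its
noiseless output passes exactly through the matching fitter (tested to
relative 1e-6):

* `generate_assay_data()` — Arrhenius-consistent Michaelis–Menten rates
  with multiplicative Gaussian noise. The default CV of 3% per rate
  reproduces the ~7% turnover-number standard errors typical of the
  published table; noise on rates is multiplicative because assay error
  scales with signal.
* `generate_itc_data()` — Wiseman heats with additive Gaussian noise (µJ),
  the instrument-appropriate model for integrated injection heats.
* `generate_denaturation_curve()` — two-state signal with additive noise.
* `generate_dihedral_trajectory()` — a hidden Markov chain over named
  rotamer wells with von Mises angular emissions (sampled by the
  Best–Fisher rejection method, implemented in-package) and a distance
  trace correlated with native-state occupancy. The bridge-present preset
  dwells in mtm180 (stationary occupancy 0.985) around 3.2 Å; the
  bridge-absent preset distributes occupancy 0.40/0.25/0.20/0.15 over
  mtm180/ptt180/ttp180/mtt180 around 6.0 Å. Preset transition matrices
  are built as $(1-\varepsilon)I + \varepsilon \mathbf{1}\pi^\top$, which
  has stationary law $\pi$ exactly.

The generators emulate the *statistical structure* of the real inputs —
they do not emulate raw absorbance traces, ITC power curves, force-field
physics, or the correlated dynamics of a real MD trajectory. Passing
recovery tests on these data therefore demonstrates correctness of the
estimators under the stated noise models, not robustness to every
instrumental artefact. In particular the rotamer analysis of real
simulations is reported qualitatively in the source study; the package's
trajectory checks are property-based (occupancy orderings, stationary
laws), which is the desk-scale analogue, and MD-scale results are not
reproducible here.

## Numerical choices

* Energies are kJ/mol externally, J/mol internally; entropies J/(mol·K).
  Report rounding mirrors the published tables: one decimal for kJ
  quantities, integers for entropies.
* All nonlinear fits are Levenberg–Marquardt (`minpack.lm`), with
  data-driven starting values described above; the ITC fit additionally
  tries a small grid of starting affinities ($10^3, 10^4, 10^5$) and
  keeps the best optimum.
* `reproduce_tables()` regenerates every derived table cell from measured
  inputs and compares at the printed rounding, allowing ±1 unit in the
  last printed digit. The allowance exists because a handful of published
  cells are rounded inconsistently with their own stated formulas
  (recomputing the HuWT row gives $T\Delta S^\# = -20.27$ where $-20.2$
  is printed, and the PhWT binding entropy gives 50.6 where 50 is
  printed); all such deviations are below one final digit.
* `crossover_temperature()` treats slope differences below a relative
  1e-10 as parallel; `compensation_curve()` reports an absent $T_c$ when
  $\Delta\Delta S = 0$.
* Degenerate inputs fail loudly: non-positive rates, temperatures or
  affinities, collinear coordinate sets, and non-stochastic transition
  matrices are all rejected with the offending field named.

## Problem sizes and reproducibility

The test suite and the acceptance script run everything from synthetic
data at deliberately modest sizes: 24-point assay designs, 25-injection
isotherms, 29-point denaturation curves, $10^4$–$10^5$-frame
trajectories, and 100–200-seed recovery ensembles. These sizes are chosen
so that the stochastic checks (estimator bias within two standard errors
of the ensemble mean; occupancies within ±0.02 of stationary laws) are
sharp enough to catch real defects while the whole suite runs in well
under a minute. `scripts/acceptance.R --seed N --out file.json`
recomputes the headline numbers from scratch; every random stream derives
from the single `--seed`.

## Known limitations

* Transition-state theory is used with a transmission coefficient of 1 and
  no tunnelling correction; $\Delta H^\#$ and $\Delta S^\#$ are treated as
  temperature-independent over the 283–318 K window.
* The ITC model is strictly 1:1 with a single site class; no sequential or
  multi-site models, and no baseline/peak integration from power traces.
* The stability module fits chemical denaturation only; three-state
  mechanisms and DSC lineshapes are out of scope.
* The flexibility module assumes uniformly spaced, pre-imaged scalar
  series; it performs no periodic-boundary corrections and does not read
  topology or binary trajectory files.
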