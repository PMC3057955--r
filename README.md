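# acptherm

Thermodynamic analysis of how an active-site salt-bridge trades
low-temperature enzyme activity for high-temperature activity, built
around the thermophilic/mesophilic acylphosphatase pair (PhAcP from
*Pyrococcus horikoshii* and human AcP) and their "mirror-image"
salt-bridge variants.

## The problem and who this is for

In thermophilic acylphosphatases the invariant catalytic arginine is
pinned by a salt-bridge to the C-terminal carboxylate; mesophilic
homologues lack it. Rigidifying the arginine costs nothing at the
transition state — where the residue must be ordered anyway — so the
bridge makes the activation entropy less negative and, through
enthalpy–entropy compensation, steepens the temperature dependence of
$k_\mathrm{cat}$. The package is for enzymologists and structural
biologists who want to run this analysis chain quantitatively on their
own variant pairs:

* **Transition-state decomposition** —
  $\Delta G^\# = RT(\ln(k_BT/h) - \ln k_\mathrm{cat})$,
  $\Delta H^\# = E_a - RT$, $T\Delta S^\# = \Delta H^\# - \Delta G^\#$,
  with first-order error propagation, paired $\Delta\Delta$ comparisons,
  compensation curves and the entropic rate fold-change
  $\exp(T\Delta\Delta S^\#/RT)$.
* **Kinetics** — Michaelis–Menten fits of raw assay rates, Arrhenius
  regression of $\ln k_\mathrm{cat}$ on $1/T$, extrapolation with proper
  covariances, and the crossover temperature where two variants swap rank.
* **Binding calorimetry** — the single-site Wiseman isotherm for a
  displacement cell (forward simulation and Levenberg–Marquardt fitting),
  and $\Delta G_b = -RT\ln K_a$, $T\Delta S_b = \Delta H_b - \Delta G_b$.
* **Stability** — two-state linear-extrapolation fits of chemical
  denaturation curves ($\Delta G_u$, $m$, $C_m = \Delta G_u/m$).
* **Flexibility** — p/t/m rotamer classification of $\chi_1$–$\chi_4$
  dihedral traces, occupancy/transition statistics, salt-bridge occupancy
  at a 4 Å cutoff, and Kabsch RMSD/RMSF from coordinate ensembles.
* **Synthetic data** — seeded generators for every input above with known
  ground truth, so the whole pipeline is testable offline.

## Worked example

Decompose the thermophilic wild type and its bridge-free variant from
their measured turnover numbers and activation energies:

```r
library(acptherm)

wt  <- eyring_decompose(c(228, 15), c(49.1, 1.4))   # PhWT:   kcat +/- se, Ea +/- se
mut <- eyring_decompose(c(211, 25), c(32.1, 1.7))   # PhG91A
wt
#> Activation thermodynamics at 298 K
#>   kcat : 228 ± 15 s^-1
#>   Ea   : 49.1 ± 1.4 kJ/mol
#>   dG#  : 59.53 ± 0.16 kJ/mol
#>   dH#  : 46.62 ± 1.4 kJ/mol
#>   TdS# : -12.91 ± 1.4 kJ/mol
#>   dS#  : -43.33 ± 4.7 J/mol/K

delta_delta(mut, wt, "PhG91A", "PhWT")
#> Paired difference PhG91A - PhWT at 298 K
#>   ddG  : 0.192 ± 0.34 kJ/mol
#>   ddH  : -17 ± 2.2 kJ/mol
#>   TddS : -17.19 ± 2.2 kJ/mol
#>   ddS  : -57.69 ± 7.5 J/mol/K
```

Removing the bridge drops the activation enthalpy and the entropic term
by ~17 kJ/mol each, leaving $\Delta G^\#$ at 298 K essentially unchanged
(0.2 kJ/mol): textbook enthalpy–entropy compensation. The variants are
equally active at `compensation_curve(...)$Tc` = 294.7 K, and a
20 kJ/mol entropic advantage corresponds to
`entropic_fold_change(20, 298)` = 3203, i.e. a >3000-fold rate gain at
constant enthalpy.

The same numbers emerge from raw (here synthetic) assay data:

```r
assay <- generate_assay_data("PhWT", noise_cv = 0.02, seed = 1)
ser <- kcat_series(assay)                 # per-temperature MM fits
fit_arrhenius(ser$T, ser$kcat)
#> Arrhenius fit (ln kcat vs 1/T), 8 points
#>   Ea : 48.96 ± 0.19 kJ/mol
#>   lnA: 25.19 ± 0.076   R^2 = 0.9999
```

and from a simulated titration:

```r
p <- titration_protocol()                 # 25 x 4 ul of 30 mM into 1.5 mM, 1 ml
f <- fit_single_site(p, generate_itc_data("PhWT", noise_sd = 10, seed = 1))
binding_decompose(f$Ka, f$dHb)
#> Binding thermodynamics at 298 K
#>   Ka  : 6581 ± 350 M^-1
#>   dGb : -21.78 ± 0.13 kJ/mol
#>   dHb : -6.7 ± 0.076 kJ/mol
#>   TdSb: 15.08 ± 0.15 kJ/mol
#>   dSb : 50.62 ± 0.51 J/mol/K
```

`reproduce_tables()` regenerates every derived activation and binding
cell for all five variants from the measured inputs and diffs them
against the published values (`$n_mismatch` is 0), and `run_pipeline()` /
`write_report()` drive all stages end-to-end from seeded synthetic data.
See `vignette("salt-bridge-thermodynamics")` for the models, assumptions
and design decisions.

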