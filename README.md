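# myokin

Kinetic and structural analysis of the myosin / actomyosin ATPase cycle,
built around human nonmuscle myosin-2C (NM2C) — one of the slowest class-2
myosins — and the converter-hub charge mutants R788K and R788E.

`myokin` is for motor-protein kineticists who fit stopped-flow transients and
steady-state ATPase data, and for structural biologists who need the standard
geometric readouts of allosteric pathways. It provides:

* a mass-action ODE model of the eight-state myosin/actomyosin cycle
  (`build_network()`, `simulate_cycle()`), with plain-face constants for
  actin-detached and bold-face ("acto") constants for attached transitions;
* projection of state occupancies onto the experimental observables
  (mant-nucleotide, pyrene-actin and tryptophan fluorescence, light
  scattering, NADH-coupled ATPase) via `project_signal()`;
* the transient-kinetics fitting ladder: exponential phase extraction
  (`fit_exponential()`), linear and hyperbolic secondary fits
  (`fit_kobs_linear()`, `fit_kobs_hyperbolic()`), Michaelis–Menten ATPase
  fits (`fit_michaelis()`);
* derived constants (`derived_constants()`): equilibrium constants
  K\_D = k\_-D/k\_+D etc., thermodynamic (K\_AD/K\_D) and kinetic
  (k\_-AD/k\_-D) coupling, nucleotide selectivity k\_+AD/K\_1k\_+2, and the
  duty ratio, computed as the Michaelis–Menten cycling flux over the
  actin-activated ADP release rate, duty = v([A]) / k\_-AD;
* structure metrics on PDB models (`read_structure()`, `superpose()`,
  `ca_angle()`, `backbone_dihedrals()`, `hbond_population()`,
  `contact_profile()`, `domain_rotation()`, `pocket_sphere_volume()`);
* synthetic-data generators with embedded ground truth for every input
  class (`generate_transient()`, `generate_series()`,
  `generate_atpase_curve()`, `generate_chase()`, `generate_trajectory()`,
  `build_backbone()`).

The measured parameter sets of all three constructs ship with the package
(`nm2c_constants("NM2C" | "R788K" | "R788E")`), including every individual
reporter measurement for precedence-aware derivations.

## Worked example

Derived kinetic signatures of wild-type NM2C from its measured rate set:

```r
library(myokin)
derived_constants(nm2c_constants("NM2C"))
#> Derived constants: NM2C
#>   K_D                      2.41 uM
#>   K_AD                     0.256 uM
#>   K_A                      0.0602 uM
#>   K_DA                     0.00755 uM
#>   K_AD/K_D                 0.106
#>   k-AD/k-D                 0.723
#>   k+AD/K1k+2               1.55
#>   K_DA/K_A                 0.125
#>   kcat/Kapp                0.00286 uM^-1 s^-1
#>   duty ratio (190 uM actin) 0.324
#>     variants: mant_chase = 0.32, light_scattering_chase = 0.56, pyrene_chase = 0.46
```

Reading: actin *weakens* ADP binding only ~10-fold less than it weakens it in
fast myosins (thermodynamic coupling 0.11) and barely accelerates ADP release
(kinetic coupling 0.7); actomyosin prefers ADP over ATP (selectivity 1.5);
the motor spends about a third of its cycle strongly bound at 190 µM F-actin
(duty ratio ~0.3). These are the signatures of a slow, tension-bearing
tether.

A synthetic round-trip — simulate a mant-ADP concentration series at 1%
noise (4 averaged shots per concentration) and refit the binding constants:

```r
s <- generate_series(nm2c_constants("NM2C"), "mant_adp_binding",
                     c(0.5, 1, 2, 4, 8, 12, 16, 20),
                     noise_spec(0.01, seed = 42, fraction = TRUE),
                     replicates = 4)
lf <- fit_kobs_linear(s)
#> k+D (slope)     = 0.390 uM^-1 s^-1   (truth 0.39)
#> k-D (intercept) = 0.940 s^-1         (truth 0.94)
```

## Analysis workflow

The `analysis/` scripts run the full study pipeline and write tables under
`results/`:

1. `01_simulate_transients.R` — single-turnover mant and pyrene transients
   of the three constructs (rise–plateau–decay shapes).
2. `02_fit_kinetics.R` — round-trip of the whole fitting ladder at 1% noise;
   truth vs recovered constants per construct.
3. `03_derived_constants.R` — the comparative signature table (couplings,
   efficiency, duty ratios) and the thermodynamic-box diagnostic.
4. `04_structure_metrics.R` — geometric metrics on synthetic coordinate
   data with planted ground truth (145° relay-style kink, 27° domain
   rotation, 55% H-bond occupancy, 697/3054 Å³ pocket spheres).

## Package layout

```
R/                  implementation (network, observables, fits, derived
                    constants, structure metrics, synthetic data)
analysis/           numbered workflow scripts (see above)
tests/testthat/     unit, property and end-to-end suites with independent
                    oracles (quaternion RMSD, brute-force scans)
vignettes/          methods vignette: model, assumptions, defaults, limits
inst/extdata/       small synthetic PDB fixtures
scripts/            acceptance script
```
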