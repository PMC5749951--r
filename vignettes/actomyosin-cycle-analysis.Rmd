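---
title: "Modelling the actomyosin ATPase cycle and its structural readouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the actomyosin ATPase cycle and its structural readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myokin)
```

## The scientific problem

Nonmuscle myosin-2C (NM2C) is one of the slowest class-2 myosins: its
steady-state ATPase is barely activated by F-actin, it binds ADP tightly, and
it spends an unusually large fraction of its cycle strongly bound to actin (a
high *duty ratio*). These signatures make it a strain-sensing actin tether
rather than a fast contractile motor. `myokin` re-implements the quantitative
machinery used to characterize such motors: a kinetic model of the
myosin/actomyosin ATPase cycle fit to stopped-flow and steady-state data, the
derived coupling constants and duty ratio, and the geometric readouts used to
describe the allosteric pathway between the converter and the active site
(superposition RMSD, relay-helix angle, dihedrals, hydrogen-bond occupancies,
contact profiles, domain rotations, pocket volumes).

Everything is testable without external data: a synthetic-data module
generates every input class with embedded ground truth.

## The kinetic scheme

The cycle is modelled as mass-action ODEs over eight myosin states
(M, M·ATP, M·ADP·Pi, M·ADP and their actin-bound counterparts AM, AM·ATP,
AM·ADP·Pi, AM·ADP) plus free ligand pools (ATP, ADP, Pi and F-actin sites A).
Plain-face rate constants govern actin-detached transitions, bold-face
("acto") constants the attached ones. Three steps are *effective* rather than
elementary, matching how the constants are measured:

* **ATP binding to myosin** is a single second-order step with rate
  $K_1 k_{+2}\,[\mathrm{ATP}]$. The collision equilibrium and the
  isomerization are not separable from the linear concentration dependence
  alone.
* **ATP binding to actomyosin** is a rapid-equilibrium collision ($1/K_1$)
  followed by an isomerization $k_{+2}$, giving the per-AM rate
  $k_{+2}[\mathrm{ATP}]/(1/K_1 + [\mathrm{ATP}])$, so the observed rate of
  ATP-induced dissociation saturates at $k_{+2}$. The AM·ATP collision state
  then detaches at a fast default rate (`detach_rate`, $10^4\,s^{-1}$), which
  keeps the isomerization rate-limiting: the sequential eigenvalues are
  $k_\text{obs}$ and `detach_rate`, and after the instrument dead time the
  slower one carries essentially all the amplitude.
* **Phosphate release** from M·ADP·Pi carries an actin-dependent rate
  $k_{basal} + (k_{cat} - k_{basal})\,[A]/(K_{app}+[A])$. This reproduces the
  Michaelis–Menten steady-state envelope without postulating weak-binding
  isomerization microstates whose constants are not experimentally resolved;
  only $k_{cat}$ and $K_{app}$ are measured.

### Defaults the experiments do not constrain

Several microscopic constants are not separately measurable; they are
package defaults, chosen once and documented:

| parameter | default | rationale |
|---|---|---|
| hydrolysis split $k_{+3}/k_{-3}$ | $K_{eq}=10$, sum as measured | the tryptophan signal constrains only $k_{+3}+k_{-3}$; hydrolysis equilibria on myosin favour products by roughly an order of magnitude |
| basal Pi release | $0.02\,s^{-1}$ | basal turnover of slow myosins-2; rate-limiting in the absence of actin |
| AM·ATP detachment | $10^4\,s^{-1}$ | weak-binding detachment is much faster than the isomerization it follows |
| M·ADP·Pi + A attachment | $0.01\,\mu M^{-1}s^{-1}$ on, $1\,s^{-1}$ off | weak-binding affinity on the $K_{app}$ scale ($\sim100\,\mu M$) |
| R788E hydrolysis sum | wild-type value | not accessible (no tryptophan signal); only affects plateau shaping in single-turnover simulations, none of the fitted constants |

All are fields of `rate_constants()` and can be overridden.

### Numerical contract

`simulate_cycle()` integrates with a stiff-capable solver (`deSolve::lsoda`)
at absolute tolerance $10^{-10}\,\mu M$ and relative $10^{-8}$. Myosin and
actin totals are verified to $10^{-6}$ relative at every output time;
violations and integrator failures raise errors rather than returning clipped
output. Pseudo-first-order clamping can hold all ligand pools constant or
only a named subset (`clamp_ligands = "ATP"` for a chase over stoichiometric
actin).

## Observables

Experiments see linear projections of the state occupancies:
`project_signal()` computes $s(t) = b + \sum_s w_s\,c_s(t)$. Signals are
relative (unitless); amplitudes are free fit parameters downstream, so only
the ordering of the weights matters. Defaults per reporter: mant fluorescence
weighs all bound-mant states 1; pyrene-actin weighs free actin and weakly
attached states 1 and the quenched rigor-like states 0; tryptophan weighs the
post-hydrolysis M·ADP·Pi highest (the relay-loop tryptophan reports the
switch-2-coupled priming); light scattering weighs attached mass; the
NADH-coupled assay is modelled as accumulated ADP production (the
coupled-enzyme cascade is instrumentation, the observable is the rate). The
mutant phenotype "no nucleotide-induced tryptophan change" is representable
as equal weights across states, which provably yields a flat signal for any
trajectory over a conserved pool.

## Fitting ladder

`fit_exponential()` (1–2 phases, Levenberg–Marquardt via `minpack.lm`) uses
start values from a tail-estimated offset and log-linear regression, with
restarts from $\times0.1/\times10$ perturbed rates. Reporting rules: phases
sorted by descending rate; a phase is flagged (not reported) if its amplitude
is below 3× the residual noise **or** it relaxes by less than one e-fold in
the fitting window (such a phase is degenerate with the offset); two phases
whose rates differ by less than 1.5× are merged into a single-exponential
refit. Dead-time samples are excluded before fitting by the generators.

Secondary fits are standard: `fit_kobs_linear()` (ordinary least squares;
slope = second-order binding constant, intercept = release rate),
`fit_kobs_hyperbolic()` ($k_{max}[S]/(K_{1/2}+[S])$; warns when saturation is
not approached and still returns estimates), and `fit_michaelis()` for the
actin-activated ATPase (basal subtraction is an explicit, default-off switch
because published $k_{cat}$ values do not state whether they are
basal-subtracted).

## Derived constants

Equilibrium constants are off/on-rate ratios ($K_D = k_{-D}/k_{+D}$, etc.).
Unavailability is first-class: a ratio whose member a construct's signals
cannot access is `NA` with a reason, and propagates. Coupling ratios:

* thermodynamic coupling $K_{AD}/K_D$ (actin's effect on ADP affinity),
* kinetic coupling $k_{-AD}/k_{-D}$ (actin's effect on ADP release),
* nucleotide selectivity $k_{+AD}/K_1k_{+2}$ (acto branch),
* actin-affinity coupling $K_{DA}/K_A$.

Where a constant was measured with several reporters, a like-vs-like
precedence (stored as data with the measurement table) selects the members:
chase-derived release rates are paired with chase-derived ones; the
wild-type kinetic coupling pairs the chase $k_{-AD}$ with the
intercept-derived $k_{-D}$, the published pairing; $K_{AD}$ uses the
series-derived mant members. For the charge-reversal mutant the published
$K_{AD}$ is **not** the ratio of its printed members (2.68 vs 3.0 µM); the
package carries the published derived value for the coupling by explicit
per-construct precedence and keeps both numbers visible rather than
smoothing the discrepancy away.

### Duty ratio

The published comparison states the conditions (190 µM F-actin, saturating
ATP) but not a formula. The package computes the attached-time fraction as
cycling flux over detachment rate,
$\mathrm{duty} = v([A]) / k_{-AD}$ with $v = k_{cat}[A]/(K_{app}+[A])$,
clipped at 1 with a flag: when ADP release gates detachment, $1/v$ is the
cycle time and $1/k_{-AD}$ the strongly bound time. This reproduces ~0.3 for
the wild type and the conservative mutant and 0.85–1.15 (reported per chase
variant, clipped at 1) for the charge-reversal mutant, whose ADP release
becomes rate-limiting. Monotonicity (increasing in $[A]$ and $k_{cat}$,
decreasing in $k_{-AD}$) is property-tested.

## Structural metrics

`read_structure()` parses fixed-width PDB ATOM/HETATM/MODEL records (via
`bio3d` behind the package surface) after validating the record layout with
line-numbered errors; altlocs resolve to the highest occupancy with ties to
"A"; multi-MODEL files become coordinate trajectories with one shared
roster. Selections use a compact `chain:resnum[-resnum][@atom]` grammar.

* `superpose()` is a least-squares Kabsch fit (SVD, proper rotation
  enforced); tests compare against an independent closed-form quaternion
  oracle on clouds of 4–500 atoms.
* `ca_angle()` gives the planar angle at a residue triple — the relay-helix
  kink readout (~145° in the kinked pre-powerstroke helix).
* `backbone_dihedrals()` follows the IUPAC sign convention, range
  (−180°, 180°]; termini and chain breaks (peptide C–N > 2 Å) yield `NA`.
* `hbond_population()` is the fraction of frames with any donor–acceptor
  heavy-atom pair within 3.5 Å (no angle term by default: crystal structures
  lack hydrogens; an angle cutoff is available for trajectories with H).
* `contact_profile()` lists inter-residue pairs within 4 Å, classed `hbond`
  (both partners N/O within the H-bond cutoff) or `vdW`.
* `domain_rotation()` superposes on a fixed core, then reports the
  axis–angle magnitude of the residual rigid fit of the domain (0–180°).
* `pocket_sphere_volume()` uses an inscribed-sphere reading: radius =
  distance from the centroid of the site selection to the nearest
  non-selected protein heavy atom minus a probe, volume $=\frac43\pi r^3$.
  The published active-site sphere volumes 697 and 3054 Å³ correspond to
  radii 5.50 and 9.0 Å under this reading; the published description does
  not specify the method, so this interpretation is documented as such, and
  reproducing the published values on deposited structures is an external
  check, not part of the test suite.

All metrics are invariant under global rigid motion, which is
property-tested.

## Synthetic data: what it emulates, what it does not

`generate_transient()`, `generate_series()`, `generate_atpase_curve()`,
`generate_chase()` and `generate_trajectory()` produce every input class the
pipeline consumes, with the generating truth embedded in the output metadata
and bit-identical reproducibility from (spec, seed). Noise is iid additive
Gaussian (the publications give no noise model); instrument dead time
(default 1.5 ms) truncates the early samples. Concentration series average
several simulated shots per concentration (default designs use 4), mirroring
stopped-flow practice.

One modelling subtlety: the species pool does not carry nucleotide labels,
so the chase generator zeroes the phosphate-release rates — ADP regenerated
from the hydrolyzed unlabeled chase ATP would be dark in the experiment and
must not repopulate the fluorescent ADP states. The labeled decay path is
untouched and the chase is a single-displacement measurement, so this
reproduces the experiment's bookkeeping rather than changing its physics.

Coordinate trajectories realize planted properties exactly: occupancies by
frame assignment (a 55% plant over 1000 frames is 550 frames), rotations by
rigid interpolation about a reproducible random axis; jitter applies only to
atoms not involved in a plant. `build_backbone()` constructs ideal chains
from standard internal coordinates, so dihedral recovery is exact by
construction.

What the generator does **not** emulate: photophysics (bleaching,
inner-filter), mixing artifacts, correlated noise, solvent/force-field
physics in the coordinate frames, and real conformational ensembles. Passing
round-trip tests therefore demonstrates the correctness of the analysis
ladder under the stated noise model, not robustness to every instrument
artifact of real data.

## Problem sizes and runtime

Test and script problem sizes are chosen so a full run is interactive:
series of 6–8 concentrations with 4 replicates and 200-point traces,
Monte-Carlo checks with 200–500 seeds, oracle comparisons up to 500 atoms,
trajectories up to 1000 frames. The whole suite runs in well under a minute
on one core; `scripts/acceptance.R` in a few seconds.

## Known limitations

* The cycle model has no lever-arm mechanics, load dependence, or filament
  gating; it is an ensemble-solution kinetics model.
* No global multi-experiment fitting: each experiment is fit separately, as
  in the original analysis workflow.
* The weak-binding actin attachment of M·ADP·Pi and the hydrolysis split are
  conventions (see defaults table); conclusions that depend on them should
  be checked by sensitivity analysis through the configurable fields.
* PDB support covers the fixed-width dialect only (no mmCIF).
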