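---
title: "Designing degradable flame-retardant derivatives: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing degradable flame-retardant derivatives: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degradesign)
```

## The problem

Chlorinated organophosphorus flame retardants (OPFRs) are poorly removed by
biological wastewater treatment and by UV/H~2~O~2~ photolysis. A
molecular-modification programme proposes substituted derivatives (TCPP–OH,
TCEP–SO~3~H, ...) and asks, for each candidate: does it degrade more easily,
does it keep its flame-retardant function, and under which external
conditions does enzymatic degradation work best? `degradesign` implements
the quantitative steps of that chain. All physics inputs — enzyme binding
free energies, UV first excited-state transition energies, enthalpies,
reaction barriers — are *inputs* here; the package performs no quantum
chemistry, docking or molecular dynamics.

## Composite degradability score

Two effect channels are scored per compound *i*:

* biodegradation: the binding free energy ΔG~bind~ (kJ/mol) between the
  compound and its degrading enzyme, entered as a magnitude |ΔG~bind~|
  (more negative binding = stronger interaction = more favourable
  enzymatic degradation);
* photodegradation: the first excited-state UV transition energy (eV);
  lower energy = easier photoexcitation.

Each value is normalized against a target value *T* into a dimensionless
efficacy coefficient, either the min/max form
$R_{S,i} = \min\{x^*_i, T\}/\max\{x^*_i, T\} \in (0, 1]$ or its reciprocal
max/min form in $[1, \infty)$; both equal 1 exactly at the target. The
comprehensive evaluation value is the weighted sum
$C_i = w_1 R_{S1,i} + w_2 R_{S2,i}$ with default equal weights
$w = (0.5, 0.5)$, chosen so neither channel dominates. Lower *C* is read as
better combined degradability.

### Orientation and target conventions

The published form of the normalization prints only the min/max ratio, but
the printed reference coefficients are reproducible only with a *mixed*
orientation: max/min on binding-energy magnitudes (e.g.
144.537/41.842 = 3.454 for TCPP) and min/max on transition energies
(7.2211/7.2874 = 0.991 for TCPP). `degradesign` therefore makes the
orientation an explicit per-channel setting ([effect_spec()]), and
[default_effects()] encodes this reconciled configuration. Note the
semantic tension this leaves: the max/min biodegradation channel penalizes
deviation from the target in *both* directions, so the strongest binder
(TEHP, |ΔG| = 268.708) still scores 1.859. The package reproduces the
published convention; it does not attempt to resolve its interpretation,
and [effect_spec()] lets users flip either orientation.

The target *T* is "taken as the median of the data" in the published
description, and both printed targets coincide with the values of the
reference compound TCIPP — whose |ΔG~bind~| is simultaneously the 11th of
the 22 ascending magnitudes (the lower median) and whose transition energy
is the 12th of the 22 energies (the upper median). A single reference-
compound rule reproduces both printed columns, so the default
[target_policy()] is `reference_compound` with `reference_id = "TCIPP"`;
an `order_statistic` mode (1-based rank into the ascending sorted
magnitudes) is provided for tables without a designated reference. Exact
even-count medians (`stats::median` would interpolate) reproduce *neither*
printed target, which is why the median itself is not a policy mode.

Internal arithmetic is unrounded; the conventional report precision
(3 decimals for coefficients, 2 for *C*) is applied only when printing or
comparing against printed references.

## Taguchi L27(3^7) condition analysis

Seven external factors (pH; temperature, K; methanol and acetic acid,
mg/L; H~2~O~2~, mg/L; voltage gradient, stored with its printed unit
string "V/m" — the accompanying text says V/cm, and the package does not
convert between them; SDS surfactant, mg/L), each at three levels, are
accommodated in a 27-run orthogonal array. One published passage calls the
design "L26", but no 26-run three-level orthogonal array exists and the
printed run table has 27 rows; the package fixes 27.

[taguchi_l27()] constructs the array over GF(3)^3: runs are the 27 points
of a ternary 3-space and columns are the 13 distinct nonzero linear
functionals up to scalar, so any two columns are linearly independent and
pairwise orthogonality (each ordered level pair exactly 3 times per column
pair) is forced by construction. [validate_orthogonal_array()] checks
balance and orthogonality by explicit counting, and accepts externally
supplied designs read by [read_doe_table()] — analysis functions are
agnostic to a design's origin.

Main effects are plain per-(factor, level) response means. Factor
importance is the *range* (max − min, "delta") of the three level means —
no signal-to-noise transform is applied, because the published ranking is
exactly the range ranking and no replicate variance is available. Rank
ties are broken by factor declaration order, deterministically. The
optimal level is the argmin of the level means: responses are binding free
energies, and more negative means stronger enzyme–substrate affinity
(`objective = "maximize"` is available for responses oriented the other
way). One flagged inconsistency: the published text states an optimal
H~2~O~2~ concentration of 200 mg/L, which is not among that factor's
declared levels {300, 350, 400}; the argmin of the printed level means is
300 mg/L, and the package reports the argmin without reinterpretation.

[affinity_improvement()] is `(|g_new| − |g_ref|)/|g_ref| × 100`;
magnitudes are used because one published reference value is printed
without its sign.

## Energetics conventions

* ΔG = ΣG(products) − ΣG(reactants); barriers ΔE = E(TS) − ΣE(reactants).
  (The published barrier equation is labelled ΔG but defines an energy
  barrier; the package names it ΔE.) Negative barriers are allowed but
  warned about.
* H°(T) = E + ΔZPE + ΔH~trans~ + ΔH~rot~ + ΔH~vib~ + RT. The trailing term
  of the published formula is printed as an undefined "OT"; it is
  implemented as the conventional ideal-gas RT term (on by default at
  298.15 K, R = 1.98720425 × 10⁻³ kcal mol⁻¹ K⁻¹, disable with
  `include_rt = FALSE`).
* The P–O bond dissociation enthalpy uses the standard homolysis form
  H(frag₁) + H(frag₂) − H(parent) — symmetric in the fragments — which is
  the only reading consistent with "lower dissociation enthalpy = better
  flame retardancy". (The published equation line is typographically
  garbled.)
* Canonical internal unit: kcal/mol, with exact conversions
  1 hartree = 627.5094740631 kcal/mol and 1 kcal = 4.184 kJ via
  [convert_energy()].
* [pathway_compare()] aligns steps by ordinal position; pathways of
  unequal length compare totals only, with a warning. Percent reduction is
  (total~ref~ − total~mod~)/total~ref~ × 100.

## Derivative screening

Three sign conventions appear in the reference tables and are exposed as
three named operations to avoid ambiguity: `reduction_intensity`
((old − new)/old × 100, also the flame-retardancy "enhanced rate"),
`increase_intensity` ((new − old)/old × 100), and `change_rate`
((new − old)/|old| × 100; the magnitude denominator keeps the sign of the
raw change for negative totals such as electronic energies in a.u.). The
environment-friendly screen requires all six criteria: comprehensive score
reduced, predicted biodegradation activity increased, predicted transition
energy reduced, P–O dissociation enthalpy reduced, minimum vibrational
frequency positive, and HOMO–LUMO gap change ≥ −5% (the gap tolerance is a
parameter; 5% is the published allowance for "slight" insulation loss).
The screen is monotone: worsening any one input can only lose a pass.

## Reference fixtures and reproduction limits

The curated tables ship as UTF-8 CSVs transcribed at printed precision
(including the Unicode minus signs of the source, which the readers
normalize). [reproduce_reference()] recomputes every derived number and
classifies each comparison as `exact` (must match after rounding to the
printed precision) or `tolerance` (quantities the source computed from
unrounded internal values; ±0.2 percentage points when recomputed from
printed inputs).

Two reproduction limits are known and deliberate — the package computes
from the stated inputs exactly and does not encode numbers those inputs
cannot produce:

* three of the 42 printed functional-property change rates differ by 0.01
  in the last printed digit from exact recomputation (the flame-retardancy
  enhanced rates of TCPP–CH~2~OH, TCPP–COOH and TCPP–CONH~2~), evidently
  because unrounded enthalpies were used upstream;
* a handful of printed prediction intensities deviate by more than 0.2
  percentage points from recomputation out of their printed 2-d.p. inputs
  (input rounding alone propagates to ~0.5 pp for the smallest
  denominators), and two comprehensive-reduction cells (TCEP–NH~2~,
  TCEP–CHO) are internally inconsistent with any printed parent value by
  7.7 and 17.1 pp. The corresponding checks are asserted at their stated
  tolerance and reported as failures rather than being widened around.

All 18 printed improvement ratios, all 66 scoring cells, all 21 level
means, the ranking, and the four text-printed energetics percentages
reproduce exactly at printed precision.

## Synthetic data: what it emulates, what it does not

The generators ([gen_compound_table()], [gen_doe_response()],
[gen_pathway_pair()]) are pure functions of a [simulation_config()] and its
seed, restore the caller's RNG state, and emulate only the *statistical
shape* each stage assumes:

* binding-energy magnitudes: log-normal, default median 100 kJ/mol and
  log-SD 0.9, spanning roughly the 9–270 kJ/mol range of the reference
  table; stored negative;
* transition energies: normal (6.5 ± 1.2 eV) truncated at zero by
  redrawing, mimicking the 4.3–8.3 eV reference range;
* factorial responses: grand mean (default −77 kJ/mol, near the reference
  study's −76.96) plus additive per-factor level offsets that sum to zero,
  plus i.i.d. Gaussian noise (default SD 3 kJ/mol);
* pathway pairs: uniform step barriers in 150–420 kcal/mol, with the
  modified pathway scaled to a planted total-barrier reduction.

These choices are emulation, not inference: real computed property tables
are neither independent nor log-normal (homologous series are strongly
structured), real condition responses can hold interactions that an L27
main-effects analysis confounds with main effects, and real pathway
modifications change steps heterogeneously rather than by a uniform scale.
Passing the synthetic tests therefore demonstrates estimator correctness
(planted main effects of range ≥ 5σ are ranked first in ≥ 95% of seeded
replicates; noiseless offsets are recovered exactly; planted barrier
reductions round-trip to 1 × 10⁻⁹), not real-world predictive validity.

Test problem sizes follow the reference study (22 compounds, 27 runs) with
200 replicates for recovery checks and 2000 for the null ranking
distribution — small enough to run in seconds while keeping Monte-Carlo
error well inside the asserted bands.

## Degenerate inputs and numerical details

* Efficacy coefficients require strictly positive inputs after magnitude
  handling; zero or negative values are domain errors, not silently
  clamped.
* Weights must sit in [0, 1] and sum to 1 within 1 × 10⁻¹².
* Physical factor levels are matched to declared levels with a relative
  tolerance of 1 × 10⁻⁸; undeclared values are errors naming the run and
  factor.
* A zero-spread generator configuration collapses every compound onto the
  target, and scoring then returns all-ones coefficients — the documented
  degenerate case.
* Grand-mean conservation of level means holds to 1 × 10⁻⁹ (relative) on
  balanced designs and is tested, not assumed.

## Known limitations

The package evaluates candidates it is given; substituent-site selection
from pharmacophore force-field maps, the pharmacophore regressions
themselves, and all quantum-chemistry/docking/MD computation are out of
scope. Compounds are opaque labels — no SMILES/SDF parsing and no
structure generation. The composite score is a convention, not a validated
predictor: no claim is made that lower *C* causes higher real-world
degradation rates.
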