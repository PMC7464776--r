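# degradesign

Chlorinated organophosphorus flame retardants (OPFRs) such as TCPP, TCEP and
TCIPP leach from plastics into wastewater and resist both the activated-sludge
and UV/H₂O₂ treatment stages. One design strategy replaces them with
substituted derivatives that keep the flame-retardant P–O chemistry but
biodegrade and photodegrade more readily. `degradesign` implements the
computational chain behind that strategy as a tested, reusable R package, for
environmental chemists and modellers who already have the underlying
quantum-chemistry and docking numbers (binding free energies, UV transition
energies, enthalpies) and need the downstream analysis to be reproducible:

* **Composite degradability scoring** (normalization method). Each compound's
  effect value is turned into a dimensionless efficacy coefficient against a
  target value *T* drawn from the data,

  R_{S,i} = min{x*_i, T} / max{x*_i, T}  (or its reciprocal max/min form),

  and the comprehensive evaluation value is the weighted sum
  C_i = w₁·R_{S1,i} + w₂·R_{S2,i} over the biodegradation channel
  (|ΔG_bind| to the degrading enzyme, kJ/mol) and the photodegradation channel
  (first excited-state UV transition energy, eV), default w = (0.5, 0.5).
* **Taguchi L27(3⁷) design analysis** of external biodegradation conditions:
  orthogonal-array construction over GF(3)³, balance/orthogonality validation,
  per-factor level means (main effects), range ("delta") ranking and
  optimal-level selection under a minimization objective, plus the
  binding-affinity improvement metric.
* **Reaction energetics bookkeeping**: ΔG = ΣG(products) − ΣG(reactants),
  barriers ΔE = E(TS) − ΣE(reactants), standard enthalpies
  H°(T) = E + ΔZPE + ΔH_trans + ΔH_rot + ΔH_vib + RT, homolytic P–O bond
  dissociation enthalpies, and pathway-to-pathway total-barrier comparison.
* **Derivative practicality screening**: improvement intensities, the
  biodegradation/photodegradation ratio, functional-property change rates, and
  a six-criterion environment-friendly verdict (score reduced, biodegradation
  up, transition energy down, P–O dissociation enthalpy down, positive minimum
  frequency, HOMO–LUMO gap within tolerance).
* **Solvation comparison** of transition energies across
  {parent, derivative} × {vacuum, solvated}.
* **Seeded synthetic-data generators** that emulate each input's statistical
  structure, so the whole pipeline is testable without external data.

Curated reference tables (22 OPFR homologs, the 27-run condition study, the
derivative prediction/property tables, solvation energies and text-printed
barriers) ship as plain-text fixtures under `inst/extdata/`.

## Worked example

```r
library(degradesign)

compounds <- opfr_compounds()          # 22 OPFRs: ΔG_bind (kJ/mol), E (eV)
scores <- score_table(compounds)       # default "reference-table-reconciled" config
attr(scores, "targets")
#>   biodegradation photodegradation
#>         144.5370           7.2211
head(cbind(scores["compound_id"], round(scores[-1], 3))[order(scores$score), ], 4)
#>  compound_id r_biodegradation r_photodegradation score
#>         TiBP            1.027              0.884 0.956
#>       TDCIPP            1.000              0.988 0.994
#>        BdPhP            1.251              0.748 1.000
#>        TCIPP            1.000              1.000 1.000
```

Both efficacy coefficients equal 1 at the target compound TCIPP; compounds
whose effect values sit far from the targets (e.g. TnPP, C = 8.30) score
worst. The external-condition study ranks the factors by the range of their
level means:

```r
rank_factors(level_means(biodegradation_doe()))
#>        factor     range rank optimal_level
#> 1          ph  8.856222    3             1
#> 2 temperature  8.438556    4             2
#> 3    methanol  6.692333    5             3
#> 4 acetic_acid  2.571444    7             1
#> 5        h2o2 13.099667    1             1
#> 6     voltage  9.995222    2             2
#> 7  surfactant  3.733111    6             3
```

H₂O₂ concentration dominates (rank 1, range 13.1 kJ/mol), acetic acid matters
least. Pathway energetics and the derivative screen:

```r
pathway_compare(pathway("TCPP", 249.4895), pathway("TCPP-OH", 210.2360))
#> total barrier 249.4895 -> 210.2360 kcal/mol (reduction 39.2535, 15.73%)
round(affinity_improvement(62.326, -109.395), 2)
#> [1] 75.52
rep <- evaluate_derivatives(derivative_predictions(), derivative_properties())
rep$derivative_id[rep$pass]
#> [1] "TCPP-OH"  "TCPP-CONH2"  "TCPP-CHO"  "TCPP-PO3H2"
#> [5] "TCEP-PO3H2" "TCEP-COOCH3" "TCEP-SO3H"
```

Seven of the fourteen candidate derivatives pass the environment-friendly
screen; the other seven fail on the flame-retardancy criterion.
`reproduce_reference()` recomputes every number in the shipped fixtures and
reports each comparison.

A thin command-line front end wrapping the same functions is installed at
`system.file("cli", "degradesign.R", package = "degradesign")`, with
subcommands `validate`, `score`, `doe-analyze`, `pathway-compare`,
`evaluate`, `solvation-report`, `simulate` and `reproduce`.

## Methods

See the methods vignette (`vignettes/degradable-derivative-design.Rmd`) for
the model, its assumptions, the orientation/target conventions that the
scoring defaults encode, numerical choices, what the synthetic generators do
and do not emulate, and known limitations — including the handful of printed
reference cells that cannot be reproduced exactly from their printed inputs.
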