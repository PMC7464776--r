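Package: degradesign
Title: Degradability Scoring and Design Analysis for Flame-Retardant Derivatives
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing degradable organophosphorus flame-retardant
    derivatives from computed molecular properties. Implements a
    normalization-based composite degradability score (dimensionless efficacy
    coefficients against a target compound, weighted into a comprehensive
    biodegradation/photodegradation value), Taguchi L27(3^7) orthogonal-array
    construction and main-effects (range) analysis of external biodegradation
    conditions, reaction-pathway energetics bookkeeping (free-energy changes,
    transition-state barriers, standard enthalpies and P-O bond dissociation
    enthalpies), derivative practicality screening with an
    environment-friendly verdict, solvated-versus-vacuum UV transition-energy
    comparison, and seeded synthetic-data generators that emulate each input's
    statistical structure. Curated reference tables for 22 OPFR homologs and
    their candidate derivatives ship as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
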