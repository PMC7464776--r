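# Loaders for the curated reference fixtures shipped under inst/extdata.
# All files are plain CSV transcriptions of published reference tables for
# the 22 OPFR homologs, their candidate derivatives, and the external
# biodegradation condition study; numeric cells keep the printed precision.

fixture_path <- function(file, fixture_dir = NULL) {
  if (is.null(fixture_dir)) {
    p <- system.file("extdata", file, package = "degradesign")
    if (!nzchar(p)) stop("fixture not found: ", file, call. = FALSE)
    p
  } else {
    file.path(fixture_dir, file)
  }
}

read_reference_csv <- function(file, fixture_dir = NULL, id_cols = NULL) {
  raw <- read_delim_chr(fixture_path(file, fixture_dir), ",")
  if (is.null(id_cols)) {
    id_cols <- names(raw)[!vapply(raw, function(col) {
      col <- trimws(normalize_minus(col))
      all(!nzchar(col) | !is.na(suppressWarnings(as.numeric(col))))
    }, logical(1))]
  }
  for (col in setdiff(names(raw), id_cols)) {
    raw[[col]] <- parse_numeric_column(raw[[col]], col)
  }
  raw
}

#' Curated reference tables
#'
#' Accessors for the plain-text fixtures shipped with the package:
#' \describe{
#'   \item{`opfr_compounds()`}{22 OPFR homologs with enzyme binding free
#'     energies (kJ/mol) and first excited-state transition energies (eV).}
#'   \item{`opfr_reference_scores()`}{the printed efficacy coefficients
#'     (3 d.p.) and comprehensive values (2 d.p.) for those 22 compounds.}
#'   \item{`biodegradation_doe()`}{the 27-run L27(3^7) external-condition
#'     study: physical factor settings and binding-free-energy responses.}
#'   \item{`reference_main_effects()`}{the printed per-factor level means
#'     (2 d.p.) and range ranking for that study.}
#'   \item{`derivative_predictions()`}{predicted comprehensive score,
#'     biodegradation activity (-log binding measure) and photodegradation
#'     transition energy for TCPP/TCEP derivatives, with the printed
#'     improvement intensities.}
#'   \item{`derivative_properties()`}{P-O bond dissociation enthalpy
#'     (kcal/mol), HOMO-LUMO gap (eV), total energy (a.u.) and minimum
#'     frequency for the 14 evaluated derivatives, with printed rates.}
#'   \item{`solvation_energies()`}{transition energies of TCPP and TCPP-OH
#'     in vacuum and in implicit hydrogen-peroxide solvent.}
#'   \item{`reference_barriers()`}{the text-printed step barriers
#'     (kcal/mol) of the biodegradation and photodegradation pathways.}
#'   \item{`optimal_binding()`}{binding free energies of TCPP and TCPP-OH
#'     under the optimal external conditions (stored as printed; the TCPP
#'     value is printed without a sign in the source).}
#' }
#'
#' @param fixture_dir directory holding the fixture files; defaults to the
#'   copies installed with the package.
#' @return A data frame (a `compound_table` for `opfr_compounds()`, a
#'   `doe_table` for `biodegradation_doe()`).
#' @name reference_fixtures
NULL

#' @rdname reference_fixtures
#' @export
opfr_compounds <- function(fixture_dir = NULL) {
  read_compound_table(fixture_path("opfr_compounds.csv", fixture_dir))
}

#' @rdname reference_fixtures
#' @export
opfr_reference_scores <- function(fixture_dir = NULL) {
  read_reference_csv("opfr_reference_scores.csv", fixture_dir, "compound_id")
}

#' @rdname reference_fixtures
#' @export
biodegradation_doe <- function(fixture_dir = NULL) {
  read_doe_table(fixture_path("taguchi_runs.csv", fixture_dir),
                 biodegradation_factors())
}

#' @rdname reference_fixtures
#' @export
reference_main_effects <- function(fixture_dir = NULL) {
  read_reference_csv("reference_main_effects.csv", fixture_dir, "factor")
}

#' @rdname reference_fixtures
#' @export
derivative_predictions <- function(fixture_dir = NULL) {
  read_reference_csv("derivative_predictions.csv", fixture_dir,
                     c("compound_id", "parent_id"))
}

#' @rdname reference_fixtures
#' @export
derivative_properties <- function(fixture_dir = NULL) {
  read_reference_csv("derivative_properties.csv", fixture_dir,
                     c("compound_id", "parent_id"))
}

#' @rdname reference_fixtures
#' @export
solvation_energies <- function(fixture_dir = NULL) {
  read_reference_csv("solvation_energies.csv", fixture_dir,
                     c("compound_id", "condition"))
}

#' @rdname reference_fixtures
#' @export
reference_barriers <- function(fixture_dir = NULL) {
  read_reference_csv("reference_barriers.csv", fixture_dir,
                     c("process", "step_label", "compound_id"))
}

#' @rdname reference_fixtures
#' @export
optimal_binding <- function(fixture_dir = NULL) {
  read_reference_csv("optimal_binding.csv", fixture_dir, "compound_id")
}

reference_fixture_files <- c(
  "opfr_compounds.csv", "opfr_reference_scores.csv", "taguchi_runs.csv",
  "reference_main_effects.csv", "derivative_predictions.csv",
  "derivative_properties.csv", "solvation_energies.csv",
  "solvation_reported.csv", "reference_barriers.csv", "optimal_binding.csv"
)

#' Recompute every reference-table quantity and compare to the printed value
#'
#' Runs the whole pipeline on the shipped fixtures: scores the 22-compound
#' table, analyses the 27-run condition study, recomputes pathway-barrier
#' and binding-affinity improvements, derivative change rates and screen
#' verdicts, and the solvation comparisons, then compares every computed
#' number against its printed counterpart. Checks in category `"exact"` must
#' agree after rounding to the printed precision; checks in category
#' `"tolerance"` (quantities the source computed from unrounded internals)
#' must agree within `tol` (percentage points).
#'
#' @param fixture_dir directory with the fixture CSVs; defaults to the
#'   installed copies. An incomplete directory raises an error listing every
#'   missing file before any check runs.
#' @param gap_tolerance energy-gap allowance handed to the screen.
#' @return A data frame with columns `category`, `check`, `expected`,
#'   `computed` and `pass`, one row per compared number.
#' @export
#' @examples
#' checks <- reproduce_reference()
#' table(checks$category, checks$pass)
reproduce_reference <- function(fixture_dir = NULL, gap_tolerance = 5) {
  if (!is.null(fixture_dir)) {
    absent <- reference_fixture_files[
      !file.exists(file.path(fixture_dir, reference_fixture_files))]
    if (length(absent)) {
      stop("missing fixture file(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  }
  rows <- list()
  add <- function(category, check, expected, computed, pass) {
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, check = check, expected = expected,
      computed = computed, pass = pass, stringsAsFactors = FALSE)
  }
  exact <- function(check, expected, computed, digits) {
    add("exact", check, expected, round(computed, digits),
        isTRUE(round(computed, digits) == expected))
  }
  within_tol <- function(check, expected, computed, tol = 0.2) {
    add("tolerance", check, expected, computed,
        isTRUE(abs(computed - expected) <= tol))
  }

  # composite degradability scores for the 22 homologs
  scores <- score_table(opfr_compounds(fixture_dir))
  printed <- opfr_reference_scores(fixture_dir)
  for (i in seq_len(nrow(printed))) {
    id <- printed$compound_id[i]
    got <- scores[scores$compound_id == id, ]
    exact(paste0("score/", id, "/r_biodegradation"),
          printed$r_biodegradation[i], got$r_biodegradation, 3)
    exact(paste0("score/", id, "/r_photodegradation"),
          printed$r_photodegradation[i], got$r_photodegradation, 3)
    exact(paste0("score/", id, "/comprehensive"), printed$score[i],
          got$score, 2)
  }

  # external-condition study: level means and range ranking
  doe <- biodegradation_doe(fixture_dir)
  eff <- level_means(doe)
  ranking <- rank_factors(eff)
  printed_me <- reference_main_effects(fixture_dir)
  for (i in seq_len(nrow(printed_me))) {
    f <- printed_me$factor[i]
    for (l in 1:3) {
      exact(sprintf("doe/level_mean/%s/level%d", f, l),
            printed_me[[paste0("level", l)]][i],
            eff$level_means[f, l], 2)
    }
    exact(paste0("doe/rank/", f), printed_me$ranking[i],
          ranking$rank[ranking$factor == f], 0)
  }

  # pathway barrier reductions
  barr <- reference_barriers(fixture_dir)
  for (proc in unique(barr$process)) {
    b <- barr[barr$process == proc, ]
    ref <- b[is.na(b$reported_reduction_pct), ]
    mod <- b[!is.na(b$reported_reduction_pct), ]
    cmpr <- pathway_compare(pathway(ref$compound_id, ref$barrier),
                            pathway(mod$compound_id, mod$barrier))
    exact(paste0("barrier_reduction/", proc), mod$reported_reduction_pct,
          cmpr$percent_reduction, 2)
  }

  # binding-affinity improvement under optimal conditions
  ob <- optimal_binding(fixture_dir)
  ref <- ob[is.na(ob$reported_improvement_pct), ]
  new <- ob[!is.na(ob$reported_improvement_pct), ]
  exact("affinity_improvement", new$reported_improvement_pct,
        affinity_improvement(ref$binding_free_energy,
                             new$binding_free_energy), 2)

  # derivative functional-property change rates and screen verdicts
  preds <- derivative_predictions(fixture_dir)
  props <- derivative_properties(fixture_dir)
  report <- evaluate_derivatives(preds, props, gap_tolerance)
  for (i in seq_len(nrow(report))) {
    id <- report$derivative_id[i]
    pr <- props[props$compound_id == id, ]
    exact(paste0("rate/", id, "/flame_enhanced"), pr$flame_enhanced_pct,
          report$flame_enhanced_rate[i], 2)
    exact(paste0("rate/", id, "/gap_change"), pr$gap_change_pct,
          report$gap_change_rate[i], 2)
    exact(paste0("rate/", id, "/energy_change"), pr$energy_change_pct,
          report$energy_change_rate[i], 2)
    # printed positive enhanced rate is the screen's discriminating criterion
    add("exact", paste0("screen/", id),
        as.numeric(pr$flame_enhanced_pct > 0), as.numeric(report$pass[i]),
        isTRUE((pr$flame_enhanced_pct > 0) == report$pass[i]))
  }

  # predicted-intensity columns (source used unrounded internals)
  deriv_preds <- preds[!is.na(preds$parent_id) & nzchar(preds$parent_id), ]
  for (i in seq_len(nrow(deriv_preds))) {
    id <- deriv_preds$compound_id[i]
    got <- report[report$derivative_id == id, ]
    if (nrow(got) == 1L) {
      within_tol(paste0("intensity/", id, "/c_reduction"),
                 deriv_preds$c_reduction_pct[i], got$c_reduction)
      within_tol(paste0("intensity/", id, "/b_increase"),
                 deriv_preds$b_increase_pct[i], got$b_increase)
      within_tol(paste0("intensity/", id, "/p_reduction"),
                 deriv_preds$p_reduction_pct[i], got$p_reduction)
    }
    # the printed ratio reproduces exactly from the printed intensity columns
    exact(paste0("ratio/", id), deriv_preds$ratio[i],
          effect_ratio(deriv_preds$b_increase_pct[i],
                       deriv_preds$p_reduction_pct[i]), 2)
  }

  # solvation comparisons
  grid <- solvation_energies(fixture_dir)
  reported <- read_reference_csv("solvation_reported.csv", fixture_dir,
                                 c("reference_compound", "reference_condition",
                                   "compound", "condition"))
  for (i in seq_len(nrow(reported))) {
    e_ref <- grid$transition_energy[
      grid$compound_id == reported$reference_compound[i] &
      grid$condition == reported$reference_condition[i]]
    e_new <- grid$transition_energy[
      grid$compound_id == reported$compound[i] &
      grid$condition == reported$condition[i]]
    within_tol(sprintf("solvation/%s_%s_vs_%s_%s", reported$compound[i],
                       reported$condition[i], reported$reference_compound[i],
                       reported$reference_condition[i]),
               reported$reported_reduction_pct[i],
               transition_reduction(e_ref, e_new))
  }

  out <- do.call(rbind, rows)
  class(out) <- c("reference_checks", "data.frame")
  out
}

#' @export
print.reference_checks <- function(x, ...) {
  n_fail <- sum(!x$pass)
  cat(sprintf("%d reference checks: %d passed, %d failed\n",
              nrow(x), sum(x$pass), n_fail))
  if (n_fail) {
    cat("failing checks:\n")
    print.data.frame(x[!x$pass, ], row.names = FALSE)
  }
  invisible(x)
}
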