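# Energy unit conversions. Canonical internal unit: kcal/mol.
HARTREE_TO_KCAL <- 627.5094740631
KCAL_TO_KJ <- 4.184
R_KCAL <- 1.98720425e-3 # gas constant, kcal mol^-1 K^-1

#' Convert between energy units
#'
#' @param x numeric energies.
#' @param from,to one of `"kcal/mol"`, `"kJ/mol"`, `"hartree"`.
#' @return `x` expressed in `to`.
#' @export
#' @examples
#' convert_energy(1, "hartree", "kcal/mol")
convert_energy <- function(x, from, to) {
  units <- c("kcal/mol" = 1, "kJ/mol" = 1 / KCAL_TO_KJ,
             "hartree" = HARTREE_TO_KCAL)
  if (!from %in% names(units) || !to %in% names(units)) {
    stop("units must be one of: ", paste(names(units), collapse = ", "),
         call. = FALSE)
  }
  x * units[[from]] / units[[to]]
}

#' Reaction free-energy change
#'
#' \eqn{\Delta G = \sum G(\mathrm{products}) - \sum G(\mathrm{reactants})}.
#'
#' @param product_g,reactant_g free energies of the product and reactant
#'   species (same unit, conventionally kcal/mol).
#' @return Scalar \eqn{\Delta G}.
#' @export
reaction_free_energy <- function(product_g, reactant_g) {
  if (length(product_g) == 0L || length(reactant_g) == 0L) {
    stop("product and reactant lists must be non-empty", call. = FALSE)
  }
  sum(product_g) - sum(reactant_g)
}

#' Reaction energy barrier
#'
#' \eqn{\Delta E = E(\mathrm{TS}) - \sum E(\mathrm{reactants})}, the
#' transition-state energy relative to the summed reactant energies. A
#' negative barrier (TS below the reactants) is allowed but flagged with a
#' warning, since it usually indicates inconsistent inputs.
#'
#' @param ts_energy transition-state energy.
#' @param reactant_e reactant energies (non-empty).
#' @return Scalar \eqn{\Delta E} in the input unit.
#' @export
reaction_barrier <- function(ts_energy, reactant_e) {
  if (length(reactant_e) == 0L) {
    stop("reactant list must be non-empty", call. = FALSE)
  }
  de <- ts_energy - sum(reactant_e)
  if (is.finite(de) && de < 0) {
    warning("negative barrier: transition state lies below the reactants")
  }
  de
}

#' Standard enthalpy of a species at temperature T
#'
#' Assembles \eqn{H^\circ(T) = E + \Delta ZPE + \Delta H_{trans} +
#' \Delta H_{rot} + \Delta H_{vib} + RT}. The ideal-gas `RT` term (the
#' conventional PV contribution at standard state) is on by default at
#' 298.15 K and can be disabled.
#'
#' @param electronic_energy electronic energy E, kcal/mol.
#' @param zpe zero-point energy, kcal/mol.
#' @param h_trans,h_rot,h_vib translational, rotational and vibrational
#'   thermal contributions, kcal/mol.
#' @param temperature temperature in K (> 0).
#' @param include_rt include the `R*T` ideal-gas term.
#' @return \eqn{H^\circ(T)} in kcal/mol.
#' @export
#' @examples
#' standard_enthalpy(0) # just R * 298.15 = 0.5925 kcal/mol
standard_enthalpy <- function(electronic_energy, zpe = 0, h_trans = 0,
                              h_rot = 0, h_vib = 0, temperature = 298.15,
                              include_rt = TRUE) {
  if (temperature <= 0) stop("temperature must be > 0 K", call. = FALSE)
  h <- electronic_energy + zpe + h_trans + h_rot + h_vib
  if (include_rt) h <- h + R_KCAL * temperature
  h
}

#' Homolytic bond dissociation enthalpy
#'
#' \eqn{BDE = H(\mathrm{frag}_1) + H(\mathrm{frag}_2) - H(\mathrm{parent})},
#' symmetric in the two fragments. For OPFRs the P-O bond dissociation
#' enthalpy is the flame-retardancy proxy: a lower BDE is read as easier
#' release of the PO radical and hence better flame retardancy.
#'
#' @param parent_h parent-species enthalpy.
#' @param fragment_h1,fragment_h2 fragment enthalpies (same unit as parent).
#' @return Scalar BDE.
#' @export
bond_dissociation_enthalpy <- function(parent_h, fragment_h1, fragment_h2) {
  fragment_h1 + fragment_h2 - parent_h
}

#' Degradation pathway
#'
#' An ordered list of reaction steps with their energy barriers; the total
#' barrier is the sum of the step barriers.
#'
#' @param pathway_id label for the pathway (e.g. the compound it degrades).
#' @param barriers numeric step barriers, kcal/mol, in step order.
#' @param step_labels optional step labels.
#' @return An object of class `pathway`.
#' @export
#' @examples
#' pathway("TCPP", c(249.4895, 120, 80))
pathway <- function(pathway_id, barriers, step_labels = NULL) {
  if (length(barriers) < 1L) stop("a pathway needs at least one step",
                                  call. = FALSE)
  if (is.null(step_labels)) {
    step_labels <- paste0("step", seq_along(barriers))
  }
  stopifnot(length(step_labels) == length(barriers))
  structure(list(pathway_id = pathway_id,
                 steps = data.frame(label = step_labels,
                                    barrier = as.numeric(barriers),
                                    stringsAsFactors = FALSE)),
            class = "pathway")
}

#' Total barrier of a pathway
#' @param p a [pathway()].
#' @return Sum of the step barriers, kcal/mol.
#' @export
total_barrier <- function(p) {
  stopifnot(inherits(p, "pathway"))
  sum(p$steps$barrier)
}

#' Compare a reference pathway against a modified one
#'
#' Aligns steps by ordinal position and reports per-step barrier
#' differences plus the total absolute and percent reduction,
#' `(total_ref - total_mod) / total_ref * 100`. If the pathways have
#' different step counts only the totals are compared (with a warning).
#'
#' @param reference,modified [pathway()] objects.
#' @return A list of class `pathway_comparison`: `steps` (data frame of
#'   aligned barriers and differences, or `NULL`), `total_reference`,
#'   `total_modified`, `reduction` and `percent_reduction`.
#' @export
#' @examples
#' cmp <- pathway_compare(pathway("TCPP", 249.4895),
#'                        pathway("TCPP-OH", 210.2360))
#' round(cmp$percent_reduction, 2) # 15.73
pathway_compare <- function(reference, modified) {
  stopifnot(inherits(reference, "pathway"), inherits(modified, "pathway"))
  tr <- total_barrier(reference)
  tm <- total_barrier(modified)
  if (tr == 0) stop("reference pathway has zero total barrier", call. = FALSE)
  steps <- NULL
  if (nrow(reference$steps) == nrow(modified$steps)) {
    steps <- data.frame(step = reference$steps$label,
                        reference = reference$steps$barrier,
                        modified = modified$steps$barrier,
                        difference = reference$steps$barrier -
                          modified$steps$barrier,
                        stringsAsFactors = FALSE)
  } else {
    warning("pathways have different step counts; comparing totals only")
  }
  structure(list(reference_id = reference$pathway_id,
                 modified_id = modified$pathway_id,
                 steps = steps,
                 total_reference = tr,
                 total_modified = tm,
                 reduction = tr - tm,
                 percent_reduction = (tr - tm) / tr * 100),
            class = "pathway_comparison")
}

#' @export
print.pathway_comparison <- function(x, digits = 2, ...) {
  cat(sprintf("Pathway comparison: %s vs %s\n", x$reference_id, x$modified_id))
  if (!is.null(x$steps)) print(x$steps)
  cat(sprintf("total barrier %.4f -> %.4f kcal/mol (reduction %.4f, %.*f%%)\n",
              x$total_reference, x$total_modified, x$reduction,
              digits, x$percent_reduction))
  invisible(x)
}
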