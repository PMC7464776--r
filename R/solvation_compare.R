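#' Percent reduction in UV transition energy
#'
#' `(e_reference - e_other) / e_reference * 100`. Lower first excited-state
#' transition energies proxy easier photodegradation, so a positive
#' reduction means the `other` condition/compound photodegrades more
#' readily.
#'
#' @param e_reference reference transition energy, eV (> 0).
#' @param e_other compared transition energy, eV.
#' @return Percent reduction. Vectorized.
#' @export
#' @examples
#' transition_reduction(7.29, 4.07) # 44.17...
transition_reduction <- function(e_reference, e_other) {
  if (any(e_reference <= 0)) {
    stop("reference transition energy must be positive", call. = FALSE)
  }
  (e_reference - e_other) / e_reference * 100
}

#' Solvation-effect comparison of transition energies
#'
#' Given a grid of first excited-state transition energies for a parent and
#' a derivative compound under vacuum and solvated (implicit-solvent)
#' conditions, reports the four pairwise percent reductions: derivative vs
#' parent within each condition, and solvated vs vacuum within each
#' compound.
#'
#' @param grid data frame with columns `compound_id`,
#'   `condition` (`"vacuum"` or `"solvated"`) and `transition_energy` (eV).
#' @param parent,derivative compound ids present in the grid.
#' @return Data frame of class `solvation_report` with columns `comparison`,
#'   `reference_energy`, `energy` and `reduction_pct`.
#' @export
#' @examples
#' solvation_report(solvation_energies(), "TCPP", "TCPP-OH")
solvation_report <- function(grid, parent, derivative) {
  grid <- as.data.frame(grid)
  stopifnot(all(c("compound_id", "condition", "transition_energy")
                %in% names(grid)))
  cell <- function(id, cond) {
    v <- grid$transition_energy[grid$compound_id == id &
                                grid$condition == cond]
    if (length(v) != 1L || is.na(v)) {
      stop(sprintf("missing transition energy for (%s, %s)", id, cond),
           call. = FALSE)
    }
    v
  }
  pv <- cell(parent, "vacuum");   ps <- cell(parent, "solvated")
  dv <- cell(derivative, "vacuum"); ds <- cell(derivative, "solvated")
  out <- data.frame(
    comparison = c(
      sprintf("%s vs %s (vacuum)", derivative, parent),
      sprintf("%s vs %s (solvated)", derivative, parent),
      sprintf("%s solvated vs vacuum", parent),
      sprintf("%s solvated vs vacuum", derivative)
    ),
    reference_energy = c(pv, ps, pv, dv),
    energy = c(dv, ds, ps, ds),
    stringsAsFactors = FALSE
  )
  out$reduction_pct <- transition_reduction(out$reference_energy, out$energy)
  class(out) <- c("solvation_report", "data.frame")
  out
}
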