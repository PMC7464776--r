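#' Percent reduction of a value
#'
#' `(old - new) / old * 100`; positive when the value dropped. This is also
#' the "enhanced rate" convention for flame retardancy, where a lower P-O
#' dissociation enthalpy counts as an enhancement.
#'
#' @param old,new old and new values; `old` must be nonzero. Vectorized.
#' @return Percent reduction (negative = increase).
#' @export
#' @examples
#' reduction_intensity(225.72, 209.57) # 7.15...
reduction_intensity <- function(old, new) {
  if (any(old == 0)) stop("old value must be nonzero", call. = FALSE)
  (old - new) / old * 100
}

#' Percent increase of a value
#'
#' `(new - old) / old * 100`.
#' @inheritParams reduction_intensity
#' @return Percent increase.
#' @export
increase_intensity <- function(old, new) {
  if (any(old == 0)) stop("old value must be nonzero", call. = FALSE)
  (new - old) / old * 100
}

#' Signed percent change rate
#'
#' `(new - old) / |old| * 100`. The magnitude denominator keeps the sign of
#' the raw change for quantities that are themselves negative (total
#' electronic energies in a.u.), matching the reporting convention of the
#' reference derivative-property table; for positive quantities it
#' coincides with [increase_intensity()].
#'
#' @inheritParams reduction_intensity
#' @return Signed percent change.
#' @export
#' @examples
#' change_rate(5.38, 5.15)          # -4.28...
#' change_rate(-1023.57, -1536.08)  # -50.07...
change_rate <- function(old, new) {
  if (any(old == 0)) stop("old value must be nonzero", call. = FALSE)
  (new - old) / abs(old) * 100
}

#' Biodegradation/photodegradation improvement ratio
#'
#' Ratio of the biodegradation increase to the photodegradation-energy
#' reduction, both in percent. Near 1 means the two channels improved in
#' step, mirroring the 50/50 weighting of the composite score.
#'
#' @param biodeg_increase percent increase of the predicted biodegradation
#'   activity.
#' @param photodeg_reduction percent reduction of the predicted transition
#'   energy; must be nonzero.
#' @return Dimensionless ratio.
#' @export
effect_ratio <- function(biodeg_increase, photodeg_reduction) {
  if (any(photodeg_reduction == 0)) {
    stop("photodegradation reduction must be nonzero", call. = FALSE)
  }
  biodeg_increase / photodeg_reduction
}

screen_criteria <- c("score_reduced", "biodegradation_increased",
                     "photodegradation_reduced", "flame_retardancy_enhanced",
                     "structure_stable", "insulation_maintained")

#' Environment-friendly derivative screen
#'
#' A derivative passes the screen when all six criteria hold:
#' \enumerate{
#'   \item the comprehensive evaluation value decreased (`c_derivative <
#'     c_parent`);
#'   \item the predicted biodegradation activity increased;
#'   \item the predicted photodegradation transition energy decreased;
#'   \item flame retardancy is enhanced, i.e. the P-O bond dissociation
#'     enthalpy decreased (enhanced rate > 0);
#'   \item the minimum vibrational frequency is positive (a true minimum,
#'     structurally stable);
#'   \item the HOMO-LUMO gap (insulation proxy) did not drop by more than
#'     `gap_tolerance` percent.
#' }
#' The screen is monotone: worsening any single input never flips a fail
#' into a pass.
#'
#' @param cmp a data frame (one row per parent/derivative comparison) with
#'   columns `c_parent`, `c_derivative`, `b_parent`, `b_derivative`,
#'   `p_parent`, `p_derivative`, `flame_parent`, `flame_derivative`,
#'   `gap_parent`, `gap_derivative`, `min_frequency`, and optionally
#'   `derivative_id`.
#' @param gap_tolerance allowed percent drop in the energy gap (default 5).
#' @return `cmp`'s identifier columns plus one logical column per criterion
#'   and a `pass` column.
#' @export
screen_environment_friendly <- function(cmp, gap_tolerance = 5) {
  cmp <- as.data.frame(cmp)
  needed <- c("c_parent", "c_derivative", "b_parent", "b_derivative",
              "p_parent", "p_derivative", "flame_parent", "flame_derivative",
              "gap_parent", "gap_derivative", "min_frequency")
  criterion_of <- c(c_parent = "score_reduced", c_derivative = "score_reduced",
                    b_parent = "biodegradation_increased",
                    b_derivative = "biodegradation_increased",
                    p_parent = "photodegradation_reduced",
                    p_derivative = "photodegradation_reduced",
                    flame_parent = "flame_retardancy_enhanced",
                    flame_derivative = "flame_retardancy_enhanced",
                    gap_parent = "insulation_maintained",
                    gap_derivative = "insulation_maintained",
                    min_frequency = "structure_stable")
  missing <- setdiff(needed, names(cmp))
  if (length(missing)) {
    stop("missing field(s) ", paste(missing, collapse = ", "),
         " required by criterion ",
         paste(unique(criterion_of[missing]), collapse = ", "), call. = FALSE)
  }
  if (anyNA(cmp[needed])) {
    bad <- needed[vapply(cmp[needed], anyNA, logical(1))]
    stop("NA in field(s) ", paste(bad, collapse = ", "),
         " required by criterion ",
         paste(unique(criterion_of[bad]), collapse = ", "), call. = FALSE)
  }
  out <- cmp[intersect(c("parent_id", "derivative_id"), names(cmp))]
  out$score_reduced <- cmp$c_derivative < cmp$c_parent
  out$biodegradation_increased <- cmp$b_derivative > cmp$b_parent
  out$photodegradation_reduced <- cmp$p_derivative < cmp$p_parent
  out$flame_retardancy_enhanced <-
    reduction_intensity(cmp$flame_parent, cmp$flame_derivative) > 0
  out$structure_stable <- cmp$min_frequency > 0
  out$insulation_maintained <-
    change_rate(cmp$gap_parent, cmp$gap_derivative) >= -gap_tolerance
  out$pass <- Reduce(`&`, out[screen_criteria])
  out
}

#' Evaluate candidate derivatives against their parents
#'
#' Joins a prediction table (comprehensive score, biodegradation activity,
#' photodegradation transition energy) with a functional-property table
#' (P-O dissociation enthalpy, HOMO-LUMO gap, total energy, minimum
#' frequency), recomputes all improvement intensities and change rates from
#' the given values, and applies the environment-friendly screen. Parent
#' compounds are the rows whose `parent_id` is empty/NA.
#'
#' @param predictions data frame with columns `compound_id`, `parent_id`,
#'   `c_pred`, `b_pred`, `p_pred` (see [derivative_predictions()]).
#' @param properties data frame with columns `compound_id`, `parent_id`,
#'   `flame_retardancy`, `energy_gap`, `total_energy`, `min_frequency`
#'   (see [derivative_properties()]). Only derivatives present here are
#'   evaluated.
#' @param gap_tolerance allowed percent drop in the energy gap.
#' @return A data frame with one row per evaluated derivative: recomputed
#'   `c_reduction`, `b_increase`, `p_reduction`, `ratio`,
#'   `flame_enhanced_rate`, `gap_change_rate`, `energy_change_rate`, the six
#'   screen booleans and `pass`.
#' @export
#' @examples
#' rep <- evaluate_derivatives(derivative_predictions(), derivative_properties())
#' rep[rep$pass, "derivative_id"]
evaluate_derivatives <- function(predictions, properties, gap_tolerance = 5) {
  is_parent <- function(df) is.na(df$parent_id) | !nzchar(df$parent_id)
  pred_parents <- predictions[is_parent(predictions), ]
  prop_parents <- properties[is_parent(properties), ]
  deriv <- properties[!is_parent(properties), ]
  rows <- lapply(seq_len(nrow(deriv)), function(i) {
    id <- deriv$compound_id[i]
    parent <- deriv$parent_id[i]
    p_pred <- predictions[predictions$compound_id == id, ]
    if (nrow(p_pred) != 1L) {
      stop("no prediction row for derivative ", id, call. = FALSE)
    }
    par_pred <- pred_parents[pred_parents$compound_id == parent, ]
    par_prop <- prop_parents[prop_parents$compound_id == parent, ]
    if (nrow(par_pred) != 1L || nrow(par_prop) != 1L) {
      stop("no parent rows for ", parent, call. = FALSE)
    }
    b_inc <- increase_intensity(par_pred$b_pred, p_pred$b_pred)
    p_red <- reduction_intensity(par_pred$p_pred, p_pred$p_pred)
    data.frame(
      parent_id = parent, derivative_id = id,
      c_reduction = reduction_intensity(par_pred$c_pred, p_pred$c_pred),
      b_increase = b_inc,
      p_reduction = p_red,
      ratio = effect_ratio(b_inc, p_red),
      flame_enhanced_rate = reduction_intensity(par_prop$flame_retardancy,
                                                deriv$flame_retardancy[i]),
      gap_change_rate = change_rate(par_prop$energy_gap, deriv$energy_gap[i]),
      energy_change_rate = change_rate(par_prop$total_energy,
                                       deriv$total_energy[i]),
      c_parent = par_pred$c_pred, c_derivative = p_pred$c_pred,
      b_parent = par_pred$b_pred, b_derivative = p_pred$b_pred,
      p_parent = par_pred$p_pred, p_derivative = p_pred$p_pred,
      flame_parent = par_prop$flame_retardancy,
      flame_derivative = deriv$flame_retardancy[i],
      gap_parent = par_prop$energy_gap, gap_derivative = deriv$energy_gap[i],
      min_frequency = deriv$min_frequency[i],
      stringsAsFactors = FALSE
    )
  })
  joined <- do.call(rbind, rows)
  verdict <- screen_environment_friendly(joined, gap_tolerance)
  cbind(joined[, c("parent_id", "derivative_id", "c_reduction", "b_increase",
                   "p_reduction", "ratio", "flame_enhanced_rate",
                   "gap_change_rate", "energy_change_rate")],
        verdict[, c(screen_criteria, "pass")])
}
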