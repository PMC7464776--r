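#' Target-selection policy for the normalization score
#'
#' The normalization method measures every compound against a target (ideal)
#' value `T` taken from the data themselves. Two policies are supported:
#' `reference_compound` takes the value of a designated compound (the default
#' configuration uses TCIPP, whose binding-free-energy magnitude is also the
#' lower median of the 22 reference magnitudes and whose transition energy is
#' the upper median of the 22 energies), while `order_statistic` takes the
#' k-th value of the ascending sorted (magnitude) data for tables without a
#' designated reference.
#'
#' @param mode `"reference_compound"` or `"order_statistic"`.
#' @param reference_id compound label; required when
#'   `mode = "reference_compound"`.
#' @param order_index 1-based rank into the ascending sorted values; required
#'   when `mode = "order_statistic"`.
#' @return An object of class `target_policy`.
#' @export
#' @examples
#' target_policy("reference_compound", reference_id = "TCIPP")
#' target_policy("order_statistic", order_index = 11)
target_policy <- function(mode = c("reference_compound", "order_statistic"),
                          reference_id = NULL, order_index = NULL) {
  mode <- match.arg(mode)
  if (mode == "reference_compound") {
    if (is.null(reference_id)) {
      stop("reference_compound mode requires reference_id", call. = FALSE)
    }
    order_index <- NULL
  } else {
    if (is.null(order_index)) {
      stop("order_statistic mode requires order_index", call. = FALSE)
    }
    order_index <- as.integer(order_index)
    reference_id <- NULL
  }
  structure(list(mode = mode, reference_id = reference_id,
                 order_index = order_index),
            class = "target_policy")
}

#' Select the target value for one effect channel
#'
#' @param values numeric effect values, one per compound.
#' @param policy a [target_policy()].
#' @param ids compound labels aligned with `values`; required for
#'   `reference_compound` mode.
#' @param use_magnitude apply `abs()` before target selection (and hence
#'   return the target on the magnitude scale).
#' @return The target value `T` (scalar).
#' @export
#' @examples
#' select_target(c(-41.8, -144.5, -123.7), target_policy("order_statistic", order_index = 2),
#'               use_magnitude = TRUE)
select_target <- function(values, policy, ids = NULL, use_magnitude = FALSE) {
  stopifnot(inherits(policy, "target_policy"))
  if (length(values) == 0L) stop("empty value list", call. = FALSE)
  if (use_magnitude) values <- abs(values)
  if (policy$mode == "reference_compound") {
    if (is.null(ids)) stop("reference_compound mode needs ids", call. = FALSE)
    i <- match(policy$reference_id, ids)
    if (is.na(i)) {
      stop("unknown reference_id: ", policy$reference_id, call. = FALSE)
    }
    values[i]
  } else {
    k <- policy$order_index
    if (k < 1L || k > length(values)) {
      stop(sprintf("order_index %d outside [1, %d]", k, length(values)),
           call. = FALSE)
    }
    sort(values)[k]
  }
}

#' Dimensionless efficacy coefficient
#'
#' Ratio of an effect value to the target value `T`. `ratio_le1` is the
#' min/max form, bounded in (0, 1]; `ratio_ge1` is the max/min form, in
#' \eqn{[1, \infty)}. Either form equals 1 exactly when `x = T`, and the two
#' are mutual reciprocals. Inputs must be positive (apply magnitudes
#' beforehand for signed quantities such as binding free energies).
#'
#' @param x positive effect value(s); vectorized.
#' @param target positive target value `T`.
#' @param orientation `"ratio_le1"` (min/max) or `"ratio_ge1"` (max/min).
#' @return Dimensionless coefficient(s), same length as `x`.
#' @export
#' @examples
#' efficacy_coefficient(41.842, 144.537, "ratio_ge1") # 3.454...
#' efficacy_coefficient(4.3292, 7.2211, "ratio_le1")  # 0.599...
efficacy_coefficient <- function(x, target,
                                 orientation = c("ratio_le1", "ratio_ge1")) {
  orientation <- match.arg(orientation)
  if (any(!is.finite(x)) || any(x <= 0) || !is.finite(target) || target <= 0) {
    stop("efficacy_coefficient requires positive finite x and target",
         call. = FALSE)
  }
  if (orientation == "ratio_le1") {
    pmin(x, target) / pmax(x, target)
  } else {
    pmax(x, target) / pmin(x, target)
  }
}

check_weights <- function(weights, n_effects) {
  if (length(weights) != n_effects) {
    stop(sprintf("expected %d weights, got %d", n_effects, length(weights)),
         call. = FALSE)
  }
  if (any(weights < 0 | weights > 1)) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-12) {
    stop("weights must sum to 1 (within 1e-12)", call. = FALSE)
  }
  invisible(weights)
}

#' Comprehensive evaluation value
#'
#' Weighted sum of a compound's efficacy coefficients across effect
#' channels. Under the default equal weights (0.5/0.5) it combines the
#' biodegradation and photodegradation channels into the composite
#' degradability score `C`; lower `C` is read as better degradability.
#'
#' @param coefficients numeric vector of coefficients for one compound, or a
#'   matrix with one row per compound and one column per effect.
#' @param weights weights in `[0, 1]` summing to 1, one per effect.
#' @return Scalar (or per-row vector) comprehensive value.
#' @export
#' @examples
#' comprehensive_score(c(3.454, 0.991), c(0.5, 0.5))
comprehensive_score <- function(coefficients, weights = NULL) {
  if (is.matrix(coefficients)) {
    k <- ncol(coefficients)
    if (is.null(weights)) weights <- rep(1 / k, k)
    check_weights(weights, k)
    drop(coefficients %*% weights)
  } else {
    k <- length(coefficients)
    if (is.null(weights)) weights <- rep(1 / k, k)
    check_weights(weights, k)
    sum(coefficients * weights)
  }
}

#' Specify one effect channel
#'
#' @param name short channel name used for the output column (`r_<name>`).
#' @param field the `compound_table` column the channel reads.
#' @param use_magnitude take `abs()` before forming ratios (needed for
#'   negative binding free energies).
#' @param orientation coefficient orientation, see [efficacy_coefficient()].
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(name, field, use_magnitude = FALSE,
                        orientation = c("ratio_le1", "ratio_ge1")) {
  structure(list(name = name, field = field,
                 use_magnitude = use_magnitude,
                 orientation = match.arg(orientation)),
            class = "effect_spec")
}

#' Default effect channels for OPFR degradability scoring
#'
#' The "reference-table-reconciled" configuration: the biodegradation channel
#' reads binding free energies as magnitudes with the max/min (`ratio_ge1`)
#' orientation, and the photodegradation channel reads transition energies
#' with the min/max (`ratio_le1`) orientation. This is the one configuration
#' that reproduces both printed coefficient columns of the curated reference
#' table from a single target rule.
#'
#' @return List of two [effect_spec()] objects.
#' @export
default_effects <- function() {
  list(
    effect_spec("biodegradation", "binding_free_energy",
                use_magnitude = TRUE, orientation = "ratio_ge1"),
    effect_spec("photodegradation", "transition_energy",
                use_magnitude = FALSE, orientation = "ratio_le1")
  )
}

#' Score a compound table
#'
#' Computes per-compound efficacy coefficients for every effect channel and
#' the weighted comprehensive evaluation value. Internal arithmetic is
#' unrounded; the conventional report precision is 3 decimals for
#' coefficients and 2 for the comprehensive value.
#'
#' @param compounds a `compound_table` (see [read_compound_table()]).
#' @param effects list of [effect_spec()]; defaults to [default_effects()].
#' @param policies a single [target_policy()] applied to every effect, or a
#'   list with one policy per effect.
#' @param weights effect weights; default equal.
#' @return A data frame of class `score_table`: `compound_id`, one
#'   `r_<effect>` column per channel, and `score`. The targets used per
#'   channel are attached as the `targets` attribute.
#' @export
#' @examples
#' tab <- read_compound_table(system.file("extdata", "opfr_compounds.csv",
#'                                        package = "degradesign"))
#' scores <- score_table(tab)
#' round(scores[scores$compound_id == "TCPP", -1], 3)
score_table <- function(compounds,
                        effects = default_effects(),
                        policies = target_policy("reference_compound",
                                                 reference_id = "TCIPP"),
                        weights = rep(1 / length(effects), length(effects))) {
  stopifnot(nrow(compounds) >= 1L)
  if (inherits(policies, "target_policy")) {
    policies <- rep(list(policies), length(effects))
  }
  stopifnot(length(policies) == length(effects))
  check_weights(weights, length(effects))

  coefs <- matrix(NA_real_, nrow = nrow(compounds), ncol = length(effects))
  targets <- numeric(length(effects))
  for (j in seq_along(effects)) {
    eff <- effects[[j]]
    if (!eff$field %in% names(compounds)) {
      stop("effect '", eff$name, "' reads missing field '", eff$field, "'",
           call. = FALSE)
    }
    x <- compounds[[eff$field]]
    if (eff$use_magnitude) x <- abs(x)
    targets[j] <- select_target(x, policies[[j]], ids = compounds$compound_id)
    coefs[, j] <- efficacy_coefficient(x, targets[j], eff$orientation)
  }
  names(targets) <- vapply(effects, `[[`, character(1), "name")

  out <- data.frame(compound_id = compounds$compound_id,
                    stringsAsFactors = FALSE)
  for (j in seq_along(effects)) {
    out[[paste0("r_", effects[[j]]$name)]] <- coefs[, j]
  }
  out$score <- comprehensive_score(coefs, weights)
  attr(out, "targets") <- targets
  attr(out, "weights") <- weights
  class(out) <- c("score_table", "data.frame")
  out
}
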