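# Run code under a fixed seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles all knobs of the synthetic-data generators. Defaults emulate the
#' curated reference data: binding-free-energy magnitudes are log-normal with
#' a median of `binding_mean` kJ/mol (the reference magnitudes span roughly
#' 9-270 kJ/mol), transition energies are normal truncated at zero (reference
#' range roughly 4.3-8.3 eV), and factorial responses are additive planted
#' main effects around a grand mean of about -77 kJ/mol plus Gaussian noise.
#' Every generator is a pure function of its configuration: the same seed
#' reproduces the same output bit-for-bit.
#'
#' @param seed integer RNG seed.
#' @param n_compounds number of compounds to generate (>= 2).
#' @param binding_mean median binding-free-energy magnitude, kJ/mol.
#' @param binding_spread log-scale SD of the magnitudes (0 = degenerate).
#' @param energy_mean,energy_spread mean and SD of the transition energies,
#'   eV (truncated below at 0).
#' @param doe_grand_mean grand mean of factorial responses, kJ/mol.
#' @param planted_effects named list, one entry per design factor, each a
#'   length-3 numeric vector of level offsets summing to 0 (kJ/mol).
#' @param noise_sd response noise SD, kJ/mol (>= 0).
#' @param pathway_steps number of steps per generated pathway (>= 1).
#' @param barrier_range range (kcal/mol) the step barriers are drawn from.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_compounds = 22L,
                              binding_mean = 100,
                              binding_spread = 0.9,
                              energy_mean = 6.5,
                              energy_spread = 1.2,
                              doe_grand_mean = -77,
                              planted_effects = NULL,
                              noise_sd = 3,
                              pathway_steps = 3L,
                              barrier_range = c(150, 420)) {
  stopifnot(binding_spread >= 0, energy_spread >= 0, noise_sd >= 0,
            binding_mean > 0, energy_mean > 0, pathway_steps >= 1,
            length(barrier_range) == 2L, barrier_range[1] > 0,
            diff(barrier_range) >= 0)
  if (n_compounds < 2) stop("n_compounds must be >= 2", call. = FALSE)
  if (!is.null(planted_effects)) {
    ok <- vapply(planted_effects,
                 function(d) length(d) == 3L && abs(sum(d)) < 1e-8,
                 logical(1))
    if (!all(ok)) {
      stop("each planted effect must be 3 offsets summing to 0", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
                 binding_mean = binding_mean, binding_spread = binding_spread,
                 energy_mean = energy_mean, energy_spread = energy_spread,
                 doe_grand_mean = doe_grand_mean,
                 planted_effects = planted_effects, noise_sd = noise_sd,
                 pathway_steps = as.integer(pathway_steps),
                 barrier_range = barrier_range),
            class = "simulation_config")
}

#' Generate a synthetic compound property table
#'
#' Binding free energies are drawn negative with log-normal magnitude;
#' transition energies are normal truncated at zero (redrawn until
#' positive). With zero spreads every compound takes exactly the central
#' value, so downstream scoring degenerates to all-ones coefficients.
#'
#' @param cfg a [simulation_config()].
#' @return A `compound_table` with `n_compounds` rows.
#' @export
#' @examples
#' tab <- gen_compound_table(simulation_config(seed = 7, n_compounds = 22))
#' head(score_table(tab, policies = target_policy("order_statistic", order_index = 11)))
gen_compound_table <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_compounds
  with_seed(cfg$seed, {
    binding <- -stats::rlnorm(n, meanlog = log(cfg$binding_mean),
                              sdlog = cfg$binding_spread)
    energy <- stats::rnorm(n, cfg$energy_mean, cfg$energy_spread)
    while (any(energy <= 0)) {
      i <- energy <= 0
      energy[i] <- stats::rnorm(sum(i), cfg$energy_mean, cfg$energy_spread)
    }
    out <- data.frame(compound_id = sprintf("CMP%02d", seq_len(n)),
                      binding_free_energy = binding,
                      transition_energy = energy,
                      stringsAsFactors = FALSE)
    class(out) <- c("compound_table", "data.frame")
    out
  })
}

#' Generate a synthetic factorial response with planted main effects
#'
#' For each run, `y = grand_mean + sum of the planted level offsets +
#' Gaussian noise`. With `noise_sd = 0` the level means recover the planted
#' offsets exactly on a balanced design.
#'
#' @param design a `taguchi_design` (or `doe_table`) whose column names key
#'   `cfg$planted_effects`; factors without a planted entry get zero offsets.
#' @param cfg a [simulation_config()].
#' @return Numeric response vector, one value per run.
#' @export
#' @examples
#' d <- taguchi_l27(7)
#' cfg <- simulation_config(seed = 3, planted_effects = list(A = c(-5, 0, 5)))
#' y <- gen_doe_response(d, cfg)
#' rank_factors(level_means(d, y))
gen_doe_response <- function(design, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (inherits(design, "doe_table")) design <- design$design
  m <- unclass(as.matrix(design))
  fnames <- colnames(m)
  deltas <- matrix(0, nrow = 3, ncol = ncol(m))
  if (!is.null(cfg$planted_effects)) {
    unknown <- setdiff(names(cfg$planted_effects), fnames)
    if (length(unknown)) {
      stop("planted effect for unknown factor(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (f in names(cfg$planted_effects)) {
      deltas[, match(f, fnames)] <- cfg$planted_effects[[f]]
    }
  }
  signal <- vapply(seq_len(nrow(m)), function(r) {
    sum(deltas[cbind(m[r, ], seq_len(ncol(m)))])
  }, numeric(1))
  with_seed(cfg$seed,
            cfg$doe_grand_mean + signal +
              stats::rnorm(nrow(m), 0, cfg$noise_sd))
}

#' Generate a reference/modified pathway pair with known barrier reduction
#'
#' The reference pathway's step barriers are drawn uniformly from
#' `cfg$barrier_range`; the modified pathway scales every step by
#' `1 - reduction_pct/100`, so the true total-barrier percent reduction is
#' `reduction_pct` by construction.
#'
#' @param cfg a [simulation_config()].
#' @param reduction_pct planted total-barrier percent reduction.
#' @return List with elements `reference`, `modified` (both [pathway()]) and
#'   `true_reduction_pct`.
#' @export
#' @examples
#' pair <- gen_pathway_pair(simulation_config(seed = 2), reduction_pct = 15.73)
#' pathway_compare(pair$reference, pair$modified)$percent_reduction
gen_pathway_pair <- function(cfg, reduction_pct = 15.73) {
  stopifnot(inherits(cfg, "simulation_config"), reduction_pct < 100)
  with_seed(cfg$seed, {
    ref <- stats::runif(cfg$pathway_steps,
                        cfg$barrier_range[1], cfg$barrier_range[2])
    list(reference = pathway("reference", ref),
         modified = pathway("modified", ref * (1 - reduction_pct / 100)),
         true_reduction_pct = reduction_pct)
  })
}
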