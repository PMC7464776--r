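#' Construct an L27(3^n) Taguchi orthogonal array
#'
#' Builds the 27-run three-level orthogonal array by evaluating ternary
#' linear functionals over GF(3)^3: the 27 runs are the points (a, b, c) of a
#' three-dimensional ternary vector space (a slowest-varying), and the 13
#' available columns are the 13 distinct nonzero functionals up to scalar
#' multiples, taken in the canonical order a, b, a+b, a+2b, c, a+c, a+2c,
#' b+c, b+2c, a+b+c, a+b+2c, a+2b+c, a+2b+2c. Any two such columns are
#' linearly independent, which forces pairwise orthogonality: every ordered
#' pair of levels occurs exactly 3 times in every column pair, and every
#' level 9 times per column.
#'
#' @param n_factors number of design columns to take, between 1 and 13.
#' @param factor_names optional column names (defaults to LETTERS).
#' @return A 27 x `n_factors` integer matrix of level indices in {1, 2, 3},
#'   of class `taguchi_design`.
#' @export
#' @examples
#' d <- taguchi_l27(7)
#' colSums(d == 1) # each level appears 9 times per column
taguchi_l27 <- function(n_factors, factor_names = NULL) {
  if (!is.numeric(n_factors) || length(n_factors) != 1L ||
      n_factors < 1 || n_factors > 13) {
    stop("n_factors must be an integer in [1, 13]", call. = FALSE)
  }
  n_factors <- as.integer(n_factors)
  # coefficient vectors (alpha, beta, gamma) of the 13 canonical functionals
  functionals <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 2, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 0, 2), c(0, 1, 1), c(0, 1, 2),
    c(1, 1, 1), c(1, 1, 2), c(1, 2, 1), c(1, 2, 2)
  )
  i <- 0:26
  points <- cbind(i %/% 9L, (i %/% 3L) %% 3L, i %% 3L)
  m <- (points %*% t(functionals[seq_len(n_factors), , drop = FALSE])) %% 3L + 1L
  storage.mode(m) <- "integer"
  if (is.null(factor_names)) factor_names <- LETTERS[seq_len(n_factors)]
  dimnames(m) <- list(NULL, factor_names)
  as_taguchi_design(m)
}

as_taguchi_design <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (!all(m %in% 1:3)) {
    stop("a taguchi_design holds level indices in {1, 2, 3}", call. = FALSE)
  }
  structure(m, class = c("taguchi_design", class(m)))
}

#' Validate balance and pairwise orthogonality of a level matrix
#'
#' Checks, by explicit counting, that every level appears `runs/3` times in
#' every column and that every ordered level pair appears `runs/9` times in
#' every column pair.
#'
#' @param design level-index matrix (values in {1, 2, 3}).
#' @return `TRUE` invisibly if valid, otherwise an error describing the first
#'   violated property.
#' @export
validate_orthogonal_array <- function(design) {
  m <- unclass(as.matrix(design))
  runs <- nrow(m)
  if (runs %% 9L != 0L) stop("run count must be a multiple of 9", call. = FALSE)
  per_level <- runs / 3L
  per_pair <- runs / 9L
  for (j in seq_len(ncol(m))) {
    counts <- tabulate(m[, j], nbins = 3L)
    if (any(counts != per_level)) {
      stop(sprintf("column %d is unbalanced: level counts %s", j,
                   paste(counts, collapse = "/")), call. = FALSE)
    }
  }
  if (ncol(m) >= 2L) {
    for (j in seq_len(ncol(m) - 1L)) {
      for (k in (j + 1L):ncol(m)) {
        combo <- (m[, j] - 1L) * 3L + m[, k]
        counts <- tabulate(combo, nbins = 9L)
        if (any(counts != per_pair)) {
          stop(sprintf("columns %d and %d are not orthogonal", j, k),
               call. = FALSE)
        }
      }
    }
  }
  invisible(TRUE)
}

#' Is a level matrix a balanced orthogonal array?
#'
#' Predicate form of [validate_orthogonal_array()].
#' @param design level-index matrix.
#' @return Logical scalar.
#' @export
is_orthogonal_array <- function(design) {
  !inherits(try(validate_orthogonal_array(design), silent = TRUE), "try-error")
}

#' Per-factor level means (main effects)
#'
#' For every factor and level, the arithmetic mean of the response over the
#' runs at that level. On a balanced design the mean of a factor's three
#' level means equals the grand mean.
#'
#' @param design a `taguchi_design` level matrix or a `doe_table`.
#' @param response numeric response vector (kJ/mol binding free energies in
#'   the reference study), one value per run. Taken from the `doe_table`
#'   when omitted.
#' @return An object of class `main_effects`: list with `level_means`
#'   (factors x 3 matrix), `grand_mean`, and `factor_names`.
#' @export
#' @examples
#' d <- taguchi_l27(3)
#' level_means(d, rowSums(unclass(d)))
level_means <- function(design, response = NULL) {
  if (inherits(design, "doe_table")) {
    if (is.null(response)) response <- design$response
    design <- design$design
  }
  m <- unclass(as.matrix(design))
  if (is.null(response)) stop("response is required", call. = FALSE)
  if (length(response) != nrow(m)) {
    stop(sprintf("response length %d != %d runs", length(response), nrow(m)),
         call. = FALSE)
  }
  fnames <- colnames(m)
  if (is.null(fnames)) fnames <- LETTERS[seq_len(ncol(m))]
  lm <- t(vapply(seq_len(ncol(m)), function(j) {
    vapply(1:3, function(l) mean(response[m[, j] == l]), numeric(1))
  }, numeric(3)))
  dimnames(lm) <- list(fnames, paste0("level", 1:3))
  structure(list(level_means = lm,
                 grand_mean = mean(response),
                 factor_names = fnames),
            class = "main_effects")
}

#' @export
print.main_effects <- function(x, digits = 2, ...) {
  cat("Main effects (level means), grand mean =",
      round(x$grand_mean, digits), "\n")
  print(round(t(x$level_means), digits))
  invisible(x)
}

#' Rank factors by the range of their level means
#'
#' Factor importance is the range (max - min, "delta") of the three level
#' means; rank 1 goes to the largest range. Ties are broken by factor
#' declaration order (deterministic). The optimal level per factor is the
#' argmin (default) or argmax of its level means: for binding free energies
#' the objective is minimization, since a more negative mean means stronger
#' affinity between derivative and degrading enzyme. No signal-to-noise
#' transform is applied.
#'
#' @param effects a [level_means()] result.
#' @param objective `"minimize"` (default) or `"maximize"`.
#' @return A data frame of class `factor_ranking` with columns `factor`,
#'   `range`, `rank` and `optimal_level`.
#' @export
rank_factors <- function(effects, objective = c("minimize", "maximize")) {
  stopifnot(inherits(effects, "main_effects"))
  objective <- match.arg(objective)
  lm <- effects$level_means
  ranges <- apply(lm, 1L, function(x) max(x) - min(x))
  ranks <- integer(length(ranges))
  ranks[order(-ranges)] <- seq_along(ranges) # stable: ties fall to earlier factors
  pick <- if (objective == "minimize") which.min else which.max
  optimal <- apply(lm, 1L, pick)
  out <- data.frame(factor = effects$factor_names,
                    range = unname(ranges),
                    rank = ranks,
                    optimal_level = unname(optimal),
                    stringsAsFactors = FALSE)
  class(out) <- c("factor_ranking", "data.frame")
  out
}

#' Binding-affinity improvement
#'
#' Percent increase in binding-free-energy magnitude of a new condition or
#' compound over a reference: `(|g_new| - |g_ref|) / |g_ref| * 100`.
#' Magnitudes are used so the sign convention of the inputs (free energies
#' are conventionally negative) does not matter.
#'
#' @param g_reference,g_new binding free energies, kJ/mol.
#' @return Percent improvement (positive = stronger affinity).
#' @export
#' @examples
#' affinity_improvement(62.326, -109.395) # 75.52...
affinity_improvement <- function(g_reference, g_new) {
  if (any(g_reference == 0)) {
    stop("reference binding energy must be nonzero", call. = FALSE)
  }
  (abs(g_new) - abs(g_reference)) / abs(g_reference) * 100
}
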