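#' Column schema for a compound property table
#'
#' Maps the package's canonical field names onto the column names actually
#' present in a CSV/TSV file. The canonical fields are `compound_id`,
#' `binding_free_energy` (kJ/mol, negative = favourable binding to the
#' degrading enzyme), `transition_energy` (eV, first excited-state UV
#' transition; must be positive) and the optional `set_tag`
#' (training/test/none).
#'
#' @param compound_id,binding_free_energy,transition_energy,set_tag column
#'   names in the file. `set_tag = NULL` means the file carries no such
#'   column.
#' @return A named list of class `compound_schema`.
#' @export
#' @examples
#' compound_schema(compound_id = "OPFR", binding_free_energy = "dG_bind")
compound_schema <- function(compound_id = "compound_id",
                            binding_free_energy = "binding_free_energy",
                            transition_energy = "transition_energy",
                            set_tag = "set_tag") {
  structure(list(compound_id = compound_id,
                 binding_free_energy = binding_free_energy,
                 transition_energy = transition_energy,
                 set_tag = set_tag),
            class = "compound_schema")
}

# Tables transcribed from published sources use the Unicode minus sign
# (U+2212); normalize it (and non-breaking spaces) before numeric parsing.
normalize_minus <- function(x) {
  x <- gsub("−", "-", x)
  gsub(" ", "", x)
}

# Parse a character column to double, erroring (not dropping) on cells that
# are neither numeric nor empty. `label` names the column in the message.
parse_numeric_column <- function(x, label) {
  x <- trimws(normalize_minus(as.character(x)))
  x[!nzchar(x)] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("column '%s' has unparseable numeric value(s) in row(s) %s: %s",
                 label, paste(bad, collapse = ", "),
                 paste(sQuote(x[bad]), collapse = ", ")), call. = FALSE)
  }
  out
}

read_delim_chr <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, sep = sep, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8",
                  strip.white = TRUE)
}

guess_sep <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

#' Read a compound property table
#'
#' Reads a CSV/TSV file of per-compound computed properties into a validated
#' `compound_table` data frame. Input row order is preserved; the Unicode
#' minus sign is accepted in numeric cells; unparseable numerics raise an
#' error naming the offending rows rather than being dropped silently.
#'
#' @param path path to a CSV (or TSV) file with a header row, UTF-8 encoded.
#' @param schema a [compound_schema()] mapping canonical fields to columns.
#' @param sep field separator; inferred from the file extension by default.
#' @return A data frame of class `compound_table` with columns
#'   `compound_id`, `binding_free_energy`, `transition_energy` and, when
#'   mapped and present, `set_tag`.
#' @seealso [write_compound_table()], [score_table()]
#' @export
#' @examples
#' path <- system.file("extdata", "opfr_compounds.csv", package = "degradesign")
#' head(read_compound_table(path))
read_compound_table <- function(path, schema = compound_schema(),
                                sep = guess_sep(path)) {
  stopifnot(inherits(schema, "compound_schema"))
  raw <- read_delim_chr(path, sep)
  required <- c("compound_id", "binding_free_energy", "transition_energy")
  for (field in required) {
    col <- schema[[field]]
    if (!col %in% names(raw)) {
      stop(sprintf("schema error: column '%s' (field '%s') not found in %s",
                   col, field, path), call. = FALSE)
    }
  }
  out <- data.frame(
    compound_id = trimws(as.character(raw[[schema$compound_id]])),
    binding_free_energy = parse_numeric_column(raw[[schema$binding_free_energy]],
                                               schema$binding_free_energy),
    transition_energy = parse_numeric_column(raw[[schema$transition_energy]],
                                             schema$transition_energy),
    stringsAsFactors = FALSE
  )
  if (!is.null(schema$set_tag) && schema$set_tag %in% names(raw)) {
    tag <- trimws(as.character(raw[[schema$set_tag]]))
    tag[!nzchar(tag)] <- "none"
    bad_tag <- setdiff(unique(tag), c("training", "test", "none"))
    if (length(bad_tag)) {
      stop("invalid set_tag value(s): ", paste(bad_tag, collapse = ", "),
           call. = FALSE)
    }
    out$set_tag <- tag
  }
  validate_compound_table(out)
  class(out) <- c("compound_table", "data.frame")
  out
}

validate_compound_table <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(!nzchar(x$compound_id) | is.na(x$compound_id))) {
    stop("compound_id must be non-empty for every row", call. = FALSE)
  }
  dup <- unique(x$compound_id[duplicated(x$compound_id)])
  if (length(dup)) {
    stop("duplicate compound_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_e <- which(!is.na(x$transition_energy) & x$transition_energy <= 0)
  if (length(bad_e)) {
    stop("transition_energy must be > 0 (violated in row(s) ",
         paste(bad_e, collapse = ", "), ")", call. = FALSE)
  }
  invisible(x)
}

#' Write a compound table back to CSV
#'
#' Numeric cells are written at full double precision so that a
#' read/write/read round trip reproduces every value bit-for-bit; report-time
#' rounding is the caller's concern.
#'
#' @param x a `compound_table` (or any data frame with the canonical columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Declare a three-level experimental factor
#'
#' @param name factor name (e.g. `"h2o2"`).
#' @param unit unit string, stored verbatim (no conversion is attempted).
#' @param levels exactly three distinct physical level values, in level
#'   order 1, 2, 3.
#' @param label optional human-readable description.
#' @return An object of class `doe_factor`.
#' @export
#' @examples
#' doe_factor("ph", "", c(6.5, 7.5, 8.5))
doe_factor <- function(name, unit, levels, label = name) {
  levels <- as.numeric(levels)
  if (length(levels) != 3L || anyDuplicated(levels)) {
    stop("a doe_factor needs exactly 3 distinct levels", call. = FALSE)
  }
  structure(list(name = name, unit = unit, levels = levels, label = label),
            class = "doe_factor")
}

#' External biodegradation condition factors
#'
#' The seven three-level factors of the reference biodegradation
#' design-of-experiments study: pH, temperature, methanol and acetic-acid
#' carbon sources, H2O2 oxidation promoter, voltage gradient and SDS
#' surfactant. Factor order A-G is the declaration order used for rank
#' tie-breaking. The voltage unit is stored as printed in the source run
#' table ("V/m").
#'
#' @return A named list of seven [doe_factor()] objects.
#' @export
biodegradation_factors <- function() {
  list(
    ph          = doe_factor("ph", "", c(6.5, 7.5, 8.5), "A: pH"),
    temperature = doe_factor("temperature", "K", c(298, 303, 308), "B: temperature"),
    methanol    = doe_factor("methanol", "mg/L", c(400, 450, 500), "C: carbon source methanol"),
    acetic_acid = doe_factor("acetic_acid", "mg/L", c(200, 300, 400), "D: acetic acid"),
    h2o2        = doe_factor("h2o2", "mg/L", c(300, 350, 400), "E: H2O2 concentration"),
    voltage     = doe_factor("voltage", "V/m", c(0.5, 1, 1.5), "F: voltage gradient"),
    surfactant  = doe_factor("surfactant", "mg/L", c(0, 375, 750), "G: surfactant SDS")
  )
}

#' Read a design-of-experiments run table
#'
#' Reads a run table whose factor columns hold physical level values (not
#' level indices), validates every cell against its factor's declared level
#' set, and returns the runs together with the implied level-index matrix.
#'
#' @param path CSV/TSV file with a run-id column, one column per declared
#'   factor, and a response column.
#' @param factors named list of [doe_factor()] objects; names must match the
#'   factor columns in the file, in design column order.
#' @param run_col,response_col names of the run-id and response columns.
#' @return A list of class `doe_table` with elements `runs` (data frame of
#'   physical settings plus response, input order preserved), `design` (a
#'   `taguchi_design` level-index matrix), `response` (numeric vector,
#'   kJ/mol) and `factors`.
#' @export
#' @examples
#' path <- system.file("extdata", "taguchi_runs.csv", package = "degradesign")
#' doe <- read_doe_table(path, biodegradation_factors())
#' doe$runs[13, ]
read_doe_table <- function(path, factors,
                           run_col = "run",
                           response_col = "binding_free_energy",
                           sep = guess_sep(path)) {
  stopifnot(is.list(factors), length(factors) >= 1L,
            all(vapply(factors, inherits, logical(1), "doe_factor")))
  raw <- read_delim_chr(path, sep)
  needed <- c(run_col, names(factors), response_col)
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("schema error: column(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  run_id <- parse_numeric_column(raw[[run_col]], run_col)
  if (anyDuplicated(run_id)) stop("duplicate run ids", call. = FALSE)
  design <- matrix(NA_integer_, nrow = nrow(raw), ncol = length(factors),
                   dimnames = list(NULL, names(factors)))
  runs <- data.frame(run = as.integer(run_id))
  for (fname in names(factors)) {
    fac <- factors[[fname]]
    vals <- parse_numeric_column(raw[[fname]], fname)
    idx <- match_level(vals, fac$levels)
    bad <- which(is.na(idx))
    if (length(bad)) {
      stop(sprintf(
        "level mismatch: run %s, factor '%s': value %s not among declared levels {%s}",
        paste(run_id[bad], collapse = ", "), fname,
        paste(vals[bad], collapse = ", "),
        paste(fac$levels, collapse = ", ")), call. = FALSE)
    }
    design[, fname] <- idx
    runs[[fname]] <- vals
  }
  response <- parse_numeric_column(raw[[response_col]], response_col)
  runs[[response_col]] <- response
  structure(list(runs = runs,
                 design = as_taguchi_design(design),
                 response = response,
                 factors = factors),
            class = "doe_table")
}

# physical value -> level index, with a small numeric tolerance
match_level <- function(values, levels, tol = 1e-8) {
  idx <- rep(NA_integer_, length(values))
  for (l in seq_along(levels)) {
    idx[abs(values - levels[l]) <= tol * max(1, abs(levels[l]))] <- l
  }
  idx
}
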