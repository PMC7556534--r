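#' Construct a life table
#'
#' A life table is an ordered set of annual death probabilities `qx` over
#' contiguous integer ages. The model multiplies these background
#' probabilities by severity-specific relative risks.
#'
#' @param age Integer ages, contiguous.
#' @param qx Annual death probabilities, strictly inside (0, 1).
#' @return An object of class `life_table` (a data.frame with columns `age`,
#'   `qx`).
#' @export
#' @examples
#' life_table(40:45, 0.00139 * exp(0.085 * (0:5)))
life_table <- function(age, qx) {
  if (length(age) != length(qx) || length(age) < 1L)
    stop("'age' and 'qx' must be non-empty and of equal length")
  if (any(age != floor(age))) stop("ages must be integers")
  if (any(diff(age) != 1)) stop("ages must be contiguous")
  if (any(qx <= 0 | qx >= 1))
    stop("death probabilities must lie strictly inside (0, 1)")
  structure(data.frame(age = as.integer(age), qx = as.numeric(qx)),
            class = c("life_table", "data.frame"))
}

#' Look up the annual death probability at an age
#'
#' Exact lookup for tabulated integer ages; non-integer ages are floored;
#' ages above the table maximum clamp to the last entry (conservative and
#' deterministic, rather than extrapolating).
#'
#' @param table A [life_table()].
#' @param age Numeric vector of ages (>= table minimum).
#' @return Annual death probabilities.
#' @export
#' @examples
#' lt <- synthetic_gompertz_table(0.00139, 40, 0.085, 100)
#' mortality_at(lt, c(40, 45.7, 200))
mortality_at <- function(table, age) {
  stopifnot(inherits(table, "life_table"))
  a <- floor(age)
  if (any(a < table$age[1]))
    stop(sprintf("age below the life table minimum (%d)", table$age[1]))
  a <- pmin(a, table$age[nrow(table)])
  table$qx[match(a, table$age)]
}

#' Synthetic Gompertz life table
#'
#' Generates a background-mortality schedule with exponentially increasing
#' death probability, `q(a) = min(0.999, q_ref * exp(slope * (a - ref_age)))`,
#' over ages `ref_age - 20` to `max_age`. A Gompertz slope near 0.085-0.09 per
#' year of age is typical of adult all-cause mortality in high-income
#' countries. Used as a stand-in for a national vital-statistics table.
#'
#' @param q_ref Death probability at the reference age (0 < q_ref < 1).
#' @param ref_age Reference age in years.
#' @param slope Log-linear increase in `qx` per year of age (> 0, or 0 for a
#'   constant-hazard table).
#' @param max_age Last tabulated age.
#' @return A [life_table()].
#' @export
#' @examples
#' synthetic_gompertz_table(0.00139, 40, 0.085, 110)
synthetic_gompertz_table <- function(q_ref, ref_age = 40, slope = 0.085,
                                     max_age = 110) {
  if (!(q_ref > 0 && q_ref < 1)) stop("'q_ref' must lie in (0, 1)")
  if (slope < 0) stop("'slope' must be non-negative")
  if (max_age <= ref_age) stop("'max_age' must exceed 'ref_age'")
  age <- seq(max(0, ref_age - 20), max_age)
  qx <- pmin(0.999, q_ref * exp(slope * (age - ref_age)))
  life_table(age, qx)
}

#' Read a life table from CSV
#'
#' Expects a two-column CSV with a header row naming `age` and `qx`.
#'
#' @param path CSV file path.
#' @return A validated [life_table()].
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(df)))
    stop("life table CSV must have columns 'age' and 'qx'")
  life_table(df$age, df$qx)
}

#' Write a life table to CSV
#'
#' @param table A [life_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "life_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' The bundled background-mortality schedule
#'
#' Returns the life table shipped with the package:
#' `us_lifetable_2007_synthetic.csv`, a synthetic Gompertz schedule (slope
#' 0.085/year, ages 20-110) calibrated so that q(40) = 0.00139, the published
#' anchor for the 2007 U.S. female life table. It is a synthetic stand-in for
#' the national vital-statistics table, which is not redistributable here;
#' substitute any real schedule via [read_life_table()].
#'
#' @return A [life_table()].
#' @export
default_life_table <- function() {
  path <- system.file("extdata", "us_lifetable_2007_synthetic.csv",
                      package = "mapcea")
  if (!nzchar(path)) stop("bundled life table fixture not found")
  read_life_table(path)
}
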