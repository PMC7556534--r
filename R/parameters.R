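#' Derive annual medical costs per severity state from the severe-state anchor
#'
#' Annual medical costs for the symptomatic states are anchored on the pooled
#' cost of severe PTSD: extreme is 20% higher than severe, moderate is 75% of
#' severe, and mild is 50% of severe. The asymptomatic cost is an independent
#' literature estimate and is passed through. Results are rounded to the
#' nearest dollar.
#'
#' @param severe_anchor Annual medical cost of severe PTSD (USD/year, > 0).
#' @param multipliers Named fractions of the severe anchor for `mild`,
#'   `moderate` and `extreme`.
#' @param asymptomatic_cost Annual cost of the asymptomatic state (USD/year).
#' @return Named numeric vector of annual costs over the five living states.
#' @export
#' @examples
#' derive_state_costs(19888)
derive_state_costs <- function(severe_anchor,
                               multipliers = c(mild = 0.5, moderate = 0.75,
                                               extreme = 1.2),
                               asymptomatic_cost = 4946) {
  if (!is.numeric(severe_anchor) || length(severe_anchor) != 1L ||
      severe_anchor <= 0)
    stop("'severe_anchor' must be a single positive cost")
  if (!all(c("mild", "moderate", "extreme") %in% names(multipliers)))
    stop("'multipliers' must name mild, moderate and extreme")
  out <- c(
    asymptomatic = asymptomatic_cost,
    mild = severe_anchor * multipliers[["mild"]],
    moderate = severe_anchor * multipliers[["moderate"]],
    severe = severe_anchor,
    extreme = severe_anchor * multipliers[["extreme"]]
  )
  round(out)
}

#' Derive mortality relative risks per severity state
#'
#' All-cause mortality for PTSD patients relative to the age-matched general
#' population is anchored at a pooled relative risk for an unstratified PTSD
#' population. Severity-specific values are constructed as: severe = anchor x
#' 1.1, extreme = severe x 1.1, moderate = anchor x 0.9, and mild = moderate x
#' 0.85; asymptomatic patients carry no excess risk (RR 1). Values are
#' returned unrounded; round to 2 decimals for reporting.
#'
#' @param base_rr Anchor relative risk (>= 1).
#' @return Named numeric vector of relative risks over the five living states.
#' @export
#' @examples
#' round(derive_mortality_rrs(2.28), 2)
derive_mortality_rrs <- function(base_rr) {
  if (!is.numeric(base_rr) || length(base_rr) != 1L || base_rr < 1)
    stop("'base_rr' must be a single relative risk >= 1")
  severe <- base_rr * 1.1
  moderate <- base_rr * 0.9
  c(asymptomatic = 1, mild = moderate * 0.85, moderate = moderate,
    severe = severe, extreme = severe * 1.1)
}

#' Pool cost estimates weighted by the square root of sample size
#'
#' Combines several published per-patient annual cost estimates into one
#' pooled value, weighting each study by the square root of its sample size
#' (a proxy for inverse statistical variance).
#'
#' @param cost Numeric vector of cost estimates (>= 0).
#' @param n Sample sizes (> 0), same length as `cost`.
#' @return Pooled cost, `sum(cost * sqrt(n)) / sum(sqrt(n))`.
#' @export
#' @examples
#' pool_cost_estimates(c(100, 200), c(4, 16))
pool_cost_estimates <- function(cost, n) {
  if (length(cost) == 0L) stop("at least one cost estimate is required")
  if (length(cost) != length(n)) stop("'cost' and 'n' must have equal length")
  if (any(n <= 0) || any(cost < 0))
    stop("sample sizes must be positive and costs non-negative")
  sum(cost * sqrt(n)) / sum(sqrt(n))
}

#' Per-patient intervention cost from micro-costed components
#'
#' @param components Named numeric vector of per-patient cost components
#'   (USD, >= 0), e.g. therapists, screening and diagnostics, pharmaceutical.
#' @return An object of class `map_intervention_cost`: a list with
#'   `components`, `total` (their sum) and `shares` (component / total).
#' @export
#' @examples
#' intervention_cost()
intervention_cost <- function(components = c(therapists = 6194,
                                             screening_diagnostics = 997,
                                             pharmaceutical = 353)) {
  if (is.null(names(components)) || any(!nzchar(names(components))))
    stop("'components' must be a named vector")
  if (any(components < 0)) stop("cost components must be non-negative")
  total <- sum(components)
  structure(
    list(components = components, total = total,
         shares = components / total),
    class = "map_intervention_cost"
  )
}

#' @export
print.map_intervention_cost <- function(x, ...) {
  cat("Per-patient intervention cost (USD)\n")
  for (nm in names(x$components))
    cat(sprintf("  %-22s %8s  (%.1f%%)\n", nm,
                formatC(x$components[[nm]], format = "d", big.mark = ","),
                100 * x$shares[[nm]]))
  cat(sprintf("  %-22s %8s\n", "total",
              formatC(round(x$total), format = "d", big.mark = ",")))
  invisible(x)
}

#' Largest-remainder apportionment
#'
#' Rounds a vector of non-negative shares to integers summing exactly to
#' `total`: each cell receives the floor of its quota, and the remaining units
#' go to the cells with the largest fractional remainders.
#'
#' @param shares Non-negative numeric vector (any scale; normalised internally).
#' @param total Target integer sum.
#' @return Integer-valued numeric vector of the same length as `shares`.
#' @export
#' @examples
#' largest_remainder(c(12.2, 31.1, 56.8), 1000)
largest_remainder <- function(shares, total) {
  stopifnot(all(shares >= 0), sum(shares) > 0, total >= 0)
  quota <- shares / sum(shares) * total
  base <- floor(quota)
  short <- round(total - sum(base))
  if (short > 0) {
    top <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  base
}

# Printed Table-style base-case inputs -----------------------------------

map_defaults <- function() {
  list(
    intake_printed = c(asymptomatic = 0, mild = 0, moderate = 122,
                       severe = 311, extreme = 568),
    followup = c(asymptomatic = 216, mild = 270, moderate = 135,
                 severe = 230, extreme = 149),
    utility = c(asymptomatic = 1, mild = 0.97, moderate = 0.851,
                severe = 0.477, extreme = 0.369),
    annual_cost = derive_state_costs(19888),
    mortality_rr = c(asymptomatic = 1, mild = 1.74, moderate = 2.05,
                     severe = 2.51, extreme = 2.76),
    effectiveness = list(mean = -37.9, sd = 28.9, n_subjects = 105),
    baseline_caps = list(mean = 85.8, sd = 19.3),
    discount_rate = 0.03, cohort_size = 1000, mean_age = 40, horizon = 30,
    phase_in = c(0, 0.25, 0.5, 0.75, 1)
  )
}

#' Base-case model parameters
#'
#' Assembles the full base case: intake and follow-up severity distributions
#' for a cohort of 1,000, state utilities, annual medical costs, mortality
#' relative risks, intervention cost, effectiveness (mean CAPS-IV change and
#' its dispersion), a 3% discount rate, a 30-year horizon, the five-year
#' phase-in of medical-cost reductions, and a background life table.
#'
#' The printed intake counts (122, 311, 568) sum to 1,001; the default
#' resolves this by largest-remainder rounding of the underlying percentages
#' (12.2 / 31.1 / 56.8) to the cohort size, giving (122, 311, 567). Use
#' `intake = "printed"` for the raw counts.
#'
#' @param overrides Optional named list of parameter overrides; names are
#'   parameter paths as listed by [valid_param_paths()].
#' @param intake `"largest_remainder"` (default) or `"printed"`.
#' @param life_table Optional [life_table()]; defaults to the bundled
#'   synthetic U.S. schedule anchored at q(40) = 0.00139.
#' @return An object of class `map_params`.
#' @seealso [set_param()], [run_cohort()], [evaluate_model()]
#' @export
#' @examples
#' p <- default_params()
#' p$followup_distribution
default_params <- function(overrides = NULL,
                           intake = c("largest_remainder", "printed"),
                           life_table = NULL) {
  intake <- match.arg(intake)
  d <- map_defaults()
  intake_dist <- switch(intake,
    largest_remainder = {
      x <- d$intake_printed
      x[x > 0] <- largest_remainder(x[x > 0], d$cohort_size)
      x
    },
    printed = d$intake_printed
  )
  if (is.null(life_table)) life_table <- default_life_table()
  p <- structure(list(
    bands = severity_bands(),
    utility = d$utility,
    annual_cost = d$annual_cost,
    mortality_rr = d$mortality_rr,
    intake_distribution = intake_dist,
    followup_distribution = d$followup,
    intervention_cost = intervention_cost(),
    effectiveness = d$effectiveness,
    baseline_caps = d$baseline_caps,
    base_effect_mean = d$effectiveness$mean,
    discount_rate = d$discount_rate,
    cohort_size = sum(intake_dist),
    mean_age = d$mean_age,
    horizon = d$horizon,
    phase_in = d$phase_in,
    inflation_multiplier = 1,
    medical_cost_multiplier = 1,
    decedent_credit = 0.5,
    life_table = life_table,
    calibration_seed = 20231,
    records = NULL
  ), class = "map_params")
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("'overrides' must be a named list of parameter paths")
    for (path in names(overrides))
      p <- set_param(p, path, overrides[[path]])
  }
  validate_params(p)
  p
}

validate_params <- function(p, check_order = TRUE) {
  states <- severity_states()
  stopifnot(inherits(p, "map_params"))
  for (fld in c("utility", "annual_cost", "mortality_rr",
                "intake_distribution", "followup_distribution"))
    if (!identical(names(p[[fld]]), states))
      stop(sprintf("'%s' must be named over the five severity states", fld))
  if (p$discount_rate < 0 || p$discount_rate > 0.2)
    stop("discount_rate must lie in [0, 0.2]")
  if (p$cohort_size <= 0) stop("cohort_size must be positive")
  if (p$horizon < 1) stop("horizon must be at least 1 year")
  if (any(diff(p$phase_in) < 0) || any(p$phase_in < 0 | p$phase_in > 1))
    stop("phase-in fractions must be non-decreasing within [0, 1]")
  if (any(p$intake_distribution < 0) || any(p$followup_distribution < 0))
    stop("severity distributions must be non-negative")
  # raw printed intake counts sum to 1,001, one more than follow-up
  if (abs(sum(p$followup_distribution) - sum(p$intake_distribution)) > 1)
    stop("intake and follow-up distributions must cover the same cohort size")
  if (check_order) {
    if (p$utility[["asymptomatic"]] != 1)
      stop("asymptomatic utility must be 1")
    if (any(diff(p$utility) > 0) || p$utility[["extreme"]] <= 0)
      stop("utilities must be non-increasing with severity and positive")
    if (any(diff(p$annual_cost) <= 0))
      stop("annual costs must be strictly increasing with severity")
    if (p$mortality_rr[["asymptomatic"]] != 1 || any(diff(p$mortality_rr) < 0))
      stop("mortality RRs must be non-decreasing with severity, anchored at 1")
  }
  invisible(p)
}

#' @export
print.map_params <- function(x, ...) {
  cat("MAP cost-effectiveness model parameters\n")
  cat(sprintf("  cohort: %d patients, mean age %.1f, horizon %d y, discount %.1f%%\n",
              round(x$cohort_size), x$mean_age, x$horizon,
              100 * x$discount_rate))
  tab <- data.frame(
    utility = x$utility, annual_cost = x$annual_cost,
    mortality_rr = round(x$mortality_rr, 2),
    intake = x$intake_distribution, followup = x$followup_distribution
  )
  print(tab)
  cat(sprintf("  intervention cost: $%s per patient; mean CAPS change %.1f (SD %.1f)\n",
              formatC(round(x$intervention_cost$total), format = "d",
                      big.mark = ","),
              x$effectiveness$mean, x$effectiveness$sd))
  invisible(x)
}

# Parameter paths ---------------------------------------------------------

#' Valid parameter override paths
#'
#' @return Character vector of the dotted paths accepted by [set_param()] and
#'   by the `overrides` argument of [default_params()].
#' @export
valid_param_paths <- function() {
  states <- severity_states()
  c("discount_rate", "cohort_size", "mean_age", "horizon",
    "inflation_multiplier", "medical_cost_multiplier", "decedent_credit",
    "calibration_seed",
    paste0("utility.", states), paste0("annual_cost.", states),
    paste0("mortality_rr.", states),
    paste0("intake.", states), paste0("followup.", states),
    "intervention_cost.total",
    paste0("intervention_cost.",
           names(intervention_cost()$components)),
    "effectiveness.mean", "effectiveness.sd")
}

#' Set a model parameter by path
#'
#' Paths address scalar model inputs with a dotted notation, e.g.
#' `"discount_rate"`, `"utility.moderate"`, `"mortality_rr.extreme"`,
#' `"intervention_cost.total"` (rescales the components proportionally) or
#' `"effectiveness.mean"` (re-derives the follow-up severity distribution from
#' the calibrated synthetic cohort when the model is next evaluated).
#'
#' @param params A `map_params` object.
#' @param path One of [valid_param_paths()].
#' @param value Replacement value.
#' @return The modified `map_params` object.
#' @export
#' @examples
#' p <- set_param(default_params(), "discount_rate", 0)
set_param <- function(params, path, value) {
  stopifnot(inherits(params, "map_params"), is.numeric(value),
            length(value) == 1L)
  if (!path %in% valid_param_paths())
    stop(sprintf("unknown parameter path '%s'; valid paths are: %s",
                 path, paste(valid_param_paths(), collapse = ", ")))
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    params[[path]] <- value
  } else if (parts[1] == "utility") {
    params$utility[[parts[2]]] <- value
  } else if (parts[1] == "annual_cost") {
    params$annual_cost[[parts[2]]] <- value
  } else if (parts[1] == "mortality_rr") {
    params$mortality_rr[[parts[2]]] <- value
  } else if (parts[1] == "intake") {
    params$intake_distribution[[parts[2]]] <- value
    params$cohort_size <- sum(params$intake_distribution)
  } else if (parts[1] == "followup") {
    params$followup_distribution[[parts[2]]] <- value
  } else if (parts[1] == "intervention_cost") {
    ic <- params$intervention_cost
    if (parts[2] == "total") {
      ic <- intervention_cost(ic$components * value / ic$total)
    } else {
      comps <- ic$components
      comps[[parts[2]]] <- value
      ic <- intervention_cost(comps)
    }
    params$intervention_cost <- ic
  } else if (parts[1] == "effectiveness") {
    params$effectiveness[[parts[2]]] <- value
  }
  params
}

#' Read parameter overrides from a YAML or JSON file
#'
#' The file holds a flat mapping of parameter paths (see
#' [valid_param_paths()]) to values, and is applied on top of the base case.
#'
#' @param path File path (`.yaml`, `.yml` or `.json`).
#' @param ... Passed to [default_params()].
#' @return A `map_params` object.
#' @export
read_params_file <- function(path, ...) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  overrides <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  default_params(overrides = as.list(overrides), ...)
}
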