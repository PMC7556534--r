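# outputs an analysis can target, computed at the params' horizon
model_output <- function(params, output, scenario = NULL) {
  res <- evaluate_model(params, horizons = params$horizon,
                        scenario = scenario)
  switch(output,
    net_cost = res$net_cost,
    qalys_gained = res$qalys_gained,
    deaths_averted = res$deaths_averted,
    icer = res$icer,
    stop(sprintf("unknown output '%s'", output))
  )
}

#' Default one-way sensitivity ranges
#'
#' Low/base/high values for the deterministic (tornado) analysis. Published
#' ranges: intervention cost +/-30%; discount rate 2.3-3.8%; mean age 35-45;
#' mild utility 0.9-1.0 and moderate +/-10% (severe and extreme take the same
#' +/-10%); relative risks swept by +/-1 SD of their lognormal specification;
#' effectiveness between the lower 95% bound of the mean CAPS change (-31.3)
#' and the symmetric upper bound. The symptomatic medical-cost multiplier has
#' no published range and defaults to 0.5-1.5.
#'
#' @param params A `map_params` object supplying base values.
#' @return A data.frame with columns `path`, `low`, `base`, `high`.
#' @export
default_sensitivity_ranges <- function(params = default_params()) {
  u <- params$utility; rr <- params$mortality_rr
  rr_sd <- c(mild = 0.70, moderate = 0.80, severe = 1.10, extreme = 1.25)
  ic <- params$intervention_cost$total
  eff <- params$effectiveness$mean
  rows <- rbind(
    data.frame(path = "medical_cost_multiplier", low = 0.5, base = 1,
               high = 1.5),
    data.frame(path = "effectiveness.mean", low = 2 * eff + 31.3,
               base = eff, high = -31.3),
    data.frame(path = "intervention_cost.total", low = 0.7 * ic, base = ic,
               high = 1.3 * ic),
    data.frame(path = "discount_rate", low = 0.023, base = 0.03,
               high = 0.038),
    data.frame(path = "mean_age", low = 35, base = 40, high = 45),
    data.frame(path = "utility.mild", low = 0.9, base = u[["mild"]],
               high = 1.0),
    do.call(rbind, lapply(c("moderate", "severe", "extreme"), function(s)
      data.frame(path = paste0("utility.", s), low = 0.9 * u[[s]],
                 base = u[[s]], high = min(1, 1.1 * u[[s]])))),
    do.call(rbind, lapply(names(rr_sd), function(s)
      data.frame(path = paste0("mortality_rr.", s),
                 low = max(1, rr[[s]] - rr_sd[[s]]), base = rr[[s]],
                 high = rr[[s]] + rr_sd[[s]])))
  )
  row.names(rows) <- NULL
  rows
}

#' One-way (tornado) sensitivity analysis
#'
#' Each parameter is varied to its low and high endpoint while all others are
#' held at base, and the chosen model output recorded; entries are returned
#' sorted by descending span for tornado plotting. The `low`/`high` of the
#' effectiveness path flow through the synthetic-cohort CAPS mapping.
#'
#' @param params A `map_params` object (its `horizon` sets the output
#'   horizon).
#' @param ranges Data.frame of `path`, `low`, `base`, `high`; see
#'   [default_sensitivity_ranges()].
#' @param output One of `"net_cost"`, `"qalys_gained"`, `"deaths_averted"`,
#'   `"icer"`.
#' @return A data.frame `path`, `low`, `high`, `output_low`, `output_high`,
#'   `span`, sorted by descending `span`, with the base-case output as
#'   attribute `"base_output"`.
#' @export
#' @examples
#' one_way(default_params(), default_sensitivity_ranges()[1:3, ])
one_way <- function(params, ranges = default_sensitivity_ranges(params),
                    output = "net_cost") {
  stopifnot(all(c("path", "low", "base", "high") %in% names(ranges)))
  if (any(ranges$low > ranges$base | ranges$base > ranges$high))
    stop("ranges must satisfy low <= base <= high")
  base_out <- model_output(params, output)
  eval_at <- function(path, value)
    model_output(set_param(params, path, value), output)
  out_low <- mapply(eval_at, ranges$path, ranges$low)
  out_high <- mapply(eval_at, ranges$path, ranges$high)
  res <- data.frame(path = ranges$path, low = ranges$low, high = ranges$high,
                    output_low = out_low, output_high = out_high,
                    span = abs(out_high - out_low), row.names = NULL)
  res <- res[order(-res$span), ]
  row.names(res) <- NULL
  attr(res, "base_output") <- base_out
  res
}

#' Two-way sensitivity grid
#'
#' Full-factorial evaluation of the model output over a grid of two
#' parameters. `"horizon"` is a valid path here, so the published grid of
#' per-patient intervention cost against analytic horizon is expressible.
#'
#' @param params A `map_params` object.
#' @param path_a,path_b Parameter paths (see [valid_param_paths()]).
#' @param values_a,values_b Numeric grids (length >= 1).
#' @param output Model output name, as in [one_way()].
#' @return A long-format data.frame with columns `a`, `b`, `output`, plus an
#'   attribute `"matrix"` holding the same values as a
#'   `length(values_a) x length(values_b)` matrix.
#' @export
two_way <- function(params, path_a, values_a, path_b, values_b,
                    output = "net_cost") {
  grid <- expand.grid(a = values_a, b = values_b)
  vals <- mapply(function(a, b) {
    p <- set_param(params, path_a, a)
    p <- set_param(p, path_b, b)
    model_output(p, output)
  }, grid$a, grid$b)
  res <- data.frame(a = grid$a, b = grid$b, output = vals)
  names(res)[1:2] <- c(path_a, path_b)
  attr(res, "matrix") <- matrix(vals, nrow = length(values_a),
                                dimnames = list(values_a, values_b))
  res
}

# plain bisection; assumes f is monotone over [lo, hi] with a sign change
bisect_root <- function(f, lo, hi, tol = 1e-6, max_iter = 200L) {
  f_lo <- f(lo); f_hi <- f(hi)
  if (sign(f_lo) == sign(f_hi))
    stop(sprintf(
      "no sign change over the bracket: f(%g) = %g, f(%g) = %g",
      lo, f_lo, hi, f_hi))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (f_mid == 0 || (hi - lo) <= tol * max(1, abs(mid)))
      return(mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  mid
}

#' Threshold value of a parameter for a target net cost
#'
#' Finds, by bisection, the value of one parameter at which the model's net
#' cost at the params' horizon crosses the target (zero by default, i.e. the
#' break-even value of the knob). The net cost must be monotone in the knob
#' over the bracket. The bracket is narrowed well below a relative width of
#' 1e-6 so that substituting the threshold back yields a net cost within a
#' dollar of the target.
#'
#' @param params A `map_params` object.
#' @param knob Parameter path to solve over.
#' @param bracket Numeric length-2 search interval.
#' @param target Target net cost (default 0).
#' @return The knob value at the crossing.
#' @export
#' @examples
#' \donttest{
#' cost_threshold(default_params(), "medical_cost_multiplier", c(0.05, 1))
#' }
cost_threshold <- function(params, knob, bracket, target = 0) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  f <- function(x)
    model_output(set_param(params, knob, x), "net_cost") - target
  bisect_root(f, bracket[1], bracket[2], tol = 1e-12)
}

#' Disease-progression scenario
#'
#' After treatment benefits have been in place for several years, MAP-arm
#' survivors may relapse: from `start_cycle` onward a fraction `p_prog` of
#' survivors in each living state below extreme moves one severity state
#' worse per cycle (extreme-state patients progress no further). Controls,
#' already chronic and stable by trial inclusion, are unchanged. The default
#' rate is 6%/year starting after year five (the published scenario sweep is
#' 0-12%); the alternative published base of 5% (0-10%) can be passed
#' explicitly.
#'
#' @param params A `map_params` object.
#' @param p_prog Annual progression probability in `[0, 0.2]`.
#' @param start_cycle First cycle at which progression applies.
#' @param horizon Horizon for the comparison.
#' @return A `map_cea` comparison of the progressing MAP arm against the
#'   unchanged control arm.
#' @export
#' @examples
#' progression_scenario(default_params(), p_prog = 0.06, horizon = 10)
progression_scenario <- function(params, p_prog = 0.06, start_cycle = 6,
                                 horizon = params$horizon) {
  if (p_prog < 0 || p_prog > 0.2)
    stop("'p_prog' must lie in [0, 0.2]")
  evaluate_model(params, horizons = horizon,
                 scenario = list(p_prog = p_prog, start_cycle = start_cycle))
}
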