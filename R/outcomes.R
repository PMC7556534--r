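# cumulative (cost, qalys, deaths) at a possibly fractional horizon,
# linearly interpolated between integer cycles; horizon 0 = upfront only
cumulative_at <- function(traj, horizon) {
  stopifnot(inherits(traj, "map_trajectory"),
            horizon >= 0, horizon <= traj$horizon)
  cum <- traj$cumulative
  at0 <- c(cost_disc = traj$upfront_cost, qalys_disc = 0, deaths = 0)
  lo <- floor(horizon); hi <- ceiling(horizon); w <- horizon - lo
  val <- function(h) {
    if (h == 0) at0 else unlist(cum[h, c("cost_disc", "qalys_disc", "deaths")])
  }
  (1 - w) * val(lo) + w * val(hi)
}

#' Incremental cost-effectiveness ratio or dominance flag
#'
#' @param net_cost Incremental cost (intervention minus comparator, USD).
#' @param qalys_gained Incremental QALYs.
#' @return A list with `icer` (USD/QALY, or `NA`) and `flag`: `"icer"` when
#'   both increments are positive, `"dominant"` (cheaper and more effective),
#'   `"dominated"` (costlier and less effective), or `"indeterminate"`.
#' @export
#' @examples
#' icer(7608691, 287.9)
#' icer(-1, 1)$flag
icer <- function(net_cost, qalys_gained) {
  if (net_cost > 0 && qalys_gained > 0)
    list(icer = net_cost / qalys_gained, flag = "icer")
  else if (net_cost < 0 && qalys_gained > 0)
    list(icer = NA_real_, flag = "dominant")
  else if (net_cost > 0 && qalys_gained < 0)
    list(icer = NA_real_, flag = "dominated")
  else
    list(icer = NA_real_, flag = "indeterminate")
}

#' Compare two arm trajectories at a horizon
#'
#' Differences the arms' cumulative discounted costs (including any upfront
#' intervention cost) and QALYs, and their cumulative undiscounted deaths, at
#' the given horizon; fractional horizons are linearly interpolated between
#' integer cycles.
#'
#' @param traj_map Trajectory of the intervention (MAP) arm.
#' @param traj_control Trajectory of the comparator arm.
#' @param horizon Horizon in years (possibly fractional); both trajectories
#'   must cover it.
#' @return An object of class `map_cea`: net cost (negative = savings), QALYs
#'   gained, deaths averted (undiscounted), per-arm totals, and the ICER or
#'   dominance flag.
#' @export
#' @examples
#' p <- default_params()
#' compare_arms(run_cohort(p, "map", 10), run_cohort(p, "control", 10), 10)
compare_arms <- function(traj_map, traj_control, horizon) {
  if (abs(traj_map$cohort_size - traj_control$cohort_size) > 1)
    stop("arms portray different cohort sizes")
  a <- cumulative_at(traj_map, horizon)
  b <- cumulative_at(traj_control, horizon)
  net_cost <- a[["cost_disc"]] - b[["cost_disc"]]
  qalys_gained <- a[["qalys_disc"]] - b[["qalys_disc"]]
  ic <- icer(net_cost, qalys_gained)
  structure(
    list(horizon = horizon,
         cost_map = a[["cost_disc"]], cost_control = b[["cost_disc"]],
         qalys_map = a[["qalys_disc"]], qalys_control = b[["qalys_disc"]],
         deaths_map = a[["deaths"]], deaths_control = b[["deaths"]],
         net_cost = net_cost, qalys_gained = qalys_gained,
         deaths_averted = b[["deaths"]] - a[["deaths"]],
         icer = ic$icer, flag = ic$flag),
    class = "map_cea"
  )
}

#' @export
print.map_cea <- function(x, ...) {
  dollars <- function(v) {
    s <- formatC(abs(round(v)), format = "d", big.mark = ",")
    if (v < 0) sprintf("($%s)", s) else sprintf("$%s", s)
  }
  cat(sprintf("Cost-effectiveness at %s years (per %s)\n",
              format(x$horizon), "cohort"))
  cat(sprintf("  cost: MAP %s vs control %s  ->  net %s\n",
              dollars(x$cost_map), dollars(x$cost_control),
              dollars(x$net_cost)))
  cat(sprintf("  QALYs gained %.1f; deaths averted %.1f (undiscounted)\n",
              x$qalys_gained, x$deaths_averted))
  cat(sprintf("  %s\n", if (x$flag == "icer")
    sprintf("ICER %s per QALY gained", dollars(x$icer)) else x$flag))
  invisible(x)
}

#' Evaluate the base-case comparison at one or more horizons
#'
#' Runs both arms once to the maximum horizon and compares them at each
#' requested horizon.
#'
#' @param params A `map_params` object.
#' @param horizons Numeric vector of horizons (years; fractional allowed).
#' @param scenario Optional progression scenario passed to [run_cohort()].
#' @return A list of `map_cea` objects, one per horizon (a single object if
#'   one horizon was requested).
#' @export
#' @examples
#' evaluate_model(default_params(), horizons = c(1, 10))
evaluate_model <- function(params, horizons = params$horizon,
                           scenario = NULL) {
  hmax <- ceiling(max(horizons))
  tm <- run_cohort(params, "map", horizon = hmax, scenario = scenario)
  tc <- run_cohort(params, "control", horizon = hmax)
  res <- lapply(horizons, function(h) compare_arms(tm, tc, h))
  if (length(res) == 1L) res[[1]] else res
}

#' Break-even horizon of the intervention
#'
#' The smallest horizon at which the cumulative discounted net cost of the
#' intervention reaches zero, linearly interpolated between the bracketing
#' integer horizons and reported to one decimal.
#'
#' @param params A `map_params` object.
#' @param max_horizon Longest horizon searched.
#' @param scenario Optional progression scenario.
#' @return Break-even horizon in years (one decimal), or `NA` if net cost
#'   never reaches zero within `max_horizon`.
#' @export
#' @examples
#' break_even_horizon(default_params())
break_even_horizon <- function(params, max_horizon = params$horizon,
                               scenario = NULL) {
  stopifnot(max_horizon >= 2)
  tm <- run_cohort(params, "map", horizon = max_horizon, scenario = scenario)
  tc <- run_cohort(params, "control", horizon = max_horizon)
  net <- tm$cumulative$cost_disc - tc$cumulative$cost_disc
  net0 <- tm$upfront_cost - tc$upfront_cost
  nets <- c(net0, net)                      # horizons 0..max
  idx <- which(nets <= 0)[1]
  if (is.na(idx)) return(NA_real_)
  if (idx == 1L) return(0)
  h_hi <- idx - 1                           # integer horizon where net <= 0
  n_lo <- nets[idx - 1]; n_hi <- nets[idx]
  round(h_hi - 1 + n_lo / (n_lo - n_hi), 1)
}
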