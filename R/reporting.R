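#' Base-case results table across horizons
#'
#' Runs the base-case comparison at the usual reporting horizons (1 year, the
#' break-even horizon, 10 and 30 years) and returns the comparisons plus the
#' break-even horizon itself.
#'
#' @param params A `map_params` object.
#' @param horizons Horizons to report; `NULL` (default) uses 1, the
#'   break-even horizon (when it exists within 30 years), 10 and 30.
#' @return A list with `results` (list of `map_cea`), `break_even` (years or
#'   `NA`) and `table` (the formatted data.frame from [render_table2()]).
#' @export
#' @examples
#' bc <- base_case_table(default_params())
#' bc$table
base_case_table <- function(params, horizons = NULL) {
  be <- break_even_horizon(params, max_horizon = max(30, params$horizon))
  if (is.null(horizons)) {
    horizons <- c(1, if (!is.na(be)) be, 10, 30)
    horizons <- sort(unique(horizons))
  }
  res <- evaluate_model(params, horizons = horizons)
  if (length(horizons) == 1L) res <- list(res)
  list(results = res, break_even = be, table = render_table2(res))
}

#' Render cost-effectiveness results as a publication-style table
#'
#' One row per (horizon, metric): discounted costs per arm, net cost
#' (negative values are savings), discounted QALYs per arm and gained,
#' undiscounted deaths per arm and averted, and the ICER or dominance flag.
#' Money is rounded to dollars, QALYs to integers, deaths to one decimal.
#'
#' @param results A `map_cea` object or list of them (>= 1 horizon).
#' @return A data.frame with columns `horizon`, `metric`, `map`, `control`,
#'   `incremental`.
#' @export
render_table2 <- function(results) {
  if (inherits(results, "map_cea")) results <- list(results)
  if (length(results) == 0L) stop("at least one horizon's results required")
  stopifnot(all(vapply(results, inherits, TRUE, "map_cea")))
  rows <- lapply(results, function(r) {
    icer_cell <- if (r$flag == "icer")
      formatC(round(r$icer), format = "d", big.mark = ",") else
      paste0(toupper(substring(r$flag, 1, 1)), substring(r$flag, 2))
    data.frame(
      horizon = r$horizon,
      metric = c("costs", "net_cost", "qalys", "qalys_gained", "deaths",
                 "deaths_averted", "net_cost_per_qaly"),
      map = c(round(r$cost_map), NA, round(r$qalys_map), NA,
              round(r$deaths_map, 1), NA, NA),
      control = c(round(r$cost_control), NA, round(r$qalys_control), NA,
                  round(r$deaths_control, 1), NA, NA),
      incremental = c(NA, as.character(round(r$net_cost)), NA,
                      as.character(round(r$qalys_gained)), NA,
                      as.character(round(r$deaths_averted, 1)), icer_cell),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Export trajectories and comparisons
#'
#' `export_trajectory()` writes a tidy CSV (one row per cycle per arm);
#' `export_results_json()` writes a JSON summary of one or more comparisons.
#'
#' @param traj_map,traj_control `map_trajectory` objects.
#' @param results A `map_cea` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj_map, traj_control, path) {
  utils::write.csv(trajectory_df(traj_map, traj_control), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname export_trajectory
#' @export
export_results_json <- function(results, path) {
  if (inherits(results, "map_cea")) results <- list(results)
  out <- lapply(results, function(r)
    r[c("horizon", "cost_map", "cost_control", "net_cost", "qalys_map",
        "qalys_control", "qalys_gained", "deaths_map", "deaths_control",
        "deaths_averted", "icer", "flag")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
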