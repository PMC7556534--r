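#' Distribution specification for one uncertain parameter
#'
#' Families follow decision-modelling convention: beta distributions for
#' probabilities and other range-bounded quantities, gamma for costs,
#' lognormal for relative risks, normal for effect sizes. Range-specified
#' parameters use a symmetric Beta(4, 4) rescaled to `[low, high]` (mass
#' centred on the midpoint with soft tails); moment-specified families are
#' parameterised by method of moments from `mean` and `sd`.
#'
#' @param path Parameter path (see [valid_param_paths()]).
#' @param family One of `"fixed"`, `"beta_range"`, `"gamma_moments"`,
#'   `"lognormal_moments"`, `"normal_moments"`.
#' @param mean,sd Moments (moment families).
#' @param low,high Range (`beta_range`), or optional truncation bounds for
#'   moment families (enforced by rejection).
#' @param value Base value (`fixed`).
#' @return An object of class `map_dist_spec`.
#' @export
#' @examples
#' dist_spec("discount_rate", "beta_range", low = 0.023, high = 0.038)
dist_spec <- function(path,
                      family = c("fixed", "beta_range", "gamma_moments",
                                 "lognormal_moments", "normal_moments"),
                      mean = NULL, sd = NULL, low = NULL, high = NULL,
                      value = NULL) {
  family <- match.arg(family)
  if (family == "beta_range") {
    if (is.null(low) || is.null(high) || low >= high)
      stop("'beta_range' requires low < high")
  } else if (family == "fixed") {
    if (is.null(value)) stop("'fixed' requires a value")
  } else {
    if (is.null(mean) || is.null(sd) || sd <= 0)
      stop(sprintf("'%s' requires a mean and a positive sd", family))
    if (family %in% c("gamma_moments", "lognormal_moments") && mean <= 0)
      stop(sprintf("'%s' requires a positive mean", family))
  }
  structure(list(path = path, family = family, mean = mean, sd = sd,
                 low = low, high = high, value = value),
            class = "map_dist_spec")
}

#' Draw from a distribution specification
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`. Uses the current RNG state.
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_spec(dist_spec("discount_rate", "beta_range",
#'                            low = 0.023, high = 0.038), 1e4))
sample_spec <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "map_dist_spec"))
  draw <- switch(spec$family,
    fixed = rep(spec$value, n),
    beta_range = spec$low + (spec$high - spec$low) * stats::rbeta(n, 4, 4),
    gamma_moments = {
      shape <- (spec$mean / spec$sd)^2
      stats::rgamma(n, shape = shape, rate = shape / spec$mean)
    },
    lognormal_moments = {
      s2 <- log(1 + (spec$sd / spec$mean)^2)
      stats::rlnorm(n, meanlog = log(spec$mean) - s2 / 2, sdlog = sqrt(s2))
    },
    normal_moments = stats::rnorm(n, spec$mean, spec$sd)
  )
  if (spec$family != "beta_range" &&
      (!is.null(spec$low) || !is.null(spec$high))) {
    lo <- if (is.null(spec$low)) -Inf else spec$low
    hi <- if (is.null(spec$high)) Inf else spec$high
    bad <- which(draw < lo | draw > hi)
    guard <- 0L
    while (length(bad) > 0L && guard < 1000L) {
      draw[bad] <- Recall(dist_spec(spec$path, spec$family, spec$mean,
                                    spec$sd, value = spec$value),
                          length(bad))
      bad <- which(draw < lo | draw > hi)
      guard <- guard + 1L
    }
    if (length(bad) > 0L) stop("truncation rejection failed to converge")
  }
  draw
}

#' Default PSA distribution specifications
#'
#' In `"all"` mode: discount rate Beta over 2.3-3.8%; intervention cost Beta
#' over +/-30%; mortality relative risks lognormal with the published SDs
#' (0.70 / 0.80 / 1.10 / 1.25), truncated below at 1; utilities Beta over
#' their ranges (mild 0.9-1.0; moderate, severe, extreme +/-10%, capped at
#' 1); mean age Beta over 35-45; effectiveness normal around the mean CAPS
#' change. Health-care costs are held fixed (their published dispersion is
#' zero; they are explored deterministically instead); pass gamma specs
#' explicitly to sample them.
#'
#' The effectiveness SD defaults to the standard error of the mean change
#' (patient-level SD divided by the square root of the pooled trial size),
#' which describes parameter uncertainty in the mean effect;
#' `use_patient_sd = TRUE` uses the raw patient-level SD instead, conflating
#' individual variability with parameter uncertainty.
#'
#' @param params A `map_params` object.
#' @param mode `"all"` (joint PSA, the default for interval reporting) or
#'   `"effectiveness"` (effectiveness-only sweep).
#' @param use_patient_sd Use the patient-level CAPS-change SD for the
#'   effectiveness spec instead of the standard error of the mean.
#' @return A list of [dist_spec()] objects.
#' @export
default_psa_specs <- function(params = default_params(),
                              mode = c("all", "effectiveness"),
                              use_patient_sd = FALSE) {
  mode <- match.arg(mode)
  eff_sd <- if (use_patient_sd) params$effectiveness$sd
            else params$effectiveness$sd / sqrt(params$effectiveness$n_subjects)
  eff <- dist_spec("effectiveness.mean", "normal_moments",
                   mean = params$effectiveness$mean, sd = eff_sd)
  if (mode == "effectiveness") return(list(eff))
  u <- params$utility; rr <- params$mortality_rr
  rr_sd <- c(mild = 0.70, moderate = 0.80, severe = 1.10, extreme = 1.25)
  specs <- list(
    eff,
    dist_spec("discount_rate", "beta_range", low = 0.023, high = 0.038),
    dist_spec("intervention_cost.total", "beta_range",
              low = 0.7 * params$intervention_cost$total,
              high = 1.3 * params$intervention_cost$total),
    dist_spec("mean_age", "beta_range", low = 35, high = 45),
    dist_spec("utility.mild", "beta_range", low = 0.9, high = 1.0)
  )
  for (s in c("moderate", "severe", "extreme"))
    specs[[length(specs) + 1L]] <-
      dist_spec(paste0("utility.", s), "beta_range",
                low = 0.9 * u[[s]], high = min(1, 1.1 * u[[s]]))
  for (s in names(rr_sd))
    specs[[length(specs) + 1L]] <-
      dist_spec(paste0("mortality_rr.", s), "lognormal_moments",
                mean = rr[[s]], sd = rr_sd[[s]], low = 1)
  specs
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: each iteration draws all
#' specifications jointly (independently across parameters), rebuilds the
#' model, runs both arms to `horizon` years and records net cost, QALYs
#' gained and deaths averted. Reproducible bit-for-bit given `seed`: a master
#' seed spawns one substream seed per iteration, so results do not depend on
#' evaluation order.
#'
#' @param params A `map_params` object.
#' @param specs List of [dist_spec()] objects;
#'   see [default_psa_specs()].
#' @param n_iter Number of iterations (>= 1).
#' @param seed Master seed (mandatory).
#' @param horizon Horizon in years.
#' @return An object of class `map_psa`: `draws` (one row per iteration with
#'   each sampled parameter and each output), `summary` (percentile
#'   intervals), `seed`, `n_iter`, `failures`.
#' @export
#' @examples
#' run_psa(default_params(), n_iter = 10, seed = 7)
run_psa <- function(params, specs = default_psa_specs(params),
                    n_iter = 1000L, seed, horizon = params$horizon) {
  stopifnot(n_iter >= 1)
  if (missing(seed)) stop("a seed is mandatory for the PSA")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
  paths <- vapply(specs, `[[`, "", "path")
  # control arm is invariant when no drawn parameter affects it
  control_paths <- c("effectiveness.mean", "effectiveness.sd",
                     grep("^intervention_cost", valid_param_paths(),
                          value = TRUE))
  fixed_control <- all(paths %in% control_paths)
  base_control <- if (fixed_control)
    run_cohort(params, "control", horizon = horizon, ledger = FALSE)
  else NULL
  if (any(paths == "effectiveness.mean") && is.null(params$records))
    params$records <- calibrate_cohort(params, seed = params$calibration_seed)
  one_iter <- function(i) {
    set.seed(sub_seeds[i])
    vals <- vapply(specs, sample_spec, 0)
    p <- params
    for (j in seq_along(specs)) p <- set_param(p, paths[j], vals[j])
    tm <- run_cohort(p, "map", horizon = horizon, ledger = FALSE)
    tc <- if (fixed_control) base_control
          else run_cohort(p, "control", horizon = horizon, ledger = FALSE)
    res <- compare_arms(tm, tc, horizon)
    c(vals, net_cost = res$net_cost, qalys_gained = res$qalys_gained,
      deaths_averted = res$deaths_averted)
  }
  rows <- vector("list", n_iter)
  failures <- integer(0)
  for (i in seq_len(n_iter)) {
    rows[i] <- list(tryCatch(one_iter(i), error = function(e) {
      warning(sprintf("PSA iteration %d failed: %s", i, conditionMessage(e)))
      NULL
    }))
    if (is.null(rows[[i]])) failures <- c(failures, i)
  }
  ok <- !vapply(rows, is.null, TRUE)
  if (!any(ok)) stop("all PSA iterations failed")
  draws <- as.data.frame(do.call(rbind, rows[ok]))
  names(draws) <- c(paths, "net_cost", "qalys_gained", "deaths_averted")
  draws <- cbind(iteration = which(ok), draws)
  summary <- lapply(c("net_cost", "qalys_gained", "deaths_averted"),
                    function(v) percentile_interval(draws[[v]], 0.9))
  names(summary) <- c("net_cost", "qalys_gained", "deaths_averted")
  structure(list(draws = draws, summary = summary, seed = seed,
                 n_iter = n_iter, horizon = horizon, failures = failures),
            class = "map_psa")
}

#' @export
print.map_psa <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d), %d-year horizon, %d failure(s)\n",
              x$n_iter, x$seed, x$horizon, length(x$failures)))
  for (v in names(x$summary))
    cat(sprintf("  %-15s median %15.1f   90%% interval [%.1f, %.1f]\n", v,
                stats::median(x$draws[[v]]), x$summary[[v]][1],
                x$summary[[v]][2]))
  invisible(x)
}

#' Empirical percentile interval
#'
#' Central interval from empirical quantiles at `(1 - level) / 2` and
#' `1 - (1 - level) / 2`, with linear interpolation (quantile type 7).
#'
#' @param samples Numeric vector (length >= 2).
#' @param level Coverage level in (0, 1).
#' @return Numeric length-2 vector `c(low, high)`.
#' @export
#' @examples
#' percentile_interval(1:100, 0.9)
percentile_interval <- function(samples, level = 0.9) {
  stopifnot(length(samples) >= 2, level > 0, level < 1)
  a <- (1 - level) / 2
  unname(stats::quantile(samples, c(a, 1 - a), type = 7))
}
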