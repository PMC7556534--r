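#' Phase-in fraction of medical-cost reductions
#'
#' Reductions in medical expenditure after symptom improvement accrue
#' gradually: none in the first year after treatment, then an additional 25%
#' of the full reduction in each successive year, saturating at 100% from
#' year five onward.
#'
#' @param t Cycle index (1-based), integer vector.
#' @param schedule Phase-in fractions for the first cycles; values beyond the
#'   schedule take its last entry.
#' @return Fractions in `[0, 1]`.
#' @export
#' @examples
#' phase_in_fraction(1:6)
phase_in_fraction <- function(t, schedule = c(0, 0.25, 0.5, 0.75, 1)) {
  if (any(t < 1) || any(t != floor(t)))
    stop("cycle index must be a positive integer")
  schedule[pmin(t, length(schedule))]
}

#' Discount a value to present terms
#'
#' End-of-cycle convention: flows of cycle `t` are divided by `(1 + r)^t`,
#' so the first annual cycle is discounted one full period.
#'
#' @param value Numeric flow(s).
#' @param t Cycle index (1-based).
#' @param rate Annual discount rate (>= 0).
#' @return Discounted value(s).
#' @export
#' @examples
#' discount(100, 1, 0.03)
discount <- function(value, t, rate) {
  if (any(rate < 0)) stop("discount rate must be non-negative")
  if (any(t < 1)) stop("cycle index must be at least 1")
  value / (1 + rate)^t
}

#' Advance the cohort one annual cycle
#'
#' Deaths in each state are `occupancy * min(1, q(age) * RR_state)`; products
#' exceeding 1 are clamped (with a warning). In the base case survivors stay
#' in their severity state. Under the disease-progression scenario a fraction
#' `progression` of survivors in each living state below extreme moves one
#' state worse; extreme-state patients progress no further.
#'
#' @param occupancy Named vector of living patients per severity state.
#' @param age Cohort age this cycle (years).
#' @param params A `map_params` object (supplies RRs and the life table).
#' @param progression Annual progression probability applied this cycle
#'   (0 for none).
#' @return List with `occupancy` (after deaths and any progression) and
#'   `deaths` (per state).
#' @export
cycle_step <- function(occupancy, age, params, progression = 0) {
  stopifnot(all(occupancy >= 0), progression >= 0, progression <= 1)
  q <- mortality_at(params$life_table, age)
  p_death <- q * params$mortality_rr
  if (any(p_death > 1)) {
    warning(sprintf("q(age %d) x RR exceeds 1 in %d state(s); clamped",
                    floor(age), sum(p_death > 1)))
    p_death <- pmin(1, p_death)
  }
  deaths <- occupancy * p_death
  surv <- occupancy - deaths
  if (progression > 0) {
    k <- length(surv)
    move <- surv[-k] * progression
    surv[-k] <- surv[-k] - move
    surv[-1] <- surv[-1] + move
  }
  list(occupancy = surv, deaths = deaths)
}

# slim engine used by run_cohort() and the PSA loop; returns cumulative
# discounted cost (incl. upfront), discounted QALYs and undiscounted deaths
# per horizon 1..T, plus the per-cycle ledger when ledger = TRUE
simulate_arm <- function(start, upfront, utility, cost, rr, life_table,
                         mean_age, rate, horizon, phase_in, intake_mix_cost,
                         blend, credit, progression = 0, prog_start = 6,
                         ledger = FALSE) {
  occ <- start
  cum_cost <- upfront + numeric(horizon)
  cum_qaly <- numeric(horizon)
  cum_death <- numeric(horizon)
  rows <- if (ledger) vector("list", horizon) else NULL
  cc <- cq <- cd <- 0
  clamped <- 0L
  for (t in seq_len(horizon)) {
    age <- mean_age + t - 1
    q <- mortality_at(life_table, age)
    p_death <- q * rr
    if (any(p_death > 1)) {
      clamped <- clamped + sum(p_death > 1)
      p_death <- pmin(1, p_death)
    }
    deaths <- occ * p_death
    surv <- occ - deaths
    py <- surv + credit * deaths      # person-years lived this cycle
    qaly <- sum(py * utility)
    cost_post <- sum(py * cost)
    med <- if (blend) {
      f <- phase_in_fraction(t, phase_in)
      (1 - f) * sum(py) * intake_mix_cost + f * cost_post
    } else {
      cost_post
    }
    disc <- (1 + rate)^-t
    cc <- cc + med * disc
    cq <- cq + qaly * disc
    cd <- cd + sum(deaths)
    cum_cost[t] <- upfront + cc
    cum_qaly[t] <- cq
    cum_death[t] <- cd
    if (progression > 0 && t >= prog_start) {
      k <- length(surv)
      move <- surv[-k] * progression
      surv[-k] <- surv[-k] - move
      surv[-1] <- surv[-1] + move
    }
    if (ledger) {
      rows[[t]] <- c(cycle = t, age = age, occ,
                     deaths = sum(deaths), medical_cost = med,
                     medical_cost_disc = med * disc, qalys = qaly,
                     qalys_disc = qaly * disc)
    }
    occ <- surv
  }
  if (clamped > 0)
    warning(sprintf(
      "background mortality x RR exceeded 1 in %d state-cycle(s); clamped",
      clamped))
  list(cum_cost = cum_cost, cum_qaly = cum_qaly, cum_death = cum_death,
       upfront = upfront,
       cycles = if (ledger) as.data.frame(do.call(rbind, rows)) else NULL)
}

#' Run one arm of the Markov cohort model
#'
#' The MAP arm starts from the post-treatment (follow-up) severity
#' distribution and is charged the per-patient intervention cost up front
#' (undiscounted, at time zero); the control arm starts from the intake
#' distribution with no upfront cost. Each annual cycle accrues deaths
#' (background mortality scaled by severity-specific relative risks), medical
#' costs and QALYs, discounted end-of-cycle. Decedents receive a half-cycle
#' of utility and medical cost by default (`params$decedent_credit`).
#'
#' During the phase-in of cost reductions the MAP arm's cycle-t medical cost
#' is a cohort-level blend: `(1 - f_t) * C_baseline(t) + f_t * C_post(t)`,
#' where `C_post` prices current survivors at their state costs and
#' `C_baseline` prices the same person-years at the intake-distribution cost
#' mix. Mortality always follows the post-treatment states immediately; only
#' costs are phased.
#'
#' @param params A `map_params` object.
#' @param arm `"map"` or `"control"`.
#' @param horizon Analytic horizon in years (defaults to `params$horizon`).
#' @param scenario Optional progression scenario, a list with `p_prog`
#'   (annual probability) and `start_cycle` (first cycle it applies,
#'   default 6, i.e. after year five). Applies to the MAP arm only.
#' @param ledger Keep the per-cycle ledger (disable for speed in large
#'   Monte Carlo loops; cumulative series are always kept).
#' @return An object of class `map_trajectory`: per-cycle ledger plus
#'   cumulative discounted costs/QALYs and undiscounted deaths by horizon.
#' @export
#' @examples
#' run_cohort(default_params(), "control", horizon = 5)
run_cohort <- function(params, arm = c("map", "control"),
                       horizon = params$horizon, scenario = NULL,
                       ledger = TRUE) {
  arm <- match.arg(arm)
  stopifnot(horizon >= 1)
  p <- resolve_effectiveness(params)
  start <- if (arm == "map") p$followup_distribution else p$intake_distribution
  cost <- effective_costs(p)
  upfront <- if (arm == "map") p$intervention_cost$total * sum(start) else 0
  intake_mix <- sum(p$intake_distribution * cost) / sum(p$intake_distribution)
  prog <- if (!is.null(scenario) && arm == "map") scenario$p_prog else 0
  prog_start <- if (!is.null(scenario) && !is.null(scenario$start_cycle))
    scenario$start_cycle else 6
  sim <- simulate_arm(
    start = start, upfront = upfront, utility = p$utility, cost = cost,
    rr = p$mortality_rr, life_table = p$life_table, mean_age = p$mean_age,
    rate = p$discount_rate, horizon = horizon, phase_in = p$phase_in,
    intake_mix_cost = intake_mix, blend = (arm == "map"),
    credit = p$decedent_credit, progression = prog, prog_start = prog_start,
    ledger = ledger
  )
  structure(
    list(arm = arm, horizon = horizon, cohort_size = sum(start),
         upfront_cost = upfront, cycles = sim$cycles,
         cumulative = data.frame(horizon = seq_len(horizon),
                                 cost_disc = sim$cum_cost,
                                 qalys_disc = sim$cum_qaly,
                                 deaths = sim$cum_death)),
    class = "map_trajectory"
  )
}

# medical costs after the inflation multiplier and the symptomatic-state
# scaling used by threshold/sensitivity analyses (asymptomatic unscaled)
effective_costs <- function(params) {
  cost <- params$annual_cost * params$inflation_multiplier
  sym <- setdiff(severity_states(), "asymptomatic")
  cost[sym] <- cost[sym] * params$medical_cost_multiplier
  cost
}

# When the effectiveness mean has been moved off the base case, re-derive the
# follow-up severity distribution by shifting the calibrated synthetic cohort.
resolve_effectiveness <- function(params) {
  if (abs(params$effectiveness$mean - params$base_effect_mean) < 1e-12)
    return(params)
  records <- params$records
  if (is.null(records))
    records <- calibrate_cohort(params, seed = params$calibration_seed)
  params$followup_distribution <-
    apply_effect_shift(records, params$effectiveness$mean,
                       bands = params$bands)
  params
}

#' @export
print.map_trajectory <- function(x, ...) {
  cat(sprintf("Markov trajectory: %s arm, %d patients, %d annual cycles\n",
              x$arm, round(x$cohort_size), x$horizon))
  cat(sprintf("  upfront cost $%s; at horizon: cost $%s, QALYs %.0f, deaths %.1f\n",
              formatC(round(x$upfront_cost), format = "d", big.mark = ","),
              formatC(round(x$cumulative$cost_disc[x$horizon]),
                      format = "d", big.mark = ","),
              x$cumulative$qalys_disc[x$horizon],
              x$cumulative$deaths[x$horizon]))
  invisible(x)
}

#' Tidy per-cycle ledger of one or more trajectories
#'
#' @param ... `map_trajectory` objects.
#' @return A data.frame with one row per cycle per arm: occupancy per state,
#'   deaths, undiscounted and discounted medical cost and QALYs.
#' @export
trajectory_df <- function(...) {
  trajs <- list(...)
  out <- lapply(trajs, function(tr) {
    cbind(arm = tr$arm, tr$cycles, row.names = NULL)
  })
  do.call(rbind, out)
}
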