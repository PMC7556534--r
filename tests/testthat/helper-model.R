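# shared fixtures built in code

# constant-hazard life table over a wide age span
flat_life_table <- function(q = 0.01, ages = 20:150) {
  life_table(ages, rep(q, length(ages)))
}

# small fully-specified model useful for hand-checkable ledgers: 100
# patients, constant background hazard, flat discounting unless overridden
toy_params <- function(q = 0.01, r = 0, credit = 0.5,
                       intake = c(asymptomatic = 60, mild = 0, moderate = 0,
                                  severe = 0, extreme = 40),
                       followup = c(asymptomatic = 70, mild = 0,
                                    moderate = 0, severe = 0, extreme = 30),
                       utility = c(asymptomatic = 1, mild = 0.9,
                                   moderate = 0.8, severe = 0.7,
                                   extreme = 0.5),
                       cost = c(asymptomatic = 0, mild = 25, moderate = 50,
                                severe = 75, extreme = 100),
                       rr = c(asymptomatic = 1, mild = 1.2, moderate = 1.4,
                              severe = 1.7, extreme = 2)) {
  p <- default_params(life_table = flat_life_table(q))
  p$intake_distribution <- intake
  p$followup_distribution <- followup
  p$utility <- utility
  p$annual_cost <- cost
  p$mortality_rr <- rr
  p$discount_rate <- r
  p$decedent_credit <- credit
  p$cohort_size <- sum(intake)
  p$intervention_cost <- intervention_cost(c(protocol = 10))
  p
}

# independent ledger oracle: a literal transcription of the cycle
# accounting rules, kept free of the package engine
oracle_ledger <- function(start, utility, cost, rr, q, r, T, credit,
                          upfront = 0, blend = FALSE,
                          phase_in = c(0, 0.25, 0.5, 0.75, 1),
                          intake_mix_cost = NULL) {
  occ <- start
  cum_cost <- upfront; cum_qaly <- 0; cum_death <- 0
  out <- NULL
  for (t in 1:T) {
    deaths <- occ * pmin(1, q * rr)
    surv <- occ - deaths
    py <- surv + credit * deaths
    qaly <- sum(py * utility)
    med <- sum(py * cost)
    if (blend) {
      f <- phase_in[min(t, length(phase_in))]
      med <- (1 - f) * sum(py) * intake_mix_cost + f * med
    }
    cum_cost <- cum_cost + med / (1 + r)^t
    cum_qaly <- cum_qaly + qaly / (1 + r)^t
    cum_death <- cum_death + sum(deaths)
    out <- rbind(out, c(cost = cum_cost, qaly = cum_qaly,
                        deaths = cum_death))
    occ <- surv
  }
  as.data.frame(out)
}

# published base-case anchors used across tests
published <- list(
  net_cost_1y = 7608691, qalys_gained_1y = 288, icer_1y = 26427,
  net_cost_10y = -36657271, qalys_gained_10y = 2517,
  net_cost_30y = -103155236, qalys_gained_30y = 5553,
  break_even = 3.1, cost_multiplier_threshold = 0.193, icer_at_10pct = 2124
)
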