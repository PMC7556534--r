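test_that("cost-reduction phase-in follows the five-year schedule", {
  expect_equal(phase_in_fraction(1:5), c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(phase_in_fraction(40), 1)
  expect_error(phase_in_fraction(0), "positive integer")
  expect_error(phase_in_fraction(1.5), "positive integer")
})

test_that("discounting uses the end-of-cycle convention", {
  expect_equal(discount(100, 1, 0.03), 100 / 1.03)
  expect_equal(discount(100, 2, 0.03), 100 / 1.03^2)
  expect_equal(discount(123.4, 7, 0), 123.4)
  expect_error(discount(1, 1, -0.01), "non-negative")
})

test_that("cycle deaths follow background hazard scaled by relative risk", {
  p <- default_params()
  # an all-asymptomatic cohort dies at exactly the background rate
  occ <- c(asymptomatic = 1000, mild = 0, moderate = 0, severe = 0,
           extreme = 0)
  st <- cycle_step(occ, 40, p)
  expect_equal(sum(st$deaths), 1000 * 0.00139)
  expect_equal(unname(st$occupancy[1]), 1000 * (1 - 0.00139))
  # hand arithmetic on the printed intake mix and relative risks
  occ2 <- c(asymptomatic = 0, mild = 0, moderate = 122, severe = 311,
            extreme = 568)
  st2 <- cycle_step(occ2, 40, p)
  expect_equal(sum(st2$deaths),
               0.00139 * (122 * 2.05 + 311 * 2.51 + 568 * 2.76),
               tolerance = 1e-12)
  # progression moves a fraction of survivors one state worse
  occ3 <- c(asymptomatic = 0, mild = 0, moderate = 100, severe = 0,
            extreme = 0)
  p_flat <- toy_params(q = 1e-15)
  st3 <- cycle_step(occ3, 40, p_flat, progression = 0.06)
  expect_equal(unname(st3$occupancy[c("moderate", "severe")]), c(94, 6),
               tolerance = 1e-9)
})

test_that("persons are conserved exactly each cycle", {
  for (arm in c("map", "control")) {
    traj <- run_cohort(default_params(), arm, horizon = 40)
    cyc <- traj$cycles
    living <- rowSums(cyc[, severity_states()])
    # occupancy recorded at cycle start: living(t) + deaths up to t-1 = N
    expect_equal(living + c(0, cumsum(cyc$deaths))[seq_len(nrow(cyc))],
                 rep(traj$cohort_size, nrow(cyc)), tolerance = 1e-9)
  }
})

test_that("without severity transitions each state only loses its own dead", {
  traj <- run_cohort(default_params(), "map", horizon = 20)
  cyc <- traj$cycles
  p <- default_params()
  for (s in severity_states()) {
    occ <- cyc[[s]]
    q <- mortality_at(p$life_table, cyc$age) * p$mortality_rr[[s]]
    expect_equal(occ[-1], (occ * (1 - q))[-length(occ)], tolerance = 1e-9)
  }
})

test_that("QALYs equal person-years when utilities are 1 and mortality nil", {
  p <- toy_params(q = 1e-15, r = 0)
  p$utility[] <- 1
  traj <- run_cohort(p, "control", horizon = 7)
  expect_equal(traj$cumulative$qalys_disc[7], sum(p$intake_distribution) * 7,
               tolerance = 1e-6)
})

test_that("the engine matches an independent ledger oracle", {
  for (credit in c(0.5, 0)) {
    p <- toy_params(q = 0.01, r = 0, credit = credit)
    ctrl <- run_cohort(p, "control", horizon = 3)
    want <- oracle_ledger(p$intake_distribution, p$utility, p$annual_cost,
                          p$mortality_rr, q = 0.01, r = 0, T = 3,
                          credit = credit)
    expect_equal(ctrl$cumulative$cost_disc, want$cost, tolerance = 1e-9)
    expect_equal(ctrl$cumulative$qalys_disc, want$qaly, tolerance = 1e-9)
    expect_equal(ctrl$cumulative$deaths, want$deaths, tolerance = 1e-9)
    # MAP arm adds the upfront charge and the phased cost blend
    p2 <- toy_params(q = 0.02, r = 0.05, credit = credit)
    mapa <- run_cohort(p2, "map", horizon = 6)
    mix <- sum(p2$intake_distribution * p2$annual_cost) /
      sum(p2$intake_distribution)
    want2 <- oracle_ledger(p2$followup_distribution, p2$utility,
                           p2$annual_cost, p2$mortality_rr, q = 0.02,
                           r = 0.05, T = 6, credit = credit,
                           upfront = 10 * sum(p2$followup_distribution),
                           blend = TRUE, intake_mix_cost = mix)
    expect_equal(mapa$cumulative$cost_disc, want2$cost, tolerance = 1e-9)
    expect_equal(mapa$cumulative$qalys_disc, want2$qaly, tolerance = 1e-9)
  }
})

test_that("everyone eventually dies on a long enough horizon", {
  p <- default_params(life_table = synthetic_gompertz_table(0.00139, 40,
                                                            0.085, 110))
  traj <- suppressWarnings(run_cohort(p, "control", horizon = 200))
  expect_equal(traj$cumulative$deaths[200], traj$cohort_size, tolerance = 1e-3)
  expect_warning(run_cohort(p, "control", horizon = 200), "clamped")
})

test_that("discounted totals are non-increasing in the discount rate", {
  rates <- c(0, 0.01, 0.03, 0.08, 0.15)
  totals <- sapply(rates, function(r) {
    p <- set_param(default_params(), "discount_rate", r)
    tr <- run_cohort(p, "control", horizon = 30)
    c(tr$cumulative$cost_disc[30], tr$cumulative$qalys_disc[30])
  })
  expect_true(all(diff(totals[1, ]) < 0))
  expect_true(all(diff(totals[2, ]) < 0))
})

test_that("treated arm gains QALYs when follow-up dominates intake", {
  p <- default_params()
  # first-order stochastic dominance on the severity ordering
  cum_int <- cumsum(p$intake_distribution)
  cum_fup <- cumsum(p$followup_distribution)
  expect_true(all(cum_fup >= cum_int))
  tm <- run_cohort(p, "map", 30); tc <- run_cohort(p, "control", 30)
  expect_true(all(tm$cumulative$qalys_disc >= tc$cumulative$qalys_disc))
})

test_that("cumulative series are non-decreasing in horizon", {
  tr <- run_cohort(default_params(), "map", 30)
  expect_true(all(diff(tr$cumulative$cost_disc) > 0))
  expect_true(all(diff(tr$cumulative$qalys_disc) > 0))
  expect_true(all(diff(tr$cumulative$deaths) > 0))
})
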