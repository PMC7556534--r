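test_that("one-way spans equal endpoint recomputation and sort descending", {
  p <- default_params()
  p$horizon <- 10
  ranges <- data.frame(
    path = c("discount_rate", "intervention_cost.total", "utility.moderate"),
    low = c(0.023, 5280, 0.766), base = c(0.03, 7544, 0.851),
    high = c(0.038, 9807, 0.936))
  tor <- one_way(p, ranges)
  expect_equal(nrow(tor), 3)
  expect_true(all(diff(tor$span) <= 0))
  # brute-force recomputation of each endpoint
  for (i in seq_len(nrow(tor))) {
    lo <- evaluate_model(set_param(p, tor$path[i], tor$low[i]), 10)$net_cost
    hi <- evaluate_model(set_param(p, tor$path[i], tor$high[i]), 10)$net_cost
    expect_equal(tor$output_low[i], lo)
    expect_equal(tor$output_high[i], hi)
    expect_equal(tor$span[i], abs(hi - lo))
  }
  # utilities cannot move net cost
  expect_equal(tor$span[tor$path == "utility.moderate"], 0)
})

test_that("degenerate ranges reproduce the base case exactly", {
  p <- default_params()
  p$horizon <- 5
  base <- evaluate_model(p, 5)$net_cost
  ranges <- data.frame(path = "discount_rate", low = 0.03, base = 0.03,
                       high = 0.03)
  tor <- one_way(p, ranges)
  expect_equal(tor$span, 0)
  expect_equal(tor$output_low, base)
  expect_equal(attr(tor, "base_output"), base)
  expect_error(one_way(p, data.frame(path = "discount_rate", low = 0.05,
                                     base = 0.03, high = 0.06)),
               "low <= base <= high")
})

test_that("medical-cost scaling dominates the tornado", {
  p <- default_params()
  tor <- one_way(p)
  expect_equal(tor$path[1], "medical_cost_multiplier")
})

test_that("two-way grids equal independent runs", {
  p <- default_params()
  g11 <- two_way(p, "discount_rate", 0.03, "horizon", 30)
  expect_equal(g11$output, evaluate_model(p, 30)$net_cost)
  costs <- c(4000, 20000); hzs <- c(5, 30)
  gr <- two_way(p, "intervention_cost.total", costs, "horizon", hzs)
  expect_equal(nrow(gr), 4)
  for (i in seq_len(4)) {
    pi <- set_param(p, "intervention_cost.total", gr[i, 1])
    pi$horizon <- gr[i, 2]
    expect_equal(gr$output[i], evaluate_model(pi, gr[i, 2])$net_cost)
  }
  expect_equal(dim(attr(gr, "matrix")), c(2, 2))
})

test_that("bisection finds monotone crossings and rejects bad brackets", {
  expect_equal(mapcea:::bisect_root(function(x) x - 0.5, 0, 1), 0.5,
               tolerance = 1e-6)
  expect_equal(mapcea:::bisect_root(function(x) exp(x) - 10, 0, 5), log(10),
               tolerance = 1e-5)
  expect_error(mapcea:::bisect_root(function(x) x + 1, 0, 1),
               "no sign change")
})

test_that("threshold values substitute back to near-zero net cost", {
  p <- default_params()
  thr <- cost_threshold(p, "medical_cost_multiplier", c(0.05, 1))
  res <- evaluate_model(set_param(p, "medical_cost_multiplier", thr), 30)
  expect_lt(abs(res$net_cost), 1)
  # per-patient intervention price that breaks even over five years
  p5 <- default_params(); p5$horizon <- 5
  thr5 <- cost_threshold(p5, "intervention_cost.total", c(0, 20000))
  expect_equal(thr5, 16232, tolerance = 0.1)
  res5 <- evaluate_model(set_param(p5, "intervention_cost.total", thr5), 5)
  expect_lt(abs(res5$net_cost), 1)
})

test_that("an expensive intervention at a short horizon yields a small ICER", {
  p <- default_params(); p$horizon <- 5
  p <- set_param(p, "intervention_cost.total", 20000)
  res <- evaluate_model(p, 5)
  expect_equal(res$flag, "icer")
  expect_equal(res$icer, 2779, tolerance = 0.2)
})

test_that("progression scenario degrades savings monotonically", {
  p <- default_params()
  base <- evaluate_model(p, 30)
  none <- progression_scenario(p, p_prog = 0)
  expect_equal(none$net_cost, base$net_cost)
  expect_equal(none$qalys_gained, base$qalys_gained)
  nets <- sapply(c(0, 0.03, 0.06, 0.12, 0.2),
                 function(pp) progression_scenario(p, pp)$net_cost)
  expect_true(all(diff(nets) > 0))  # savings shrink as progression rises
  expect_error(progression_scenario(p, 0.5), "0, 0.2")
})

test_that("total relapse drives all treated survivors to the extreme state", {
  p <- toy_params(q = 1e-15)
  p$followup_distribution <- c(asymptomatic = 20, mild = 20, moderate = 20,
                               severe = 20, extreme = 20)
  p$intake_distribution <- c(asymptomatic = 0, mild = 0, moderate = 0,
                             severe = 0, extreme = 100)
  traj <- run_cohort(p, "map", horizon = 9,
                     scenario = list(p_prog = 1, start_cycle = 5))
  occ9 <- traj$cycles[9, severity_states()]
  expect_equal(unname(unlist(occ9)),
               c(0, 0, 0, 0, 100), tolerance = 1e-9)
  # four full steps are needed: one state still occupied a cycle earlier
  occ8 <- traj$cycles[8, severity_states()]
  expect_gt(sum(unlist(occ8)[1:4]), 0)
})
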