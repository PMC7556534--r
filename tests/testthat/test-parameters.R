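test_that("CAPS banding follows the published cutpoints and floors scores", {
  expect_equal(classify_caps(0), "asymptomatic")
  expect_equal(classify_caps(c(19, 20)), c("asymptomatic", "mild"))
  expect_equal(classify_caps(c(39, 40, 59, 60, 79, 80, 85)),
               c("mild", "moderate", "moderate", "severe", "severe",
                 "extreme", "extreme"))
  # non-integer scores floored before banding
  expect_equal(classify_caps(c(19.9, 59.7)), c("asymptomatic", "moderate"))
  expect_error(classify_caps(-1), "non-negative")
  expect_error(classify_caps(NA_real_), "finite")
})

test_that("classification is total and monotone over the score range", {
  states <- severity_states()
  scores <- seq(0, 200, by = 0.5)
  idx <- match(classify_caps(scores), states)
  expect_false(anyNA(idx))
  expect_true(all(diff(idx) >= 0))
})

test_that("state costs derive from the severe anchor", {
  got <- derive_state_costs(19888)
  expect_equal(unname(got[c("moderate", "mild", "extreme")]),
               c(14916, 9944, 23866))
  expect_equal(got[["asymptomatic"]], 4946)
  expect_equal(unname(derive_state_costs(
    100, asymptomatic_cost = 10)[c("extreme", "moderate", "mild")]),
    c(120, 75, 50))
  # the alternative pooled anchor quoted in running text
  expect_equal(derive_state_costs(19899)[["extreme"]], 23879)
  expect_error(derive_state_costs(0), "positive")
  expect_error(derive_state_costs(100, multipliers = c(mild = 0.5)),
               "multipliers")
})

test_that("mortality relative risks derive from the pooled anchor", {
  got <- round(derive_mortality_rrs(2.28), 2)
  expect_equal(unname(got[c("mild", "moderate", "severe", "extreme")]),
               c(1.74, 2.05, 2.51, 2.76))
  expect_equal(got[["asymptomatic"]], 1)
  base1 <- derive_mortality_rrs(1)
  expect_equal(unname(base1[c("mild", "moderate", "severe", "extreme")]),
               c(0.765, 0.9, 1.1, 1.21))
  base2 <- derive_mortality_rrs(2)
  expect_equal(unname(base2[c("severe", "extreme")]), c(2.2, 2.42))
  expect_error(derive_mortality_rrs(0.9), ">= 1")
})

test_that("cost pooling weights by the square root of sample size", {
  expect_equal(pool_cost_estimates(c(100, 200), c(4, 16)), 500 / 3)
  expect_equal(pool_cost_estimates(150, 9), 150)
  # equal n reduces to the arithmetic mean
  expect_equal(pool_cost_estimates(c(10, 20, 60), c(7, 7, 7)), 30)
  # order invariance and containment within the input range
  set.seed(42)
  for (i in 1:5) {
    cost <- runif(6, 100, 1000); n <- sample(1:50, 6)
    perm <- sample(6)
    pooled <- pool_cost_estimates(cost, n)
    expect_equal(pool_cost_estimates(cost[perm], n[perm]), pooled)
    expect_gte(pooled, min(cost))
    expect_lte(pooled, max(cost))
  }
  expect_error(pool_cost_estimates(numeric(0), numeric(0)), "at least one")
  expect_error(pool_cost_estimates(100, 0), "positive")
})

test_that("intervention cost totals its micro-costed components", {
  ic <- intervention_cost()
  expect_lte(abs(ic$total - 7543), 2)   # printed components are rounded
  expect_equal(round(100 * 353 / 7543, 1), 4.7)  # pharmaceutical share
  expect_equal(sum(ic$shares), 1)
  single <- intervention_cost(c(only = 100))
  expect_equal(single$total, 100)
  expect_equal(unname(single$shares), 1)
  expect_error(intervention_cost(c(5, 10)), "named")
  expect_error(intervention_cost(c(a = -1)), "non-negative")
})

test_that("largest-remainder apportionment resolves the printed intake", {
  expect_equal(largest_remainder(c(12.2, 31.1, 56.8), 1000),
               c(122, 311, 567))
  expect_equal(sum(largest_remainder(c(1, 1, 1), 100)), 100)
  expect_equal(largest_remainder(c(25, 25, 25, 25), 8), rep(2, 4))
})

test_that("base-case parameters reproduce the printed inputs", {
  p <- default_params()
  expect_equal(unname(p$followup_distribution), c(216, 270, 135, 230, 149))
  expect_equal(sum(p$intake_distribution), 1000)
  expect_equal(sum(p$followup_distribution), 1000)
  expect_equal(unname(p$intake_distribution), c(0, 0, 122, 311, 567))
  expect_equal(unname(p$utility), c(1, 0.97, 0.851, 0.477, 0.369))
  expect_equal(unname(p$annual_cost), c(4946, 9944, 14916, 19888, 23866))
  expect_equal(p$discount_rate, 0.03)
  expect_equal(p$phase_in, c(0, 0.25, 0.5, 0.75, 1))
  # idempotent construction
  expect_equal(default_params()[setdiff(names(p), "life_table")],
               p[setdiff(names(p), "life_table")])
  # printed variant keeps the raw counts (which sum to 1,001)
  expect_equal(sum(default_params(intake = "printed")$intake_distribution),
               1001)
})

test_that("overrides apply by path and unknown paths are rejected", {
  p <- default_params(overrides = list(discount_rate = 0))
  expect_equal(p$discount_rate, 0)
  expect_equal(p$utility, default_params()$utility)
  p2 <- set_param(default_params(), "utility.moderate", 0.9)
  expect_equal(p2$utility[["moderate"]], 0.9)
  # scaling the intervention total keeps component shares
  p3 <- set_param(default_params(), "intervention_cost.total", 20000)
  expect_equal(p3$intervention_cost$total, 20000)
  expect_equal(p3$intervention_cost$shares,
               default_params()$intervention_cost$shares)
  expect_error(set_param(default_params(), "not.a.path", 1),
               "valid paths are")
  expect_error(default_params(overrides = list(nonsense = 1)), "valid paths")
})

test_that("parameter files round-trip through YAML and JSON", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("discount_rate: 0.0", "mean_age: 45"), yml)
  p <- read_params_file(yml)
  expect_equal(p$discount_rate, 0)
  expect_equal(p$mean_age, 45)
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(list(discount_rate = 0.05), jsn, auto_unbox = TRUE)
  expect_equal(read_params_file(jsn)$discount_rate, 0.05)
  expect_error(read_params_file("no-such-file.yaml"), "not found")
})
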