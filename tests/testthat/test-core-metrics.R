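test_that("dalys_per_1000 is the reciprocal ratio and rejects bad input", {
  expect_equal(dalys_per_1000(1000), 1.0)
  expect_equal(dalys_per_1000(50), 20.0)
  # a $22/DALY intervention averts ~45 DALYs per $1000 after table rounding
  expect_equal(round(dalys_per_1000(22)), 45)
  expect_error(dalys_per_1000(0), "positive")
  expect_error(dalys_per_1000(-5), "positive")
  # cost-saving entries have no defined ratio
  expect_true(is.na(dalys_per_1000(c(10, NA), cost_saving = c(FALSE, TRUE))[2]))
})

test_that("value metrics scale linearly and implement the net-DALY formula", {
  econ <- economy_params(61, numeric(0))
  iv <- toy_interventions(data.frame(
    id = c("a", "b", "c", "d"),
    icer = c(NA, 50, 61, 10),
    cost_saving = c(TRUE, FALSE, FALSE, FALSE),
    cost_full = c(-6100, 1000, 61000, 0),
    dalys_full = c(100, 500, 1000, 400),
    level = c(1, 0.13, 1, 1)))

  vm <- value_metrics(iv, "full", econ)
  # cost-saving adds the health its savings can buy: 100 - (-6100/61) = 200
  expect_equal(vm$net_dalys[1], 200)
  # exactly-at-threshold intervention nets zero
  expect_equal(vm$net_dalys[3], 0)
  expect_equal(vm$financial_value[3], 0)
  # zero-cost intervention nets its full DALYs
  expect_equal(vm$net_dalys[4], 400)

  # partial implementation scales components linearly
  vma <- value_metrics(iv, "actual", econ)
  expect_equal(vma$total_dalys[2], 500 * 0.13)
  expect_equal(vma$total_cost[2], 1000 * 0.13)

  expect_error(value_metrics(iv, 1.2, econ), "\\[0, 1\\]")
})

test_that("the published schistosomiasis partial-implementation DALYs reproduce", {
  iv <- toy_interventions(data.frame(id = "s", icer = 29,
                                     cost_full = 76527, dalys_full = 23754))
  vm <- value_metrics(iv, 0.13, economy_params(61, numeric(0)))
  expect_equal(round(vm$total_dalys), 3088)
})

test_that("scale_metrics is the identity at level 1, zero at level 0", {
  econ <- economy_params(61, numeric(0))
  iv <- simulate_interventions(8, seed = 11)
  full <- value_metrics(iv, "full", econ)
  expect_equal(scale_metrics(full, 1), full)
  z <- scale_metrics(full, 0)
  expect_true(all(z$total_cost == 0 & z$total_dalys == 0 &
                  z$net_dalys == 0 & z$financial_value == 0))
  expect_error(scale_metrics(full, 1.01), "\\[0, 1\\]")
  expect_error(scale_metrics(scale_metrics(full, 0.5), 0.5), "level 1")
})

test_that("financial value / k round-trips to net DALYs for generated sets", {
  for (seed in 1:5) {
    set.seed(seed)
    iv <- simulate_interventions(30, seed = seed)
    k <- exp(stats::runif(1, log(5), log(500)))
    vm <- value_metrics(iv, "actual", economy_params(k, numeric(0)))
    expect_equal(vm$financial_value / k, vm$net_dalys, tolerance = 1e-12)
  }
})

test_that("sign rule: net DALYs positive iff ICER below k for consistent records", {
  iv <- simulate_interventions(60, seed = 7)
  pos <- !iv$cost_saving
  for (k in c(10, 61, 500)) {
    vm <- value_metrics(iv, "full", economy_params(k, numeric(0)))
    expect_equal(vm$net_dalys[pos] > 0, iv$icer[pos] < k)
  }
})

test_that("net DALYs are monotonically increasing in k for cost-positive interventions", {
  iv <- simulate_interventions(20, seed = 3)
  iv <- iv[!iv$cost_saving & iv$cost_full > 0, ]
  ks <- c(5, 20, 61, 200, 1000)
  nets <- sapply(ks, function(k)
    value_metrics(iv, "full", economy_params(k, numeric(0)))$net_dalys)
  for (i in seq_len(nrow(nets)))
    expect_true(all(diff(nets[i, ]) > 0))
})

test_that("evaluating at level a*b equals scaling level-a metrics by b", {
  econ <- economy_params(61, numeric(0))
  iv <- simulate_interventions(15, seed = 21)
  full <- value_metrics(iv, "full", econ)
  for (case in list(c(0.3, 0.5), c(1, 0.2), c(0.7, 1))) {
    a <- case[1]; b <- case[2]
    direct <- value_metrics(iv, a * b, econ)
    staged <- scale_metrics(full, a)
    staged <- data.frame(intervention_id = staged$intervention_id,
                         implementation = staged$implementation * b,
                         total_cost = staged$total_cost * b,
                         total_dalys = staged$total_dalys * b,
                         net_dalys = NA, financial_value = NA)
    staged$net_dalys <- staged$total_dalys - staged$total_cost / 61
    staged$financial_value <- staged$net_dalys * 61
    expect_equal(direct$total_cost, staged$total_cost, tolerance = 1e-12)
    expect_equal(direct$net_dalys, staged$net_dalys, tolerance = 1e-12)
  }
})

test_that("metric_delta subtracts matched rows exactly", {
  econ <- economy_params(61, numeric(0))
  set.seed(5)
  iv <- simulate_interventions(12, seed = 5)
  full <- value_metrics(iv, "full", econ)
  actual <- value_metrics(iv, "actual", econ)
  d <- metric_delta(full, actual[sample(nrow(actual)), ])
  expect_equal(d$total_dalys, full$total_dalys - actual$total_dalys)
  expect_equal(d$net_dalys, full$net_dalys - actual$net_dalys)
})

test_that("intervention validation enforces the domain invariants", {
  base <- data.frame(id = "x", name = "X", icer = 10, cost_saving = FALSE,
                     cases = 10, cost_full = 100, dalys_full = 10, level = 0.5)
  expect_s3_class(interventions(base), "interventions")
  bad <- base; bad$level <- 1.3
  expect_error(interventions(bad), "\\[0, 1\\]")
  bad <- base; bad$cost_full <- -5
  expect_error(interventions(bad), "cost-saving")
  bad <- base; bad$icer <- NA
  expect_error(interventions(bad), "cost-saving")
  bad <- base; bad$cases <- -1
  expect_error(interventions(bad), "cases")
  expect_error(interventions(rbind(base, base)), "unique")
})

test_that("economy_params validates k and scenario ordering", {
  expect_error(economy_params(0), "> 0")
  expect_error(economy_params(61, c(A = 100, B = 50)), "increasing")
  expect_error(economy_params(61, c(61, 372)), "labelled")
  econ <- economy_params(61, c(A = 61, B = 372, C = 1116))
  expect_equal(econ$threshold_scenarios[["C"]], 1116)
})
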