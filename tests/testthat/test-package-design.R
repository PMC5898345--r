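test_that("rank_by_icer puts cost-savers first, then ascending ICER with stable ties", {
  iv <- toy_interventions(data.frame(
    id = c("a", "b", "c", "d", "e"),
    name = c("Zeta", "Alpha", "Beta", "Gamma", "Saver"),
    icer = c(29, 22, 29, 29, NA),
    cost_saving = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    cost_full = c(10, 10, 10, 10, -5),
    dalys_full = c(1, 1, 1, 1, 1)))
  r <- rank_by_icer(iv)
  expect_equal(r$id, c("e", "b", "c", "d", "a"))  # saver, 22, then 29s by name
  expect_equal(r$icer_order, 1:5)
  expect_error(rank_by_icer(iv[0, ]), "empty")
})

test_that("ICER ties order deterministically, matching an exhaustive comparison sort", {
  set.seed(9)
  iv <- simulate_interventions(25, seed = 9)
  iv$icer[!iv$cost_saving] <- sample(c(10, 20, 30), sum(!iv$cost_saving), TRUE)
  r <- rank_by_icer(iv)
  key <- ifelse(iv$cost_saving, -Inf, iv$icer)
  expected <- iv$id[order(key, iv$name, iv$id)]
  expect_equal(r$id, expected)
})

test_that("Malawi league ranks: cotrimoxazole tops the ICER order, mass media second", {
  r <- rank_by_icer(malawi_interventions())
  expect_equal(r$name[1], "Cotrimoxazole for children")
  expect_equal(r$name[2], "Mass media")
})

test_that("threshold selection at k=$61 reproduces the 48-intervention, ~$265M package", {
  iv <- malawi_interventions()
  pkg <- hbp_select(iv, economy_params(61))
  expect_length(pkg$included_ids, 48)
  expect_equal(round(pkg$budget / 1e6), 265)
  expect_setequal(pkg$included_ids, iv$id[iv$icer_rank <= 48])
  # inclusion boundary: every cost-positive member has icer <= k, every
  # cost-positive non-member icer > k
  inc <- iv[iv$id %in% pkg$included_ids & !iv$cost_saving, ]
  exc <- iv[!iv$id %in% pkg$included_ids & !iv$cost_saving, ]
  expect_true(all(inc$icer <= 61))
  expect_true(all(exc$icer > 61))
})

test_that("threshold selection handles edge thresholds", {
  iv <- toy_interventions(data.frame(id = c("a", "b"), icer = c(100, 200),
                                     cost_full = c(10, 20), dalys_full = c(1, 1)))
  empty <- hbp_select(iv, economy_params(50, numeric(0)))
  expect_length(empty$included_ids, 0)
  expect_equal(empty$budget, 0)
  all_in <- hbp_select(iv, economy_params(201, numeric(0)))
  expect_equal(all_in$budget, 30)
})

test_that("frontier cumulative costs are exact sums", {
  iv <- malawi_interventions()
  ft <- frontier_table(iv)
  # after the two most net-valuable interventions (circumcision + obstructed
  # labour) cumulative spend is ~$147.8M
  cum2 <- sum(iv$cost_full[iv$name %in%
    c("Male circumcision", "Management of obstructed labour")])
  expect_equal(round(cum2 / 1000), 147830)
  expect_equal(ft$cumulative_cost[nrow(ft)], sum(iv$cost_full))

  one <- frontier_table(iv[5, ])
  expect_equal(one$cumulative_cost, one$cost_full)

  syn <- simulate_interventions(40, seed = 2)
  expect_equal(frontier_table(syn)$cumulative_cost[40], sum(syn$cost_full))
})

test_that("net-DALY league table reorders away from the ICER ranking", {
  iv <- malawi_interventions()
  lt <- league_table(iv, economy_params(61), "full")
  expect_equal(lt$name[1], "Male circumcision")
  # ICER rank 30 climbs to second place on net-DALY scale
  expect_equal(lt$name[2], "Management of obstructed labour")
  expect_equal(iv$icer_rank[iv$name == lt$name[2]], 30)
  expect_true(all(diff(lt$net_dalys) <= 1e-9))
})

test_that("league table breaks net-DALY ties by name", {
  iv <- toy_interventions(data.frame(
    id = c("x", "y", "z"), name = c("C", "A", "B"),
    icer = c(10, 10, 10), cost_full = c(100, 100, 100),
    dalys_full = c(50, 50, 50)))
  lt <- league_table(iv, economy_params(61, numeric(0)))
  expect_equal(lt$name, c("A", "B", "C"))
})

test_that("budgets across scenarios are evaluated per threshold and grow with k", {
  iv <- malawi_interventions()
  econ <- economy_params(61, c(A = 61, B = 372, C = 1116))
  b <- budget_at_thresholds(iv, econ)
  expect_named(b, c("A", "B", "C"))
  expect_equal(round(b[["A"]] / 1e6), 265)
  expect_true(all(diff(b) >= 0))  # budget monotone in k

  expect_length(budget_at_thresholds(iv, economy_params(61, numeric(0))), 0)

  syn <- simulate_interventions(30, seed = 4)
  top <- economy_params(61, c(X = max(syn$icer, na.rm = TRUE) + 1))
  expect_equal(budget_at_thresholds(syn, top)[["X"]], sum(syn$cost_full))
})

test_that("threshold package matches the exhaustive net-DALY optimum on small sets", {
  for (seed in 1:6) {
    set.seed(seed)
    iv <- simulate_interventions(12, seed = seed)
    k <- exp(stats::runif(1, log(10), log(1000)))
    pkg <- hbp_select(iv, economy_params(k, numeric(0)))
    oracle <- oracle_best_subset(iv, k)
    expect_equal(pkg$total_net_dalys, oracle$net, tolerance = 1e-9)
    # net-positive members are identical; zero-net members are indifferent
    strict <- iv$id[(iv$dalys_full - iv$cost_full / k) > 1e-9]
    expect_setequal(intersect(pkg$included_ids, strict),
                    intersect(oracle$ids, strict))
  }
})

test_that("perturbing the threshold package strictly lowers net health", {
  iv <- simulate_interventions(30, seed = 15)
  k <- 61
  pkg <- hbp_select(iv, economy_params(k, numeric(0)))
  net0 <- pkg$total_net_dalys
  out <- setdiff(iv$id, pkg$included_ids)
  for (id in out)
    expect_lt(oracle_net_dalys(iv, c(pkg$included_ids, id), k), net0)
  keep <- iv$id[iv$id %in% pkg$included_ids &
                (iv$cost_saving | iv$icer < k)]
  for (id in keep)
    expect_lt(oracle_net_dalys(iv, setdiff(pkg$included_ids, id), k), net0)
})

test_that("budget-capped greedy fill respects the cap and forced sets", {
  iv <- toy_interventions(data.frame(
    id = letters[1:4], icer = c(10, 20, 30, 40),
    cost_full = c(50, 30, 30, 10), dalys_full = c(5, 1.5, 1, 0.25)))
  econ <- economy_params(61, numeric(0))
  pkg <- select_budget(iv, econ, budget = 80)
  expect_setequal(pkg$included_ids, c("a", "b"))  # c does not fit; fill stops
  expect_lte(pkg$budget, 80)

  forced <- select_budget(iv, econ, budget = 80, forced_in = "d")
  expect_true("d" %in% forced$included_ids)
  expect_lte(forced$budget, 80)

  expect_error(select_budget(iv, econ, budget = 5, forced_in = "a"),
               "infeasible")
  expect_error(select_budget(iv, econ, budget = 80,
                             forced_in = "a", forced_out = "a"), "disjoint")
})

test_that("exact budget-capped selection matches the enumeration oracle", {
  for (seed in 1:4) {
    iv <- simulate_interventions(10, seed = 100 + seed)
    k <- 61
    budget <- stats::quantile(cumsum(sort(iv$cost_full)), 0.5)
    pkg <- select_budget(iv, economy_params(k, numeric(0)), budget,
                         method = "exact")
    oracle <- oracle_best_subset(iv, k, budget)
    expect_equal(pkg$total_net_dalys, oracle$net, tolerance = 1e-9)
    # greedy is a lower bound on the exact optimum
    greedy <- select_budget(iv, economy_params(k, numeric(0)), budget)
    expect_lte(greedy$total_net_dalys, pkg$total_net_dalys + 1e-9)
  }
})
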