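test_that("units required per batch follow the cost behavior", {
  expect_equal(units_required("variable", 2, 12), 24)
  expect_equal(units_required("step_fixed", 1, 12, block_capacity = 8), 2)
  # block boundaries found by brute-force enumeration: smallest number of
  # whole blocks of 8 covering n samples
  for (n in 1:40) {
    blocks <- which(seq_len(n) * 8 >= n)[1]
    expect_equal(units_required("step_fixed", 1, n, block_capacity = 8),
                 blocks)
  }
  expect_equal(units_required("step_fixed", 1, 16, block_capacity = 8), 2)
  expect_equal(units_required("step_fixed", 1, 17, block_capacity = 8), 3)
  expect_error(units_required("fixed", 1, 12), "annual")
  expect_error(units_required("variable", 1, 0), ">= 1")
  expect_error(units_required("step_fixed", 1, 12), "block_capacity")
})

test_that("equivalent annual cost matches the discounted-annuity oracle", {
  # oracle: the annuity A satisfying sum_{t=1..L} A / (1+r)^t = P
  annuity_oracle <- function(P, r, L, M) {
    P / sum((1 + r)^-(1:L)) + M
  }
  expect_equal(equivalent_annual_cost(1000, 0, 5, 0), 200)
  expect_equal(equivalent_annual_cost(0, 0.07, 3, 2000), 2000)
  expect_equal(equivalent_annual_cost(100000, 0.04, 5, 2000),
               annuity_oracle(100000, 0.04, 5, 2000))
  expect_equal(round(equivalent_annual_cost(100000, 0.04, 5, 2000), 2),
               24462.71)
  for (case in list(c(50000, 0.04, 10, 0), c(7e6, 0.04, 5, 160000),
                    c(123456, 0.1, 7, 500))) {
    expect_equal(equivalent_annual_cost(case[1], case[2], case[3], case[4]),
                 annuity_oracle(case[1], case[2], case[3], case[4]))
  }
  expect_error(equivalent_annual_cost(1000, 0.04, 0.5), "lifetime")
})

test_that("annuitization approaches the straight-line limit as r -> 0", {
  expect_equal(equivalent_annual_cost(100000, 1e-8, 7, 0), 100000 / 7,
               tolerance = 1e-6)
})

test_that("annual fixed costs cover equipment, space and license routes", {
  space <- as_inventory(item_row("sp", 4, "equipment", "fixed", "space",
                                 area_m2 = 10, rate_per_m2_year = 100,
                                 allocation_weight = 0.5, currency = "USD"))
  expect_equal(annual_fixed_cost(space[1, ], 0.04), 500)

  license <- as_inventory(item_row("lic", 6, "software_storage", "fixed",
                                   "unit_price", quantity_base = 1,
                                   unit_cost = 12000, currency = "USD"))
  expect_equal(annual_fixed_cost(license[1, ], 0.04), 12000)

  equip <- bind_inventory(instrument("eq", price = 100000, lifetime = 5,
                                     maintenance = 2000, weight = 0.5))
  expect_equal(round(annual_fixed_cost(equip[1, ], 0.04), 2), 12231.36)

  variable <- bind_inventory(consumable("v"))
  expect_error(annual_fixed_cost(variable[1, ], 0.04), "fixed items only")
})

test_that("storage is valued per sample over the full horizon", {
  st <- function(g, price, years) {
    as_inventory(item_row("st", 9, "software_storage", "variable", "storage",
                          gb_base = g, price_per_gb_year = price,
                          storage_years = years, currency = "USD"))[1, ]
  }
  expect_equal(storage_cost_per_sample(st(0, 0.5, 10)), 0)
  expect_equal(storage_cost_per_sample(st(10, 0.5, 10)), 50)
  expect_equal(storage_cost_per_sample(st(1, 1, 1)), 1)
})

test_that("item cost per sample applies behavior, batch size and currency", {
  p12 <- cost_params(batch_size = 12)
  # variable consumable cost is invariant to batch size
  v <- bind_inventory(consumable("v", price = 10))[1, ]
  for (n in c(1, 12, 64))
    expect_equal(item_cost_per_sample(v, cost_params(batch_size = n)), 10)
  # fixed annual cost is spread over the yearly throughput
  lic <- as_inventory(item_row("lic", 6, "software_storage", "fixed",
                               "unit_price", quantity_base = 1,
                               unit_cost = 62400, currency = "USD"))[1, ]
  expect_equal(item_cost_per_sample(lic, p12), 100)
  # step-fixed: 2 blocks of 8 at price 80 cover a batch of 12
  sf <- bind_inventory(consumable("sf", price = 80, behavior = "step_fixed",
                                  capacity = 8))[1, ]
  expect_equal(item_cost_per_sample(sf, p12), 2 * 80 / 12)
  # personnel: time x loaded wage, NOK converted to USD
  task <- bind_inventory(staff_task("t", hours = 2, salary = 700000))[1, ]
  expect_equal(item_cost_per_sample(task, p12),
               2 * (700000 * 1.4125 / 1695) / 10.7433)
})

test_that("an empty inventory yields an all-zero matrix", {
  empty <- as_inventory(data.frame(id = character(), step = integer(),
                                   category = character(),
                                   behavior = character(),
                                   valuation = character()))
  m <- compute_matrix(empty, cost_params())
  expect_equal(m$grand_total, 0)
  expect_true(all(m$per_sample == 0))
  expect_equal(unname(m$category_share), rep(0, 5))
})

test_that("cost matrices satisfy the additivity and normalization invariants", {
  p <- cost_params()
  for (seed in 1:25) {
    inv <- synthetic_inventory(seed, n_items = 18)
    m <- compute_matrix(inv, p)
    expect_true(all(m$per_sample >= 0))
    expect_equal(m$grand_total, sum(m$step_total), tolerance = 1e-9)
    expect_equal(m$grand_total,
                 (1 + p$overhead_rate) * sum(m$category_total),
                 tolerance = 1e-9)
    expect_equal(m$overhead_total, p$overhead_rate * sum(m$category_total),
                 tolerance = 1e-9)
    expect_equal(sum(m$category_share), 100, tolerance = 1e-9)
    expect_equal(sum(m$step_share), 100, tolerance = 1e-9)
  }
})

test_that("matrix entries are homogeneous of degree one in all prices", {
  k <- 3.7
  inv <- synthetic_inventory(42, n_items = 20)
  scaled <- as.data.frame(inv)
  for (col in c("unit_cost", "annual_salary", "purchase_price",
                "annual_maintenance", "rate_per_m2_year", "price_per_gb_year"))
    scaled[[col]] <- scaled[[col]] * k
  p <- cost_params()
  m1 <- compute_matrix(inv, p)
  m2 <- compute_matrix(as_inventory(scaled), p)
  expect_equal(m2$per_sample, k * m1$per_sample, tolerance = 1e-12)
  expect_equal(m2$grand_total, k * m1$grand_total, tolerance = 1e-12)
})

test_that("variable-only inventories are batch-size invariant and fixed-only halve", {
  var_only <- synthetic_inventory(
    7, n_items = 12,
    mix = list(categories = c(consumables = 0.5, personnel = 0.3,
                              equipment = 0.1, software_storage = 0.1),
               behaviors = c(variable = 1, fixed = 0, step_fixed = 0)))
  totals <- sapply(c(1, 12, 64), function(n)
    compute_matrix(var_only, cost_params(batch_size = n))$grand_total)
  expect_equal(totals[1], totals[2], tolerance = 1e-12)
  expect_equal(totals[2], totals[3], tolerance = 1e-12)

  fixed_only <- synthetic_inventory(
    8, n_items = 12,
    mix = list(categories = c(consumables = 0.3, personnel = 0.3,
                              equipment = 0.3, software_storage = 0.1),
               behaviors = c(variable = 0, fixed = 1, step_fixed = 0)))
  # storage items are per-sample; restrict to truly annual items
  fixed_only <- as_inventory(
    as.data.frame(fixed_only)[fixed_only$valuation != "storage", ])
  t12 <- compute_matrix(fixed_only, cost_params(batch_size = 12))$grand_total
  t24 <- compute_matrix(fixed_only, cost_params(batch_size = 24))$grand_total
  expect_equal(t24, t12 / 2, tolerance = 1e-12)
})

test_that("estimate bounds order per-sample totals for time-like inputs", {
  inv <- bind_inventory(staff_task("t", hours = 2))
  inv$hours_low <- 1; inv$hours_high <- 4
  totals <- sapply(c("low", "base", "high"), function(e)
    compute_matrix(inv, cost_params(estimate = e))$grand_total)
  expect_true(totals[["low"]] < totals[["base"]])
  expect_true(totals[["base"]] < totals[["high"]])
})
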