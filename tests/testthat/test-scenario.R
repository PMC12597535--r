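test_that("the identity scenario is a no-op", {
  inv <- calibrated_inventory()
  p <- cost_params()
  res <- run_scenario(scenario_spec("identity"), inv, p)
  expect_identical(res$matrix$per_sample, res$base_matrix$per_sample)
  expect_equal(res$pct_change_total, 0)
  mod <- apply_scenario(scenario_spec("identity"), inv, p)
  expect_equal(as.data.frame(mod$inventory), as.data.frame(inv))
  expect_equal(mod$params, p)
})

test_that("price adjustments scale only the targeted items", {
  inv <- calibrated_inventory()
  p <- cost_params()
  mod <- apply_scenario(
    scenario_spec("rebate", price_adjustments = c(consumables = -50)), inv, p)
  cons <- mod$inventory$category == "consumables"
  expect_equal(mod$inventory$unit_cost[cons], inv$unit_cost[cons] / 2)
  expect_equal(mod$inventory$unit_cost[!cons], inv$unit_cost[!cons])
  expect_equal(mod$inventory$annual_salary, inv$annual_salary)
  # original untouched
  expect_equal(as.data.frame(inv), as.data.frame(calibrated_inventory()))
  # by item id
  mod2 <- apply_scenario(
    scenario_spec("one item", price_adjustments = list(c4_libprep_reagent_kit = 10)),
    inv, p)
  expect_equal(mod2$inventory$unit_cost[mod2$inventory$id == "c4_libprep_reagent_kit"],
               inv$unit_cost[inv$id == "c4_libprep_reagent_kit"] * 1.1)
  expect_error(
    apply_scenario(scenario_spec("bad", price_adjustments = c(nonexistent = -10)),
                   inv, p),
    "target not found")
})

test_that("sequential +/-p adjustments compose multiplicatively", {
  inv <- calibrated_inventory()
  p <- cost_params()
  base <- compute_matrix(inv, p)$grand_total
  pct <- 30
  step1 <- apply_scenario(
    scenario_spec(price_adjustments = c(consumables = -pct)), inv, p)
  step2 <- apply_scenario(
    scenario_spec(price_adjustments = c(consumables = +pct)),
    step1$inventory, p)
  got <- compute_matrix(step2$inventory, p)$grand_total
  cons_direct <- compute_matrix(inv, p)$category_total[["consumables"]]
  shrink <- (1 - (pct / 100)^2)  # (1 - p)(1 + p) on the consumables share
  want <- base - (1 + p$overhead_rate) * cons_direct * (1 - shrink)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("step exclusion removes exactly that step's contribution", {
  inv <- calibrated_inventory()
  p <- cost_params()
  base <- compute_matrix(inv, p)
  res <- run_scenario(scenario_spec("no MTB", excluded_steps = 8), inv, p)
  expect_true(all(res$matrix$per_sample[8, ] == 0))
  expect_equal(res$matrix$grand_total,
               base$grand_total - base$step_total[[8]], tolerance = 1e-12)
})

test_that("step weights scale direct costs with overhead following", {
  inv <- calibrated_inventory()
  p <- cost_params()
  base <- compute_matrix(inv, p)
  res <- run_scenario(
    scenario_spec("weights", step_weights = c("3" = 1.1, "4" = 1.1, "5" = 1.1)),
    inv, p)
  expect_equal(res$matrix$step_total[3:5], 1.1 * base$step_total[3:5],
               tolerance = 1e-12)
  expect_equal(res$matrix$step_total[c(1:2, 6:9)],
               base$step_total[c(1:2, 6:9)], tolerance = 1e-12)
})

test_that("investments add exactly total/amortization_samples times (1+o)", {
  inv <- calibrated_inventory()
  p <- cost_params()
  base <- compute_matrix(inv, p)$grand_total
  spec <- scenario_spec("invest", investments = list(
    list(label = "dev", total_cost = 150000, currency = "USD",
         amortization_samples = 624)))
  res <- run_scenario(spec, inv, p)
  expect_equal(res$matrix$grand_total,
               base + 150000 / 624 * (1 + p$overhead_rate),
               tolerance = 1e-9)
  # default amortization basis: one year of samples at the current batch size
  spec_default <- scenario_spec("invest", investments = list(
    list(label = "dev", total_cost = 150000, currency = "USD")))
  res_default <- run_scenario(spec_default, inv, p)
  expect_equal(res_default$matrix$grand_total, res$matrix$grand_total,
               tolerance = 1e-9)
})

test_that("batch and estimate overrides and variant inventories substitute", {
  inv <- calibrated_inventory()
  p <- cost_params()
  res24 <- run_scenario(scenario_spec("n24", batch_size = 24), inv, p)
  expect_equal(res24$matrix$batch_size, 24L)
  expect_equal(res24$matrix$grand_total,
               compute_matrix(inv, cost_params(batch_size = 24))$grand_total)

  auto <- automated_inventory()
  res_auto <- run_scenario(scenario_spec("auto", variant_inventory = auto,
                                         batch_size = 16), inv, p)
  expect_equal(res_auto$matrix$grand_total,
               compute_matrix(auto, cost_params(batch_size = 16))$grand_total)
})

test_that("matrix comparison is zero on itself and tracks known ratios", {
  inv <- calibrated_inventory()
  p <- cost_params()
  m <- compute_matrix(inv, p)
  self <- compare_matrices(m, m)
  expect_equal(self$total, 0)
  expect_equal(unname(self$by_category), rep(0, 4))
  # doubling every price doubles the total: +100%
  doubled <- as.data.frame(inv)
  for (col in c("unit_cost", "annual_salary", "purchase_price",
                "annual_maintenance", "rate_per_m2_year", "price_per_gb_year"))
    doubled[[col]] <- doubled[[col]] * 2
  m2 <- compute_matrix(as_inventory(doubled), p)
  expect_equal(compare_matrices(m2, m)$total, 100, tolerance = 1e-9)
  # a scenario total of 2622.0 against a base of 2944.8 is a -10.96% change
  expect_equal(round(100 * (2622.0 / 2944.8 - 1), 2), -10.96)
  empty <- compute_matrix(as_inventory(
    data.frame(id = character(), step = integer(), category = character(),
               behavior = character(), valuation = character())), p)
  expect_error(compare_matrices(m, empty), "zero base")
})

test_that("scenarios read from YAML behave like in-code specs", {
  dir <- system.file("extdata", "scenarios", package = "seqcost")
  inv <- calibrated_inventory()
  p <- cost_params()
  rebate <- read_scenario(file.path(dir, "consumables_rebate.yaml"))
  expect_equal(rebate$price_adjustments$consumables, -50)
  expect_equal(
    run_scenario(rebate, inv, p)$matrix$grand_total,
    run_scenario(scenario_spec(price_adjustments = c(consumables = -50)),
                 inv, p)$matrix$grand_total)
  invest <- read_scenario(file.path(dir, "bioinformatic_investment.yaml"))
  res <- run_scenario(invest, inv, p)
  expect_gt(res$matrix$grand_total, compute_matrix(inv, p)$grand_total)
})
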