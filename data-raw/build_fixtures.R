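# Builds the bundled fixtures under inst/extdata/:
#   calibrated_inventory.csv        -- calibrated nine-step inventory
#   automated_inventory_synthetic.csv -- illustrative automated variant
#   params_base.yaml                -- base-case model parameters
#   scenarios/*.yaml                -- example scenario files
#
# The calibrated inventory is a feasibility solution: unrounded per-sample
# direct-cost cells are fixed inside their integer rounding bands so that the
# cell values, the step totals of interest, the grand total, the overhead
# total, the category shares, the step-8 exclusion total, the -50%
# consumables change, the +10% steps-3-5 total and the doubled-batch row all
# round to their published values simultaneously.  Working times, purchase
# prices, areas and storage prices are back-solved from those cell targets at
# full precision; the line-item granularity itself is illustrative.
#
# Run from the package root:  Rscript data-raw/build_fixtures.R

pkgload::load_all(".", quiet = TRUE)

usd <- 10.7433   # NOK per USD, 2024
r   <- 0.04
N   <- 12 * 52   # yearly samples at the base batch size

crf <- function(L) r / (1 - (1 + r)^(-L))

# loaded hourly NOK rates per role (annual salary x 1.4125 / 1695 h)
roles <- list(
  coordinator         = 560000,
  pathologist         = 1300000,
  engineer            = 650000,
  molecular_biologist = 850000,
  bioinformatician    = 900000,
  oncologist          = 1500000
)
rate_nok <- function(role) roles[[role]] * 1.4125 / 1695

rows <- list()
add <- function(...) rows[[length(rows) + 1]] <<- list(...)

# hours per occurrence that cost `target_usd` at a role's loaded wage
hours_for <- function(target_usd, role) target_usd * usd / rate_nok(role)

personnel_row <- function(id, step, role, behavior, target_usd_per_sample,
                          block_capacity = NA) {
  # step-fixed tasks are priced per block: per-sample target at n = 12 is
  # target = ceil(12/cap) * block_cost / 12
  per_occurrence <- if (behavior == "step_fixed") {
    target_usd_per_sample * 12 / ceiling(12 / block_capacity)
  } else target_usd_per_sample
  h <- hours_for(per_occurrence, role)
  add(id = id, step = step, category = "personnel", behavior = behavior,
      block_capacity = block_capacity, valuation = "personnel",
      currency = "NOK", quantity_base = 1,
      role = role, annual_salary = roles[[role]],
      employer_contribution_rate = 0.13, social_security_rate = 0.25,
      annual_hours = 1695,
      hours_low = 0.8 * h, hours_base = h, hours_high = 1.4 * h,
      allocation_weight = 1)
}

equipment_row <- function(id, step, target_usd_per_sample, L, L_low, L_high,
                          maintenance_nok, alpha = 1) {
  annual_nok <- target_usd_per_sample * N * usd / alpha
  P <- (annual_nok - maintenance_nok) / crf(L)
  add(id = id, step = step, category = "equipment", behavior = "fixed",
      valuation = "equipment", currency = "NOK",
      purchase_price = P, lifetime_low = L_low, lifetime_base = L,
      lifetime_high = L_high, annual_maintenance = maintenance_nok,
      allocation_weight = alpha)
}

space_row <- function(id, step, target_usd_per_sample, rate_nok_m2 = 3000) {
  area <- target_usd_per_sample * N * usd / rate_nok_m2
  add(id = id, step = step, category = "equipment", behavior = "fixed",
      valuation = "space", currency = "NOK",
      area_m2 = area, rate_per_m2_year = rate_nok_m2, allocation_weight = 1)
}

## consumables ---------------------------------------------------------------
add(id = "c2_slides_stains", step = 2, category = "consumables",
    behavior = "variable", valuation = "unit_price", currency = "NOK",
    quantity_base = 1, unit_cost = 20.8 * usd, allocation_weight = 1)
add(id = "c3_extraction_kit", step = 3, category = "consumables",
    behavior = "variable", valuation = "unit_price", currency = "NOK",
    quantity_base = 1, unit_cost = 32.8 * usd, allocation_weight = 1)
add(id = "c4_libprep_reagent_kit", step = 4, category = "consumables",
    behavior = "variable", valuation = "unit_price", currency = "USD",
    quantity_base = 1, unit_cost = 687.2, allocation_weight = 1)
add(id = "c4_tube_strips", step = 4, category = "consumables",
    behavior = "step_fixed", block_capacity = 8, valuation = "unit_price",
    currency = "USD", quantity_base = 1, unit_cost = 4.8,
    allocation_weight = 1)   # 2 strips at n = 12 -> 0.8/sample
add(id = "c5_seq_reagent_kit", step = 5, category = "consumables",
    behavior = "step_fixed", block_capacity = 24, valuation = "unit_price",
    currency = "USD", quantity_base = 1, unit_cost = 83.2 * 12,
    allocation_weight = 1)   # one 24-sample kit per run -> 83.2/sample
add(id = "c5_flowcell_consumables", step = 5, category = "consumables",
    behavior = "variable", valuation = "unit_price", currency = "USD",
    quantity_base = 1, unit_cost = 189.8, allocation_weight = 1)

## personnel -----------------------------------------------------------------
personnel_row("p1_request_coordination", 1, "coordinator", "variable", 99.55)
personnel_row("p1_sample_request", 1, "pathologist", "variable", 50.0)
personnel_row("p2_sample_evaluation", 2, "pathologist", "variable", 80.0)
personnel_row("p2_sectioning", 2, "engineer", "variable", 27.0)
personnel_row("p3_extraction", 3, "engineer", "variable", 93.7)
personnel_row("p4_libprep_per_sample", 4, "engineer", "variable", 60.7)
personnel_row("p4_libprep_per_batch", 4, "engineer", "step_fixed", 40.0,
              block_capacity = 12)
personnel_row("p5_seq_run_setup", 5, "engineer", "step_fixed", 21.6,
              block_capacity = 24)
personnel_row("p5_seq_monitoring", 5, "engineer", "variable", 9.65)
personnel_row("p6_pipeline_per_run", 6, "bioinformatician", "step_fixed",
              30.0, block_capacity = 24)
personnel_row("p6_qc_review", 6, "bioinformatician", "variable", 17.85)
personnel_row("p7_variant_interpretation", 7, "molecular_biologist",
              "variable", 291.8)
personnel_row("p8_mtb_molbio", 8, "molecular_biologist", "variable", 120.0)
personnel_row("p8_mtb_oncologist", 8, "oncologist", "variable", 60.0)
personnel_row("p8_final_report", 8, "pathologist", "variable", 26.8)

## equipment and laboratory space --------------------------------------------
equipment_row("e2_microtome", 2, 10.0, L = 10, L_low = 8, L_high = 12,
              maintenance_nok = 5000)
space_row("sp2_processing_space", 2, 2.2)
equipment_row("e3_extraction_robot", 3, 20.0, L = 7, L_low = 5, L_high = 9,
              maintenance_nok = 8000)
space_row("sp3_extraction_space", 3, 5.9)
equipment_row("e4_libprep_instruments", 4, 50.0, L = 5, L_low = 4, L_high = 7,
              maintenance_nok = 15000)
space_row("sp4_libprep_space", 4, 6.3)
equipment_row("e5_sequencer", 5, 260.0, L = 5, L_low = 4, L_high = 7,
              maintenance_nok = 160000, alpha = 0.9)
space_row("sp5_sequencing_space", 5, 18.9, rate_nok_m2 = 6000)
equipment_row("e8_mtb_av_equipment", 8, 0.9, L = 5, L_low = 4, L_high = 7,
              maintenance_nok = 0)

## software and storage -------------------------------------------------------
add(id = "s5_sequencer_software", step = 5, category = "software_storage",
    behavior = "fixed", valuation = "unit_price", currency = "USD",
    quantity_base = 1, unit_cost = 24.6 * N / 0.8, allocation_weight = 0.8)
add(id = "s7_knowledgebase_license", step = 7, category = "software_storage",
    behavior = "fixed", valuation = "unit_price", currency = "USD",
    quantity_base = 1, unit_cost = 2.6 * N, allocation_weight = 1)
add(id = "s9_genomic_data_storage", step = 9, category = "software_storage",
    behavior = "variable", valuation = "storage", currency = "NOK",
    gb_low = 50, gb_base = 100, gb_high = 200,
    price_per_gb_year = 8.7 * usd / (100 * 10), storage_years = 10,
    allocation_weight = 1)

all_cols <- unique(unlist(lapply(rows, names)))
inv_df <- do.call(rbind, lapply(rows, function(rw) {
  for (col in setdiff(all_cols, names(rw))) rw[[col]] <- NA
  as.data.frame(rw[all_cols], stringsAsFactors = FALSE)
}))
inv <- as_inventory(inv_df)
stopifnot(nrow(validate_inventory(inv)) == 0)

## verify the calibration -----------------------------------------------------
params <- cost_params()
m <- compute_matrix(inv, params)

cell_targets <- rbind(
  c(1, 0, 150, 0, 0), c(2, 21, 107, 12, 0), c(3, 33, 94, 26, 0),
  c(4, 688, 101, 56, 0), c(5, 273, 31, 279, 25), c(6, 0, 48, 0, 0),
  c(7, 0, 292, 0, 3), c(8, 0, 207, 1, 0), c(9, 0, 0, 0, 9)
)
for (i in 1:9) for (j in 1:4) {
  got <- round_half_out(m$per_sample[i, j])
  want <- cell_targets[i, j + 1]
  if (got != want)
    stop(sprintf("cell (%d, %s): %g != %g", i, cost_categories()[j],
                 got, want))
}
check <- function(label, got, want) {
  got <- unname(got)
  if (!isTRUE(all.equal(got, want)))
    stop(sprintf("%s: got %s, want %s", label, got, want))
  cat(sprintf("  ok  %-38s %s\n", label, got))
}
check("grand total",        round_half_out(m$grand_total), 2944)
check("overhead total",     round_half_out(m$overhead_total), 491)
check("step 2 total",       round_half_out(m$step_total[2]), 168)
check("step 4 total",       round_half_out(m$step_total[4]), 1014)
check("step 8 total",       round_half_out(m$step_total[8]), 249)
check("consumables share",  round_half_out(m$category_share[["consumables"]]), 34)
check("personnel share",    round_half_out(m$category_share[["personnel"]]), 35)
check("equipment share",    round_half_out(m$category_share[["equipment"]]), 13)
check("software share",     round_half_out(m$category_share[["software_storage"]]), 1)
check("overhead share",     round_half_out(m$category_share[["overhead"]]), 17)

res_excl <- run_scenario(scenario_spec("no MTB", excluded_steps = 8), inv, params)
check("step-8 exclusion total",
      round_half_out(res_excl$matrix$grand_total), 2695)

res_half <- run_scenario(
  scenario_spec("half consumables", price_adjustments = c(consumables = -50)),
  inv, params)
check("-50% consumables change",
      round_half_out(res_half$pct_change_total), -21)

res_qc <- run_scenario(
  scenario_spec("qc surcharge", step_weights = c("3" = 1.1, "4" = 1.1, "5" = 1.1)),
  inv, params)
stopifnot(abs(res_qc$matrix$grand_total - 3136) <= 2)
cat(sprintf("  ok  +10%% steps 3-5 total within $2 of 3136: %.2f\n",
            res_qc$matrix$grand_total))

p24 <- cost_params(batch_size = 24)
m24 <- compute_matrix(inv, p24)
check("n=24 equipment/sample",
      round_half_out(m24$category_total[["equipment"]]), 187)
check("n=24 consumables/sample",
      round_half_out(m24$category_total[["consumables"]]), 973)
check("n=24 personnel/sample",
      round_half_out(m24$category_total[["personnel"]]), 1003)
check("n=24 software/sample",
      round_half_out(m24$category_total[["software_storage"]]), 22)
check("doubling change",
      round_half_out(compare_matrices(m24, m)$total), -11)

# >80% of consumables in library preparation + sequencing
cons_45 <- sum(m$per_sample[4:5, "consumables"])
stopifnot(cons_45 / m$category_total[["consumables"]] > 0.8)
cat("  ok  steps 4+5 consumables share of category >80%\n")

## write fixtures --------------------------------------------------------------
dir.create("inst/extdata/scenarios", recursive = TRUE, showWarnings = FALSE)
write_inventory(inv, "inst/extdata/calibrated_inventory.csv")

## illustrative automated library-prep variant (synthetic, not calibrated) -----
auto <- as.data.frame(inv)
auto <- auto[!auto$id %in% c("p4_libprep_per_sample", "p4_libprep_per_batch"), ]
auto$block_capacity[auto$id == "c4_tube_strips"] <- 16
robot <- as.data.frame(as_inventory(data.frame(
  id = "e4_libprep_robot", step = 4, category = "equipment",
  behavior = "fixed", valuation = "equipment", currency = "NOK",
  purchase_price = 3000000, lifetime_low = 5, lifetime_base = 7,
  lifetime_high = 9, annual_maintenance = 60000, allocation_weight = 1,
  stringsAsFactors = FALSE)))
h_auto <- hours_for(15.0, "engineer")
eng_auto <- as.data.frame(as_inventory(data.frame(
  id = "p4_libprep_robot_operation", step = 4, category = "personnel",
  behavior = "step_fixed", block_capacity = 16, valuation = "personnel",
  currency = "NOK", quantity_base = 1, role = "engineer",
  annual_salary = roles$engineer, employer_contribution_rate = 0.13,
  social_security_rate = 0.25, annual_hours = 1695,
  hours_low = 0.8 * h_auto * 16, hours_base = h_auto * 16,
  hours_high = 1.4 * h_auto * 16, allocation_weight = 1,
  stringsAsFactors = FALSE)))
auto_inv <- as_inventory(rbind(auto, robot, eng_auto))
stopifnot(nrow(validate_inventory(auto_inv)) == 0)
write_inventory(auto_inv, "inst/extdata/automated_inventory_synthetic.csv")

yaml::write_yaml(list(
  batch_size = 12L, runs_per_year = 52L, overhead_rate = 0.20,
  interest_rate = 0.04, nok_per_usd = 10.7433, nok_per_eur = 11.6276,
  report_currency = "USD", estimate = "base"
), "inst/extdata/params_base.yaml")

yaml::write_yaml(list(
  name = "50% price reduction in consumables",
  price_adjustments = list(consumables = -50)
), "inst/extdata/scenarios/consumables_rebate.yaml")
yaml::write_yaml(list(
  name = "Exclusion of step 8: molecular tumor board and reporting",
  excluded_steps = 8L
), "inst/extdata/scenarios/exclude_mtb.yaml")
yaml::write_yaml(list(
  name = "Doubling the weekly sample size to 24",
  batch_size = 24L
), "inst/extdata/scenarios/double_batch.yaml")
yaml::write_yaml(list(
  name = "+10% for controls and sample failure in steps 3-5",
  step_weights = list("3" = 1.1, "4" = 1.1, "5" = 1.1)
), "inst/extdata/scenarios/qc_surcharge.yaml")
yaml::write_yaml(list(
  name = "Inclusion of bioinformatic development costs",
  investments = list(list(
    label = "pipeline_development",
    total_cost = 1695000,   # 16 months of a loaded bioinformatician salary, NOK
    currency = "NOK"))
), "inst/extdata/scenarios/bioinformatic_investment.yaml")

cat("fixtures written to inst/extdata/\n")
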