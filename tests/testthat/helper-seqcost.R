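# shorthand for building small inventories in code

item_row <- function(id, step, category, behavior, valuation, ...) {
  as.data.frame(c(list(id = id, step = step, category = category,
                       behavior = behavior, valuation = valuation), list(...)),
                stringsAsFactors = FALSE)
}

consumable <- function(id, step = 4, price = 10, qty = 1, behavior = "variable",
                       capacity = NA, currency = "USD", weight = 1) {
  item_row(id, step, "consumables", behavior, "unit_price",
           block_capacity = capacity, quantity_base = qty, unit_cost = price,
           currency = currency, allocation_weight = weight)
}

staff_task <- function(id, step = 7, hours = 1, salary = 700000,
                       behavior = "variable", capacity = NA, role = "engineer",
                       annual_hours = 1695) {
  item_row(id, step, "personnel", behavior, "personnel",
           block_capacity = capacity, quantity_base = 1, role = role,
           annual_salary = salary, annual_hours = annual_hours,
           employer_contribution_rate = 0.13, social_security_rate = 0.25,
           hours_base = hours, currency = "NOK")
}

instrument <- function(id, step = 5, price = 100000, lifetime = 5,
                       maintenance = 0, weight = 1, currency = "USD") {
  item_row(id, step, "equipment", "fixed", "equipment",
           purchase_price = price, lifetime_base = lifetime,
           annual_maintenance = maintenance, allocation_weight = weight,
           currency = currency)
}

bind_inventory <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  as_inventory(do.call(rbind, lapply(dfs, function(d) {
    for (col in setdiff(cols, names(d))) d[[col]] <- NA
    d[cols]
  })))
}

usd_params <- function(...) cost_params(...)
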