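#' Declare a costing scenario
#'
#' A scenario is a declarative, composable modification of an inventory and
#' parameter pair. Supported modifications, applied in this order:
#' substitution of an alternate workflow variant inventory; percentage
#' adjustments of unit valuations (by cost category or by item id); batch
#' size and estimate overrides; exclusion of whole workflow steps;
#' investment costs appended as fixed software/storage items; and per-step
#' weights multiplying the affected steps' direct costs (overhead follows
#' proportionally).
#'
#' @param name Scenario label.
#' @param price_adjustments Named numeric vector or list: names are cost
#'   categories or item ids, values are percent changes (e.g. `-50` halves
#'   prices; must be > -100).
#' @param step_weights Named numeric vector or list: names are step indices
#'   (1..9), values are non-negative multipliers (e.g. `1.10`).
#' @param excluded_steps Integer vector of step indices whose items are
#'   dropped.
#' @param batch_size Optional batch-size override.
#' @param estimate Optional estimate override (`"low"`, `"base"`, `"high"`).
#' @param variant_inventory Optional alternate `inventory` replacing the
#'   input inventory (e.g. an automated library-preparation workflow).
#' @param investments List of investments, each a list with `label`,
#'   `total_cost`, `currency` (default `"USD"`) and optional
#'   `amortization_samples` (default: one year of samples at the effective
#'   batch size). Each investment contributes exactly
#'   `total_cost / amortization_samples` per sample before overhead.
#' @return An object of class `scenario_spec`.
#' @export
#' @examples
#' scenario_spec("consumables rebate", price_adjustments = c(consumables = -50))
scenario_spec <- function(name = "scenario",
                          price_adjustments = list(),
                          step_weights = list(),
                          excluded_steps = integer(),
                          batch_size = NULL,
                          estimate = NULL,
                          variant_inventory = NULL,
                          investments = list()) {
  price_adjustments <- as.list(price_adjustments)
  step_weights <- as.list(step_weights)
  excluded_steps <- as.integer(excluded_steps)
  if (length(price_adjustments) > 0 &&
      any(unlist(price_adjustments) <= -100))
    stop("price adjustments must be > -100 percent", call. = FALSE)
  if (length(step_weights) > 0) {
    if (any(unlist(step_weights) < 0))
      stop("step weights must be >= 0", call. = FALSE)
    if (!all(names(step_weights) %in% as.character(1:9)))
      stop("step weight names must be step indices 1..9", call. = FALSE)
  }
  if (length(excluded_steps) > 0 && !all(excluded_steps %in% 1:9))
    stop("excluded steps must be step indices 1..9", call. = FALSE)
  if (!is.null(estimate))
    estimate <- match.arg(estimate, c("low", "base", "high"))
  if (!is.null(variant_inventory))
    stopifnot(inherits(variant_inventory, "inventory"))
  structure(
    list(name = name,
         price_adjustments = price_adjustments,
         step_weights = step_weights,
         excluded_steps = excluded_steps,
         batch_size = batch_size,
         estimate = estimate,
         variant_inventory = variant_inventory,
         investments = investments),
    class = "scenario_spec"
  )
}

#' Read a scenario from a YAML file
#'
#' The file may contain any field of [scenario_spec()];
#' `variant_inventory` is given as a path (absolute or relative to the
#' scenario file) to an inventory CSV.
#'
#' @param path Path to a YAML scenario file.
#' @return A `scenario_spec` object.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(scenario_spec))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0)
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$variant_inventory)) {
    p <- raw$variant_inventory
    if (!file.exists(p)) p <- file.path(dirname(path), raw$variant_inventory)
    raw$variant_inventory <- read_inventory(p)
  }
  do.call(scenario_spec, raw)
}

# every monetary field of a line item that a price adjustment scales
monetary_fields <- c("unit_cost", "annual_salary", "purchase_price",
                     "annual_maintenance", "rate_per_m2_year",
                     "price_per_gb_year")

#' Apply a scenario to an inventory and parameters
#'
#' Returns modified copies; the inputs are never mutated. Step weights are
#' not applied here (they act on the computed matrix): they are returned so
#' [run_scenario()] can post-multiply the affected steps' direct costs.
#'
#' @param spec A [scenario_spec()].
#' @param inv An `inventory` object.
#' @param params A [cost_params()] object.
#' @return A list with elements `inventory`, `params` and `step_weights`.
#' @export
apply_scenario <- function(spec, inv, params) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(inv, "inventory"),
            inherits(params, "cost_params"))
  if (!is.null(spec$variant_inventory)) inv <- spec$variant_inventory
  inv <- as.data.frame(inv)

  if (length(spec$price_adjustments) > 0) {
    for (target in names(spec$price_adjustments)) {
      factor <- 1 + spec$price_adjustments[[target]] / 100
      rows <- if (target %in% cost_categories()) inv$category == target
              else inv$id == target
      if (!any(rows))
        stop("price adjustment target not found in inventory: ", target,
             call. = FALSE)
      for (col in monetary_fields)
        inv[[col]][rows] <- inv[[col]][rows] * factor
    }
  }

  if (!is.null(spec$batch_size)) params$batch_size <- as.integer(spec$batch_size)
  if (!is.null(spec$estimate)) params$estimate <- spec$estimate

  if (length(spec$excluded_steps) > 0)
    inv <- inv[!inv$step %in% spec$excluded_steps, , drop = FALSE]

  if (length(spec$investments) > 0) {
    n_year <- params$batch_size * params$runs_per_year
    for (k in seq_along(spec$investments)) {
      iv <- spec$investments[[k]]
      if (is.null(iv$total_cost) || iv$total_cost < 0)
        stop("investment entries require a non-negative `total_cost`",
             call. = FALSE)
      amort <- if (is.null(iv$amortization_samples)) n_year
               else iv$amortization_samples
      label <- if (is.null(iv$label)) paste0("investment_", k) else iv$label
      # annual fee chosen so the per-sample contribution is exactly
      # total_cost / amortization_samples at the effective batch size
      inv <- rbind(inv, as.data.frame(as_inventory(data.frame(
        id = make.unique(c(inv$id, label))[nrow(inv) + 1],
        step = 6L,
        category = "software_storage",
        behavior = "fixed",
        valuation = "unit_price",
        currency = if (is.null(iv$currency)) "USD" else iv$currency,
        quantity_base = 1,
        unit_cost = iv$total_cost * n_year / amort,
        stringsAsFactors = FALSE
      ))))
    }
  }

  list(inventory = as_inventory(inv), params = params,
       step_weights = spec$step_weights)
}

#' Run a scenario against a base case
#'
#' Computes the base matrix from the unmodified inputs and the scenario
#' matrix from the scenario-modified inputs, applies any per-step weights to
#' the scenario's direct costs (overhead then follows proportionally), and
#' reports percent changes.
#'
#' @inheritParams apply_scenario
#' @return An object of class `scenario_result`: list with `name`, `matrix`,
#'   `base_matrix`, `pct_change_total` and `pct_change_by_category` (signed
#'   percent changes, `100 * (scenario / base - 1)`, unrounded).
#' @export
#' @examples
#' inv <- calibrated_inventory()
#' p <- cost_params()
#' res <- run_scenario(
#'   scenario_spec("half-price consumables",
#'                 price_adjustments = c(consumables = -50)),
#'   inv, p)
#' res$pct_change_total
run_scenario <- function(spec, inv, params) {
  base_matrix <- compute_matrix(inv, params)
  mod <- apply_scenario(spec, inv, params)
  m <- compute_matrix(mod$inventory, mod$params)
  if (length(mod$step_weights) > 0) {
    per_sample <- m$per_sample
    for (s in names(mod$step_weights))
      per_sample[s, ] <- per_sample[s, ] * mod$step_weights[[s]]
    m <- new_cost_matrix(per_sample, mod$params)
  }
  chg <- compare_matrices(m, base_matrix)
  structure(
    list(name = spec$name,
         matrix = m,
         base_matrix = base_matrix,
         pct_change_total = chg$total,
         pct_change_by_category = chg$by_category),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> '%s'\n", x$name))
  cat(sprintf("  total per sample: %.2f %s (base %.2f, change %+.2f%%)\n",
              x$matrix$grand_total, x$matrix$currency,
              x$base_matrix$grand_total, x$pct_change_total))
  invisible(x)
}

#' Percent change between two cost matrices
#'
#' Signed percent changes of `a` relative to the base `b`:
#' `100 * (a / b - 1)`, for the overhead-inclusive grand total and per
#' category. Categories with a zero base total yield `NA`.
#'
#' @param a,b `cost_matrix` objects in the same currency.
#' @return List with `total` (scalar) and `by_category` (named vector).
#' @export
compare_matrices <- function(a, b) {
  stopifnot(inherits(a, "cost_matrix"), inherits(b, "cost_matrix"))
  if (!identical(a$currency, b$currency))
    stop("matrices must share one currency to be compared", call. = FALSE)
  if (b$grand_total == 0)
    stop("percent change is undefined against a zero base total",
         call. = FALSE)
  by_cat <- ifelse(b$category_total > 0,
                   100 * (a$category_total / b$category_total - 1), NA_real_)
  names(by_cat) <- names(b$category_total)
  list(total = 100 * (a$grand_total / b$grand_total - 1),
       by_category = by_cat)
}
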