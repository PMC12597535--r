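#' Units consumed per batch
#'
#' For `variable` items consumption is proportional to the batch size; for
#' `step_fixed` items it increases stepwise, one block of `block_capacity`
#' samples at a time (`quantity` units per block). `fixed` items accrue per
#' year, not per batch, and are rejected here.
#'
#' @param behavior `"variable"` or `"step_fixed"`.
#' @param quantity Units per sample (`variable`) or per block (`step_fixed`).
#' @param n Batch size (samples per run), `n >= 1`.
#' @param block_capacity Samples per capacity block (`step_fixed` only).
#' @return Number of units consumed by one batch of `n` samples.
#' @export
#' @examples
#' units_required("variable", 2, 12)
#' units_required("step_fixed", 1, 12, block_capacity = 8)
units_required <- function(behavior, quantity, n, block_capacity = NULL) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  switch(behavior,
    variable = quantity * n,
    step_fixed = {
      if (is.null(block_capacity) || is.na(block_capacity) ||
          block_capacity < 1)
        stop("step_fixed items require a positive `block_capacity`",
             call. = FALSE)
      quantity * ceiling(n / block_capacity)
    },
    fixed = stop(
      "fixed items accrue annually; use annual_fixed_cost(), not units_required()",
      call. = FALSE),
    stop("unknown behavior: ", behavior, call. = FALSE)
  )
}

#' Equivalent annual cost of a capital purchase
#'
#' Annuitizes a purchase price over the asset's lifetime with the
#' capital-recovery factor `r / (1 - (1 + r)^-L)` and adds undiscounted
#' annual maintenance. At `r = 0` the straight-line limit `P / L + M`
#' applies.
#'
#' @param price Purchase price P.
#' @param rate Annual interest rate r (fraction, >= 0).
#' @param lifetime Expected lifetime L in years (>= 1).
#' @param maintenance Annual maintenance cost M (default 0).
#' @return Equivalent annual cost (money/year).
#' @export
#' @examples
#' equivalent_annual_cost(100000, 0.04, 5, 2000)
equivalent_annual_cost <- function(price, rate, lifetime, maintenance = 0) {
  if (price < 0) stop("`price` must be >= 0", call. = FALSE)
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  if (lifetime < 1) stop("`lifetime` must be >= 1 year", call. = FALSE)
  annuity <- if (rate == 0) price / lifetime
             else price * rate / (1 - (1 + rate)^(-lifetime))
  annuity + maintenance
}

# pick the low/base/high value of a three-point field for one inventory row
resolve_bound <- function(item, stem, estimate) {
  item[[paste0(stem, "_", estimate)]]
}

#' Annual cost of a fixed line item
#'
#' Routes: amortized equipment (equivalent annual cost of the purchase plus
#' maintenance), laboratory space (area times internal per-square-meter
#' rate), or an annual fee (`quantity * unit_cost`, e.g. a software license).
#' All routes are weighted by the item's allocation weight, the fraction of
#' the cost attributed to this workflow.
#'
#' @param item A single-row `inventory` subset with behavior `"fixed"`.
#' @param rate Annual interest rate used for equipment amortization.
#' @param estimate `"low"`, `"base"` or `"high"` (selects e.g. the lifetime
#'   bound).
#' @return Annual cost in the item's own currency.
#' @export
annual_fixed_cost <- function(item, rate, estimate = "base") {
  if (!identical(item$behavior, "fixed"))
    stop("annual_fixed_cost() applies to fixed items only (got '",
         item$behavior, "')", call. = FALSE)
  alpha <- item$allocation_weight
  switch(item$valuation,
    equipment = {
      L <- resolve_bound(item, "lifetime", estimate)
      m <- if (is.na(item$annual_maintenance)) 0 else item$annual_maintenance
      equivalent_annual_cost(item$purchase_price, rate, L, m) * alpha
    },
    space = item$area_m2 * item$rate_per_m2_year * alpha,
    unit_price = {
      q <- resolve_bound(item, "quantity", estimate)
      q * item$unit_cost * alpha
    },
    personnel = {
      # annual working time (hours/year) on a standing task
      h <- resolve_bound(item, "hours", estimate)
      h * item_hourly_rate(item) * alpha
    },
    stop("fixed behavior is not defined for valuation '", item$valuation,
         "'", call. = FALSE)
  )
}

item_hourly_rate <- function(item) {
  loaded_hourly_rate(personnel_rate(
    annual_salary = item$annual_salary,
    annual_hours = item$annual_hours,
    employer_contribution_rate =
      if (is.na(item$employer_contribution_rate)) 0.13
      else item$employer_contribution_rate,
    social_security_rate =
      if (is.na(item$social_security_rate)) 0.25
      else item$social_security_rate
  ))
}

#' Storage cost per sample
#'
#' Data storage is valued as gigabytes per sample times the price per
#' gigabyte-year times the storage horizon in years; the full horizon cost is
#' attributed to the sample that generated the data.
#'
#' @param item A single-row `inventory` subset with valuation `"storage"`.
#' @param estimate `"low"`, `"base"` or `"high"` (selects the data-volume
#'   bound).
#' @return Cost per sample in the item's own currency.
#' @export
storage_cost_per_sample <- function(item, estimate = "base") {
  if (!identical(item$valuation, "storage"))
    stop("storage_cost_per_sample() requires a storage-valued item",
         call. = FALSE)
  g <- resolve_bound(item, "gb", estimate)
  if (is.na(g) || is.na(item$price_per_gb_year) || is.na(item$storage_years))
    stop("storage item '", item$id,
         "' is missing gb, price_per_gb_year or storage_years", call. = FALSE)
  g * item$price_per_gb_year * item$storage_years * item$allocation_weight
}

#' Cost of one line item per sample
#'
#' Applies the item's cost behavior and valuation route at the batch size and
#' estimate selected in `params`, and converts to the report currency.
#' Variable and step-fixed items are costed per batch and divided by the
#' batch size; fixed items are costed per year and divided by the yearly
#' sample throughput; storage is costed directly per sample.
#'
#' @param item A single-row `inventory` subset.
#' @param params A [cost_params()] object.
#' @return Cost per sample in the report currency.
#' @export
item_cost_per_sample <- function(item, params) {
  est <- params$estimate
  n <- params$batch_size
  own <- if (item$valuation == "storage") {
    storage_cost_per_sample(item, est)
  } else if (item$behavior == "fixed") {
    annual_fixed_cost(item, params$interest_rate, est) / yearly_samples(params)
  } else {
    unit_value <- switch(item$valuation,
      unit_price = item$unit_cost,
      personnel = resolve_bound(item, "hours", est) * item_hourly_rate(item),
      stop("behavior '", item$behavior, "' is not defined for valuation '",
           item$valuation, "'", call. = FALSE)
    )
    q <- resolve_bound(item, "quantity", est)
    units <- units_required(item$behavior, q, n, item$block_capacity)
    units * unit_value * item$allocation_weight / n
  }
  convert_currency(own, item$currency, params$report_currency, params)
}

#' Compute the per-sample cost matrix
#'
#' Sums [item_cost_per_sample()] over every line item into a 9-step by
#' 4-category table of direct costs per sample, then derives the overhead
#' column (a flat markup on each step's direct costs), step and category
#' totals, the grand total, and percentage shares. All arithmetic is
#' unrounded; rounding happens only when rendering reports.
#'
#' @param inv An `inventory` object (may be empty: the result is a zero
#'   matrix).
#' @param params A [cost_params()] object.
#' @return An object of class `cost_matrix` with elements `per_sample`
#'   (9 x 4 matrix), `overhead`, `step_total`, `category_total`,
#'   `overhead_total`, `grand_total`, `step_share`, `category_share`
#'   (shares of the grand total, in percent, including an `overhead`
#'   entry), `currency`, `batch_size`, `overhead_rate`, `estimate`.
#' @export
#' @examples
#' inv <- calibrated_inventory()
#' m <- compute_matrix(inv, cost_params(batch_size = 12))
#' m$grand_total
compute_matrix <- function(inv, params) {
  stopifnot(inherits(inv, "inventory"), inherits(params, "cost_params"))
  per_sample <- matrix(
    0, nrow = 9, ncol = 4,
    dimnames = list(step = as.character(1:9), category = cost_categories())
  )
  for (i in seq_len(nrow(inv))) {
    item <- inv[i, ]
    per_sample[item$step, item$category] <-
      per_sample[item$step, item$category] + item_cost_per_sample(item, params)
  }
  new_cost_matrix(per_sample, params)
}

# assemble the derived fields of a cost matrix from its direct-cost table
new_cost_matrix <- function(per_sample, params) {
  o <- params$overhead_rate
  direct_step <- rowSums(per_sample)
  overhead <- o * direct_step
  step_total <- direct_step + overhead
  category_total <- colSums(per_sample)
  overhead_total <- sum(overhead)
  grand_total <- sum(step_total)
  share_of <- function(x) if (grand_total > 0) 100 * x / grand_total else x * 0
  structure(
    list(
      per_sample = per_sample,
      overhead = overhead,
      step_total = step_total,
      category_total = category_total,
      overhead_total = overhead_total,
      grand_total = grand_total,
      step_share = share_of(step_total),
      category_share = c(share_of(category_total),
                         overhead = unname(share_of(overhead_total))),
      currency = params$report_currency,
      batch_size = params$batch_size,
      overhead_rate = o,
      estimate = params$estimate
    ),
    class = "cost_matrix"
  )
}

#' @export
print.cost_matrix <- function(x, ...) {
  cat(sprintf("<cost_matrix> per-sample costs, %s, batch size %d (%s estimates)\n",
              x$currency, x$batch_size, x$estimate))
  print(render_base_table(x))
  invisible(x)
}

#' @export
as.data.frame.cost_matrix <- function(x, ...) {
  data.frame(
    step = 1:9,
    label = workflow_steps()$label,
    as.data.frame(x$per_sample),
    overhead = x$overhead,
    total = x$step_total,
    pct_of_total = x$step_share,
    row.names = NULL
  )
}
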