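#' @keywords internal
inventory_columns <- function() {
  c(
    "id", "step", "category", "behavior", "block_capacity", "valuation",
    "currency",
    "quantity_low", "quantity_base", "quantity_high",
    "unit_cost",
    "role", "annual_salary", "employer_contribution_rate",
    "social_security_rate", "annual_hours",
    "hours_low", "hours_base", "hours_high",
    "allocation_weight",
    "purchase_price", "lifetime_low", "lifetime_base", "lifetime_high",
    "annual_maintenance",
    "area_m2", "rate_per_m2_year",
    "gb_low", "gb_base", "gb_high", "price_per_gb_year", "storage_years"
  )
}

numeric_inventory_columns <- function() {
  setdiff(inventory_columns(),
          c("id", "category", "behavior", "valuation", "currency", "role"))
}

#' Construct an inventory from a data frame
#'
#' An inventory is a flat table with one row per resource line item. Each row
#' names its workflow step (1..9), cost category, cost behavior and valuation
#' route, plus the numeric fields that route requires. Three-point fields
#' (quantity, working hours, equipment lifetime, storage volume) are stored as
#' `*_low` / `*_base` / `*_high` columns; a missing low or high defaults to
#' the base value.
#'
#' @section Column dictionary:
#' \describe{
#'   \item{id}{Unique line-item identifier.}
#'   \item{step}{Workflow step index, 1..9 (see [workflow_steps()]).}
#'   \item{category}{One of [cost_categories()].}
#'   \item{behavior}{One of [cost_behaviors()]; `step_fixed` requires
#'     `block_capacity` (samples per capacity block).}
#'   \item{valuation}{One of [valuation_kinds()].}
#'   \item{currency}{Currency tag of the row's monetary fields
#'     (`NOK`, `USD`, `EUR`).}
#'   \item{quantity_low/base/high}{Units consumed: per sample (`variable`),
#'     per block (`step_fixed`) or per year (`fixed`).}
#'   \item{unit_cost}{Price per unit (route `unit_price`; for `fixed`
#'     behavior, `quantity * unit_cost` is the annual fee, e.g. a license).}
#'   \item{role, annual_salary, employer_contribution_rate,
#'     social_security_rate, annual_hours}{Personnel valuation: the loaded
#'     hourly wage is `annual_salary * (1 + employer_contribution_rate) *
#'     (1 + social_security_rate) / annual_hours`.}
#'   \item{hours_low/base/high}{Working time per occurrence (route
#'     `personnel`).}
#'   \item{allocation_weight}{Fraction of the cost attributed to this
#'     workflow, in (0, 1]; default 1.}
#'   \item{purchase_price, lifetime_low/base/high, annual_maintenance}{
#'     Equipment amortization inputs (route `equipment`).}
#'   \item{area_m2, rate_per_m2_year}{Laboratory space (route `space`).}
#'   \item{gb_low/base/high, price_per_gb_year, storage_years}{Data storage
#'     (route `storage`): gigabytes per sample, price per gigabyte-year,
#'     storage horizon in years.}
#' }
#'
#' @param df A data frame with at least the columns `id`, `step`, `category`,
#'   `behavior` and `valuation`; other columns default to `NA` (or 1 for
#'   `allocation_weight`, `"NOK"` for `currency`).
#' @return An object of class `inventory` (a data frame).
#' @export
as_inventory <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("id", "step", "category", "behavior", "valuation")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("inventory is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(df), inventory_columns())
  if (length(unknown) > 0)
    stop("unknown inventory column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in setdiff(inventory_columns(), names(df))) {
    fill <- if (col == "allocation_weight") 1
            else if (col == "currency") "NOK"
            else NA
    df[[col]] <- rep(fill, nrow(df))
  }
  df <- df[, inventory_columns()]
  for (col in numeric_inventory_columns()) df[[col]] <- as.numeric(df[[col]])
  df$step <- as.integer(df$step)
  df$allocation_weight[is.na(df$allocation_weight)] <- 1
  # missing low/high bounds collapse to the base value
  for (stem in c("quantity", "hours", "lifetime", "gb")) {
    base <- df[[paste0(stem, "_base")]]
    for (side in c("low", "high")) {
      col <- paste0(stem, "_", side)
      df[[col]] <- ifelse(is.na(df[[col]]), base, df[[col]])
    }
  }
  check_inventory_rows(df)
  rownames(df) <- NULL
  class(df) <- c("inventory", "data.frame")
  df
}

# hard schema errors: conditions under which a row cannot be costed at all
check_inventory_rows <- function(df) {
  fail <- function(i, field, msg)
    stop(sprintf("inventory row %d (id '%s'), field '%s': %s",
                 i, as.character(df$id[i]), field, msg), call. = FALSE)
  if (anyDuplicated(df$id) > 0)
    stop("inventory ids must be unique; duplicated: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(df))) {
    if (is.na(df$step[i]) || !df$step[i] %in% 1:9)
      fail(i, "step", "must be a workflow step index in 1..9")
    if (!df$category[i] %in% cost_categories())
      fail(i, "category", paste("must be one of",
                                paste(cost_categories(), collapse = ", ")))
    if (!df$behavior[i] %in% cost_behaviors())
      fail(i, "behavior", paste("must be one of",
                                paste(cost_behaviors(), collapse = ", ")))
    if (!df$valuation[i] %in% valuation_kinds())
      fail(i, "valuation", paste("must be one of",
                                 paste(valuation_kinds(), collapse = ", ")))
    if (df$behavior[i] == "step_fixed" &&
        (is.na(df$block_capacity[i]) || df$block_capacity[i] < 1))
      fail(i, "block_capacity",
           "step_fixed items require a positive samples-per-block capacity")
    for (col in c("quantity_base", "unit_cost", "annual_salary", "hours_base",
                  "purchase_price", "annual_maintenance", "area_m2",
                  "rate_per_m2_year", "gb_base", "price_per_gb_year")) {
      v <- df[[col]][i]
      if (!is.na(v) && v < 0) fail(i, col, "must be non-negative")
    }
  }
  invisible(df)
}

#' Read a resource inventory from CSV
#'
#' Reads a flat inventory table (comma-separated, UTF-8, header row, dot
#' decimal separator) following the column dictionary documented in
#' [as_inventory()]. Schema violations raise an error naming the offending
#' row and field.
#'
#' @param path Path to a CSV file.
#' @return An `inventory` object.
#' @export
#' @seealso [write_inventory()], [validate_inventory()]
read_inventory <- function(path) {
  if (!file.exists(path)) stop("inventory file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  as_inventory(df)
}

#' Write a resource inventory to CSV
#'
#' Inverse of [read_inventory()]: a written inventory re-reads to a
#' structurally identical object.
#'
#' @param inv An `inventory` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_inventory <- function(inv, path) {
  stopifnot(inherits(inv, "inventory"))
  utils::write.csv(as.data.frame(inv), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = TRUE, na = "")
  invisible(path)
}

#' @export
print.inventory <- function(x, ...) {
  cat(sprintf("<inventory> %d line items over %d workflow steps\n",
              nrow(x), length(unique(x$step))))
  tab <- table(factor(x$category, levels = cost_categories()))
  cat("  items by category:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Validate an inventory against the model's invariants
#'
#' Unlike the schema errors raised by [read_inventory()], validation returns
#' findings rather than throwing: each finding names the line item, the
#' invariant violated and a severity. An empty result means the inventory
#' satisfies every invariant.
#'
#' Checked invariants: bound ordering (low <= base <= high) for every
#' three-point field; allocation weight in (0, 1]; valuation routes carrying
#' their required fields; route/category consistency (equipment amortization
#' requires category `equipment` and behavior `fixed`; space requires
#' `equipment`; storage requires `software_storage`); known currency tags.
#'
#' @param inv An `inventory` object.
#' @return A data frame with columns `id`, `field`, `severity`, `message`;
#'   zero rows when the inventory is valid.
#' @export
validate_inventory <- function(inv) {
  stopifnot(inherits(inv, "inventory"))
  findings <- list()
  note <- function(id, field, message, severity = "error") {
    findings[[length(findings) + 1]] <<- data.frame(
      id = id, field = field, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(inv))) {
    it <- inv[i, ]
    for (stem in c("quantity", "hours", "lifetime", "gb")) {
      lo <- it[[paste0(stem, "_low")]]
      ba <- it[[paste0(stem, "_base")]]
      hi <- it[[paste0(stem, "_high")]]
      if (!any(is.na(c(lo, ba, hi))) && !(lo <= ba && ba <= hi))
        note(it$id, stem, sprintf(
          "bounds must satisfy low <= base <= high (got %g/%g/%g)",
          lo, ba, hi))
    }
    if (is.na(it$allocation_weight) || it$allocation_weight <= 0 ||
        it$allocation_weight > 1)
      note(it$id, "allocation_weight", "must lie in (0, 1]")
    if (!it$currency %in% known_currencies())
      note(it$id, "currency", paste("unknown currency tag:", it$currency))
    switch(it$valuation,
      unit_price = {
        if (is.na(it$unit_cost) || is.na(it$quantity_base))
          note(it$id, "unit_cost",
               "unit_price valuation requires unit_cost and quantity")
      },
      personnel = {
        if (is.na(it$annual_salary) || is.na(it$annual_hours) ||
            is.na(it$hours_base))
          note(it$id, "personnel",
               "personnel valuation requires annual_salary, annual_hours and hours")
        else if (it$annual_salary <= 0 || it$annual_hours <= 0)
          note(it$id, "personnel", "salary and annual hours must be positive")
        if (!identical(it$category, "personnel"))
          note(it$id, "category", "personnel valuation requires category 'personnel'")
      },
      equipment = {
        if (is.na(it$purchase_price) || is.na(it$lifetime_base))
          note(it$id, "amortization",
               "equipment valuation requires purchase_price and lifetime")
        else if (it$lifetime_base < 1)
          note(it$id, "lifetime_base", "equipment lifetime must be >= 1 year")
        if (!identical(it$category, "equipment"))
          note(it$id, "category", "amortized equipment requires category 'equipment'")
        if (!identical(it$behavior, "fixed"))
          note(it$id, "behavior", "amortized equipment requires behavior 'fixed'")
      },
      space = {
        if (is.na(it$area_m2) || is.na(it$rate_per_m2_year))
          note(it$id, "space",
               "space valuation requires area_m2 and rate_per_m2_year")
        if (!identical(it$category, "equipment"))
          note(it$id, "category", "laboratory space requires category 'equipment'")
      },
      storage = {
        if (is.na(it$gb_base) || is.na(it$price_per_gb_year) ||
            is.na(it$storage_years))
          note(it$id, "storage",
               "storage valuation requires gb, price_per_gb_year and storage_years")
        if (!identical(it$category, "software_storage"))
          note(it$id, "category", "data storage requires category 'software_storage'")
      }
    )
  }
  if (length(findings) == 0)
    data.frame(id = character(), field = character(), severity = character(),
               message = character(), stringsAsFactors = FALSE)
  else
    do.call(rbind, findings)
}

#' Personnel wage rate
#'
#' A role's annual salary with statutory loadings. The loaded hourly cost is
#' `annual_salary * (1 + employer_contribution_rate) *
#' (1 + social_security_rate) / annual_hours`: the two loadings compound
#' multiplicatively, following Norwegian unit-cost convention (13% employer
#' contributions, 25% social security costs by default).
#'
#' @param annual_salary Annual salary (money/year).
#' @param annual_hours Annual working hours of the role.
#' @param employer_contribution_rate Employer contribution loading (default 0.13).
#' @param social_security_rate Social-security loading (default 0.25).
#' @return An object of class `personnel_rate`.
#' @export
#' @examples
#' loaded_hourly_rate(personnel_rate(700000, 1695))
personnel_rate <- function(annual_salary, annual_hours,
                           employer_contribution_rate = 0.13,
                           social_security_rate = 0.25) {
  if (annual_salary < 0) stop("`annual_salary` must be >= 0", call. = FALSE)
  if (annual_hours <= 0) stop("`annual_hours` must be > 0", call. = FALSE)
  structure(
    list(annual_salary = annual_salary,
         annual_hours = annual_hours,
         employer_contribution_rate = employer_contribution_rate,
         social_security_rate = social_security_rate),
    class = "personnel_rate"
  )
}

#' @rdname personnel_rate
#' @param rate A `personnel_rate` object.
#' @return `loaded_hourly_rate()`: the loaded hourly cost (money/hour).
#' @export
loaded_hourly_rate <- function(rate) {
  stopifnot(inherits(rate, "personnel_rate"))
  rate$annual_salary *
    (1 + rate$employer_contribution_rate) *
    (1 + rate$social_security_rate) / rate$annual_hours
}
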