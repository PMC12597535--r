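#' The nine-step diagnostic workflow
#'
#' The costing model structures a genomic-profiling service into nine ordered
#' activity steps, from receipt of the analysis request through long-term
#' storage of the genomic data. Every resource line item in an inventory is
#' attached to exactly one of these steps.
#'
#' @return A data frame with columns `step` (integer 1..9) and `label`.
#' @export
#' @examples
#' workflow_steps()
workflow_steps <- function() {
  data.frame(
    step = 1:9,
    label = c(
      "Analysis request and sampling",
      "Sample registration and processing",
      "DNA/RNA extraction",
      "Library preparation",
      "Sequencing",
      "Data analysis",
      "Data interpretation",
      "Molecular tumor board and reporting",
      "Storage"
    ),
    stringsAsFactors = FALSE
  )
}

#' Direct cost categories
#'
#' The four direct cost categories of the model. Equipment subsumes laboratory
#' space; software/storage subsumes licenses and data storage. Overhead is
#' never a stored category: it is always derived as a flat markup on the sum
#' of the direct categories.
#'
#' @return Character vector of the four category codes, in report order.
#' @export
cost_categories <- function() {
  c("consumables", "personnel", "equipment", "software_storage")
}

#' Cost behavior codes
#'
#' `variable` costs accrue per sample, `fixed` costs accrue per year
#' independently of volume, and `step_fixed` costs accrue per capacity block
#' of `block_capacity` samples, increasing stepwise with batch size.
#'
#' @return Character vector of the three behavior codes.
#' @export
cost_behaviors <- function() {
  c("variable", "fixed", "step_fixed")
}

#' Valuation routes
#'
#' Each line item is valued through exactly one route: a unit price, a
#' personnel wage and working time, an amortized equipment purchase, a
#' laboratory-space rate, or a per-gigabyte storage price.
#'
#' @return Character vector of the five valuation codes.
#' @export
valuation_kinds <- function() {
  c("unit_price", "personnel", "equipment", "space", "storage")
}

known_currencies <- function() c("NOK", "USD", "EUR")
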