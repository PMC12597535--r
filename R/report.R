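#' Round half away from zero
#'
#' Commercial rounding used everywhere in rendered reports: ties round away
#' from zero (so 0.5 -> 1, -0.5 -> -1), unlike base R's round-half-to-even.
#' Internal arithmetic is never rounded; rounding is applied exactly once,
#' at render time.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits (default 0).
#' @return Rounded vector.
#' @export
#' @examples
#' round_half_out(c(0.5, 1.5, -0.5))
round_half_out <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Render the base-case cost table
#'
#' One row per workflow step plus a totals row and a category-share row;
#' columns are the four direct cost categories, overhead, the step total and
#' the step's share of the grand total. Every rendered figure is recomputed
#' from unrounded values and then rounded to integer dollars/percents
#' (half away from zero), so a rendered row may differ by +/-1 from the sum
#' of its rendered cells.
#'
#' @param m A `cost_matrix`.
#' @return A data frame of integers (plus the `step` label column).
#' @export
#' @examples
#' render_base_table(compute_matrix(calibrated_inventory(), cost_params()))
render_base_table <- function(m) {
  stopifnot(inherits(m, "cost_matrix"))
  steps <- workflow_steps()
  body <- data.frame(
    step = paste0(steps$step, ": ", steps$label),
    round_half_out(m$per_sample),
    overhead = round_half_out(m$overhead),
    total = round_half_out(m$step_total),
    pct_of_total = round_half_out(m$step_share),
    row.names = NULL,
    check.names = FALSE
  )
  totals <- data.frame(
    step = "Total costs",
    t(round_half_out(m$category_total)),
    overhead = round_half_out(m$overhead_total),
    total = round_half_out(m$grand_total),
    pct_of_total = 100,
    check.names = FALSE
  )
  shares <- data.frame(
    step = "% of total costs",
    t(round_half_out(m$category_share[cost_categories()])),
    overhead = round_half_out(m$category_share[["overhead"]]),
    total = 100,
    pct_of_total = NA,
    check.names = FALSE
  )
  out <- rbind(body, totals, shares)
  rownames(out) <- NULL
  out
}

#' Render a scenario comparison table
#'
#' One row per scenario (preceded by the shared base case), with rounded
#' category totals, overhead, the grand total, and the rounded percent
#' change against the base.
#'
#' @param results A list of `scenario_result` objects sharing one base
#'   matrix.
#' @return A data frame with one row per scenario plus the base-case row.
#' @export
render_scenario_table <- function(results) {
  if (inherits(results, "scenario_result")) results <- list(results)
  stopifnot(length(results) > 0,
            all(vapply(results, inherits, TRUE, "scenario_result")))
  base <- results[[1]]$base_matrix
  for (r in results)
    if (abs(r$base_matrix$grand_total - base$grand_total) > 1e-9)
      stop("all scenario results must share one base case", call. = FALSE)
  row_of <- function(label, m, pct_change) {
    data.frame(
      scenario = label,
      t(round_half_out(m$category_total)),
      overhead = round_half_out(m$overhead_total),
      total = round_half_out(m$grand_total),
      pct_change = if (is.na(pct_change)) NA
                   else round_half_out(pct_change),
      check.names = FALSE
    )
  }
  out <- rbind(
    row_of("Base case", base, NA),
    do.call(rbind, lapply(results, function(r)
      row_of(r$name, r$matrix, r$pct_change_total)))
  )
  rownames(out) <- NULL
  out
}

#' Export a cost matrix
#'
#' Writes the per-step cost decomposition with fixed column order
#' (`step`, the four categories, `overhead`, `total`, `pct_of_total`)
#' as CSV or JSON. Unrounded values are written; rendered (rounded) tables
#' are produced by [render_base_table()].
#'
#' @param m A `cost_matrix`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cost_matrix <- function(m, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(m)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(
      list(batch_size = m$batch_size,
           currency = m$currency,
           overhead_rate = m$overhead_rate,
           estimate = m$estimate,
           steps = df,
           category_total = as.list(m$category_total),
           overhead_total = m$overhead_total,
           grand_total = m$grand_total),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
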