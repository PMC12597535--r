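#' Global model parameters
#'
#' Economic parameters shared by every costing computation. The yearly sample
#' throughput is `batch_size * runs_per_year`; annual (fixed) costs are spread
#' over it. Overhead is a flat markup applied to all direct costs. Currency
#' conversion uses fixed 2024 exchange rates against the Norwegian krone.
#'
#' @param batch_size Samples processed in one weekly workflow run (default 12).
#' @param runs_per_year Workflow runs per year (default 52, one per week).
#' @param overhead_rate Flat markup on total direct costs (default 0.20).
#' @param interest_rate Annual interest rate used to annuitize equipment
#'   purchases (default 0.04).
#' @param nok_per_usd,nok_per_eur Fixed exchange rates, NOK per unit of the
#'   foreign currency (2024 rates: 10.7433 and 11.6276).
#' @param report_currency Currency in which results are expressed
#'   (`"USD"`, `"NOK"` or `"EUR"`; default `"USD"`).
#' @param estimate Which bound of every three-point (low/base/high) input to
#'   use: `"low"`, `"base"` or `"high"`.
#'
#' @return An object of class `cost_params`.
#' @export
#' @examples
#' p <- cost_params(batch_size = 12)
#' yearly_samples(p)
cost_params <- function(batch_size = 12L,
                        runs_per_year = 52L,
                        overhead_rate = 0.20,
                        interest_rate = 0.04,
                        nok_per_usd = 10.7433,
                        nok_per_eur = 11.6276,
                        report_currency = "USD",
                        estimate = c("base", "low", "high")) {
  estimate <- match.arg(estimate)
  batch_size <- as.integer(batch_size)
  runs_per_year <- as.integer(runs_per_year)
  if (is.na(batch_size) || batch_size < 1L)
    stop("`batch_size` must be a positive integer", call. = FALSE)
  if (is.na(runs_per_year) || runs_per_year < 1L)
    stop("`runs_per_year` must be a positive integer", call. = FALSE)
  if (overhead_rate < 0) stop("`overhead_rate` must be >= 0", call. = FALSE)
  if (interest_rate < 0) stop("`interest_rate` must be >= 0", call. = FALSE)
  if (!report_currency %in% known_currencies())
    stop("`report_currency` must be one of ",
         paste(known_currencies(), collapse = ", "), call. = FALSE)
  structure(
    list(
      batch_size = batch_size,
      runs_per_year = runs_per_year,
      overhead_rate = overhead_rate,
      interest_rate = interest_rate,
      nok_per_usd = nok_per_usd,
      nok_per_eur = nok_per_eur,
      report_currency = report_currency,
      estimate = estimate
    ),
    class = "cost_params"
  )
}

#' @export
print.cost_params <- function(x, ...) {
  cat("<cost_params>\n")
  cat(sprintf("  batch size     : %d samples/run, %d runs/year (N = %d)\n",
              x$batch_size, x$runs_per_year, yearly_samples(x)))
  cat(sprintf("  overhead rate  : %.0f%%\n", 100 * x$overhead_rate))
  cat(sprintf("  interest rate  : %.1f%%\n", 100 * x$interest_rate))
  cat(sprintf("  exchange rates : %.4f NOK/USD, %.4f NOK/EUR\n",
              x$nok_per_usd, x$nok_per_eur))
  cat(sprintf("  reporting      : %s, %s estimates\n",
              x$report_currency, x$estimate))
  invisible(x)
}

#' Yearly sample throughput
#'
#' @param params A [cost_params()] object.
#' @return `batch_size * runs_per_year`, the number of samples over which
#'   annual costs are spread.
#' @export
yearly_samples <- function(params) {
  params$batch_size * params$runs_per_year
}

#' Read model parameters from a YAML file
#'
#' Any field accepted by [cost_params()] may appear in the file; missing
#' fields take the documented defaults.
#'
#' @param path Path to a YAML file.
#' @return A [cost_params()] object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(cost_params))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0)
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(cost_params, raw)
}

#' Convert an amount between currencies
#'
#' Conversion pivots through NOK at the fixed 2024 rates held in `params`;
#' it is a linear bijection among NOK, USD and EUR, so round trips preserve
#' amounts to floating-point precision.
#'
#' @param amount Numeric amount(s).
#' @param from,to Currency tags (`"NOK"`, `"USD"` or `"EUR"`).
#' @param params A [cost_params()] object carrying the exchange rates.
#' @return The amount expressed in `to`.
#' @export
#' @examples
#' convert_currency(10.7433, "NOK", "USD", cost_params())
convert_currency <- function(amount, from, to, params = cost_params()) {
  rate_to_nok <- function(cur) {
    switch(cur,
      NOK = 1,
      USD = params$nok_per_usd,
      EUR = params$nok_per_eur,
      stop("unknown currency tag: ", cur, call. = FALSE)
    )
  }
  amount * rate_to_nok(from) / rate_to_nok(to)
}
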