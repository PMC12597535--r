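#' Default batch-size grid
#'
#' The batch sizes over which cost decomposition is explored by default.
#'
#' @return Integer vector `c(1, 4, 8, 12, 16, 24, 32, 64)`.
#' @export
default_batch_sizes <- function() c(1L, 4L, 8L, 12L, 16L, 24L, 32L, 64L)

#' Sweep per-sample costs over batch sizes
#'
#' Recomputes the full cost matrix independently at each batch size, tracks
#' the weekly personnel load per role, and flags roles whose load exceeds a
#' configured weekly hour capacity. Variable costs are invariant to the batch
#' size, fixed costs are diluted proportionally, and step-fixed costs trace a
#' sawtooth that is non-increasing along common multiples of the block
#' capacities.
#'
#' @param inv An `inventory` object.
#' @param params A [cost_params()] object; its `batch_size` is overridden by
#'   each swept size in turn.
#' @param sizes Batch sizes to evaluate (default [default_batch_sizes()]).
#' @param capacities Optional named numeric vector, weekly hour capacity per
#'   role; roles absent from it are never flagged.
#' @return An object of class `sweep_result`: list with `sizes`, `matrices`
#'   (one `cost_matrix` per size), `personnel_hours` (one named vector per
#'   size) and `flags` (one character vector of over-capacity roles per
#'   size).
#' @export
#' @examples
#' sw <- batch_sweep(calibrated_inventory(), cost_params(), c(12, 24))
#' sapply(sw$matrices, function(m) m$grand_total)
batch_sweep <- function(inv, params, sizes = default_batch_sizes(),
                        capacities = NULL) {
  stopifnot(inherits(inv, "inventory"), inherits(params, "cost_params"))
  sizes <- as.integer(sizes)
  if (length(sizes) == 0 || any(is.na(sizes)) || any(sizes < 1))
    stop("`sizes` must be a nonempty vector of batch sizes >= 1",
         call. = FALSE)
  matrices <- vector("list", length(sizes))
  hours <- vector("list", length(sizes))
  flags <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    p <- params
    p$batch_size <- sizes[k]
    matrices[[k]] <- compute_matrix(inv, p)
    hours[[k]] <- personnel_load(inv, sizes[k], estimate = params$estimate)
    over <- character()
    if (!is.null(capacities)) {
      for (role in names(capacities)) {
        load <- hours[[k]][role]
        if (!is.na(load) && load > capacities[[role]])
          over <- c(over, role)
      }
    }
    flags[[k]] <- over
  }
  names(matrices) <- names(hours) <- names(flags) <- as.character(sizes)
  structure(list(sizes = sizes, matrices = matrices,
                 personnel_hours = hours, flags = flags),
            class = "sweep_result")
}

#' Weekly personnel load by role
#'
#' Sums working hours per role over one weekly batch: variable tasks accrue
#' per sample, step-fixed tasks per capacity block, and fixed (annual,
#' standing) tasks are spread evenly over the weeks of the year.
#'
#' @param inv An `inventory` object.
#' @param n Batch size (samples per weekly run).
#' @param estimate `"low"`, `"base"` or `"high"` working-time bound.
#' @param runs_per_year Weeks over which annual standing tasks are spread.
#' @return Named numeric vector, hours per week by role (empty when the
#'   inventory has no personnel items).
#' @export
#' @examples
#' personnel_load(calibrated_inventory(), 12)
personnel_load <- function(inv, n, estimate = "base", runs_per_year = 52L) {
  stopifnot(inherits(inv, "inventory"))
  staff <- inv[inv$valuation == "personnel", , drop = FALSE]
  out <- numeric(0)
  for (i in seq_len(nrow(staff))) {
    item <- staff[i, ]
    h <- resolve_bound(item, "hours", estimate)
    weekly <- if (item$behavior == "fixed") {
      h / runs_per_year
    } else {
      q <- resolve_bound(item, "quantity", estimate)
      units_required(item$behavior, q, n, item$block_capacity) * h
    }
    role <- if (is.na(item$role)) "unspecified" else item$role
    out[role] <- if (role %in% names(out)) out[[role]] + weekly else weekly
  }
  out
}

#' Long-format sweep export
#'
#' Flattens a sweep into one row per batch size, step and category (plus
#' overhead), suitable for stacked-area plotting or CSV export.
#'
#' @param sw A `sweep_result`.
#' @return Data frame with columns `batch_size`, `step`, `category`,
#'   `cost_per_sample`.
#' @export
sweep_long <- function(sw) {
  stopifnot(inherits(sw, "sweep_result"))
  rows <- lapply(seq_along(sw$sizes), function(k) {
    m <- sw$matrices[[k]]
    direct <- as.data.frame(as.table(m$per_sample), stringsAsFactors = FALSE)
    names(direct) <- c("step", "category", "cost_per_sample")
    oh <- data.frame(step = as.character(1:9), category = "overhead",
                     cost_per_sample = as.numeric(m$overhead),
                     stringsAsFactors = FALSE)
    out <- rbind(direct, oh)
    out$batch_size <- sw$sizes[k]
    out
  })
  out <- do.call(rbind, rows)
  out$step <- as.integer(out$step)
  out[, c("batch_size", "step", "category", "cost_per_sample")]
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d batch sizes\n", length(x$sizes)))
  tot <- sapply(x$matrices, function(m) m$grand_total)
  print(data.frame(batch_size = x$sizes, total_per_sample = round(tot, 2),
                   flagged_roles = sapply(x$flags, function(f)
                     if (length(f) == 0) "" else paste(f, collapse = ",")),
                   row.names = NULL))
  invisible(x)
}

#' Stacked-area plot of cost decomposition across batch sizes
#'
#' Renders per-sample costs by cost category (including overhead) along the
#' swept batch sizes. Requires ggplot2.
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.sweep_result <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting a sweep requires the ggplot2 package", call. = FALSE)
  long <- sweep_long(x)
  agg <- stats::aggregate(cost_per_sample ~ batch_size + category, long, sum)
  agg$category <- factor(agg$category,
                         levels = c(rev(cost_categories()), "overhead"))
  ggplot2::ggplot(agg, ggplot2::aes(
    x = .data$batch_size, y = .data$cost_per_sample,
    fill = .data$category)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "weekly batch size", y = "cost per sample",
                  fill = "cost category") +
    ggplot2::theme_minimal()
}
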