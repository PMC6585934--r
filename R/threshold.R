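# From posterior elasticity draws to the k-threshold.

#' Summarize the k-threshold over posterior elasticity draws
#'
#' For each elasticity draw, the incremental discounted cost, QALYs and life
#' years of the marginal spending increase are computed. The point estimate
#' is mean incremental cost divided by mean incremental QALYs across draws.
#' The reported 95% interval follows the study's convention: the
#' cost-effectiveness ratio is evaluated at the 0.025 and 0.975 quantiles of
#' the elasticity draws (not a percentile interval of per-draw ratios; that
#' alternative is also returned, as `ci95_qaly_ratio_quantiles`). If the mean
#' incremental QALY is not positive the point estimate is undefined (`NA`)
#' and flagged.
#'
#' @param draw_elasticities Numeric vector of elasticity draws (alpha + beta).
#' @param inputs A [life_table_inputs()].
#' @param spend_increase Proportional spending increase (default 0.10).
#' @param discounts A [discount_spec()].
#' @param mode Mortality-adjustment convention, see [adjust_mortality()].
#' @return An object of class `threshold_summary`: `cost_per_qaly`,
#'   `cost_per_ly`, `ci95_qaly`, `ci95_ly` (ratio at elasticity quantiles),
#'   `ci95_qaly_ratio_quantiles`, `n_draws`, `share_nonpositive_dqaly`,
#'   `flags`, and the per-draw `deltas` matrix.
#' @export
summarize_threshold <- function(draw_elasticities, inputs,
                                spend_increase = 0.10,
                                discounts = discount_spec(),
                                mode = c("power", "linear")) {
  mode <- match.arg(mode)
  e <- as.numeric(draw_elasticities)
  if (length(e) < 1 || anyNA(e))
    stop_kthresh("at least one finite elasticity draw is required")
  f <- make_delta_fn(inputs, spend_increase, discounts, mode)
  deltas <- t(vapply(e, f, numeric(3)))
  colnames(deltas) <- c("delta_cost", "delta_qaly", "delta_ly")

  flags <- character(0)
  mean_dq <- mean(deltas[, "delta_qaly"])
  mean_dl <- mean(deltas[, "delta_ly"])
  mean_dc <- mean(deltas[, "delta_cost"])
  cost_per_qaly <- if (mean_dq > 0) mean_dc / mean_dq else NA_real_
  cost_per_ly <- if (mean_dl > 0) mean_dc / mean_dl else NA_real_
  if (mean_dq <= 0)
    flags <- c(flags, "mean incremental QALYs <= 0: point estimate undefined")

  # interval convention: ratio evaluated at the elasticity quantiles
  qe <- quantile(e, c(0.025, 0.975), names = FALSE, type = 7)
  ratio_at <- function(el) {
    d <- f(el)
    c(qaly = if (d[["delta_qaly"]] > 0) d[["delta_cost"]] / d[["delta_qaly"]]
      else NA_real_,
      ly = if (d[["delta_ly"]] > 0) d[["delta_cost"]] / d[["delta_ly"]]
      else NA_real_)
  }
  r_lo <- ratio_at(qe[1])
  r_hi <- ratio_at(qe[2])
  ci95_qaly <- sort(c(r_lo[["qaly"]], r_hi[["qaly"]]), na.last = TRUE)
  ci95_ly <- sort(c(r_lo[["ly"]], r_hi[["ly"]]), na.last = TRUE)

  pos <- deltas[, "delta_qaly"] > 0
  icer <- ifelse(pos, deltas[, "delta_cost"] / deltas[, "delta_qaly"], NA)
  ci_ratio <- if (any(pos))
    quantile(icer[pos], c(0.025, 0.975), names = FALSE, type = 7)
  else c(NA_real_, NA_real_)

  structure(list(
    cost_per_qaly = cost_per_qaly, cost_per_ly = cost_per_ly,
    ci95_qaly = ci95_qaly, ci95_ly = ci95_ly,
    ci95_qaly_ratio_quantiles = ci_ratio,
    n_draws = length(e),
    share_nonpositive_dqaly = mean(!pos),
    elasticities = e,
    elasticity_quantiles = qe,
    deltas = deltas, flags = flags,
    spend_increase = spend_increase, discounts = discounts, mode = mode
  ), class = "threshold_summary")
}

#' @export
print.threshold_summary <- function(x, ...) {
  fmt100 <- function(v) ifelse(is.na(v), "NA",
                               format(round(v / 100) * 100, big.mark = ","))
  cat("k-threshold summary (", x$n_draws, " draws)\n", sep = "")
  cat("  cost per QALY: ", fmt100(x$cost_per_qaly),
      " (", fmt100(x$ci95_qaly[1]), "/", fmt100(x$ci95_qaly[2]), ")\n",
      sep = "")
  cat("  cost per life year: ", fmt100(x$cost_per_ly),
      " (", fmt100(x$ci95_ly[1]), "/", fmt100(x$ci95_ly[2]), ")\n", sep = "")
  cat("  share of draws with non-positive incremental QALYs: ",
      format(x$share_nonpositive_dqaly), "\n", sep = "")
  for (f in x$flags) cat("  flag: ", f, "\n", sep = "")
  invisible(x)
}

#' Probability that the threshold lies below a monetary value
#'
#' Per draw, the incremental cost-effectiveness ratio of the marginal
#' spending increase is computed; the curve at a grid value x is the fraction
#' of draws with positive incremental QALYs whose ratio is at most x. Draws
#' with non-positive incremental QALYs never count as below any finite value,
#' so the curve stays below 1 when a fraction of draws shows no health gain.
#'
#' @inheritParams summarize_threshold
#' @param grid Ascending numeric vector of monetary values.
#' @return An object of class `probability_curve`: data frame with `value`
#'   and `probability` (non-decreasing, in \[0,1\]), plus attributes with the
#'   per-draw ratios.
#' @export
probability_below <- function(draw_elasticities, inputs,
                              spend_increase = 0.10,
                              discounts = discount_spec(),
                              grid, mode = c("power", "linear")) {
  mode <- match.arg(mode)
  if (missing(grid) || length(grid) == 0)
    stop_kthresh("a non-empty monetary grid is required")
  if (is.unsorted(grid, strictly = FALSE))
    stop_kthresh("grid must be sorted ascending")
  e <- as.numeric(draw_elasticities)
  f <- make_delta_fn(inputs, spend_increase, discounts, mode)
  deltas <- t(vapply(e, f, numeric(3)))
  pos <- deltas[, 2] > 0
  icer <- deltas[pos, 1] / deltas[pos, 2]
  prob <- vapply(grid, function(x) sum(icer <= x), 0) / length(e)
  structure(
    data.frame(value = grid, probability = prob),
    icer = icer, n_draws = length(e),
    share_nonpositive_dqaly = mean(!pos),
    class = c("probability_curve", "data.frame")
  )
}

#' Write a probability curve as a two-column table
#'
#' @param curve A `probability_curve`.
#' @param path Output path.
#' @param meta Named list written as `# key: value` header lines.
#' @return The path, invisibly.
#' @export
write_curve <- function(curve, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  write.csv(as.data.frame(curve)[c("value", "probability")], con,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
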