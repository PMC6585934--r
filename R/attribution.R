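# Attribution of the life-expectancy gain to spending growth.

#' Share of the life-expectancy gain attributable to spending growth
#'
#' Compares, at a reference age, three undiscounted life expectancies built
#' on the life-table inputs' other-cause mortality: one with cardiovascular
#' mortality as observed in the panel's first year (baseline), one with the
#' first-year rates scaled by the spending-attributable factor
#' `(c_last / c_first)^elasticity` per age group (via [adjust_mortality()]),
#' and one with the last year's observed rates (the full change). The
#' returned fraction is the attributable life-expectancy gain divided by the
#' full observed gain, with gains aggregated over genders using the inputs'
#' population weights.
#'
#' @param panel A panel data frame spanning at least two years.
#' @param inputs A [life_table_inputs()] covering the reference age.
#' @param elasticity Spending elasticity of mortality.
#' @param reference_age Age at which life expectancy is evaluated.
#' @param mode Mortality-adjustment convention.
#' @return An object of class `le_attribution`: `fraction`, `numerator`
#'   (attributable LE gain in years), `denominator` (full LE gain),
#'   `per_gender` detail, and `flags`. A zero denominator gives `NA` and a
#'   flag.
#' @export
attribute_le_gain <- function(panel, inputs, elasticity, reference_age,
                              mode = c("power", "linear")) {
  mode <- match.arg(mode)
  validate_panel(panel)
  stopifnot(inherits(inputs, "life_table_inputs"))
  y0 <- min(panel$year); y1 <- max(panel$year)
  if (y1 <= y0) stop_kthresh("panel must span at least two years")

  groups <- unique(panel$age_group)
  starts <- sort(unique(age_group_start(groups)))
  if (reference_age < min(starts))
    stop_kthresh(sprintf("reference_age %d below the panel's age coverage",
                         reference_age))
  nodisc <- discount_spec(0, 0)
  genders <- unique(inputs$population$gender)
  wg <- vapply(genders, function(g)
    sum(inputs$population$population[inputs$population$gender == g]), 0)
  wg <- wg / sum(wg)

  per_gender <- lapply(genders, function(g) {
    prep <- prepare_cohort(inputs, reference_age, g)
    # per-age panel lookups: each single age takes its group's value
    gidx <- findInterval(prep$ages, starts)
    glab <- groups[match(starts[gidx], age_group_start(groups))]
    pick <- function(yr, col) {
      i <- match(paste(glab, g, yr), paste(panel$age_group, panel$gender,
                                           panel$year))
      if (anyNA(i))
        stop_kthresh(sprintf(
          "panel does not cover age group %s / gender %s in year %d",
          glab[which(is.na(i))[1]], g, yr))
      panel[[col]][i]
    }
    m_first <- pick(y0, "mortality_rate")
    m_last <- pick(y1, "mortality_rate")
    c_mult <- pick(y1, "spending") / pick(y0, "spending")
    m_attr <- adjust_mortality(m_first, c_mult, elasticity, mode)
    le <- function(cvd) project_prepared(prep, nodisc, cvd = cvd)$ly
    le_base <- le(m_first)
    c(gain_attr = le(m_attr) - le_base, gain_full = le(m_last) - le_base)
  })
  names(per_gender) <- genders
  num <- sum(wg * vapply(per_gender, `[[`, 0, "gain_attr"))
  den <- sum(wg * vapply(per_gender, `[[`, 0, "gain_full"))

  flags <- character(0)
  fraction <- if (abs(den) < .Machine$double.eps * 100) {
    flags <- "full observed life-expectancy change is zero: fraction undefined"
    warning(flags, call. = FALSE)
    NA_real_
  } else num / den
  structure(list(fraction = fraction, numerator = num, denominator = den,
                 per_gender = per_gender, reference_age = reference_age,
                 elasticity = elasticity, years = c(y0, y1), flags = flags),
            class = "le_attribution")
}

#' @export
print.le_attribution <- function(x, ...) {
  cat(sprintf(
    "life-expectancy gain at age %d, %d-%d: %.3f of the gain attributable to spending growth (%.3f / %.3f years)\n",
    x$reference_age, x$years[1], x$years[2],
    x$fraction, x$numerator, x$denominator))
  invisible(x)
}
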