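# Differenced design construction.

#' Build the first-differenced model frame
#'
#' Turns a spending/mortality panel into the regression design: one row per
#' stratum and year `y` for which both `y-1` and `y-2` are present, carrying
#' the change in log mortality, the change in log spending, and the lagged
#' change in log spending, all computed within the stratum:
#' \deqn{\Delta \log m_y = \log m_y - \log m_{y-1},\quad
#'       \Delta \log c_y = \log c_y - \log c_{y-1},\quad
#'       \Delta \log c_{y-1} = \log c_{y-1} - \log c_{y-2}.}
#' The lag consumes a second leading year, so a stratum observed over T
#' consecutive years contributes T-2 rows. Year and stratum ids are assigned
#' densely (1..n) over the years/strata that survive the windowing.
#'
#' @param panel A panel data frame (see [validate_panel()]).
#' @param year_min,year_max Optional inclusive calendar window applied before
#'   differencing (the window must still leave >= 3 consecutive years).
#' @return An object of class `model_frame`: a data frame with columns
#'   age_group, gender, year, dlog_m, dlog_c, dlog_c_lag, year_id,
#'   stratum_id, plus attributes `year_levels` and `stratum_levels`.
#' @export
build_model_frame <- function(panel, year_min = NULL, year_max = NULL) {
  validate_panel(panel)
  if (!is.null(year_min)) panel <- panel[panel$year >= year_min, , drop = FALSE]
  if (!is.null(year_max)) panel <- panel[panel$year <= year_max, , drop = FALSE]
  if (nrow(panel) == 0)
    stop_kthresh(sprintf("no panel rows in the year window [%s, %s]",
                         year_min %||% "-Inf", year_max %||% "Inf"))

  panel <- panel[order(panel$gender, panel$age_group, panel$year), ]
  key <- paste(panel$age_group, panel$gender, sep = "|")
  pieces <- lapply(split(panel, key), function(d) {
    if (nrow(d) < 3) {
      stop_kthresh(sprintf(
        "stratum %s/%s has only %d year(s) in the window; >= 3 consecutive years are required",
        d$age_group[1], d$gender[1], nrow(d)))
    }
    lm_ <- log(d$mortality_rate)
    lc <- log(d$spending)
    i <- 3:nrow(d)
    data.frame(
      age_group = d$age_group[i], gender = d$gender[i], year = d$year[i],
      dlog_m = lm_[i] - lm_[i - 1L],
      dlog_c = lc[i] - lc[i - 1L],
      dlog_c_lag = lc[i - 1L] - lc[i - 2L],
      stringsAsFactors = FALSE
    )
  })
  frame <- do.call(rbind, pieces)
  rownames(frame) <- NULL
  if (!all(is.finite(frame$dlog_m)) || !all(is.finite(frame$dlog_c)) ||
      !all(is.finite(frame$dlog_c_lag)))
    stop_kthresh("non-finite values in the differenced design")

  year_levels <- sort(unique(frame$year))
  stratum_levels <- sort(unique(paste(frame$age_group, frame$gender,
                                      sep = "|")))
  frame$year_id <- match(frame$year, year_levels)
  frame$stratum_id <- match(paste(frame$age_group, frame$gender, sep = "|"),
                            stratum_levels)
  frame <- frame[order(frame$stratum_id, frame$year_id), ]
  rownames(frame) <- NULL
  structure(frame, year_levels = year_levels,
            stratum_levels = stratum_levels,
            class = c("model_frame", "data.frame"))
}
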