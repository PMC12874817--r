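#' Kaplan-Meier survival curve
#'
#' Product-limit estimate `prod(1 - d_i / n_i)` over event times up to `t`,
#' optionally stratified by a grouping vector. Ties between censored and
#' event times at the same instant are handled with the standard convention
#' (events first).
#'
#' @param time follow-up times (> 0).
#' @param event event indicators (0/1).
#' @param group optional grouping vector (e.g. transplant status).
#' @return object of class `km_curve`: data.frame with columns `group`,
#'   `time`, `n_risk`, `n_event`, `survival`.
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  if (!length(time)) stop("empty input to kaplan_meier()")
  if (any(time <= 0)) stop("times must be > 0")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  df <- data.frame(time = time, event = event,
                   group = if (is.null(group)) "all" else as.character(group))
  out <- lapply(split(df, df$group), function(d) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    data.frame(group = d$group[1], time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, survival = sf$surv)
  })
  structure(do.call(rbind, c(out, list(make.row.names = FALSE))),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function evaluation; S(t) = 1 before the first
#' observed time.
#'
#' @param curve a `km_curve` (single group).
#' @param times evaluation times.
#' @return survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  if (length(unique(curve$group)) > 1)
    stop("km_survival_at() expects a single-group curve; subset first")
  idx <- findInterval(times, curve$time)
  c(1, curve$survival)[idx + 1L]
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The smallest time at which the curve reaches 0.5 or below; `NA` ("not
#' reached") when the curve plateaus above 0.5. No interpolation is used.
#'
#' @param curve a `km_curve`.
#' @return named numeric vector, one entry per group (`NA` = not reached).
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(split(curve, curve$group), function(d) {
    hit <- which(d$survival <= 0.5)
    if (length(hit)) d$time[min(hit)] else NA_real_
  }, numeric(1))
}

#' Descriptive summary table
#'
#' Mean +/- SD for numeric columns and n (%) for categorical columns, both
#' overall and within each level of `group_by`. Percentages are computed
#' within column totals; the `formatted` column rounds counts with
#' thousands separators and percents to one decimal.
#'
#' @param cohort cohort data.frame.
#' @param group_by optional name of a grouping column.
#' @param exclude columns to skip (default `id` plus follow-up columns).
#' @return data.frame `variable,level,group,n,percent,mean,sd,formatted`.
#' @export
descriptive_table <- function(cohort, group_by = NULL,
                              exclude = c("id", "time", "event")) {
  if (!is.null(group_by) && !group_by %in% names(cohort))
    stop("unknown grouping column: '", group_by, "'")
  vars <- setdiff(names(cohort), c(exclude, group_by))
  groups <- list(overall = rep(TRUE, nrow(cohort)))
  if (!is.null(group_by)) {
    gv <- as.character(cohort[[group_by]])
    for (g in sort(unique(gv)))
      groups[[paste0(group_by, "=", g)]] <- gv == g
  }
  rows <- list()
  for (v in vars) {
    col <- cohort[[v]]
    for (g in names(groups)) {
      sub <- col[groups[[g]]]
      if (is.numeric(col)) {
        m <- mean(sub); s <- stats::sd(sub)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = NA_character_, group = g,
          n = length(sub), percent = NA_real_, mean = m, sd = s,
          formatted = sprintf("%.1f ± %.1f", m, s))
      } else {
        for (lv in sort(unique(as.character(col)))) {
          n <- sum(sub == lv)
          pct <- 100 * n / length(sub)
          rows[[length(rows) + 1L]] <- data.frame(
            variable = v, level = lv, group = g,
            n = n, percent = pct, mean = NA_real_, sd = NA_real_,
            formatted = sprintf("%s (%.1f%%)",
                                format(n, big.mark = ",", scientific = FALSE),
                                pct))
        }
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
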