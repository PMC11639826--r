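# Survival and response endpoints: Kaplan-Meier estimation, log-rank tests,
# objective response / disease control rates, and median follow-up by the
# reverse Kaplan-Meier method. Estimation is delegated to the survival
# package; this layer fixes the conventions (median = smallest t with
# S(t) <= 0.5; events before censorings at tied times, the product-limit
# standard).

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator. The median is the smallest observed time with
#' `S(t) <= 0.5`, `NA` when the curve never reaches 0.5.
#'
#' @param time Non-negative times in months.
#' @param event Logical; `TRUE` = event observed, `FALSE` = censored.
#' @return A `km_curve`: list with `time`, `n_risk`, `n_event`, `surv`
#'   (values at the distinct observed times) and `median`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("empty input")
  if (any(time < 0)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  med <- km_median(fit$time, fit$surv)
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 surv = fit$surv, median = med),
            class = "km_curve")
}

km_median <- function(time, surv) {
  hit <- which(surv <= 0.5 + 1e-12)
  if (length(hit) == 0) NA_real_ else time[hit[1]]
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$time), "time points, median =",
      ifelse(is.na(x$median), "not reached", format(x$median)), "\n")
  invisible(x)
}

#' Log-rank test across two or more groups
#'
#' Unweighted (Mantel-Haenszel) log-rank chi-square with (g - 1) degrees of
#' freedom, two-sided.
#'
#' @param time Times in months.
#' @param event Logical event indicators.
#' @param group Group labels (length of `time`).
#' @return List: `statistic`, `df`, `p_value`, `group_sizes`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) == 0)) stop("empty group")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  df <- nlevels(group) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       group_sizes = as.integer(table(group)))
}

#' Objective response and disease control rates
#'
#' ORR = percentage with best response CR or PR; DCR adds SD. Percentages are
#' reported rounded half-up to one decimal. Patients with best response NE
#' count in the denominator by default (conservative); set
#' `include_ne = FALSE` to drop them.
#'
#' @param best_response Character vector of RECIST categories
#'   (CR/PR/SD/PD/NE).
#' @param include_ne Keep NE patients in the denominator; default `TRUE`.
#' @return List: `n`, `orr_pct`, `dcr_pct`.
#' @export
response_rates <- function(best_response, include_ne = TRUE) {
  if (length(best_response) == 0) stop("empty input")
  r <- toupper(best_response)
  bad <- setdiff(unique(r), c("CR", "PR", "SD", "PD", "NE"))
  if (length(bad) > 0) stop("unknown best_response: ", paste(bad, collapse = ", "))
  if (!include_ne) r <- r[r != "NE"]
  n <- length(r)
  if (n == 0) stop("no evaluable patients")
  list(n = n,
       orr_pct = round_half_up(100 * sum(r %in% c("CR", "PR")) / n, 1),
       dcr_pct = round_half_up(100 * sum(r %in% c("CR", "PR", "SD")) / n, 1))
}

#' Median follow-up
#'
#' Reverse Kaplan-Meier by default: the censoring indicator is flipped (so
#' censored patients become "events") and the KM median of that curve is the
#' follow-up estimate; `NA` when undefined (e.g. everyone died). The naive
#' median of observation times is available via `method = "naive"`.
#'
#' @param time Observation times in months.
#' @param event Logical event indicators.
#' @param method `"reverse_km"` (default) or `"naive"`.
#' @return Months (may be `NA` for reverse KM).
#' @export
median_followup <- function(time, event, method = c("reverse_km", "naive")) {
  method <- match.arg(method)
  if (length(time) == 0) stop("empty input")
  if (method == "naive") return(stats::median(time))
  km_estimate(time, !event)$median
}
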