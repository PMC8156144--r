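#' Kaplan-Meier product-limit estimate
#'
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over the distinct event
#' times, with \eqn{d_i} events among \eqn{n_i} at risk. Subjects censored at
#' an event time are counted at risk for that event (the standard
#' convention). Delegates to [survival::survfit()].
#'
#' @param times Non-negative follow-up times (months).
#' @param events Event indicators (1 = event, 0 = censored).
#' @return `data.frame` with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1L)
  if (any(is.na(times)) || any(times < 0)) {
    stop("times must be non-negative and non-missing")
  }
  if (!all(events %in% c(0, 1))) stop("events must be coded 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected event counts across the pooled distinct event
#' times with the hypergeometric variance, referred to a chi-square on one
#' degree of freedom. Delegates to [survival::survdiff()]. With no events at
#' all, the statistic is 0 and p = 1 by convention.
#'
#' @param times,events As in [kaplan_meier()].
#' @param groups Binary group labels (two nonempty groups).
#' @return A `sig_test` with `statistic` (chi-square), `p`.
#' @export
log_rank <- function(times, events, groups) {
  stopifnot(length(times) == length(events),
            length(times) == length(groups))
  groups <- .binary_labels(groups, length(times))
  if (length(unique(groups)) < 2L) stop("both groups must be nonempty")
  if (sum(events) == 0) {
    return(.sig_test(0, 1, method = "log-rank test (no events)"))
  }
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  chisq <- unname(fit$chisq)
  .sig_test(chisq, stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
            method = "log-rank test")
}

#' Score-group survival analysis within a treatment stratum
#'
#' Subsets the clinical table to one stratum (e.g. `chemotherapy == "yes"`),
#' joins the dichotomized score groups by sample id, and runs a per-group
#' Kaplan-Meier fit plus a two-group log-rank test for the requested
#' endpoint.
#'
#' @param clinical Clinical `data.frame` in the canonical layout
#'   (see [read_clinical()]).
#' @param groups `data.frame` with `sample_id` and `group` columns (as from
#'   [dichotomize_top_fraction()]).
#' @param endpoint One of `"OS"`, `"DFS"`, `"DSS"`.
#' @param stratum Value of the stratification variable to keep, or `NULL`
#'   for no stratification.
#' @param stratum_var Clinical column to stratify on.
#' @return A `survival_fit`: list with `endpoint`, `stratum`, `n`, `fits`
#'   (named list of per-group KM tables), `log_rank` (a `sig_test`).
#' @export
stratified_survival_analysis <- function(clinical, groups, endpoint,
                                         stratum = NULL,
                                         stratum_var = "chemotherapy") {
  stopifnot(endpoint %in% .endpoints,
            all(c("sample_id", "group") %in% colnames(groups)))
  time_col <- paste0(endpoint, "_time")
  event_col <- paste0(endpoint, "_event")
  if (!all(c(time_col, event_col) %in% colnames(clinical))) {
    stop("clinical table lacks ", endpoint, " columns")
  }
  sub <- clinical
  if (!is.null(stratum)) {
    sub <- sub[sub[[stratum_var]] == stratum, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("no samples in stratum ", stratum_var, " = ", stratum)
    }
  }
  merged <- merge(sub, groups[, c("sample_id", "group")], by = "sample_id")
  merged <- merged[!is.na(merged[[time_col]]) &
                     !is.na(merged[[event_col]]), , drop = FALSE]
  lv <- levels(factor(merged$group))
  if (length(lv) < 2L || any(table(merged$group) == 0L)) {
    stop("a score group is empty within stratum ",
         if (is.null(stratum)) "(none)" else paste(stratum_var, "=", stratum))
  }
  fits <- lapply(stats::setNames(lv, lv), function(g) {
    rows <- merged$group == g
    kaplan_meier(merged[[time_col]][rows], merged[[event_col]][rows])
  })
  lr <- log_rank(merged[[time_col]], merged[[event_col]],
                 as.integer(merged$group == lv[[2L]]))
  structure(list(endpoint = endpoint, stratum = stratum,
                 stratum_var = if (is.null(stratum)) NA_character_ else
                   stratum_var,
                 n = nrow(merged), fits = fits, log_rank = lr),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("Kaplan-Meier fit, endpoint ", x$endpoint,
      if (!is.na(x$stratum_var)) paste0(", ", x$stratum_var, " = ", x$stratum),
      ", n = ", x$n, "\n", sep = "")
  print(x$log_rank)
  invisible(x)
}
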