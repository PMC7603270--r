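#' Kaplan-Meier estimation and log-rank tests between phenotype groups
#'
#' Thin, convention-explicit layer over the `survival` package: the
#' product-limit estimator with median defined as the first time the
#' curve reaches 0.5 or below, pairwise and global log-rank tests, and
#' the IDH wild-type clinical filter.
#'
#' @name survival_analysis
NULL

#' Kaplan-Meier curve of a set of survival records
#'
#' @param time_days positive follow-up times in days.
#' @param event 1 = death observed, 0 = censored.
#' @return a `km_curve`: time, survival, n at risk, n events, and the
#'   median (`NA` if the curve never reaches 0.5).
#' @export
km_estimate <- function(time_days, event) {
  if (length(time_days) < 1) stop("need at least one record")
  if (any(time_days <= 0)) stop("survival times must be positive")
  fit <- survival::survfit(survival::Surv(time_days, event) ~ 1,
                           conf.type = "none")
  med <- km_median(fit$time, fit$surv)
  structure(list(time = fit$time, survival = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 median = med, n = length(time_days)),
            class = "km_curve")
}

# First time at which S(t) <= 0.5; NA when the curve stays above 0.5.
km_median <- function(time, surv) {
  hit <- which(surv <= 0.5)
  if (length(hit) == 0) NA_real_ else time[hit[1]]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, median = %s days\n",
              x$n, sum(x$n_event),
              ifelse(is.na(x$median), "not reached", format(x$median))))
  invisible(x)
}

#' Log-rank test between two (or k) groups
#'
#' Standard observed-minus-expected chi-squared with hypergeometric
#' variance. With exactly two groups the statistic has 1 df; with more,
#' `k - 1` df (the global test).
#'
#' @param time_days,event survival records.
#' @param group group membership vector.
#' @return list: `statistic`, `df`, `p_value`, `n`, `n_events`.
#' @export
logrank <- function(time_days, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2) stop("need at least two non-empty groups")
  if (sum(event) < 1) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ group)
  df <- nlevels(group) - 1
  stat <- sd$chisq
  list(statistic = unname(stat), df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       n = length(time_days), n_events = sum(event))
}

#' Pairwise log-rank tests across phenotype groups
#'
#' @param records data frame with columns `time_days` (or
#'   `survival_days`), `event`, `group`.
#' @return data frame of all group pairs with statistic and p-value, plus
#'   the global test as attribute `"global"`.
#' @export
pairwise_logrank <- function(records) {
  tm <- records$time_days %||% records$survival_days
  groups <- sort(unique(records$group))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    idx <- records$group %in% p
    lr <- tryCatch(logrank(tm[idx], records$event[idx], records$group[idx]),
                   error = function(e) list(statistic = NA, p_value = NA))
    data.frame(group_a = p[1], group_b = p[2],
               statistic = lr$statistic, p_value = lr$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(groups) > 2) {
    attr(out, "global") <- tryCatch(logrank(tm, records$event, records$group),
                                    error = function(e) NULL)
  }
  out
}

#' Keep only IDH wild-type patients
#'
#' @param clinical data frame with an `idh_status` column (values like
#'   "wild-type"/"WT" vs "mutant").
#' @return filtered data frame; counts are reported via message, and an
#'   empty result triggers a warning.
#' @export
idh_filter <- function(clinical) {
  if (!"idh_status" %in% names(clinical)) stop("missing idh_status column")
  st <- tolower(gsub("[^a-z]", "", tolower(clinical$idh_status)))
  keep <- st %in% c("wildtype", "wt")
  message(sprintf("idh_filter: retained %d wild-type of %d patients",
                  sum(keep), nrow(clinical)))
  out <- clinical[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no wild-type patients remain after filtering")
  out
}

#' Export KM curves for a set of groups as CSV
#'
#' @param records data frame with `time_days`/`survival_days`, `event`,
#'   `group`.
#' @param path CSV path (columns: group, time, survival, at_risk).
#' @export
write_km_csv <- function(records, path) {
  tm <- records$time_days %||% records$survival_days
  rows <- lapply(sort(unique(records$group)), function(g) {
    idx <- records$group == g
    km <- km_estimate(tm[idx], records$event[idx])
    data.frame(group = g, time = km$time, survival = km$survival,
               at_risk = km$n_risk)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
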