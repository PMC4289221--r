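#' Survival group container
#'
#' @param label group label.
#' @param times positive follow-up times in years.
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @return An object of class `survival_group`.
#' @export
survival_group <- function(label, times, events) {
  if (length(times) != length(events)) stop("times and events must match")
  if (length(times) < 1) stop("need at least 1 subject")
  if (any(!is.finite(times)) || any(times <= 0)) stop("times must be positive")
  events <- as.integer(events)
  if (!all(events %in% c(0L, 1L))) stop("events must be 0 or 1")
  structure(list(label = as.character(label), times = as.numeric(times),
                 events = events), class = "survival_group")
}

# administrative truncation at the horizon: events after the horizon are
# censored at the horizon
truncate_horizon <- function(g, horizon) {
  if (is.null(horizon)) return(g)
  past <- g$times > horizon
  g$events[past] <- 0L
  g$times[past] <- horizon
  g
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator over the distinct event times, with optional
#' administrative truncation at a horizon (events beyond the horizon are
#' censored there; the convention for 10-year endpoints).
#'
#' @param g a [survival_group()].
#' @param horizon truncation horizon in years, or `NULL` for none.
#' @return An object of class `km_curve`: data.frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, plus attributes `label` and
#'   `horizon`.
#' @export
km_estimate <- function(g, horizon = NULL) {
  stopifnot(inherits(g, "survival_group"))
  g <- truncate_horizon(g, horizon)
  fit <- survival::survfit(survival::Surv(g$times, g$events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  attr(out, "label") <- g$label
  attr(out, "horizon") <- horizon
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability at a time point
#'
#' Step-function evaluation of a Kaplan-Meier curve: `S(t)` with `S(0) = 1`.
#'
#' @param curve a `km_curve`.
#' @param t time (years).
#' @return Survival probability at `t`.
#' @export
km_surv_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  s <- c(1, curve$surv)
  idx <- findInterval(t, curve$time) + 1
  s[idx]
}

#' Multi-group log-rank test
#'
#' Standard (unweighted) log-rank chi-square test across two or more groups,
#' with `df = n_groups - 1` and a two-sided p-value from the chi-square
#' distribution. Tied event times share the aggregate risk set.
#'
#' @param groups list of [survival_group()] objects (>= 2), with at least one
#'   event overall.
#' @param horizon optional truncation horizon (years).
#' @return List of class `logrank_test`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected` (named per group).
#' @export
logrank_test <- function(groups, horizon = NULL) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  groups <- lapply(groups, truncate_horizon, horizon = horizon)
  time <- unlist(lapply(groups, `[[`, "times"))
  event <- unlist(lapply(groups, `[[`, "events"))
  if (sum(event) == 0) stop("log-rank statistic undefined with zero events")
  lab <- unlist(mapply(function(g, i) rep(if (nzchar(g$label)) g$label else paste0("group", i),
                                          length(g$times)),
                       groups, seq_along(groups), SIMPLIFY = FALSE))
  lab <- factor(lab, levels = unique(lab))
  sd <- survival::survdiff(survival::Surv(time, event) ~ lab)
  df <- length(groups) - 1
  structure(list(statistic = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 observed = stats::setNames(sd$obs, levels(lab)),
                 expected = stats::setNames(sd$exp, levels(lab))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(data.frame(group = names(x$observed), observed = x$observed,
                   expected = round(x$expected, 3)), row.names = FALSE)
  invisible(x)
}

#' O/E hazard ratio between two groups
#'
#' Mantel-Haenszel/Peto estimate from the log-rank observed/expected
#' decomposition: `HR = (O_a / E_a) / (O_b / E_b)`, with a log-scale
#' confidence interval using variance `1/E_a + 1/E_b`.
#'
#' @param a,b [survival_group()] objects, each with at least one event.
#' @param horizon optional truncation horizon (years).
#' @param conf_level confidence level (default 0.95).
#' @return List of class `hazard_ratio`: `hr`, `ci_lower`, `ci_upper`,
#'   `p_value` (log-rank), `observed`, `expected`.
#' @export
hazard_ratio <- function(a, b, horizon = NULL, conf_level = 0.95) {
  stopifnot(inherits(a, "survival_group"), inherits(b, "survival_group"))
  lr <- logrank_test(list(a, b), horizon = horizon)
  O <- lr$observed; E <- lr$expected
  if (any(E <= 0)) stop("a group has zero expected events; HR undefined")
  if (any(O == 0)) stop("both groups need at least one observed event")
  hr <- (O[1] / E[1]) / (O[2] / E[2])
  se <- sqrt(1 / E[1] + 1 / E[2])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(hr = unname(hr),
                 ci_lower = unname(hr * exp(-z * se)),
                 ci_upper = unname(hr * exp(z * se)),
                 p_value = lr$p_value,
                 observed = O, expected = E),
            class = "hazard_ratio")
}

#' @export
print.hazard_ratio <- function(x, ...) {
  cat(sprintf("O/E hazard ratio: %.3f (95%% CI %.3f-%.3f), log-rank p = %.4g\n",
              x$hr, x$ci_lower, x$ci_upper, x$p_value))
  invisible(x)
}

#' Landmark comparison of early and late follow-up
#'
#' Splits follow-up at the landmark (default 5 years). The early period
#' censors everyone still event-free at the landmark; the late period
#' conditions on being at risk at the landmark (event-free with follow-up
#' beyond it) and resets the clock to zero. Reports event counts per period
#' and, when two strata (e.g. treated vs untreated) are supplied, a
#' per-period O/E hazard ratio and log-rank p-value.
#'
#' @param times,events follow-up (years) and 0/1 event indicators.
#' @param strata optional two-level factor (e.g. treatment) for per-period
#'   comparisons.
#' @param landmark landmark time in years (default 5).
#' @param horizon optional overall truncation horizon (default 10).
#' @return List of class `landmark_comparison`: `landmark`, per-period event
#'   counts and at-risk counts, `majority_late` (logical: most events after
#'   the landmark), and with strata the per-period `hr`/`p_value`
#'   (`NA`, flagged, when a period is undefined).
#' @export
landmark_compare <- function(times, events, strata = NULL, landmark = 5,
                             horizon = 10) {
  if (landmark <= 0) stop("landmark must be positive")
  if (!is.null(horizon) && horizon <= landmark)
    stop("horizon must exceed the landmark")
  events <- as.integer(events)
  if (!is.null(horizon)) {
    events[times > horizon] <- 0L
    times <- pmin(times, horizon)
  }

  early_event <- events == 1L & times <= landmark
  at_risk_late <- times > landmark
  late_event <- events == 1L & times > landmark

  out <- list(landmark = landmark, horizon = horizon,
              n = length(times),
              events_early = sum(early_event),
              events_late = sum(late_event),
              n_at_risk_late = sum(at_risk_late),
              majority_late = sum(late_event) > sum(early_event))

  if (!is.null(strata)) {
    strata <- factor(strata)
    if (nlevels(strata) != 2)
      stop("strata must have exactly 2 levels for per-period comparison")
    lv <- levels(strata)
    mk_group <- function(keep, tt, ee, lvl)
      survival_group(lvl, tt[keep & strata == lvl], ee[keep & strata == lvl])
    # early period: censor at the landmark
    t_early <- pmin(times, landmark)
    e_early <- ifelse(times <= landmark, events, 0L)
    # late period: clock reset at the landmark
    t_late <- times[at_risk_late] - landmark
    e_late <- events[at_risk_late]
    s_late <- strata[at_risk_late]

    out$early <- tryCatch({
      hr <- hazard_ratio(survival_group(lv[1], t_early[strata == lv[1]], e_early[strata == lv[1]]),
                         survival_group(lv[2], t_early[strata == lv[2]], e_early[strata == lv[2]]))
      list(hr = hr$hr, p_value = hr$p_value, defined = TRUE)
    }, error = function(e) list(hr = NA_real_, p_value = NA_real_,
                                defined = FALSE, reason = conditionMessage(e)))
    out$late <- if (sum(at_risk_late) == 0 || length(unique(s_late)) < 2) {
      list(hr = NA_real_, p_value = NA_real_, defined = FALSE,
           reason = "no comparable subjects at risk after the landmark")
    } else tryCatch({
      hr <- hazard_ratio(survival_group(lv[1], t_late[s_late == lv[1]], e_late[s_late == lv[1]]),
                         survival_group(lv[2], t_late[s_late == lv[2]], e_late[s_late == lv[2]]))
      list(hr = hr$hr, p_value = hr$p_value, defined = TRUE)
    }, error = function(e) list(hr = NA_real_, p_value = NA_real_,
                                defined = FALSE, reason = conditionMessage(e)))
  }
  class(out) <- "landmark_comparison"
  out
}

#' @export
print.landmark_comparison <- function(x, ...) {
  cat(sprintf("landmark at %g years (horizon %s): %d early events, %d late events (%d at risk late)\n",
              x$landmark, ifelse(is.null(x$horizon), "none", x$horizon),
              x$events_early, x$events_late, x$n_at_risk_late))
  if (!is.null(x$early))
    cat(sprintf("  early HR = %.3f (p = %.3g); late HR = %.3f (p = %.3g)\n",
                x$early$hr, x$early$p_value, x$late$hr, x$late$p_value))
  invisible(x)
}

#' Per-subgroup survival summary
#'
#' Kaplan-Meier estimates per subgroup plus the omnibus log-rank test, the
#' standard readout for comparing subgroup outcomes at a fixed horizon.
#'
#' @param clinical data.frame in the [load_clinical_table()] layout.
#' @param labels named subgroup label per sample (names = sample IDs).
#' @param horizon truncation horizon in years (default 10).
#' @return List of class `subgroup_survival`: `per_group` (data.frame with
#'   subgroup, n, events, survival at the horizon), `logrank`
#'   (a `logrank_test`), `horizon`.
#' @export
subgroup_survival <- function(clinical, labels, horizon = 10) {
  idx <- match(clinical$sample_id, names(labels))
  if (all(is.na(idx))) stop("no overlap between clinical samples and labels")
  keep <- !is.na(idx)
  cl <- clinical[keep, , drop = FALSE]
  lab <- labels[idx[keep]]

  # KM requires positive times
  pos <- cl$time_years > 0
  cl <- cl[pos, , drop = FALSE]; lab <- lab[pos]

  groups <- lapply(sort(unique(lab)), function(g)
    survival_group(as.character(g), cl$time_years[lab == g], cl$event[lab == g]))
  per_group <- do.call(rbind, lapply(groups, function(g) {
    gt <- truncate_horizon(g, horizon)
    curve <- km_estimate(gt)
    data.frame(subgroup = g$label, n = length(gt$times),
               events = sum(gt$events),
               surv_at_horizon = km_surv_at(curve, horizon),
               stringsAsFactors = FALSE)
  }))
  lr <- tryCatch(logrank_test(groups, horizon = horizon), error = function(e) NULL)
  structure(list(per_group = per_group, logrank = lr, horizon = horizon),
            class = "subgroup_survival")
}

#' @export
print.subgroup_survival <- function(x, ...) {
  cat(sprintf("subgroup survival (horizon %g years)\n", x$horizon))
  print(x$per_group, row.names = FALSE)
  if (!is.null(x$logrank)) print(x$logrank)
  invisible(x)
}
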