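# Kaplan-Meier / log-rank / Cox wrappers ---------------------------------

.check_surv <- function(time, event) {
  if (length(time) != length(event)) {
    stop("time and event must have equal length", call. = FALSE)
  }
  if (anyNA(time) || any(time < 0)) {
    stop("survival times must be non-negative and non-missing",
         call. = FALSE)
  }
  ev <- as.integer(as.logical(event))
  if (anyNA(ev)) stop("event indicators must be 0/1", call. = FALSE)
  ev
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square comparing the
#' survival experience of two groups, with the hypergeometric variance
#' and simultaneous risk-set evaluation at tied event times (via
#' [survival::survdiff()]). Symmetric in the group labels and
#' deterministic for fixed input.
#'
#' @param time Follow-up times (months).
#' @param event Event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param group Two-level grouping vector; both groups must be non-empty.
#' @return Object of class `logrank_test`: `statistic` (chi-square),
#'   `p.value`, `observed`/`expected` event counts per group, `n`.
#' @examples
#' logrank_test(c(1, 2, 3, 4, 5, 6), rep(1, 6), rep(c("A", "B"), each = 3))
#' @export
logrank_test <- function(time, event, group) {
  event <- .check_surv(time, event)
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must have exactly two levels",
                            call. = FALSE)
  if (any(tabulate(g, 2) == 0)) {
    stop("both groups must contain observations", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  structure(list(statistic = unname(sd$chisq),
                 p.value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 observed = sd$obs, expected = sd$exp,
                 n = length(time), groups = levels(g)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank chi-square = %.4f (1 df), P = %.4g, n = %d\n",
              x$statistic, x$p.value, x$n))
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function: at each observed
#' event time the curve steps down by the fraction of the risk set that
#' fails; censored subjects leave the risk set without a step.
#'
#' @inheritParams logrank_test
#' @return Object of class `km_curve`: data frame `steps` with columns
#'   `time`, `n.risk`, `n.event`, `n.censor`, `surv`, plus `n` and the
#'   underlying [survival::survfit] object (`fit`).
#' @examples
#' km_estimate(c(3, 5, 7, 9, 11), c(1, 0, 1, 1, 0))
#' @export
km_estimate <- function(time, event) {
  event <- .check_surv(time, event)
  if (length(time) < 1) stop("empty input", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  steps <- data.frame(time = fit$time, n.risk = fit$n.risk,
                      n.event = fit$n.event, n.censor = fit$n.censor,
                      surv = fit$surv)
  structure(list(steps = steps, n = length(time), fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve, n = %d (%d events)\n", x$n,
              sum(x$steps$n.event)))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Months", ylab = "Survival", ...) {
  plot(x$fit, xlab = xlab, ylab = ylab, mark.time = TRUE, ...)
  invisible(x)
}

#' Cox proportional hazards for a binary covariate
#'
#' Maximum partial likelihood fit of a single two-level covariate with
#' Breslow handling of tied event times (via [survival::coxph()], Newton
#' iterations to gradient tolerance 1e-9). Reports the hazard ratio with
#' its Wald standard error and confidence interval, together with the
#' log-rank p of the corresponding two-group comparison. When either
#' group has no events the partial likelihood is monotone and the
#' coefficient diverges; the fit is then flagged non-estimable and the
#' reported coefficient is capped. Wald intervals are additionally
#' flagged unstable when either group has fewer than 5 events.
#'
#' @inheritParams logrank_test
#' @param level Confidence level for the Wald interval.
#' @param cap Absolute bound on the log-hazard coefficient when the
#'   likelihood is monotone.
#' @return Object of class `cox_binary`: `coef`, `hr`, `se`, `ci`
#'   (Wald), `wald_p`, `logrank_p`, `events` (per group), `estimable`,
#'   `small_events` flags.
#' @examples
#' set.seed(1)
#' g <- rep(0:1, each = 30)
#' t <- rexp(60, rate = ifelse(g == 1, 0.02, 0.1))
#' cox_binary(pmin(t, 60), t < 60, g)
#' @export
cox_binary <- function(time, event, group, level = 0.95, cap = 10) {
  event <- .check_surv(time, event)
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must have exactly two levels",
                            call. = FALSE)
  events <- tapply(event, g, sum)
  estimable <- all(events > 0)
  lr <- logrank_test(time, event, g)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ g, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)))
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!estimable) {
    beta <- sign(beta) * min(abs(beta), cap)
    se <- NA_real_
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- exp(beta + c(-1, 1) * z * se)
  structure(
    list(coef = beta, hr = exp(beta), se = se,
         ci = c(lower = ci[1], upper = ci[2]),
         wald_p = if (estimable) 2 * pnorm(-abs(beta / se)) else NA_real_,
         logrank_p = lr$p.value,
         logrank_statistic = lr$statistic,
         events = events,
         estimable = estimable,
         small_events = any(events < 5),
         level = level, n = length(time), groups = levels(g)),
    class = "cox_binary")
}

#' @export
print.cox_binary <- function(x, ...) {
  cat(sprintf("Cox HR = %.3f (%s vs %s reference)", x$hr, x$groups[2],
              x$groups[1]))
  if (x$estimable) {
    cat(sprintf("; %d%% CI %.3f-%.3f; Wald P = %.3g", round(100 * x$level),
                x$ci[["lower"]], x$ci[["upper"]], x$wald_p))
  } else {
    cat(" [non-estimable: a group has zero events; coefficient capped]")
  }
  cat(sprintf("\n  log-rank P = %.4g; events: %s = %d, %s = %d\n",
              x$logrank_p, x$groups[1], x$events[1], x$groups[2],
              x$events[2]))
  if (x$small_events && x$estimable) {
    cat("  note: < 5 events in a group; Wald CI may be unstable\n")
  }
  invisible(x)
}

#' Group mean survival summaries
#'
#' Mean follow-up per group with the between-group difference, reported
#' under two estimators because study reports rarely state which is
#' meant: `arithmetic` is the plain mean of the recorded follow-up times
#' (events and censorings pooled); `rmst` is the restricted mean survival
#' time, the area under the Kaplan--Meier curve up to a horizon (default
#' 60 months). With no censoring and a horizon past the last time the
#' two coincide.
#'
#' @inheritParams logrank_test
#' @param horizon Restriction time in months for the RMST.
#' @return Object of class `surv_means`: data frame `means` with one row
#'   per (group, method) and the per-method differences `delta`
#'   (group 1 minus group 2 in factor-level order).
#' @export
mean_survival <- function(time, event, group, horizon = 60) {
  event <- .check_surv(time, event)
  g <- factor(group)
  if (any(tabulate(g, nlevels(g)) == 0)) {
    stop("every group needs at least one subject", call. = FALSE)
  }
  rmst1 <- function(tt, ee) {
    km <- km_estimate(tt, ee)$steps
    km <- km[km$time <= horizon & km$n.event > 0, , drop = FALSE]
    ts <- c(0, km$time, horizon)
    ss <- c(1, km$surv)
    sum(diff(ts) * ss)
  }
  rows <- lapply(levels(g), function(lv) {
    tt <- time[g == lv]; ee <- event[g == lv]
    data.frame(group = lv, n = length(tt),
               method = c("arithmetic", "RMST"),
               mean = c(mean(tt), rmst1(tt, ee)))
  })
  means <- do.call(rbind, rows)
  delta <- sapply(c("arithmetic", "RMST"), function(m) {
    v <- means$mean[means$method == m]
    v[1] - v[2]
  })
  structure(list(means = means, delta = delta, horizon = horizon,
                 groups = levels(g)),
            class = "surv_means")
}

#' @export
print.surv_means <- function(x, ...) {
  for (m in c("arithmetic", "RMST")) {
    v <- x$means[x$means$method == m, ]
    cat(sprintf("mean (%s%s): %s\n", m,
                if (m == "RMST") sprintf(", horizon %g mo", x$horizon)
                else "",
                paste(sprintf("%s = %.1f", v$group, v$mean),
                      collapse = " vs ")))
  }
  cat(sprintf("delta (%s - %s): arithmetic %+.1f, RMST %+.1f\n",
              x$groups[1], x$groups[2], x$delta[["arithmetic"]],
              x$delta[["RMST"]]))
  invisible(x)
}
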