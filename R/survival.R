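# Endpoint derivation and survival association: EFS24 status, Kaplan-Meier,
# log-rank, Cox proportional hazards (Efron ties).

#' Derive 24-month event-free status
#'
#' A sample fails the horizon if it has an event at or before `horizon`
#' months; it achieves if it is event-free past the horizon (regardless of
#' later events); it is unevaluable if censored before the horizon.
#'
#' @param clin Clinical tibble with `sample_id`, `efs_time`, `efs_event`.
#' @param horizon Months (default 24).
#' @return A tibble of class `efs24_status`: `sample_id`, `efs24` (factor
#'   fail / achieve / unevaluable).
#' @export
derive_efs24 <- function(clin, horizon = 24) {
  if (horizon <= 0) abort("horizon must be positive")
  status <- dplyr::case_when(
    clin$efs_event & clin$efs_time <= horizon ~ "fail",
    clin$efs_time >= horizon ~ "achieve",
    TRUE ~ "unevaluable")
  out <- tibble::tibble(
    sample_id = clin$sample_id,
    efs24 = factor(status, levels = c("fail", "achieve", "unevaluable")))
  class(out) <- c("efs24_status", class(out))
  attr(out, "horizon") <- horizon
  attr(out, "counts") <- table(out$efs24)
  out
}

#' Kaplan-Meier estimates with optional group comparison
#'
#' Product-limit survival estimates per group; the median is the first time
#' the curve reaches 0.5 or below (undefined when it never does). With two
#' or more groups a log-rank test is attached. An optional truncation
#' horizon limits the reported curves (display only; the test uses the full
#' follow-up).
#'
#' @param times Event/censoring times (months).
#' @param events Logical or 0/1 event indicators.
#' @param groups Optional group labels.
#' @param truncate Optional horizon at which to truncate the reported
#'   curves.
#' @return A list of class `km_result`: `curves` (tibble time, n_risk,
#'   n_event, surv, group), `medians` (tibble group, median), `logrank`
#'   (list chisq, df, p or `NULL`).
#' @export
kaplan_meier <- function(times, events, groups = NULL, truncate = NULL) {
  events <- as.integer(as.logical(events))
  if (is.null(groups)) groups <- rep("all", length(times))
  if (length(times) == 0L || any(table(groups) == 0L) || nlevels(as.factor(groups)) == 0L) {
    abort("every group needs at least one subject")
  }
  groups <- droplevels(as.factor(groups))
  df <- data.frame(t = times, e = events, g = groups)
  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = df)
  sm <- summary(fit, censor = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(groups)[1L], length(sm$time)) else
    sub("^g=", "", as.character(sm$strata))
  curves <- tibble::tibble(group = grp, time = sm$time, n_risk = sm$n.risk,
                           n_event = sm$n.event, surv = sm$surv)
  medians <- tibble::tibble(
    group = unique(curves$group),
    median = vapply(unique(curves$group), function(g) {
      sub <- curves[curves$group == g, ]
      hit <- sub$time[sub$surv <= 0.5]
      if (length(hit) > 0L) min(hit) else NA_real_
    }, numeric(1), USE.NAMES = FALSE))
  if (!is.null(truncate)) curves <- curves[curves$time <= truncate, , drop = FALSE]
  lr <- if (nlevels(groups) >= 2L) logrank_test(times, events, groups) else NULL
  structure(list(curves = curves, medians = medians, logrank = lr),
            class = "km_result")
}

#' Log-rank test across survival groups
#'
#' Standard observed-versus-expected log-rank statistic with
#' `groups - 1` degrees of freedom. When no events occur at all the test is
#' undefined; `p = 1` is returned with a warning.
#'
#' @inheritParams kaplan_meier
#' @return A list: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  events <- as.integer(as.logical(events))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) abort("log-rank test needs at least 2 groups")
  if (sum(events) == 0L) {
    warn("no events observed; log-rank test undefined, returning p = 1")
    return(list(chisq = 0, df = nlevels(groups) - 1L, p = 1))
  }
  df <- data.frame(t = times, e = events, g = groups)
  sd_ <- survival::survdiff(survival::Surv(t, e) ~ g, data = df)
  k <- nlevels(groups) - 1L
  list(chisq = unname(sd_$chisq), df = k,
       p = stats::pchisq(sd_$chisq, df = k, lower.tail = FALSE))
}

#' Cox proportional hazards model
#'
#' Partial-likelihood fit with the Efron tie approximation. Character or
#' factor covariates are expanded with the field-standard references: risk
#' strata with `low` as reference and cell-of-origin with `GCB` as
#' reference; other factors use their first level. Hazard ratios, Wald 95%
#' confidence intervals and p-values are reported per expanded term.
#'
#' @param times Event/censoring times.
#' @param events Logical or 0/1 event indicators.
#' @param covariates Data frame of named covariates (no constant columns;
#'   events must be at least as many as covariate columns).
#' @return A list of class `cox_result`: `tidy` (tibble term, estimate, hr,
#'   ci_low, ci_high, p), `loglik`, `ties`, `n`, `n_event`, and the
#'   underlying `fit`.
#' @export
cox_model <- function(times, events, covariates) {
  events <- as.integer(as.logical(events))
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) == 0L) abort("at least one covariate is required")
  for (nm in colnames(covariates)) {
    v <- covariates[[nm]]
    if (is.character(v)) v <- factor(v)
    if (is.factor(v)) {
      v <- droplevels(v)
      if (all(levels(v) %in% c("low", "intermediate", "high"))) {
        v <- factor(v, levels = intersect(c("low", "intermediate", "high"), levels(v)))
      } else if ("GCB" %in% levels(v)) {
        v <- relevel(v, ref = "GCB")
      }
      if (nlevels(v) < 2L) abort(sprintf("covariate '%s' is constant", nm))
    } else if (length(unique(v[!is.na(v)])) < 2L) {
      abort(sprintf("covariate '%s' is constant", nm))
    }
    covariates[[nm]] <- v
  }
  if (sum(events, na.rm = TRUE) < ncol(covariates)) {
    abort("fewer events than covariates; model not identifiable")
  }
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  rhs <- paste(sprintf("`%s`", colnames(covariates)), collapse = " + ")
  fml <- as.formula(sprintf("survival::Surv(.time, .event) ~ %s", rhs))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep_warn) {
    warn("possible complete separation; refitting with a light ridge penalty")
    fml_r <- as.formula(sprintf(
      "survival::Surv(.time, .event) ~ survival::ridge(%s, theta = 1e-6, scale = FALSE)",
      paste(sprintf("`%s`", colnames(covariates)), collapse = ", ")))
    fit <- survival::coxph(fml_r, data = dat, ties = "efron")
  }
  sm <- summary(fit)
  co <- sm$coefficients
  est <- co[, "coef"]
  se <- co[, if ("se(coef)" %in% colnames(co)) "se(coef)" else "se2"]
  tid <- tibble::tibble(
    term = rownames(co), estimate = unname(est), hr = exp(unname(est)),
    ci_low = exp(unname(est) - qnorm(0.975) * unname(se)),
    ci_high = exp(unname(est) + qnorm(0.975) * unname(se)),
    p = 2 * pnorm(-abs(unname(est) / unname(se))))
  structure(list(tidy = tid, loglik = fit$loglik[length(fit$loglik)],
                 ties = "efron", n = fit$n, n_event = fit$nevent, fit = fit),
            class = "cox_result")
}

#' @export
tidy.cox_result <- function(x, ...) x$tidy

#' @export
glance.cox_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event, loglik = x$loglik, ties = x$ties)
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties), n = %d, events = %d\n",
              x$ties, x$n, x$n_event))
  print(x$tidy)
  invisible(x)
}
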