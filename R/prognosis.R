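# Downstream prognostic statistics: two-group comparisons, ROC analysis
# with Youden cut-offs, Kaplan-Meier + log-rank, and forward-stepwise Cox
# proportional-hazards regression.

#' Compare a variable between the failure and control groups
#'
#' Continuous variables are tested with Student's t-test when both groups
#' pass a Shapiro-Wilk normality screen at alpha = 0.05, otherwise with
#' the Mann-Whitney U test. Binary categorical variables use the
#' chi-square test (without continuity correction); ordered categoricals
#' (e.g. N stage) use the Wilcoxon rank-sum test on the ordinal codes.
#' All tests are two-sided.
#'
#' @param table A `cohort_table` (or data.frame with a `group` column).
#' @param variable Column to compare.
#' @param type `"auto"` (default: inferred from the column class),
#'   `"continuous"`, `"categorical"` or `"ordinal"`.
#' @return An object of class `group_comparison` with the test used, the
#'   statistic, the two-sided p-value and per-group summaries.
#' @export
compare_groups <- function(table, variable,
                           type = c("auto", "continuous", "categorical",
                                    "ordinal")) {
  type <- match.arg(type)
  stopifnot(is.data.frame(table), "group" %in% names(table))
  x <- table[[variable]]
  g <- factor(table$group)
  if (nlevels(droplevels(g)) != 2L)
    stop_ivim("both groups must be non-empty", "ivimprog_input_error")
  lv <- levels(droplevels(g))
  if (type == "auto") {
    type <- if (is.numeric(x)) "continuous"
    else if (is.ordered(x)) "ordinal"
    else "categorical"
  }
  x1 <- x[g == lv[1L]]
  x2 <- x[g == lv[2L]]

  if (type == "continuous") {
    summ <- lapply(list(x1, x2), function(v)
      c(mean = mean(v), sd = sd(v), n = length(v)))
    names(summ) <- lv
    if (sd(x1) == 0 && sd(x2) == 0) {
      equal <- isTRUE(all.equal(mean(x1), mean(x2)))
      res <- list(test = "equality", statistic = as.numeric(equal),
                  p_value = if (equal) 1 else 0)
    } else {
      normal <- vapply(list(x1, x2), function(v) {
        if (length(v) < 3L || sd(v) == 0) return(FALSE)
        shapiro.test(v)$p.value > 0.05
      }, logical(1))
      if (all(normal)) {
        tt <- t.test(x1, x2, var.equal = TRUE)
        res <- list(test = "t", statistic = unname(tt$statistic),
                    p_value = tt$p.value)
      } else {
        wt <- suppressWarnings(wilcox.test(x1, x2, exact = FALSE))
        res <- list(test = "mann-whitney", statistic = unname(wt$statistic),
                    p_value = wt$p.value)
      }
    }
  } else if (type == "ordinal") {
    wt <- suppressWarnings(wilcox.test(as.numeric(x1), as.numeric(x2),
                                       exact = FALSE))
    res <- list(test = "rank-sum", statistic = unname(wt$statistic),
                p_value = wt$p.value)
    summ <- base::table(g, x)
  } else {
    ct <- suppressWarnings(chisq.test(base::table(g, x), correct = FALSE))
    res <- list(test = "chi-square", statistic = unname(ct$statistic),
                p_value = ct$p.value)
    summ <- base::table(g, x)
  }
  structure(list(variable = variable, test = res$test,
                 statistic = res$statistic, p_value = res$p_value,
                 groups = summ),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s test, statistic = %.4g, p = %.4g\n",
              x$variable, x$test, x$statistic, x$p_value))
  invisible(x)
}

#' ROC analysis with Youden-optimal cut-off
#'
#' Builds the empirical ROC curve of a continuous marker against a binary
#' outcome, with treatment failure as the positive class. The AUC is
#' computed through the Mann-Whitney U identity (pairwise concordance
#' with ties counted 1/2) and oriented so AUC >= 0.5; the recorded
#' `orientation` says whether higher-risk patients lie above or below the
#' cut-off. The cut-off maximizes Youden's J = sensitivity + specificity
#' - 1 over the observed values, the cut-off value itself being assigned
#' to the positive (higher-risk) side; ties in J are resolved toward
#' higher sensitivity, then the smaller cut-off.
#'
#' @param values Numeric marker values, one per patient.
#' @param labels Group labels; `positive` marks the positive class.
#' @param positive Label of the positive (higher-risk) class; default
#'   `"failure"`.
#' @return An object of class `roc_result` with `auc`, `auc_p_value`
#'   (two-sided Mann-Whitney test of AUC = 0.5), `cutoff`, `sensitivity`
#'   and `specificity` in percent, `orientation`, and the full
#'   threshold table in `thresholds`.
#' @export
roc_analysis <- function(values, labels, positive = "failure") {
  stopifnot(length(values) == length(labels), is.numeric(values))
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop_ivim("both classes must be present", "ivimprog_input_error")
  r <- rank(values)
  auc_above <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  orientation <- if (auc_above >= 0.5) "above" else "below"
  auc <- max(auc_above, 1 - auc_above)
  p <- suppressWarnings(
    wilcox.test(values[pos], values[!pos], exact = FALSE)$p.value)
  thr <- sort(unique(values))
  rows <- lapply(thr, function(t) {
    call_pos <- if (orientation == "above") values >= t else values <= t
    sens <- 100 * sum(call_pos & pos) / n1
    spec <- 100 * sum(!call_pos & !pos) / n0
    c(cutoff = t, sensitivity = sens, specificity = spec,
      youden = sens + spec - 100)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  ord <- order(-tab$youden, -tab$sensitivity, tab$cutoff)
  best <- tab[ord[1L], ]
  structure(list(auc = auc, auc_p_value = p, cutoff = best$cutoff,
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 orientation = orientation, thresholds = tab,
                 n_positive = n1, n_negative = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f (p = %.4g), cut-off = %g (risk %s), sens %.1f%%, spec %.1f%%\n",
    x$auc, x$auc_p_value, x$cutoff, x$orientation, x$sensitivity,
    x$specificity))
  invisible(x)
}

#' Kaplan-Meier product-limit estimate for one sample
#'
#' Thin wrapper returning the survival step function of a single group.
#'
#' @param time Follow-up times.
#' @param event Logical event indicators (FALSE = censored).
#' @return A data.frame with columns `time`, `n_risk`, `n_event`,
#'   `surv`.
#' @export
km_estimate <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             surv = sf$surv)
}

#' Kaplan-Meier curves and log-rank test for a dichotomized marker
#'
#' Splits the cohort at `cutoff` into "< cutoff" and ">= cutoff" strata,
#' estimates the product-limit survival curve per stratum and compares
#' them with the two-sided log-rank test. When `cutoff` is `NULL` the
#' variable is used as a grouping factor directly (e.g. N stage classes).
#' The median survival is undefined (NA) when a curve never drops below
#' 0.5.
#'
#' @param table A `cohort_table` (needs `pfs_months` and `event`).
#' @param variable Marker column.
#' @param cutoff Dichotomization threshold, or `NULL` for a categorical
#'   variable.
#' @param time,event Names of the time and event columns.
#' @return An object of class `km_result`: per-group `n`, `events`,
#'   `incidence` (percent), `median_survival` (months), the log-rank
#'   `chisq` and `p_value`, and the fitted `survfit` object.
#' @export
km_logrank <- function(table, variable, cutoff = NULL,
                       time = "pfs_months", event = "event") {
  stopifnot(is.data.frame(table),
            all(c(variable, time, event) %in% names(table)))
  x <- table[[variable]]
  if (is.null(cutoff)) {
    grp <- droplevels(factor(x))
  } else {
    grp <- factor(ifelse(x < cutoff, sprintf("<%g", cutoff),
                         sprintf(">=%g", cutoff)),
                  levels = c(sprintf("<%g", cutoff), sprintf(">=%g", cutoff)))
  }
  if (any(tabulate(grp, nlevels(grp)) == 0L) || nlevels(grp) < 2L)
    stop_ivim("each stratum must be non-empty", "ivimprog_input_error")
  srv <- survival::Surv(table[[time]], table[[event]])
  sf <- survival::survfit(srv ~ grp)
  # with zero events the log-rank statistic is undefined (0/0); report NaN
  # quietly rather than propagating arithmetic warnings
  sd <- suppressWarnings(survival::survdiff(srv ~ grp))
  p <- suppressWarnings(pchisq(sd$chisq, df = nlevels(grp) - 1L,
                               lower.tail = FALSE))
  st <- summary(sf)$table
  if (is.null(dim(st))) st <- matrix(st, nrow = 1, dimnames = list(
    levels(grp), names(st)))
  n <- st[, "records"]
  ev <- st[, "events"]
  structure(list(variable = variable, cutoff = cutoff,
                 groups = levels(grp), n = unname(n), events = unname(ev),
                 incidence = unname(100 * ev / n),
                 median_survival = unname(st[, "median"]),
                 chisq = sd$chisq, p_value = p, fit = sf),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("Kaplan-Meier for %s%s: log-rank chisq = %.3f, p = %.4g\n",
              x$variable,
              if (!is.null(x$cutoff)) sprintf(" at cut-off %g", x$cutoff)
              else "", x$chisq, x$p_value))
  print(data.frame(group = x$groups, n = x$n, events = x$events,
                   incidence = round(x$incidence, 1),
                   median = x$median_survival), row.names = FALSE)
  invisible(x)
}

#' Forward-stepwise Cox proportional-hazards regression
#'
#' Candidate covariates are first screened by a univariate test at
#' `pool_alpha` (default 0.1): either the log-rank test of the marker
#' dichotomized at its ROC cut-off (default, mirroring a
#' Kaplan-Meier-then-Cox workflow) or a univariate Cox Wald test
#' (`screen = "cox"`). Pooled candidates then enter a forward selection:
#' at each step the candidate with the smallest Wald p in the augmented
#' model is added if below `entry_alpha`, otherwise selection stops. The
#' final model is refitted with all selected covariates using Efron tie
#' handling; continuous covariates enter on their reported scale, so
#' hazard ratios are per printed unit.
#'
#' @param table A `cohort_table`.
#' @param candidates Covariate names to consider.
#' @param entry_alpha Forward-entry threshold (default 0.05).
#' @param pool_alpha Screening threshold (default 0.1).
#' @param screen `"logrank"` (default) or `"cox"`.
#' @param cutoffs Optional named vector of dichotomization cut-offs for
#'   the log-rank screen; missing entries fall back to the ROC cut-off
#'   against the group label.
#' @param time,event Names of the outcome columns.
#' @return An object of class `cox_result`: a `coefficients` data.frame
#'   (variable, hr, ci_lower, ci_upper, p_value), the screening
#'   `pool`, the selection `trace` and the fitted `model`.
#' @export
cox_forward <- function(table, candidates, entry_alpha = 0.05,
                        pool_alpha = 0.1, screen = c("logrank", "cox"),
                        cutoffs = NULL, time = "pfs_months",
                        event = "event") {
  screen <- match.arg(screen)
  stopifnot(is.data.frame(table), all(candidates %in% names(table)))
  if (sum(table[[event]]) < 1L)
    stop_ivim("at least one event is required", "ivimprog_input_error")
  srv <- survival::Surv(table[[time]], table[[event]])

  screen_p <- vapply(candidates, function(v) {
    if (screen == "logrank") {
      cut <- if (!is.null(cutoffs) && v %in% names(cutoffs)) cutoffs[[v]]
      else roc_analysis(table[[v]], table$group)$cutoff
      res <- tryCatch(km_logrank(table, v, cut, time = time, event = event),
                      ivimprog_error = function(e) NULL)
      if (is.null(res)) NA_real_ else res$p_value
    } else {
      fit <- survival::coxph(srv ~ x, data = data.frame(x = table[[v]]),
                             ties = "efron")
      summary(fit)$coefficients[1L, "Pr(>|z|)"]
    }
  }, numeric(1))
  pool <- candidates[!is.na(screen_p) & screen_p < pool_alpha]

  selected <- character(0)
  trace <- data.frame(step = integer(0), variable = character(0),
                      p_entry = numeric(0), stringsAsFactors = FALSE)
  remaining <- pool
  step <- 0L
  while (length(remaining)) {
    ps <- vapply(remaining, function(v) {
      dat <- table[, c(selected, v), drop = FALSE]
      names(dat) <- c(selected, v)
      fit <- tryCatch(
        survival::coxph(srv ~ ., data = dat, ties = "efron"),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      summary(fit)$coefficients[v, "Pr(>|z|)"]
    }, numeric(1))
    if (all(is.na(ps))) break
    best <- names(ps)[which.min(ps)]
    if (ps[[best]] < entry_alpha) {
      step <- step + 1L
      selected <- c(selected, best)
      remaining <- setdiff(remaining, best)
      trace <- rbind(trace, data.frame(step = step, variable = best,
                                       p_entry = ps[[best]]))
    } else break
  }

  if (length(selected)) {
    dat <- table[, selected, drop = FALSE]
    final <- survival::coxph(srv ~ ., data = dat, ties = "efron")
    sm <- summary(final)
    coefs <- data.frame(
      variable = selected,
      hr = unname(sm$conf.int[, "exp(coef)"]),
      ci_lower = unname(sm$conf.int[, "lower .95"]),
      ci_upper = unname(sm$conf.int[, "upper .95"]),
      p_value = unname(sm$coefficients[, "Pr(>|z|)"]),
      stringsAsFactors = FALSE)
  } else {
    final <- NULL
    coefs <- data.frame(variable = character(0), hr = numeric(0),
                        ci_lower = numeric(0), ci_upper = numeric(0),
                        p_value = numeric(0))
  }
  structure(list(coefficients = coefs, selected = selected,
                 pool = data.frame(variable = candidates,
                                   screen_p = unname(screen_p)),
                 trace = trace, model = final, screen = screen,
                 entry_alpha = entry_alpha, pool_alpha = pool_alpha),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Forward Cox regression (screen:", x$screen, ")\n")
  if (nrow(x$coefficients)) {
    out <- x$coefficients
    out$hr <- round(out$hr, 3)
    out$ci <- sprintf("(%.3f-%.3f)", out$ci_lower, out$ci_upper)
    print(out[, c("variable", "hr", "ci", "p_value")], row.names = FALSE)
  } else cat("  no covariates selected\n")
  invisible(x)
}

#' Run the full prognostic pipeline on a cohort table
#'
#' For each IVIM parameter: group comparison, ROC analysis, Kaplan-Meier
#' log-rank at the ROC cut-off; then forward Cox regression over the
#' parameters whose log-rank p is below `pool_alpha`. Also compares
#' N stage by rank-sum and log-rank (N0 vs N1-3).
#'
#' @param table A `cohort_table`.
#' @param entry_alpha,pool_alpha Selection thresholds, see
#'   [cox_forward()].
#' @return A list with data.frames `comparison`, `roc`, `km` and the
#'   `cox` result.
#' @export
prognosis_tables <- function(table, entry_alpha = 0.05, pool_alpha = 0.1) {
  params <- intersect(cohort_param_names(), names(table))
  comparison <- do.call(rbind, lapply(params, function(v) {
    gc <- compare_groups(table, v)
    mf <- gc$groups[["failure"]]
    mc <- gc$groups[["control"]]
    data.frame(parameter = v, test = gc$test,
               mean_failure = mf[["mean"]], sd_failure = mf[["sd"]],
               mean_control = mc[["mean"]], sd_control = mc[["sd"]],
               p_value = gc$p_value, stringsAsFactors = FALSE)
  }))
  rocs <- lapply(params, function(v) roc_analysis(table[[v]], table$group))
  names(rocs) <- params
  roc_tab <- do.call(rbind, lapply(params, function(v) {
    r <- rocs[[v]]
    data.frame(parameter = v, auc = r$auc, p_value = r$auc_p_value,
               cutoff = r$cutoff, sensitivity = r$sensitivity,
               specificity = r$specificity, orientation = r$orientation,
               stringsAsFactors = FALSE)
  }))
  kms <- lapply(params, function(v)
    tryCatch(km_logrank(table, v, rocs[[v]]$cutoff),
             ivimprog_error = function(e) NULL))
  names(kms) <- params
  km_tab <- do.call(rbind, lapply(params, function(v) {
    k <- kms[[v]]
    if (is.null(k))
      return(data.frame(parameter = v, cutoff = rocs[[v]]$cutoff,
                        group = NA_character_, n = NA, events = NA,
                        incidence = NA, median_survival = NA,
                        logrank_p = NA, stringsAsFactors = FALSE))
    data.frame(parameter = v, cutoff = k$cutoff,
               group = k$groups, n = k$n, events = k$events,
               incidence = k$incidence, median_survival = k$median_survival,
               logrank_p = k$p_value, stringsAsFactors = FALSE)
  }))
  cutoffs <- vapply(rocs, `[[`, numeric(1), "cutoff")
  cox <- tryCatch(
    cox_forward(table, params, entry_alpha = entry_alpha,
                pool_alpha = pool_alpha, screen = "logrank",
                cutoffs = cutoffs),
    ivimprog_error = function(e) e)
  if ("n_stage" %in% names(table)) {
    comparison <- rbind(
      data.frame(parameter = "n_stage",
                 test = compare_groups(table, "n_stage")$test,
                 mean_failure = NA, sd_failure = NA, mean_control = NA,
                 sd_control = NA,
                 p_value = compare_groups(table, "n_stage")$p_value),
      comparison)
  }
  list(comparison = comparison, roc = roc_tab, km = km_tab, cox = cox)
}
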