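# Simulated two-group patient cohorts: IVIM parameter draws from truncated
# normal distributions (moment-matched to the target group means), N stage
# frequencies, and progression-free survival with administrative censoring.
#
# All parameters are on reporting units: diffusivities in 10^-3 mm^2/s,
# perfusion fraction in percent, alpha dimensionless, PFS in months.

#' Default per-group parameter distribution table
#'
#' Group-wise means and SDs of the nine IVIM measures for the treatment
#' failure and local control groups, with the truncation bounds used by
#' the generator (diffusivities > 0, f in (1, 99) percent, alpha in
#' (0.1, 1]).
#'
#' @return A data.frame with columns `parameter`, `mean_failure`,
#'   `sd_failure`, `mean_control`, `sd_control`, `lower`, `upper`.
#' @export
default_cohort_params <- function() {
  data.frame(
    parameter    = c("ADCmean", "ADCmax", "ADCmin", "ADCrange", "D",
                     "Dstar", "f", "DDC", "alpha"),
    mean_failure = c(1.00, 1.51, 0.60, 1.28, 0.92, 88.86, 28, 0.24, 0.59),
    sd_failure   = c(0.33, 0.54, 0.33, 0.46, 0.45, 66.48, 17, 3.97, 0.16),
    mean_control = c(1.31, 1.91, 0.81, 1.31, 1.17, 33.27, 45, 0.42, 0.89),
    sd_control   = c(0.26, 0.33, 0.25, 0.43, 0.32, 52.10, 20, 2.18, 0.74),
    lower        = c(0, 0, 0, 0, 0, 0, 1, 0, 0.1),
    upper        = c(Inf, Inf, Inf, Inf, Inf, Inf, 99, Inf, 1),
    stringsAsFactors = FALSE)
}

#' Specification of a simulated two-group cohort
#'
#' @param n_failure,n_control Group sizes (default 31 and 14).
#' @param params Parameter distribution table as in
#'   [default_cohort_params()].
#' @param surv_family Event-time family for the failure group:
#'   `"lognormal"` (default), `"weibull"` or `"exponential"`.
#' @param surv_mean,surv_sd Target mean and SD in months of the observed
#'   (administratively censored) failure-group PFS; defaults 13.97 and
#'   12.31.
#' @param censor_time Administrative censoring time in months (default
#'   60); control patients are all censored there.
#' @param n_stage_prob_failure,n_stage_prob_control Frequencies of N
#'   stages 0-3 per group (defaults 4/3/19/5 and 6/3/4/1).
#' @param seed Master seed; per-stage child seeds are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_failure = 31L, n_control = 14L,
                        params = default_cohort_params(),
                        surv_family = c("lognormal", "weibull", "exponential"),
                        surv_mean = 13.97, surv_sd = 12.31,
                        censor_time = 60,
                        n_stage_prob_failure = c(4, 3, 19, 5) / 31,
                        n_stage_prob_control = c(6, 3, 4, 1) / 14,
                        seed = 1L) {
  surv_family <- match.arg(surv_family)
  stopifnot(n_failure >= 1L, n_control >= 1L, censor_time > 0,
            surv_mean > 0, surv_sd >= 0,
            all(c("parameter", "mean_failure", "sd_failure", "mean_control",
                  "sd_control", "lower", "upper") %in% names(params)),
            all(params$sd_failure >= 0), all(params$sd_control >= 0),
            length(n_stage_prob_failure) == 4L,
            length(n_stage_prob_control) == 4L)
  structure(list(n_failure = as.integer(n_failure),
                 n_control = as.integer(n_control), params = params,
                 surv_family = surv_family, surv_mean = surv_mean,
                 surv_sd = surv_sd, censor_time = censor_time,
                 n_stage_prob_failure = n_stage_prob_failure,
                 n_stage_prob_control = n_stage_prob_control,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# ---- survival-time calibration ---------------------------------------------

# Survival function of the chosen event-time family.
surv_fn <- function(family, p) {
  switch(family,
         lognormal = function(t) plnorm(t, p[1L], p[2L], lower.tail = FALSE),
         weibull = function(t) pweibull(t, exp(p[1L]), exp(p[2L]),
                                        lower.tail = FALSE),
         exponential = function(t) pexp(t, exp(p[1L]), lower.tail = FALSE))
}

# Mean and SD of min(X, censor): E[min] = int_0^C S, E[min^2] = int_0^C 2 t S.
censored_moments <- function(family, p, censor) {
  S <- surv_fn(family, p)
  m1 <- integrate(S, 0, censor, rel.tol = 1e-10)$value
  m2 <- integrate(function(t) 2 * t * S(t), 0, censor, rel.tol = 1e-10)$value
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Calibrate the family so the censored observation has the target moments.
calibrate_event_times <- function(family, mean, sd, censor) {
  if (family == "exponential") {
    f <- function(lr) censored_moments("exponential", lr, censor)[["mean"]] - mean
    lr <- uniroot(f, c(log(1e-4), log(100)), tol = 1e-12)$root
    return(lr)
  }
  start <- if (family == "lognormal") {
    s2 <- log(1 + (sd / mean)^2)
    c(log(mean) - s2 / 2, sqrt(s2))
  } else {
    c(log(1.2), log(mean))
  }
  obj <- function(p) {
    mom <- censored_moments(family, p, censor)
    (mom[["mean"]] - mean)^2 + (mom[["sd"]] - sd)^2
  }
  optim(start, obj, method = "Nelder-Mead",
        control = list(reltol = 1e-14, maxit = 2000))$par
}

draw_event_times <- function(family, p, n) {
  switch(family,
         lognormal = rlnorm(n, p[1L], p[2L]),
         weibull = rweibull(n, exp(p[1L]), exp(p[2L])),
         exponential = rexp(n, exp(p[1L])))
}

# ---- cohort generation -----------------------------------------------------

#' Simulate a two-group patient cohort
#'
#' IVIM parameters are drawn per group from truncated normal
#' distributions whose parent (mu, sigma) are solved so the
#' post-truncation mean equals the target exactly and the SD is as close
#' as the family permits (see [solve_truncnorm()]). Failure-group PFS is
#' drawn from the spec's event-time family calibrated so the
#' censored-at-`censor_time` observation has the target mean and SD;
#' draws beyond the censoring time are censored. Control patients are all
#' censored at `censor_time` with no event. Identical specs (including
#' seed) give identical tables.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` of class `cohort_table` with columns `id`,
#'   `group`, the nine IVIM parameters, `n_stage` (ordered factor),
#'   `pfs_months` and `event`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- spec$params
  n <- c(failure = spec$n_failure, control = spec$n_control)
  draws <- list()
  for (grp in c("failure", "control")) {
    seed_g <- derive_seed(spec$seed, paste0("params-", grp))
    mcol <- paste0("mean_", grp)
    scol <- paste0("sd_", grp)
    vals <- with_seed(seed_g, {
      out <- lapply(seq_len(nrow(p)), function(i) {
        sol <- memo(
          paste("tn", p[[mcol]][i], p[[scol]][i], p$lower[i], p$upper[i],
                sep = "|"),
          function() solve_truncnorm(p[[mcol]][i], p[[scol]][i],
                                     p$lower[i], p$upper[i]))
        rtruncnorm(n[[grp]], sol$mu, sol$sigma, p$lower[i], p$upper[i])
      })
      names(out) <- p$parameter
      out
    })
    draws[[grp]] <- as.data.frame(vals)
  }
  stage_f <- with_seed(derive_seed(spec$seed, "nstage-failure"),
                       sample(0:3, spec$n_failure, replace = TRUE,
                              prob = spec$n_stage_prob_failure))
  stage_c <- with_seed(derive_seed(spec$seed, "nstage-control"),
                       sample(0:3, spec$n_control, replace = TRUE,
                              prob = spec$n_stage_prob_control))
  cal <- memo(
    paste("surv", spec$surv_family, spec$surv_mean, spec$surv_sd,
          spec$censor_time, sep = "|"),
    function() calibrate_event_times(spec$surv_family, spec$surv_mean,
                                     spec$surv_sd, spec$censor_time))
  t_fail <- with_seed(derive_seed(spec$seed, "survival"),
                      draw_event_times(spec$surv_family, cal, spec$n_failure))
  pfs_f <- pmin(t_fail, spec$censor_time)
  ev_f <- t_fail < spec$censor_time
  tab <- rbind(
    data.frame(id = sprintf("F%04d", seq_len(spec$n_failure)),
               group = "failure", draws$failure,
               n_stage = stage_f, pfs_months = pfs_f, event = ev_f,
               stringsAsFactors = FALSE),
    data.frame(id = sprintf("C%04d", seq_len(spec$n_control)),
               group = "control", draws$control,
               n_stage = stage_c, pfs_months = spec$censor_time,
               event = FALSE, stringsAsFactors = FALSE))
  tab$group <- factor(tab$group, levels = c("failure", "control"))
  tab$n_stage <- factor(tab$n_stage, levels = 0:3, ordered = TRUE)
  class(tab) <- c("cohort_table", "data.frame")
  attr(tab, "spec") <- spec
  tab
}

#' IVIM parameter column names of a cohort table
#' @return Character vector of the nine parameter columns.
#' @export
cohort_param_names <- function() {
  c("ADCmean", "ADCmax", "ADCmin", "ADCrange", "D", "Dstar", "f", "DDC",
    "alpha")
}

#' Inject a known proportional-hazards effect into a cohort
#'
#' Replaces the survival outcome of every patient with event times drawn
#' from an exponential proportional-hazards model with per-patient hazard
#' `h0 * hazard_ratio^z`, where z is the chosen covariate (optionally
#' standardized). Administrative censoring is reapplied. This creates a
#' cohort with known ground-truth hazard ratio for calibration and
#' coverage testing of the Cox stage.
#'
#' @param table A `cohort_table`.
#' @param covariate Name of the covariate column (its reported units
#'   define "per unit").
#' @param hazard_ratio True hazard ratio per covariate unit, > 0.
#' @param seed Integer seed.
#' @param baseline_hazard Events per month at covariate 0; the default is
#'   chosen so the median event time at the cohort-average covariate
#'   value is 14 months.
#' @param standardize Center and scale the covariate before applying the
#'   effect.
#' @param censor_time Administrative censoring time in months.
#' @return The modified `cohort_table`, with the injected truth recorded
#'   in `attr(, "injected")`.
#' @export
inject_effect <- function(table, covariate, hazard_ratio, seed = 1L,
                          baseline_hazard = NULL, standardize = FALSE,
                          censor_time = 60) {
  stopifnot(is.data.frame(table))
  if (!covariate %in% names(table))
    stop_ivim(paste("no such covariate:", covariate), "ivimprog_input_error")
  if (!is.numeric(hazard_ratio) || hazard_ratio <= 0)
    stop_ivim("hazard_ratio must be positive", "ivimprog_input_error")
  z <- as.numeric(table[[covariate]])
  if (standardize) z <- as.numeric(scale(z))
  if (is.null(baseline_hazard))
    baseline_hazard <- log(2) / (14 * hazard_ratio^mean(z))
  rate <- baseline_hazard * hazard_ratio^z
  t_ev <- with_seed(seed, rexp(length(z), rate))
  table$pfs_months <- pmin(t_ev, censor_time)
  table$event <- t_ev < censor_time
  attr(table, "injected") <- list(covariate = covariate,
                                  hazard_ratio = hazard_ratio,
                                  baseline_hazard = baseline_hazard,
                                  standardize = standardize,
                                  censor_time = censor_time, seed = seed)
  table
}

#' Read or write a cohort table as CSV
#'
#' Columns: `id`, `group` (failure/control), the nine IVIM parameters
#' (diffusivities in 10^-3 mm^2/s, f in percent), `n_stage` (0-3),
#' `pfs_months`, `event` (TRUE/FALSE).
#'
#' @param table A `cohort_table`.
#' @param path CSV path.
#' @rdname cohort_io
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", cohort_param_names(), "n_stage", "pfs_months",
            "event")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop_ivim(paste("cohort CSV lacks columns:",
                    paste(missing, collapse = ", ")),
              "ivimprog_input_error")
  tab$group <- factor(tab$group, levels = c("failure", "control"))
  tab$n_stage <- factor(tab$n_stage, levels = 0:3, ordered = TRUE)
  tab$event <- as.logical(tab$event)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
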