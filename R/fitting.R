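# Parameter estimation from signal curves. All fits work on the normalized
# signal s/s0 so the baseline intensity is never a free parameter, and all
# nonlinear fits are bounded Levenberg-Marquardt (minpack.lm::nls.lm).
#
# Box bounds, in mm^2/s: D in [1e-5, 3e-3], D* in [D, 0.5], f in [0, 1],
# DDC in [1e-6, 5e-3], alpha in [0.1, 1]. These bracket reported
# head-and-neck tumor values with wide margins.

.D_MIN <- 1e-5
.D_MAX <- 3e-3
.DSTAR_MAX <- 0.5
.DDC_MIN <- 1e-6
.DDC_MAX <- 5e-3
.ALPHA_MIN <- 0.1

#' High-b segmentation rule for the segmented bi-exponential fit
#'
#' At b-values above the threshold the pseudo-diffusion compartment has
#' decayed to a negligible signal contribution (D* >> D), so the true
#' diffusion coefficient can be estimated there by a log-linear fit.
#'
#' @param b_threshold Threshold in s/mm^2; b-values strictly greater are
#'   the high-b subset. Default 200.
#' @return An object of class `segmentation_rule`.
#' @export
segmentation_rule <- function(b_threshold = 200) {
  stopifnot(is.numeric(b_threshold), length(b_threshold) == 1L, b_threshold >= 0)
  structure(list(b_threshold = as.numeric(b_threshold)),
            class = "segmentation_rule")
}

# Assemble a FitResult.
fit_result <- function(model, params, rss, converged, n_points_used,
                       init_rss = NA_real_) {
  structure(list(model = model, params = params, rss = rss,
                 converged = converged, n_points_used = n_points_used,
                 init_rss = init_rss),
            class = "ivim_fit")
}

#' @export
print.ivim_fit <- function(x, ...) {
  cat("IVIM fit (", x$model, ")",
      if (!x$converged) " [NOT CONVERGED]" else "", "\n", sep = "")
  p <- unlist(x$params)
  cat(paste(sprintf("  %s = %g", names(p), p), collapse = "\n"), "\n")
  cat(sprintf("  rss = %.3e on %d points\n", x$rss, x$n_points_used))
  invisible(x)
}

check_fittable <- function(curve) {
  stopifnot(inherits(curve, "signal_curve"))
  if (any(curve$s <= 0) || curve$s0 <= 0)
    stop_ivim("signal contains non-positive intensities",
              "ivimprog_degenerate_signal")
}

# Ordinary least squares of y on x with intercept; returns c(intercept, slope).
ols_line <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(yb - slope * xb, slope)
}

# Bounded LM with one deterministic restart (the coefficient named by
# restart_index multiplied by 1.5) when the first attempt does not converge.
lm_bounded <- function(residual_fn, start, lower, upper, restart_index = 2L) {
  run <- function(par0) {
    minpack.lm::nls.lm(
      par = par0, lower = lower, upper = upper, fn = residual_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12))
  }
  fit <- run(start)
  ok <- fit$info %in% 1:3 && all(is.finite(unlist(fit$par)))
  if (!ok) {
    start2 <- start
    start2[restart_index] <- min(start2[restart_index] * 1.5,
                                 upper[restart_index])
    fit2 <- run(start2)
    if (fit2$info %in% 1:3 && all(is.finite(unlist(fit2$par)))) {
      fit <- fit2
      ok <- TRUE
    } else if (fit2$deviance < fit$deviance) {
      fit <- fit2
    }
  }
  list(par = fit$par, rss = fit$deviance, converged = ok)
}

#' Log-linear mono-exponential (ADC) fit
#'
#' Fits ln(s/s0) = c - b * ADC by ordinary least squares over all
#' b-values; the ADC is the negated slope, clamped at 0 if the slope is
#' positive. The residual sum of squares is reported on the normalized
#' signal scale against s/s0 = exp(-b ADC).
#'
#' @param curve A [signal_curve()] with strictly positive intensities.
#' @return An object of class `ivim_fit` with [monoexp_params()].
#' @export
fit_monoexp <- function(curve) {
  check_fittable(curve)
  b <- curve$protocol$b_values
  if (length(b) < 2L)
    stop_ivim("need at least two b-values", "ivimprog_protocol_error")
  sn <- normalized_signal(curve)
  coefs <- ols_line(b, log(sn))
  adc <- max(0, -coefs[2L])
  rss <- sum((sn - monoexp_decay(b, adc))^2)
  fit_result("mono", monoexp_params(adc), rss, TRUE, length(b))
}

#' Segmented bi-exponential (IVIM) fit
#'
#' Two-step estimator. Step 1: the true diffusion coefficient D comes from
#' a log-linear fit restricted to b-values above the segmentation
#' threshold, where pseudo-diffusion has decayed away (the intercept is
#' free and absorbs 1 - f). Step 2: with D fixed, the perfusion fraction f
#' and pseudo-diffusion coefficient D* are estimated by bounded nonlinear
#' least squares of the bi-exponential model over all b-values,
#' initialized at f0 = 1 - exp(intercept) (clipped to [0.01, 0.99]) and
#' D*0 = 10 D.
#'
#' @param curve A [signal_curve()] spanning b-values on both sides of the
#'   threshold.
#' @param rule A [segmentation_rule()]; default threshold 200 s/mm^2.
#' @return An `ivim_fit` with [biexp_params()].
#' @export
fit_biexp_segmented <- function(curve, rule = segmentation_rule()) {
  check_fittable(curve)
  stopifnot(inherits(rule, "segmentation_rule"))
  b <- curve$protocol$b_values
  sn <- normalized_signal(curve)
  hi <- b > rule$b_threshold
  if (sum(hi) < 2L)
    stop_ivim("need at least two b-values above the segmentation threshold",
              "ivimprog_protocol_error")
  if (all(hi))
    stop_ivim("curve has no b-values at or below the segmentation threshold",
              "ivimprog_protocol_error")
  coefs <- ols_line(b[hi], log(sn[hi]))
  d <- min(max(-coefs[2L], .D_MIN), .D_MAX)
  f0 <- min(max(1 - exp(coefs[1L]), 0.01), 0.99)
  dstar0 <- min(max(10 * d, d), .DSTAR_MAX)
  resid_fn <- function(p) sn - biexp_decay(b, d, p[["dstar"]], p[["f"]])
  sol <- lm_bounded(resid_fn, c(f = f0, dstar = dstar0),
                    lower = c(0, d), upper = c(1, .DSTAR_MAX))
  init_rss <- sum(resid_fn(c(f = f0, dstar = dstar0))^2)
  fit_result("biexp_segmented",
             biexp_params(d, sol$par[["dstar"]], sol$par[["f"]]),
             sol$rss, sol$converged, length(b), init_rss)
}

#' Simultaneous bounded bi-exponential fit
#'
#' Fits (D, D*, f) jointly by bounded nonlinear least squares over all
#' b-values, initialized from the segmented fit. Internally D* is
#' parameterized as D + delta with delta >= 0 so the constraint D* >= D
#' holds throughout. Serves as a cross-check on the segmented estimator.
#'
#' @inheritParams fit_biexp_segmented
#' @param init Optional [biexp_params()] starting point; default is the
#'   segmented fit of the same curve.
#' @return An `ivim_fit` with [biexp_params()].
#' @export
fit_biexp_full <- function(curve, init = NULL) {
  check_fittable(curve)
  if (is.null(init)) {
    seg <- tryCatch(fit_biexp_segmented(curve), ivimprog_error = function(e) NULL)
    init <- if (!is.null(seg)) seg$params else biexp_params(1e-3, 1e-2, 0.2)
  }
  stopifnot(inherits(init, "biexp_params"))
  b <- curve$protocol$b_values
  sn <- normalized_signal(curve)
  start <- c(d = min(max(init$d, .D_MIN), .D_MAX),
             delta = min(max(init$d_star - init$d, 0), .DSTAR_MAX),
             f = min(max(init$f, 0), 1))
  resid_fn <- function(p)
    sn - biexp_decay(b, p[["d"]], p[["d"]] + p[["delta"]], p[["f"]])
  sol <- lm_bounded(resid_fn, start,
                    lower = c(.D_MIN, 0, 0), upper = c(.D_MAX, .DSTAR_MAX, 1))
  init_rss <- sum(resid_fn(start)^2)
  fit_result("biexp_full",
             biexp_params(sol$par[["d"]], sol$par[["d"]] + sol$par[["delta"]],
                          sol$par[["f"]]),
             sol$rss, sol$converged, length(b), init_rss)
}

#' Stretched-exponential fit
#'
#' Fits (DDC, alpha) by bounded nonlinear least squares of
#' s/s0 = exp(-(b DDC)^alpha) over the b > 0 points (the b = 0 point is
#' identically 1), initialized at the mono-exponential ADC and
#' alpha0 = 0.8.
#'
#' @inheritParams fit_biexp_segmented
#' @return An `ivim_fit` with [stretched_params()].
#' @export
fit_stretched <- function(curve) {
  check_fittable(curve)
  b <- curve$protocol$b_values
  sn <- normalized_signal(curve)
  pos <- b > 0
  if (sum(pos) < 2L)
    stop_ivim("need at least two non-zero b-values", "ivimprog_protocol_error")
  adc <- fit_monoexp(curve)$params$adc
  start <- c(ddc = min(max(adc, .DDC_MIN), .DDC_MAX), alpha = 0.8)
  resid_fn <- function(p)
    sn[pos] - stretched_decay(b[pos], p[["ddc"]], p[["alpha"]])
  sol <- lm_bounded(resid_fn, start,
                    lower = c(.DDC_MIN, .ALPHA_MIN), upper = c(.DDC_MAX, 1),
                    restart_index = 1L)
  init_rss <- sum(resid_fn(start)^2)
  fit_result("stretched",
             stretched_params(sol$par[["ddc"]], sol$par[["alpha"]]),
             sol$rss, sol$converged, sum(pos), init_rss)
}
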