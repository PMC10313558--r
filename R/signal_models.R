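# Forward IVIM signal models. All diffusion coefficients are held internally
# in mm^2/s; exporters multiply by 1e3 to report on the conventional
# 10^-3 mm^2/s scale, so the b * D products here are always dimensionless.

#' Parameter containers for the three IVIM signal models
#'
#' `monoexp_params` holds the apparent diffusion coefficient of the
#' mono-exponential model; `biexp_params` the true diffusion coefficient
#' `d`, pseudo-diffusion coefficient `d_star` and perfusion fraction `f`
#' of the bi-exponential (IVIM) model; `stretched_params` the distributed
#' diffusion coefficient `ddc` and heterogeneity index `alpha` of the
#' stretched-exponential model.
#'
#' @param adc,d,d_star,ddc Diffusion coefficients in mm^2/s (non-negative).
#' @param f Perfusion fraction in [0, 1].
#' @param alpha Heterogeneity index in (0, 1]; 1 is mono-exponential decay.
#' @return A classed list of validated parameters.
#' @rdname ivim_params
#' @export
monoexp_params <- function(adc) {
  if (!is.numeric(adc) || length(adc) != 1L || is.na(adc) || adc < 0)
    stop_ivim("adc must be a single non-negative number",
              "ivimprog_invalid_parameter")
  structure(list(adc = as.numeric(adc)),
            class = c("monoexp_params", "ivim_params"))
}

#' @rdname ivim_params
#' @export
biexp_params <- function(d, d_star, f) {
  ok <- is.numeric(d) && is.numeric(d_star) && is.numeric(f) &&
    length(d) == 1L && length(d_star) == 1L && length(f) == 1L &&
    !anyNA(c(d, d_star, f))
  if (!ok || d < 0 || d_star < 0)
    stop_ivim("d and d_star must be single non-negative numbers",
              "ivimprog_invalid_parameter")
  if (f < 0 || f > 1)
    stop_ivim("perfusion fraction f must lie in [0, 1]",
              "ivimprog_invalid_parameter")
  structure(list(d = as.numeric(d), d_star = as.numeric(d_star),
                 f = as.numeric(f)),
            class = c("biexp_params", "ivim_params"))
}

#' @rdname ivim_params
#' @export
stretched_params <- function(ddc, alpha) {
  ok <- is.numeric(ddc) && is.numeric(alpha) &&
    length(ddc) == 1L && length(alpha) == 1L && !anyNA(c(ddc, alpha))
  if (!ok || ddc < 0)
    stop_ivim("ddc must be a single non-negative number",
              "ivimprog_invalid_parameter")
  if (alpha <= 0 || alpha > 1)
    stop_ivim("alpha must lie in (0, 1]", "ivimprog_invalid_parameter")
  structure(list(ddc = as.numeric(ddc), alpha = as.numeric(alpha)),
            class = c("stretched_params", "ivim_params"))
}

# Vectorised normalized-signal kernels (s/s0 as a function of b).
monoexp_decay <- function(b, adc) exp(-b * adc)

biexp_decay <- function(b, d, d_star, f) {
  # exponent of the fast compartment is -(D* + D) b, as written in the
  # source model (some IVIM software uses -D* b instead).
  (1 - f) * exp(-b * d) + f * exp(-b * (d_star + d))
}

stretched_decay <- function(b, ddc, alpha) exp(-(b * ddc)^alpha)

#' Signal curve over a protocol
#'
#' Bundles per-b signal intensities with their protocol. `s0` is the b = 0
#' intensity; the normalized view `s / s0` is what the models describe.
#'
#' @param protocol A [bvalue_protocol()].
#' @param s Numeric vector of non-negative intensities, one per b-value.
#' @return An object of class `signal_curve` with elements `protocol`,
#'   `s` and `s0`.
#' @export
signal_curve <- function(protocol, s) {
  stopifnot(inherits(protocol, "bvalue_protocol"))
  s <- as.numeric(s)
  if (length(s) != length(protocol$b_values))
    stop_ivim("signal length must match the protocol", "ivimprog_invalid_curve")
  if (anyNA(s) || any(s < 0))
    stop_ivim("signal intensities must be non-negative", "ivimprog_invalid_curve")
  structure(list(protocol = protocol, s = s, s0 = s[1L]),
            class = "signal_curve")
}

#' @export
print.signal_curve <- function(x, ...) {
  cat("IVIM signal curve, s0 =", format(x$s0), "\n")
  print(data.frame(b_value = x$protocol$b_values, s = x$s), row.names = FALSE)
  invisible(x)
}

#' Normalized signal s/s0 of a curve
#' @param curve A [signal_curve()].
#' @return Numeric vector of s/s0, one value per b.
#' @export
normalized_signal <- function(curve) {
  stopifnot(inherits(curve, "signal_curve"))
  if (curve$s0 <= 0)
    stop_ivim("cannot normalize a curve with s0 <= 0", "ivimprog_degenerate_signal")
  curve$s / curve$s0
}

check_s0 <- function(s0) {
  if (!is.numeric(s0) || length(s0) != 1L || is.na(s0) || s0 <= 0)
    stop_ivim("s0 must be a single positive intensity",
              "ivimprog_invalid_parameter")
  as.numeric(s0)
}

#' Evaluate the IVIM forward models over a protocol
#'
#' `monoexp_signal` evaluates s = s0 exp(-b ADC); `biexp_signal` evaluates
#' s/s0 = (1 - f) exp(-b D) + f exp(-b (D* + D)); `stretchedexp_signal`
#' evaluates s/s0 = exp(-(b DDC)^alpha). All return exactly s0 at b = 0 and
#' are non-increasing in b for valid parameters.
#'
#' @param params The matching parameter object (see [monoexp_params()]).
#' @param protocol A [bvalue_protocol()].
#' @param s0 Baseline (b = 0) intensity, > 0.
#' @return A [signal_curve()].
#' @rdname forward_models
#' @export
monoexp_signal <- function(params, protocol, s0 = 1) {
  stopifnot(inherits(params, "monoexp_params"))
  s0 <- check_s0(s0)
  signal_curve(protocol, s0 * monoexp_decay(protocol$b_values, params$adc))
}

#' @rdname forward_models
#' @export
biexp_signal <- function(params, protocol, s0 = 1) {
  stopifnot(inherits(params, "biexp_params"))
  s0 <- check_s0(s0)
  signal_curve(protocol,
               s0 * biexp_decay(protocol$b_values, params$d, params$d_star,
                                params$f))
}

#' @rdname forward_models
#' @export
stretchedexp_signal <- function(params, protocol, s0 = 1) {
  stopifnot(inherits(params, "stretched_params"))
  s0 <- check_s0(s0)
  signal_curve(protocol,
               s0 * stretched_decay(protocol$b_values, params$ddc, params$alpha))
}
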