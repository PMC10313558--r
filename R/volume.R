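# Per-voxel fitting of a 4-D DWI stack into parameter maps.

model_map_names <- function(model) {
  switch(model,
         mono = "ADC",
         biexp = c("D", "Dstar", "f"),
         biexp_full = c("D", "Dstar", "f"),
         stretched = c("DDC", "alpha"),
         stop_ivim(paste("unknown model:", model), "ivimprog_input_error"))
}

extract_map_values <- function(fit, model) {
  p <- fit$params
  switch(model,
         mono = c(ADC = p$adc),
         biexp = ,
         biexp_full = c(D = p$d, Dstar = p$d_star, f = p$f),
         stretched = c(DDC = p$ddc, alpha = p$alpha))
}

#' Fit an IVIM model voxel-wise over a 4-D DWI stack
#'
#' Runs the scalar fitter of the chosen model in every masked voxel and
#' assembles 3-D parameter maps. Voxels with degenerate signal (any
#' non-positive intensity) or a non-converged fit are set to `NA` and
#' counted in the fit-quality report.
#'
#' @param dwi 4-D numeric array (x, y, slice, b), one volume per b-value.
#' @param protocol A [bvalue_protocol()] whose length matches `dim(dwi)[4]`.
#' @param model One of `"mono"`, `"biexp"` (segmented), `"biexp_full"`,
#'   `"stretched"`.
#' @param mask Optional 3-D logical array of voxels to fit; default all.
#' @param rule [segmentation_rule()] used by the segmented fit.
#' @return An object of class `param_maps`: list of 3-D `maps` (named by
#'   parameter), the `model`, the `protocol` and a `report` with counts of
#'   masked, fitted and failed voxels.
#' @export
fit_volume <- function(dwi, protocol, model = c("mono", "biexp", "biexp_full",
                                                "stretched"),
                       mask = NULL, rule = segmentation_rule()) {
  model <- match.arg(model)
  stopifnot(inherits(protocol, "bvalue_protocol"))
  dims <- dim(dwi)
  if (length(dims) != 4L || dims[4L] != length(protocol$b_values))
    stop_ivim("dwi must be 4-D with one volume per protocol b-value",
              "ivimprog_input_error")
  spatial <- dims[1:3]
  if (is.null(mask)) mask <- array(TRUE, spatial)
  if (!identical(dim(mask), as.integer(spatial)) &&
      !identical(dim(mask), spatial))
    stop_ivim("mask shape must match the spatial grid", "ivimprog_input_error")

  names_out <- model_map_names(model)
  maps <- lapply(names_out, function(nm) array(NA_real_, spatial))
  names(maps) <- names_out

  idx <- which(mask)
  n_failed <- 0L
  flat <- matrix(dwi, nrow = prod(spatial), ncol = dims[4L])
  fitter <- switch(model,
                   mono = fit_monoexp,
                   biexp = function(cv) fit_biexp_segmented(cv, rule),
                   biexp_full = fit_biexp_full,
                   stretched = fit_stretched)
  for (v in idx) {
    sig <- flat[v, ]
    fit <- tryCatch({
      if (any(sig <= 0)) stop_ivim("degenerate", "ivimprog_degenerate_signal")
      fitter(signal_curve(protocol, sig))
    }, ivimprog_error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    vals <- extract_map_values(fit, model)
    for (nm in names_out) maps[[nm]][v] <- vals[[nm]]
  }
  structure(list(
    maps = maps, model = model, protocol = protocol,
    report = list(n_voxels = prod(spatial), n_masked = length(idx),
                  n_fitted = length(idx) - n_failed, n_failed = n_failed)),
    class = "param_maps")
}

#' @export
print.param_maps <- function(x, ...) {
  cat("IVIM parameter maps (", x$model, "): ",
      paste(names(x$maps), collapse = ", "), "\n", sep = "")
  cat(sprintf("  %d voxels masked, %d fitted, %d failed\n",
              x$report$n_masked, x$report$n_fitted, x$report$n_failed))
  invisible(x)
}

map_units <- c(ADC = "mm^2/s", D = "mm^2/s", Dstar = "mm^2/s",
               f = "fraction", DDC = "mm^2/s", alpha = "dimensionless")

#' Write parameter maps to NIfTI files plus a JSON fit-quality report
#'
#' One NIfTI-1 volume per parameter, named `<prefix>_<parameter>.nii`, the
#' parameter name and units recorded in the header description; the fit
#' report goes to `<prefix>_fit_report.json`.
#'
#' @param maps A `param_maps` object from [fit_volume()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; default the model name.
#' @param pixel_spacing In-plane pixel spacing in mm (default 1.625, from a
#'   260 mm field of view on a 160 matrix); slice thickness 5 mm.
#' @return Invisibly, the paths written.
#' @export
write_param_maps <- function(maps, dir, prefix = maps$model,
                             pixel_spacing = 1.625) {
  stopifnot(inherits(maps, "param_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(maps$maps)) {
    img <- RNifti::asNifti(maps$maps[[nm]])
    RNifti::pixdim(img) <- c(pixel_spacing, pixel_spacing, 5)
    img$descrip <- sprintf("%s (%s)", nm, map_units[[nm]])
    path <- file.path(dir, sprintf("%s_%s.nii", prefix, nm))
    RNifti::writeNifti(img, path)
    paths <- c(paths, path)
  }
  rp <- file.path(dir, sprintf("%s_fit_report.json", prefix))
  jsonlite::write_json(maps$report, rp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, rp))
}

#' Read a parameter map written by [write_param_maps()]
#' @param path Path to a `.nii` file.
#' @return A 3-D numeric array with attribute `descrip`.
#' @export
read_param_map <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "descrip") <- RNifti::niftiHeader(img)$descrip
  arr
}
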