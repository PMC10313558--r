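# Digital DWI phantoms: a lesion disc embedded in background tissue, built
# voxel-wise from the forward signal models, with optional Rician noise
# scaled by the per-b NEX of the protocol.

#' Specification of a digital DWI phantom
#'
#' The phantom is a rectangular grid holding two tissue classes: a
#' background and a cylindrical (per-slice circular) lesion, each with its
#' own model parameters. Signal is generated from one chosen forward
#' model; the ground-truth parameter values are stored as maps alongside.
#'
#' @param dim Grid dimensions `c(nx, ny, nslices)`.
#' @param model Forward model: `"mono"`, `"biexp"` or `"stretched"`.
#' @param background,lesion Parameter objects of the matching class (see
#'   [monoexp_params()], [biexp_params()], [stretched_params()]).
#' @param lesion_center Voxel coordinates `c(x, y, slice)`, 0-based; the
#'   lesion occupies this slice only.
#' @param lesion_radius Lesion radius in mm.
#' @param pixel_spacing In-plane mm per pixel; default 1.625.
#' @param s0 Baseline (b = 0) intensity.
#' @param noise_sigma Rician channel SD, intensity units; 0 = noiseless.
#' @param seed Integer seed for the noise draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(32L, 32L, 3L), model = "biexp",
                         background = biexp_params(1.3e-3, 20e-3, 0.1),
                         lesion = biexp_params(0.673e-3, 67.5e-3, 0.266),
                         lesion_center = c(15, 15, 1), lesion_radius = 3.3,
                         pixel_spacing = 1.625, s0 = 1000, noise_sigma = 0,
                         seed = 1L) {
  model <- match.arg(model, c("mono", "biexp", "stretched"))
  cls <- switch(model, mono = "monoexp_params", biexp = "biexp_params",
                stretched = "stretched_params")
  stopifnot(inherits(background, cls), inherits(lesion, cls),
            length(dim) == 3L, all(dim >= 1), s0 > 0)
  if (noise_sigma < 0)
    stop_ivim("noise_sigma must be non-negative", "ivimprog_invalid_parameter")
  roi <- circular_roi(lesion_center, lesion_radius,
                      pixel_spacing = pixel_spacing, check_area = FALSE)
  # validates the lesion fits inside the grid
  invisible(roi_mask(roi, dim))
  structure(list(dim = as.integer(dim), model = model,
                 background = background, lesion = lesion,
                 lesion_center = lesion_center, lesion_radius = lesion_radius,
                 pixel_spacing = pixel_spacing, s0 = s0,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

params_decay <- function(model, params, b) {
  switch(model,
         mono = monoexp_decay(b, params$adc),
         biexp = biexp_decay(b, params$d, params$d_star, params$f),
         stretched = stretched_decay(b, params$ddc, params$alpha))
}

truth_values <- function(model, params) {
  switch(model,
         mono = c(ADC = params$adc),
         biexp = c(D = params$d, Dstar = params$d_star, f = params$f),
         stretched = c(DDC = params$ddc, alpha = params$alpha))
}

#' Build a digital DWI phantom
#'
#' Generates the noiseless 4-D stack voxel-wise from the forward model of
#' the spec, stores ground-truth parameter maps and the lesion mask, and
#' (when `noise_sigma > 0`) adds Rician noise via [add_rician_noise()]
#' using the spec's seed. Identical specs give bit-identical phantoms.
#'
#' @param spec A [phantom_spec()].
#' @param protocol A [bvalue_protocol()].
#' @return An object of class `phantom`: `dwi` (4-D array), `truth`
#'   (named list of 3-D maps), `mask` (lesion voxels), `spec`, `protocol`.
#' @export
make_phantom <- function(spec, protocol) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(protocol, "bvalue_protocol"))
  b <- protocol$b_values
  roi <- circular_roi(spec$lesion_center, spec$lesion_radius,
                      pixel_spacing = spec$pixel_spacing, check_area = FALSE)
  mask <- roi_mask(roi, spec$dim)
  nvox <- prod(spec$dim)
  bg_curve <- spec$s0 * params_decay(spec$model, spec$background, b)
  ls_curve <- spec$s0 * params_decay(spec$model, spec$lesion, b)
  flat <- matrix(rep(bg_curve, each = nvox), nrow = nvox)
  flat[which(mask), ] <- matrix(rep(ls_curve, each = sum(mask)),
                                nrow = sum(mask))
  dwi <- array(flat, c(spec$dim, length(b)))
  if (spec$noise_sigma > 0)
    dwi <- add_rician_noise(dwi, spec$noise_sigma, protocol$nex,
                            seed = spec$seed)
  bg_truth <- truth_values(spec$model, spec$background)
  ls_truth <- truth_values(spec$model, spec$lesion)
  truth <- lapply(names(bg_truth), function(nm) {
    m <- array(bg_truth[[nm]], spec$dim)
    m[mask] <- ls_truth[[nm]]
    m
  })
  names(truth) <- names(bg_truth)
  structure(list(dwi = dwi, truth = truth, mask = mask, spec = spec,
                 protocol = protocol),
            class = "phantom")
}

#' Add Rician noise to a DWI stack
#'
#' Each voxel intensity s is replaced by the magnitude sqrt((s + g1)^2 +
#' g2^2) with g1, g2 independent zero-mean Gaussians of SD
#' `sigma / sqrt(nex_b)`: averaging NEX excitations reduces the channel SD
#' by sqrt(NEX). `sigma = 0` returns the input unchanged. At zero signal
#' the output is Rayleigh with mean `sigma_eff * sqrt(pi / 2)`, the noise
#' floor of magnitude MRI.
#'
#' @param stack 4-D array (x, y, slice, b).
#' @param sigma Channel SD in intensity units, >= 0.
#' @param nex Integer vector of signal averages, one per b-volume.
#' @param seed Integer seed.
#' @return A 4-D array of the same shape.
#' @export
add_rician_noise <- function(stack, sigma, nex, seed = 1L) {
  dims <- dim(stack)
  stopifnot(length(dims) == 4L, length(nex) == dims[4L], all(nex >= 1))
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop_ivim("sigma must be a single non-negative number",
              "ivimprog_invalid_parameter")
  if (sigma == 0) return(stack)
  nvox <- prod(dims[1:3])
  with_seed(seed, {
    out <- stack
    for (k in seq_len(dims[4L])) {
      sd_eff <- sigma / sqrt(nex[k])
      g1 <- rnorm(nvox, 0, sd_eff)
      g2 <- rnorm(nvox, 0, sd_eff)
      vol <- as.numeric(stack[, , , k])
      out[, , , k] <- sqrt((vol + g1)^2 + g2^2)
    }
    out
  })
}

#' Write a phantom to NIfTI plus a JSON truth sidecar
#'
#' Writes `<prefix>_dwi.nii` (4-D), `<prefix>_mask.nii`, the protocol
#' sidecar `<prefix>_protocol.txt` and `<prefix>_truth.json` holding the
#' generating model, parameter values (synthetic ground truth) and seed.
#'
#' @param phantom A `phantom` from [make_phantom()].
#' @param dir Output directory.
#' @param prefix File-name prefix, default `"phantom"`.
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- phantom$spec
  dwi_path <- file.path(dir, paste0(prefix, "_dwi.nii"))
  img <- RNifti::asNifti(phantom$dwi)
  RNifti::pixdim(img) <- c(sp$pixel_spacing, sp$pixel_spacing, 5, 1)
  img$descrip <- "synthetic IVIM DWI phantom"
  RNifti::writeNifti(img, dwi_path)
  mask_path <- file.path(dir, paste0(prefix, "_mask.nii"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(phantom$mask), sp$dim)),
                     mask_path)
  proto_path <- file.path(dir, paste0(prefix, "_protocol.txt"))
  write_protocol(phantom$protocol, proto_path)
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(list(
    model = sp$model,
    background = unclass(sp$background), lesion = unclass(sp$lesion),
    lesion_center = sp$lesion_center, lesion_radius = sp$lesion_radius,
    pixel_spacing = sp$pixel_spacing, s0 = sp$s0,
    noise_sigma = sp$noise_sigma, seed = sp$seed,
    note = "synthetic ground truth"), truth_path,
    auto_unbox = TRUE, digits = NA)
  invisible(c(dwi_path, mask_path, proto_path, truth_path))
}
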