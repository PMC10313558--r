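# Circular-ROI definition, signal extraction and parameter summaries.

#' Circular region of interest on one slice
#'
#' A fixed circular ROI placed on the slice of largest solid tumor area.
#' A voxel belongs to the ROI when its center lies within `radius` mm of
#' the ROI center. Under the default spacing (260 mm field of view on a
#' 160 matrix, 1.625 mm pixels) the in-plane area must fall in
#' [25, 50] mm^2 unless `check_area = FALSE`.
#'
#' @param center Voxel coordinates `c(x, y, slice)`, 0-based.
#' @param radius Radius in mm.
#' @param pixel_spacing In-plane mm per pixel; default 1.625.
#' @param check_area Enforce the 25-50 mm^2 area convention.
#' @return An object of class `circular_roi`.
#' @export
circular_roi <- function(center, radius, pixel_spacing = 1.625,
                         check_area = TRUE) {
  stopifnot(length(center) == 3L, is.numeric(center), is.numeric(radius),
            radius > 0, pixel_spacing > 0)
  area <- pi * radius^2
  if (check_area && (area < 25 - 1e-9 || area > 50 + 1e-9))
    stop_ivim(sprintf(
      "ROI area %.1f mm^2 outside [25, 50]; use check_area = FALSE to override",
      area), "ivimprog_invalid_roi")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 pixel_spacing = as.numeric(pixel_spacing), area_mm2 = area),
            class = "circular_roi")
}

#' Digitize a circular ROI into a 3-D logical mask
#'
#' Area-preserving digitization: the ROI consists of the
#' `ceiling(pi r^2 / voxel_area)` voxels whose centers lie closest to the
#' ROI center (ties broken deterministically by distance, then row, then
#' column). This keeps the digitized area within one voxel of the
#' requested circular area regardless of where the center falls relative
#' to the voxel lattice, while selecting essentially the
#' center-within-radius disc.
#'
#' @param roi A [circular_roi()].
#' @param dim Spatial grid dimensions `c(nx, ny, nslices)`.
#' @return Logical array of `dim`, TRUE inside the ROI (single slice).
#' @export
roi_mask <- function(roi, dim) {
  stopifnot(inherits(roi, "circular_roi"), length(dim) == 3L)
  cx <- roi$center[1L]
  cy <- roi$center[2L]
  sl <- roi$center[3L] + 1L  # 0-based slice index to R index
  if (sl < 1L || sl > dim[3L] ||
      cx < 0 || cx > dim[1L] - 1L || cy < 0 || cy > dim[2L] - 1L)
    stop_ivim("ROI center outside the image grid", "ivimprog_invalid_roi")
  voxel_area <- roi$pixel_spacing^2
  n_target <- max(1L, ceiling(roi$area_mm2 / voxel_area))
  x <- (seq_len(dim[1L]) - 1L - cx) * roi$pixel_spacing
  y <- (seq_len(dim[2L]) - 1L - cy) * roi$pixel_spacing
  d2 <- outer(x^2, y^2, `+`)
  ij <- arrayInd(seq_along(d2), dim(d2))
  ord <- order(d2, ij[, 1L], ij[, 2L])
  if (n_target > length(ord))
    stop_ivim("ROI larger than the image grid", "ivimprog_invalid_roi")
  sel <- ord[seq_len(n_target)]
  disc <- array(FALSE, dim(d2))
  disc[sel] <- TRUE
  if (any(disc[1L, ]) || any(disc[nrow(disc), ]) ||
      any(disc[, 1L]) || any(disc[, ncol(disc)]))
    stop_ivim("ROI extends beyond the image grid", "ivimprog_invalid_roi")
  mask <- array(FALSE, dim)
  mask[, , sl] <- disc
  mask
}

#' Mean ROI signal per b-value
#'
#' Averages the signal over all ROI voxels separately at each b-value,
#' emulating per-ROI signal integration used to stabilize the
#' signal-to-noise ratio before curve fitting.
#'
#' @param dwi 4-D DWI array (x, y, slice, b).
#' @param roi A [circular_roi()].
#' @param protocol The matching [bvalue_protocol()].
#' @return A [signal_curve()] of ROI-mean intensities.
#' @export
roi_mean_signal <- function(dwi, roi, protocol) {
  dims <- dim(dwi)
  stopifnot(length(dims) == 4L, dims[4L] == length(protocol$b_values))
  mask <- roi_mask(roi, dims[1:3])
  n <- sum(mask)
  if (n < 1L) stop_ivim("ROI contains no voxels", "ivimprog_invalid_roi")
  flat <- matrix(dwi, nrow = prod(dims[1:3]), ncol = dims[4L])
  signal_curve(protocol, colMeans(flat[which(mask), , drop = FALSE]))
}

roi_summary_fields <- c("adc_mean", "adc_max", "adc_min", "adc_range",
                        "d", "d_star", "f", "ddc", "alpha")

new_roi_summary <- function(values, n_voxels) {
  structure(c(as.list(values), list(n_voxels = n_voxels)),
            class = "roi_summary")
}

#' Summarize parameter maps over an ROI
#'
#' The mono-exponential ADC map is summarized by its mean, maximum,
#' minimum and range (max - min) over the non-missing ROI voxels;
#' bi-exponential and stretched-exponential maps by their ROI means.
#' Missing (unfitted) voxels are excluded and counted.
#'
#' @param maps A `param_maps` object or a list of them (e.g. one per
#'   model); map names among ADC, D, Dstar, f, DDC, alpha.
#' @param roi A [circular_roi()].
#' @return An object of class `roi_summary` with fields `adc_mean`,
#'   `adc_max`, `adc_min`, `adc_range`, `d`, `d_star`, `f`, `ddc`,
#'   `alpha` (NA when the map is absent) and `n_voxels`.
#' @export
summarize_roi <- function(maps, roi) {
  if (inherits(maps, "param_maps")) maps <- list(maps)
  all_maps <- do.call(c, unname(lapply(maps, function(m) {
    stopifnot(inherits(m, "param_maps"))
    m$maps
  })))
  dims <- dim(all_maps[[1L]])
  mask <- roi_mask(roi, dims)
  vox <- which(mask)
  pick <- function(nm) {
    if (!nm %in% names(all_maps)) return(NULL)
    v <- all_maps[[nm]][vox]
    v[is.finite(v)]
  }
  adc <- pick("ADC")
  present <- unlist(lapply(names(all_maps), function(nm) {
    length(pick(nm))
  }))
  if (all(present == 0L))
    stop_ivim("no non-missing voxels in the ROI", "ivimprog_invalid_roi")
  out <- c(adc_mean = NA_real_, adc_max = NA_real_, adc_min = NA_real_,
           adc_range = NA_real_, d = NA_real_, d_star = NA_real_,
           f = NA_real_, ddc = NA_real_, alpha = NA_real_)
  if (length(adc)) {
    out["adc_mean"] <- mean(adc)
    out["adc_max"] <- max(adc)
    out["adc_min"] <- min(adc)
    out["adc_range"] <- out[["adc_max"]] - out[["adc_min"]]
  }
  means <- c(d = "D", d_star = "Dstar", f = "f", ddc = "DDC", alpha = "alpha")
  for (field in names(means)) {
    v <- pick(means[[field]])
    if (length(v)) out[field] <- mean(v)
  }
  new_roi_summary(out, n_voxels = length(vox))
}

#' @export
print.roi_summary <- function(x, ...) {
  cat("ROI summary over", x$n_voxels, "voxels\n")
  v <- unlist(x[roi_summary_fields])
  print(round(v, 6))
  invisible(x)
}

#' Average triplicate ROI measurements
#'
#' Lesion measurements are taken three times and averaged field-wise;
#' voxel counts are summed. For arithmetic means the averaged range stays
#' equal to averaged max minus averaged min, which is asserted.
#'
#' @param summaries A list of exactly three `roi_summary` objects.
#' @return A single averaged `roi_summary`.
#' @export
average_triplicate <- function(summaries) {
  if (!is.list(summaries) || length(summaries) != 3L ||
      !all(vapply(summaries, inherits, logical(1), "roi_summary")))
    stop_ivim("exactly three roi_summary objects are required",
              "ivimprog_invalid_roi")
  mat <- vapply(summaries, function(s) unlist(s[roi_summary_fields]),
                numeric(length(roi_summary_fields)))
  avg <- rowMeans(mat)
  rng <- avg[["adc_max"]] - avg[["adc_min"]]
  stopifnot(is.na(rng) || abs(rng - avg[["adc_range"]]) < 1e-9)
  new_roi_summary(avg, n_voxels = sum(vapply(summaries, `[[`, numeric(1),
                                             "n_voxels")))
}

#' Export ROI summaries to CSV on reporting units
#'
#' One row per lesion with columns ADCmean, ADCmax, ADCmin, ADCrange, D,
#' Dstar, f, DDC, alpha and n_voxels. Diffusivities are exported on the
#' 10^-3 mm^2/s scale and the perfusion fraction in percent.
#'
#' @param summaries Named list of `roi_summary` objects (names become the
#'   lesion id column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_summaries <- function(summaries, path) {
  if (inherits(summaries, "roi_summary")) summaries <- list(lesion = summaries)
  rows <- lapply(names(summaries), function(id) {
    s <- summaries[[id]]
    data.frame(
      lesion = id,
      ADCmean = s$adc_mean * 1e3, ADCmax = s$adc_max * 1e3,
      ADCmin = s$adc_min * 1e3, ADCrange = s$adc_range * 1e3,
      D = s$d * 1e3, Dstar = s$d_star * 1e3, f = s$f * 100,
      DDC = s$ddc * 1e3, alpha = s$alpha, n_voxels = s$n_voxels)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read or write an ROI specification as JSON
#'
#' The JSON records the 0-based center voxel, radius in mm and pixel
#' spacing.
#'
#' @param roi A [circular_roi()].
#' @param path JSON file path.
#' @rdname roi_io
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "circular_roi"))
  jsonlite::write_json(list(center = roi$center, radius_mm = roi$radius,
                            pixel_spacing = roi$pixel_spacing),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname roi_io
#' @param check_area Passed to [circular_roi()].
#' @export
read_roi <- function(path, check_area = TRUE) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  circular_roi(spec$center, spec$radius_mm,
               spec$pixel_spacing %||% 1.625, check_area = check_area)
}
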