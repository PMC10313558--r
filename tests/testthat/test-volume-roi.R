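protocol <- default_protocol()

test_that("voxel-wise fitting recovers a uniform noiseless phantom", {
  spec <- phantom_spec(dim = c(8, 8, 2), model = "biexp",
                       background = fig1_biexp(), lesion = fig1_biexp(),
                       lesion_center = c(3, 3, 0), lesion_radius = 2,
                       noise_sigma = 0)
  ph <- make_phantom(spec, protocol)
  maps <- fit_volume(ph$dwi, protocol, "biexp", mask = ph$mask)
  expect_equal(maps$report$n_failed, 0L)
  truth <- fig1_biexp()
  expect_true(all(rel_err(maps$maps$D[ph$mask], truth$d) < 0.01))
  expect_true(all(rel_err(maps$maps$Dstar[ph$mask], truth$d_star) < 0.01))
  expect_true(all(rel_err(maps$maps$f[ph$mask], truth$f) < 0.01))
  # unmasked voxels stay missing
  expect_true(all(is.na(maps$maps$D[!ph$mask])))
})

test_that("empty masks and degenerate voxels are handled and counted", {
  spec <- phantom_spec(dim = c(6, 6, 1), model = "mono",
                       background = monoexp_params(1e-3),
                       lesion = monoexp_params(0.6e-3),
                       lesion_center = c(2, 2, 0), lesion_radius = 1.7)
  ph <- make_phantom(spec, protocol)
  empty <- fit_volume(ph$dwi, protocol, "mono",
                      mask = array(FALSE, c(6, 6, 1)))
  expect_equal(empty$report$n_masked, 0L)
  expect_equal(empty$report$n_fitted, 0L)
  expect_true(all(is.na(empty$maps$ADC)))
  # zero out some voxels: exactly those must be flagged missing
  dwi <- ph$dwi
  kill <- c(1L, 7L, 19L, 30L)
  for (v in kill) {
    ij <- arrayInd(v, c(6, 6, 1))
    dwi[ij[1], ij[2], ij[3], 5] <- 0
  }
  maps <- fit_volume(dwi, protocol, "mono")
  expect_equal(maps$report$n_failed, length(kill))
  expect_identical(which(is.na(maps$maps$ADC)), kill)
  # shape mismatch is caught before compute
  expect_error(fit_volume(ph$dwi[, , , 1:5], protocol, "mono"),
               class = "ivimprog_input_error")
})

test_that("parameter maps round-trip through NIfTI with labelled headers", {
  spec <- phantom_spec(dim = c(6, 6, 1), model = "mono",
                       background = monoexp_params(1e-3),
                       lesion = monoexp_params(0.6e-3),
                       lesion_center = c(2, 2, 0), lesion_radius = 1.7)
  ph <- make_phantom(spec, protocol)
  maps <- fit_volume(ph$dwi, protocol, "mono")
  dir <- withr::local_tempdir()
  write_param_maps(maps, dir)
  back <- read_param_map(file.path(dir, "mono_ADC.nii"))
  expect_equal(as.numeric(back), as.numeric(maps$maps$ADC))
  expect_match(attr(back, "descrip"), "ADC \\(mm\\^2/s\\)")
  rep <- jsonlite::read_json(file.path(dir, "mono_fit_report.json"))
  expect_equal(rep$n_fitted, maps$report$n_fitted)
})

test_that("ROI digitization respects area fidelity and the 25-50 mm^2 window", {
  expect_error(circular_roi(c(15, 15, 1), 2), class = "ivimprog_invalid_roi")
  expect_error(circular_roi(c(15, 15, 1), 5), class = "ivimprog_invalid_roi")
  pixarea <- 1.625^2
  for (area in seq(25, 50, length.out = 11)) {
    roi <- circular_roi(c(15, 15, 1), sqrt(area / pi))
    n <- sum(roi_mask(roi, c(31, 31, 3)))
    expect_gte(n, 10)
    expect_lte(n, 19)
    expect_lte(abs(n * pixarea - area), pixarea)
  }
  expect_error(roi_mask(circular_roi(c(1, 1, 0), 3.3), c(31, 31, 1)),
               class = "ivimprog_invalid_roi")
})

test_that("ROI mean signal averages voxels exactly", {
  spec <- phantom_spec(dim = c(12, 12, 3), model = "biexp",
                       background = fig1_biexp(), lesion = fig1_biexp(),
                       lesion_center = c(5, 5, 1), lesion_radius = 3.3)
  ph <- make_phantom(spec, protocol)
  roi <- circular_roi(c(5, 5, 1), 3.3)
  cv <- roi_mean_signal(ph$dwi, roi, protocol)
  expect_equal(cv$s, ph$dwi[1, 1, 1, ])  # uniform phantom: mean = voxel value
  # two-voxel ROI with intensities 100 and 200 averages to 150
  dwi <- array(100, c(12, 12, 1, 12))
  roi2 <- circular_roi(c(5.5, 5, 0), 1.0, check_area = FALSE)
  m <- roi_mask(roi2, c(12, 12, 1))
  expect_equal(sum(m), 2L)
  vox <- which(m, arr.ind = TRUE)
  dwi[vox[2, 1], vox[2, 2], 1, ] <- 200
  expect_equal(roi_mean_signal(dwi, roi2, protocol)$s, rep(150, 12))
})

test_that("ROI averaging reduces noise like one over root n voxels", {
  s0 <- 1000
  sigma <- 50
  spec0 <- phantom_spec(dim = c(12, 12, 1), model = "mono",
                        background = monoexp_params(1e-3),
                        lesion = monoexp_params(1e-3),
                        lesion_center = c(5, 5, 0), lesion_radius = 3.3,
                        s0 = s0, noise_sigma = 0)
  clean <- make_phantom(spec0, protocol)$dwi
  roi <- circular_roi(c(5, 5, 0), 3.3)
  n_vox <- sum(roi_mask(roi, c(12, 12, 1)))
  b0_mean <- vapply(1:500, function(i) {
    noisy <- add_rician_noise(clean, sigma, protocol$nex, seed = 100 + i)
    roi_mean_signal(noisy, roi, protocol)$s[1]
  }, numeric(1))
  # at SNR 20 the magnitude noise is near-Gaussian with SD sigma/sqrt(nex)
  expect_equal(sd(b0_mean), sigma / sqrt(2) / sqrt(n_vox), tolerance = 0.15)
})

test_that("ROI summaries compute ADC statistics over map voxels", {
  roi <- circular_roi(c(3, 3, 0), 3.3)
  dims <- c(8, 8, 1)
  const <- fake_maps(list(ADC = array(1.1e-3, dims)))
  s <- summarize_roi(const, roi)
  expect_equal(s$adc_mean, 1.1e-3)
  expect_equal(s$adc_max, s$adc_min)
  expect_equal(s$adc_range, 0)
  # three distinct voxels: brute-force summary
  m <- array(NA_real_, dims)
  vox <- which(roi_mask(roi, dims))
  m[vox[1:3]] <- c(0.5e-3, 1.0e-3, 1.5e-3)
  s <- summarize_roi(fake_maps(list(ADC = m)), roi)
  expect_equal(s$adc_mean, 1.0e-3)
  expect_equal(s$adc_max, 1.5e-3)
  expect_equal(s$adc_min, 0.5e-3)
  expect_equal(s$adc_range, 1.0e-3)
  # ordering invariant on random maps
  set.seed(12)
  for (i in 1:20) {
    mm <- array(runif(prod(dims), 0.1e-3, 3e-3), dims)
    s <- summarize_roi(fake_maps(list(ADC = mm)), roi)
    expect_lte(s$adc_min, s$adc_mean)
    expect_lte(s$adc_mean, s$adc_max)
  }
  # uniform truth map reproduces the generating value exactly
  s <- summarize_roi(fake_maps(list(ADC = array(1.31e-3, dims))), roi)
  expect_lt(abs(s$adc_mean - 1.31e-3), 1e-9)
  # all-missing ROI errors
  expect_error(summarize_roi(fake_maps(list(ADC = array(NA_real_, dims))), roi),
               class = "ivimprog_invalid_roi")
})

test_that("triplicate averaging is field-wise and bounded by its inputs", {
  roi <- circular_roi(c(3, 3, 0), 3.3)
  dims <- c(8, 8, 1)
  mk <- function(adc) summarize_roi(fake_maps(list(ADC = array(adc, dims))), roi)
  same <- average_triplicate(list(mk(1e-3), mk(1e-3), mk(1e-3)))
  expect_equal(same$adc_mean, 1e-3)
  trip <- average_triplicate(list(mk(0.9e-3), mk(1.0e-3), mk(1.1e-3)))
  expect_equal(trip$adc_mean, 1.0e-3)
  expect_error(average_triplicate(list(mk(1e-3), mk(1e-3))),
               class = "ivimprog_invalid_roi")
  set.seed(9)
  for (i in 1:100) {
    vals <- runif(3, 0.2e-3, 2e-3)
    out <- average_triplicate(lapply(vals, mk))
    expect_gte(out$adc_mean, min(vals))
    expect_lte(out$adc_mean, max(vals))
  }
})
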