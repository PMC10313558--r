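protocol <- default_protocol()

test_that("phantom generation is deterministic and respects its spec", {
  spec <- phantom_spec(dim = c(10, 10, 2), noise_sigma = 40, seed = 77,
                       lesion_center = c(4, 4, 0), lesion_radius = 2.5)
  ph1 <- make_phantom(spec, protocol)
  ph2 <- make_phantom(spec, protocol)
  expect_identical(ph1$dwi, ph2$dwi)
  # uniform when lesion parameters equal background parameters
  spec_u <- phantom_spec(dim = c(10, 10, 2), noise_sigma = 0,
                         background = fig2_biexp(), lesion = fig2_biexp(),
                         lesion_center = c(4, 4, 0), lesion_radius = 2.5)
  dwi <- make_phantom(spec_u, protocol)$dwi
  for (k in c(1L, 6L, 12L)) expect_equal(length(unique(c(dwi[, , , k]))), 1L)
  # lesion voxels carry lesion truth in the ground-truth maps
  expect_equal(unique(ph1$truth$D[ph1$mask]), spec$lesion$d)
  expect_equal(unique(ph1$truth$D[!ph1$mask]), spec$background$d)
})

test_that("noiseless worked-case phantom yields the printed parameters end-to-end", {
  spec <- phantom_spec(dim = c(14, 14, 3), model = "biexp",
                       background = biexp_params(1.3e-3, 20e-3, 0.1),
                       lesion = fig1_biexp(), lesion_center = c(6, 6, 1),
                       lesion_radius = 3.3, noise_sigma = 0)
  ph <- make_phantom(spec, protocol)
  maps <- fit_volume(ph$dwi, protocol, "biexp", mask = ph$mask)
  summ <- summarize_roi(maps, circular_roi(c(6, 6, 1), 3.3))
  truth <- fig1_biexp()
  expect_lt(rel_err(summ$d, truth$d), 0.01)
  expect_lt(rel_err(summ$d_star, truth$d_star), 0.01)
  expect_lt(rel_err(summ$f, truth$f), 0.01)
})

test_that("Rician noise has the Rayleigh floor and vanishes at sigma zero", {
  stack <- array(500, c(4, 4, 2, 12))
  expect_identical(add_rician_noise(stack, 0, protocol$nex), stack)
  expect_error(add_rician_noise(stack, -1, protocol$nex),
               class = "ivimprog_invalid_parameter")
  # zero signal: mean = sigma_eff * sqrt(pi / 2), per-b NEX scaling
  zeros <- array(0, c(50, 50, 40, 12))
  sigma <- 30
  noisy <- add_rician_noise(zeros, sigma, protocol$nex, seed = 4)
  for (k in c(1L, 12L)) {
    sigma_eff <- sigma / sqrt(protocol$nex[k])
    expect_equal(mean(noisy[, , , k]), sigma_eff * sqrt(pi / 2),
                 tolerance = 0.02)
  }
  # high SNR: no material magnitude bias at b = 0
  s0 <- 1000
  highsnr <- add_rician_noise(array(s0, c(30, 30, 10, 12)), s0 / 100,
                              protocol$nex, seed = 8)
  expect_lt(abs(mean(highsnr[, , , 1]) - s0) / s0, 0.005)
})

test_that("magnitude bias keeps noisy signal means above noiseless means", {
  spec <- phantom_spec(dim = c(32, 32, 6), model = "biexp",
                       background = fig2_biexp(), lesion = fig2_biexp(),
                       lesion_center = c(14, 14, 2), lesion_radius = 3.3,
                       s0 = 1000, noise_sigma = 0)
  clean <- make_phantom(spec, protocol)$dwi
  noisy <- add_rician_noise(clean, 100, protocol$nex, seed = 21)  # s0 / 10
  for (k in seq_len(12)) {
    expect_gte(mean(noisy[, , , k]), mean(clean[, , , k]))
  }
})

test_that("cohort simulation is deterministic with the documented structure", {
  spec <- cohort_spec(seed = 88)
  t1 <- simulate_cohort(spec)
  t2 <- simulate_cohort(spec)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 45L)
  expect_equal(sum(t1$group == "failure"), 31L)
  # control patients: administratively censored at 60 months, no events
  ctrl <- t1[t1$group == "control", ]
  expect_true(all(ctrl$pfs_months == 60))
  expect_true(all(!ctrl$event))
  expect_true(all(t1$pfs_months > 0))
  expect_true(all(t1$f > 0 & t1$f < 100))
  expect_true(all(t1$alpha > 0 & t1$alpha <= 1))
  # zero SD pins a parameter at its mean
  pars <- default_cohort_params()
  pars$sd_failure[pars$parameter == "ADCmean"] <- 0
  t3 <- simulate_cohort(cohort_spec(params = pars, seed = 88))
  expect_true(all(t3$ADCmean[t3$group == "failure"] == 1.00))
  # infeasible truncation target errors
  bad <- default_cohort_params()
  bad$mean_failure[bad$parameter == "alpha"] <- 1.5
  expect_error(simulate_cohort(cohort_spec(params = bad)),
               class = "ivimprog_infeasible_truncation")
})

test_that("post-truncation moments are calibrated at n = 1e5", {
  big <- simulate_cohort(cohort_spec(n_failure = 1e5, n_control = 1e5,
                                     seed = 314))
  pars <- default_cohort_params()
  # rows whose printed SD is achievable for a truncated normal on the
  # stated support; the others (DDC both groups, D* control, alpha
  # control) keep an exact mean with the closest attainable SD
  sd_ok <- list(failure = setdiff(pars$parameter, "DDC"),
                control = setdiff(pars$parameter, c("DDC", "Dstar", "alpha")))
  for (grp in c("failure", "control")) {
    sub <- big[big$group == grp, ]
    for (i in seq_len(nrow(pars))) {
      m <- pars[[paste0("mean_", grp)]][i]
      s <- pars[[paste0("sd_", grp)]][i]
      x <- sub[[pars$parameter[i]]]
      expect_lt(abs(mean(x) - m) / m, 0.01)
      if (pars$parameter[i] %in% sd_ok[[grp]])
        expect_lt(abs(sd(x) - s) / s, 0.01)
    }
  }
  # censored failure-group PFS reproduces the target moments
  pf <- big$pfs_months[big$group == "failure"]
  expect_lt(abs(mean(pf) - 13.97) / 13.97, 0.01)
  expect_lt(abs(sd(pf) - 12.31) / 12.31, 0.02)
})

test_that("injected proportional-hazards effects are recovered by Cox", {
  tab <- simulate_cohort(cohort_spec(n_failure = 500, n_control = 500,
                                     seed = 55))
  # null effect: covariate independent of survival
  null <- inject_effect(tab, "ADCmean", hazard_ratio = 1, seed = 2)
  fit <- survival::coxph(survival::Surv(pfs_months, event) ~ ADCmean,
                         data = null, ties = "efron")
  ci <- exp(confint(fit))
  expect_lt(ci[1], 1)
  expect_gt(ci[2], 1)
  # a strong effect flips the estimate in the right direction
  eff <- inject_effect(tab, "Dstar", hazard_ratio = 1.01, seed = 3)
  fit2 <- survival::coxph(survival::Surv(pfs_months, event) ~ Dstar,
                          data = eff, ties = "efron")
  expect_gt(exp(coef(fit2)), 1)
  expect_true(!is.null(attr(eff, "injected")))
  expect_error(inject_effect(tab, "nope", 1.2), class = "ivimprog_input_error")
  expect_error(inject_effect(tab, "Dstar", -1), class = "ivimprog_input_error")
})
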