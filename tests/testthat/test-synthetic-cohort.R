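test_that("zero texture contrast gives a constant tumour interior", {
  cfg <- cohort_config(n_subjects = 2, vol_dim = c(16, 16, 16),
                       roi_semiaxes = c(5, 4, 4),
                       texture = list(contrast_mean = 0, contrast_sd = 0,
                                      contrast_min = 0),
                       seed = 1)
  s <- generate_phantom(cfg, 1)
  inside <- s$volumes$PDw$data[s$roi > 0]
  expect_equal(max(inside) - min(inside), 0)
  expect_equal(s$truth$roi_variance, 0)
})

test_that("phantom generation is deterministic given config and seed", {
  cfg <- cohort_config(n_subjects = 3, vol_dim = c(16, 16, 16),
                       roi_semiaxes = c(5, 4, 4), seed = 7)
  a <- generate_phantom(cfg, 2)
  b <- generate_phantom(cfg, 2)
  expect_identical(a$volumes$PDw$data, b$volumes$PDw$data)
  expect_identical(a$truth$ktrans, b$truth$ktrans)
})

test_that("doubling the contrast parameter increases in-ROI variance", {
  wins <- vapply(1:20, function(seed) {
    lo <- cohort_config(n_subjects = 2, vol_dim = c(16, 16, 16),
                        roi_semiaxes = c(5, 4, 4),
                        texture = list(contrast_mean = 10, contrast_sd = 0),
                        seed = seed)
    hi <- cohort_config(n_subjects = 2, vol_dim = c(16, 16, 16),
                        roi_semiaxes = c(5, 4, 4),
                        texture = list(contrast_mean = 20, contrast_sd = 0),
                        seed = seed)
    v_lo <- generate_phantom(lo, 1)$truth$roi_variance
    v_hi <- generate_phantom(hi, 1)$truth$roi_variance
    v_hi > v_lo
  }, TRUE)
  expect_true(all(wins))
})

test_that("ROI larger than the volume is rejected", {
  expect_error(ellipsoid_mask(c(10, 10, 10), c(8, 3, 3)), "fit inside")
})

test_that("null and plasma-only kinetics give exact closed forms", {
  tt <- seq(0, 5, length.out = 30)
  aif <- population_aif(tt)
  null <- simulate_dce(list(ktrans = 0, ve = 0.1, vp = 0), aif, tt)
  expect_equal(as.numeric(null$data), rep(0, 30))
  plasma <- simulate_dce(list(ktrans = 0, ve = 0.1, vp = 0.05), aif, tt)
  expect_equal(as.numeric(plasma$data[1, 1, 1, ]), 0.05 * aif)
})

test_that("ve = 0 with positive K-trans is rejected", {
  tt <- seq(0, 5, length.out = 10)
  expect_error(
    simulate_dce(list(ktrans = 0.2, ve = 0, vp = 0.05),
                 population_aif(tt), tt),
    "undefined k-ep")
})

test_that("DCE forward model matches a fine-grid quadrature oracle", {
  tt <- seq(0, 5, length.out = 200)
  aif <- population_aif(tt)
  sim <- simulate_dce(list(ktrans = 0.2, ve = 0.4, vp = 0.05), aif, tt)
  ct <- as.numeric(sim$data[1, 1, 1, ])
  ct_oracle <- oracle_tofts(0.2, 0.4, 0.05, tt, aif)
  rel <- abs(ct - ct_oracle)[-1] / pmax(abs(ct_oracle)[-1], 1e-12)
  expect_lt(max(rel[ct_oracle[-1] > 1e-3]), 0.001)
})

test_that("noiseless simulation is reproducible and noise respects the seed", {
  tt <- seq(0, 5, length.out = 20)
  aif <- population_aif(tt)
  truth <- list(ktrans = 0.2, ve = 0.4, vp = 0.05)
  a <- simulate_dce(truth, aif, tt, noise_sd = 0.05, seed = 3)
  b <- simulate_dce(truth, aif, tt, noise_sd = 0.05, seed = 3)
  expect_identical(a$data, b$data)
  c0 <- simulate_dce(truth, aif, tt, noise_sd = 0)
  expect_false(identical(a$data, c0$data))
})

test_that("with beta = 0 and no censoring, times are exponential(h0)", {
  z <- matrix(rnorm(1000), 1000, 1)
  s <- generate_survival(z, h0 = 0.05, beta = 0, censor_rate = 0, seed = 2)
  expect_true(all(s$event == 1))
  # mean of Exp(0.05) is 20, SE = 20/sqrt(1000)
  expect_lt(abs(mean(s$time_months) - 20), 3 * 20 / sqrt(1000))
})

test_that("censored fraction tracks the target rate", {
  z <- matrix(rnorm(400), 400, 1)
  for (target in c(0.2, 0.5)) {
    s <- generate_survival(z, h0 = 0.03, beta = 0.5, censor_rate = target,
                           seed = 4)
    expect_lt(abs(mean(s$event == 0) - target), 0.05)
  }
})

test_that("raising the linear predictor of a subgroup shortens its survival", {
  wins <- vapply(1:20, function(seed) {
    z <- matrix(c(rep(0, 100), rep(1, 100)), 200, 1)
    s <- generate_survival(z, h0 = 0.02, beta = 1, censor_rate = 0,
                           seed = seed)
    median(s$time_months[101:200]) < median(s$time_months[1:100])
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("cohort simulation is deterministic and writes a lossless manifest", {
  cfg <- cohort_config(n_subjects = 3, vol_dim = c(12, 12, 12),
                       roi_semiaxes = c(4, 3, 3),
                       dce_times = seq(0, 3, length.out = 8), seed = 5)
  coh1 <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh1$survival, coh2$survival)
  expect_identical(coh1$subjects[[3]]$dce$data, coh2$subjects[[3]]$dce$data)

  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh1, dir)
  expect_equal(sum(manifest$kind == "mask"), 3)
  surv <- read.csv(manifest$path[manifest$kind == "survival"])
  expect_equal(nrow(surv), 3)

  back <- read_cohort(manifest)
  expect_equal(back$subjects[[1]]$volumes$PDw$data,
               coh1$subjects[[1]]$volumes$PDw$data, tolerance = 1e-6)
  expect_equal(back$subjects[[1]]$dce$times, coh1$subjects[[1]]$dce$times)
  expect_equal(back$survival$time_months, coh1$survival$time_months)
})
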