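test_that("sigma of the attenuation factor follows Poisson error propagation", {
  expect_equal(sigma_attenuation_factor(1e4, 1e3), sqrt(1.1e-3))
  expect_equal(sigma_attenuation_factor(100, 100), sqrt(2 / 100))
  # ideal-reference limit: dropping the air term leaves sqrt(1/C')
  expect_equal(sigma_attenuation_factor(1e12, 400),
               sqrt(1 / 400), tolerance = 1e-3)
  expect_equal(sigma_attenuation_factor(100, 400, include_air_noise = FALSE),
               sqrt(1 / 400))
  expect_identical(sigma_attenuation_factor(0, 100), Inf)
})

condition_budget <- function(kv, eb, mat_name, t_mm, n, include_air_noise = TRUE) {
  mat <- pc_material(mat_name)
  setup <- pcthresh:::condition_setup(kv, eb, mat, t_mm, n_total = n)
  ca <- bin_counts(setup$spectrum_air, setup$bins)$counts
  co <- bin_counts(transmit(setup$spectrum_air, mat, t_mm), setup$bins)$counts
  propagate_sigma_z(ca, co, setup$curves, setup$calibration, include_air_noise)
}

test_that("propagated sigma(Z) scales as 1/sqrt(N) and vanishes without noise", {
  b4 <- condition_budget(80, 37, "pmma", 80, 1e4)
  b6 <- condition_budget(80, 37, "pmma", 80, 1e6)
  expect_equal(b4$sigma_z / b6$sigma_z, 10, tolerance = 1e-6)
  # doubling all counts scales sigma(Z) by 1/sqrt(2)
  b2 <- condition_budget(80, 37, "pmma", 80, 2e4)
  expect_equal(b4$sigma_z / b2$sigma_z, sqrt(2), tolerance = 1e-6)
  # zero-count bins yield the infinite-uncertainty sentinel
  mat <- pc_material("pmma")
  setup <- pcthresh:::condition_setup(80, 37, mat, 80, n_total = 1e4)
  bad <- propagate_sigma_z(c(0, 10), c(5, 5), setup$curves, setup$calibration)
  expect_identical(bad$sigma_z, Inf)
  expect_false(bad$valid)
})

test_that("sigma(Z) blows up toward both edges of the threshold range", {
  for (mat in c("pmma", "al")) {
    t_mm <- if (mat == "pmma") 80 else 8
    sig <- vapply(c(21, 35, 59), function(eb)
      condition_budget(60, eb, mat, t_mm, 1e5)$sigma_z, 0)
    expect_gt(sig[1], sig[2])
    expect_gt(sig[3], sig[2])
  }
})

test_that("analytic sigma(Z) matches a large-repeat Monte-Carlo SD at a mid threshold", {
  an <- condition_budget(60, 35, "pmma", 80, 1e5)
  mc <- mc_summary(60, 35, "pmma", 80, n_total = 1e5, n_repeats = 4000,
                   master_seed = 123)
  expect_equal(mc$z_sd, an$sigma_z, tolerance = 0.1)
  expect_equal(mc$z_mean, 6.47, tolerance = 0.05)
})

test_that("mc_summary is reproducible and reports invalid repeats", {
  a <- mc_summary(80, 37, "al", 8, n_total = 1e4, n_repeats = 5, master_seed = 7)
  b <- mc_summary(80, 37, "al", 8, n_total = 1e4, n_repeats = 5, master_seed = 7)
  expect_identical(a, b)
  c <- mc_summary(80, 37, "al", 8, n_total = 1e4, n_repeats = 5, master_seed = 8)
  expect_false(identical(a$z_mean, c$z_mean))
  expect_error(mc_summary(80, 37, "al", 8, n_total = 1e4, n_repeats = 1),
               class = "pcthresh_config_error")

  # a 5-repeat SD is itself noisy: only a wide consistency band is expected
  an <- condition_budget(80, 37, "al", 8, 1e5)
  m5 <- mc_summary(80, 37, "al", 8, n_total = 1e5, n_repeats = 5,
                   master_seed = 21)
  expect_gt(m5$z_sd, an$sigma_z / 3)
  expect_lt(m5$z_sd, an$sigma_z * 3)
})

test_that("starved bins at extreme thresholds are flagged, not fatal", {
  # 1e3 total counts, threshold at the spectrum endpoint: the high bin is
  # nearly empty and some repeats draw zero counts
  m <- mc_summary(60, 59, "al", 16, n_total = 1e3, n_repeats = 50,
                  master_seed = 5)
  expect_gte(m$n_invalid, 1)
  expect_true(is.na(m$z_mean) || is.finite(m$z_mean))
})
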