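test_that("attenuation factor is ln(C/C') with the documented edge behaviour", {
  expect_equal(attenuation_factor(100, 100)$value, 0)
  expect_equal(attenuation_factor(exp(1) * 50, 50)$value, 1)
  expect_error(attenuation_factor(100, 0), class = "pcthresh_invalid_measurement")
  under_noise <- attenuation_factor(90, 100)
  expect_lt(under_noise$value, 0)
  expect_true(under_noise$negative)

  # brute-force channel summation oracle: 60 kV, PMMA 80 mm, Eb = 35, BIN1
  s <- generate_spectrum(60) |> normalize_to_counts(1e5)
  pmma <- pc_material("pmma")
  obj <- transmit(s, pmma, 80)
  bins <- bin_config(60, 35)
  bc_air <- bin_counts(s, bins)$counts
  bc_obj <- bin_counts(obj, bins)$counts
  sel <- s$energy_kev >= 20 & s$energy_kev < 35
  expect_equal(attenuation_factor(bc_air[1], bc_obj[1])$value,
               log(sum(s$fluence[sel]) / sum(obj$fluence[sel])),
               tolerance = 1e-12)
})

test_that("effective energy is the count-weighted mean of the air bin", {
  one <- make_spectrum(c(0, 0, 7, 0, 0), e_min = 20, tube_voltage = 30)
  expect_equal(effective_energy(one, bin_config(30, 25), "bin1"), 22.5)
  two <- make_spectrum(c(0, 3, 3, 0), e_min = 20, tube_voltage = 30)
  expect_equal(effective_energy(two, bin_config(30, 24), "bin1"), 22)
  empty <- make_spectrum(c(1, 0, 0), e_min = 20, tube_voltage = 23)
  expect_error(effective_energy(empty, bin_config(23, 21), "bin2"),
               class = "pcthresh_invalid_measurement")

  s <- generate_spectrum(60) |> normalize_to_counts(1e5)
  bins <- bin_config(60, 35)
  sel <- s$energy_kev >= 35 & s$energy_kev < 60
  expect_equal(effective_energy(s, bins, "bin2"),
               sum((s$energy_kev[sel] + 0.5) * s$fluence[sel]) /
                 sum(s$fluence[sel]),
               tolerance = 1e-12)
})

test_that("beam-hardening curve is monotone, zero at zero, and matches the forward model", {
  s <- generate_spectrum(60) |> normalize_to_counts(1e5)
  pmma <- pc_material("pmma")
  bins <- bin_config(60, 35)
  curve <- build_bh_curve(s, bins, "bin1", pmma, rho_t_max = 2 * 1.19 * 16)
  expect_equal(curve$mu_prime_t[1], 0)
  expect_true(all(diff(curve$mu_prime_t) > 0))
  expect_true(curve$e_eff > 20 && curve$e_eff < 35)

  # grid-free oracle: mu't at rho_t = 1.19 * 8 g/cm^2 from an independent
  # 80 mm transmission
  curve8 <- build_bh_curve(s, bins, "bin1", pmma, rho_t_max = 1.19 * 8)
  bc_air <- bin_counts(s, bins)$counts
  bc_obj <- bin_counts(transmit(s, pmma, 80), bins)$counts
  expect_equal(tail(curve8$mu_prime_t, 1), log(bc_air[1] / bc_obj[1]),
               tolerance = 1e-10)
})

test_that("beam-hardening correction inverts the forward map", {
  s <- generate_spectrum(60) |> normalize_to_counts(1e5)
  pmma <- pc_material("pmma")
  bins <- bin_config(60, 35)
  curve <- build_bh_curve(s, bins, "bin1", pmma, rho_t_max = 2 * 1.19 * 16)

  zero <- correct_beam_hardening(attenuation_factor(50, 50), curve)
  expect_equal(zero$value, 0)
  expect_true(zero$corrected)

  # round trip: mu't generated from thickness t recovers rho * t
  for (t_mm in c(20, 80, 160)) {
    bc_air <- bin_counts(s, bins)$counts
    bc_obj <- bin_counts(transmit(s, pmma, t_mm), bins)$counts
    raw <- attenuation_factor(bc_air[1], bc_obj[1])
    corrected <- correct_beam_hardening(raw, curve)
    expect_equal(corrected$rho_t, 1.19 * t_mm / 10, tolerance = 1e-3)
    # and the corrected value sits on the monochromatic line
    expect_equal(corrected$value, curve$slope * corrected$rho_t)
  }

  # a value between grid points inverts between the bracketing grid rho_t
  i <- 100
  mid <- (curve$mu_prime_t[i] + curve$mu_prime_t[i + 1]) / 2
  corrected <- correct_beam_hardening(
    structure(list(value = mid, bin = "bin1", corrected = FALSE,
                   negative = FALSE), class = "pc_mu"), curve)
  expect_gt(corrected$rho_t, curve$rho_t[i])
  expect_lt(corrected$rho_t, curve$rho_t[i + 1])

  # above-range input names the remedy
  expect_error(correct_beam_hardening(attenuation_factor(1e9, 1), curve),
               "rho_t_max", class = "pcthresh_range_error")
  # negative input clamps to zero with a warning
  expect_warning(
    clamped <- correct_beam_hardening(attenuation_factor(90, 100), curve),
    "clamped")
  expect_equal(clamped$value, 0)
})

test_that("calibration curve is monotone and matches direct table lookups", {
  els <- calibration_elements()
  expect_error(build_calibration_curve(els, 40, 40),
               class = "pcthresh_config_error")
  cal <- build_calibration_curve(els, 35, 55)
  expect_true(all(diff(cal$z[order(cal$x)]) < 0))

  # Al entry at (30, 50) keV equals the ratio of the two fixture lookups
  cal2 <- build_calibration_curve(els, 30, 50)
  al <- els$tables[[which(els$z == 13)]]
  x_al <- mass_attenuation(al, 50) / mass_attenuation(al, 30)
  expect_equal(cal2$x[cal2$z == 13], x_al, tolerance = 1e-12)
})

test_that("calibration inversion returns each element's own Z exactly", {
  els <- calibration_elements()
  cal <- build_calibration_curve(els, 32, 58)
  for (k in seq_along(els$z)) {
    x_k <- mass_attenuation(els$tables[[k]], 58) /
      mass_attenuation(els$tables[[k]], 32)
    est <- estimate_z(corrected_mu(1, "bin1"), corrected_mu(x_k, "bin2"), cal)
    expect_equal(est$z, as.double(els$z[k]), tolerance = 1e-9)
    expect_false(est$out_of_range)
  }
  # out-of-range X clamps with a flag
  oob <- estimate_z(corrected_mu(1, "bin1"), corrected_mu(0.01, "bin2"), cal)
  expect_true(oob$out_of_range)
  expect_equal(oob$z, 20)
  expect_error(estimate_z(attenuation_factor(2, 1), corrected_mu(1, "bin2"), cal),
               class = "pcthresh_config_error")
})

test_that("noise-free estimates recover nominal Z independent of thickness and threshold", {
  # spot-check across the condition grid; the full grid runs in the
  # acceptance suite
  for (cond in list(list(kv = 50, eb = 25), list(kv = 80, eb = 37),
                    list(kv = 120, eb = 100))) {
    z_pmma <- vapply(c(20, 40, 80, 160), function(t)
      estimate_condition(cond$kv, cond$eb, "pmma", t)$z, 0)
    z_al <- vapply(c(2, 4, 8, 16), function(t)
      estimate_condition(cond$kv, cond$eb, "al", t)$z, 0)
    expect_true(all(abs(z_pmma - 6.5) < 0.2))
    expect_true(all(abs(z_al - 13) < 0.2))
    # thickness independence: estimates agree with each other even closer
    expect_lt(diff(range(z_pmma)), 0.02)
    expect_lt(diff(range(z_al)), 0.02)
  }
})
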