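#' Standard deviation of an attenuation factor
#'
#' First-order propagation of independent Poisson counting noise
#' (\eqn{\sigma(C) = \sqrt{C}}) through \eqn{\mu' t = \ln(C/C')}:
#' \eqn{\sigma(\mu' t) = \sqrt{1/C + 1/C'}}.  With `include_air_noise =
#' FALSE` the air scan is treated as ideal and the \eqn{1/C} term is
#' dropped.
#'
#' @param c_air Air bin counts.
#' @param c_obj Object bin counts.
#' @param include_air_noise Include the air-count term (default `TRUE`).
#' @return \eqn{\sigma(\mu' t)} (dimensionless); `Inf` if either count is
#'   zero or negative (condition unanalyzable).
#' @export
sigma_attenuation_factor <- function(c_air, c_obj, include_air_noise = TRUE) {
  bad <- c_air <= 0 | c_obj <= 0
  out <- sqrt(ifelse(include_air_noise, 1 / c_air, 0) + 1 / c_obj)
  out[bad] <- Inf
  out
}

#' Analytic uncertainty of the Z estimate
#'
#' Propagates per-bin Poisson counting noise through the full estimation
#' chain by the delta method: \eqn{\sigma(\mu' t) = \sqrt{1/C + 1/C'}} per
#' bin, then through the beam-hardening correction with the locally
#' evaluated numerical slope \eqn{d\mu t/d\mu' t = \text{slope}_{mono} \cdot
#' d\rho t/d\mu' t}, then into the ratio
#' \eqn{\sigma(X) = X \sqrt{(\sigma(\mu_2 t)/\mu_2 t)^2 +
#' (\sigma(\mu_1 t)/\mu_1 t)^2}} (bins are disjoint energy ranges, hence
#' independent), and finally \eqn{\sigma(Z) = |dZ/dX| \, \sigma(X)} with the
#' calibration slope from central finite differences.
#'
#' @param c_air,c_obj Length-2 vectors of ideal (expected) bin counts,
#'   `(bin1, bin2)`.
#' @param bh_curves List with elements `bin1`, `bin2` from
#'   [build_bh_curve()].
#' @param calibration A [build_calibration_curve()] result.
#' @param include_air_noise Include the \eqn{1/C} term (see
#'   [sigma_attenuation_factor()]).
#' @return A one-row tibble uncertainty budget: per-bin counts, `mu_prime_t`
#'   and `mu_t` per bin, per-stage sigmas, `x`, `z`, `dz_dx`, `sigma_z`, and
#'   flags (`valid`, `boundary`).
#' @export
propagate_sigma_z <- function(c_air, c_obj, bh_curves, calibration,
                              include_air_noise = TRUE) {
  stopifnot(length(c_air) == 2, length(c_obj) == 2,
            inherits(calibration, "pc_calibration"))
  if (any(c_air <= 0) || any(c_obj <= 0)) {
    return(tibble(
      c_air_bin1 = c_air[1], c_air_bin2 = c_air[2],
      c_obj_bin1 = c_obj[1], c_obj_bin2 = c_obj[2],
      mu_prime_t1 = NA_real_, mu_prime_t2 = NA_real_,
      mu_t1 = NA_real_, mu_t2 = NA_real_,
      sigma_mu_prime_t1 = Inf, sigma_mu_prime_t2 = Inf,
      sigma_mu_t1 = Inf, sigma_mu_t2 = Inf,
      x = NA_real_, z = NA_real_, sigma_x = Inf, dz_dx = NA_real_,
      sigma_z = Inf, valid = FALSE, boundary = NA
    ))
  }
  mu_prime <- log(c_air / c_obj)
  sigma_mu_prime <- sigma_attenuation_factor(c_air, c_obj, include_air_noise)
  rho_t <- vapply(1:2, function(b) bh_invert(bh_curves[[b]], mu_prime[b]), 0)
  mu_t <- c(bh_curves$bin1$slope, bh_curves$bin2$slope) * rho_t
  drho_dmu <- vapply(1:2, function(b) bh_slope(bh_curves[[b]], mu_prime[b]), 0)
  sigma_mu_t <- c(bh_curves$bin1$slope, bh_curves$bin2$slope) *
    drho_dmu * sigma_mu_prime
  x <- mu_t[2] / mu_t[1]
  sigma_x <- abs(x) * sqrt((sigma_mu_t[2] / mu_t[2])^2 +
                             (sigma_mu_t[1] / mu_t[1])^2)
  inv <- calibration_invert(calibration, x)
  sl <- calibration_slope(calibration, x)
  sigma_z <- abs(sl$slope) * sigma_x
  tibble(
    c_air_bin1 = c_air[1], c_air_bin2 = c_air[2],
    c_obj_bin1 = c_obj[1], c_obj_bin2 = c_obj[2],
    mu_prime_t1 = mu_prime[1], mu_prime_t2 = mu_prime[2],
    mu_t1 = mu_t[1], mu_t2 = mu_t[2],
    sigma_mu_prime_t1 = sigma_mu_prime[1], sigma_mu_prime_t2 = sigma_mu_prime[2],
    sigma_mu_t1 = sigma_mu_t[1], sigma_mu_t2 = sigma_mu_t[2],
    x = x, z = inv$z, sigma_x = sigma_x, dz_dx = sl$slope,
    sigma_z = sigma_z,
    valid = is.finite(sigma_z) && !is.na(rho_t[1]) && !is.na(rho_t[2]),
    boundary = sl$boundary
  )
}

# Vectorized noisy pipeline used by mc_summary(): given matrices of noisy
# bin counts (repeats in columns), returns the per-repeat Z estimate (NA for
# unanalyzable repeats: a non-positive bin count or mu't above the curve).
mc_estimate_z <- function(ca1, ca2, co1, co2, curves, calibration) {
  bad <- ca1 <= 0 | ca2 <= 0 | co1 <= 0 | co2 <= 0
  mu_prime1 <- log(ca1 / co1)
  mu_prime2 <- log(ca2 / co2)
  bad <- bad | mu_prime1 > max(curves$bin1$mu_prime_t) |
    mu_prime2 > max(curves$bin2$mu_prime_t)
  rho1 <- bh_invert(curves$bin1, mu_prime1)
  rho2 <- bh_invert(curves$bin2, mu_prime2)
  mu_t1 <- curves$bin1$slope * rho1
  mu_t2 <- curves$bin2$slope * rho2
  bad <- bad | !is.finite(mu_t1) | !is.finite(mu_t2) | mu_t1 <= 0
  x <- mu_t2 / mu_t1
  z <- rep(NA_real_, length(x))
  ok <- !bad & is.finite(x)
  if (any(ok)) z[ok] <- calibration_invert(calibration, x[ok])$z
  z
}

#' Monte-Carlo summary of the noisy Z estimate
#'
#' Runs the full noisy pipeline `n_repeats` times with distinct child seeds
#' derived from `master_seed` (see [child_seed()]) and summarises the mean
#' and sample standard deviation of the Z estimate.  Per-channel Poisson
#' noise is applied to both the air and the object spectrum (the air term
#' can be disabled with `noise_air = FALSE`); the beam-hardening and
#' calibration curves are precomputed from the ideal spectrum, exactly as in
#' a calibrated acquisition.
#'
#' @inheritParams estimate_condition
#' @param n_total Total incident photons over the whole air spectrum.
#' @param n_repeats Number of Monte-Carlo repetitions (>= 2; default 5).
#' @param master_seed Master seed expanded into per-repeat child seeds.
#' @param cell_index Condition index used in the child-seed rule (default 1;
#'   [run_sweep()] passes the grid row).
#' @return A one-row tibble: condition columns, `z_mean`, `z_sd`,
#'   `n_repeats`, `n_invalid`.
#' @export
#' @examples
#' mc_summary(60, 35, "pmma", 80, n_total = 1e5, master_seed = 1)
mc_summary <- function(tube_voltage_kv, e_b, material, thickness_mm, n_total,
                       n_repeats = 5, master_seed = 1, cell_index = 1L,
                       noise_air = TRUE,
                       e_a = 20, filtration_mm_al = 2.5,
                       elements = calibration_elements(),
                       model = spectrum_model(),
                       bh_n_grid = 256) {
  if (n_repeats < 2) {
    abort("n_repeats must be at least 2 for a defined SD",
          class = "pcthresh_config_error")
  }
  if (is.character(material)) material <- pc_material(material)
  setup <- condition_setup(tube_voltage_kv, e_b, material, thickness_mm,
                           n_total = n_total, e_a = e_a,
                           filtration_mm_al = filtration_mm_al,
                           elements = elements, model = model,
                           bh_n_grid = bh_n_grid)
  spec_air <- setup$spectrum_air
  spec_obj <- transmit(spec_air, material, thickness_mm)
  e <- spec_air$energy_kev
  sel1 <- e >= setup$bins$e_a & e < setup$bins$e_b
  sel2 <- e >= setup$bins$e_b & e < setup$bins$e_c
  nch <- length(e)
  seeds <- child_seed(master_seed, cell_index, seq_len(n_repeats))
  # each repeat is fully determined by its child seed: the air draw then the
  # object draw come from that one seeded stream
  counts <- vapply(seq_len(n_repeats), function(r) {
    withr::with_seed(seeds[r], {
      air <- if (noise_air) rpois(nch, spec_air$fluence) else spec_air$fluence
      obj <- rpois(nch, spec_obj$fluence)
      c(sum(air[sel1]), sum(air[sel2]), sum(obj[sel1]), sum(obj[sel2]))
    })
  }, numeric(4))
  z <- mc_estimate_z(counts[1, ], counts[2, ], counts[3, ], counts[4, ],
                     setup$curves, setup$calibration)
  n_invalid <- sum(is.na(z))
  if (n_invalid == n_repeats) {
    z_mean <- NA_real_
    z_sd <- NA_real_
  } else {
    z_mean <- mean(z, na.rm = TRUE)
    z_sd <- if (sum(!is.na(z)) >= 2) sd(z, na.rm = TRUE) else NA_real_
  }
  tibble(
    tube_voltage_kv = tube_voltage_kv, e_b = e_b,
    material = material$material, thickness_mm = thickness_mm,
    n_total = n_total, z_mean = z_mean, z_sd = z_sd,
    n_repeats = n_repeats, n_invalid = n_invalid
  )
}
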