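#' Attenuation factor of one bin
#'
#' Step 1 of the estimation algorithm: \eqn{\mu' t = \ln(C / C')} with
#' \eqn{C} the bin counts through air and \eqn{C'} the bin counts behind the
#' object.  Under noise \eqn{C' > C} can occur; the value is then negative
#' and flagged.  A zero or negative \eqn{C'} (fully absorbed or
#' noise-starved bin) signals an invalid measurement.
#'
#' @param c_air Bin counts without the object (> 0).
#' @param c_obj Bin counts with the object (> 0).
#' @param bin Bin label (`"bin1"` or `"bin2"`).
#' @return A `pc_mu` object: `value`, `bin`, `corrected = FALSE`, `negative`
#'   flag.
#' @export
attenuation_factor <- function(c_air, c_obj, bin = "bin1") {
  if (c_air <= 0 || c_obj <= 0) {
    abort(sprintf("non-positive bin counts (C = %g, C' = %g): condition unanalyzable",
                  c_air, c_obj),
          class = "pcthresh_invalid_measurement")
  }
  value <- log(c_air / c_obj)
  structure(list(value = value, bin = bin, corrected = FALSE,
                 negative = value < 0),
            class = "pc_mu")
}

#' @export
print.pc_mu <- function(x, ...) {
  cat(sprintf("<pc_mu> %s %s = %.6g%s\n", x$bin,
              if (x$corrected) "mu*t" else "mu't", x$value,
              if (isTRUE(x$negative)) " [negative]" else ""))
  invisible(x)
}

#' Effective energy of a bin
#'
#' The count-weighted mean channel-centre energy of the unattenuated (air)
#' spectrum within the bin.  It is the energy at which the monochromatic
#' reference line \eqn{\mu t = (\mu/\rho)(E_{eff}) \rho t} is drawn for the
#' beam-hardening correction.
#'
#' @param spectrum_air The air (no object) `pc_spectrum`.
#' @param bins A [bin_config()].
#' @param bin `"bin1"` or `"bin2"`.
#' @return Effective energy in keV.
#' @export
effective_energy <- function(spectrum_air, bins, bin = c("bin1", "bin2")) {
  bin <- match.arg(bin)
  e <- spectrum_air$energy_kev
  lo <- if (bin == "bin1") bins$e_a else bins$e_b
  hi <- if (bin == "bin1") bins$e_b else bins$e_c
  sel <- e >= lo & e < hi
  w <- spectrum_air$fluence[sel]
  if (sum(w) <= 0) {
    abort(sprintf("empty %s: no counts in [%g, %g) keV", bin, lo, hi),
          class = "pcthresh_invalid_measurement")
  }
  sum((e[sel] + 0.5) * w) / sum(w)
}

#' Beam-hardening correction curve for one bin
#'
#' Step 2 preparation: tabulates the polychromatic attenuation factor
#' \eqn{\mu' t(\rho t)} of a material over a mass-thickness grid using the
#' full forward model (Beer-Lambert transmission of the air spectrum, bin
#' integration, log ratio), together with the monochromatic slope
#' \eqn{(\mu/\rho)(E_{eff})} that defines the linear reference
#' \eqn{\mu t = \text{slope} \cdot \rho t}.
#'
#' @param spectrum_air The air `pc_spectrum`.
#' @param bins A [bin_config()].
#' @param bin `"bin1"` or `"bin2"`.
#' @param material A `pc_attenuation` with density.
#' @param rho_t_max Upper end of the mass-thickness grid (g/cm\eqn{^2});
#'   should be at least twice the largest analyzed mass thickness.
#' @param n_grid Number of grid points (default 256).
#' @return A `pc_bh_curve`: grids `rho_t`, `mu_prime_t`, the monochromatic
#'   `slope` (cm\eqn{^2}/g), `e_eff`, and metadata.
#' @export
build_bh_curve <- function(spectrum_air, bins, bin, material, rho_t_max,
                           n_grid = 256) {
  stopifnot(inherits(material, "pc_attenuation"), rho_t_max > 0, n_grid >= 8)
  e <- spectrum_air$energy_kev
  lo <- if (bin == "bin1") bins$e_a else bins$e_b
  hi <- if (bin == "bin1") bins$e_b else bins$e_c
  sel <- e >= lo & e < hi
  fl <- spectrum_air$fluence[sel]
  c_air <- sum(fl)
  if (c_air <= 0) {
    abort(sprintf("empty %s in air spectrum", bin),
          class = "pcthresh_invalid_measurement")
  }
  mu_ch <- mass_attenuation(material, e[sel] + 0.5)
  rho_t <- seq(0, rho_t_max, length.out = n_grid)
  # channels x grid transmission; bin counts behind each mass thickness
  c_obj <- as.vector(crossprod(fl, exp(-outer(mu_ch, rho_t))))
  mu_prime_t <- log(c_air / c_obj)
  if (any(diff(mu_prime_t) <= 0)) {
    abort("polychromatic curve is not strictly increasing",
          class = "pcthresh_internal_error")
  }
  e_eff <- sum((e[sel] + 0.5) * fl) / c_air
  structure(
    list(material = material$material, bin = bin, e_eff = e_eff,
         rho_t = rho_t, mu_prime_t = mu_prime_t,
         slope = mass_attenuation(material, e_eff),
         tube_voltage = attr(spectrum_air, "tube_voltage"),
         e_a = bins$e_a, e_b = bins$e_b, e_c = bins$e_c),
    class = "pc_bh_curve"
  )
}

#' @export
print.pc_bh_curve <- function(x, ...) {
  cat(sprintf(
    "<pc_bh_curve> %s %s [%g, %g) keV: E_eff = %.2f keV, slope = %.4g cm^2/g, rho_t <= %.3g g/cm^2\n",
    x$material, x$bin,
    if (x$bin == "bin1") x$e_a else x$e_b,
    if (x$bin == "bin1") x$e_b else x$e_c,
    x$e_eff, x$slope, max(x$rho_t)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pc_bh_curve <- function(x, ...) {
  tibble(rho_t = x$rho_t, mu_prime_t = x$mu_prime_t,
         mu_t = x$slope * x$rho_t)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pc_bh_curve <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rho_t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mu_prime_t, linetype = "polychromatic mu't")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mu_t, linetype = "monochromatic mu t")) +
    ggplot2::labs(x = "Mass thickness rho t (g/cm^2)", y = "Attenuation factor",
                  linetype = NULL,
                  title = sprintf("%s, %s, E_eff = %.1f keV",
                                  object$material, object$bin, object$e_eff))
}

# Piecewise-linear inversion of the polychromatic curve.  Vectorized; returns
# NA for values above the curve maximum and clamps negatives to zero.
bh_invert <- function(curve, values) {
  rho <- approx(curve$mu_prime_t, curve$rho_t, xout = pmax(values, 0),
                rule = 1)$y
  rho[values <= 0] <- 0
  rho
}

# Local slope d(rho_t)/d(mu't) by central differences on the stored grid
# (one grid interval step; one-sided at the ends).
bh_slope <- function(curve, values) {
  i <- findInterval(values, curve$mu_prime_t, all.inside = TRUE)
  lo <- pmax(i - 1L, 1L)
  hi <- pmin(i + 2L, length(curve$rho_t))
  (curve$rho_t[hi] - curve$rho_t[lo]) /
    (curve$mu_prime_t[hi] - curve$mu_prime_t[lo])
}

#' Correct the beam-hardening effect
#'
#' Step 2 of the algorithm: the mass thickness \eqn{\rho t} matching the raw
#' polychromatic \eqn{\mu' t} is found by inverse interpolation of the
#' beam-hardening curve, then mapped onto the monochromatic line to give the
#' corrected \eqn{\mu t = \text{slope} \cdot \rho t}.
#'
#' @param raw An uncorrected `pc_mu` from [attenuation_factor()].
#' @param curve The matching [build_bh_curve()] result.
#' @return A corrected `pc_mu` carrying `value` (\eqn{\mu t}), `rho_t`, and a
#'   `clamped` flag when a noise-driven negative input was clamped to zero.
#' @export
correct_beam_hardening <- function(raw, curve) {
  stopifnot(inherits(raw, "pc_mu"), inherits(curve, "pc_bh_curve"))
  if (isTRUE(raw$corrected)) {
    abort("attenuation factor is already corrected", class = "pcthresh_config_error")
  }
  clamped <- FALSE
  value <- raw$value
  if (value < 0) {
    warn("negative attenuation factor clamped to zero (noise exceeds attenuation)")
    value <- 0
    clamped <- TRUE
  }
  if (value > max(curve$mu_prime_t)) {
    abort(sprintf(
      "mu't = %.4g above the curve maximum %.4g; rebuild the curve with rho_t_max > %.4g",
      value, max(curve$mu_prime_t), max(curve$rho_t)),
      class = "pcthresh_range_error")
  }
  rho_t <- bh_invert(curve, value)
  structure(list(value = curve$slope * rho_t, bin = raw$bin, corrected = TRUE,
                 rho_t = rho_t, negative = raw$negative, clamped = clamped),
            class = "pc_mu")
}

#' Calibration curve: atomic number versus attenuation ratio
#'
#' Step 3 preparation: for each calibration element the attenuation-factor
#' index \eqn{X = (\mu/\rho)(E_{eff,2}) / (\mu/\rho)(E_{eff,1})} is computed
#' (density and thickness cancel in the \eqn{\mu_2 t / \mu_1 t} ratio), giving
#' the monotone relation between \eqn{X} and Z that is inverted to estimate
#' the atomic number.  Inversion uses a monotone (Hyman-filtered) cubic
#' interpolant in \eqn{X \to Z}.
#'
#' @param elements A [calibration_elements()] set.
#' @param e_eff1 Effective energy of BIN1 (keV), `e_eff1 < e_eff2`.
#' @param e_eff2 Effective energy of BIN2 (keV).
#' @return A `pc_calibration` with element grids `x`, `z` (sorted by `x`) and
#'   the energy pair.
#' @export
build_calibration_curve <- function(elements, e_eff1, e_eff2) {
  stopifnot(inherits(elements, "pc_element_set"))
  if (!(e_eff1 < e_eff2)) {
    abort("need e_eff1 < e_eff2", class = "pcthresh_config_error")
  }
  x <- vapply(elements$tables, function(tb) {
    mass_attenuation(tb, e_eff2) / mass_attenuation(tb, e_eff1)
  }, 0)
  z <- as.double(elements$z)
  if (any(diff(x) >= 0)) {
    abort("attenuation ratio is not strictly decreasing in Z; bad energy pair or table",
          class = "pcthresh_validation_error")
  }
  ord <- order(x)
  structure(
    list(x = x[ord], z = z[ord], e_eff_pair = c(e_eff1, e_eff2),
         fun = splinefun(x[ord], z[ord], method = "hyman")),
    class = "pc_calibration"
  )
}

#' @export
print.pc_calibration <- function(x, ...) {
  cat(sprintf("<pc_calibration> Z = %g..%g at E_eff = (%.2f, %.2f) keV, X in [%.4g, %.4g]\n",
              min(x$z), max(x$z), x$e_eff_pair[1], x$e_eff_pair[2],
              min(x$x), max(x$x)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pc_calibration <- function(x, ...) tibble(z = x$z, x = x$x)

#' @exportS3Method ggplot2::autoplot
autoplot.pc_calibration <- function(object, ...) {
  grid <- tibble(x = seq(min(object$x), max(object$x), length.out = 200))
  grid$z <- object$fun(grid$x)
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Attenuation factor index X = mu2/mu1",
                  y = "Atomic number Z",
                  title = sprintf("Calibration at E_eff = (%.1f, %.1f) keV",
                                  object$e_eff_pair[1], object$e_eff_pair[2]))
}

# Vectorized calibration inversion with range clamping; returns list(z, oob).
calibration_invert <- function(curve, x) {
  oob <- x < min(curve$x) | x > max(curve$x)
  z <- curve$fun(pmin(pmax(x, min(curve$x)), max(curve$x)))
  list(z = z, out_of_range = oob)
}

# Local slope dZ/dX by central differences spanning the containing element
# interval (one-sided at the range ends; `boundary` flags that case).
calibration_slope <- function(curve, x) {
  i <- findInterval(x, curve$x, all.inside = TRUE)
  h <- curve$x[i + 1L] - curve$x[i]
  x_lo <- pmax(x - h / 2, min(curve$x))
  x_hi <- pmin(x + h / 2, max(curve$x))
  list(slope = (curve$fun(x_hi) - curve$fun(x_lo)) / (x_hi - x_lo),
       boundary = (x - h / 2 < min(curve$x)) | (x + h / 2 > max(curve$x)))
}

#' Estimate the effective atomic number
#'
#' Step 3 of the algorithm: forms the thickness-independent attenuation
#' factor index \eqn{X = \mu_2 t / \mu_1 t} from the two corrected bin
#' attenuation factors and inverts the calibration curve at \eqn{X}.  An
#' \eqn{X} outside the calibration range yields the range-end Z with
#' `out_of_range = TRUE`.
#'
#' @param mu1,mu2 Corrected `pc_mu` values for BIN1 and BIN2.
#' @param curve A [build_calibration_curve()] result.
#' @return A one-row tibble: `z`, `x`, `out_of_range`.
#' @export
estimate_z <- function(mu1, mu2, curve) {
  stopifnot(inherits(mu1, "pc_mu"), inherits(mu2, "pc_mu"),
            inherits(curve, "pc_calibration"))
  if (!isTRUE(mu1$corrected) || !isTRUE(mu2$corrected)) {
    abort("both attenuation factors must be beam-hardening corrected",
          class = "pcthresh_config_error")
  }
  if (mu1$value <= 0) {
    abort("mu1 must be positive to form the ratio X = mu2/mu1",
          class = "pcthresh_invalid_measurement")
  }
  x <- mu2$value / mu1$value
  inv <- calibration_invert(curve, x)
  tibble(z = inv$z, x = x, out_of_range = inv$out_of_range)
}
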