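# Shared setup for analyzing one (kV, Eb, material) condition: air spectrum,
# bin configuration, per-bin beam-hardening curves and the calibration curve.
# Curves are always built from the noise-free air spectrum ("calculated in
# advance"); noise only ever enters through the measured counts.
condition_setup <- function(tube_voltage_kv, e_b, material,
                            thickness_mm_max,
                            n_total = NULL,
                            e_a = 20,
                            filtration_mm_al = 2.5,
                            elements = calibration_elements(),
                            model = spectrum_model(),
                            bh_n_grid = 256,
                            spectrum_air = NULL,
                            calibration = NULL) {
  spec <- spectrum_air %||% generate_spectrum(tube_voltage_kv, filtration_mm_al,
                                              model)
  if (!is.null(n_total)) spec <- normalize_to_counts(spec, n_total)
  bins <- bin_config(tube_voltage_kv, e_b, e_a)
  rho_t_max <- 2 * material$density * thickness_mm_max / 10
  curves <- list(
    bin1 = build_bh_curve(spec, bins, "bin1", material, rho_t_max, bh_n_grid),
    bin2 = build_bh_curve(spec, bins, "bin2", material, rho_t_max, bh_n_grid)
  )
  calib <- calibration %||%
    build_calibration_curve(elements, curves$bin1$e_eff, curves$bin2$e_eff)
  list(spectrum_air = spec, bins = bins, curves = curves, calibration = calib)
}

#' Estimate Z for a single simulated condition
#'
#' Convenience wrapper running the full pipeline for one combination of tube
#' voltage, threshold, material and thickness: spectrum generation,
#' transmission, binning, (optional) Poisson noise, attenuation factors,
#' beam-hardening correction and calibration inversion.
#'
#' @param tube_voltage_kv Tube voltage (kV).
#' @param e_b Energy threshold (keV).
#' @param material A `pc_attenuation` with density, or a name accepted by
#'   [pc_material()].
#' @param thickness_mm Object thickness (mm).
#' @param n_total Total incident photons over the whole spectrum (required
#'   when `noise = "poisson"`); `NULL` leaves the generated spectrum scale.
#' @param noise `"ideal"` (noise-free) or `"poisson"` (per-channel counting
#'   noise on both the air and the object spectrum).
#' @param seed Seed for the Poisson draws.
#' @param noise_air Set `FALSE` to treat the air scan as ideal (noise on the
#'   object spectrum only).
#' @param e_a,filtration_mm_al,elements,model,bh_n_grid Simulation settings;
#'   see [sweep_config()].
#' @return A one-row tibble: condition columns, `z`, `x`, `e_eff1`, `e_eff2`,
#'   per-bin counts and flags.
#' @export
#' @examples
#' estimate_condition(60, 35, "pmma", 80)
estimate_condition <- function(tube_voltage_kv, e_b, material, thickness_mm,
                               n_total = NULL,
                               noise = c("ideal", "poisson"),
                               seed = NULL,
                               noise_air = TRUE,
                               e_a = 20,
                               filtration_mm_al = 2.5,
                               elements = calibration_elements(),
                               model = spectrum_model(),
                               bh_n_grid = 256) {
  noise <- match.arg(noise)
  if (is.character(material)) material <- pc_material(material)
  if (noise == "poisson" && is.null(n_total)) {
    abort("n_total is required for noisy estimation", class = "pcthresh_config_error")
  }
  setup <- condition_setup(tube_voltage_kv, e_b, material, thickness_mm,
                           n_total = n_total, e_a = e_a,
                           filtration_mm_al = filtration_mm_al,
                           elements = elements, model = model,
                           bh_n_grid = bh_n_grid)
  spec_air <- setup$spectrum_air
  spec_obj <- transmit(spec_air, material, thickness_mm)
  if (noise == "poisson") {
    seeds <- if (is.null(seed)) c(NA, NA) else c(seed, seed + 1L)
    if (noise_air) {
      spec_air <- add_poisson_noise(spec_air, if (is.na(seeds[1])) NULL else seeds[1])
    }
    spec_obj <- add_poisson_noise(spec_obj, if (is.na(seeds[2])) NULL else seeds[2])
  }
  ca <- bin_counts(spec_air, setup$bins)$counts
  co <- bin_counts(spec_obj, setup$bins)$counts
  mu1 <- correct_beam_hardening(attenuation_factor(ca[1], co[1], "bin1"),
                                setup$curves$bin1)
  mu2 <- correct_beam_hardening(attenuation_factor(ca[2], co[2], "bin2"),
                                setup$curves$bin2)
  est <- estimate_z(mu1, mu2, setup$calibration)
  tibble(
    tube_voltage_kv = tube_voltage_kv, e_b = e_b,
    material = material$material, thickness_mm = thickness_mm,
    n_total = n_total %||% NA_real_, noise = noise,
    z = est$z, x = est$x, out_of_range = est$out_of_range,
    e_eff1 = setup$curves$bin1$e_eff, e_eff2 = setup$curves$bin2$e_eff,
    c_air_bin1 = ca[1], c_air_bin2 = ca[2],
    c_obj_bin1 = co[1], c_obj_bin2 = co[2]
  )
}
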