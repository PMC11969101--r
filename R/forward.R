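#' Beer-Lambert transmission through a slab
#'
#' Attenuates each channel by \eqn{\exp(-(\mu/\rho)(E_c)\,\rho\,t)} with the
#' mass attenuation coefficient evaluated at the channel-centre energy
#' \eqn{E_c}.  Thickness is in mm; the material must carry a density.
#'
#' @param spectrum A `pc_spectrum`.
#' @param material A `pc_attenuation` with density (see [pc_material()]).
#' @param thickness_mm Slab thickness in mm (>= 0).
#' @return The transmitted `pc_spectrum`.
#' @export
#' @examples
#' s <- generate_spectrum(60) |> normalize_to_counts(1e5)
#' transmit(s, pc_material("pmma"), 80) |> total_counts()
transmit <- function(spectrum, material, thickness_mm) {
  stopifnot(inherits(spectrum, "pc_spectrum"), inherits(material, "pc_attenuation"))
  if (thickness_mm < 0) {
    abort("thickness must be non-negative", class = "pcthresh_config_error")
  }
  if (is.null(material$density)) {
    abort(sprintf("material '%s' has no density; cannot transmit", material$material),
          class = "pcthresh_config_error")
  }
  if (thickness_mm == 0) return(spectrum)
  mu <- mass_attenuation(material, channel_centres(spectrum))
  with_fluence(spectrum,
               spectrum$fluence * exp(-mu * material$density * thickness_mm / 10))
}

#' Two-bin configuration
#'
#' Defines the two counting bins: BIN1 = \eqn{[E_a, E_b)} and BIN2 =
#' \eqn{[E_b, E_c)} keV.  \eqn{E_a} defaults to 20 keV (the typical lowest
#' threshold of a photon-counting detector); \eqn{E_c} equals the tube
#' voltage; the threshold \eqn{E_b} must be an integer in
#' \eqn{[E_a + 1, E_c - 1]}.
#'
#' @param tube_voltage_kv Tube voltage, fixing the upper bin edge \eqn{E_c}.
#' @param e_b Energy threshold dividing the bins (keV).
#' @param e_a Lower edge of BIN1 (keV, default 20).
#' @return A `pc_bins` list with elements `e_a`, `e_b`, `e_c`.
#' @export
bin_config <- function(tube_voltage_kv, e_b, e_a = 20) {
  e_c <- tube_voltage_kv
  if (e_b != round(e_b)) {
    abort("threshold e_b must be an integer keV value", class = "pcthresh_config_error")
  }
  if (!(e_a < e_b && e_b < e_c)) {
    abort(sprintf("need e_a < e_b < e_c; got (%g, %g, %g)", e_a, e_b, e_c),
          class = "pcthresh_config_error")
  }
  structure(list(e_a = e_a, e_b = as.integer(e_b), e_c = e_c),
            class = "pc_bins")
}

#' Threshold rule for a tube voltage
#'
#' All configurable thresholds at a tube voltage: 21 to \eqn{E_c - 1} keV at
#' 1 keV steps, with \eqn{E_c} equal to the tube voltage.
#'
#' @param tube_voltage_kv Tube voltage in kV.
#' @param e_a Lower edge of BIN1 (default 20 keV).
#' @return Integer vector of thresholds (keV).
#' @export
threshold_grid <- function(tube_voltage_kv, e_a = 20) {
  seq.int(e_a + 1L, as.integer(tube_voltage_kv) - 1L)
}

#' Integrate a spectrum over the two bins
#'
#' Sums the per-channel fluence over BIN1 \eqn{[E_a, E_b)} and BIN2
#' \eqn{[E_b, E_c)}.  Bin edges must fall on channel boundaries.
#'
#' @param spectrum A `pc_spectrum` on an integer-keV channel grid.
#' @param bins A [bin_config()].
#' @return A tibble with columns `bin` (`"bin1"`, `"bin2"`) and `counts`.
#' @export
bin_counts <- function(spectrum, bins) {
  stopifnot(inherits(spectrum, "pc_spectrum"), inherits(bins, "pc_bins"))
  e <- spectrum$energy_kev
  edges <- c(bins$e_a, bins$e_b, bins$e_c)
  if (any(edges != round(edges)) || any(e != round(e))) {
    abort("bin edges must lie on integer channel boundaries",
          class = "pcthresh_config_error")
  }
  tibble(
    bin = c("bin1", "bin2"),
    counts = c(sum(spectrum$fluence[e >= bins$e_a & e < bins$e_b]),
               sum(spectrum$fluence[e >= bins$e_b & e < bins$e_c]))
  )
}

#' Add per-channel Poisson counting noise
#'
#' Replaces each channel's expected fluence by an independent Poisson draw
#' with that mean, emulating the counting statistics of a photon-counting
#' acquisition.  Zero-mean channels stay zero.  With `seed` given the draw is
#' reproducible and the caller's RNG state is left untouched.
#'
#' @param spectrum A `pc_spectrum` of expected (non-negative) fluence.
#' @param seed Optional integer seed.
#' @return A `pc_spectrum` of integer counts.
#' @export
add_poisson_noise <- function(spectrum, seed = NULL) {
  stopifnot(inherits(spectrum, "pc_spectrum"))
  fl <- spectrum$fluence
  if (any(!is.finite(fl)) || any(fl < 0)) {
    abort("fluence must be finite and non-negative", class = "pcthresh_validation_error")
  }
  draw <- function() as.double(rpois(length(fl), fl))
  noisy <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  with_fluence(spectrum, noisy)
}

#' Deterministic child seeds
#'
#' Expands one master seed into per-(condition, repeat) child seeds so any
#' single cell of a sweep can be replayed in isolation.  The rule is
#' `(master + 1000003 * cell + rep) mod (2^31 - 1)`, with `cell` the row
#' index of the condition in the deterministic sweep grid and `rep` the
#' repeat index (1-based).
#'
#' @param master_seed Master integer seed.
#' @param cell Condition index (integer scalar or vector).
#' @param rep Repeat index (integer scalar or vector).
#' @return Integer seed(s) in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master_seed, cell, rep = 1L) {
  as.integer((as.double(master_seed) + 1000003 * as.double(cell) +
                as.double(rep)) %% 2147483647)
}
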