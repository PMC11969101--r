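#' Tube spectrum model
#'
#' Parameters of the default analytic tungsten-anode spectrum model: Kramers
#' bremsstrahlung with per-channel fluence proportional to
#' \eqn{E_{max}/E - 1}, plus the tungsten K-series characteristic lines
#' (K\eqn{\alpha_1}, K\eqn{\alpha_2}, K\eqn{\beta_1}, K\eqn{\beta_2} at
#' 59.32, 57.98, 67.24 and 69.07 keV) whenever the tube voltage exceeds the
#' W K-shell binding energy of 69.5 keV.  The line group carries
#' `line_total_fraction` of the total unfiltered counts, split
#' `line_split` across the four lines.
#'
#' A replacement model can be supplied as `fluence_fn`, a
#' `function(tube_voltage_kv, energy_kev)` returning unfiltered relative
#' fluence per 1 keV channel at the given channel-centre energies; it must
#' return zero at and above the tube voltage.
#'
#' @param id Model identifier string.
#' @param e_min Lowest channel edge (keV) of the generated grid.
#' @param line_energies Characteristic line energies (keV).
#' @param line_split Relative intensities of the lines (any scale).
#' @param line_total_fraction Fraction of total unfiltered counts carried by
#'   the line group when the lines are excited.
#' @param k_edge_kev Tube voltage above which the lines are excited.
#' @param fluence_fn Optional replacement bremsstrahlung function.
#' @return A `pc_spectrum_model` list.
#' @export
spectrum_model <- function(id = "kramers-w",
                           e_min = 10,
                           line_energies = c(59.32, 57.98, 67.24, 69.07),
                           line_split = c(50, 28, 15, 7),
                           line_total_fraction = 0.05,
                           k_edge_kev = 69.5,
                           fluence_fn = NULL) {
  stopifnot(length(line_energies) == length(line_split), e_min >= 10)
  structure(
    list(id = id, e_min = e_min, line_energies = line_energies,
         line_split = line_split / sum(line_split),
         line_total_fraction = line_total_fraction,
         k_edge_kev = k_edge_kev, fluence_fn = fluence_fn),
    class = "pc_spectrum_model"
  )
}

new_spectrum <- function(energy, fluence, tube_voltage, filtration_mm_al,
                         model_id) {
  out <- tibble(energy_kev = energy, fluence = fluence)
  class(out) <- c("pc_spectrum", class(out))
  attr(out, "tube_voltage") <- tube_voltage
  attr(out, "filtration_mm_al") <- filtration_mm_al
  attr(out, "model_id") <- model_id
  out
}

spectrum_attrs <- function(spectrum) {
  list(tube_voltage = attr(spectrum, "tube_voltage"),
       filtration_mm_al = attr(spectrum, "filtration_mm_al"),
       model_id = attr(spectrum, "model_id"))
}

with_fluence <- function(spectrum, fluence) {
  a <- spectrum_attrs(spectrum)
  new_spectrum(spectrum$energy_kev, fluence, a$tube_voltage,
               a$filtration_mm_al, a$model_id)
}

#' Total counts of a spectrum
#'
#' @param spectrum A `pc_spectrum`.
#' @return Sum of the per-channel fluence.
#' @export
total_counts <- function(spectrum) sum(spectrum$fluence)

#' Channel-centre energies of a spectrum
#' @param spectrum A `pc_spectrum`.
#' @return Channel-centre energies in keV.
#' @export
channel_centres <- function(spectrum) spectrum$energy_kev + 0.5

#' Generate a filtered tube spectrum
#'
#' Builds the expected (noise-free) photon fluence per 1 keV energy channel
#' for a tungsten-anode tube at the given voltage, then applies aluminium
#' filtration channel-wise via the Beer-Lambert law evaluated at channel
#' centres.  Channels are half-open intervals \eqn{[E_i, E_i + 1)} keV;
#' fluence is zero for channels at or above the tube voltage.
#'
#' The returned fluence is on an arbitrary scale; use
#' [normalize_to_counts()] to fix the total number of incident photons.
#'
#' @param tube_voltage_kv Tube voltage in kV (50-120 expected; a warning is
#'   issued outside that range).
#' @param filtration_mm_al Total aluminium filtration in mm (default 2.5).
#' @param model A [spectrum_model()].
#' @return A `pc_spectrum` tibble (`energy_kev` = lower channel edge,
#'   `fluence`) with tube-voltage metadata.
#' @export
#' @examples
#' s <- generate_spectrum(80) |> normalize_to_counts(1e5)
#' total_counts(s)
generate_spectrum <- function(tube_voltage_kv, filtration_mm_al = 2.5,
                              model = spectrum_model()) {
  if (tube_voltage_kv <= 20) {
    abort("tube voltage must exceed 20 kV (lowest analysis energy)",
          class = "pcthresh_config_error")
  }
  if (tube_voltage_kv < 50 || tube_voltage_kv > 120) {
    warn(sprintf("tube voltage %g kV outside the validated 50-120 kV range",
                 tube_voltage_kv))
  }
  if (filtration_mm_al < 0) {
    abort("filtration must be non-negative", class = "pcthresh_config_error")
  }
  energy <- seq(model$e_min, ceiling(tube_voltage_kv) - 1)
  centres <- energy + 0.5
  if (is.null(model$fluence_fn)) {
    fl <- pmax(tube_voltage_kv / centres - 1, 0)
  } else {
    fl <- model$fluence_fn(tube_voltage_kv, centres)
    if (any(fl < 0) || any(fl[centres >= tube_voltage_kv] != 0)) {
      abort("fluence_fn must be non-negative and zero at/above the tube voltage",
            class = "pcthresh_validation_error")
    }
  }
  if (tube_voltage_kv > model$k_edge_kev && is.null(model$fluence_fn)) {
    line_total <- sum(fl) * model$line_total_fraction / (1 - model$line_total_fraction)
    idx <- match(floor(model$line_energies), energy)
    ok <- !is.na(idx)
    fl[idx[ok]] <- fl[idx[ok]] + line_total * model$line_split[ok]
  }
  if (filtration_mm_al > 0) {
    al <- pc_material("al")
    fl <- fl * exp(-mass_attenuation(al, centres) * al$density *
                     0.1 * filtration_mm_al)
  }
  new_spectrum(energy, fl, tube_voltage_kv, filtration_mm_al, model$id)
}

#' Scale a spectrum to a total photon count
#'
#' Rescales the fluence so that the channel sum equals `n_total`; the
#' spectral shape is unchanged.
#'
#' @param spectrum A `pc_spectrum`.
#' @param n_total Target total number of photons (> 0).
#' @return The rescaled `pc_spectrum`.
#' @export
normalize_to_counts <- function(spectrum, n_total) {
  stopifnot(inherits(spectrum, "pc_spectrum"))
  if (n_total <= 0) {
    abort("n_total must be positive", class = "pcthresh_config_error")
  }
  tot <- total_counts(spectrum)
  if (tot <= 0) {
    abort("cannot normalize an all-zero spectrum", class = "pcthresh_validation_error")
  }
  with_fluence(spectrum, spectrum$fluence * (n_total / tot))
}

#' Mean energy of a spectrum
#' @param spectrum A `pc_spectrum`.
#' @return Fluence-weighted mean of the channel-centre energies (keV).
#' @export
mean_energy <- function(spectrum) {
  sum(channel_centres(spectrum) * spectrum$fluence) / total_counts(spectrum)
}

#' Write / read a spectrum as two-column text
#'
#' Serialization used by the command-line interface and tests: `#` headers
#' carrying the tube voltage and filtration, then one `energy fluence` row
#' per channel (energy = lower channel edge, keV).
#'
#' @param spectrum A `pc_spectrum`.
#' @param path Output (input) file path.
#' @return `write_spectrum()` returns `path` invisibly; `read_spectrum()`
#'   returns a `pc_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  a <- spectrum_attrs(spectrum)
  writeLines(c(
    sprintf("# tube_voltage_kv: %g", a$tube_voltage),
    sprintf("# filtration_mm_al: %g", a$filtration_mm_al),
    sprintf("# model_id: %s", a$model_id),
    "# columns: energy_keV fluence",
    sprintf("%g %.10g", spectrum$energy_kev, spectrum$fluence)
  ), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- regmatches(hdr, regexec(paste0("^#\\s*", key, ":\\s*(.+)$"), hdr))
    val <- unlist(lapply(m, function(x) if (length(x) == 2) x[2]))
    if (length(val)) val[[1]] else NA
  }
  dat <- read.table(text = grep("^#", lines, value = TRUE, invert = TRUE),
                    col.names = c("energy_kev", "fluence"))
  new_spectrum(dat$energy_kev, dat$fluence,
               as.numeric(get("tube_voltage_kv")),
               as.numeric(get("filtration_mm_al")),
               as.character(get("model_id")))
}

#' @exportS3Method ggplot2::autoplot
autoplot.pc_spectrum <- function(object, ...) {
  a <- spectrum_attrs(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$energy_kev + 0.5,
                                       y = .data$fluence)) +
    ggplot2::geom_step(direction = "mid") +
    ggplot2::labs(
      x = "Energy (keV)", y = "Photons / channel",
      title = sprintf("%g kV, %g mm Al", a$tube_voltage, a$filtration_mm_al)
    )
}
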