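#' Read a mass-attenuation-coefficient table
#'
#' Parses a plain-text two-column table (energy in keV, mass attenuation
#' coefficient \eqn{\mu/\rho} in cm\eqn{^2}/g).  Lines starting with `#` are
#' header lines; recognised `key: value` headers (`material`, `density_g_cm3`,
#' `nominal_z`) populate the returned object's metadata.  The energy grid must
#' be strictly increasing and all coefficients positive.
#'
#' @param path Path to the table file.
#' @param material Optional material name overriding the header.
#' @param density Optional density in g/cm\eqn{^3} overriding the header.
#' @param nominal_z Optional nominal effective atomic number overriding the
#'   header.
#' @return A `pc_attenuation` object: the validated table plus metadata and a
#'   log-log interpolator used by [mass_attenuation()].
#' @seealso [mass_attenuation()], [pc_material()]
#' @export
#' @examples
#' al <- pc_material("al")
#' mass_attenuation(al, 50)
load_attenuation_table <- function(path, material = NULL, density = NULL,
                                   nominal_z = NULL) {
  if (!file.exists(path)) {
    abort(paste0("attenuation table not found: ", path), class = "pcthresh_io_error")
  }
  lines <- readLines(path)
  meta <- list()
  energies <- numeric(0)
  mu <- numeric(0)
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "") next
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*([A-Za-z0-9_]+):\\s*(.+)$", line))[[1]]
      if (length(m) == 3) meta[[m[2]]] <- m[3]
      next
    }
    fields <- strsplit(line, "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2 || anyNA(vals)) {
      abort(sprintf("malformed attenuation table row at line %d of '%s': '%s'",
                    i, basename(path), line),
            class = "pcthresh_parse_error")
    }
    energies <- c(energies, vals[1])
    mu <- c(mu, vals[2])
  }
  new_attenuation_table(
    energies, mu,
    material = material %||% meta$material %||% basename(path),
    density = density %||% (if (!is.null(meta$density_g_cm3)) as.numeric(meta$density_g_cm3)),
    nominal_z = nominal_z %||% (if (!is.null(meta$nominal_z)) as.numeric(meta$nominal_z))
  )
}

new_attenuation_table <- function(energies, mu, material, density = NULL,
                                  nominal_z = NULL) {
  if (length(energies) < 2) {
    abort("attenuation table needs at least two grid points",
          class = "pcthresh_validation_error")
  }
  if (any(diff(energies) <= 0)) {
    abort("attenuation table energies must be strictly increasing",
          class = "pcthresh_validation_error")
  }
  if (any(mu <= 0)) {
    abort("attenuation coefficients must all be positive",
          class = "pcthresh_validation_error")
  }
  if (!is.null(density) && density <= 0) {
    abort("density must be positive", class = "pcthresh_validation_error")
  }
  structure(
    list(
      material = material,
      density = density,
      nominal_z = nominal_z,
      table = tibble(energy_kev = energies, mu_over_rho = mu),
      interp = approxfun(log(energies), log(mu), rule = 1)
    ),
    class = "pc_attenuation"
  )
}

#' @export
print.pc_attenuation <- function(x, ...) {
  cat(sprintf("<pc_attenuation> %s: %d points, %g-%g keV",
              x$material, nrow(x$table),
              min(x$table$energy_kev), max(x$table$energy_kev)))
  if (!is.null(x$density)) cat(sprintf(", rho = %g g/cm^3", x$density))
  if (!is.null(x$nominal_z)) cat(sprintf(", Z = %g", x$nominal_z))
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pc_attenuation <- function(x, ...) x$table

#' Interpolated mass attenuation coefficient
#'
#' Log-log linear interpolation of \eqn{\mu/\rho} between the bracketing grid
#' points; exact at grid points.  Queries outside the tabulated energy range
#' raise a range error (no extrapolation).
#'
#' @param table A `pc_attenuation` object.
#' @param energy_kev Energy (keV); may be a vector.
#' @return Mass attenuation coefficient(s) in cm\eqn{^2}/g.
#' @export
mass_attenuation <- function(table, energy_kev) {
  stopifnot(inherits(table, "pc_attenuation"))
  rng <- range(table$table$energy_kev)
  if (any(energy_kev < rng[1] | energy_kev > rng[2])) {
    abort(sprintf("energy outside tabulated range [%g, %g] keV for %s",
                  rng[1], rng[2], table$material),
          class = "pcthresh_range_error")
  }
  exp(table$interp(log(energy_kev)))
}

pkg_extdata <- function(...) {
  system.file("extdata", "attenuation", ..., package = "pcthresh", mustWork = TRUE)
}

#' Analysis materials
#'
#' The shipped analysis materials: PMMA (density 1.19 g/cm\eqn{^3}, nominal
#' effective Z 6.5, a soft-tissue surrogate) and aluminium (2.699 g/cm\eqn{^3},
#' Z = 13, a cortical-bone surrogate).
#'
#' @param name `"pmma"` or `"al"` (case-insensitive).
#' @return A `pc_attenuation` object with density and nominal Z set.
#' @export
#' @examples
#' pmma <- pc_material("pmma")
#' pmma$density
pc_material <- function(name) {
  key <- tolower(name)
  file <- switch(key,
    pmma = "PMMA_synthetic.txt",
    al = "Al.txt",
    aluminium = "Al.txt",
    aluminum = "Al.txt",
    abort(sprintf("unknown material '%s'; available: %s", name,
                  paste(material_library()$name, collapse = ", ")),
          class = "pcthresh_config_error")
  )
  load_attenuation_table(pkg_extdata(file))
}

#' @rdname pc_material
#' @return `material_library()` returns a tibble listing the available
#'   analysis materials with densities and nominal atomic numbers.
#' @export
material_library <- function() {
  mats <- lapply(c("pmma", "al"), pc_material)
  tibble(
    name = c("pmma", "al"),
    material = vapply(mats, `[[`, "", "material"),
    density_g_cm3 = vapply(mats, `[[`, 0, "density"),
    nominal_z = vapply(mats, `[[`, 0, "nominal_z")
  )
}

#' Calibration element set
#'
#' Attenuation tables for the elements used to build the Z-versus-attenuation
#' ratio calibration curve.  The default set spans Z = 4 (Be) to Z = 20 (Ca),
#' bracketing both analysis materials (PMMA at 6.5 and Al at 13) with margin
#' for stable interpolation.
#'
#' @param z Integer atomic numbers to include, a subset of 4:20, strictly
#'   increasing.
#' @return A `pc_element_set`: list with `z` (atomic numbers) and `tables`
#'   (one `pc_attenuation` per element).
#' @export
calibration_elements <- function(z = 4:20) {
  z <- as.integer(z)
  if (length(z) < 2 || any(diff(z) <= 0)) {
    abort("element set needs at least two strictly increasing atomic numbers",
          class = "pcthresh_validation_error")
  }
  symbols <- c("Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
               "Si", "P", "S", "Cl", "Ar", "K", "Ca")
  if (any(z < 4L | z > 20L)) {
    abort("shipped element tables span Z = 4..20", class = "pcthresh_config_error")
  }
  tables <- lapply(z, function(zi) {
    load_attenuation_table(
      pkg_extdata(sprintf("element_%02d_%s_synthetic.txt", zi, symbols[zi - 3L]))
    )
  })
  structure(list(z = z, tables = tables), class = "pc_element_set")
}

#' @export
print.pc_element_set <- function(x, ...) {
  cat(sprintf("<pc_element_set> Z = %s\n", paste(x$z, collapse = ", ")))
  invisible(x)
}
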