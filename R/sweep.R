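#' Sweep configuration
#'
#' The default grid reproduces the study conditions: tube voltages 50-120 kV
#' in 10 kV steps, thresholds 21 to \eqn{E_c - 1} keV at 1 keV steps
#' (regenerated per voltage since \eqn{E_c} equals the tube voltage), PMMA at
#' 20/40/80/160 mm and Al at 2/4/8/16 mm, total incident counts
#' \eqn{10^3}-\eqn{10^6}, and five Monte-Carlo repeats.
#'
#' @param tube_voltages_kv Tube voltages (kV).
#' @param materials Named list mapping material names accepted by
#'   [pc_material()] to thickness vectors (mm).
#' @param n_totals Total incident photon counts to evaluate.
#' @param thresholds Optional fixed threshold vector (keV) replacing the
#'   per-voltage `21..Ec-1` rule; thresholds at or above a voltage's
#'   \eqn{E_c} are dropped for that voltage.
#' @param modes Which estimates to compute per grid cell: `"ideal"`
#'   (noise-free Z), `"analytic"` (propagated \eqn{\sigma(Z)}), `"mc"`
#'   (Monte-Carlo mean/SD over `n_repeats`).
#' @param n_repeats Monte-Carlo repeats per cell (mode `"mc"`).
#' @param master_seed Master seed for the Monte-Carlo child seeds.
#' @param e_a Lower edge of BIN1 (keV).
#' @param filtration_mm_al Total aluminium filtration (mm).
#' @param include_air_noise Propagate (and simulate) noise on the air scan as
#'   well as the object scan.
#' @param elements Calibration element set.
#' @param model Spectrum model.
#' @param bh_n_grid Beam-hardening curve grid size.
#' @return A `pc_sweep_config` list.
#' @export
sweep_config <- function(tube_voltages_kv = seq(50, 120, by = 10),
                         materials = list(pmma = c(20, 40, 80, 160),
                                          al = c(2, 4, 8, 16)),
                         n_totals = 10^(3:6),
                         thresholds = NULL,
                         modes = c("ideal", "analytic"),
                         n_repeats = 5,
                         master_seed = 1,
                         e_a = 20,
                         filtration_mm_al = 2.5,
                         include_air_noise = TRUE,
                         elements = calibration_elements(),
                         model = spectrum_model(),
                         bh_n_grid = 256) {
  modes <- match.arg(modes, c("ideal", "analytic", "mc"), several.ok = TRUE)
  if (is.null(names(materials)) || any(names(materials) == "")) {
    abort("materials must be a named list of thickness vectors",
          class = "pcthresh_config_error")
  }
  structure(
    list(tube_voltages_kv = tube_voltages_kv, materials = materials,
         n_totals = sort(n_totals), thresholds = thresholds,
         modes = modes, n_repeats = n_repeats,
         master_seed = master_seed, e_a = e_a,
         filtration_mm_al = filtration_mm_al,
         include_air_noise = include_air_noise,
         elements = elements, model = model, bh_n_grid = bh_n_grid),
    class = "pc_sweep_config"
  )
}

#' Run the full threshold sweep
#'
#' Evaluates every cell of the condition grid (tube voltage x threshold x
#' material x thickness x photon count): the noise-free Z estimate, the
#' analytically propagated \eqn{\sigma(Z)}, and optionally a seeded
#' Monte-Carlo mean/SD.  Unanalyzable cells (empty or fully absorbed bins)
#' are flagged, never fatal.  The result is deterministic given
#' `master_seed`.
#'
#' @param config A [sweep_config()].
#' @param progress Print per-voltage progress to stderr.
#' @return A `pc_sweep` object: `records` (one row per grid cell), `summary`
#'   (per-voltage optimum per photon count, when mode `"analytic"` is on),
#'   and the resolved `config`.  Use [tidy()], [glance()],
#'   [threshold_summary()], [optimal_threshold()] to inspect it.
#' @export
#' @examples
#' cfg <- sweep_config(tube_voltages_kv = 60, n_totals = 1e5,
#'                     materials = list(pmma = 80, al = 8))
#' sw <- run_sweep(cfg)
#' glance(sw)
run_sweep <- function(config = sweep_config(), progress = FALSE) {
  stopifnot(inherits(config, "pc_sweep_config"))
  mats <- lapply(names(config$materials), pc_material)
  names(mats) <- names(config$materials)
  do_ideal <- "ideal" %in% config$modes
  do_analytic <- "analytic" %in% config$modes
  do_mc <- "mc" %in% config$modes
  n_totals <- if (do_analytic || do_mc) config$n_totals else NA_real_
  frames <- list()
  cell_counter <- 0L
  for (kv in config$tube_voltages_kv) {
    if (progress) message(sprintf("sweep: %g kV", kv))
    spec_air <- normalize_to_counts(
      generate_spectrum(kv, config$filtration_mm_al, config$model), 1)
    e <- spec_air$energy_kev
    trans <- lapply(names(mats), function(m) {
      lapply(config$materials[[m]],
             function(t) transmit(spec_air, mats[[m]], t)$fluence)
    })
    names(trans) <- names(mats)
    ebs <- config$thresholds %||% threshold_grid(kv, config$e_a)
    ebs <- ebs[ebs > config$e_a & ebs < kv]
    for (e_b in ebs) {
      bins <- bin_config(kv, e_b, config$e_a)
      sel1 <- e >= bins$e_a & e < bins$e_b
      sel2 <- e >= bins$e_b & e < bins$e_c
      ca <- c(sum(spec_air$fluence[sel1]), sum(spec_air$fluence[sel2]))
      curves <- lapply(seq_along(mats), function(mi) {
        mat <- mats[[mi]]
        rho_max <- 2 * mat$density * max(config$materials[[mi]]) / 10
        list(
          bin1 = build_bh_curve(spec_air, bins, "bin1", mat, rho_max,
                                config$bh_n_grid),
          bin2 = build_bh_curve(spec_air, bins, "bin2", mat, rho_max,
                                config$bh_n_grid)
        )
      })
      names(curves) <- names(mats)
      calib <- build_calibration_curve(config$elements,
                                       curves[[1]]$bin1$e_eff,
                                       curves[[1]]$bin2$e_eff)
      for (mi in seq_along(mats)) {
        mat <- mats[[mi]]
        mname <- names(mats)[mi]
        for (ti in seq_along(config$materials[[mi]])) {
          thick <- config$materials[[mi]][ti]
          co <- c(sum(trans[[mi]][[ti]][sel1]), sum(trans[[mi]][[ti]][sel2]))
          z_ideal <- NA_real_
          ideal_oob <- NA
          if (do_ideal && all(co > 0)) {
            mu1 <- correct_beam_hardening(
              attenuation_factor(ca[1], co[1], "bin1"), curves[[mi]]$bin1)
            mu2 <- correct_beam_hardening(
              attenuation_factor(ca[2], co[2], "bin2"), curves[[mi]]$bin2)
            est <- estimate_z(mu1, mu2, calib)
            z_ideal <- est$z
            ideal_oob <- est$out_of_range
          }
          for (n in n_totals) {
            cell_counter <- cell_counter + 1L
            sigma_z <- NA_real_
            valid <- NA
            z_mc_mean <- NA_real_
            z_mc_sd <- NA_real_
            n_invalid <- NA_integer_
            if (do_analytic && !is.na(n)) {
              budget <- propagate_sigma_z(ca * n, co * n, curves[[mi]], calib,
                                          config$include_air_noise)
              sigma_z <- budget$sigma_z
              valid <- budget$valid
            }
            if (do_mc && !is.na(n)) {
              zr <- mc_draw_cell(spec_air$fluence * n, trans[[mi]][[ti]] * n,
                                 sel1, sel2, curves[[mi]], calib,
                                 config$n_repeats, config$master_seed,
                                 cell_counter, config$include_air_noise)
              n_invalid <- sum(is.na(zr))
              if (n_invalid < config$n_repeats) z_mc_mean <- mean(zr, na.rm = TRUE)
              if (sum(!is.na(zr)) >= 2) z_mc_sd <- sd(zr, na.rm = TRUE)
            }
            frames[[length(frames) + 1L]] <- data.frame(
              tube_voltage_kv = kv, e_b = e_b, material = mname,
              thickness_mm = thick, n_total = n, cell = cell_counter,
              z_ideal = z_ideal, ideal_out_of_range = ideal_oob,
              sigma_z = sigma_z, analytic_valid = valid,
              z_mc_mean = z_mc_mean, z_mc_sd = z_mc_sd,
              mc_invalid = n_invalid
            )
          }
        }
      }
    }
  }
  records <- as_tibble(dplyr::bind_rows(frames))
  summary <- if (do_analytic) sweep_summarize(records) else
    tibble(tube_voltage_kv = numeric(), n_total = numeric(),
           optimal_e_b = integer(), sigma_min = numeric(),
           optimal_e_b_rss = integer(), sigma_min_rss = numeric())
  structure(list(records = records, summary = summary, config = config),
            class = "pc_sweep")
}

# Seeded per-repeat Monte-Carlo draws for one grid cell.
mc_draw_cell <- function(air_fl, obj_fl, sel1, sel2, curves, calib,
                         n_repeats, master_seed, cell, include_air_noise) {
  seeds <- child_seed(master_seed, cell, seq_len(n_repeats))
  counts <- vapply(seq_len(n_repeats), function(r) {
    withr::with_seed(seeds[r], {
      air <- if (include_air_noise) rpois(length(air_fl), air_fl) else air_fl
      obj <- rpois(length(obj_fl), obj_fl)
      c(sum(air[sel1]), sum(air[sel2]), sum(obj[sel1]), sum(obj[sel2]))
    })
  }, numeric(4))
  mc_estimate_z(counts[1, ], counts[2, ], counts[3, ], counts[4, ],
                curves, calib)
}

# Per-(kV, n_total) worst-case / combined uncertainty and optimal threshold.
sweep_summarize <- function(records) {
  worst <- records |>
    dplyr::filter(!is.na(.data$n_total)) |>
    dplyr::group_by(.data$tube_voltage_kv, .data$n_total, .data$e_b,
                    .data$material) |>
    dplyr::summarise(
      worst_sigma = max(ifelse(is.na(.data$sigma_z) | !.data$analytic_valid,
                               Inf, .data$sigma_z)),
      .groups = "drop"
    )
  combined <- worst |>
    dplyr::group_by(.data$tube_voltage_kv, .data$n_total, .data$e_b) |>
    dplyr::summarise(
      combined_max = max(.data$worst_sigma),
      combined_rss = sqrt(sum(.data$worst_sigma^2)),
      .groups = "drop"
    )
  combined |>
    dplyr::group_by(.data$tube_voltage_kv, .data$n_total) |>
    dplyr::summarise(
      optimal_e_b = .data$e_b[which.min(.data$combined_max)],
      sigma_min = min(.data$combined_max),
      optimal_e_b_rss = .data$e_b[which.min(.data$combined_rss)],
      sigma_min_rss = min(.data$combined_rss),
      .groups = "drop"
    )
}

#' Worst-case uncertainty over thicknesses
#'
#' The largest analytically propagated \eqn{\sigma(Z)} across the analyzed
#' thicknesses of one material at one (voltage, threshold, count) cell; the
#' quantity plotted per material when comparing thresholds.  If any
#' thickness is unanalyzable the worst case is `Inf`.
#'
#' @param sweep A `pc_sweep` from [run_sweep()] (mode `"analytic"`).
#' @param tube_voltage_kv,e_b,material,n_total Cell coordinates (`material`
#'   by configured name, e.g. `"pmma"`).
#' @return Worst-case \eqn{\sigma(Z)} (possibly `Inf`).
#' @export
worst_case_sigma <- function(sweep, tube_voltage_kv, e_b, material, n_total) {
  r <- sweep_cells(sweep, tube_voltage_kv, e_b, n_total)
  r <- r[r$material == material, ]
  if (nrow(r) == 0) {
    abort("no matching records; check the cell coordinates",
          class = "pcthresh_config_error")
  }
  max(ifelse(is.na(r$sigma_z) | !r$analytic_valid, Inf, r$sigma_z))
}

#' Combined uncertainty over both materials
#'
#' Combines the per-material worst cases at one (voltage, threshold, count)
#' cell.  The default rule is the conservative maximum over materials;
#' `"rss"` gives the root sum of squares alternative.
#'
#' @inheritParams worst_case_sigma
#' @param rule `"max"` (default) or `"rss"`.
#' @return Combined \eqn{\sigma(Z)}.
#' @export
combined_sigma <- function(sweep, tube_voltage_kv, e_b, n_total,
                           rule = c("max", "rss")) {
  rule <- match.arg(rule)
  per_mat <- vapply(
    unique(sweep_cells(sweep, tube_voltage_kv, e_b, n_total)$material),
    function(m) worst_case_sigma(sweep, tube_voltage_kv, e_b, m, n_total), 0)
  if (rule == "max") max(per_mat) else sqrt(sum(per_mat^2))
}

sweep_cells <- function(sweep, tube_voltage_kv, e_b, n_total) {
  stopifnot(inherits(sweep, "pc_sweep"))
  r <- sweep$records
  r[r$tube_voltage_kv == tube_voltage_kv & r$e_b == e_b &
      !is.na(r$n_total) & r$n_total == n_total, ]
}

#' Optimal energy threshold at a tube voltage
#'
#' The threshold minimising the combined worst-case propagated
#' \eqn{\sigma(Z)}; ties are broken toward the lower threshold.
#'
#' @inheritParams combined_sigma
#' @return Optimal threshold \eqn{E_b} in keV.
#' @export
optimal_threshold <- function(sweep, tube_voltage_kv, n_total = 1e5,
                              rule = c("max", "rss")) {
  rule <- match.arg(rule)
  r <- sweep$records
  e_bs <- sort(unique(r$e_b[r$tube_voltage_kv == tube_voltage_kv]))
  if (length(e_bs) == 0) {
    abort("no thresholds evaluated at this voltage", class = "pcthresh_config_error")
  }
  sig <- vapply(e_bs, function(eb)
    combined_sigma(sweep, tube_voltage_kv, eb, n_total, rule), 0)
  if (all(!is.finite(sig))) {
    abort("all thresholds unanalyzable at this voltage",
          class = "pcthresh_invalid_measurement")
  }
  e_bs[which.min(sig)]
}

#' Per-voltage optimum summary
#'
#' @param sweep A `pc_sweep`.
#' @return Tibble with one row per (tube voltage, photon count): the optimal
#'   threshold and minimum combined \eqn{\sigma(Z)} under the max rule and
#'   the root-sum-square alternative.
#' @export
threshold_summary <- function(sweep) {
  stopifnot(inherits(sweep, "pc_sweep"))
  sweep$summary
}

#' Appropriate threshold range
#'
#' The `[min, max]` range of the per-voltage optimal thresholds at one
#' photon count — the "appropriate energy threshold range" of the study.
#'
#' @param sweep A `pc_sweep`.
#' @param n_total Photon count level (default \eqn{10^5}).
#' @param rule Combination rule, `"max"` or `"rss"`.
#' @return Named numeric vector `c(min = , max = )` in keV.
#' @export
threshold_range <- function(sweep, n_total = 1e5, rule = c("max", "rss")) {
  rule <- match.arg(rule)
  s <- sweep$summary[sweep$summary$n_total == n_total, ]
  if (nrow(s) == 0) {
    abort(sprintf("no summary rows at n_total = %g", n_total),
          class = "pcthresh_config_error")
  }
  col <- if (rule == "max") "optimal_e_b" else "optimal_e_b_rss"
  c(min = min(s[[col]]), max = max(s[[col]]))
}

#' @export
print.pc_sweep <- function(x, ...) {
  cat(sprintf("<pc_sweep> %d records, %d voltages, modes: %s\n",
              nrow(x$records), length(x$config$tube_voltages_kv),
              paste(x$config$modes, collapse = "/")))
  if (nrow(x$summary)) {
    print(x$summary, n = 10)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pc_sweep <- function(x, ...) x$records

#' @exportS3Method generics::glance
glance.pc_sweep <- function(x, ...) {
  n_ref <- if (1e5 %in% x$summary$n_total) 1e5 else
    suppressWarnings(max(x$summary$n_total))
  rng <- if (nrow(x$summary)) threshold_range(x, n_ref) else c(NA, NA)
  tibble(
    n_records = nrow(x$records),
    n_voltages = length(x$config$tube_voltages_kv),
    n_total_ref = if (nrow(x$summary)) n_ref else NA_real_,
    threshold_min = rng[[1]], threshold_max = rng[[2]],
    master_seed = x$config$master_seed
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.pc_sweep <- function(object, n_total = 1e5, rule = "max", ...) {
  s <- object$records |>
    dplyr::filter(!is.na(.data$n_total), .data$n_total == !!n_total) |>
    dplyr::group_by(.data$tube_voltage_kv, .data$e_b, .data$material) |>
    dplyr::summarise(worst_sigma = max(ifelse(.data$analytic_valid,
                                              .data$sigma_z, Inf)),
                     .groups = "drop") |>
    dplyr::group_by(.data$tube_voltage_kv, .data$e_b) |>
    dplyr::summarise(combined = if (rule == "max") max(.data$worst_sigma) else
      sqrt(sum(.data$worst_sigma^2)), .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$e_b, y = .data$combined,
                                  colour = factor(.data$tube_voltage_kv))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Energy threshold Eb (keV)",
                  y = "Combined worst-case sigma(Z)",
                  colour = "Tube voltage (kV)",
                  title = sprintf("N = %g incident photons", n_total))
}

#' Write sweep results to disk
#'
#' Writes `records.csv` (long format, one row per grid cell, stable column
#' order), `summary.json` (per-voltage optima, the appropriate threshold
#' range per photon count, and the resolved configuration including the
#' master seed for exact replay).
#'
#' @param sweep A `pc_sweep`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(sweep, dir) {
  stopifnot(inherits(sweep, "pc_sweep"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(sprintf("cannot create output directory '%s'", dir),
          class = "pcthresh_io_error")
  }
  csv <- file.path(dir, "records.csv")
  readr::write_csv(sweep$records, csv)
  ranges <- lapply(unique(sweep$summary$n_total), function(n) {
    rng <- threshold_range(sweep, n)
    list(n_total = n, min_kev = rng[["min"]], max_kev = rng[["max"]])
  })
  cfg <- sweep$config
  json <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(
      per_voltage_optima = sweep$summary,
      appropriate_threshold_range = ranges,
      config = list(
        tube_voltages_kv = cfg$tube_voltages_kv,
        materials = cfg$materials,
        n_totals = cfg$n_totals,
        thresholds = cfg$thresholds %||% "21..Ec-1 step 1",
        modes = cfg$modes,
        n_repeats = cfg$n_repeats,
        master_seed = cfg$master_seed,
        e_a = cfg$e_a,
        filtration_mm_al = cfg$filtration_mm_al,
        include_air_noise = cfg$include_air_noise,
        elements_z = cfg$elements$z,
        spectrum_model = cfg$model$id,
        bh_n_grid = cfg$bh_n_grid
      )
    ),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(records = csv, summary = json))
}
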