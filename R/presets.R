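# Instrument, tissue and cell presets.
#
# Presets are shipped as a YAML file under inst/extdata and materialised as
# small validated S3 objects. Instrument presets describe the indenter and
# acquisition settings (SI units); tissue presets describe the regional
# Young's modulus distribution (kPa) that the synthetic generator targets;
# cell presets are Bernoulli probabilities for positive-cell scoring.

.preset_env <- new.env(parent = emptyenv())

#' Load the built-in preset table
#'
#' Reads the YAML preset file shipped with the package (or a user-supplied
#' one) and returns the raw named list with `instruments`, `tissues` and
#' `cells` entries.
#'
#' @param path Path to a preset YAML file; defaults to the packaged file.
#' @return A named list of preset definitions.
#' @export
load_presets <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.preset_env$builtin)) return(.preset_env$builtin)
    path <- system.file("extdata", "presets.yaml", package = "cardioelast")
    presets <- yaml::read_yaml(path)
    .preset_env$builtin <- presets
    return(presets)
  }
  yaml::read_yaml(path)
}

#' List the names of built-in presets
#'
#' @return A list with character vectors `instruments`, `tissues`, `cells`.
#' @export
preset_names <- function() {
  p <- load_presets()
  lapply(p[c("instruments", "tissues", "cells")], names)
}

validate_instrument <- function(x) {
  stopifnot(is.list(x))
  num_fields <- c("R", "k", "nu", "setpoint", "z_length", "z_step",
                  "grid_n", "grid_extent", "max_fit_depth", "noise_sd",
                  "baseline_slope_sd")
  for (f in num_fields) {
    if (!is.numeric(x[[f]]) || length(x[[f]]) != 1L || !is.finite(x[[f]]))
      stop_user("instrument preset field '", f, "' must be a finite number")
  }
  if (x$R <= 0) stop_user("tip radius R must be > 0")
  if (x$k <= 0) stop_user("spring constant k must be > 0")
  if (x$nu < 0 || x$nu > 0.5 + 1e-9)
    stop_user("poisson ratio must be in [0, 0.5]")
  if (x$grid_n < 1) stop_user("grid_n must be >= 1")
  if (x$max_fit_depth <= 0) stop_user("max_fit_depth must be > 0")
  if (x$z_step <= 0 || x$z_length <= x$z_step)
    stop_user("z_length must exceed z_step > 0")
  if (!x$tip_shape %in% c("sphere", "cono_spherical"))
    stop_user("tip_shape must be 'sphere' or 'cono_spherical'")
  if (length(x$offset_range) != 2L || any(x$offset_range < 0) ||
      diff(x$offset_range) < 0)
    stop_user("contact offset range must be increasing and non-negative")
  x
}

#' Instrument preset
#'
#' Fetch a built-in instrument preset by name, optionally overriding fields.
#' The two built-ins are `"colloidal"` (spherical colloidal-probe AFM tip,
#' R = 5.4 um, k = 0.2 N/m, 16 nN setpoint, 6 um ramp, 16x16 grid over
#' 20x20 um) and `"nanoindenter"` (rigid cono-spherical probe, R = 100 um,
#' treated as a sphere for indentation depths below 30 um).
#'
#' @param name Preset name, or `NULL` to build one purely from `...`.
#' @param ... Field overrides: `tip_shape`, `R`, `k`, `nu`, `setpoint`,
#'   `z_length`, `z_step`, `grid_n`, `grid_extent`, `max_fit_depth`,
#'   `noise_sd`, `baseline_slope_sd`, `offset_range` (length 2, m).
#' @return An object of class `instrument_preset`.
#' @examples
#' instrument_preset("colloidal")
#' instrument_preset("colloidal", grid_n = 8, noise_sd = 0)
#' @export
instrument_preset <- function(name = "colloidal", ...) {
  over <- list(...)
  x <- list()
  if (!is.null(name)) {
    raw <- load_presets()$instruments[[name]]
    if (is.null(raw)) stop_user("unknown instrument preset '", name, "'")
    x <- list(
      name = name,
      tip_shape = raw$tip_shape,
      R = raw$tip_radius_m,
      k = raw$spring_constant_N_per_m,
      nu = raw$poisson_ratio,
      setpoint = raw$setpoint_force_N,
      z_length = raw$z_length_m,
      z_step = raw$z_step_m,
      grid_n = as.integer(raw$grid_n),
      grid_extent = raw$grid_extent_m,
      max_fit_depth = raw$max_fit_depth_m,
      noise_sd = raw$noise_sd_force_N,
      baseline_slope_sd = raw$baseline_slope_sd_N_per_m,
      offset_range = c(raw$contact_offset_min_m, raw$contact_offset_max_m),
      source = raw$source
    )
  }
  x[names(over)] <- over
  x$name <- x$name %||% "custom"
  x$grid_n <- as.integer(x$grid_n)
  x <- validate_instrument(x)
  class(x) <- "instrument_preset"
  x
}

#' @export
print.instrument_preset <- function(x, ...) {
  cat(sprintf("Instrument preset '%s' (%s tip)\n", x$name, x$tip_shape))
  cat(sprintf("  R = %.3g um, k = %.3g N/m, nu = %.2f\n",
              x$R * 1e6, x$k, x$nu))
  cat(sprintf("  setpoint = %.3g nN, ramp = %.3g um (step %.3g nm)\n",
              x$setpoint * 1e9, x$z_length * 1e6, x$z_step * 1e9))
  cat(sprintf("  grid %dx%d over %.3g um, max fit depth %.3g um\n",
              x$grid_n, x$grid_n, x$grid_extent * 1e6,
              x$max_fit_depth * 1e6))
  invisible(x)
}

#' Tissue preset
#'
#' A tissue preset fixes the across-section distribution of the regional
#' Young's modulus (section-scale mean and SD, in kPa) together with the
#' within-section pixel coefficient of variation used by the synthetic
#' stiffness-field generator.
#'
#' @param name Built-in preset name (see [preset_names()]), or `NULL` for a
#'   custom preset specified via `mean_kPa`/`sd_kPa`/`pixel_cv`.
#' @param mean_kPa,sd_kPa,pixel_cv Overrides for the section-scale mean and
#'   SD (kPa) and the within-section pixel coefficient of variation.
#' @return An object of class `tissue_preset`.
#' @examples
#' tissue_preset("cortical")
#' tissue_preset(NULL, mean_kPa = 5, sd_kPa = 1)
#' @export
tissue_preset <- function(name = NULL, mean_kPa = NULL, sd_kPa = NULL,
                          pixel_cv = NULL) {
  x <- list(name = "custom", mean_kPa = NA_real_, sd_kPa = NA_real_,
            pixel_cv = 0.3, source = "user-defined")
  if (!is.null(name)) {
    raw <- load_presets()$tissues[[name]]
    if (is.null(raw)) stop_user("unknown tissue preset '", name, "'")
    x <- list(name = name, mean_kPa = raw$E_mean_kPa, sd_kPa = raw$E_sd_kPa,
              pixel_cv = raw$pixel_cv, source = raw$source)
  }
  if (!is.null(mean_kPa)) x$mean_kPa <- mean_kPa
  if (!is.null(sd_kPa)) x$sd_kPa <- sd_kPa
  if (!is.null(pixel_cv)) x$pixel_cv <- pixel_cv
  if (!is.finite(x$mean_kPa) || x$mean_kPa <= 0)
    stop_user("tissue preset mean must be > 0")
  if (!is.finite(x$sd_kPa) || x$sd_kPa < 0)
    stop_user("tissue preset sd must be >= 0")
  if (!is.finite(x$pixel_cv) || x$pixel_cv < 0)
    stop_user("tissue preset pixel_cv must be >= 0")
  class(x) <- "tissue_preset"
  x
}

#' @export
print.tissue_preset <- function(x, ...) {
  cat(sprintf("Tissue preset '%s': E = %.3g +/- %.3g kPa, pixel CV %.2f\n",
              x$name, x$mean_kPa, x$sd_kPa, x$pixel_cv))
  cat(" ", x$source, "\n")
  invisible(x)
}

#' Cell preset
#'
#' A Bernoulli probability for a positive-cell score (e.g. nuclear-YAP
#' localisation), used by [generate_cell_table()].
#'
#' @param name Built-in preset name, or `NULL` with `p_positive` given.
#' @param p_positive Override probability in `[0, 1]`.
#' @return An object of class `cell_preset`.
#' @export
cell_preset <- function(name = NULL, p_positive = NULL) {
  x <- list(name = "custom", p_positive = NA_real_, source = "user-defined")
  if (!is.null(name)) {
    raw <- load_presets()$cells[[name]]
    if (is.null(raw)) stop_user("unknown cell preset '", name, "'")
    x <- list(name = name, p_positive = raw$p_positive, source = raw$source)
  }
  if (!is.null(p_positive)) x$p_positive <- p_positive
  if (!is.finite(x$p_positive) || x$p_positive < 0 || x$p_positive > 1)
    stop_user("p_positive must be in [0, 1]")
  class(x) <- "cell_preset"
  x
}

#' @export
print.cell_preset <- function(x, ...) {
  cat(sprintf("Cell preset '%s': P(positive) = %.3f\n  %s\n",
              x$name, x$p_positive, x$source))
  invisible(x)
}
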