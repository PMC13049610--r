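# Synthetic-data generators: force curves, stiffness fields, section
# phantoms and cell tables with known ground truth.
#
# The stiffness model is a two-level log-normal. A section-level scale E_s
# is drawn from a log-normal moment-matched to the preset's across-section
# (mean, SD); per-pixel moduli are log-normal with MEDIAN E_s and a fixed
# coefficient of variation. Median-targeting at the pixel level makes the
# pooled-median aggregation of the analysis pipeline an unbiased estimator
# of E_s, so recovery of the preset mean across sections is well-posed.

# meanlog/sdlog of a log-normal with the requested mean and sd
lognormal_params <- function(mean, sd) {
  if (mean <= 0) stop_user("log-normal mean must be > 0")
  if (sd < 0) stop_user("log-normal sd must be >= 0")
  s2 <- log1p((sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Sample ground-truth stiffness fields
#'
#' Draws `n_sections` sections. Each section receives a scale `E_s` from a
#' log-normal whose mean and SD equal the tissue preset's `mean_kPa` and
#' `sd_kPa`, and `n_fields` pixel grids whose per-pixel moduli are
#' log-normal with median `E_s` and coefficient of variation
#' `preset$pixel_cv`.
#'
#' @param preset A [tissue_preset()].
#' @param instrument An [instrument_preset()] (supplies the grid geometry).
#' @param n_sections Number of sections to draw.
#' @param n_fields Number of pixel grids (maps) per section.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A list of sections; each section is a list with `scale_kPa`
#'   (the ground-truth `E_s`) and `fields`, a list of `grid_n x grid_n`
#'   matrices of moduli in Pa (class `stiffness_field`, with `pixel_size_m`
#'   and `region` attributes).
#' @export
sample_stiffness_field <- function(preset, instrument, n_sections = 1L,
                                   n_fields = 3L, seed = NULL) {
  stopifnot(inherits(preset, "tissue_preset"),
            inherits(instrument, "instrument_preset"))
  if (n_sections < 1L || n_fields < 1L)
    stop_user("n_sections and n_fields must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p_s <- lognormal_params(preset$mean_kPa, preset$sd_kPa)
  sd_pix <- sqrt(log1p(preset$pixel_cv^2))
  n <- instrument$grid_n
  px <- instrument$grid_extent / n
  lapply(seq_len(n_sections), function(s) {
    scale_kPa <- if (preset$sd_kPa == 0) preset$mean_kPa else
      stats::rlnorm(1, p_s["meanlog"], p_s["sdlog"])
    fields <- lapply(seq_len(n_fields), function(m) {
      vals <- if (preset$pixel_cv == 0) rep(scale_kPa * 1000, n * n) else
        stats::rlnorm(n * n, log(scale_kPa * 1000), sd_pix)
      structure(matrix(vals, n, n), class = "stiffness_field",
                pixel_size_m = px, region = preset$name)
    })
    list(scale_kPa = scale_kPa, fields = fields)
  })
}

#' Generate one synthetic force-distance curve
#'
#' The extend segment has a pre-contact region (affine baseline tilt plus
#' Gaussian force noise) followed by contact obeying the spherical Hertz
#' law. Cantilever bending is modelled self-consistently: at piezo height z
#' the indentation solves `delta + F(delta)/k = z - z*`. The ramp is
#' truncated once the setpoint force is reached; the retract segment
#' mirrors extend (no adhesion unless requested). The deflection channel is
#' `d = F/k`.
#'
#' @param E_true Ground-truth Young's modulus (Pa), > 0.
#' @param instrument An [instrument_preset()].
#' @param contact_offset Piezo height of first contact `z*` (m), within the
#'   ramp.
#' @param seed Optional integer seed (`NULL`: current RNG stream).
#' @param noise_sd Gaussian force noise SD (N); default from the preset.
#' @param baseline_slope Baseline tilt (N/m); default drawn from
#'   `N(0, preset$baseline_slope_sd)`.
#' @param adhesion_force Optional adhesion dip (N) applied to the retract
#'   segment only, to exercise extend-only fitting.
#' @param retract Include a retract segment?
#' @return A [force_curve()]; the ground truth (`E_true`,
#'   `contact_offset`) is attached as the `"truth"` attribute and is never
#'   read by the fitting code.
#' @export
generate_force_curve <- function(E_true, instrument, contact_offset = NULL,
                                 seed = NULL, noise_sd = NULL,
                                 baseline_slope = NULL,
                                 adhesion_force = 0, retract = TRUE) {
  stopifnot(inherits(instrument, "instrument_preset"))
  if (!is.numeric(E_true) || length(E_true) != 1L || E_true <= 0)
    stop_user("E_true must be a single positive modulus in Pa")
  if (!is.null(seed)) set.seed(seed)
  contact_offset <- contact_offset %||%
    stats::runif(1, instrument$offset_range[1], instrument$offset_range[2])
  if (contact_offset < 0 || contact_offset >= instrument$z_length)
    stop_user("contact_offset must lie within the z ramp")
  noise_sd <- noise_sd %||% instrument$noise_sd
  baseline_slope <- baseline_slope %||%
    (if (instrument$baseline_slope_sd > 0)
      stats::rnorm(1, 0, instrument$baseline_slope_sd) else 0)

  k <- instrument$k
  AE <- hertz_prefactor(instrument$R, instrument$nu) * E_true
  z <- seq(0, instrument$z_length, by = instrument$z_step)
  f_true <- numeric(length(z))
  post <- z > contact_offset
  if (any(post)) {
    zz <- z[post] - contact_offset
    delta <- solve_indentation(zz, AE / k)
    f_true[post] <- AE * delta^1.5
  }
  hit <- which(f_true >= instrument$setpoint)
  if (length(hit)) {
    z <- z[1:hit[1L]]
    f_true <- f_true[1:hit[1L]]
  } else {
    floor_f <- max(20 * noise_sd, 0.01 * instrument$setpoint)
    if (max(f_true) < floor_f)
      stop_user("setpoint unreachable within the z ramp: sample too soft ",
                "for this setpoint/ramp combination")
  }
  n <- length(z)
  f_ext <- f_true + baseline_slope * z +
    (if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0)
  seg <- rep("extend", n)
  z_all <- z
  f_all <- f_ext
  if (retract) {
    f_ret_true <- rev(f_true)
    z_ret <- rev(z)
    if (adhesion_force > 0) {
      w <- 20 * instrument$z_step
      f_ret_true <- f_ret_true -
        adhesion_force * exp(-((z_ret - contact_offset) / w)^2)
    }
    f_ret <- f_ret_true + baseline_slope * z_ret +
      (if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0)
    z_all <- c(z_all, z_ret)
    f_all <- c(f_all, f_ret)
    seg <- c(seg, rep("retract", n))
  }
  meta <- list(tip_radius_m = instrument$R,
               spring_constant_N_per_m = k,
               poisson_ratio = instrument$nu,
               instrument = instrument$name)
  curve <- force_curve(z = z_all, deflection = f_all / k, force = f_all,
                       segment = seg, metadata = meta)
  attr(curve, "truth") <- list(E_true = E_true,
                               contact_offset = contact_offset)
  curve
}

# invert z - z* = delta + c * delta^(3/2) for delta (Newton, vectorised)
solve_indentation <- function(zz, c_ratio, iters = 60L, tol = 1e-18) {
  delta <- zz
  for (i in seq_len(iters)) {
    g <- delta + c_ratio * delta^1.5 - zz
    step <- g / (1 + 1.5 * c_ratio * sqrt(delta))
    delta <- pmax(delta - step, 0)
    if (max(abs(step)) < tol) break
  }
  delta
}

#' Generate a full synthetic indentation map dataset
#'
#' One synthetic section: a section scale, `n_maps` ground-truth stiffness
#' fields, and one force curve per pixel with a random contact offset.
#'
#' @param preset A [tissue_preset()].
#' @param instrument An [instrument_preset()].
#' @param n_maps Number of maps (pixel grids).
#' @param seed Optional integer seed.
#' @param ... Passed to [generate_force_curve()] (e.g. `noise_sd = 0`).
#' @return A list with `scale_kPa`, `fields` (ground truth) and `curves`
#'   (a list of maps, each a list of `grid_n^2` pixel-tagged curves).
#' @export
generate_map_dataset <- function(preset, instrument, n_maps = 3L,
                                 seed = NULL, ...) {
  if (n_maps < 1L) stop_user("n_maps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  section <- sample_stiffness_field(preset, instrument, n_sections = 1L,
                                    n_fields = n_maps)[[1L]]
  n <- instrument$grid_n
  curves <- lapply(section$fields, function(field) {
    cv_list <- vector("list", n * n)
    for (j in seq_len(n)) {
      for (i in seq_len(n)) {
        off <- stats::runif(1, instrument$offset_range[1],
                            instrument$offset_range[2])
        cv <- generate_force_curve(field[i, j], instrument,
                                   contact_offset = off, ...)
        cv$pixel <- c(i, j)
        cv_list[[(j - 1L) * n + i]] <- cv
      }
    }
    cv_list
  })
  list(scale_kPa = section$scale_kPa, fields = section$fields,
       curves = curves)
}

#' Generate a synthetic histology section phantom
#'
#' Emulates a stained transverse heart section at a regeneration stage with
#' a regionalised injury: a cell-rich injury centre (DAPI++), a cell-poor
#' fibrin band (DAPI-) of known rectangular geometry, an injury border
#' (DAPI+), and surrounding myocardium. Regions are horizontal stripes with
#' the fibrin band embedded as a rectangle of the requested length/width;
#' nuclei are placed by a homogeneous Poisson process per region; all masks
#' are recorded as ground truth.
#'
#' @param extent_um Width/height of the phantom (um), length-2 vector.
#' @param pixel_um Mask pixel size (um).
#' @param band_length_um,band_width_um Fibrin band geometry (um), > 0.
#' @param densities Named nuclei densities per um^2 for `center`, `border`,
#'   `fibrin`, `myocardium`; must satisfy center >= border >= fibrin.
#' @param stiffness Named list mapping region labels to [tissue_preset()]
#'   names used for the ground-truth stiffness field.
#' @param seed Optional integer seed.
#' @return An object of class `section_phantom`: `labels` (character
#'   matrix, rows = y from bottom), `nuclei` (data frame `x_um`, `y_um`,
#'   `region`), `E_kPa` (matrix), `pixel_um`, `extent_um`, `band`
#'   (geometry), `densities`.
#' @export
generate_section_phantom <- function(extent_um = c(600, 600),
                                     pixel_um = 2,
                                     band_length_um = 300,
                                     band_width_um = 40,
                                     densities = c(center = 0.008,
                                                   border = 0.003,
                                                   fibrin = 0.0005,
                                                   myocardium = 0.004),
                                     stiffness = list(
                                       DAPI_plus_plus = "injury14_center",
                                       DAPI_minus = "injury14_dapi_neg",
                                       DAPI_plus = "injury14_myocardium",
                                       myocardium = "injury14_myocardium"),
                                     seed = NULL) {
  if (band_length_um <= 0 || band_width_um <= 0)
    stop_user("band length and width must be > 0")
  if (any(densities < 0)) stop_user("densities must be >= 0")
  req <- c("center", "border", "fibrin", "myocardium")
  if (!all(req %in% names(densities)))
    stop_user("densities must be named: ", paste(req, collapse = ", "))
  if (!(densities["center"] >= densities["border"] &&
        densities["border"] >= densities["fibrin"]))
    stop_user("nuclei densities must satisfy center >= border >= fibrin")
  if (!is.null(seed)) set.seed(seed)
  W <- extent_um[1]; H <- extent_um[2]
  ncol_px <- round(W / pixel_um)
  nrow_px <- round(H / pixel_um)
  y_center_top <- 0.25 * H
  y_band_top <- y_center_top + band_width_um
  y_border_top <- y_band_top + 0.2 * H
  if (y_border_top >= H || band_length_um > W)
    stop_user("overlapping region geometry: band does not fit the extent")

  yc <- (seq_len(nrow_px) - 0.5) * pixel_um   # pixel-centre y, bottom-up
  xc <- (seq_len(ncol_px) - 0.5) * pixel_um
  labels <- matrix("myocardium", nrow_px, ncol_px)
  labels[yc < y_border_top, ] <- "DAPI_plus"
  band_rows <- yc >= y_center_top & yc < y_band_top
  x0 <- (W - band_length_um) / 2
  band_cols <- xc >= x0 & xc < x0 + band_length_um
  labels[band_rows, ] <- "DAPI_plus"
  labels[band_rows, band_cols] <- "DAPI_minus"
  labels[yc < y_center_top, ] <- "DAPI_plus_plus"

  dens_of <- c(DAPI_plus_plus = unname(densities["center"]),
               DAPI_plus = unname(densities["border"]),
               DAPI_minus = unname(densities["fibrin"]),
               myocardium = unname(densities["myocardium"]))
  nuclei <- list()
  for (lab in names(dens_of)) {
    idx <- which(labels == lab)
    if (!length(idx)) next
    area <- length(idx) * pixel_um^2
    n_nuc <- stats::rpois(1, dens_of[[lab]] * area)
    if (n_nuc == 0L) next
    pick <- idx[sample.int(length(idx), n_nuc, replace = TRUE)]
    row <- (pick - 1L) %% nrow_px + 1L
    col <- (pick - 1L) %/% nrow_px + 1L
    nuclei[[lab]] <- data.frame(
      x_um = (col - 1L) * pixel_um + stats::runif(n_nuc, 0, pixel_um),
      y_um = (row - 1L) * pixel_um + stats::runif(n_nuc, 0, pixel_um),
      region = lab, stringsAsFactors = FALSE)
  }
  nuclei <- if (length(nuclei)) do.call(rbind, c(nuclei,
                                                 make.row.names = FALSE))
            else data.frame(x_um = numeric(0), y_um = numeric(0),
                            region = character(0))

  E_kPa <- matrix(NA_real_, nrow_px, ncol_px)
  for (lab in names(stiffness)) {
    idx <- which(labels == lab)
    if (!length(idx)) next
    tp <- tissue_preset(stiffness[[lab]])
    p_s <- lognormal_params(tp$mean_kPa, tp$sd_kPa)
    scale_kPa <- stats::rlnorm(1, p_s["meanlog"], p_s["sdlog"])
    E_kPa[idx] <- stats::rlnorm(length(idx), log(scale_kPa),
                                sqrt(log1p(tp$pixel_cv^2)))
  }
  structure(list(labels = labels, nuclei = nuclei, E_kPa = E_kPa,
                 pixel_um = pixel_um, extent_um = extent_um,
                 band = list(length_um = band_length_um,
                             width_um = band_width_um,
                             y0_um = y_center_top, x0_um = x0),
                 densities = densities, seed = seed),
            class = "section_phantom")
}

#' @export
print.section_phantom <- function(x, ...) {
  cat(sprintf("Section phantom %g x %g um (%g um pixels)\n",
              x$extent_um[1], x$extent_um[2], x$pixel_um))
  cat(sprintf("  fibrin band %g x %g um; %d nuclei\n",
              x$band$length_um, x$band$width_um, nrow(x$nuclei)))
  print(table(x$labels))
  invisible(x)
}

#' Generate a synthetic scored-cell table
#'
#' Cells receive i.i.d. Bernoulli positive flags (e.g. nuclear-YAP
#' localisation) with the preset probability.
#'
#' @param preset A [cell_preset()].
#' @param n_cells Number of cells, >= 1.
#' @param seed Optional integer seed.
#' @return A data frame with `cell_id`, `region` (the preset name) and
#'   logical `positive`.
#' @export
generate_cell_table <- function(preset, n_cells, seed = NULL) {
  stopifnot(inherits(preset, "cell_preset"))
  if (n_cells < 1L) stop_user("n_cells must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  data.frame(cell_id = seq_len(n_cells), region = preset$name,
             positive = stats::runif(n_cells) < preset$p_positive,
             stringsAsFactors = FALSE)
}
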