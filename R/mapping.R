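# Stiffness-map assembly and the hierarchical aggregation:
# per-map grids -> per-region pooled medians (E_A, E_B, E_C) ->
# mean-of-medians E_final per section.

#' Assemble per-pixel fit results into a stiffness map
#'
#' @param results A `hertz_batch` (from [batch_fit()]) or a data frame with
#'   `pixel_row`, `pixel_col`, `E_Pa`, `valid`.
#' @param instrument An [instrument_preset()] supplying grid size and
#'   physical extent.
#' @param region,section_id,map_id Optional labels carried as attributes.
#' @return An object of class `stiffness_map`: a `grid_n x grid_n` numeric
#'   matrix of moduli in Pa with `NA` at invalid/missing pixels, plus
#'   `extent_m`, `region`, `section_id`, `map_id` and `valid_fraction`
#'   attributes.
#' @export
assemble_map <- function(results, instrument, region = NA_character_,
                         section_id = NA_character_,
                         map_id = NA_character_) {
  if (inherits(results, "hertz_batch")) results <- as.data.frame(results)
  stopifnot(is.data.frame(results))
  n <- instrument$grid_n
  if (!nrow(results)) stop_user("no fit results to assemble")
  if (any(is.na(results$pixel_row)) || any(is.na(results$pixel_col)))
    stop_user("all results must carry pixel keys")
  if (any(results$pixel_row < 1 | results$pixel_row > n |
          results$pixel_col < 1 | results$pixel_col > n))
    stop_user("pixel index out of grid bounds")
  key <- paste(results$pixel_row, results$pixel_col)
  if (anyDuplicated(key)) stop_user("duplicate pixel keys in fit results")
  grid <- matrix(NA_real_, n, n)
  ok <- results$valid & is.finite(results$E_Pa)
  grid[cbind(results$pixel_row[ok], results$pixel_col[ok])] <-
    results$E_Pa[ok]
  structure(grid, class = c("stiffness_map", "matrix"),
            extent_m = instrument$grid_extent, region = region,
            section_id = section_id, map_id = map_id,
            valid_fraction = sum(ok) / (n * n))
}

map_values <- function(x) {
  if (inherits(x, "stiffness_map") || is.matrix(x)) as.numeric(x)
  else as.numeric(x)
}

#' @export
print.stiffness_map <- function(x, ...) {
  v <- map_values(x)
  cat(sprintf(
    "Stiffness map %dx%d over %.3g um (%.0f%% valid pixels)\n",
    nrow(x), ncol(x), attr(x, "extent_m") * 1e6,
    100 * attr(x, "valid_fraction")))
  cat(sprintf("  E median %.3g kPa, range %.3g .. %.3g kPa\n",
              stats::median(v, na.rm = TRUE) / 1000,
              min(v, na.rm = TRUE) / 1000, max(v, na.rm = TRUE) / 1000))
  invisible(x)
}

#' @export
plot.stiffness_map <- function(x, zlim_kPa = NULL, ...) {
  m <- unclass(x) / 1000
  ext <- attr(x, "extent_m") * 1e6
  xs <- seq(0, ext, length.out = ncol(m))
  ys <- seq(0, ext, length.out = nrow(m))
  graphics::image(xs, ys, t(m), zlim = zlim_kPa,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (um)", ylab = "y (um)", useRaster = TRUE, ...)
  invisible(x)
}

#' Pooled median modulus of one region
#'
#' The median over ALL valid pixels pooled across the region's maps (not a
#' median of per-map medians). Even pooled counts use the midpoint
#' convention of [stats::median()].
#'
#' @param maps A list of `stiffness_map`s / matrices / numeric vectors
#'   belonging to one region (typically 2-4 maps), or a single one.
#' @return The pooled median in the input unit (Pa for maps from
#'   [assemble_map()]).
#' @export
pooled_region_median <- function(maps) {
  if (!is.list(maps) || inherits(maps, "stiffness_map")) maps <- list(maps)
  if (!length(maps)) stop_user("pooled_region_median needs >= 1 map")
  vals <- unlist(lapply(maps, map_values), use.names = FALSE)
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop_user("no valid pixels in region")
  stats::median(vals)
}

#' Section summary E_final: mean of the per-region pooled medians
#'
#' @param region_medians Numeric vector of pooled region medians (E_A, E_B,
#'   E_C, ...).
#' @return Their arithmetic mean.
#' @export
aggregate_E_final <- function(region_medians) {
  region_medians <- unlist(region_medians, use.names = FALSE)
  if (!length(region_medians)) stop_user("no region medians supplied")
  mean(region_medians)
}

#' Region-level aggregate for one section
#'
#' Applies the pooled-median / mean-of-medians aggregation to maps grouped
#' by region and returns the tidy per-section table.
#'
#' @param maps_by_region Named list: one entry per region, each a list of
#'   maps (Pa).
#' @param section_id Section identifier.
#' @return An object of class `region_aggregate`: a data frame with
#'   `section_id`, `region`, `E_region_kPa`, `n_values`, and the section
#'   `E_final_kPa` attached both as a column and as an attribute.
#' @export
region_aggregate <- function(maps_by_region, section_id = "S1") {
  stopifnot(is.list(maps_by_region), length(maps_by_region) >= 1L)
  regions <- names(maps_by_region) %||%
    LETTERS[seq_along(maps_by_region)]
  med <- vapply(maps_by_region, pooled_region_median, numeric(1))
  nv <- vapply(maps_by_region, function(m) {
    if (!is.list(m) || inherits(m, "stiffness_map")) m <- list(m)
    sum(is.finite(unlist(lapply(m, map_values))))
  }, numeric(1))
  e_final <- aggregate_E_final(med)
  out <- data.frame(section_id = section_id, region = regions,
                    E_region_kPa = unname(med) / 1000,
                    n_values = unname(nv),
                    E_final_kPa = e_final / 1000,
                    stringsAsFactors = FALSE)
  attr(out, "E_final_kPa") <- e_final / 1000
  class(out) <- c("region_aggregate", "data.frame")
  out
}

#' Frequency distribution of map moduli
#'
#' Histogram counts of the valid pixel moduli pooled over the supplied
#' maps; the total count equals the number of valid pixels.
#'
#' @param maps A map, matrix, numeric vector, or list of them (Pa).
#' @param bin_width Bin width in kPa, > 0.
#' @return A data frame with `bin_left_kPa`, `bin_right_kPa`, `count`.
#' @export
frequency_distribution <- function(maps, bin_width = 1) {
  if (bin_width <= 0) stop_user("bin_width must be > 0")
  if (!is.list(maps) || inherits(maps, "stiffness_map")) maps <- list(maps)
  vals <- unlist(lapply(maps, map_values), use.names = FALSE)
  vals <- vals[is.finite(vals)] / 1000
  if (!length(vals))
    return(data.frame(bin_left_kPa = numeric(0),
                      bin_right_kPa = numeric(0), count = integer(0)))
  lo <- floor(min(vals) / bin_width) * bin_width
  breaks <- seq(lo, max(vals) + bin_width, by = bin_width)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE,
                      right = FALSE, include.lowest = TRUE)
  data.frame(bin_left_kPa = h$breaks[-length(h$breaks)],
             bin_right_kPa = h$breaks[-1], count = h$counts)
}

#' Write a stiffness map as CSV plus a JSON sidecar
#'
#' The CSV holds the grid in kPa with `NA` for invalid pixels; the sidecar
#' (`<path>.json`) records extent, region and identifiers.
#'
#' @param map A `stiffness_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stiffness_map <- function(map, path) {
  utils::write.table(unclass(map) / 1000, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  side <- list(extent_m = attr(map, "extent_m"),
               region = attr(map, "region"),
               section_id = attr(map, "section_id"),
               map_id = attr(map, "map_id"),
               valid_fraction = attr(map, "valid_fraction"),
               unit = "kPa")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
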