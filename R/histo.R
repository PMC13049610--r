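# Histology-derived quantifications: nuclei densities, DAPI-based region
# classification, fibrin-band morphometry, area and positive-cell
# fractions.

#' Nuclei density in sampling windows
#'
#' Counts nuclei whose centres fall inside each rectangular window
#' (left/top-closed, right/bottom-open boundaries) and divides by the
#' window area. The conventional sampling window is a small square (e.g.
#' 50 x 50 um) placed inside a region of interest.
#'
#' @param nuclei Data frame with `x_um`, `y_um` columns (e.g. from
#'   [generate_section_phantom()]).
#' @param windows Data frame with `x0`, `y0`, `x1`, `y1` (um), one row per
#'   window; `x1 > x0`, `y1 > y0`.
#' @return A data frame with `window`, `count`, `area_um2`,
#'   `density_per_um2`.
#' @export
nuclei_density <- function(nuclei, windows) {
  stopifnot(is.data.frame(nuclei), is.data.frame(windows))
  if (any(windows$x1 <= windows$x0) || any(windows$y1 <= windows$y0))
    stop_user("degenerate sampling window (zero or negative area)")
  counts <- vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sum(nuclei$x_um >= w$x0 & nuclei$x_um < w$x1 &
        nuclei$y_um >= w$y0 & nuclei$y_um < w$y1)
  }, numeric(1))
  area <- (windows$x1 - windows$x0) * (windows$y1 - windows$y0)
  data.frame(window = seq_len(nrow(windows)), count = counts,
             area_um2 = area, density_per_um2 = counts / area)
}

#' Tile a nuclei table into a density map
#'
#' Covers the extent with non-overlapping square windows and returns the
#' per-window density grid used by [classify_regions()].
#'
#' @param nuclei Data frame with `x_um`, `y_um`.
#' @param extent_um Length-2 extent (um).
#' @param window_um Window side (um); the default (75 um) keeps the Poisson
#'   counting noise small enough for reliable three-way classification at
#'   typical nuclei densities.
#' @return A list with `density` (matrix, rows = y from bottom), `x`, `y`
#'   (window-centre coordinates, um) and `window_um`.
#' @export
density_map <- function(nuclei, extent_um, window_um = 75) {
  nx <- max(1L, floor(extent_um[1] / window_um))
  ny <- max(1L, floor(extent_um[2] / window_um))
  wins <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  windows <- data.frame(x0 = (wins$ix - 1) * window_um,
                        y0 = (wins$iy - 1) * window_um,
                        x1 = wins$ix * window_um,
                        y1 = wins$iy * window_um)
  dens <- nuclei_density(nuclei, windows)$density_per_um2
  list(density = matrix(dens, ny, nx, byrow = TRUE),
       x = ((seq_len(nx)) - 0.5) * window_um,
       y = ((seq_len(ny)) - 0.5) * window_um,
       window_um = window_um)
}

#' Classify regions from a nuclei density map
#'
#' Three-way DAPI classification: `DAPI_minus` where density < `t_low`,
#' `DAPI_plus_plus` where density > `t_high`, `DAPI_plus` otherwise. The
#' default thresholds bracket the typical injury-centre/border/fibrin
#' densities.
#'
#' @param density Numeric matrix (or vector) of densities per um^2.
#' @param t_low,t_high Thresholds with `0 < t_low < t_high`.
#' @return A character matrix (or vector) of the same shape with labels
#'   `DAPI_minus`, `DAPI_plus`, `DAPI_plus_plus`.
#' @export
classify_regions <- function(density, t_low = 0.0012, t_high = 0.0055) {
  if (!(t_low > 0 && t_high > t_low))
    stop_user("thresholds must satisfy 0 < t_low < t_high")
  lab <- ifelse(density < t_low, "DAPI_minus",
                ifelse(density > t_high, "DAPI_plus_plus", "DAPI_plus"))
  if (is.matrix(density)) lab <- matrix(lab, nrow(density), ncol(density))
  lab
}

#' Fibrin-band morphometry
#'
#' Measures a band-like binary deposit: the length is the extent of the
#' mask along its principal axis, and the width is the mean of three
#' transects perpendicular to that axis at 25/50/75% of the length.
#'
#' @param mask Logical (or 0/1) matrix; rows = y, columns = x. Must be
#'   non-empty and connected (8-neighbourhood).
#' @param pixel_um Pixel size (um).
#' @return A list with `length_um`, `width_um`, `transect_positions`
#'   (fractions along the axis) and `transect_widths_um`.
#' @export
fibrin_morphometry <- function(mask, pixel_um = 1) {
  mask <- mask > 0
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop_user("empty mask")
  if (!mask_connected(mask)) stop_user("mask is not a connected deposit")
  # pixel-centre coordinates in um
  x <- (idx[, 2] - 0.5) * pixel_um
  y <- (idx[, 1] - 0.5) * pixel_um
  if (nrow(idx) == 1L)
    return(list(length_um = pixel_um, width_um = pixel_um,
                transect_positions = c(0.25, 0.5, 0.75),
                transect_widths_um = rep(pixel_um, 3)))
  cm <- cbind(x - mean(x), y - mean(y))
  ev <- eigen(crossprod(cm) / nrow(cm), symmetric = TRUE)$vectors
  u <- cm %*% ev[, 1]   # along principal axis
  v <- cm %*% ev[, 2]   # across
  len <- diff(range(u)) + pixel_um
  pos <- c(0.25, 0.5, 0.75)
  u_q <- min(u) + pos * diff(range(u))
  widths <- vapply(u_q, function(uq) {
    strip <- abs(u - uq) <= pixel_um / 2
    if (!any(strip)) return(NA_real_)
    diff(range(v[strip])) + pixel_um
  }, numeric(1))
  list(length_um = len, width_um = mean(widths, na.rm = TRUE),
       transect_positions = pos, transect_widths_um = widths)
}

# flood fill (8-neighbourhood) connectivity check
mask_connected <- function(mask) {
  idx <- which(mask)
  if (length(idx) <= 1L) return(TRUE)
  nr <- nrow(mask)
  nc <- ncol(mask)
  visited <- logical(length(mask))
  stack <- idx[1L]
  visited[stack] <- TRUE
  n_seen <- 1L
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    r <- (cur - 1L) %% nr + 1L
    cc <- (cur - 1L) %/% nr + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      j <- (c2 - 1L) * nr + r2
      if (mask[j] && !visited[j]) {
        visited[j] <- TRUE
        n_seen <- n_seen + 1L
        stack <- c(stack, j)
      }
    }
  }
  n_seen == length(idx)
}

#' Area fraction of a target mask within a region of interest
#'
#' `100 * |target AND roi| / |roi|`, e.g. the GFP-positive area fraction of
#' the inner injury site.
#'
#' @param target_mask,roi_mask Logical (or 0/1) matrices of equal shape;
#'   the ROI must be non-empty.
#' @return Percentage in `[0, 100]`.
#' @export
area_fraction <- function(target_mask, roi_mask) {
  target_mask <- target_mask > 0
  roi_mask <- roi_mask > 0
  stopifnot(identical(dim(target_mask), dim(roi_mask)))
  n_roi <- sum(roi_mask)
  if (n_roi == 0) stop_user("empty region of interest")
  100 * sum(target_mask & roi_mask) / n_roi
}

#' Positive-cell fraction per group
#'
#' `100 * positives / total` within each group (e.g. percentage of
#' endocardial cells with nuclear YAP per region).
#'
#' @param cell_table Data frame with a logical/0-1 `positive` column.
#' @param group_by Name of the grouping column (default `"region"`).
#' @return A data frame with the group, `n`, `n_positive`,
#'   `percent_positive`.
#' @export
positive_fraction <- function(cell_table, group_by = "region") {
  stopifnot(is.data.frame(cell_table), "positive" %in% names(cell_table))
  if (!group_by %in% names(cell_table))
    stop_user("no grouping column '", group_by, "'")
  if (!nrow(cell_table)) stop_user("empty cell table")
  groups <- split(cell_table$positive > 0, cell_table[[group_by]])
  out <- data.frame(group = names(groups),
                    n = vapply(groups, length, numeric(1)),
                    n_positive = vapply(groups, sum, numeric(1)),
                    stringsAsFactors = FALSE)
  names(out)[1] <- group_by
  out$percent_positive <- 100 * out$n_positive / out$n
  rownames(out) <- NULL
  out
}

#' Write / read a region mask
#'
#' Masks travel as plain CSV matrices by default (labels or 0/1); TIFF
#' output is available when the `tiff` package is installed.
#'
#' @param mask Matrix (logical, numeric or character labels).
#' @param path Output path.
#' @param format `"csv"` or `"tiff"` (single channel; numeric masks only).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, format = c("csv", "tiff")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.table(mask, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop_user("the 'tiff' package is required for TIFF output")
    m <- mask
    if (is.character(m)) stop_user("TIFF masks must be numeric or logical")
    m <- m * 1
    tiff::writeTIFF(m / max(m, 1), path)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                              stringsAsFactors = FALSE))
}
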