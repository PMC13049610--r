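# Force-distance curve container and plain-text I/O.
#
# A force curve records piezo height z (m, increasing toward the sample on
# extend) against cantilever deflection d (m) and/or force F (N), split into
# an extend and an optional retract segment. All internal units are SI.

#' Construct a force-distance curve
#'
#' @param z Numeric vector of piezo heights (m). Within each segment z must
#'   be strictly monotone (increasing on extend, decreasing on retract).
#' @param deflection Optional numeric vector of cantilever deflections (m).
#' @param force Optional numeric vector of forces (N). At least one of
#'   `deflection`/`force` must be present.
#' @param segment Character vector (recycled) with values `"extend"` /
#'   `"retract"`.
#' @param pixel Optional integer pair `c(row, col)` locating the curve in a
#'   map grid.
#' @param metadata Named list of instrument metadata (e.g. `tip_radius_m`,
#'   `spring_constant_N_per_m`, `poisson_ratio`).
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(z, deflection = NULL, force = NULL,
                        segment = "extend", pixel = NULL,
                        metadata = list()) {
  n <- length(z)
  segment <- rep_len(as.character(segment), n)
  if (!is.null(deflection) && length(deflection) != n)
    stop_user("deflection length must match z")
  if (!is.null(force) && length(force) != n)
    stop_user("force length must match z")
  if (is.null(deflection) && is.null(force))
    stop_user("a force curve needs a deflection or a force channel")
  if (!any(segment == "extend"))
    stop_user("the extend segment must be non-empty")
  for (seg in unique(segment)) {
    zi <- z[segment == seg]
    if (length(zi) > 1L) {
      dz <- diff(zi)
      if (!(all(dz > 0) || all(dz < 0)))
        stop_user("z must be strictly monotone within the '", seg,
                  "' segment")
    }
  }
  if (!is.null(pixel)) pixel <- as.integer(pixel[1:2])
  structure(list(z = as.numeric(z), d = deflection, f = force,
                 segment = segment, pixel = pixel, metadata = metadata),
            class = "force_curve")
}

extend_idx <- function(curve) which(curve$segment == "extend")

#' @export
print.force_curve <- function(x, ...) {
  ne <- sum(x$segment == "extend")
  nr <- sum(x$segment == "retract")
  ch <- c(if (!is.null(x$d)) "deflection", if (!is.null(x$f)) "force")
  cat(sprintf("Force curve: %d extend + %d retract samples (%s)\n",
              ne, nr, paste(ch, collapse = " + ")))
  cat(sprintf("  z range %.4g .. %.4g um\n",
              min(x$z) * 1e6, max(x$z) * 1e6))
  if (!is.null(x$pixel))
    cat(sprintf("  pixel (%d, %d)\n", x$pixel[1], x$pixel[2]))
  invisible(x)
}

#' @export
plot.force_curve <- function(x, ...) {
  f <- x$f %||% (x$d * (x$metadata$spring_constant_N_per_m %||% 1))
  ext <- x$segment == "extend"
  graphics::plot(x$z[ext] * 1e6, f[ext] * 1e9, type = "l",
                 xlab = "piezo height (um)", ylab = "force (nN)", ...)
  if (any(!ext))
    graphics::lines(x$z[!ext] * 1e6, f[!ext] * 1e9, col = "grey60")
  invisible(x)
}

#' Convert the deflection channel to force via Hooke's law
#'
#' Computes `F = k * d` elementwise. If the curve already carries a force
#' channel it is checked for consistency with `k * d` and an error is raised
#' when the two disagree beyond tolerance.
#'
#' @param curve A [force_curve()].
#' @param k Cantilever spring constant (N/m), > 0.
#' @param tol Relative tolerance for the consistency check.
#' @return The curve with a force channel.
#' @export
deflection_to_force <- function(curve, k, tol = 1e-6) {
  stopifnot(inherits(curve, "force_curve"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop_user("spring constant k must be a single positive number")
  if (is.null(curve$d)) stop_user("curve has no deflection channel")
  f_new <- k * curve$d
  if (!is.null(curve$f)) {
    scale <- max(abs(curve$f), k * max(abs(curve$d)), 1e-300)
    if (max(abs(curve$f - f_new)) > tol * scale)
      stop_user("existing force channel is inconsistent with k * deflection")
  }
  curve$f <- f_new
  curve$metadata$spring_constant_N_per_m <- k
  curve
}

curve_meta_keys <- c("tip_radius_m", "spring_constant_N_per_m",
                     "poisson_ratio")

#' Write force curves in the cardioelast TSV dialect
#'
#' The dialect is a plain-text stream: a `# cardioelast-curve v1` header,
#' `# key: value` metadata lines, a column header
#' `segment  z_m  deflection_m  force_N`, then one TSV row per sample
#' (missing channels left empty). Multiple curves are separated by a blank
#' line.
#'
#' @param curve A `force_curve` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  curves <- if (inherits(curve, "force_curve")) list(curve) else curve
  con <- file(path, open = "w")
  on.exit(close(con))
  first <- TRUE
  for (cv in curves) {
    stopifnot(inherits(cv, "force_curve"))
    if (!first) writeLines("", con)
    first <- FALSE
    writeLines("# cardioelast-curve v1", con)
    meta <- cv$metadata
    if (!is.null(cv$pixel)) {
      meta$pixel_row <- cv$pixel[1]
      meta$pixel_col <- cv$pixel[2]
    }
    for (key in names(meta)) {
      val <- meta[[key]]
      if (is.numeric(val)) val <- fmt_num(val)
      writeLines(sprintf("# %s: %s", key, paste(val, collapse = " ")), con)
    }
    writeLines("segment\tz_m\tdeflection_m\tforce_N", con)
    n <- length(cv$z)
    dcol <- if (is.null(cv$d)) rep("", n) else fmt_vec(cv$d)
    fcol <- if (is.null(cv$f)) rep("", n) else fmt_vec(cv$f)
    writeLines(paste(cv$segment, fmt_vec(cv$z), dcol, fcol, sep = "\t"), con)
  }
  invisible(path)
}

fmt_vec <- function(x) sprintf("%.17g", x)

#' Read force curves written in the cardioelast TSV dialect
#'
#' @param path Input file path.
#' @return A list of `force_curve` objects (possibly of length one).
#' @seealso [write_force_curve()]
#' @export
read_force_curves <- function(path) {
  lines <- readLines(path)
  # split into blocks at blank lines
  blank <- grepl("^\\s*$", lines)
  block_id <- cumsum(blank)
  blocks <- split(lines[!blank], block_id[!blank])
  lapply(unname(blocks), parse_curve_block)
}

#' Read a single force curve
#'
#' Convenience wrapper around [read_force_curves()] returning the first
#' curve in the file.
#'
#' @param path Input file path.
#' @return A `force_curve`.
#' @export
read_force_curve <- function(path) read_force_curves(path)[[1L]]

parse_curve_block <- function(lines) {
  if (!grepl("^# cardioelast-curve v1", lines[1]))
    stop_user("not a cardioelast curve block (missing version header)")
  meta_lines <- grep("^#", lines, value = TRUE)[-1L]
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([^:]+):\\s*(.*)$", ml))[[1L]]
    if (length(m) == 3L) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1L]]
  req <- c("segment", "z_m")
  if (!all(req %in% header))
    stop_user("curve file is missing required columns: ",
              paste(setdiff(req, header), collapse = ", "))
  if (!any(c("deflection_m", "force_N") %in% header))
    stop_user("curve file needs a deflection_m or force_N column")
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  tab <- do.call(rbind, lapply(rows, function(r) {
    length(r) <- length(header)
    r
  }))
  colnames(tab) <- header
  seg <- tab[, "segment"]
  z <- as.numeric(tab[, "z_m"])
  getcol <- function(name) {
    if (!name %in% header) return(NULL)
    v <- tab[, name]
    v[v == "" | is.na(v)] <- NA
    v <- as.numeric(v)
    if (all(is.na(v))) NULL else v
  }
  d <- getcol("deflection_m")
  f <- getcol("force_N")
  pixel <- NULL
  if (!is.null(meta$pixel_row) && !is.null(meta$pixel_col)) {
    pixel <- c(meta$pixel_row, meta$pixel_col)
    meta$pixel_row <- NULL
    meta$pixel_col <- NULL
  }
  force_curve(z = z, deflection = d, force = f, segment = seg,
              pixel = pixel, metadata = meta)
}
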