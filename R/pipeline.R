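# End-to-end pipeline: simulate -> preprocess -> fit -> map -> aggregate ->
# statistics, with a deterministic seed scheme and optional on-disk
# outputs.

#' Pipeline configuration
#'
#' @param tissue Tissue preset name or [tissue_preset()].
#' @param instrument Instrument preset name or [instrument_preset()].
#' @param n_sections Number of sections (hearts) to simulate.
#' @param n_regions Regions per section (maps are split evenly across
#'   regions A, B, C, ...).
#' @param maps_per_region Maps recorded per region.
#' @param grid_n Optional override of the per-map grid side.
#' @param seed Integer base seed; every downstream stream derives from it.
#' @param r2_min,min_points Curve QC thresholds passed to [hertz_fit()].
#' @param out_dir Optional output directory for CSV/JSON artefacts.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(tissue, instrument = "colloidal",
                            n_sections = 24L, n_regions = 3L,
                            maps_per_region = 1L, grid_n = NULL,
                            seed = 1L, r2_min = 0.8, min_points = 50L,
                            out_dir = NULL) {
  tissue <- if (inherits(tissue, "tissue_preset")) tissue
            else tissue_preset(tissue)
  instrument <- if (inherits(instrument, "instrument_preset")) instrument
               else instrument_preset(instrument)
  if (!is.null(grid_n)) instrument <- instrument_preset(
    instrument$name, grid_n = as.integer(grid_n))
  stopifnot(n_sections >= 1L, n_regions >= 1L, maps_per_region >= 1L)
  structure(list(tissue = tissue, instrument = instrument,
                 n_sections = as.integer(n_sections),
                 n_regions = as.integer(n_regions),
                 maps_per_region = as.integer(maps_per_region),
                 seed = as.integer(seed), r2_min = r2_min,
                 min_points = as.integer(min_points), out_dir = out_dir),
            class = "pipeline_config")
}

#' Fit and aggregate one section's curve dataset
#'
#' The recovery path of the pipeline: takes ONLY the curves (never the
#' ground truth), fits every pixel, assembles maps, groups them into
#' regions and applies the pooled-median / mean-of-medians aggregation.
#'
#' @param curves List of maps (each a list of pixel-tagged curves), e.g.
#'   the `curves` element of [generate_map_dataset()].
#' @param instrument An [instrument_preset()].
#' @param n_regions Number of regions the maps are split across.
#' @param section_id Section identifier.
#' @param ... QC arguments passed to [hertz_fit()].
#' @return A list with `aggregate` (a [region_aggregate()]), `maps`, and
#'   `n_valid`/`n_total` curve counts.
#' @export
fit_section_dataset <- function(curves, instrument, n_regions = 3L,
                                section_id = "S1", ...) {
  n_maps <- length(curves)
  if (n_maps %% n_regions != 0L)
    stop_user("number of maps (", n_maps,
              ") must be divisible by n_regions (", n_regions, ")")
  maps <- lapply(seq_len(n_maps), function(m) {
    batch <- batch_fit(curves[[m]], instrument, ...)
    assemble_map(batch, instrument, section_id = section_id,
                 map_id = sprintf("%s_map%d", section_id, m))
  })
  region_of <- rep(LETTERS[seq_len(n_regions)], each = n_maps / n_regions)
  by_region <- split(maps, region_of)
  agg <- region_aggregate(by_region, section_id = section_id)
  n_valid <- sum(vapply(maps, function(m) sum(is.finite(m)), numeric(1)))
  list(aggregate = agg, maps = maps, n_valid = n_valid,
       n_total = n_maps * instrument$grid_n^2)
}

#' Run a full simulated elasticity-mapping experiment
#'
#' For each section: draw the ground-truth stiffness field, generate the
#' per-pixel force curves, preprocess and fit them, assemble stiffness
#' maps, pool region medians and compute the section's E_final. The ground
#' truth is carried alongside for evaluation but is never visible to the
#' fitting stage (see [fit_section_dataset()]).
#'
#' @param config A [pipeline_config()].
#' @param progress Print per-section progress?
#' @return An object of class `elasticity_experiment` with `aggregates`
#'   (tidy per-region table), `sections` (per-section E_final and ground
#'   truth scale), `summary` (across-section describe of E_final) and
#'   `config`.
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  n_maps <- config$n_regions * config$maps_per_region
  agg_list <- vector("list", config$n_sections)
  sec_list <- vector("list", config$n_sections)
  n_valid <- 0; n_total <- 0
  # per-section sub-seeds drawn from one base stream: keeps sections
  # reproducible yet statistically independent
  set.seed(config$seed)
  section_seeds <- sample.int(2147483646L, config$n_sections)
  for (s in seq_len(config$n_sections)) {
    sid <- sprintf("S%02d", s)
    ds <- generate_map_dataset(config$tissue, config$instrument,
                               n_maps = n_maps,
                               seed = section_seeds[s])
    fit <- fit_section_dataset(ds$curves, config$instrument,
                               n_regions = config$n_regions,
                               section_id = sid,
                               r2_min = config$r2_min,
                               min_points = config$min_points)
    agg_list[[s]] <- as.data.frame(fit$aggregate)
    sec_list[[s]] <- data.frame(
      section_id = sid,
      E_final_kPa = attr(fit$aggregate, "E_final_kPa"),
      true_scale_kPa = ds$scale_kPa,
      n_valid = fit$n_valid, n_total = fit$n_total,
      stringsAsFactors = FALSE)
    n_valid <- n_valid + fit$n_valid
    n_total <- n_total + fit$n_total
    if (progress)
      message(sprintf("section %s: E_final = %.3g kPa (%d/%d valid)",
                      sid, sec_list[[s]]$E_final_kPa, fit$n_valid,
                      fit$n_total))
  }
  out <- list(config = config,
              aggregates = do.call(rbind, agg_list),
              sections = do.call(rbind, sec_list),
              summary = describe(vapply(sec_list, function(x)
                x$E_final_kPa, numeric(1))),
              counts = c(n_valid = n_valid, n_total = n_total))
  class(out) <- "elasticity_experiment"
  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

#' @export
print.elasticity_experiment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Elasticity experiment: tissue '%s', instrument '%s', %d sections\n",
    cfg$tissue$name, cfg$instrument$name, cfg$n_sections))
  cat(sprintf("  curves: %d/%d valid (%.1f%%)\n", x$counts["n_valid"],
              x$counts["n_total"],
              100 * x$counts["n_valid"] / x$counts["n_total"]))
  cat(sprintf(
    "  E_final across sections: %.3g +/- %.3g kPa (preset %.3g +/- %.3g)\n",
    x$summary$mean, x$summary$sd, cfg$tissue$mean_kPa, cfg$tissue$sd_kPa))
  invisible(x)
}

write_experiment <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$aggregates, file.path(out_dir, "aggregates.csv"),
                   row.names = FALSE)
  utils::write.csv(x$sections, file.path(out_dir, "sections.csv"),
                   row.names = FALSE)
  cfg <- x$config
  manifest <- list(
    package = "cardioelast",
    version = as.character(utils::packageVersion("cardioelast")),
    tissue = cfg$tissue$name, instrument = cfg$instrument$name,
    n_sections = cfg$n_sections, n_regions = cfg$n_regions,
    maps_per_region = cfg$maps_per_region,
    grid_n = cfg$instrument$grid_n, seed = cfg$seed,
    r2_min = cfg$r2_min, min_points = cfg$min_points)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Compare experimental conditions
#'
#' Cross-condition inference on section-level aggregates: one-way ANOVA
#' with Tukey's HSD on E_final (and on each region label present in all
#' conditions), plus pairwise variance-ratio heterogeneity screens.
#'
#' @param experiments Named list (>= 2 entries) of
#'   `elasticity_experiment` objects or data frames with an `E_final_kPa`
#'   column; each condition needs >= 2 sections.
#' @return An object of class `condition_comparison` with `anova` (on
#'   E_final), `tukey`, and `variance_ratio` (pairwise table).
#' @export
compare_conditions <- function(experiments) {
  if (length(experiments) < 2L)
    stop_user("need >= 2 conditions to compare")
  if (is.null(names(experiments)) || any(names(experiments) == ""))
    names(experiments) <- paste0("condition", seq_along(experiments))
  vals <- lapply(experiments, function(e) {
    df <- if (inherits(e, "elasticity_experiment")) e$sections else e
    v <- df$E_final_kPa
    if (length(v) < 2L)
      stop_user("each condition needs >= 2 sections for comparison")
    v
  })
  aov_res <- one_way_anova(vals)
  pairs <- utils::combn(length(vals), 2)
  vr <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    t <- variance_ratio_test(vals[[a]], vals[[b]])
    data.frame(comparison = paste(names(vals)[a], "vs", names(vals)[b]),
               F = t$statistic, df1 = t$df[1], df2 = t$df[2],
               p = t$p_value, stringsAsFactors = FALSE)
  })
  structure(list(anova = aov_res, tukey = aov_res$tukey,
                 variance_ratio = do.call(rbind, vr),
                 means = vapply(vals, mean, numeric(1))),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Condition comparison (section-level E_final)\n")
  print(x$anova)
  cat("Variance-ratio screens:\n")
  print(x$variance_ratio, row.names = FALSE)
  invisible(x)
}

#' Simulate a whole-organ indentation study
#'
#' Emulates large-displacement depth-sensing indentation: `n_hearts`
#' hearts, each with a heart-level stiffness scale from the tissue preset
#' and `n_per_heart` single-point indentations (log-normal around the
#' heart scale with the preset pixel CV), fitted with the spherical Hertz
#' model up to the instrument's fit-depth cap (30 um for the built-in
#' cono-spherical preset).
#'
#' @param tissue Tissue preset name or object.
#' @param instrument Instrument preset name or object (default
#'   `"nanoindenter"`).
#' @param n_hearts,n_per_heart Study size.
#' @param seed Integer seed.
#' @return A list with `fits` (data frame: heart, indentation, `E_kPa`,
#'   `valid`), `grand_mean_kPa` (over valid fits) and `per_heart`
#'   (means by heart).
#' @export
global_indentation_study <- function(tissue, instrument = "nanoindenter",
                                     n_hearts = 20L, n_per_heart = 20L,
                                     seed = 1L) {
  tissue <- if (inherits(tissue, "tissue_preset")) tissue
            else tissue_preset(tissue)
  instrument <- if (inherits(instrument, "instrument_preset")) instrument
               else instrument_preset(instrument)
  p_s <- lognormal_params(tissue$mean_kPa, tissue$sd_kPa)
  sd_pix <- sqrt(log1p(tissue$pixel_cv^2))
  rows <- vector("list", n_hearts * n_per_heart)
  i <- 0L
  set.seed(seed)
  heart_seeds <- sample.int(2147483646L, n_hearts)
  for (h in seq_len(n_hearts)) {
    set.seed(heart_seeds[h])
    scale_kPa <- stats::rlnorm(1, p_s["meanlog"], p_s["sdlog"])
    for (j in seq_len(n_per_heart)) {
      E_true <- stats::rlnorm(1, log(scale_kPa * 1000), sd_pix)
      off <- stats::runif(1, instrument$offset_range[1],
                          instrument$offset_range[2])
      fit <- tryCatch({
        cv <- generate_force_curve(E_true, instrument,
                                   contact_offset = off)
        hertz_fit(cv, instrument)
      }, error = function(e) NULL)
      i <- i + 1L
      rows[[i]] <- data.frame(
        heart = h, indentation = j,
        E_kPa = if (!is.null(fit) && fit$valid) fit$E / 1000 else NA_real_,
        true_kPa = E_true / 1000,
        valid = !is.null(fit) && fit$valid)
    }
  }
  fits <- do.call(rbind, rows)
  ok <- fits$valid
  per_heart <- tapply(fits$E_kPa[ok], fits$heart[ok], mean)
  list(fits = fits, grand_mean_kPa = mean(fits$E_kPa[ok]),
       per_heart = per_heart)
}
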