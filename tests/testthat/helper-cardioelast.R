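# Shared fixtures and cached simulations for the test suite.

.sim_cache <- new.env(parent = emptyenv())

# default-noise simulation reused by the contact-point and fit-accuracy
# checks (one generation pass, several assertions)
sim_default_noise_fits <- function(n = 500, E_true = 3000, seed = 2024) {
  key <- sprintf("fits_%d_%g_%d", n, E_true, seed)
  got <- .sim_cache[[key]]
  if (!is.null(got)) return(got)
  inst <- instrument_preset("colloidal")
  set.seed(seed)
  offs <- stats::runif(n, inst$offset_range[1], inst$offset_range[2])
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    cv <- generate_force_curve(E_true, inst, contact_offset = offs[i],
                               retract = FALSE)
    fits[[i]] <- hertz_fit(cv, inst)
  }
  out <- list(offsets = offs, E_true = E_true, fits = fits,
              instrument = inst)
  .sim_cache[[key]] <- out
  out
}

# quiet, fast instrument variants
inst_noiseless <- function(name = "colloidal", ...) {
  instrument_preset(name, noise_sd = 0, baseline_slope_sd = 0, ...)
}

# column variances without matrixStats
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  (colSums(m^2) - colSums(m)^2 / n) / (n - 1)
}

# section-scale draws straight from the generator's top level (cheap
# stand-in for section-level aggregates in calibration/power checks)
draw_section_scales <- function(preset, n, seed) {
  if (!inherits(preset, "tissue_preset")) preset <- tissue_preset(preset)
  tiny <- instrument_preset("colloidal", grid_n = 1)
  secs <- sample_stiffness_field(preset, tiny, n_sections = n,
                                 n_fields = 1, seed = seed)
  vapply(secs, function(s) s$scale_kPa, numeric(1))
}
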