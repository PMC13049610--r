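# Hertzian contact models and the per-curve Young's modulus fit.
#
# The working model is the paraboloidal Hertz closed form for a spherical
# indenter, F = (4/3) * E / (1 - nu^2) * sqrt(R) * delta^(3/2), which is the
# form implemented by vendor "Hertz-Sneddon (sphere)" fitters. The exact
# Sneddon sphere solution (parametric in contact radius) is available for
# sensitivity checks; at shallow relative depths (delta << R) the two agree
# to within a few percent.

# prefactor A such that F = A * E * delta^(3/2)
hertz_prefactor <- function(R, nu) (4 / 3) * sqrt(R) / (1 - nu^2)

#' Hertz force for a spherical indenter
#'
#' `F = (4/3) * E/(1 - nu^2) * sqrt(R) * delta^(3/2)`, vectorised over
#' `delta`.
#'
#' @param delta Indentation depth(s), m, >= 0.
#' @param E Young's modulus, Pa, > 0.
#' @param R Indenter radius, m, > 0.
#' @param nu Poisson ratio in `[0, 1)`; 0.5 for incompressible soft tissue.
#' @return Force(s) in N.
#' @examples
#' hertz_force_sphere(1e-6, E = 1000, R = 5.4e-6, nu = 0.5) # ~4.13 nN
#' @export
hertz_force_sphere <- function(delta, E, R, nu = 0.5) {
  if (any(delta < 0)) stop_user("indentation delta must be >= 0")
  if (E <= 0) stop_user("Young's modulus must be > 0")
  if (R <= 0) stop_user("indenter radius must be > 0")
  if (nu < 0 || nu >= 1) stop_user("poisson ratio must be in [0, 1)")
  hertz_prefactor(R, nu) * E * delta^1.5
}

#' Exact Sneddon force for a spherical indenter
#'
#' The exact axisymmetric sphere solution, parametric in the contact radius
#' `a`: `delta = (a/2) log((R+a)/(R-a))` and
#' `F = E/(1-nu^2) * ((a^2 + R^2)/2 * log((R+a)/(R-a)) - a R)`. Provided for
#' sensitivity checks against the paraboloidal Hertz form used by
#' [hertz_fit()].
#'
#' @inheritParams hertz_force_sphere
#' @return Force(s) in N.
#' @export
sneddon_force_sphere <- function(delta, E, R, nu = 0.5) {
  if (any(delta < 0)) stop_user("indentation delta must be >= 0")
  if (E <= 0 || R <= 0) stop_user("E and R must be > 0")
  vapply(delta, function(dl) {
    if (dl == 0) return(0)
    g <- function(a) (a / 2) * log((R + a) / (R - a)) - dl
    a <- stats::uniroot(g, c(1e-12 * R, R * (1 - 1e-12)),
                        tol = R * 1e-14)$root
    (E / (1 - nu^2)) *
      ((a^2 + R^2) / 2 * log((R + a) / (R - a)) - a * R)
  }, numeric(1))
}

#' Fit the Hertz model to a force curve
#'
#' The central estimator of the package. For a baseline-corrected extend
#' segment the contact point `z_c` and modulus `E` are fitted jointly: for
#' each candidate `z_c` the modulus has a closed-form linear least-squares
#' solution (regression of force on `delta^(3/2)` through the origin), and
#' `z_c` is refined by grid search plus a continuous polish that minimises
#' the residual sum of squares (see [find_contact_point()]). Only
#' indentations `0 <= delta <= max_fit_depth` enter the fit (the
#' cono-spherical preset caps this at 30 um, inside its sphere-dominated
#' regime).
#'
#' @param curve A [force_curve()] (raw; preprocessing is applied
#'   internally).
#' @param instrument An [instrument_preset()].
#' @param min_points Minimum number of in-contact samples for a valid fit.
#' @param r2_min Minimum in-contact R-squared for a valid fit.
#' @param max_fit_depth Optional override (m) of the instrument's fit-depth
#'   cap.
#' @param ... Further arguments to the contact pipeline
#'   (`pre_contact_fraction`, `smooth_window`, `refine_halfwidth`).
#' @return An object of class `hertz_fit` with elements `E` (Pa), `z_c`
#'   (m), `rss`, `r_squared`, `n_points`, `delta_max_used` (m), `valid`,
#'   `reason`, plus diagnostics, supporting `print()`, `summary()`,
#'   `coef()`, `predict()`, `fitted()`, `residuals()`, `plot()` and
#'   `simulate()`.
#' @export
hertz_fit <- function(curve, instrument, min_points = 50L, r2_min = 0.8,
                      max_fit_depth = NULL, ...) {
  stopifnot(inherits(curve, "force_curve"),
            inherits(instrument, "instrument_preset"))
  ef <- extend_force(curve, instrument$k)
  core <- contact_core(ef$z, ef$f, instrument,
                       min_points = min_points,
                       max_fit_depth = max_fit_depth, ...)
  res <- list(E = NA_real_, z_c = NA_real_, d_c = NA_real_,
              rss = NA_real_, r_squared = NA_real_, n_points = 0L,
              delta_max_used = NA_real_, valid = FALSE,
              reason = core$reason, noise_sd = core$baseline$noise_sd,
              baseline = core$baseline[c("slope", "offset")],
              instrument = instrument, pixel = curve$pixel,
              data = NULL)
  class(res) <- "hertz_fit"
  if (!core$found) return(res)

  # final slope: iterate with the model-predicted (rather than measured)
  # bending in the indentation, removing the errors-in-variables
  # attenuation that correlated force noise would otherwise cause
  b <- core$slope
  delta <- (ef$z - core$z_c) - core$f_corr / instrument$k
  for (it in 1:3) {
    f_pred <- b * pmax(delta, 0)^1.5
    delta <- (ef$z - core$z_c) - f_pred / instrument$k
    xh <- pmax(delta, 0)
    xh[xh > core$depth_cap] <- 0
    xh <- xh^1.5
    sxx <- sum(xh * xh)
    if (sxx <= 0) break
    b_new <- sum(xh * core$f_corr) / sxx
    if (!is.finite(b_new) || b_new <= 0) break
    b <- b_new
  }
  sel <- delta > 0 & delta <= core$depth_cap
  n_pts <- sum(sel)
  E <- b / core$A
  fit_vals <- b * pmax(delta, 0)^1.5
  r_in <- core$f_corr[sel] - fit_vals[sel]
  tss <- sum((core$f_corr[sel] - mean(core$f_corr[sel]))^2)
  r2 <- if (tss > 0) 1 - sum(r_in^2) / tss else 1
  res$E <- E
  res$z_c <- core$z_c
  res$d_c <- deflection_at(curve, ef, core$z_c, instrument$k)
  res$rss <- sum(r_in^2)
  res$r_squared <- max(min(r2, 1), -Inf)
  res$n_points <- n_pts
  res$delta_max_used <- if (n_pts) max(delta[sel]) else NA_real_
  res$data <- list(z = ef$z, f_corr = core$f_corr, delta = delta,
                   fitted = fit_vals, in_fit = sel)
  if (n_pts < min_points) {
    res$reason <- "too_few_points"
  } else if (!is.finite(E) || E <= 0) {
    res$reason <- "nonpositive_modulus"
  } else if (res$r_squared < r2_min) {
    res$reason <- "poor_fit"
  } else {
    res$valid <- TRUE
    res$reason <- "ok"
  }
  res
}

#' @rdname hertz_fit
#' @param processed Synonym accepted for `curve` in the module-surface alias
#'   `fit_hertz()`.
#' @export
fit_hertz <- function(processed, instrument, ...)
  hertz_fit(processed, instrument, ...)

#' @export
print.hertz_fit <- function(x, ...) {
  if (x$valid) {
    cat(sprintf(
      "Hertz fit: E = %.4g kPa (z_c = %.4g um, R^2 = %.4f, n = %d)\n",
      x$E / 1000, x$z_c * 1e6, x$r_squared, x$n_points))
  } else {
    cat(sprintf("Hertz fit: invalid (%s)\n", x$reason))
  }
  invisible(x)
}

#' @export
summary.hertz_fit <- function(object, ...) {
  out <- list(
    E_kPa = object$E / 1000,
    z_c_um = object$z_c * 1e6,
    d_c_nm = object$d_c * 1e9,
    r_squared = object$r_squared,
    rss = object$rss,
    n_points = object$n_points,
    delta_max_um = object$delta_max_used * 1e6,
    noise_sd_pN = object$noise_sd * 1e12,
    valid = object$valid,
    reason = object$reason,
    tip = object$instrument$name
  )
  class(out) <- "summary.hertz_fit"
  out
}

#' @export
print.summary.hertz_fit <- function(x, ...) {
  cat("Hertz contact fit summary\n")
  cat(sprintf("  tip preset:      %s\n", x$tip))
  cat(sprintf("  Young's modulus: %.4g kPa\n", x$E_kPa))
  cat(sprintf("  contact point:   %.4g um (deflection %.3g nm)\n",
              x$z_c_um, x$d_c_nm))
  cat(sprintf("  fit: R^2 = %.4f over %d points, max depth %.3g um\n",
              x$r_squared, x$n_points, x$delta_max_um))
  cat(sprintf("  noise SD %.3g pN; %s\n", x$noise_sd_pN,
              if (x$valid) "valid" else paste("INVALID:", x$reason)))
  invisible(x)
}

#' @export
coef.hertz_fit <- function(object, ...) {
  c(E_Pa = object$E, z_c_m = object$z_c)
}

#' @export
fitted.hertz_fit <- function(object, ...) {
  if (is.null(object$data)) return(numeric(0))
  object$data$fitted
}

#' @export
residuals.hertz_fit <- function(object, ...) {
  if (is.null(object$data)) return(numeric(0))
  object$data$f_corr - object$data$fitted
}

#' @param object,newdata `predict()` evaluates the fitted Hertz law at new
#'   indentation depths (m).
#' @rdname hertz_fit
#' @export
predict.hertz_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  delta <- if (is.list(newdata)) newdata$delta else newdata
  hertz_force_sphere(delta, E = object$E, R = object$instrument$R,
                     nu = object$instrument$nu)
}

#' @export
plot.hertz_fit <- function(x, ...) {
  if (is.null(x$data)) {
    warning("nothing to plot for an unfitted curve")
    return(invisible(x))
  }
  d <- x$data
  graphics::plot(d$delta * 1e6, d$f_corr * 1e9, pch = 16, cex = 0.4,
                 col = ifelse(d$in_fit, "black", "grey70"),
                 xlab = "indentation (um)", ylab = "force (nN)", ...)
  ord <- order(d$delta)
  graphics::lines(d$delta[ord] * 1e6, d$fitted[ord] * 1e9, col = "red3",
                  lwd = 2)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' @param nsim,seed `simulate()` draws new synthetic curves from the fitted
#'   modulus under the fit's instrument preset.
#' @rdname hertz_fit
#' @export
simulate.hertz_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$valid) stop_user("cannot simulate from an invalid fit")
  if (!is.null(seed)) set.seed(seed)
  inst <- object$instrument
  lapply(seq_len(nsim), function(i) {
    off <- stats::runif(1, inst$offset_range[1], inst$offset_range[2])
    generate_force_curve(object$E, inst, contact_offset = off)
  })
}

#' Batch Hertz fitting of many curves
#'
#' Fits every curve with [hertz_fit()]; per-curve failures are recorded as
#' invalid results and never abort the batch. Results keep the curves'
#' pixel keys, so the output is invariant to input order up to reordering.
#'
#' @param curves List of [force_curve()] objects sharing one instrument
#'   preset.
#' @param instrument An [instrument_preset()].
#' @param ... Passed to [hertz_fit()].
#' @return An object of class `hertz_batch`: a list of `hertz_fit` results
#'   with a `summary` attribute (`n_valid`, `n_invalid`).
#'   `as.data.frame()` flattens it to the tidy per-pixel table.
#' @export
batch_fit <- function(curves, instrument, ...) {
  if (!length(curves)) stop_user("batch_fit needs at least one curve")
  results <- lapply(curves, function(cv) {
    tryCatch(hertz_fit(cv, instrument, ...), error = function(e) {
      res <- list(E = NA_real_, z_c = NA_real_, d_c = NA_real_,
                  rss = NA_real_, r_squared = NA_real_, n_points = 0L,
                  delta_max_used = NA_real_, valid = FALSE,
                  reason = paste0("error: ", conditionMessage(e)),
                  noise_sd = NA_real_, baseline = NULL,
                  instrument = instrument,
                  pixel = cv$pixel, data = NULL)
      class(res) <- "hertz_fit"
      res
    })
  })
  nv <- sum(vapply(results, function(r) isTRUE(r$valid), logical(1)))
  structure(results, class = "hertz_batch",
            summary = list(n = length(results), n_valid = nv,
                           n_invalid = length(results) - nv))
}

#' @export
print.hertz_batch <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Hertz batch: %d curves, %d valid, %d invalid\n",
              s$n, s$n_valid, s$n_invalid))
  invisible(x)
}

#' @export
as.data.frame.hertz_batch <- function(x, ...) {
  rows <- lapply(unclass(x), function(r) {
    px <- r$pixel %||% c(NA_integer_, NA_integer_)
    data.frame(pixel_row = px[1], pixel_col = px[2],
               E_Pa = r$E, z_c_m = r$z_c, r_squared = r$r_squared,
               n_points = r$n_points, valid = r$valid, reason = r$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write batch fit results as CSV
#'
#' Columns: pixel_row, pixel_col, E_Pa, z_c_m, r_squared, n_points, valid,
#' reason.
#'
#' @param batch A `hertz_batch`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_results <- function(batch, path) {
  utils::write.csv(as.data.frame(batch), path, row.names = FALSE)
  invisible(path)
}
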