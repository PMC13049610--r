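# Force-curve preprocessing: baseline correction, contact-point detection,
# indentation computation.
#
# Conventions: z increases toward the sample during extend; indentation
# delta = (z - z_c) - (d - d_c) >= 0 in contact; everything SI.

# extract the extend-segment (z, f) arrays, deriving force from deflection
# via the metadata spring constant when needed
extend_force <- function(curve, k = NULL) {
  ext <- extend_idx(curve)
  z <- curve$z[ext]
  f <- curve$f[ext]
  if (is.null(f)) {
    k <- k %||% curve$metadata$spring_constant_N_per_m
    if (is.null(k))
      stop_user("curve has no force channel and no spring constant metadata")
    f <- k * curve$d[ext]
  }
  list(z = z, f = f, idx = ext)
}

#' Fit the pre-contact baseline of a force curve
#'
#' Fits a least-squares line to the first `pre_contact_fraction` of the
#' extend segment (default 60%). If the residuals trend upward at the end of
#' the window -- the signature of the window overshooting the contact point
#' -- the baseline is refit on the first `refit_fraction` (default 40%) and
#' flagged. The SD of the residuals provides the per-curve force noise
#' estimate used by the contact-point detector.
#'
#' @param curve A [force_curve()] with a force channel (or a spring constant
#'   in its metadata).
#' @param pre_contact_fraction Fraction of extend samples in the baseline
#'   window.
#' @param refit_fraction Fallback fraction used when the residual-trend
#'   diagnostic fires.
#' @return A list with `slope` (N/m), `offset` (N), `noise_sd` (N), `refit`
#'   (logical), and `n_used`.
#' @export
fit_baseline <- function(curve, pre_contact_fraction = 0.6,
                         refit_fraction = 0.4) {
  ef <- extend_force(curve)
  fit_baseline_zf(ef$z, ef$f, pre_contact_fraction, refit_fraction)
}

fit_baseline_zf <- function(z, f, pre_contact_fraction = 0.6,
                            refit_fraction = 0.4) {
  n <- length(z)
  w <- floor(n * pre_contact_fraction)
  if (w < 20L)
    stop_user("too few samples for baseline fit (need >= 20 in window, ",
              "have ", w, ")")
  # shrink the window while its residuals trend upward (window overlaps
  # the contact region); first shrink target is refit_fraction
  refit <- FALSE
  repeat {
    bl <- line_fit(z[1:w], f[1:w])
    if (!baseline_trend_up(z[1:w], f[1:w], bl)) break
    w2 <- if (!refit) min(floor(n * refit_fraction), floor(w * 0.66))
          else floor(w * 0.66)
    if (w2 < 20L) break
    w <- w2
    refit <- TRUE
  }
  r <- f[1:w] - (bl$offset + bl$slope * z[1:w])
  list(slope = bl$slope, offset = bl$offset,
       noise_sd = stats::sd(r), refit = refit, n_used = w)
}

line_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- if (sxx > 0) sum((x - mx) * (y - my)) / sxx else 0
  list(slope = slope, offset = my - slope * mx)
}

# TRUE when the tail of the baseline window sits systematically above a
# line fitted to the window's first half (window overshoots into contact).
# Fitting on the half keeps the reference line and the noise estimate
# clean even when the tail is contaminated.
baseline_trend_up <- function(z, f, bl) {
  w <- length(f)
  nh <- floor(w / 2)
  lf <- line_fit(z[1:nh], f[1:nh])
  r <- f - (lf$offset + lf$slope * z)
  noise_h <- stats::sd(r[1:nh])
  m <- max(10L, ceiling(0.15 * w))
  # 1/m: mean of m residuals; 28/nh: extrapolation variance of the
  # half-window line at the far end of the window
  thr <- 3 * noise_h * sqrt(1 / m + 28 / nh) +
    1e-12 * max(abs(f), 1e-300)
  mean(r[(w - m + 1L):w]) > thr
}

# Full two-stage contact pipeline shared by find_contact_point() and
# hertz_fit(). Returns baseline, corrected force, coarse index, refined z_c
# and the profile-likelihood Hertz slope at the optimum.
contact_core <- function(z, f, instrument,
                         pre_contact_fraction = 0.6,
                         smooth_window = 11L,
                         refine_halfwidth = 15L,
                         min_points = 50L,
                         max_fit_depth = NULL) {
  k <- instrument$k
  A <- hertz_prefactor(instrument$R, instrument$nu)
  depth_cap <- max_fit_depth %||% instrument$max_fit_depth
  dz <- if (length(z) > 1L) stats::median(diff(z)) else instrument$z_step

  bl <- fit_baseline_zf(z, f, pre_contact_fraction)
  fc <- f - (bl$offset + bl$slope * z)
  coarse <- coarse_contact(fc, bl$noise_sd, smooth_window)

  # iterate: refit the baseline strictly before the detected contact and
  # rescan, until the window stabilises; handles curves whose pre-contact
  # region is a small fraction of the ramp
  w <- bl$n_used
  for (iter in 1:4) {
    if (is.na(coarse)) break
    w_new <- min(max(20L, coarse - smooth_window - 4L),
                 length(z) - 1L)
    if (abs(w_new - w) <= 2L) break
    w <- w_new
    b2 <- line_fit(z[1:w], f[1:w])
    r2 <- f[1:w] - (b2$offset + b2$slope * z[1:w])
    bl <- list(slope = b2$slope, offset = b2$offset,
               noise_sd = stats::sd(r2), refit = bl$refit, n_used = w)
    fc <- f - (bl$offset + bl$slope * z)
    coarse <- coarse_contact(fc, bl$noise_sd, smooth_window)
  }
  if (is.na(coarse)) {
    return(list(found = FALSE, reason = "no_contact", baseline = bl,
                f_corr = fc))
  }

  # linearised initial contact estimate: F^(2/3) is linear in the tip-sample
  # separation x = z - d for the spherical Hertz law
  fmax <- max(fc)
  lo <- max(10 * bl$noise_sd, 0.02 * fmax)
  pts <- which(fc > lo & fc < 0.5 * fmax)
  pts <- pts[pts >= coarse - 2L * smooth_window]
  z_init <- z[coarse]
  if (length(pts) >= 5L) {
    x <- z[pts] - fc[pts] / k
    y <- fc[pts]^(2 / 3)
    lf <- line_fit(x, y)
    if (is.finite(lf$slope) && lf$slope > 0) {
      cand <- -lf$offset / lf$slope
      lo_b <- z[coarse] - 100 * dz
      hi_b <- z[coarse] + 10 * dz
      z_init <- min(max(cand, lo_b), hi_b)
    }
  }
  z_init <- min(max(z_init, z[1]), z[length(z)] - dz)

  # fixed evaluation window so candidate RSS values are comparable
  i_lo <- max(1L, findInterval(z_init, z) - refine_halfwidth - 25L)
  d_init <- (z - z_init) - fc / k
  in_depth <- which(d_init <= depth_cap)
  i_hi <- if (length(in_depth)) max(in_depth) else length(z)
  i_hi <- max(i_hi, min(length(z), i_lo + 2L * min_points))
  S <- i_lo:i_hi
  zS <- z[S]; fS <- fc[S]; dS <- fc[S] / k

  obj <- function(zc) {
    delta <- (zS - zc) - dS
    xh <- pmax(delta, 0)
    xh <- ifelse(xh > depth_cap, 0, xh)^1.5
    sxx <- sum(xh * xh)
    if (sxx <= 0) return(list(rss = Inf, b = NA_real_))
    b <- sum(xh * fS) / sxx
    if (!is.finite(b) || b <= 0) return(list(rss = Inf, b = b))
    list(rss = sum((fS - b * xh)^2), b = b)
  }

  cand <- z_init + dz * seq(-refine_halfwidth, refine_halfwidth)
  cand <- cand[cand >= z[1] & cand <= z[length(z)] - dz]
  if (!length(cand)) cand <- z_init
  rss <- vapply(cand, function(zc) obj(zc)$rss, numeric(1))
  best <- which.min(rss)
  if (!is.finite(rss[best])) {
    return(list(found = FALSE, reason = "degenerate_fit", baseline = bl,
                f_corr = fc))
  }
  lo_c <- cand[max(1L, best - 1L)]
  hi_c <- cand[min(length(cand), best + 1L)]
  zc <- cand[best]
  if (hi_c > lo_c) {
    op <- stats::optimize(function(zc) obj(zc)$rss, c(lo_c, hi_c),
                          tol = max(dz * 1e-7, 1e-15))
    if (is.finite(op$objective) && op$objective <= rss[best])
      zc <- op$minimum
  }
  fit <- obj(zc)
  list(found = TRUE, reason = "ok", baseline = bl, f_corr = fc,
       coarse_index = coarse, z_c = zc, slope = fit$b, rss = fit$rss,
       A = A, depth_cap = depth_cap, eval_idx = S)
}

# coarse gate: first index where the smoothed corrected force exceeds
# 5 x noise and stays above for >= 10 samples
coarse_contact <- function(fc, noise_sd, smooth_window = 11L,
                           run_len = 10L) {
  n <- length(fc)
  sm <- moving_average(fc, smooth_window)
  noise_sm <- noise_sd / sqrt(max(smooth_window, 1L))
  thr <- max(5 * noise_sm, 1e-6 * max(sm, 0), 1e-300)
  above <- sm > thr
  if (!any(above)) return(NA_integer_)
  run <- min(run_len, n)
  cs <- cumsum(c(0L, as.integer(above)))
  i_max <- n - run + 1L
  if (i_max < 1L) return(NA_integer_)
  counts <- cs[(run + 1L):(n + 1L)] - cs[1:i_max]
  hit <- which(counts == run)
  if (length(hit)) return(hit[1L])
  # short curves that end in contact: accept the final crossing
  last <- which(above)
  tail_run <- n - last[length(last)] + 1L
  if (all(above[last[length(last)]:n]) && tail_run >= 5L)
    return(last[length(last)])
  NA_integer_
}

#' Locate the contact point of a force curve
#'
#' Two-stage estimate: a coarse noise-gated threshold crossing of the
#' smoothed, baseline-corrected force (5 x noise SD sustained for >= 10
#' samples) followed by a model-based refinement -- a grid search plus
#' continuous polish of the contact position that minimises the residual sum
#' of squares of the joint Hertz fit (modulus profiled out in closed form).
#'
#' @param curve A [force_curve()].
#' @param instrument An [instrument_preset()] (tip radius, spring constant,
#'   Poisson ratio enter the refinement model).
#' @param ... Passed to the internal pipeline (`pre_contact_fraction`,
#'   `smooth_window`, `refine_halfwidth`, `max_fit_depth`).
#' @return A list with `z_c` (m), `d_c` (m), `valid`, `reason`.
#' @export
find_contact_point <- function(curve, instrument, ...) {
  ef <- extend_force(curve, instrument$k)
  core <- contact_core(ef$z, ef$f, instrument, ...)
  if (!core$found)
    return(list(z_c = NA_real_, d_c = NA_real_, valid = FALSE,
                reason = core$reason))
  d_c <- deflection_at(curve, ef, core$z_c, instrument$k)
  list(z_c = core$z_c, d_c = d_c, valid = TRUE, reason = "ok")
}

deflection_at <- function(curve, ef, z_c, k) {
  d <- if (!is.null(curve$d)) curve$d[ef$idx] else ef$f / k
  if (length(ef$z) < 2L) return(d[1L])
  stats::approx(ef$z, d, xout = z_c, rule = 2)$y
}

#' Compute the indentation channel of a curve
#'
#' Applies `delta = (z - z_c) - (d - d_c)` on the extend segment, marking
#' records with `delta < 0` as pre-contact, and attaches the
#' baseline-corrected force.
#'
#' @param curve A [force_curve()].
#' @param z_c,d_c Contact point (m) and deflection at contact (m), e.g. from
#'   [find_contact_point()].
#' @param instrument Optional [instrument_preset()]; used for the spring
#'   constant when the curve lacks a force channel.
#' @return An object of class `processed_curve` with fields `delta`,
#'   `f_corr`, `z_c`, `d_c`, `baseline`, `noise_sd`, `pre_contact`.
#' @export
compute_indentation <- function(curve, z_c, d_c, instrument = NULL) {
  ef <- extend_force(curve, instrument$k %||% NULL)
  bl <- fit_baseline_zf(ef$z, ef$f)
  f_corr <- ef$f - (bl$offset + bl$slope * ef$z)
  d <- if (!is.null(curve$d)) curve$d[ef$idx] else
    ef$f / (instrument$k %||% curve$metadata$spring_constant_N_per_m)
  delta <- (ef$z - z_c) - (d - d_c)
  structure(list(delta = delta, f_corr = f_corr, z = ef$z,
                 z_c = z_c, d_c = d_c,
                 baseline = bl[c("slope", "offset")],
                 noise_sd = bl$noise_sd,
                 pre_contact = delta < 0,
                 metadata = curve$metadata, pixel = curve$pixel),
            class = "processed_curve")
}

#' @export
print.processed_curve <- function(x, ...) {
  cat(sprintf(
    "Processed curve: %d samples, %d in contact, z_c = %.4g um\n",
    length(x$delta), sum(!x$pre_contact), x$z_c * 1e6))
  cat(sprintf("  max indentation %.4g um, noise SD %.3g pN\n",
              max(x$delta) * 1e6, x$noise_sd * 1e12))
  invisible(x)
}
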