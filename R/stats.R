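# Inference layer, implemented from first principles: one-way ANOVA with
# Tukey's HSD (own studentized-range CDF), variance-ratio F test, two-sample
# t tests and descriptive summaries. Base R equivalents (aov/TukeyHSD,
# var.test, t.test) serve only as independent cross-checks in the test
# suite.

.gl_env <- new.env(parent = emptyenv())

gl_nodes <- function(n, a, b) {
  key <- sprintf("%d_%.17g_%.17g", n, a, b)
  got <- .gl_env[[key]]
  if (!is.null(got)) return(got)
  g <- pracma::gaussLegendre(n, a, b)
  .gl_env[[key]] <- g
  g
}

#' Studentized-range distribution function
#'
#' `P(Q <= q)` for the studentized range of `k` means with `df` error
#' degrees of freedom, computed by nested Gauss-Legendre quadrature of the
#' range-distribution integral (absolute accuracy ~1e-5). Used for Tukey's
#' honestly-significant-difference adjusted p-values.
#'
#' @param q Quantile, >= 0.
#' @param k Number of groups, >= 2.
#' @param df Error degrees of freedom, >= 1.
#' @return `P(Q <= q)`.
#' @export
ptukey_range <- function(q, k, df) {
  stopifnot(k >= 2, df >= 1)
  if (!is.finite(q)) return(if (q > 0) 1 else 0)
  if (q <= 0) return(0)
  # inner: P(range of k std normals <= q * s)
  inner <- function(qs) {
    gz <- gl_nodes(128L, -8, 8 + qs)
    fz <- stats::dnorm(gz$x) *
      (stats::pnorm(gz$x) - stats::pnorm(gz$x - qs))^(k - 1)
    k * sum(gz$w * fz)
  }
  # outer: s = sqrt(chi^2_df / df)
  gs <- gl_nodes(128L, 1e-10, 4)
  dens <- 2 * exp((df / 2) * log(df / 2) - lgamma(df / 2) +
                    (df - 1) * log(gs$x) - df * gs$x^2 / 2)
  vals <- vapply(gs$x, function(s) inner(q * s), numeric(1))
  min(max(sum(gs$w * dens * vals), 0), 1)
}

#' One-way analysis of variance with Tukey's HSD
#'
#' Classical fixed-effects decomposition: `F = MS_between / MS_within` with
#' `df = (k - 1, N - k)`; the p-value comes from the F distribution.
#' Pairwise comparisons use the Tukey-Kramer studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))` with adjusted
#' p-values from [ptukey_range()]; unadjusted pairwise p-values (same MSE
#' and df) are reported alongside.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2),
#'   or a numeric vector together with `g`.
#' @param g Optional grouping factor when `groups` is a vector.
#' @param tukey Compute the pairwise table? (Skipping it makes large
#'   simulation loops cheap.)
#' @return An object of class `anova_oneway` with `statistic`, `df`,
#'   `p_value`, a per-group summary table, and (optionally) `tukey`, a data
#'   frame with one row per pair.
#' @export
one_way_anova <- function(groups, g = NULL, tukey = TRUE) {
  if (!is.list(groups)) {
    stopifnot(!is.null(g))
    groups <- split(as.numeric(groups), g)
  }
  k <- length(groups)
  if (k < 2L) stop_user("need >= 2 groups")
  n_i <- vapply(groups, length, numeric(1))
  if (any(n_i < 2L)) stop_user("each group needs n >= 2")
  N <- sum(n_i)
  m_i <- vapply(groups, mean, numeric(1))
  s_i <- vapply(groups, stats::sd, numeric(1))
  grand <- sum(n_i * m_i) / N
  ss_between <- sum(n_i * (m_i - grand)^2)
  ss_within <- sum(vapply(groups, function(x) sum((x - mean(x))^2),
                          numeric(1)))
  df_b <- k - 1L
  df_w <- N - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  if (ss_within == 0 && ss_between == 0) {
    f_stat <- 0; p <- 1
  } else if (ss_within == 0) {
    f_stat <- Inf; p <- 0
  } else {
    f_stat <- ms_b / ms_w
    p <- stats::pf(f_stat, df_b, df_w, lower.tail = FALSE)
  }
  nm <- names(groups) %||% paste0("g", seq_len(k))
  out <- list(statistic = f_stat,
              df = c(df_between = as.integer(df_b),
                     df_within = as.integer(df_w)),
              p_value = p,
              groups = data.frame(group = nm, n = unname(n_i),
                                  mean = unname(m_i), sd = unname(s_i),
                                  stringsAsFactors = FALSE),
              ss = c(between = ss_between, within = ss_within),
              ms_within = ms_w)
  if (tukey && is.finite(f_stat)) {
    pairs <- utils::combn(k, 2)
    tk <- lapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      diff <- m_i[i2] - m_i[i1]
      se <- sqrt(ms_w / 2 * (1 / n_i[i1] + 1 / n_i[i2]))
      q <- abs(diff) / se
      data.frame(comparison = paste(nm[i2], "-", nm[i1]),
                 difference = unname(diff), q = unname(q),
                 p_adj = 1 - ptukey_range(q, k, df_w),
                 p_unadj = 2 * stats::pt(-q / sqrt(2), df_w),
                 stringsAsFactors = FALSE)
    })
    out$tukey <- do.call(rbind, tk)
  }
  class(out) <- "anova_oneway"
  out
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$statistic, x$p_value))
  print(x$groups, row.names = FALSE)
  if (!is.null(x$tukey)) {
    cat("Tukey HSD:\n")
    print(x$tukey, row.names = FALSE)
  }
  invisible(x)
}

#' Two-sample variance-ratio (F) test
#'
#' The spreadsheet-style heterogeneity screen: `F` is the ratio of the
#' larger to the smaller sample variance (so `F >= 1`), with a two-tailed
#' p-value `2 * min(P(F_df > F), 1 - P(F_df > F))` capped at 1 by default.
#'
#' @param a,b Numeric samples, each n >= 2; not both of zero variance.
#' @param two_tailed Use the two-tailed p (default) or one-tailed.
#' @return An object of class `var_ratio_test` with `statistic`, `df`,
#'   `p_value`, and the two sample variances.
#' @export
variance_ratio_test <- function(a, b, two_tailed = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop_user("both samples need n >= 2")
  v <- c(stats::var(a), stats::var(b))
  n <- c(length(a), length(b))
  if (all(v == 0)) stop_user("both samples have zero variance")
  top <- which.max(v)
  bot <- 3L - top
  f_stat <- v[top] / v[bot]
  df <- c(df1 = n[top] - 1L, df2 = n[bot] - 1L)
  tail_p <- stats::pf(f_stat, df[1], df[2], lower.tail = FALSE)
  p <- if (two_tailed) min(2 * min(tail_p, 1 - tail_p), 1) else tail_p
  structure(list(statistic = f_stat, df = df, p_value = p,
                 variances = c(a = v[1], b = v[2]),
                 two_tailed = two_tailed),
            class = "var_ratio_test")
}

#' @export
print.var_ratio_test <- function(x, ...) {
  cat(sprintf("Variance-ratio F test: F(%d, %d) = %.4g, %s p = %.4g\n",
              x$df[1], x$df[2], x$statistic,
              if (x$two_tailed) "two-tailed" else "one-tailed",
              x$p_value))
  invisible(x)
}

#' Two-sample t test (pooled or Welch)
#'
#' @param a,b Numeric samples, each n >= 2.
#' @param welch Use the Welch (unequal-variance) variant?
#' @return A list with `statistic` (sign follows `mean(a) - mean(b)`),
#'   `df`, `p_value`, `method`.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop_user("both samples need n >= 2")
  v1 <- stats::var(a); v2 <- stats::var(b)
  d <- mean(a) - mean(b)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    t_stat <- d / sqrt(se2)
    method <- "welch"
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    t_stat <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
    method <- "student"
  }
  if (!is.finite(t_stat)) t_stat <- 0
  list(statistic = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df), method = method)
}

#' Descriptive summary of a sample
#'
#' Mean, sample SD (n - 1 denominator; reported as 0 with a flag when
#' n = 1), midpoint-convention median and n.
#'
#' @param values Numeric vector, n >= 1.
#' @return A one-row data frame with `mean`, `sd`, `median`, `n`,
#'   `sd_defined`.
#' @export
describe <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop_user("describe() needs n >= 1")
  n <- length(values)
  data.frame(mean = mean(values),
             sd = if (n > 1L) stats::sd(values) else 0,
             median = stats::median(values), n = n,
             sd_defined = n > 1L)
}
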