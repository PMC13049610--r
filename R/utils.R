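# Small internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a base seed
#'
#' Deterministically maps a base seed and a stream index to a new seed in
#' `[1, 2^31 - 2]`, so that independent stages (sections, maps, replicates)
#' get decoupled but fully reproducible RNG streams.
#'
#' @param seed Integer base seed.
#' @param index Integer stream index (>= 0).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), length(index) == 1L)
  m <- 2147483647
  x <- (abs(as.double(seed)) %% m) * 48271 + as.double(index) * 104729 + 1
  as.integer(x %% (m - 1) + 1)
}

# moving average with centred window (odd), ends padded by shrinking window
moving_average <- function(x, window = 11L) {
  n <- length(x)
  if (n == 0L || window <= 1L) return(x)
  window <- min(window, n)
  if (window %% 2L == 0L) window <- window - 1L
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# format a length-1 number for metadata output
fmt_num <- function(x) formatC(x, format = "g", digits = 17)

stop_user <- function(...) stop(..., call. = FALSE)
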