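#' @useDynLib gaitstab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Classed error helper. `class` becomes condition class "gaitstab_<class>",
# so callers can catch e.g. gaitstab_missing_channel specifically.
gs_stop <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("gaitstab_", class), "gaitstab_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

gs_warn <- function(class, message) {
  warning(structure(
    class = c(paste0("gaitstab_", class), "gaitstab_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

#' Locate local maxima with prominence and separation constraints
#'
#' Finds strict local maxima of a numeric series, computes each peak's
#' topographic prominence (height above the higher of the two minima
#' separating it from taller terrain on either side) and greedily enforces a
#' minimum peak-to-peak distance, keeping taller peaks first.
#'
#' @param x numeric series.
#' @param min_distance minimum separation between retained peaks, in samples.
#' @param min_prominence minimum prominence, in the units of `x`.
#' @return data.frame with columns `sample` (index into `x`), `height`,
#'   `prominence`, sorted by `sample`.
#' @keywords internal
find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) {
    return(data.frame(sample = integer(), height = numeric(), prominence = numeric()))
  }
  dx <- diff(x)
  # rising-then-falling sign change; first sample of any flat top
  cand <- which(dx[-1] < 0 & dx[-(n - 1L)] > 0) + 1L
  if (!length(cand)) {
    return(data.frame(sample = integer(), height = numeric(), prominence = numeric()))
  }
  prom <- vapply(cand, function(i) {
    h <- x[i]
    # walk left to previous higher point (or start), tracking the minimum
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]
  prom <- prom[keep]
  if (!length(cand)) {
    return(data.frame(sample = integer(), height = numeric(), prominence = numeric()))
  }
  # greedy distance pruning, tallest first
  ord <- order(x[cand], decreasing = TRUE)
  taken <- integer(0)
  taken_prom <- numeric(0)
  for (k in ord) {
    if (!length(taken) || all(abs(cand[k] - taken) >= min_distance)) {
      taken <- c(taken, cand[k])
      taken_prom <- c(taken_prom, prom[k])
    }
  }
  o <- order(taken)
  data.frame(sample = taken[o], height = x[taken[o]], prominence = taken_prom[o])
}

# Central-difference derivative; one-sided at the ends. Exact on linear data.
central_diff <- function(x, fs) {
  n <- length(x)
  if (n < 2L) gs_stop("too_short", "need at least 2 samples to differentiate")
  v <- numeric(n)
  if (n == 2L) {
    v[] <- (x[2L] - x[1L]) * fs
    return(v)
  }
  v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  v[1L] <- (x[2L] - x[1L]) * fs
  v[n] <- (x[n] - x[n - 1L]) * fs
  v
}

# Quintic (minimum-jerk style) segment matching position, velocity and
# acceleration at both ends; returns position evaluated at `t`.
quintic_segment <- function(t, t0, t1, p0, p1, v0 = 0, v1 = 0, a0 = 0, a1 = 0) {
  T <- t1 - t0
  s <- (t - t0) / T
  # Hermite quintic basis in normalized time
  s2 <- s * s; s3 <- s2 * s; s4 <- s3 * s; s5 <- s4 * s
  h00 <- 1 - 10 * s3 + 15 * s4 - 6 * s5
  h10 <- s - 6 * s3 + 8 * s4 - 3 * s5
  h20 <- 0.5 * s2 - 1.5 * s3 + 1.5 * s4 - 0.5 * s5
  h01 <- 10 * s3 - 15 * s4 + 6 * s5
  h11 <- -4 * s3 + 7 * s4 - 3 * s5
  h21 <- 0.5 * s3 - s4 + 0.5 * s5
  h00 * p0 + h10 * T * v0 + h20 * T^2 * a0 +
    h01 * p1 + h11 * T * v1 + h21 * T^2 * a1
}

# Minimum-jerk blend 0 -> 1 with zero end velocity/acceleration.
minjerk_s <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  10 * s^3 - 15 * s^4 + 6 * s^5
}
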