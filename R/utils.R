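# Internal numeric helpers shared across modules.

#' Moving average with shrinking edge windows
#'
#' Averages `x` in a centred window of `width` samples; at the boundaries the
#' window shrinks rather than padding, so the output has the same length as
#' the input.  `NA` values are dropped from each window.
#'
#' @param x numeric vector.
#' @param width window width in samples (odd values are symmetric).
#' @return numeric vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, width = 5L) {
  n <- length(x)
  if (n == 0L || width <= 1L) return(x)
  half <- (width - 1L) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, ceiling(i - half))
    hi <- min(n, floor(i + half))
    w <- x[lo:hi]
    out[i] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  out
}

# Discretised Gaussian kernel on the 1 ms grid, normalised to unit sum so that
# convolution conserves total mass exactly.
gaussian_kernel <- function(sd_ms, radius = ceiling(5 * sd_ms)) {
  k <- stats::dnorm(seq(-radius, radius), sd = sd_ms)
  k / sum(k)
}

# Convolve x with a unit-sum kernel, keeping the central (same-length) part.
conv_same <- function(x, kernel) {
  nk <- length(kernel)
  half <- (nk - 1L) / 2
  full <- stats::convolve(x, rev(kernel), type = "open")
  full[(half + 1L):(half + length(x))]
}

# Smooth Gaussian noise with unit marginal s.d. (up to edge effects), obtained
# by low-pass filtering white noise and rescaling by the theoretical shrinkage.
smooth_noise <- function(n, smooth_ms) {
  if (smooth_ms <= 0) return(stats::rnorm(n))
  k <- gaussian_kernel(smooth_ms)
  conv_same(stats::rnorm(n), k) / sqrt(sum(k^2))
}

# First index at which `flag` holds for at least `min_run` consecutive samples,
# or NA if no such run exists.
first_sustained <- function(flag, min_run) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= min_run
  if (!any(ok)) return(NA_integer_)
  starts[which(ok)[1L]]
}

# Column-wise Pearson correlation between two equal-dimension matrices
# (rows = trials).  Columns with zero variance give NA.
col_cor <- function(a, b) {
  n <- nrow(a)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  num <- colSums(ac * bc)
  den <- sqrt(colSums(ac^2) * colSums(bc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Clamp helper
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
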