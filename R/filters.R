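#' Zero-lag Butterworth low-pass filter
#'
#' Applies a second-order Butterworth low-pass filter forward and backward
#' (the conventional "4th-order zero-lag" smoother of motion analysis) with
#' odd-symmetric end reflection to limit edge transients. No cutoff
#' correction for the double pass is applied; the stated cutoff is the
#' single-pass -3 dB frequency.
#'
#' @param x numeric vector (may contain no NAs).
#' @param fs sampling rate (Hz).
#' @param fc cutoff frequency (Hz); must satisfy \code{0 < fc < fs/2}.
#' @return filtered vector, same length as \code{x}.
#' @export
low_pass <- function(x, fs, fc) {
  if (!is.numeric(fc) || fc <= 0 || fc >= fs / 2)
    stop("configuration error: cutoff must lie in (0, fs/2)")
  n <- length(x)
  if (n < 5) return(x)
  co <- butter2_coeffs(fc, fs)
  npad <- min(n - 1L, 3L * ceiling(fs / fc))
  pre <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  xe <- c(pre, x, post)
  y <- biquad(xe, co)
  y <- rev(biquad(rev(y), co))
  y[seq(npad + 1L, npad + n)]
}

# 2nd-order Butterworth low-pass via bilinear transform
butter2_coeffs <- function(fc, fs) {
  ita <- 1 / tan(pi * fc / fs)
  q <- sqrt(2)
  b0 <- 1 / (1 + q * ita + ita^2)
  list(b = c(b0, 2 * b0, b0),
       a = c(2 * b0 * (1 - ita^2), b0 * (1 - q * ita + ita^2)))
}

biquad <- function(x, co) {
  b <- co$b; a <- co$a
  n <- length(x)
  y <- numeric(n)
  # steady-state initialisation (unit DC gain) avoids startup transients
  y[1] <- b[1] * x[1] + (b[2] + b[3]) * x[1] - (a[1] + a[2]) * x[1]
  y[2] <- b[1] * x[2] + (b[2] + b[3]) * x[1] - a[1] * y[1] - a[2] * x[1]
  for (i in 3:n) {
    y[i] <- b[1] * x[i] + b[2] * x[i - 1] + b[3] * x[i - 2] -
      a[1] * y[i - 1] - a[2] * y[i - 2]
  }
  y
}

# central differences with one-sided endpoints; x may be a matrix (by column)
central_diff <- function(x, dt) {
  if (is.matrix(x)) return(apply(x, 2, central_diff, dt = dt))
  n <- length(x)
  if (n < 2) stop("input error: need at least 2 samples to differentiate")
  d <- numeric(n)
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}
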