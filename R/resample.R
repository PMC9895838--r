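#' @include utils.R
NULL

#' Polyphase rational resampling of a signal
#'
#' Zero-phase anti-aliased resampling: the signal is upsampled by the rational
#' factor's numerator (zero stuffing), low-pass filtered forward-backward with
#' a Hamming-window FIR (so the net group delay is zero), and decimated by the
#' denominator. Non-integer rates are approximated by a rational factor with
#' denominator up to 1000.
#'
#' @param x Numeric vector.
#' @param fromRate Original sampling rate in Hz.
#' @param toRate Target sampling rate in Hz.
#' @return Numeric vector of length `round(length(x) * toRate / fromRate)`.
#' @examples
#' y <- resampleSignal(sin(2 * pi * 5 * (0:1023) / 1024), 1024, 128)
#' length(y)  # 128
#' @export
resampleSignal <- function(x, fromRate, toRate) {
  if (toRate <= 0 || fromRate <= 0) stop("rates must be positive")
  nOut <- round(length(x) * toRate / fromRate)
  if (abs(fromRate - toRate) < 1e-12) return(x)
  frac <- rationalApprox(toRate / fromRate)
  p <- frac[1L]; q <- frac[2L]
  up <- if (p > 1L) {
    u <- numeric(length(x) * p)
    u[seq(1L, length(u), by = p)] <- x
    u
  } else x
  fc <- 1 / max(p, q)                    # normalized cutoff (Nyquist = 1)
  nTaps <- ceiling(2 * 3.3 / fc)         # Hamming design rule, generous order
  if (nTaps %% 2 == 1L) nTaps <- nTaps + 1L
  nTaps <- min(nTaps, max(4L, 2L * (floor((length(up) - 1) / 2))))
  if (nTaps %% 2 == 1L) nTaps <- nTaps - 1L
  b <- signal::fir1(nTaps, fc * 0.9, type = "low",
                    window = signal::hamming(nTaps + 1L))
  b <- as.numeric(b) / sum(b)         # exact unit DC gain
  filt <- firFiltFilt(b, up) * p      # restore amplitude lost to zero-stuffing
  out <- filt[seq(1L, length(filt), by = q)]
  if (length(out) >= nOut) out[seq_len(nOut)]
  else c(out, rep(out[length(out)], nOut - length(out)))
}

# Best rational approximation p/q to r with q bounded (continued fractions).
rationalApprox <- function(r, maxDen = 1000L) {
  if (abs(r - round(r)) < 1e-9) return(c(as.integer(round(r)), 1L))
  if (abs(1 / r - round(1 / r)) < 1e-9) return(c(1L, as.integer(round(1 / r))))
  h0 <- 0; h1 <- 1; k0 <- 1; k1 <- 0
  x <- r
  repeat {
    a <- floor(x)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > maxDen) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    if (abs(h1 / k1 - r) < 1e-12) break
    x <- 1 / (x - a)
  }
  d <- gcd2(h1, k1)
  c(as.integer(h1 / d), as.integer(k1 / d))
}
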