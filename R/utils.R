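#' @include AllClasses.R
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs unseeded.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage seed derivation from one global seed. `stage` is a
# short label, `k` a counter. Result stays inside the 32-bit integer range.
deriveSeed <- function(seed, stage = "", k = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  val <- (as.numeric(seed) %% 2147483647) * 48271 + h * 1009 + k * 101
  as.integer(val %% 2147483629) + 1L
}

norm01 <- function(v) {
  r <- range(v)
  if (diff(r) == 0) return(rep(0, length(v)))
  (v - r[1L]) / diff(r)
}

# Centered moving average with full windows only (NA at the edges).
movingAverage <- function(y, window) {
  if (window <= 1L) return(y)
  as.numeric(stats::filter(y, rep(1 / window, window), sides = 2L))
}

# Gaussian noise with a 1/f amplitude spectrum, unit variance, deterministic
# under the caller's RNG state.
pinkNoise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  freq <- c(1, seq_len(n - 1L))
  freq <- pmin(freq, n - freq + 1)      # mirror for negative frequencies
  spec <- spec / sqrt(freq)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# Magnitude of the analytic signal (envelope) via the frequency-domain
# Hilbert transform.
analyticEnvelope <- function(x) {
  n <- length(x)
  spec <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(spec * h, inverse = TRUE) / n)
}

# Zero-phase FIR filtering with reflection padding of one filter length.
# `b` is the FIR coefficient vector (class Ma or numeric).
firFiltFilt <- function(b, x) {
  b <- as.numeric(b)
  npad <- length(b)
  n <- length(x)
  if (n < 2L) stop("signal too short to filter")
  npad <- min(npad, n - 1L)
  xp <- c(2 * x[1L] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  y <- signal::filtfilt(signal::Ma(b), xp)
  y[(npad + 1L):(npad + n)]
}

# Zero-phase IIR filtering with reflection padding. The default padding is
# generous because low-cutoff IIR transients decay slowly.
iirFiltFilt <- function(flt, x, npad = NULL) {
  n <- length(x)
  if (is.null(npad)) npad <- min(n - 1L, max(100L, 10L * (length(flt$a) +
                                                            length(flt$b))))
  xp <- c(2 * x[1L] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  y <- signal::filtfilt(flt, xp)
  y[(npad + 1L):(npad + n)]
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# Nearest-sample index (0-based) for a time point; exact half-sample ties
# round down.
nearestSample <- function(time, rate) {
  s <- time * rate
  as.integer(ceiling(s - 0.5))
}

stopIfNotFinite <- function(x, what) {
  if (any(!is.finite(x))) stop(what, " contains non-finite values")
  invisible(TRUE)
}
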