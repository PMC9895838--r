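#' @include utils.R
NULL

.pkgCache <- new.env(parent = emptyenv())

#' Phoneme-to-phonological-feature mapping table
#'
#' Loads the ARPAbet to 14-feature binary table shipped with the package (or a
#' user-supplied CSV of the same layout: a `phoneme` column plus one 0/1
#' column per feature). The shipped table is a documented convention assembled
#' from standard articulatory classifications, not ground truth; override it
#' with `file` to use another inventory.
#'
#' @param file Optional path to a CSV replacing the shipped table.
#' @return Binary matrix, phonemes (rownames) by the 14 features of
#'   [phonologicalFeatureNames()].
#' @examples
#' m <- phonemeFeatureMap()
#' m["B", ]  # voiced labial plosive obstruent
#' @export
phonemeFeatureMap <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(.pkgCache$phonemeMap)) return(.pkgCache$phonemeMap)
    file <- system.file("extdata", "arpabet_phonological_features.csv",
                        package = "mTRFknee", mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  tab <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  need <- phonologicalFeatureNames()
  if (!all(need %in% colnames(tab)))
    stop("mapping table must contain the 14 feature columns: ",
         paste(setdiff(need, colnames(tab)), collapse = ", "))
  m <- as.matrix(tab[, need])
  rownames(m) <- toupper(tab$phoneme)
  storage.mode(m) <- "numeric"
  if (!all(m %in% c(0, 1))) stop("mapping table entries must be 0/1")
  if (cache) .pkgCache$phonemeMap <- m
  m
}

#' Extract the acoustic envelope of a speech waveform
#'
#' Magnitude of the analytic (Hilbert) signal, low-passed with a zero-phase
#' 3rd-order Butterworth filter at 25 Hz, then resampled to the target rate.
#' Tiny negative filter ripple is clipped to zero.
#'
#' @param audio Numeric vector of mono waveform samples (a one-column matrix is
#'   accepted; true multichannel audio is rejected).
#' @param rate Audio sampling rate in Hz (must exceed 50 Hz).
#' @param targetRate Output sampling rate in Hz (default 128).
#' @return A [FeatureMatrix-class] with one row named `"envelope"`.
#' @examples
#' fs <- 8000
#' tone <- sin(2 * pi * 440 * (0:(fs - 1)) / fs)
#' env <- extractEnvelope(tone, fs, 128)
#' @export
extractEnvelope <- function(audio, rate, targetRate = 128) {
  if (is.matrix(audio)) {
    if (min(dim(audio)) > 1L)
      stop("multichannel audio is not supported; downmix to mono first")
    audio <- as.numeric(audio)
  }
  if (rate <= 50) stop("audio rate must exceed 50 Hz")
  env <- analyticEnvelope(audio)
  flt <- signal::butter(3, 25 / (rate / 2), type = "low")
  # pad by several filter time constants so edge transients stay at the rim
  env <- iirFiltFilt(flt, env, npad = min(length(env) - 1L, round(3 * rate / 25)))
  env <- resampleSignal(env, rate, targetRate)
  env <- pmax(env, 0)
  FeatureMatrix(matrix(env, nrow = 1L), targetRate, "envelope")
}

#' Binary phonological onset matrix from a phoneme annotation
#'
#' For each phoneme interval, a 1 is placed at the sample nearest its start
#' time (exact half-sample ties round down) in every feature row the mapping
#' activates. Row order is fixed to the 14 labels of
#' [phonologicalFeatureNames()]. A sustained mode marking the whole interval
#' instead of its onset is available behind `sustained`.
#'
#' @param annotation Data frame with columns `label`, `start`, `end` (seconds);
#'   intervals must be non-overlapping and ascending.
#' @param duration Total duration in seconds (sets the column count).
#' @param targetRate Sampling rate in Hz.
#' @param mapping Phoneme-to-feature matrix from [phonemeFeatureMap()].
#' @param skipLabels Labels ignored silently (silence/pause markers).
#' @param onUnknown `"error"` (default) to fail on a label absent from the
#'   mapping, `"skip"` to drop it.
#' @param sustained If `TRUE`, mark every sample of the interval instead of
#'   the onset only.
#' @return A [FeatureMatrix-class] with 14 binary rows.
#' @examples
#' ann <- data.frame(label = "B", start = 0.5, end = 0.55)
#' pm <- phonologicalOnsetMatrix(ann, duration = 1, targetRate = 128)
#' which(pm@values["voiced", ] == 1)  # sample 65 (0-based 64)
#' @export
phonologicalOnsetMatrix <- function(annotation, duration, targetRate,
                                    mapping = phonemeFeatureMap(),
                                    skipLabels = c("sp", "sil", "spn", ""),
                                    onUnknown = c("error", "skip"),
                                    sustained = FALSE) {
  onUnknown <- match.arg(onUnknown)
  feats <- phonologicalFeatureNames()
  nT <- max(1L, round(duration * targetRate))
  out <- matrix(0, length(feats), nT, dimnames = list(feats, NULL))
  if (nrow(annotation)) {
    if (is.unsorted(annotation$start))
      stop("annotation intervals must be ascending")
    if (any(annotation$end <= annotation$start))
      stop("annotation intervals must have start < end")
    for (i in seq_len(nrow(annotation))) {
      lab <- annotation$label[i]
      if (tolower(lab) %in% tolower(skipLabels)) next
      key <- toupper(gsub("[0-9]+$", "", lab))
      if (!key %in% rownames(mapping)) {
        if (onUnknown == "skip") next
        stop(sprintf("unknown phoneme label '%s' (not in the mapping table)",
                     lab))
      }
      active <- which(mapping[key, ] == 1)
      if (!length(active)) next
      if (sustained) {
        s0 <- nearestSample(annotation$start[i], targetRate) + 1L
        s1 <- nearestSample(annotation$end[i], targetRate) + 1L
        s0 <- max(1L, min(s0, nT)); s1 <- max(1L, min(s1, nT))
        out[active, s0:s1] <- 1
      } else {
        s0 <- nearestSample(annotation$start[i], targetRate) + 1L
        if (s0 >= 1L && s0 <= nT) out[active, s0] <- 1
      }
    }
  }
  FeatureMatrix(out, targetRate)
}

#' Pitch (f0) feature row from a pitch track
#'
#' Sample-and-hold interpolation of the f0 values onto the target grid:
#' each output sample takes the most recent track value at or before its time
#' (zero before the first track point). Unvoiced spans (f0 = 0) stay zero.
#'
#' @param track Data frame with columns `time` (seconds, strictly ascending)
#'   and `f0` (Hz, 0 where unvoiced, never negative).
#' @param duration Total duration in seconds.
#' @param targetRate Sampling rate in Hz.
#' @return A [FeatureMatrix-class] with one row named `"pitch"`.
#' @export
pitchFeature <- function(track, duration, targetRate) {
  if (duration <= 0) stop("duration must be positive")
  if (any(track$f0 < 0)) stop("negative f0 values are not allowed")
  if (nrow(track) > 1L && any(diff(track$time) <= 0))
    stop("track times must be strictly ascending")
  nT <- max(1L, round(duration * targetRate))
  grid <- (seq_len(nT) - 1L) / targetRate
  out <- numeric(nT)
  if (nrow(track)) {
    idx <- findInterval(grid + 1e-12, track$time)
    nz <- idx > 0
    out[nz] <- track$f0[idx[nz]]
  }
  FeatureMatrix(matrix(out, nrow = 1L), targetRate, "pitch")
}

#' Locate a stimulus inside a recorded audio channel (matched filter)
#'
#' Slides the stimulus along the recorded channel and evaluates the normalized
#' cross-correlation (cosine similarity per window). The onset is the offset
#' (in samples, 0-based: 0 means aligned with the first recorded sample)
#' maximizing the score; the result is reported as found only when the peak
#' score reaches the threshold.
#'
#' @param recorded Numeric vector, the recorded audio channel.
#' @param recordedRate Its sampling rate in Hz.
#' @param stimulus Numeric vector, the presented stimulus waveform.
#' @param stimulusRate Its sampling rate in Hz (resampled internally to
#'   `recordedRate` when different).
#' @param threshold Normalized-correlation cutoff in (0, 1] (default 0.5).
#' @return List with `found`, `onset` (0-based sample offset, NA when not
#'   found), `offset` (onset + stimulus length - 1), `peakScore`.
#' @examples
#' set.seed(1)
#' stim <- rnorm(500)
#' rec <- c(rnorm(1000) * 0.3, stim + rnorm(500) * 0.3, rnorm(200) * 0.3)
#' alignMatchFilter(rec, 8000, stim, 8000)$onset  # 1000
#' @export
alignMatchFilter <- function(recorded, recordedRate, stimulus, stimulusRate,
                             threshold = 0.5) {
  if (abs(recordedRate - stimulusRate) > 1e-9)
    stimulus <- resampleSignal(stimulus, stimulusRate, recordedRate)
  L <- length(stimulus)
  N <- length(recorded)
  if (L > N) stop("stimulus is longer than the recorded channel")
  sEnergy <- sqrt(sum(stimulus^2))
  # cross-correlation via FFT: num[k] = sum_i recorded[k+i] * stimulus[i]
  nfft <- stats::nextn(N + L - 1L, 2L)
  fr <- stats::fft(c(recorded, numeric(nfft - N)))
  fs <- stats::fft(c(rev(stimulus), numeric(nfft - L)))
  xc <- Re(stats::fft(fr * fs, inverse = TRUE)) / nfft
  num <- xc[L:(N)]                               # lags 0 .. N-L
  csum <- cumsum(c(0, recorded^2))
  winEnergy <- sqrt(pmax(csum[(L + 1L):(N + 1L)] - csum[1:(N - L + 1L)], 0))
  denom <- winEnergy * sEnergy
  score <- ifelse(denom > 0, num / denom, 0)
  peak <- max(score)
  onset <- which.max(score) - 1L
  if (peak < threshold)
    return(list(found = FALSE, onset = NA_integer_, offset = NA_integer_,
                peakScore = peak))
  list(found = TRUE, onset = onset, offset = onset + L - 1L,
       peakScore = min(peak, 1))
}
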