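#' @include utils.R
NULL

#' Read phoneme intervals from a Praat TextGrid
#'
#' Parses long-format TextGrid files and returns the intervals of one
#' interval tier as an annotation data frame. Empty-text intervals are kept
#' (downstream code treats them as silence markers).
#'
#' @param path Path to a TextGrid file.
#' @param tier Tier name (e.g. `"phones"`); default: the first interval tier.
#' @return Data frame with columns `label`, `start`, `end` (seconds),
#'   ascending and non-overlapping.
#' @export
readTextGrid <- function(path, tier = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  grab <- function(pat, line) {
    m <- regmatches(line, regexec(pat, line))[[1L]]
    if (length(m) < 2L) NA_character_ else m[2L]
  }
  tierStarts <- grep("^item\\s*\\[[0-9]+\\]", lines)
  if (!length(tierStarts)) stop("no tiers found in ", path)
  tierEnds <- c(tierStarts[-1L] - 1L, length(lines))
  chosen <- NULL
  for (k in seq_along(tierStarts)) {
    block <- lines[tierStarts[k]:tierEnds[k]]
    cls <- grab('class\\s*=\\s*"([^"]*)"', block[grep("class", block)[1L]])
    nm <- grab('name\\s*=\\s*"([^"]*)"', block[grep("^name", block)[1L]])
    if (!identical(cls, "IntervalTier")) next
    if (is.null(tier) || identical(nm, tier)) {
      chosen <- block
      break
    }
  }
  if (is.null(chosen))
    stop(if (is.null(tier)) "no interval tier found"
         else sprintf("no interval tier named '%s'", tier))
  xmins <- grep("^xmin", chosen, value = TRUE)
  xmaxs <- grep("^xmax", chosen, value = TRUE)
  texts <- grep("^text", chosen, value = TRUE)
  # first xmin/xmax describe the tier itself; intervals follow
  if (length(xmins) != length(texts) + 1L)
    xmins <- xmins[seq_len(length(texts) + 1L)]
  val <- function(v) as.numeric(sub(".*=\\s*", "", v))
  lab <- vapply(texts, function(l) {
    m <- regmatches(l, regexec('"(.*)"', l))[[1L]]
    if (length(m) < 2L) "" else m[2L]
  }, character(1), USE.NAMES = FALSE)
  out <- data.frame(label = lab,
                    start = val(xmins[-1L]),
                    end = val(xmaxs[-1L]),
                    stringsAsFactors = FALSE)
  if (any(diff(out$start) < 0)) stop("TextGrid intervals are not ascending")
  out
}

#' Read phoneme intervals from a tab-separated label file
#'
#' Three columns: label, start (s), end (s); a header row is detected and
#' skipped automatically.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `label`, `start`, `end`.
#' @export
readPhonemeLabels <- function(path) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE)
  hasHeader <- is.na(suppressWarnings(as.numeric(first[[2L]])))
  tab <- utils::read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("expected 3 columns: label, start, end")
  out <- data.frame(label = as.character(tab[[1L]]),
                    start = as.numeric(tab[[2L]]),
                    end = as.numeric(tab[[3L]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$start)) || any(is.na(out$end)))
    stop("non-numeric start/end values in ", path)
  out
}

#' Read a pitch (f0) track from a two-column text file
#'
#' Whitespace- or comma-separated `time f0` pairs; time in seconds
#' (strictly ascending), f0 in Hz with 0 marking unvoiced frames.
#'
#' @param path Path to the file.
#' @return Data frame with columns `time`, `f0`.
#' @export
readPitchTrack <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,\\s]+", perl = TRUE)
  firstNum <- suppressWarnings(as.numeric(parts[[1L]][1L]))
  if (is.na(firstNum)) parts <- parts[-1L]          # header row
  times <- vapply(parts, function(p) as.numeric(p[1L]), numeric(1))
  f0 <- vapply(parts, function(p) as.numeric(p[2L]), numeric(1))
  if (any(is.na(times)) || any(is.na(f0)))
    stop("malformed pitch track in ", path)
  if (any(f0 < 0)) stop("negative f0 values in ", path)
  if (is.unsorted(times, strictly = TRUE))
    stop("pitch track times must be strictly ascending")
  data.frame(time = times, f0 = f0)
}
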