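#' Count spikes in half-open windows
#'
#' Counts spikes falling in `[start, stop)` for each window. Spike times must
#' be sorted ascending; windows may overlap and may be given in any order.
#'
#' @param times sorted numeric vector of spike times (seconds)
#' @param starts,stops numeric vectors of equal length; window bounds in
#'   seconds, each window `[start, stop)`
#' @return integer vector of counts, one per window
#' @keywords internal
count_in_windows <- function(times, starts, stops) {
  if (length(starts) != length(stops)) {
    stop("`starts` and `stops` must have the same length")
  }
  # findInterval(..., left.open = TRUE) returns #{t < x}
  findInterval(stops, times, left.open = TRUE) -
    findInterval(starts, times, left.open = TRUE)
}

#' Maximal runs of TRUE meeting a minimum length
#'
#' @param flag logical vector
#' @param min_len minimum run length (elements)
#' @return data.frame with columns `first`, `last` (indices), one row per
#'   maximal run of length >= min_len
#' @keywords internal
flag_runs <- function(flag, min_len = 1L) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(first = starts[keep], last = ends[keep])
}

#' Derive a reproducible sub-seed from a top-level seed and a stage tag
#'
#' One top-level seed spawns per-stage (and per-unit) sub-seeds so that any
#' stage can be rerun in isolation and reproduce its part of a full run. The
#' derivation is a fixed integer hash: the tag is folded character-by-character
#' into a 31-bit accumulator seeded by the parent seed (Lehmer-style
#' multiplicative mixing, modulus 2^31 - 1). It is stable across platforms and
#' keeps every derived seed a valid positive 32-bit integer.
#'
#' @param seed integer parent seed
#' @param tag character scalar naming the stage or unit
#' @return a positive integer seed
#' @export
#' @examples
#' derive_seed(1, "modulation")
derive_seed <- function(seed, tag) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed %% m)
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 48271 + code) %% m
  }
  as.integer(h + 1)
}

#' Population (divide-by-n) standard deviation
#' @keywords internal
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
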