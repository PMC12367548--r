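#' Construct a spike train
#'
#' A single neuron's sorted spike times together with the session span it was
#' recorded over. The session mean rate (count / span length) is derived and
#' stored.
#'
#' @param times numeric vector of spike times in seconds; sorted ascending
#'   (unsorted input is sorted with a warning)
#' @param span length-2 numeric, session `[start, stop)` in seconds
#' @param neuron_id identifier
#' @return object of class `spike_train`
#' @export
spike_train <- function(times, span, neuron_id = 1L) {
  stopifnot(length(span) == 2L, span[2] > span[1])
  if (is.unsorted(times)) {
    warning("spike times were not sorted; sorting")
    times <- sort(times)
  }
  if (length(times) && (times[1] < span[1] || times[length(times)] >= span[2])) {
    stop("spike times must lie within the session span [start, stop)")
  }
  structure(list(neuron_id = neuron_id,
                 times = as.numeric(times),
                 span = as.numeric(span),
                 mean_rate = length(times) / diff(span)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train %s: %d spikes over %.1f s (%.2f Hz)\n",
              format(x$neuron_id), length(x$times), diff(x$span),
              x$mean_rate))
  invisible(x)
}

#' Keep tonically active units
#'
#' Filters a list of spike trains to the units whose session mean firing rate
#' exceeds `min_rate` (strictly), the standard criterion for isolating
#' tonically active SNr units from curated recordings.
#'
#' @param trains list of [spike_train()]
#' @param min_rate Hz threshold; units are kept when mean rate > `min_rate`
#' @return filtered list, with attributes `n_kept` and `n_dropped`
#' @export
filter_tonic_units <- function(trains, min_rate = 5) {
  if (length(trains) == 0L) {
    warning("no spike trains supplied")
    return(structure(list(), n_kept = 0L, n_dropped = 0L))
  }
  rates <- vapply(trains, function(tr) tr$mean_rate, 0)
  keep <- rates > min_rate
  structure(trains[keep],
            n_kept = sum(keep), n_dropped = sum(!keep))
}
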