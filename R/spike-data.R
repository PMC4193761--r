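#' Spike data container
#'
#' A tibble of spike events (`time` in ms, `neuron` id, optional `population`
#' label) carrying the simulation `duration` as an attribute. All analysis
#' functions accept either this class or a plain data frame plus an explicit
#' `duration` argument.
#'
#' @param time Spike times (ms).
#' @param neuron Integer neuron ids.
#' @param population Optional character population labels (recycled).
#' @param duration Recording duration (ms).
#' @return A tibble of class `spike_data`, sorted by time.
#' @export
spike_data <- function(time = numeric(), neuron = integer(),
                       population = NA_character_, duration) {
  assert_that(length(time) == length(neuron), "time and neuron lengths differ")
  x <- tibble::tibble(time = as.double(time), neuron = as.integer(neuron),
                      population = rep_len(as.character(population),
                                           length(time)))
  x <- x[order(x$time, x$neuron), ]
  assert_that(all(x$time >= 0) && all(x$time <= duration),
              "spike times must lie within [0, duration]")
  structure(x, duration = as.double(duration),
            class = c("spike_data", class(tibble::tibble())))
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("<spike_data> %d spikes, %d neurons, %g ms\n",
              nrow(x), length(unique(x$neuron)), spike_duration(x)))
  NextMethod()
}

#' Duration of a spike recording
#'
#' @param spikes A [spike_data()] object or data frame of spikes.
#' @param duration Override; required when `spikes` carries no duration.
#' @return Duration in ms.
#' @export
spike_duration <- function(spikes, duration = NULL) {
  d <- duration %||% attr(spikes, "duration")
  assert_that(!is.null(d), "duration not available: pass `duration`")
  as.double(d)
}

#' Per-neuron spike trains
#'
#' @param spikes Spike data.
#' @param neurons Ids to extract; defaults to all ids present.
#' @return Named list of increasing spike-time vectors (one per neuron;
#'   neurons without spikes get `numeric(0)`).
#' @export
spike_trains <- function(spikes, neurons = NULL) {
  ids <- neurons %||% sort(unique(spikes$neuron))
  out <- split(spikes$time, factor(spikes$neuron, levels = ids))
  lapply(out, function(t) sort(as.double(t)))
}
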