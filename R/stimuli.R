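#' Independent homogeneous Poisson spike sources
#'
#' @param n Number of sources.
#' @param rate Firing rate per source (Hz).
#' @param duration Duration (ms).
#' @param seed Integer seed; identical seeds give identical trains.
#' @return A [spike_data()] tibble with neuron ids `1:n`.
#' @export
poisson_sources <- function(n, rate, duration, seed = NULL) {
  assert_that(rate >= 0, "rate must be >= 0")
  with_seed(seed, {
    counts <- stats::rpois(n, rate * duration / 1000)
    neuron <- rep.int(seq_len(n), counts)
    time <- stats::runif(sum(counts), 0, duration)
    spike_data(time, neuron, population = "poisson", duration = duration)
  })
}

#' Realize a pulse packet as spike times
#'
#' Each source emits spikes drawn from a Gaussian around the packet center.
#' For fractional `a`, the total count is the nearest integer to
#' `n_sources * a` and the extra spikes are assigned round-robin to sources
#' `1, 2, ...` so the realization is deterministic in everything but the
#' spike times themselves.
#'
#' @param pp A [pulse_packet()].
#' @param seed Integer seed.
#' @param duration Duration of the returned recording (ms); defaults to a
#'   window generously covering the packet.
#' @return A [spike_data()] tibble with neuron ids `1:n_sources`.
#' @export
pulse_packet_spikes <- function(pp, seed = NULL, duration = NULL) {
  assert_that(inherits(pp, "pulse_packet"), "pp must be a pulse_packet()")
  n <- pp$n_sources
  total <- round(n * pp$a)
  base <- total %/% n
  extra <- total - base * n
  counts <- rep.int(base, n)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  duration <- duration %||% (pp$t_center + 10 * max(pp$sigma, 1))
  with_seed(seed, {
    neuron <- rep.int(seq_len(n), counts)
    time <- if (pp$sigma > 0) {
      stats::rnorm(total, pp$t_center, pp$sigma)
    } else {
      rep.int(pp$t_center, total)
    }
    time <- pmin(pmax(time, 0), duration)
    spike_data(time, neuron, population = "pulse_packet", duration = duration)
  })
}

#' Per-spike effective weights under short-term plasticity
#'
#' Evaluates the Tsodyks-Markram utilization/recovery recursions at the given
#' presynaptic spike times and returns the effective synaptic weight released
#' by each spike (`weight * u_n * R_n`). The recursions are closed-form
#' between spikes, so this is exact for any spike train.
#'
#' @param pre_spike_times Sorted presynaptic spike times (ms).
#' @param stp An [stp_params()] object.
#' @param weight Static synaptic weight (nS).
#' @return Numeric vector of effective weights, one per spike.
#' @export
apply_stp <- function(pre_spike_times, stp, weight) {
  assert_that(inherits(stp, "stp_params"), "stp must be stp_params()")
  assert_that(!is.unsorted(pre_spike_times), "spike times must be sorted")
  n <- length(pre_spike_times)
  if (n == 0) return(numeric())
  eff <- numeric(n)
  R_after <- 1
  u_after <- stp$u
  for (k in seq_len(n)) {
    if (k == 1) {
      R_n <- 1
      u_n <- stp$u
    } else {
      dt_isi <- pre_spike_times[k] - pre_spike_times[k - 1]
      R_n <- 1 - (1 - R_after) * exp(-dt_isi / stp$tau_rec)
      u_n <- if (stp$mode == "facilitation") {
        stp$u + u_after * (1 - stp$u) * exp(-dt_isi / stp$tau_facil)
      } else {
        stp$u
      }
    }
    eff[k] <- weight * u_n * R_n
    R_after <- R_n * (1 - u_n)
    u_after <- u_n
  }
  eff
}
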