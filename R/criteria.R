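# Functionality criteria for the three benchmark architectures.

# -- Attractor memory --------------------------------------------------------

#' Detect active attractor episodes
#'
#' Smooths each pattern's pyramidal population rate with a Gaussian kernel and
#' marks a pattern as active while its rate exceeds `lambda_on` times the
#' all-pattern mean rate, with hysteresis down to `lambda_off`; simultaneous
#' super-threshold patterns are resolved winner-take-all by rate, so episodes
#' never overlap. Dwell times are episode lengths; the remaining time is
#' competition time.
#'
#' @param spikes Spike data with `population` labels.
#' @param patterns Tibble mapping `population` to `pattern` id (e.g. from
#'   [l23_patterns()]); only listed populations enter the analysis.
#' @param duration Recording duration (ms), defaulted from `spikes`.
#' @param smooth_sigma Gaussian kernel width (ms).
#' @param lambda_on,lambda_off Activation / deactivation thresholds as
#'   multiples of the mean rate.
#' @param bin Rate histogram bin (ms).
#' @param min_dwell Episodes shorter than this are discarded (ms).
#' @return Tibble of class `attractor_episodes` (`pattern`, `t_start`,
#'   `t_end`, `dwell`), with attributes `competition_time` and `duration`.
#' @export
detect_attractors <- function(spikes, patterns, duration = NULL,
                              smooth_sigma = 20, lambda_on = 3,
                              lambda_off = 2, bin = 5, min_dwell = 20) {
  duration <- spike_duration(spikes, duration)
  sp <- spikes[spikes$population %in% patterns$population, ]
  edges <- seq(0, duration, by = bin)
  n_bins <- length(edges) - 1L
  pat_ids <- sort(unique(patterns$pattern))
  pat_size <- table(factor(patterns$population))
  # per-pattern PYR count for rate normalization comes from the caller's map;
  # use spike counts per pattern per bin, smoothed
  rates <- sapply(pat_ids, function(p) {
    pops <- patterns$population[patterns$pattern == p]
    t <- sp$time[sp$population %in% pops]
    h <- graphics::hist(t, breaks = edges, plot = FALSE)$counts
    smooth_gauss(h, smooth_sigma / bin)
  })
  if (n_bins == 0 || nrow(sp) == 0) {
    return(empty_episodes(duration))
  }
  rates <- matrix(rates, nrow = n_bins)
  grand <- mean(rates)
  if (grand == 0) return(empty_episodes(duration))
  on_thr <- lambda_on * grand
  off_thr <- lambda_off * grand

  winner <- apply(rates, 1, which.max)
  wrate <- rates[cbind(seq_len(n_bins), winner)]
  active <- integer(n_bins) # 0 = competition
  cur <- 0L
  for (i in seq_len(n_bins)) {
    if (cur != 0L && rates[i, cur] >= off_thr && winner[i] == cur) {
      active[i] <- cur
    } else if (wrate[i] >= on_thr) {
      active[i] <- winner[i]
      cur <- winner[i]
    } else {
      cur <- 0L
    }
    if (active[i] == 0L) cur <- 0L
  }

  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0L
  ep <- tibble::tibble(
    pattern = pat_ids[runs$values[keep]],
    t_start = edges[starts[keep]],
    t_end = edges[ends[keep] + 1L]
  )
  ep$dwell <- ep$t_end - ep$t_start
  ep <- ep[ep$dwell >= min_dwell, ]
  structure(ep, competition_time = duration - sum(ep$dwell),
            duration = duration,
            class = c("attractor_episodes", class(tibble::tibble())))
}

empty_episodes <- function(duration) {
  structure(tibble::tibble(pattern = integer(), t_start = double(),
                           t_end = double(), dwell = double()),
            competition_time = duration, duration = duration,
            class = c("attractor_episodes", class(tibble::tibble())))
}

smooth_gauss <- function(x, sigma_bins) {
  if (sigma_bins <= 0 || length(x) < 2) return(x)
  half <- max(1L, ceiling(3 * sigma_bins))
  k <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[half + seq_len(n)]
}

#' Average membrane voltage around attractor episodes (UP / DOWN profiles)
#'
#' Averages recorded pyramidal voltages in windows around episodes of the
#' parent attractor (UP) and of foreign attractors (DOWN), on a time axis in
#' multiples of the mean dwell time.
#'
#' @param traces Voltage tibble (`time`, `neuron`, `v`).
#' @param episodes An `attractor_episodes` tibble.
#' @param neuron_patterns Tibble (`neuron`, `pattern`) giving each recorded
#'   neuron's parent pattern.
#' @param span Half-width of the window in mean dwell times.
#' @param n_points Samples per curve.
#' @return Tibble (`phase` UP/DOWN, `tau` in mean dwell times, `v`).
#' @export
up_down_voltage_profile <- function(traces, episodes, neuron_patterns,
                                    span = 2, n_points = 81) {
  assert_that(nrow(episodes) > 0, "no episodes: cannot form UP/DOWN profiles")
  t_dwell <- mean(episodes$dwell)
  tau <- seq(-span, span, length.out = n_points)
  ids <- unique(traces$neuron)
  acc <- list(UP = matrix(0, n_points, 2), DOWN = matrix(0, n_points, 2))
  for (id in ids) {
    tr <- traces[traces$neuron == id, ]
    pat <- neuron_patterns$pattern[match(id, neuron_patterns$neuron)]
    for (k in seq_len(nrow(episodes))) {
      mid <- (episodes$t_start[k] + episodes$t_end[k]) / 2
      tt <- mid + tau * t_dwell
      ok <- tt >= min(tr$time) & tt <= max(tr$time)
      if (!any(ok)) next
      v <- stats::approx(tr$time, tr$v, xout = tt[ok])$y
      phase <- if (!is.na(pat) && episodes$pattern[k] == pat) "UP" else "DOWN"
      acc[[phase]][ok, 1] <- acc[[phase]][ok, 1] + v
      acc[[phase]][ok, 2] <- acc[[phase]][ok, 2] + 1
    }
  }
  dplyr::bind_rows(lapply(names(acc), function(ph) {
    m <- acc[[ph]]
    tibble::tibble(phase = ph, tau = tau,
                   v = ifelse(m[, 2] > 0, m[, 1] / m[, 2], NA_real_))
  }))
}

# -- Population rate spectrum ------------------------------------------------

#' Power spectrum of the population rate
#'
#' Bins the pooled spike train, removes the mean, and reports the
#' Gaussian-smoothed periodogram together with the position of the non-zero
#' peak.
#'
#' @param spikes Spike data (optionally pre-filtered to one population).
#' @param duration Recording duration (ms).
#' @param bin Rate bin (ms).
#' @param smooth_sigma Gaussian smoothing width in frequency (Hz).
#' @param f_min Frequencies below this are excluded from the peak search (Hz).
#' @return Tibble of class `rate_spectrum` (`freq` Hz, `power`, `power_raw`)
#'   with attribute `peak_freq` (`NA` if the recording is silent).
#' @export
rate_spectrum <- function(spikes, duration = NULL, bin = 1,
                          smooth_sigma = 2, f_min = 1) {
  duration <- spike_duration(spikes, duration)
  edges <- seq(0, duration, by = bin)
  if (nrow(spikes) == 0) {
    out <- tibble::tibble(freq = double(), power = double(),
                          power_raw = double())
    return(structure(out, peak_freq = NA_real_, silent = TRUE,
                     class = c("rate_spectrum", class(tibble::tibble()))))
  }
  h <- graphics::hist(spikes$time[spikes$time <= max(edges)], breaks = edges,
                      plot = FALSE)$counts
  x <- h - mean(h)
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  freq <- seq(0, by = 1000 / (n * bin), length.out = n %/% 2 + 1)
  raw <- sp[seq_along(freq)]
  df <- freq[2] - freq[1]
  sm <- smooth_gauss(raw, smooth_sigma / df)
  sel <- freq >= f_min
  peak <- if (any(sel)) freq[sel][which.max(sm[sel])] else NA_real_
  structure(tibble::tibble(freq = freq, power = sm, power_raw = raw),
            peak_freq = peak, silent = FALSE,
            class = c("rate_spectrum", class(tibble::tibble())))
}

# -- Synfire chain -----------------------------------------------------------

#' Measure a pulse-packet volley
#'
#' Activation `a` = spikes per neuron of the group inside the window; `sigma`
#' = sample standard deviation of the spike times. A silent group yields
#' `a = 0` and `sigma = NA` (flagged via `fired = FALSE`).
#'
#' @param spikes Spike data.
#' @param neurons Ids of the group's excitatory neurons.
#' @param window `c(t0, t1)` response window (ms).
#' @return One-row tibble (`a`, `sigma`, `n_spikes`, `t_mean`, `fired`).
#' @export
measure_pulse_packet <- function(spikes, neurons, window) {
  t <- spikes$time[spikes$neuron %in% neurons &
                     spikes$time >= window[1] & spikes$time < window[2]]
  n <- length(t)
  tibble::tibble(
    a = n / length(neurons),
    sigma = if (n >= 2) stats::sd(t) else NA_real_,
    n_spikes = n,
    t_mean = if (n > 0) mean(t) else NA_real_,
    fired = n > 0
  )
}

#' Classify pulse propagation success
#'
#' Successful propagation means the activation of the last group reaches the
#' threshold (closed boundary: `a >= threshold` is a success). In the
#' undistorted chain last-group activations cluster near 0 and 1, so the
#' default sits halfway.
#'
#' @param last_group One-row tibble from [measure_pulse_packet()] (or a
#'   number).
#' @param threshold Activation threshold.
#' @return Logical.
#' @export
classify_propagation <- function(last_group, threshold = 0.5) {
  a <- if (is.data.frame(last_group)) last_group$a else last_group
  a >= threshold
}

#' Group-wise volley trajectory of a synfire simulation
#'
#' @param spikes Spike data from a synfire run.
#' @param net The synfire `network_spec`.
#' @param t_stim Stimulus packet center (ms).
#' @param half_window Half-width of each group's response window (ms).
#' @return Tibble (`group`, `a`, `sigma`, `n_spikes`, `t_mean`, `fired`).
#' @export
synfire_trajectory <- function(spikes, net, t_stim = 20, half_window = 10) {
  n_groups <- net$meta$n_groups
  d_ff <- net$meta$config$d_ff
  dplyr::bind_rows(lapply(seq_len(n_groups), function(g) {
    center <- t_stim + g * d_ff
    m <- measure_pulse_packet(spikes, pop_ids(net, paste0("RS", g)),
                              c(center - half_window, center + half_window))
    dplyr::mutate(m, group = g, .before = 1)
  }))
}

#' Remove spikes outside spike volleys
#'
#' Keeps a spike only if at least `m` spikes of the same population fall
#' within `+/- w` ms of it (itself included). Idempotent on its own output
#' for the same parameters whenever volleys are internally denser than the
#' criterion.
#'
#' @param spikes Spike data with `population` labels.
#' @param m Minimum co-active spikes.
#' @param w Half-window (ms).
#' @return Filtered spike data.
#' @export
spike_filter <- function(spikes, m = 10, w = 2) {
  keep <- logical(nrow(spikes))
  for (pop in unique(spikes$population)) {
    idx <- which(spikes$population == pop)
    t <- spikes$time[idx] # already sorted
    lo <- findInterval(t - w - 1e-9, t)
    hi <- findInterval(t + w + 1e-9, t)
    keep[idx] <- (hi - lo) >= m
  }
  out <- spikes[keep, ]
  attr(out, "duration") <- attr(spikes, "duration")
  class(out) <- class(spikes)
  out
}

#' Fit a separatrix in the (sigma, a) stimulus plane
#'
#' Logistic regression of propagation success on the initial pulse-packet
#' parameters, with a polynomial in `sigma`. The separatrix is the 50%
#' probability contour `a*(sigma)`; the transition-region width is the
#' distance in `a` between the 5% and 95% contours.
#'
#' @param samples Tibble (`sigma`, `a`, `success`).
#' @param degree Polynomial degree in `sigma`.
#' @return Object of class `separatrix_fit` with the glm, boundary function
#'   and width.
#' @export
fit_separatrix <- function(samples, degree = 1) {
  assert_that(length(unique(samples$success)) == 2,
              "both success classes must be present")
  samples$success <- as.logical(samples$success)
  fml <- stats::as.formula(paste0("success ~ a + poly(sigma, ", degree,
                                  ", raw = TRUE)"))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = samples))
  cf <- stats::coef(fit)
  boundary <- function(sigma, prob = 0.5) {
    z <- stats::qlogis(prob)
    sig_terms <- outer(sigma, seq_len(degree), `^`)
    (z - cf[1] - as.vector(sig_terms %*% cf[-(1:2)])) / cf[2]
  }
  sig_range <- range(samples$sigma)
  sig_grid <- seq(sig_range[1], sig_range[2], length.out = 50)
  width <- mean(abs(boundary(sig_grid, 0.95) - boundary(sig_grid, 0.05)))
  structure(list(fit = fit, boundary = boundary, width = width,
                 degree = degree, samples = samples, sigma_range = sig_range),
            class = "separatrix_fit")
}

#' @export
print.separatrix_fit <- function(x, ...) {
  cat(sprintf("<separatrix_fit> a*(sigma) over sigma in [%.2g, %.2g]; transition width %.3g\n",
              x$sigma_range[1], x$sigma_range[2], x$width))
  invisible(x)
}

# -- Asynchronous-irregular statistics ---------------------------------------

#' Statistics of an asynchronous-irregular recording
#'
#' * `survived`: the population still emits spikes within `survival_window`
#'   ms of the end of the recording;
#' * `rate`: mean firing rate over the given neurons (silent ones included);
#' * `cv_rates`: coefficient of variation of per-neuron rates;
#' * `cv_isi`: mean over neurons (with at least `min_isis` intervals) of the
#'   per-neuron ISI coefficient of variation;
#' * `cc`: mean pairwise Pearson correlation of binned spike counts over a
#'   random sample of neuron pairs;
#' * `peak_freq`: non-zero peak of the population-rate power spectrum.
#'
#' @param spikes Spike data.
#' @param neurons Ids of the analyzed (pyramidal) population.
#' @param duration Recording duration (ms).
#' @param t_start Analysis start (ms; discards the stimulation transient).
#' @param bin Correlation bin (ms).
#' @param n_pairs Number of sampled pairs for the correlation estimate.
#' @param survival_window Silence tolerance at the end of the run (ms).
#' @param min_isis Minimum ISI count per neuron for the irregularity measure.
#' @param pair_seed Seed for the pair sample.
#' @return One-row tibble of class `ai_stats`.
#' @export
ai_statistics <- function(spikes, neurons, duration = NULL, t_start = 0,
                          bin = 2, n_pairs = 1000, survival_window = 100,
                          min_isis = 3, pair_seed = 1L) {
  duration <- spike_duration(spikes, duration)
  sp <- spikes[spikes$neuron %in% neurons & spikes$time >= t_start, ]
  if (nrow(sp) == 0) {
    return(tibble::tibble(survived = FALSE, rate = 0, cv_rates = NA_real_,
                          cv_isi = NA_real_, cc = NA_real_,
                          peak_freq = NA_real_, n_neurons = length(neurons)))
  }
  survived <- (duration - max(spikes$time)) <= survival_window

  rts <- firing_rates(sp, neurons, duration, t_start)$rate
  rate <- mean(rts)
  cv_rates <- stats::sd(rts) / rate

  trains <- spike_trains(sp, neurons)
  cvs <- vapply(trains, function(t) {
    if (length(t) < min_isis + 1) return(NA_real_)
    isi <- diff(t)
    stats::sd(isi) / mean(isi)
  }, numeric(1))
  cv_isi <- mean(cvs, na.rm = TRUE)

  cc <- with_seed(pair_seed, {
    edges <- seq(t_start, duration, by = bin)
    counts <- lapply(trains, function(t) {
      graphics::hist(t[t <= max(edges)], breaks = edges, plot = FALSE)$counts
    })
    active <- which(vapply(counts, function(x) stats::sd(x) > 0, logical(1)))
    if (length(active) < 2) {
      NA_real_
    } else {
      n_avail <- length(active) * (length(active) - 1) / 2
      npair <- min(n_pairs, n_avail)
      i <- sample(active, npair, replace = TRUE)
      j <- sample(active, npair, replace = TRUE)
      fix <- i == j
      while (any(fix)) {
        j[fix] <- sample(active, sum(fix), replace = TRUE)
        fix <- i == j
      }
      mean(vapply(seq_len(npair), function(k) {
        stats::cor(counts[[i[k]]], counts[[j[k]]])
      }, numeric(1)))
    }
  })

  spec <- rate_spectrum(sp, duration = duration, bin = 1, smooth_sigma = 2)

  out <- tibble::tibble(survived = survived, rate = rate,
                        cv_rates = cv_rates, cv_isi = cv_isi, cc = cc,
                        peak_freq = attr(spec, "peak_freq"),
                        n_neurons = length(neurons))
  class(out) <- c("ai_stats", class(out))
  out
}
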