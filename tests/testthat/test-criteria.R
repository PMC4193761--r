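# Functionality criteria on scripted, fully-known inputs.

script_raster <- function(episodes, n_per_pattern = 30, rate_hi = 30,
                          rate_lo = 0.5, duration = 3000, n_patterns = 3,
                          seed = 1) {
  # piecewise-constant inhomogeneous Poisson raster: pattern p fires at
  # rate_hi inside its episodes, rate_lo outside
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_patterns)) {
    for (n in seq_len(n_per_pattern)) {
      t_lo <- stats::runif(stats::rpois(1, rate_lo * duration / 1000), 0,
                           duration)
      t_hi <- numeric()
      eps <- episodes[episodes$pattern == p, , drop = FALSE]
      if (nrow(eps)) {
        for (k in seq_len(nrow(eps))) {
          len <- eps$t_end[k] - eps$t_start[k]
          t_hi <- c(t_hi, stats::runif(stats::rpois(1, rate_hi * len / 1000),
                                       eps$t_start[k], eps$t_end[k]))
        }
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        time = c(t_lo, t_hi),
        neuron = (p - 1) * n_per_pattern + n,
        population = paste0("P", p)
      )
    }
  }
  sp <- dplyr::bind_rows(rows)
  spike_data(sp$time, sp$neuron, sp$population, duration = duration)
}

pattern_map <- function(n = 3) {
  tibble::tibble(population = paste0("P", seq_len(n)),
                 pattern = seq_len(n))
}

test_that("scripted alternating episodes are recovered with tight boundaries", {
  eps <- tibble::tibble(pattern = c(1L, 2L, 3L),
                        t_start = c(200, 1200, 2200),
                        t_end = c(700, 1700, 2700))
  sp <- script_raster(eps)
  got <- detect_attractors(sp, pattern_map())
  expect_equal(nrow(got), 3L)
  expect_equal(got$pattern, eps$pattern)
  expect_lt(max(abs(got$t_start - eps$t_start)), 50)
  expect_lt(max(abs(got$t_end - eps$t_end)), 50)
  # dwell + competition accounts for the full duration
  expect_equal(sum(got$dwell) + attr(got, "competition_time"), 3000)
})

test_that("uniform low-rate activity yields no episodes, silence yields full competition", {
  sp <- script_raster(tibble::tibble(pattern = integer(), t_start = double(),
                                     t_end = double()), rate_lo = 2)
  got <- detect_attractors(sp, pattern_map())
  expect_equal(nrow(got), 0L)
  expect_equal(attr(got, "competition_time"), 3000)

  silent <- spike_data(duration = 1000)
  got2 <- detect_attractors(silent, pattern_map())
  expect_equal(nrow(got2), 0L)
  expect_equal(attr(got2, "competition_time"), 1000)
})

test_that("UP/DOWN voltage profiles read scripted depolarizations", {
  eps <- structure(tibble::tibble(pattern = c(1L, 2L), t_start = c(200, 700),
                                  t_end = c(400, 900),
                                  dwell = c(200, 200)),
                   class = c("attractor_episodes",
                             class(tibble::tibble())))
  t <- seq(0, 1200, by = 1)
  base <- -70
  v1 <- base + 5 * (t >= 200 & t < 400) # neuron of pattern 1
  v2 <- base + 5 * (t >= 700 & t < 900) # neuron of pattern 2
  traces <- dplyr::bind_rows(
    tibble::tibble(time = t, neuron = 1L, v = v1),
    tibble::tibble(time = t, neuron = 2L, v = v2)
  )
  np <- tibble::tibble(neuron = 1:2, pattern = 1:2)
  prof <- up_down_voltage_profile(traces, eps, np, span = 0.4, n_points = 41)
  up <- prof$v[prof$phase == "UP" & abs(prof$tau) < 0.3]
  down <- prof$v[prof$phase == "DOWN" & abs(prof$tau) < 0.3]
  expect_equal(mean(up) - mean(down), 5, tolerance = 0.1)

  # constant traces give flat profiles at that constant
  flat <- dplyr::bind_rows(tibble::tibble(time = t, neuron = 1L, v = base),
                           tibble::tibble(time = t, neuron = 2L, v = base))
  pf <- up_down_voltage_profile(flat, eps, np, span = 0.4, n_points = 21)
  expect_true(all(abs(pf$v - base) < 1e-9, na.rm = TRUE))
  expect_error(up_down_voltage_profile(traces,
                                       spikefidelity:::empty_episodes(100),
                                       np), "episodes")
})

test_that("rate spectrum finds an implanted oscillation and stays flat for Poisson", {
  set.seed(4)
  dur <- 20000
  # pooled inhomogeneous Poisson (50 neurons at 25 Hz each) with a 25 Hz
  # sinusoidal rate modulation, realized by thinning
  lam_max <- 50 * 25 * 1.8
  n_cand <- stats::rpois(1, lam_max * dur / 1000)
  t_cand <- stats::runif(n_cand, 0, dur)
  lam <- 50 * 25 * (1 + 0.8 * sin(2 * pi * 25 * t_cand / 1000))
  t_keep <- sort(t_cand[stats::runif(n_cand) < lam / lam_max])
  sp <- spike_data(t_keep, rep(1L, length(t_keep)), duration = dur)
  spec <- rate_spectrum(sp, bin = 1, smooth_sigma = 1)
  expect_lt(abs(attr(spec, "peak_freq") - 25), 1)

  # homogeneous Poisson: no significant non-zero peak
  tp <- sort(stats::runif(30000, 0, dur))
  spp <- spike_data(tp, rep(1L, length(tp)), duration = dur)
  sp2 <- rate_spectrum(spp, bin = 1, smooth_sigma = 2)
  expect_lt(max(sp2$power[sp2$freq >= 1]),
            3 * stats::median(sp2$power[sp2$freq >= 1]))

  silent <- rate_spectrum(spike_data(duration = 1000))
  expect_true(attr(silent, "silent"))
  expect_true(is.na(attr(silent, "peak_freq")))
})

test_that("volley measurement reports activation and spread", {
  sp <- spike_data(rep(50, 100), 1:100, duration = 100)
  m <- measure_pulse_packet(sp, 1:100, c(40, 60))
  expect_equal(m$a, 1)
  expect_equal(m$sigma, 0)

  set.seed(7)
  t <- stats::rnorm(300, 50, 2)
  spg <- spike_data(t, sample(1:100, 300, replace = TRUE), duration = 100)
  mg <- measure_pulse_packet(spg, 1:100, c(30, 70))
  expect_lt(abs(mg$sigma - 2), 0.25)
  expect_equal(mg$a, 3)

  empty <- measure_pulse_packet(spike_data(duration = 100), 1:100, c(0, 100))
  expect_equal(empty$a, 0)
  expect_false(empty$fired)
  expect_true(is.na(empty$sigma))
})

test_that("propagation classification uses a closed success boundary", {
  expect_false(classify_propagation(0))
  expect_true(classify_propagation(1))
  expect_true(classify_propagation(0.5)) # boundary convention
})

test_that("separatrix fit recovers a known logistic boundary", {
  set.seed(11)
  n <- 4000
  sigma <- stats::runif(n, 0, 5)
  a <- stats::runif(n, 0, 1.5)
  alpha <- 0.3; beta <- 0.15 # true boundary a* = alpha + beta sigma
  p <- stats::plogis(12 * (a - alpha - beta * sigma))
  succ <- stats::runif(n) < p
  fit <- fit_separatrix(tibble::tibble(sigma = sigma, a = a, success = succ))
  sg <- c(1, 2.5, 4)
  expect_lt(max(abs(fit$boundary(sg) - (alpha + beta * sg)) /
                  (alpha + beta * sg)), 0.1)
  expect_gt(fit$width, 0)

  # vertical band: success iff a > 0.5 regardless of sigma
  succ2 <- a > 0.5
  fit2 <- fit_separatrix(tibble::tibble(sigma = sigma, a = a,
                                        success = succ2))
  expect_lt(max(abs(fit2$boundary(sg) - 0.5)), 0.05)
  expect_error(fit_separatrix(tibble::tibble(sigma = 1:3, a = 1:3,
                                             success = c(TRUE, TRUE, TRUE))),
               "both")
})

test_that("volley filter strips background and keeps volleys", {
  expect_equal(nrow(spike_filter(
    spike_data(50, 1L, "G", duration = 100), m = 2, w = 2)), 0L)

  dense <- spike_data(stats::runif(100, 50, 51), 1:100, "G", duration = 100)
  expect_equal(nrow(spike_filter(dense, m = 10, w = 2)), 100L)

  set.seed(3)
  volley_t <- stats::rnorm(200, 100, 0.5)
  bg_t <- stats::runif(60, 0, 1000)
  bg_t <- bg_t[abs(bg_t - 100) > 10]
  sp <- spike_data(c(volley_t, bg_t),
                   c(sample(1:100, 200, replace = TRUE),
                     sample(1:100, length(bg_t), replace = TRUE)),
                   "G", duration = 1000)
  out <- spike_filter(sp, m = 10, w = 2)
  expect_gte(sum(out$time > 90 & out$time < 110), 198) # volley kept
  expect_equal(sum(abs(out$time - 100) > 10), 0L)      # background gone
  # idempotent
  expect_equal(nrow(spike_filter(out, m = 10, w = 2)), nrow(out))
})

test_that("AI statistics reach their analytic limits", {
  # perfectly regular common-clock trains: CV_ISI = 0, CC = 1
  t <- seq(10, 1990, by = 20)
  sp <- spike_data(rep(t, 4), rep(1:4, each = length(t)), duration = 2000)
  st <- ai_statistics(sp, 1:4, duration = 2000, n_pairs = 6)
  expect_equal(st$cv_isi, 0, tolerance = 1e-12)
  expect_equal(st$cc, 1, tolerance = 1e-12)
  expect_true(st$survived)
  expect_equal(st$rate, length(t) / 2, tolerance = 1e-9)

  # independent Poisson: CV_ISI ~ 1, CC ~ 0
  set.seed(5)
  n <- 40; rate <- 20; dur <- 10000
  sp2 <- poisson_sources(n, rate, dur, seed = 8)
  st2 <- ai_statistics(sp2, 1:n, duration = dur, n_pairs = 400)
  expect_lt(abs(st2$cv_isi - 1), 4 / sqrt(rate * dur / 1000))
  expect_lt(abs(st2$cc), 0.01)
  expect_lt(abs(st2$rate - rate), 4 * sqrt(rate * 1000 / dur / n))

  # empty recording
  st3 <- ai_statistics(spike_data(duration = 500), 1:10, duration = 500)
  expect_false(st3$survived)
  expect_equal(st3$rate, 0)
})

test_that("statistics are invariant under neuron relabeling", {
  sp <- poisson_sources(20, 15, 5000, seed = 13)
  perm <- sample(1:20)
  sp2 <- spike_data(sp$time, perm[sp$neuron], duration = 5000)
  a <- ai_statistics(sp, 1:20, duration = 5000, pair_seed = 2)
  b <- ai_statistics(sp2, 1:20, duration = 5000, pair_seed = 2)
  expect_equal(a$rate, b$rate)
  expect_equal(a$cv_rates, b$cv_rates, tolerance = 1e-12)
  expect_equal(a$cv_isi, b$cv_isi, tolerance = 1e-12)
})
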