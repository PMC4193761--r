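# Compensation strategies.

test_that("1/(1-p) weight scaling conserves expected projection conductance", {
  net <- instantiate_synapses(build_synfire(n_groups = 3), seed = 2)
  w_before <- sum(net$synapses$weight[net$synapses$projection == "RS->RS"])
  cfg <- distortion_config(loss_p = list("RS->RS" = 0.5),
                           exempt_external = TRUE, seed = 4)
  lost <- apply_synapse_loss(net, cfg)
  comp <- compensate_loss_by_weights(lost, list("RS->RS" = 0.5))
  w_after <- sum(comp$synapses$weight[comp$synapses$projection == "RS->RS"])
  n <- sum(net$synapses$projection == "RS->RS")
  # sum of survivors * 2 is an unbiased estimate of the original mass
  se <- 2 * sqrt(n * 0.25) * net$synapses$weight[1]
  expect_lt(abs(w_after - w_before), 4 * se)
  # p = 0 is the identity, p = 1 is rejected
  expect_identical(compensate_loss_by_weights(net, 0)$synapses$weight,
                   net$synapses$weight)
  expect_error(compensate_loss_by_weights(net, 1), "p = 1")
})

test_that("multi-source background preserves drive and hits the overlap law", {
  net <- build_synfire(n_groups = 2)
  net <- instantiate_synapses(net, seed = 3)
  rate0 <- net$populations$rate[net$populations$name == "background"]
  k <- 10; pool <- 1000
  out <- multi_source_background(net, pool_size = pool, k_per_neuron = k)
  # per-neuron aggregate rate and weight are unchanged:
  pr <- out$populations[out$populations$name == "background_pool", ]
  expect_equal(pr$rate * k, rate0)
  bg <- out$synapses[out$synapses$projection == "background", ]
  expect_true(all(table(bg$target) == k))
  expect_equal(unique(bg$weight),
               net$synapses$weight[net$synapses$projection == "background"][1])

  # pairwise overlap of source sets ~ k^2 / pool
  sets <- split(bg$source, bg$target)
  ids <- names(sets)
  set.seed(1)
  ov <- vapply(1:2000, function(i) {
    pick <- sample(ids, 2)
    length(intersect(sets[[pick[1]]], sets[[pick[2]]]))
  }, numeric(1))
  expect_lt(abs(mean(ov) - k^2 / pool), 4 * stats::sd(ov) / sqrt(2000))

  # k = 1 with a pool as large as the target set reduces to one source per
  # neuron
  one <- multi_source_background(net, pool_size = n_neurons(net),
                                 k_per_neuron = 1)
  bg1 <- one$synapses[one$synapses$projection == "background", ]
  expect_true(all(table(bg1$target) == 1))
})

test_that("rest-potential compensation restores free-membrane statistics", {
  p <- adex_params(v_t = 1000) # free membrane: no spiking
  bg <- list(rate = 2000, weight = 1, tau_syn = p$tau_e, e_rev = 0)
  r <- 0.3

  adj <- compensate_noise_via_rest_potential(p, bg, r)
  expect_lt(adj$weight, bg$weight)
  expect_gt(adj$neuron$e_l, p$e_l)
  id <- compensate_noise_via_rest_potential(p, bg, 0)
  expect_identical(id$neuron, p)
  expect_equal(id$weight, bg$weight)

  sim_stats <- function(neuron, weights, seed) {
    pops <- tibble::tibble(
      name = c("cell", "in"), size = c(1L, length(weights)),
      cell_type = c("probe", "source"), params = list(neuron, NULL),
      rate = c(NA_real_, bg$rate / length(weights)),
      x = list(NULL), y = list(NULL)
    )
    syn <- synapse_params(1, e_rev = 0, tau_syn = neuron$tau_e)
    prj <- tibble::tibble(label = "bg", source = "in", target = "cell",
                          rule = list(rule_all()), syn = list(syn),
                          delay = list(delay_constant(1)), external = TRUE)
    net <- instantiate_synapses(network_spec(pops, prj), 1)
    net$synapses$weight <- weights
    res <- simulate_network(net, 20000, dt = 0.05, seed = seed, record = 1L)
    v <- res$voltages$v[res$voltages$time > 200]
    c(mean(v), stats::var(v))
  }

  ref <- sim_stats(p, 1, seed = 5)
  # frozen multiplicative weight noise across 40 parallel input channels
  set.seed(9)
  noisy_w <- pmax(0, stats::rnorm(40, 1, r))
  dist <- sim_stats(p, noisy_w, seed = 5)
  comp <- sim_stats(adj$neuron, noisy_w * adj$weight, seed = 5)

  drive_ref <- ref[1] - p$e_l
  expect_lt(abs((comp[1] - p$e_l) - drive_ref) / abs(drive_ref), 0.02)
  expect_lt(abs(comp[2] - ref[2]) / ref[2], 0.05)
  # and the distorted cell was indeed off before compensation
  expect_gt(abs(dist[2] - ref[2]) / ref[2],
            abs(comp[2] - ref[2]) / ref[2])
})

test_that("inhibition reshaping scales tau and weight coherently", {
  net <- build_synfire()
  out <- compensate_delay_via_inhibition(net, tau_factor = 3,
                                         w_inh_scale = 0.5)
  i <- which(out$projections$label == "FS->RS")[1]
  s0 <- net$projections$syn[[which(net$projections$label == "FS->RS")[1]]]
  s1 <- out$projections$syn[[i]]
  expect_equal(s1$tau_syn, 3 * s0$tau_syn)
  expect_equal(s1$weight, 0.5 * s0$weight)
  rs <- out$populations[out$populations$name == "RS1", ]
  expect_equal(rs$params[[1]]$tau_i, 3 * net$populations$params[[
    which(net$populations$name == "RS1")]]$tau_i)
  # identity configuration changes nothing
  idn <- compensate_delay_via_inhibition(net, 1, 1)
  expect_equal(idn$projections$syn[[i]], s0)
  # charge bookkeeping: w * tau product
  meta <- out$meta$compensations[[length(out$meta$compensations)]]
  expect_equal(meta$charge_per_event, s0$weight * s0$tau_syn * 1.5)
})

test_that("gain function is zero without drive, monotone with it, and obeys the trial sqrt-law", {
  cfg <- ai_config()
  syn_e <- synapse_params(cfg$g_exc, 0, cfg$py$tau_e)
  # excitation-dominated probe: weak inhibition so the low-rate gain is
  # monotone non-decreasing
  syn_i <- synapse_params(5, -80, cfg$py$tau_i)
  g <- measure_gain_function(cfg$py, syn_e, syn_i, k_exc = 63, k_inh = 16,
                             rate_grid = c(0, 2, 5, 10), trials = 2,
                             duration = 400, t_start = 100, seed = 3)
  expect_equal(g$rate_out[g$rate_in == 0], 0)
  expect_true(all(diff(g$rate_out) >= -1)) # monotone up to estimator noise

  g4 <- measure_gain_function(cfg$py, syn_e, syn_i, k_exc = 63, k_inh = 16,
                              rate_grid = 10, trials = 8,
                              duration = 400, t_start = 100, seed = 3)
  # stderr shrinks like 1/sqrt(trials) within a loose band
  expect_lt(g4$stderr, g$stderr[g$rate_in == 10] * 1.2)
})

test_that("self-consistent rate solves tabulated gain functions", {
  nu <- seq(0, 100, by = 1)
  lin <- tibble::tibble(rate_in = nu, rate_out = 20 + 0.5 * nu)
  expect_equal(self_consistent_rate(lin), 40, tolerance = 1e-6)

  sub <- tibble::tibble(rate_in = nu, rate_out = nu / 2)
  expect_equal(self_consistent_rate(sub, nu_min = 0), 0, tolerance = 1e-6)
  expect_error(self_consistent_rate(sub), "no self-sustained")

  # cubic with an analytically known stable upper fixed point
  gfun <- function(x) x + (x - 0) * (x - 20) * (60 - x) / 500
  cub <- tibble::tibble(rate_in = nu, rate_out = pmax(0, gfun(nu)))
  expect_equal(self_consistent_rate(cub), 60, tolerance = 0.5)
})

test_that("time rescaling halves deterministic spike times at lambda = 2", {
  p <- adex_params(c_m = 0.2, g_l = 10, e_l = -60, v_t = -50, delta_t = 2,
                   v_spike = -35, v_reset = -58, tau_ref = 2, a = 2, b = 30,
                   tau_w = 200)
  syn <- synapse_params(15, e_rev = 0, tau_syn = p$tau_e)
  net <- one_neuron_net(p, sources = 1, syn = syn)
  stim <- tibble::tibble(time = seq(5, 195, by = 5), neuron = 2L)
  r1 <- simulate_network(net, 200, dt = 0.02, stim_spikes = stim)

  lam <- 2
  net2 <- rescale_time(net, lam)
  stim2 <- tibble::tibble(time = stim$time / lam, neuron = 2L)
  r2 <- simulate_network(net2, 100, dt = 0.02 / lam, stim_spikes = stim2)
  expect_gt(nrow(r1$spikes), 3)
  expect_equal(r2$spikes$time, r1$spikes$time / lam, tolerance = 1e-12)
})

test_that("mean-field compensation is the identity for equal gain functions", {
  g <- structure(tibble::tibble(rate_in = c(0, 10, 20, 30),
                                rate_out = c(2, 8, 22, 28)),
                 class = c("gain_function", class(tibble::tibble())))
  net <- instantiate_synapses(build_synfire(n_groups = 2), seed = 1)
  out <- mean_field_compensate(net, g, g)
  expect_equal(out$meta$compensations[[1]]$lambda, 1)
  expect_equal(out$synapses$delay, net$synapses$delay)
  expect_equal(out$populations$params[[1]]$g_l,
               net$populations$params[[1]]$g_l)
})

test_that("iterative compensation solves a one-neuron analytic fixed point", {
  # LIF at constant current I: rate = 1000 / (tau_ref + tau_m log(...)), so
  # the threshold v* giving the target rate is known in closed form
  p <- adex_params(c_m = 0.2, g_l = 10, e_l = -60, v_t = -50, delta_t = 0,
                   v_reset = -60, tau_ref = 5, i_ext = 300)
  tau_m <- p$c_m / p$g_l * 1000
  v_inf <- p$e_l + p$i_ext / p$g_l
  nu_target <- 40
  t_isi <- 1000 / nu_target
  v_star <- v_inf - (v_inf - p$v_reset) * exp(-(t_isi - p$tau_ref) / tau_m)

  net <- one_neuron_net(p)
  out <- iterative_compensate(net, nu_target, alpha = 0.15, n_iter = 12,
                              duration = 4000, dt = 0.01, t_start = 0,
                              seed = 2)
  got_thr <- p$v_t + out$net$vt_offset[1]
  expect_lt(abs(got_thr - v_star), 0.25)
  expect_lt(abs(out$trace$rate[nrow(out$trace)] - nu_target) / nu_target,
            0.05)
  # near the fixed point the rate error shrinks between iterations
  errs <- abs(out$trace$rate - nu_target)
  expect_lt(errs[nrow(out$trace)], errs[1])
})

test_that("tidiers expose fit and trace summaries", {
  set.seed(2)
  n <- 500
  sigma <- stats::runif(n, 0, 4); a <- stats::runif(n, 0, 1.2)
  fit <- fit_separatrix(tibble::tibble(sigma = sigma, a = a,
                                       success = a > 0.4))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, n)

  g <- structure(tibble::tibble(rate_in = c(0, 50), rate_out = c(20, 45)),
                 k_exc = 63, k_inh = 16, p = 0,
                 class = c("gain_function", class(tibble::tibble())))
  expect_equal(glance(g)$fixed_point, 40, tolerance = 1e-6)
})
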