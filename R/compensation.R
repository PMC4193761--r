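# Compensation strategies restoring distorted network functionality.

#' Compensate synapse loss by rescaling surviving weights
#'
#' After deletion with probability `p`, the expected total conductance a
#' neuron receives from a projection is restored by multiplying every
#' surviving weight of that projection by `1/(1-p)`.
#'
#' @param net Distorted, instantiated `network_spec`.
#' @param p_loss Single probability or named per-projection-label map
#'   (matching the probabilities used for the loss); projections missing from
#'   the map are left untouched.
#' @return The network with rescaled weights.
#' @export
compensate_loss_by_weights <- function(net, p_loss) {
  assert_that(!is.null(net$synapses), "network not instantiated")
  p <- loss_p_for(p_loss, net$synapses$projection)
  assert_that(all(p < 1), "p = 1 leaves nothing to scale")
  net$synapses$weight <- net$synapses$weight / (1 - p)
  net$meta$compensations <- c(net$meta$compensations, list(
    list(type = "loss_by_weights", p_loss = p_loss)
  ))
  net
}

#' Replace single background sources by a shared multi-source pool
#'
#' Swaps the per-neuron background of a network for a pool of `pool_size`
#' Poisson sources from which every target neuron draws `k_per_neuron`
#' distinct sources. Each source fires at `total_rate_per_neuron /
#' k_per_neuron` and synapse weights are kept, so the expected background
#' conductance per neuron is unchanged while single-synapse weight noise
#' averages out. Two neurons share on average `k^2 / pool_size` sources.
#'
#' The returned specification is re-instantiated (ids change); the previous
#' instantiation seed is reused when present.
#'
#' @param net A `network_spec` whose background projections carry the given
#'   label.
#' @param pool_size Number of sources in the shared pool.
#' @param k_per_neuron Sources per target neuron (`<= pool_size`).
#' @param total_rate_per_neuron Aggregate background rate per neuron (Hz);
#'   defaults to the rate of the replaced sources.
#' @param label Projection label of the background to replace.
#' @return The modified network.
#' @export
multi_source_background <- function(net, pool_size, k_per_neuron,
                                    total_rate_per_neuron = NULL,
                                    label = "background") {
  assert_that(k_per_neuron <= pool_size, "k_per_neuron exceeds pool_size")
  prj <- net$projections
  old <- prj[prj$label == label, ]
  assert_that(nrow(old) > 0, paste0("no projection labeled '", label, "'"))
  old_sources <- unique(old$source)
  old_rate <- net$populations$rate[match(old_sources, net$populations$name)]
  total_rate_per_neuron <- total_rate_per_neuron %||% old_rate[1]

  pops <- net$populations[!(net$populations$name %in% old_sources), ]
  pops <- pops[, setdiff(names(pops), c("id_start", "id_end"))]
  pool <- tibble::tibble(name = "background_pool", size = as.integer(pool_size),
                         cell_type = "source", params = list(NULL),
                         rate = total_rate_per_neuron / k_per_neuron,
                         x = list(NULL), y = list(NULL))
  pops <- dplyr::bind_rows(pops, pool)

  keep <- prj[prj$label != label, ]
  new_rows <- dplyr::bind_rows(lapply(seq_len(nrow(old)), function(i) {
    tibble::tibble(label = label, source = "background_pool",
                   target = old$target[i],
                   rule = list(rule_fixed_in(k_per_neuron)),
                   syn = old$syn[i], delay = old$delay[i], external = TRUE)
  }))
  new_rows <- new_rows[!duplicated(new_rows$target), ]

  out <- network_spec(pops, dplyr::bind_rows(keep, new_rows),
                      meta = utils::modifyList(net$meta, list(
                        compensations = c(net$meta$compensations, list(
                          list(type = "multi_source_background",
                               pool_size = pool_size, k = k_per_neuron,
                               total_rate = total_rate_per_neuron)
                        ))
                      )))
  seed <- net$meta$instantiation_seed
  if (!is.null(seed)) out <- instantiate_synapses(out, seed)
  out
}

#' Compensate background weight noise via resting potential and weight
#'
#' Under multiplicative weight noise of ratio `r`, the second moment of the
#' background synaptic weight grows by `(1 + r^2)`, inflating the free
#' membrane-potential variance; the mean is (almost) unchanged. In the
#' effective-current / diffusion approximation the stationary free-membrane
#' statistics of a neuron driven by one Poisson background synapse are
#' \deqn{\mu_V = E_L + w \nu \tau_{syn} (E_{rev} - \mu_V^{(0)}) / g_{tot},
#'   \qquad \sigma_V^2 \propto w^2 (1 + r^2).}
#' Restoring both moments therefore requires `w' = w / sqrt(1 + r^2)` and a
#' leak-potential shift that re-absorbs the lost mean drive:
#' `E_L' = E_L + (1 - 1/sqrt(1 + r^2)) * mu_drive / g_L`, with `mu_drive` the
#' mean background current at the operating point.
#'
#' @param neuron [adex_params()] of the compensated cell.
#' @param background List with `rate` (Hz), `weight` (nS), `tau_syn` (ms),
#'   `e_rev` (mV) of the background synapse.
#' @param noise_ratio Weight-noise ratio `r`.
#' @return List (`neuron` with adjusted `e_l`, `weight`) — apply the weight to
#'   the background projection.
#' @export
compensate_noise_via_rest_potential <- function(neuron, background,
                                                noise_ratio) {
  r <- noise_ratio
  if (r == 0) {
    return(list(neuron = neuron, weight = background$weight, factor = 1))
  }
  scale <- 1 / sqrt(1 + r^2)
  w0 <- background$weight
  # operating point of the undistorted cell (effective-current approximation)
  g_bg <- w0 * background$rate / 1000 * background$tau_syn # mean conductance, nS
  mu_v0 <- (neuron$g_l * neuron$e_l + g_bg * background$e_rev) /
    (neuron$g_l + g_bg)
  mu_i <- g_bg * (background$e_rev - mu_v0) # mean background current, pA
  e_l_new <- neuron$e_l + (1 - scale) * mu_i / neuron$g_l
  w_new <- w0 * scale
  assert_that(w_new >= 0, "no solution with non-negative weight")
  e_l_shift <- e_l_new - neuron$e_l
  neuron$e_l <- e_l_new
  list(neuron = neuron, weight = w_new, factor = scale, e_l_shift = e_l_shift)
}

#' Reshape local inhibition to mimic a configurable delay
#'
#' Multiplies the synaptic time constant of the local inhibitory projection
#' by `tau_factor` (default 3) while scaling its weight by `w_inh_scale`,
#' extending the duration of inhibition when its onset cannot be delayed.
#' The inhibitory charge per event (proportional to `w * tau`) is reported in
#' the metadata.
#'
#' @param net Synfire `network_spec` (instantiated or not).
#' @param tau_factor Factor on the inhibitory synaptic time constant.
#' @param w_inh_scale Factor on the local inhibitory weight.
#' @param label Projection label of local inhibition.
#' @return The modified network.
#' @export
compensate_delay_via_inhibition <- function(net, tau_factor = 3,
                                            w_inh_scale = 1,
                                            label = "FS->RS") {
  prj <- net$projections
  rows <- which(prj$label == label)
  assert_that(length(rows) > 0, paste0("no projection labeled '", label, "'"))
  targets <- unique(prj$target[rows])
  charge0 <- NULL
  for (i in rows) {
    s <- prj$syn[[i]]
    charge0 <- charge0 %||% (s$weight * s$tau_syn)
    s$weight <- s$weight * w_inh_scale
    s$tau_syn <- s$tau_syn * tau_factor
    prj$syn[[i]] <- s
  }
  net$projections <- prj
  for (tg in targets) {
    k <- match(tg, net$populations$name)
    p <- net$populations$params[[k]]
    p$tau_i <- p$tau_i * tau_factor
    net$populations$params[[k]] <- p
  }
  if (!is.null(net$synapses)) {
    sel <- net$synapses$projection == label
    net$synapses$weight[sel] <- net$synapses$weight[sel] * w_inh_scale
    net$synapses$tau_syn[sel] <- net$synapses$tau_syn[sel] * tau_factor
  }
  net$meta$compensations <- c(net$meta$compensations, list(
    list(type = "delay_via_inhibition", tau_factor = tau_factor,
         w_inh_scale = w_inh_scale,
         charge_per_event = charge0 * w_inh_scale * tau_factor)
  ))
  net
}

#' Measure a single-neuron gain function
#'
#' Stimulates one neuron with `(1-p) K_E` excitatory and `(1-p) K_I`
#' inhibitory independent Poisson afferents at each grid rate and records its
#' mean output rate; the self-consistent solution of this curve predicts the
#' self-sustained network rate.
#'
#' @param cell [adex_params()] of the probed cell.
#' @param syn_exc,syn_inh [synapse_params()] of the afferent synapses.
#' @param k_exc,k_inh Undistorted afferent counts.
#' @param p Synapse-loss probability thinning the afferents.
#' @param rate_grid Afferent rates (Hz).
#' @param trials Repetitions per grid point.
#' @param duration Per-trial duration (ms).
#' @param t_start Rate-estimation start (ms).
#' @param dt Integration step (ms).
#' @param seed Integer seed.
#' @return Tibble of class `gain_function` (`rate_in`, `rate_out`, `stderr`)
#'   with the context in attributes.
#' @export
measure_gain_function <- function(cell, syn_exc, syn_inh, k_exc, k_inh,
                                  p = 0, rate_grid, trials = 3,
                                  duration = 1000, t_start = 100, dt = 0.05,
                                  seed = 1L) {
  assert_that(length(rate_grid) > 0, "rate grid must be non-empty")
  ke <- round((1 - p) * k_exc)
  ki <- round((1 - p) * k_inh)
  rows <- lapply(seq_along(rate_grid), function(gidx) {
    nu <- rate_grid[gidx]
    rates <- vapply(seq_len(trials), function(tr) {
      s <- derive_seed(seed, gidx, tr)
      net <- gain_probe_network(cell, syn_exc, syn_inh, ke, ki, nu)
      net <- instantiate_synapses(net, seed = s)
      res <- simulate_network(net, duration, dt = dt, seed = s)
      sum(res$spikes$neuron == 1L & res$spikes$time >= t_start) /
        (duration - t_start) * 1000
    }, numeric(1))
    tibble::tibble(rate_in = nu, rate_out = mean(rates),
                   stderr = stats::sd(rates) / sqrt(trials))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, k_exc = k_exc, k_inh = k_inh, p = p, cell = cell,
            class = c("gain_function", class(tibble::tibble())))
}

gain_probe_network <- function(cell, syn_exc, syn_inh, ke, ki, nu) {
  pops <- tibble::tibble(
    name = c("cell", "exc_in", "inh_in"),
    size = c(1L, max(ke, 1L), max(ki, 1L)),
    cell_type = c("probe", "source", "source"),
    params = list(cell, NULL, NULL),
    rate = c(NA_real_, if (ke > 0) nu else 0, if (ki > 0) nu else 0),
    x = list(NULL), y = list(NULL)
  )
  prj <- dplyr::bind_rows(
    tibble::tibble(label = "exc", source = "exc_in", target = "cell",
                   rule = list(rule_all()), syn = list(syn_exc),
                   delay = list(delay_constant(1)), external = TRUE),
    tibble::tibble(label = "inh", source = "inh_in", target = "cell",
                   rule = list(rule_all()), syn = list(syn_inh),
                   delay = list(delay_constant(1)), external = TRUE)
  )
  if (ke == 0) prj <- prj[prj$label != "exc", ]
  if (ki == 0) prj <- prj[prj$label != "inh", ]
  network_spec(pops, prj, meta = list(model = "gain_probe"))
}

#' Stable self-consistent rate of a gain function
#'
#' Finds the fixed point `g(nu) = nu` with `g'(nu) < 1` by monotone
#' interpolation of the tabulated gain function and root bracketing.
#'
#' @param g A `gain_function` tibble (or any tibble with `rate_in`,
#'   `rate_out`).
#' @param nu_min Ignore fixed points below this rate (the extinguished state
#'   at 0 Hz is always a trivial solution); set to 0 to allow it.
#' @return Fixed-point rate (Hz).
#' @export
self_consistent_rate <- function(g, nu_min = 1e-9) {
  f <- stats::approxfun(g$rate_in, g$rate_out, rule = 2)
  h <- function(nu) f(nu) - nu
  grid <- sort(unique(c(g$rate_in, seq(min(g$rate_in), max(g$rate_in),
                                       length.out = 201))))
  grid <- grid[grid >= nu_min]
  vals <- h(grid)
  sgn <- sign(vals)
  flips <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-1] != 0)
  roots <- c(grid[which(vals == 0)],
             vapply(flips, function(i) {
               stats::uniroot(h, c(grid[i], grid[i + 1]))$root
             }, numeric(1)))
  if (length(roots) == 0) {
    stop("no self-sustained solution: gain function does not cross the diagonal")
  }
  eps <- max(diff(range(g$rate_in)) * 1e-3, 1e-6)
  stable <- roots[vapply(roots, function(r) {
    (f(r + eps) - f(max(r - eps, 0))) / (r + eps - max(r - eps, 0)) < 1
  }, logical(1))]
  if (length(stable) == 0) {
    stop("no stable self-consistent solution (gain slope >= 1 at all crossings)")
  }
  max(stable)
}

#' Mean-field compensation by time rescaling
#'
#' Computes the factor `lambda` mapping the distorted network's
#' self-consistent rate onto the reference one and applies the time-rescaling
#' transition of [rescale_time()]: membrane (via `g_l`, `C_m` fixed),
#' synaptic and adaptation time constants, refractory periods and all
#' synaptic delays are scaled so the dynamics run `lambda` times adjusted,
#' with every conductance jump keeping its strength relative to the leak. A
#' system rescaled this way replays the same trajectories with time divided
#' by `lambda`, so its self-sustained rate becomes `lambda` times the
#' distorted one.
#'
#' @param net Distorted, instantiated `network_spec`.
#' @param g_ref,g_dist Gain functions of the reference and distorted
#'   single-neuron configurations.
#' @param lambda Optional explicit factor overriding the gain-function ratio.
#' @return The rescaled network, with `lambda` stored in the metadata.
#' @export
mean_field_compensate <- function(net, g_ref, g_dist, lambda = NULL) {
  if (is.null(lambda)) {
    nu_ref <- self_consistent_rate(g_ref)
    nu_dist <- self_consistent_rate(g_dist)
    lambda <- nu_ref / nu_dist
  }
  net <- rescale_time(net, lambda)
  net$meta$compensations <- c(net$meta$compensations, list(
    list(type = "mean_field", lambda = lambda)
  ))
  net
}

#' Rescale all characteristic times of a network
#'
#' Internal workhorse of [mean_field_compensate()], exported for the
#' time-rescaling identity checks. If `x(t)` solves the network equations,
#' the rescaled network's solution is `x(lambda t)`: every time constant
#' (`tau_w`, `tau_ref`, `tau_e`, `tau_i`, synaptic `tau_syn`, STP constants)
#' and every delay is divided by `lambda`, and every term of the membrane
#' equation's right-hand side is multiplied by it (`g_l`, `a`, `b`, `i_ext`,
#' and — because a Dirac spike train compressed in time carries a `1/lambda`
#' density factor — the synaptic conductance jumps, i.e. the weights). The
#' relative strength of each conductance jump against the leak is thereby
#' unchanged. All firing rates of a self-sustained solution scale by exactly
#' `lambda`.
#'
#' @param net A `network_spec`.
#' @param lambda Time-compression factor (`> 0`).
#' @export
rescale_time <- function(net, lambda) {
  assert_that(lambda > 0, "lambda must be > 0")
  for (k in seq_len(nrow(net$populations))) {
    p <- net$populations$params[[k]]
    if (is.null(p)) next
    p$g_l <- p$g_l * lambda
    p$a <- p$a * lambda
    p$b <- p$b * lambda
    p$i_ext <- p$i_ext * lambda
    p$tau_w <- p$tau_w / lambda
    p$tau_ref <- p$tau_ref / lambda
    p$tau_e <- p$tau_e / lambda
    p$tau_i <- p$tau_i / lambda
    net$populations$params[[k]] <- p
  }
  net$projections$syn <- lapply(net$projections$syn, function(s) {
    s$tau_syn <- s$tau_syn / lambda
    s$weight <- s$weight * lambda
    if (!is.null(s$stp)) {
      s$stp$tau_rec <- s$stp$tau_rec / lambda
      s$stp$tau_facil <- s$stp$tau_facil / lambda
    }
    s
  })
  net$projections$delay <- lapply(net$projections$delay, function(d) {
    if (d$type == "constant") d$d <- d$d / lambda
    if (d$type == "distance") {
      d$velocity <- d$velocity * lambda
      d$min <- d$min / lambda
    }
    d
  })
  if (!is.null(net$synapses)) {
    net$synapses$delay <- net$synapses$delay / lambda
    net$synapses$tau_syn <- net$synapses$tau_syn / lambda
    net$synapses$weight <- net$synapses$weight * lambda
    net$synapses$stp_tau_rec <- net$synapses$stp_tau_rec / lambda
    net$synapses$stp_tau_facil <- net$synapses$stp_tau_facil / lambda
  }
  net
}

#' Iterative per-neuron threshold calibration
#'
#' Repeatedly simulates the (frozen-pattern) distorted network and nudges
#' each neuron's spike-initiation threshold in proportion to the difference
#' between its measured rate and the population target:
#' `V_T,i += alpha * (nu_i - nu_target)`. Requires that re-instantiation is
#' deterministic so every iteration sees the identical substrate.
#'
#' @param net_distorted Instantiated, frozen-distortion `network_spec`.
#' @param nu_target Target rate (Hz): a scalar applied to every calibrated
#'   neuron, or a vector with one target per entry of `neurons` (e.g. the
#'   reference rate of each neuron's population).
#' @param alpha Threshold step (mV per Hz).
#' @param alpha_decay Multiplicative decay of the step per iteration
#'   (`alpha_t = alpha * alpha_decay^(t-1)`); a decaying schedule averages
#'   out rate-estimation noise near the fixed point.
#' @param n_iter Number of iterations.
#' @param simulate_fn Function `(net, seed)` returning a `sim_result`;
#'   defaults to a plain [simulate_network()] call with the given duration.
#' @param neurons Ids whose thresholds are calibrated (and whose rates are
#'   measured); defaults to all network neurons.
#' @param duration,dt,t_start Simulation and rate-estimation settings used by
#'   the default backend.
#' @param deadband Rate deviations below this (Hz) leave the threshold
#'   untouched.
#' @param seed Integer seed (per-iteration seeds are derived from it).
#' @param resimulate_each_iter `TRUE` redraws background noise per iteration.
#' @return List of class `iterative_compensation`: `net` (calibrated),
#'   `trace` (tibble `iteration`, `rate`, `cv_rates`, `max_abs_dvt`),
#'   `converged`.
#' @export
iterative_compensate <- function(net_distorted, nu_target, alpha = 0.1,
                                 alpha_decay = 1,
                                 n_iter = 10, simulate_fn = NULL,
                                 neurons = NULL, duration = 2000, dt = 0.05,
                                 t_start = 500, deadband = 0,
                                 seed = 1L, resimulate_each_iter = TRUE) {
  net <- net_distorted
  neurons <- neurons %||% seq_len(n_neurons(net))
  nu_target <- rep_len(nu_target, length(neurons))
  nu_bar <- mean(nu_target)
  simulate_fn <- simulate_fn %||% function(net, s) {
    simulate_network(net, duration, dt = dt, seed = s)
  }
  trace <- list()
  err_prev <- Inf
  grow <- 0L
  for (it in seq_len(n_iter)) {
    s <- if (resimulate_each_iter) derive_seed(seed, it) else seed
    res <- simulate_fn(net, s)
    rts <- firing_rates(res$spikes,
                        neurons,
                        duration = res$duration %||% duration,
                        t_start = t_start)$rate
    dnu <- rts - nu_target
    dnu[abs(dnu) < deadband] <- 0
    dvt <- alpha * alpha_decay^(it - 1) * dnu
    net$vt_offset[neurons] <- net$vt_offset[neurons] + dvt
    trace[[it]] <- tibble::tibble(
      iteration = it, rate = mean(rts),
      cv_rates = stats::sd(rts) / max(mean(rts), 1e-12),
      max_abs_dvt = max(abs(dvt))
    )
    err <- abs(mean(rts) - nu_bar)
    # divergence = materially growing error three iterations in a row
    grow <- if (err > err_prev * 1.05) grow + 1L else 0L
    if (grow >= 3L) {
      warning("iterative compensation diverging; aborting after ", it,
              " iterations")
      break
    }
    err_prev <- err
  }
  structure(list(net = net, trace = dplyr::bind_rows(trace),
                 nu_target = nu_bar, alpha = alpha,
                 converged = grow < 3L),
            class = "iterative_compensation")
}

#' @export
print.iterative_compensation <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("<iterative_compensation> %d iterations: rate %.2f Hz (target %.2f), CV %.3f\n",
              nrow(x$trace), last$rate, x$nu_target, last$cv_rates))
  invisible(x)
}
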