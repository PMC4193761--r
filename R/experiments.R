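# Experiment orchestration: build -> distort -> compensate -> simulate ->
# analyze pipelines with per-cell derived seeds and crash isolation.

#' One synfire propagation trial
#'
#' Builds (or reuses) a synfire network, applies loss/compensation, runs the
#' pulse-packet protocol and returns the state-space trajectory plus the
#' propagation verdict at the last group.
#'
#' @param net Optional pre-built, uninstantiated synfire spec.
#' @param a0,sigma0 Stimulus packet parameters.
#' @param loss_p Homogeneous loss probability applied to the internal and
#'   stimulus projections (the Poisson background is exempt).
#' @param compensated Scale surviving lossy weights by `1/(1-p)`.
#' @param seed Integer seed governing instantiation, distortion, stimulus and
#'   background.
#' @param dt Integration step (ms).
#' @param t_stim Packet center (ms).
#' @param threshold Success threshold on the last-group activation.
#' @param params Builder overrides (ignored when `net` is given).
#' @return List (`trajectory`, `a_last`, `success`, `spikes`).
#' @export
synfire_propagation_trial <- function(net = NULL, a0 = 1, sigma0 = 1,
                                      loss_p = 0, compensated = FALSE,
                                      seed = 1L, dt = 0.02, t_stim = 20,
                                      threshold = 0.5, params = list()) {
  net <- net %||% build_synfire(params = params)
  net <- instantiate_synapses(net, seed = derive_seed(seed, 101))
  if (loss_p > 0) {
    # loss hits internal projections and the stimulus projection; the
    # background keeps its external exemption
    labels <- setdiff(unique(net$synapses$projection), "background")
    lp <- stats::setNames(rep(loss_p, length(labels)), labels)
    cfg <- distortion_config(loss_p = as.list(lp), exempt_external = FALSE,
                             seed = derive_seed(seed, 102))
    bg <- net$synapses$projection == "background"
    bg_syn <- net$synapses[bg, ]
    net <- apply_synapse_loss(net, cfg)
    if (compensated) net <- compensate_loss_by_weights(net, as.list(lp))
    stopifnot(nrow(net$synapses[net$synapses$projection == "background", ]) ==
                nrow(bg_syn))
  }
  stim <- synfire_stimulus(net, a = a0, sigma = sigma0, t_center = t_stim,
                           seed = derive_seed(seed, 103))
  n_groups <- net$meta$n_groups
  duration <- t_stim + n_groups * net$meta$config$d_ff + 20
  res <- simulate_network(net, duration, dt = dt,
                          seed = derive_seed(seed, 104), stim_spikes = stim)
  traj <- synfire_trajectory(res$spikes, net, t_stim = t_stim)
  a_last <- traj$a[traj$group == n_groups]
  list(trajectory = traj, a_last = a_last,
       success = classify_propagation(a_last, threshold), spikes = res$spikes)
}

#' Synapse-loss scan of the synfire chain
#'
#' For every loss value, runs `repetitions` independent trials (fresh
#' connectivity, loss draw, stimulus and background per derived seed) and
#' reports the majority-vote propagation verdict. `first_failure` names the
#' smallest scanned loss at which the majority of trials fail.
#'
#' @param loss_grid Loss probabilities to scan.
#' @param compensated Apply the `1/(1-p)` weight compensation.
#' @param repetitions Trials per grid value.
#' @param a0,sigma0 Stimulus parameters (inside the stable basin).
#' @param seed Master seed.
#' @param dt Integration step (ms).
#' @param params Builder overrides.
#' @return Tibble (`loss_p`, `n_success`, `n_trials`, `success_rate`,
#'   `majority_success`) with attribute `first_failure` (NA if none fails).
#' @export
synfire_loss_scan <- function(loss_grid = seq(0, 0.9, by = 0.1),
                              compensated = FALSE, repetitions = 5,
                              a0 = 1, sigma0 = 1, seed = 1L, dt = 0.02,
                              params = list()) {
  net0 <- build_synfire(params = params)
  rows <- lapply(seq_along(loss_grid), function(i) {
    p <- loss_grid[i]
    succ <- vapply(seq_len(repetitions), function(rep) {
      tr <- synfire_propagation_trial(net = net0, a0 = a0, sigma0 = sigma0,
                                      loss_p = p,
                                      compensated = compensated && p > 0,
                                      seed = derive_seed(seed, i, rep),
                                      dt = dt)
      tr$success
    }, logical(1))
    tibble::tibble(loss_p = p, n_success = sum(succ),
                   n_trials = repetitions,
                   success_rate = mean(succ),
                   majority_success = mean(succ) > 0.5)
  })
  out <- dplyr::bind_rows(rows)
  fail <- which(!out$majority_success)
  structure(out, first_failure = if (length(fail)) out$loss_p[min(fail)] else NA_real_,
            compensated = compensated)
}

#' Simulate and score one state of the AI network
#'
#' Builds (or reuses) an AI network at the given synaptic weights, applies an
#' optional distortion, kick-starts it with the initial stimulus and returns
#' the asynchronous-irregular statistics of the pyramidal population.
#'
#' @param g_exc,g_inh Synaptic weights (nS).
#' @param n_neurons Network size.
#' @param duration Simulated time (ms).
#' @param dt Integration step (ms).
#' @param t_start Statistics window start (ms).
#' @param distortion Optional [distortion_config()].
#' @param net Optional pre-built spec overriding the weight arguments.
#' @param seed Integer seed (instantiation, distortion and stimulus seeds are
#'   derived from it).
#' @param params Builder overrides.
#' @return One-row `ai_stats` tibble.
#' @export
ai_state_run <- function(g_exc = NULL, g_inh = NULL, n_neurons = 3920,
                         duration = 4000, dt = 0.05, t_start = 500,
                         distortion = NULL, net = NULL, seed = 1L,
                         params = list()) {
  net <- net %||% build_ai(n_neurons = n_neurons, g_exc = g_exc,
                           g_inh = g_inh, params = params,
                           position_seed = derive_seed(seed, 1))
  net <- instantiate_synapses(net, seed = derive_seed(seed, 2))
  if (!is.null(distortion)) {
    distortion$seed <- derive_seed(seed, 3)
    net <- apply_distortions(net, distortion)
  }
  stim <- ai_stimulus(net, seed = derive_seed(seed, 4))
  res <- simulate_network(net, duration, dt = dt,
                          seed = derive_seed(seed, 5), stim_spikes = stim)
  ai_statistics(res$spikes, pop_ids(net, "PY"), duration = duration,
                t_start = t_start)
}

#' Built-in sweep protocols addressable by name
#'
#' Used by YAML-driven runs (and the command-line wrapper) where a protocol
#' cannot be given as an R function:
#' * `"synfire_propagation"`: pulse-packet stimulus, state-space trajectory
#'   and propagation verdict; honors `cfg$stimulus$a0` / `sigma0`.
#' * `"ai_state"`: initial stimulation then [ai_statistics()]; honors
#'   `cfg$analysis$duration` / `dt` / `t_start`.
#'
#' @param name Protocol name.
#' @return A function `(net, seed, cfg)` usable as `cfg$protocol`.
#' @export
experiment_protocol <- function(name) {
  switch(name,
    synfire_propagation = function(net, seed, cfg) {
      a0 <- cfg$stimulus$a0 %||% 1
      sigma0 <- cfg$stimulus$sigma0 %||% 1
      stim <- synfire_stimulus(net, a = a0, sigma = sigma0,
                               seed = derive_seed(seed, 201))
      duration <- 20 + net$meta$n_groups * net$meta$config$d_ff + 20
      res <- simulate_network(net, duration, dt = cfg$analysis$dt %||% 0.02,
                              seed = derive_seed(seed, 202),
                              stim_spikes = stim)
      traj <- synfire_trajectory(res$spikes, net)
      last <- traj[traj$group == net$meta$n_groups, ]
      dplyr::mutate(last, success = classify_propagation(last$a))
    },
    ai_state = function(net, seed, cfg) {
      duration <- cfg$analysis$duration %||% 4000
      stim <- ai_stimulus(net, seed = derive_seed(seed, 201))
      res <- simulate_network(net, duration,
                              dt = cfg$analysis$dt %||% 0.05,
                              seed = derive_seed(seed, 202),
                              stim_spikes = stim)
      ai_statistics(res$spikes, pop_ids(net, "PY"), duration = duration,
                    t_start = cfg$analysis$t_start %||% 500)
    },
    stop("unknown protocol: ", name)
  )
}

#' Run a configured experiment sweep
#'
#' Generic build/distort/compensate/simulate/analyze pipeline over a
#' parameter grid. Each grid cell and repetition receives a seed derived from
#' the master seed so any cell can be regenerated in isolation; a failing
#' cell is recorded as an error without disturbing its neighbors.
#'
#' @param cfg Nested list with entries:
#'   * `model`: `list(name = "synfire"|"l23"|"ai", args = list(...))`
#'   * `sweep`: named list of value vectors, each name a path into `cfg`
#'     (e.g. `"distortion.noise_ratio"`, `"model.args.g_exc"`)
#'   * `distortion`: arguments for [distortion_config()] (optional)
#'   * `compensation`: `list(loss_by_weights = TRUE)` and friends (optional)
#'   * `protocol`: function `(net, seed, cell_cfg)` returning a one-row
#'     tibble or list of criteria
#'   * `repetitions`: trials per cell (default 1)
#' @param seed Master seed.
#' @return Tibble of class `sweep_result`: one row per cell and repetition
#'   with the sweep coordinates, `seed`, `error` (NA when fine) and a
#'   `report` list column.
#' @export
run_experiment <- function(cfg, seed = 1L) {
  sweep <- cfg$sweep %||% list()
  grid <- if (length(sweep)) {
    do.call(tidyr::expand_grid, sweep)
  } else {
    tibble::tibble(.single = 1)[, 0]
  }
  reps <- cfg$repetitions %||% 1
  cells <- if (nrow(grid)) nrow(grid) else 1L
  rows <- list()
  for (ci in seq_len(cells)) {
    cell_cfg <- cfg
    if (nrow(grid)) {
      for (nm in names(grid)) {
        cell_cfg <- assign_path(cell_cfg, nm, grid[[nm]][ci])
      }
    }
    for (rep in seq_len(reps)) {
      s <- derive_seed(seed, ci, rep)
      report <- tryCatch({
        net <- build_from_cfg(cell_cfg, s)
        proto <- cell_cfg$protocol
        if (is.character(proto)) proto <- experiment_protocol(proto)
        proto(net, s, cell_cfg)
      }, error = function(e) e)
      row <- if (nrow(grid)) grid[ci, ] else tibble::tibble(.rows = 1)
      row$repetition <- rep
      row$seed <- s
      if (inherits(report, "error")) {
        row$error <- conditionMessage(report)
        row$report <- list(NULL)
      } else {
        row$error <- NA_character_
        row$report <- list(report)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, cfg = cfg, seed = seed,
            class = c("sweep_result", class(out)))
}

assign_path <- function(lst, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  set_in <- function(l, ks, v) {
    if (length(ks) == 1) {
      l[[ks]] <- v
    } else {
      l[[ks[1]]] <- set_in(l[[ks[1]]] %||% list(), ks[-1], v)
    }
    l
  }
  set_in(lst, keys, value)
}

build_from_cfg <- function(cfg, seed) {
  m <- cfg$model
  net <- switch(m$name,
    synfire = do.call(build_synfire, m$args %||% list()),
    l23 = do.call(build_l23, m$args %||% list()),
    ai = do.call(build_ai, m$args %||% list()),
    stop("unknown model: ", m$name)
  )
  net <- instantiate_synapses(net, seed = derive_seed(seed, 11))
  if (!is.null(cfg$distortion)) {
    dcfg <- do.call(distortion_config,
                    utils::modifyList(cfg$distortion,
                                      list(seed = derive_seed(seed, 12))))
    net <- apply_distortions(net, dcfg)
    if (isTRUE(cfg$compensation$loss_by_weights)) {
      net <- compensate_loss_by_weights(net, dcfg$loss_p)
    }
  }
  net
}

#' Pattern completion and attentional-blink protocols
#'
#' Completion: stimulates `n_stim` of a pattern's minicolumns through their
#' layer-4 cells and scores whether the pattern activates. Blink: fully
#' stimulates pattern 1, then partially stimulates pattern 2 after a lag
#' `delta_t`, and scores the activation of pattern 2; the 50% iso-contour of
#' the resulting (lag, stimulated-MC) map summarizes how long the first
#' attractor suppresses the second.
#'
#' The simulation backend is pluggable so large protocols can be delegated
#' (or mocked): `simulate_fn(net, stim_spikes, duration, seed, stim_info)`
#' must return spike data. The default backend runs [simulate_network()].
#'
#' @param net An (uninstantiated) layer 2/3 `network_spec`.
#' @param mode `"completion"` or `"blink"`.
#' @param stim_mc_counts Numbers of stimulated minicolumns to scan.
#' @param delta_t_grid Lags between the two stimuli (ms), blink mode only.
#' @param trials Trials per grid point.
#' @param l4_rate,stim_duration Stimulus strength (Hz per layer-4 source) and
#'   duration (ms).
#' @param duration Simulated time per trial (ms).
#' @param dt Integration step (ms).
#' @param simulate_fn Optional backend override.
#' @param detect_args Extra arguments for [detect_attractors()].
#' @param seed Master seed.
#' @return Completion: tibble (`n_stim`, `success_ratio`). Blink: tibble
#'   (`delta_t`, `n_stim`, `success_ratio`) with attribute `iso50` (tibble
#'   `delta_t`, `n_stim_50`).
#' @export
pattern_protocols <- function(net, mode = c("completion", "blink"),
                              stim_mc_counts, delta_t_grid = NULL,
                              trials = 25, l4_rate = 300, stim_duration = 50,
                              duration = 600, dt = 0.05, simulate_fn = NULL,
                              detect_args = list(), seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "blink") {
    assert_that(!is.null(delta_t_grid), "blink mode needs delta_t_grid")
    trials <- if (trials == 25) 14 else trials
  }
  simulate_fn <- simulate_fn %||% function(net, stim_spikes, duration, seed,
                                           stim_info) {
    simulate_network(net, duration, dt = dt, seed = seed,
                     stim_spikes = stim_spikes)$spikes
  }
  pats <- l23_patterns(net)
  n_pat <- max(pats$pattern)

  l4_stim <- function(net, pattern, n_stim, t0, seed) {
    hcs <- sample(unique(pats$hc), n_stim)
    ids <- unlist(lapply(hcs, function(h) {
      pop_ids(net, sprintf("L4_h%d_m%d", h, pattern))
    }))
    if (length(ids) == 0) return(NULL)
    sp <- poisson_sources(length(ids), l4_rate, stim_duration, seed = seed)
    tibble::tibble(time = sp$time + t0, neuron = ids[sp$neuron])
  }
  activates <- function(spikes, pattern, t_from) {
    ep <- do.call(detect_attractors,
                  c(list(spikes = spikes, patterns = pats,
                         duration = duration), detect_args))
    any(ep$pattern == pattern & ep$t_end > t_from)
  }

  run_one <- function(n_stim, delta_t, trial) {
    s <- derive_seed(seed, n_stim * 1000 + (delta_t %||% 0), trial)
    net_i <- net
    t1 <- 100
    stim_info <- list(mode = mode, n_stim = n_stim, delta_t = delta_t,
                      t1 = t1, pattern_full = 1L,
                      pattern_probe = if (mode == "blink") 2L else 1L,
                      n_hc = length(unique(pats$hc)))
    stim <- with_seed(s, {
      if (mode == "completion") {
        l4_stim(net_i, 1L, n_stim, t1, derive_seed(s, 1))
      } else {
        dplyr::bind_rows(
          l4_stim(net_i, 1L, stim_info$n_hc, t1, derive_seed(s, 1)),
          l4_stim(net_i, 2L, n_stim, t1 + delta_t, derive_seed(s, 2))
        )
      }
    })
    spikes <- simulate_fn(net_i, stim, duration, s, stim_info)
    probe_t <- if (mode == "completion") t1 else t1 + (delta_t %||% 0)
    activates(spikes, stim_info$pattern_probe, probe_t)
  }

  if (mode == "completion") {
    out <- dplyr::bind_rows(lapply(stim_mc_counts, function(ns) {
      succ <- vapply(seq_len(trials), function(tr) run_one(ns, NULL, tr),
                     logical(1))
      tibble::tibble(n_stim = ns, success_ratio = mean(succ))
    }))
    return(out)
  }

  grid <- tidyr::expand_grid(delta_t = delta_t_grid, n_stim = stim_mc_counts)
  out <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(gi) {
    succ <- vapply(seq_len(trials), function(tr) {
      run_one(grid$n_stim[gi], grid$delta_t[gi], tr)
    }, logical(1))
    tibble::tibble(delta_t = grid$delta_t[gi], n_stim = grid$n_stim[gi],
                   success_ratio = mean(succ))
  }))
  iso <- dplyr::bind_rows(lapply(split(out, out$delta_t), function(d) {
    d <- d[order(d$n_stim), ]
    cross <- which(d$success_ratio >= 0.5)
    n50 <- if (length(cross) == 0) {
      NA_real_
    } else {
      i <- min(cross)
      if (i == 1) {
        d$n_stim[1]
      } else {
        # linear interpolation between the bracketing stimulated-MC counts
        x0 <- d$n_stim[i - 1]; x1 <- d$n_stim[i]
        y0 <- d$success_ratio[i - 1]; y1 <- d$success_ratio[i]
        x0 + (0.5 - y0) / (y1 - y0) * (x1 - x0)
      }
    }
    tibble::tibble(delta_t = d$delta_t[1], n_stim_50 = n50)
  }))
  structure(out, iso50 = iso)
}
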