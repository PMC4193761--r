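# Orchestration: sweeps, seed provenance, crash isolation, protocols.

test_that("an empty sweep is a single run and reports flow through", {
  calls <- 0
  cfg <- list(
    model = list(name = "synfire", args = list(n_groups = 2)),
    protocol = function(net, seed, cell_cfg) {
      calls <<- calls + 1
      tibble::tibble(n_syn = nrow(net$synapses), seed_used = seed)
    }
  )
  res <- run_experiment(cfg, seed = 5)
  expect_equal(nrow(res), 1L)
  expect_equal(calls, 1)
  expect_true(is.na(res$error))
  expect_equal(res$report[[1]]$n_syn, nrow(res$report[[1]]) * 0 +
                 res$report[[1]]$n_syn) # report survives round trip
})

test_that("sweeps cover the grid, repeat, and regenerate bit-identically", {
  cfg <- list(
    model = list(name = "synfire", args = list(n_groups = 2)),
    distortion = list(loss_p = 0.2, exempt_external = TRUE),
    sweep = list("distortion.noise_ratio" = c(0, 0.3)),
    repetitions = 2,
    protocol = function(net, seed, cell_cfg) {
      tibble::tibble(wsum = sum(net$synapses$weight),
                     noise = cell_cfg$distortion$noise_ratio)
    }
  )
  res <- run_experiment(cfg, seed = 9)
  expect_equal(nrow(res), 4L)
  expect_equal(sort(unique(res$distortion.noise_ratio)), c(0, 0.3))
  # repetitions see different derived seeds, cells are reproducible
  expect_false(any(duplicated(res$seed)))
  res2 <- run_experiment(cfg, seed = 9)
  expect_identical(res$report, res2$report)
  # noise actually flowed into the cell config
  w0 <- vapply(res$report[res$distortion.noise_ratio == 0], `[[`,
               numeric(1), "wsum")
  wn <- vapply(res$report[res$distortion.noise_ratio == 0.3], `[[`,
               numeric(1), "wsum")
  expect_false(isTRUE(all.equal(w0, wn)))
})

test_that("a failing cell is isolated", {
  cfg <- list(
    model = list(name = "synfire", args = list(n_groups = 2)),
    sweep = list("model.args.n_rs" = c(20, -5)),
    protocol = function(net, seed, cell_cfg) tibble::tibble(n = n_neurons(net))
  )
  res <- run_experiment(cfg, seed = 1)
  ok <- res[res$model.args.n_rs == 20, ]
  bad <- res[res$model.args.n_rs == -5, ]
  expect_true(is.na(ok$error))
  expect_false(is.na(bad$error))
  expect_equal(ok$report[[1]]$n, 90L)  # 2 groups * (20 RS + 25 FS)
  expect_null(bad$report[[1]])
})

test_that("experiment configs load and validate from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "model:",
    "  name: synfire",
    "  args:",
    "    n_groups: 3",
    "distortion:",
    "  loss_p: 0.2",
    "repetitions: 2",
    "sweep:",
    "  distortion.noise_ratio: [0.0, 0.2]"
  ), path)
  cfg <- read_experiment_config(path)
  expect_equal(cfg$model$args$n_groups, 3)
  writeLines(c("model:", "  name: nonsense"), path)
  expect_error(read_experiment_config(path), "model name")
})

mock_l23_backend <- function(rule) {
  # returns a raster in which the probed pattern is active iff rule() says
  # so, using the stimulus metadata the protocol hands over
  function(net, stim_spikes, duration, seed, stim_info) {
    pats <- l23_patterns(net)
    if (!rule(stim_info)) {
      return(spike_data(duration = duration))
    }
    pops <- pats$population[pats$pattern == stim_info$pattern_probe]
    t0 <- stim_info$t1 + (stim_info$delta_t %||% 0)
    set.seed(seed %% 1000 + 1)
    rows <- dplyr::bind_rows(lapply(pops, function(nm) {
      ids <- pop_ids(net, nm)
      n_sp <- 40 * length(ids)
      tibble::tibble(time = stats::runif(n_sp, t0 + 10,
                                         min(t0 + 250, duration)),
                     neuron = rep(ids, length.out = n_sp),
                     population = nm)
    }))
    spike_data(rows$time, rows$neuron, rows$population, duration = duration)
  }
}

test_that("pattern completion recovers a scripted activation rule", {
  net <- suppressWarnings(build_l23(4, 3, 5))
  backend <- mock_l23_backend(function(info) info$n_stim >= 3)
  out <- pattern_protocols(net, "completion", stim_mc_counts = 1:4,
                           trials = 4, simulate_fn = backend, seed = 2)
  expect_equal(out$success_ratio, c(0, 0, 1, 1))
})

test_that("attentional-blink iso-line matches an analytic 50% contour", {
  net <- suppressWarnings(build_l23(4, 3, 5))
  # scripted blink: activation probability 1 iff n_stim > 4 - delta_t/100,
  # deterministic, so the 50% contour is that straight line
  backend <- mock_l23_backend(function(info) {
    if (identical(info$pattern_probe, 2L)) {
      info$n_stim > 4 - info$delta_t / 100
    } else {
      TRUE
    }
  })
  out <- pattern_protocols(net, "blink", stim_mc_counts = 1:4,
                           delta_t_grid = c(100, 200, 300), trials = 3,
                           simulate_fn = backend, seed = 2)
  iso <- attr(out, "iso50")
  # deterministic rule: the 50% contour interpolates midway between the last
  # failing and first succeeding counts
  expect_equal(iso$n_stim_50, c(3.5, 2.5, 1.5))
})

test_that("spike rasters and reports round-trip through their formats", {
  sp <- poisson_sources(5, 50, 200, seed = 1)
  f <- withr::local_tempfile(fileext = ".gdf")
  write_spikes(sp, f)
  back <- read_spikes(f, duration = 200)
  expect_equal(back$time, sp$time, tolerance = 1e-9)
  expect_equal(back$neuron, sp$neuron)

  j <- withr::local_tempfile(fileext = ".json")
  write_spikes_json(sp, j)
  bj <- read_spikes_json(j)
  expect_equal(bj$time, sp$time)
  expect_equal(spike_duration(bj), 200)

  net <- instantiate_synapses(build_synfire(n_groups = 2), seed = 1)
  nj <- withr::local_tempfile(fileext = ".json")
  sc <- withr::local_tempfile(fileext = ".csv")
  write_network_json(net, nj, synapse_csv = sc)
  desc <- jsonlite::read_json(nj)
  expect_equal(length(desc$populations), nrow(net$populations))
  syn <- utils::read.csv(sc)
  expect_equal(nrow(syn), nrow(net$synapses))

  v <- tibble::tibble(time = rep(c(0, 1), 2), neuron = rep(1:2, each = 2),
                      v = c(-70, -69, -70, -68))
  vf <- withr::local_tempfile(fileext = ".csv")
  write_voltages(v, vf)
  expect_equal(names(utils::read.csv(vf)), c("time", "v1", "v2"))
})
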