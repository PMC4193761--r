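# Construction of the three benchmark architectures.

test_that("default layer 2/3 network has the canonical neuron count", {
  net <- build_l23(9, 9, 30)
  expect_equal(n_neurons(net), 2673L) # (30 + 2 + 1) * 9 * 9
  pats <- l23_patterns(net)
  # orthogonal patterns: one MC per HC per pattern, no sharing
  expect_false(any(duplicated(pats$population)))
  expect_equal(as.integer(table(pats$pattern)), rep(9L, 9))
})

test_that("degenerate single-column network has no pattern-rivalry pathways", {
  net <- suppressWarnings(build_l23(1, 1, 10))
  expect_false(any(net$projections$label == "PYR->RSNP"))
  expect_false(any(net$projections$label == "PYR->PYR(global)"))
})

test_that("PYR->RSNP wiring matches a brute-force reading of the rule", {
  # PYR of (hc, mc) project to RSNP of minicolumns outside their pattern
  # (different mc index) and outside their home hypercolumn
  net <- suppressWarnings(build_l23(2, 2, 5))
  got <- net$projections[net$projections$label == "PYR->RSNP",
                         c("source", "target")]
  expected <- list()
  for (h in 1:2) for (m in 1:2) {
    for (h2 in setdiff(1:2, h)) for (m2 in setdiff(1:2, m)) {
      expected[[length(expected) + 1]] <-
        c(sprintf("PYR_h%d_m%d", h, m), sprintf("RSNP_h%d_m%d", h2, m2))
    }
  }
  exp_df <- do.call(rbind, expected)
  expect_setequal(paste(got$source, got$target),
                  paste(exp_df[, 1], exp_df[, 2]))
})

test_that("basket cells listen to the ring-closest minicolumns", {
  net <- build_l23(1, 9, 5)
  src <- net$projections$source[net$projections$label == "PYR->BAS" &
                                  net$projections$target == "BAS_h1_m1"]
  # for 9 MCs the 8 ring-closest other MCs are all others
  expect_setequal(src, sprintf("PYR_h1_m%d", 2:9))
  expect_warning(build_l23(1, 5, 5), "basket")
})

test_that("synfire chain realizes its counts, in-degrees and feed-forward order", {
  net <- build_synfire()
  expect_equal(n_neurons(net), 750L) # 6 * (100 + 25)
  net <- instantiate_synapses(net, seed = 3)
  syn <- net$synapses[!net$synapses$external, ]

  # exact in-degree for every RS neuron of groups 2..6
  ff <- syn[syn$projection == "RS->RS", ]
  expect_true(all(table(ff$target) == 60L))
  fs <- syn[syn$projection == "FS->RS", ]
  expect_true(all(table(fs$target) == 25L))

  # feed-forward DAG apart from the local FS -> RS edges
  group_of <- function(id) (findInterval(id, seq(1, 751, by = 125)))
  internal <- syn[syn$projection %in% c("RS->RS", "RS->FS"), ]
  expect_true(all(group_of(internal$target) == group_of(internal$source) + 1))
  expect_true(all(group_of(fs$target) == group_of(fs$source)))
})

test_that("two-group chain is a single feed-forward stage", {
  net <- build_synfire(n_groups = 2)
  expect_equal(sum(net$projections$label == "RS->RS"), 1L)
})

test_that("torus metric wraps around and matches brute force", {
  net <- build_ai(n_neurons = 200, position_seed = 2,
                  params = list(stim_k = 5L))
  net <- instantiate_synapses(net, seed = 2)
  syn <- net$synapses[net$synapses$projection == "PY->PY", ]
  x <- net$populations$x[[1]]; y <- net$populations$y[[1]]
  L <- attr(x, "torus_side")
  idx <- seq_len(min(100, nrow(syn)))
  brute <- vapply(idx, function(i) {
    s <- syn$source[i]; t <- syn$target[i]
    dx <- min(abs(x[s] - x[t]), L - abs(x[s] - x[t]))
    dy <- min(abs(y[s] - y[t]), L - abs(y[s] - y[t]))
    sqrt(dx^2 + dy^2)
  }, numeric(1))
  expect_equal(syn$distance[idx], brute, tolerance = 1e-12)
  # velocity conversion: delay = distance / v with a floor
  v <- net$meta$config$velocity
  expect_equal(syn$delay[idx], pmax(brute / v, net$meta$config$min_delay),
               tolerance = 1e-12)
})

test_that("identical-position sources connect at the profile ceiling", {
  # Bernoulli Gaussian profile: at distance zero the probability equals p0
  xs <- structure(rep(0.5, 2000), torus_side = 2)
  ys <- structure(rep(0.5, 2000), torus_side = 2)
  src <- tibble::tibble(name = "s", size = 2000L, x = list(xs), y = list(ys))
  tgt <- tibble::tibble(name = "t", size = 2000L, x = list(xs), y = list(ys))
  set.seed(9)
  pair <- spikefidelity:::draw_pairs(rule_gaussian(sigma = 0.1,
                                                   k_expected = 100),
                                     src[1, ], tgt[1, ])
  # all pairs at distance 0: expected in-degree = k_expected = p0 * n
  deg <- length(pair$source) / 2000
  expect_lt(abs(deg - 100), 4 * sqrt(100 * 0.05))
})

test_that("mean conduction delay of the default AI geometry is 1.55 ms", {
  net <- instantiate_synapses(build_ai(), seed = 4)
  d <- net$synapses$delay[!net$synapses$external]
  expect_equal(mean(d), 1.55, tolerance = 0.03)
})

test_that("bernoulli synapse counts stay within binomial bounds and re-instantiation is exact", {
  net <- suppressWarnings(build_l23(2, 2, 20))
  net <- instantiate_synapses(net, seed = 7)
  syn <- net$synapses
  loc <- sum(syn$projection == "PYR->PYR(local)")
  n_pairs <- 4 * 20 * 19 # ordered pairs per MC, 4 MCs
  expnum <- n_pairs * 0.25
  expect_lt(abs(loc - expnum), 4 * sqrt(n_pairs * 0.25 * 0.75))

  net2 <- instantiate_synapses(suppressWarnings(build_l23(2, 2, 20)), seed = 7)
  expect_identical(syn, net2$synapses)
})

test_that("scaling preserves population structure and fan-in", {
  # identity
  net <- scale_model("ai", 3920)
  expect_equal(n_neurons(net), 3920L)

  # AI downscale: fixed in-degrees carry over exactly
  small <- instantiate_synapses(scale_model("ai", 980), seed = 1)
  fi <- mean_fan_in(small)
  expect_equal(fi$fan_in[fi$cell_type == "PY"], 63 + 16, tolerance = 1e-9)

  # synfire scaling keeps in-degrees while populations resize
  big <- instantiate_synapses(scale_model("synfire", 1500), seed = 1)
  expect_equal(n_neurons(big), 1500L)
  ff <- big$synapses[big$synapses$projection == "RS->RS", ]
  expect_true(all(table(ff$target) == 60L))

  # L2/3 PYR downscaling trades population size against weights
  ds <- scale_model("l23", 9 * 9 * 23, rules = list(mode = "pyr_downscale"))
  expect_equal(ds$meta$n_pyr_per_mc, 20)
  w_ref <- l23_config()$w_pyr_local
  i <- which(ds$projections$label == "PYR->PYR(local)")[1]
  expect_equal(ds$projections$syn[[i]]$weight, w_ref * 30 / 20)
})
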