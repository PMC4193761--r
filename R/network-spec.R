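#' Network specification
#'
#' The editable object the whole package revolves around: populations of
#' neurons (or external spike sources), projection rules between them, and —
#' after [instantiate_synapses()] — the expanded synapse table that the
#' distortion and compensation transforms operate on.
#'
#' Populations are laid out in one global id space; all neuron populations
#' come before all source populations. Source populations with a `rate` are
#' realized as independent Poisson trains at simulation time; sources with
#' `rate = NA` are stimulus carriers whose spikes the caller supplies.
#'
#' @param populations Tibble with columns `name`, `size`, `cell_type`,
#'   `params` (list of [adex_params()], `NULL` for sources), `rate`,
#'   `x`, `y` (list columns of positions or `NULL`).
#' @param projections Tibble with columns `label`, `source`, `target`,
#'   `rule`, `syn`, `delay` (list columns), `external` (logical: mediates
#'   external input).
#' @param meta Named list of metadata (model name, scale, seeds).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(populations, projections, meta = list()) {
  pops <- tibble::as_tibble(populations)
  is_src <- pops$cell_type == "source"
  assert_that(all(diff(is_src) >= 0),
              "source populations must come after all neuron populations")
  assert_that(all(pops$size >= 1), "population sizes must be >= 1")
  pops$id_start <- cumsum(c(1L, utils::head(pops$size, -1L)))
  pops$id_end <- pops$id_start + pops$size - 1L
  net <- structure(
    list(populations = pops,
         projections = tibble::as_tibble(projections),
         synapses = NULL,
         vt_offset = rep(0, sum(pops$size[!is_src])),
         meta = meta),
    class = "network_spec"
  )
  validate_network(net)
  net
}

#' @export
print.network_spec <- function(x, ...) {
  n_neu <- n_neurons(x)
  n_src <- sum(x$populations$size) - n_neu
  cat(sprintf("<network_spec: %s> %d neurons, %d sources, %d projections",
              x$meta$model %||% "custom", n_neu, n_src,
              nrow(x$projections)), "\n")
  if (!is.null(x$synapses)) {
    cat(sprintf("  %d instantiated synapses (seed %s)\n", nrow(x$synapses),
                format(x$meta$instantiation_seed %||% NA)))
  } else {
    cat("  synapses not instantiated\n")
  }
  invisible(x)
}

#' Number of network neurons (excluding external sources)
#' @param net A `network_spec`.
#' @export
n_neurons <- function(net) {
  sum(net$populations$size[net$populations$cell_type != "source"])
}

pop_row <- function(net, name) {
  i <- match(name, net$populations$name)
  assert_that(!is.na(i), paste0("unknown population: ", name))
  net$populations[i, ]
}

#' Global neuron ids of a population
#' @param net A `network_spec`.
#' @param name Population name.
#' @export
pop_ids <- function(net, name) {
  r <- pop_row(net, name)
  seq.int(r$id_start, r$id_end)
}

#' Population label for each neuron id
#' @param net A `network_spec`.
#' @param ids Integer ids; defaults to all.
#' @export
population_of <- function(net, ids = NULL) {
  pops <- net$populations
  ids <- ids %||% seq_len(sum(pops$size))
  idx <- findInterval(ids, pops$id_start)
  pops$name[idx]
}

validate_network <- function(net) {
  pops <- net$populations
  prj <- net$projections
  assert_that(!anyDuplicated(pops$name), "duplicate population names")
  for (k in seq_len(nrow(prj))) {
    assert_that(prj$source[k] %in% pops$name && prj$target[k] %in% pops$name,
                sprintf("projection '%s': unresolved population", prj$label[k]))
    tgt <- pop_row(net, prj$target[k])
    assert_that(tgt$cell_type != "source",
                sprintf("projection '%s' targets a source population", prj$label[k]))
    syn <- prj$syn[[k]]
    tp <- tgt$params[[1]]
    tau_ch <- if (receptor_of(syn$e_rev) == "exc") tp$tau_e else tp$tau_i
    assert_that(isTRUE(all.equal(syn$tau_syn, tau_ch)),
                sprintf("projection '%s': tau_syn %g does not match the %s channel (%g) of '%s'",
                        prj$label[k], syn$tau_syn, receptor_of(syn$e_rev),
                        tau_ch, prj$target[k]))
    rule <- prj$rule[[k]]
    if (rule$type == "bernoulli") {
      assert_that(rule$p >= 0 && rule$p <= 1, "connection probability outside [0,1]")
    }
    if (rule$type %in% c("fixed_in", "gaussian_in")) {
      src <- pop_row(net, prj$source[k])
      assert_that(rule$k <= src$size, "fixed in-degree exceeds source size")
    }
  }
  invisible(net)
}

# Projection rule / delay-rule constructors -----------------------------------

#' Connection rules for projections
#'
#' * `rule_bernoulli(p)`: every source/target pair connected independently
#'   with probability `p`.
#' * `rule_fixed_in(k)`: each target draws exactly `k` distinct sources.
#' * `rule_gaussian(sigma, k_expected)`: distance-dependent Bernoulli profile
#'   `p(d) = p0 exp(-d^2/(2 sigma^2))` on the torus, with `p0` normalized per
#'   source network so the expected in-degree is `k_expected`.
#' * `rule_all()`: all-to-all (excluding self-connections).
#' * `rule_one_to_one()`: pairs the i-th source with the i-th target.
#'
#' @param p Connection probability.
#' @param k In-degree.
#' @param sigma Spatial width (mm).
#' @param k_expected Expected in-degree used to normalize the profile.
#' @name connection-rules
NULL

#' @rdname connection-rules
#' @export
rule_bernoulli <- function(p) list(type = "bernoulli", p = p)
#' @rdname connection-rules
#' @export
rule_fixed_in <- function(k) list(type = "fixed_in", k = as.integer(k))
#' @rdname connection-rules
#' @export
rule_gaussian <- function(sigma, k_expected) {
  list(type = "gaussian", sigma = sigma, k_expected = k_expected)
}
#' @rdname connection-rules
#' @export
rule_gaussian_in <- function(k, sigma) {
  list(type = "gaussian_in", k = as.integer(k), sigma = sigma)
}
#' @rdname connection-rules
#' @export
rule_all <- function() list(type = "all")
#' @rdname connection-rules
#' @export
rule_one_to_one <- function() list(type = "one_to_one")

#' Delay rules for projections
#'
#' `delay_constant(d)` assigns `d` ms to every synapse; `delay_distance(v)`
#' derives delays from source-target distance at propagation velocity `v`
#' (mm/ms, equivalently m/s), with a floor of `min` ms.
#'
#' @param d Delay (ms), `> 0`.
#' @param v Propagation velocity (mm/ms).
#' @param min Minimum delay (ms).
#' @name delay-rules
NULL

#' @rdname delay-rules
#' @export
delay_constant <- function(d) {
  assert_that(d > 0, "delay must be > 0")
  list(type = "constant", d = d)
}
#' @rdname delay-rules
#' @export
delay_distance <- function(v, min = 0.1) {
  assert_that(v > 0, "velocity must be > 0")
  list(type = "distance", velocity = v, min = min)
}

# Instantiation ---------------------------------------------------------------

#' Expand projection rules into a concrete synapse list
#'
#' Draws the probabilistic connectivity of every projection with the given
#' seed and stores the result in `net$synapses`. Re-running with the same
#' seed reproduces the identical synapse table — the deterministic mapping
#' that iterative compensation relies on.
#'
#' @param net A `network_spec`.
#' @param seed Integer seed.
#' @return The network with an instantiated synapse table.
#' @export
instantiate_synapses <- function(net, seed = 1L) {
  pops <- net$populations
  with_seed(seed, {
    parts <- lapply(seq_len(nrow(net$projections)), function(k) {
      prj <- net$projections[k, ]
      src <- pop_row(net, prj$source)
      tgt <- pop_row(net, prj$target)
      rule <- prj$rule[[1]]
      pair <- draw_pairs(rule, src, tgt)
      if (length(pair$source) == 0) return(NULL)
      syn <- prj$syn[[1]]
      drule <- prj$delay[[1]]
      delay <- if (drule$type == "constant") {
        rep(drule$d, length(pair$source))
      } else {
        dist <- pair$distance %||% pair_distance(src, tgt, pair)
        pmax(dist / drule$velocity, drule$min)
      }
      stp <- syn$stp
      tibble::tibble(
        source = src$id_start - 1L + pair$source,
        target = tgt$id_start - 1L + pair$target,
        weight = syn$weight,
        delay = delay,
        e_rev = syn$e_rev,
        tau_syn = syn$tau_syn,
        receptor = receptor_of(syn$e_rev),
        projection = prj$label,
        external = prj$external,
        stp_mode = if (is.null(stp)) 0L else if (stp$mode == "depression") 1L else 2L,
        stp_u = if (is.null(stp)) 0 else stp$u,
        stp_tau_rec = if (is.null(stp)) 1 else stp$tau_rec,
        stp_tau_facil = if (is.null(stp)) 1 else stp$tau_facil,
        distance = pair$distance %||% NA_real_
      )
    })
    net$synapses <- dplyr::bind_rows(c(list(empty_synapse_table()), parts))
  })
  net$meta$instantiation_seed <- seed
  net
}

empty_synapse_table <- function() {
  tibble::tibble(
    source = integer(), target = integer(), weight = double(),
    delay = double(), e_rev = double(), tau_syn = double(),
    receptor = character(), projection = character(), external = logical(),
    stp_mode = integer(), stp_u = double(), stp_tau_rec = double(),
    stp_tau_facil = double(), distance = double()
  )
}

# Draw (source, target) index pairs (1-based within each population).
draw_pairs <- function(rule, src, tgt) {
  self_ok <- !identical(src$name, tgt$name)
  switch(rule$type,
    bernoulli = {
      n_pairs <- src$size * tgt$size
      hit <- which(stats::runif(n_pairs) < rule$p)
      s <- ((hit - 1L) %% src$size) + 1L
      t <- ((hit - 1L) %/% src$size) + 1L
      if (!self_ok) {
        keep <- s != t
        s <- s[keep]; t <- t[keep]
      }
      list(source = s, target = t)
    },
    fixed_in = {
      s <- unlist(lapply(seq_len(tgt$size), function(j) {
        pool <- if (self_ok) seq_len(src$size) else setdiff(seq_len(src$size), j)
        sample(pool, rule$k)
      }))
      list(source = s, target = rep(seq_len(tgt$size), each = rule$k))
    },
    gaussian = {
      xs <- src$x[[1]]; ys <- src$y[[1]]
      xt <- tgt$x[[1]]; yt <- tgt$y[[1]]
      assert_that(!is.null(xs) && !is.null(xt),
                  "gaussian rule requires population positions")
      L <- attr(xs, "torus_side") %||% stop("positions carry no torus_side")
      mass <- mean(.torus_kernel_mass_cpp(xs, ys, xt, yt, L, rule$sigma, self_ok))
      p0 <- rule$k_expected / mass
      if (p0 > 1) {
        warning("gaussian profile saturated (p0 > 1); expected in-degree not reachable")
      }
      .torus_connect_cpp(xs, ys, xt, yt, L, rule$sigma, p0, self_ok)
    },
    all = {
      g <- expand.grid(source = seq_len(src$size), target = seq_len(tgt$size))
      if (!self_ok) g <- g[g$source != g$target, ]
      list(source = g$source, target = g$target)
    },
    one_to_one = {
      n <- min(src$size, tgt$size)
      list(source = seq_len(n), target = seq_len(n))
    },
    one_to_one_offset = {
      # pairs target i with source (offset + i); used for population blocks
      # that share one large source pool (e.g. per-neuron background)
      n <- tgt$size
      assert_that(rule$offset + n <= src$size, "one_to_one_offset exhausts pool")
      list(source = rule$offset + seq_len(n), target = seq_len(n))
    },
    gaussian_in = {
      # exact in-degree k, sources drawn without replacement with Gaussian
      # distance weights: keeps afferent counts identical across neurons
      # while the connectivity stays spatially local
      xs <- src$x[[1]]; ys <- src$y[[1]]
      xt <- tgt$x[[1]]; yt <- tgt$y[[1]]
      assert_that(!is.null(xs) && !is.null(xt),
                  "gaussian_in rule requires population positions")
      L <- attr(xs, "torus_side") %||% stop("positions carry no torus_side")
      half <- L / 2
      s_list <- vector("list", tgt$size)
      d_list <- vector("list", tgt$size)
      for (j in seq_len(tgt$size)) {
        dx <- abs(xs - xt[j]); dx <- pmin(dx, L - dx)
        dy <- abs(ys - yt[j]); dy <- pmin(dy, L - dy)
        d2 <- dx^2 + dy^2
        w <- exp(-d2 / (2 * rule$sigma^2))
        if (!self_ok) w[j] <- 0
        pick <- sample.int(src$size, rule$k, prob = w)
        s_list[[j]] <- pick
        d_list[[j]] <- sqrt(d2[pick])
      }
      list(source = unlist(s_list),
           target = rep(seq_len(tgt$size), each = rule$k),
           distance = unlist(d_list))
    },
    stop("unknown connection rule: ", rule$type)
  )
}

pair_distance <- function(src, tgt, pair) {
  xs <- src$x[[1]]; ys <- src$y[[1]]
  xt <- tgt$x[[1]]; yt <- tgt$y[[1]]
  if (is.null(xs) || is.null(xt)) {
    stop("distance-dependent delays require population positions")
  }
  L <- attr(xs, "torus_side")
  dx <- abs(xs[pair$source] - xt[pair$target])
  dy <- abs(ys[pair$source] - yt[pair$target])
  if (!is.null(L)) {
    dx <- pmin(dx, L - dx)
    dy <- pmin(dy, L - dy)
  }
  sqrt(dx^2 + dy^2)
}
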