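# Benchmark network builders.
#
# Parameter values that the benchmark descriptions leave to supplementary
# material are exposed here as config entries with documented defaults taken
# from the standard modeling literature for each architecture; they are
# placeholders, not authoritative values (see the methods vignette).

#' Default configuration for the synfire chain with feed-forward inhibition
#'
#' LIF neurons (exponential term disconnected), fixed in-degree feed-forward
#' connectivity, all-to-all local inhibition, and an independent 2 kHz / 1 nS
#' Poisson background source per neuron.
#'
#' @return Named list of defaults, overridable via the `params` argument of
#'   [build_synfire()].
#' @export
synfire_config <- function() {
  list(
    neuron = adex_params(c_m = 0.25, g_l = 25, e_l = -70, v_t = -57,
                         delta_t = 0, a = 0, b = 0, tau_w = 100,
                         v_reset = -70, tau_ref = 2,
                         tau_e = 1.5, tau_i = 5, e_e = 0, e_i = -80),
    k_ff = 60L,            # feed-forward in-degree (RS -> RS, RS -> FS)
    k_inh = 25L,           # local FS -> RS in-degree
    w_ff_rs = 0.7,         # nS, RS -> next RS
    w_ff_fs = 0.7,         # nS, RS -> next FS
    w_inh = 7,             # nS, local FS -> RS
    d_ff = 20,             # ms, intergroup delay (visualization convention)
    d_inh = 4,             # ms, local inhibition delay (adjustable)
    bg_rate = 2000,        # Hz per neuron
    bg_weight = 1          # nS
  )
}

#' Build the synfire chain with feed-forward inhibition
#'
#' A chain of `n_groups` groups, each with `n_rs` regular-spiking excitatory
#' and `n_fs` fast-spiking inhibitory LIF neurons. Each excitatory population
#' projects to both populations of the next group; each inhibitory population
#' projects back onto the excitatory population of its own group with delay
#' `d_inh`. A stimulus source population of `n_rs` cells is wired to group 1
#' exactly like an upstream excitatory group, and every network neuron has an
#' independent Poisson background source.
#'
#' @param n_groups Number of groups (`>= 2`), default 6.
#' @param n_rs,n_fs Neurons per excitatory / inhibitory population.
#' @param d_inh Local inhibition delay (ms).
#' @param params Overrides for [synfire_config()] entries.
#' @return An (uninstantiated) `network_spec`.
#' @export
build_synfire <- function(n_groups = 6, n_rs = 100, n_fs = 25,
                          d_inh = NULL, params = list()) {
  assert_that(n_groups >= 2, "n_groups must be >= 2")
  cfg <- utils::modifyList(synfire_config(), params)
  if (!is.null(d_inh)) cfg$d_inh <- d_inh
  nrn <- cfg$neuron
  k_ff <- min(cfg$k_ff, n_rs)
  k_inh <- min(cfg$k_inh, n_fs)

  rs_names <- paste0("RS", seq_len(n_groups))
  fs_names <- paste0("FS", seq_len(n_groups))
  pops <- tibble::tibble(
    name = c(rbind(rs_names, fs_names), "stimulus", "background"),
    size = c(rbind(rep(n_rs, n_groups), rep(n_fs, n_groups)),
             n_rs, n_groups * (n_rs + n_fs)),
    cell_type = c(rbind(rep("RS", n_groups), rep("FS", n_groups)),
                  "source", "source"),
    params = c(rep(list(nrn), 2 * n_groups), list(NULL), list(NULL)),
    rate = c(rep(NA_real_, 2 * n_groups), NA_real_, cfg$bg_rate),
    x = list(NULL), y = list(NULL)
  )

  syn_e <- synapse_params(cfg$w_ff_rs, e_rev = 0, tau_syn = nrn$tau_e)
  syn_e_fs <- synapse_params(cfg$w_ff_fs, e_rev = 0, tau_syn = nrn$tau_e)
  syn_i <- synapse_params(cfg$w_inh, e_rev = nrn$e_i, tau_syn = nrn$tau_i)
  syn_bg <- synapse_params(cfg$bg_weight, e_rev = 0, tau_syn = nrn$tau_e)

  prj <- list()
  add <- function(label, source, target, rule, syn, delay, external = FALSE) {
    tibble::tibble(label = label, source = source, target = target,
                   rule = list(rule), syn = list(syn), delay = list(delay),
                   external = external)
  }
  for (g in seq_len(n_groups - 1)) {
    prj <- c(prj, list(
      add("RS->RS", rs_names[g], rs_names[g + 1], rule_fixed_in(k_ff),
          syn_e, delay_constant(cfg$d_ff)),
      add("RS->FS", rs_names[g], fs_names[g + 1], rule_fixed_in(k_ff),
          syn_e_fs, delay_constant(cfg$d_ff))
    ))
  }
  for (g in seq_len(n_groups)) {
    prj <- c(prj, list(
      add("FS->RS", fs_names[g], rs_names[g], rule_fixed_in(k_inh),
          syn_i, delay_constant(cfg$d_inh))
    ))
  }
  prj <- c(prj, list(
    add("stimulus->RS", "stimulus", rs_names[1], rule_fixed_in(k_ff),
        syn_e, delay_constant(cfg$d_ff), external = TRUE),
    add("stimulus->FS", "stimulus", fs_names[1], rule_fixed_in(k_ff),
        syn_e_fs, delay_constant(cfg$d_ff), external = TRUE),
    add("background", "background", "__all__", rule_one_to_one(),
        syn_bg, delay_constant(1), external = TRUE)
  ))
  prj <- dplyr::bind_rows(prj)

  # expand the background one-to-one block onto each network population
  bg_row <- prj[prj$target == "__all__", ]
  prj <- prj[prj$target != "__all__", ]
  offset <- 0L
  for (nm in c(rbind(rs_names, fs_names))) {
    sz <- pops$size[pops$name == nm]
    prj <- dplyr::bind_rows(prj, tibble::tibble(
      label = "background", source = "background", target = nm,
      rule = list(list(type = "one_to_one_offset", offset = offset)),
      syn = list(syn_bg), delay = list(delay_constant(1)), external = TRUE
    ))
    offset <- offset + sz
  }

  network_spec(pops, prj,
               meta = list(model = "synfire", n_groups = n_groups,
                           n_rs = n_rs, n_fs = n_fs, config = cfg))
}

#' Pulse-packet stimulus spikes for a synfire network
#'
#' Realizes a pulse packet on the stimulus population of a [build_synfire()]
#' network, returning spike rows with global source ids ready for
#' [simulate_network()]'s `stim_spikes`.
#'
#' @param net Synfire `network_spec`.
#' @param a Spikes per stimulus source.
#' @param sigma Temporal spread (ms).
#' @param t_center Packet center (ms).
#' @param seed Integer seed.
#' @export
synfire_stimulus <- function(net, a, sigma, t_center = 20, seed = 1L) {
  ids <- pop_ids(net, "stimulus")
  pp <- pulse_packet(length(ids), a, sigma, t_center)
  sp <- pulse_packet_spikes(pp, seed = seed,
                            duration = t_center + 10 * max(sigma, 1))
  tibble::tibble(time = sp$time, neuron = ids[sp$neuron])
}

# -- Layer 2/3 attractor memory ----------------------------------------------

#' Default configuration for the layer 2/3 attractor memory
#'
#' Neuron parameters are LIF-reduced AdEx fits (exponential term
#' disconnected); connection probabilities and weights are literature-style
#' placeholders for values that live outside the main model description.
#'
#' @return Named list of defaults for [build_l23()].
#' @export
l23_config <- function() {
  list(
    pyr = adex_params(c_m = 0.28, g_l = 14, e_l = -70, v_t = -55, delta_t = 0,
                      a = 2, b = 60, tau_w = 300, v_reset = -70, tau_ref = 3,
                      tau_e = 6, tau_i = 6, e_e = 0, e_i = -80),
    rsnp = adex_params(c_m = 0.1, g_l = 10, e_l = -70, v_t = -55, delta_t = 0,
                       a = 1, b = 20, tau_w = 200, v_reset = -70, tau_ref = 2,
                       tau_e = 6, tau_i = 6, e_e = 0, e_i = -80),
    bas = adex_params(c_m = 0.1, g_l = 10, e_l = -70, v_t = -55, delta_t = 0,
                      a = 0, b = 0, tau_w = 100, v_reset = -70, tau_ref = 1,
                      tau_e = 6, tau_i = 6, e_e = 0, e_i = -80),
    p_pyr_local = 0.25,     # PYR-PYR within an MC (stated by the model)
    p_pyr_global = 0.25,    # PYR-PYR between same-pattern MCs
    p_pyr_rsnp = 0.3,
    p_pyr_bas = 0.7,
    p_bas_pyr = 0.7,
    p_rsnp_pyr = 0.7,
    p_l4_pyr = 0.75,
    w_pyr_local = 3, w_pyr_global = 1.5, w_pyr_rsnp = 1.5, w_pyr_bas = 3,
    w_bas_pyr = 15, w_rsnp_pyr = 8, w_l4_pyr = 4,            # nS
    stp_pyr = stp_params(u = 0.25, tau_rec = 575, mode = "depression"),
    n_l4_per_mc = 5L,
    bg_rate = 500, bg_weight = 1.5,   # one diffuse source per PYR
    velocity = 0.2,                   # mm/ms axonal propagation
    hc_spacing = 0.7,                 # mm between neighboring hypercolumns
    min_delay = 0.5                   # ms (intra-HC delay)
  )
}

hex_grid <- function(n, spacing) {
  ncol <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  row <- idx %/% ncol
  col <- idx %% ncol
  tibble::tibble(x = (col + 0.5 * (row %% 2)) * spacing,
                 y = row * (sqrt(3) / 2) * spacing)
}

#' Build the layer 2/3 attractor memory network
#'
#' `n_hc` hypercolumns on a hexagonal grid, each holding `n_mc_per_hc`
#' minicolumns of `n_pyr_per_mc` pyramidal (PYR), 2 regular-spiking
#' non-pyramidal (RSNP) and 1 basket (BAS) cell. The minicolumns with the same
#' index across hypercolumns form one orthogonal pattern (attractor):
#' * PYR-PYR at 25% connectivity within an MC, plus long-range PYR-PYR
#'   between MCs of the same pattern;
#' * BAS receive from the PYR of the 8 ring-closest other MCs in their home
#'   HC and inhibit all PYR of that HC (soft winner-take-all);
#' * PYR project to the RSNP of MCs outside their pattern and outside their
#'   HC; RSNP inhibit the PYR of their own MC (disynaptic pattern rivalry);
#' * 5 layer-4 source cells per MC drive its PYR; one diffuse Poisson
#'   background source per PYR.
#'
#' Axonal delays are distances between home-HC centroids divided by the
#' propagation velocity, with the intra-HC delay at the configured minimum.
#'
#' @param n_hc Number of hypercolumns.
#' @param n_mc_per_hc Minicolumns (= patterns) per hypercolumn.
#' @param n_pyr_per_mc PYR cells per minicolumn.
#' @param params Overrides for [l23_config()].
#' @param pyr_weight_scale Factor applied to the weights of all PYR-sourced
#'   projections; used by the population-downscaling compensation to preserve
#'   fan-in drive with fewer PYR cells.
#' @return An (uninstantiated) `network_spec`.
#' @export
build_l23 <- function(n_hc = 9, n_mc_per_hc = 9, n_pyr_per_mc = 30,
                      params = list(), pyr_weight_scale = 1) {
  assert_that(n_hc >= 1 && n_mc_per_hc >= 1 && n_pyr_per_mc >= 1,
              "counts must be >= 1")
  cfg <- utils::modifyList(l23_config(), params)
  if (n_mc_per_hc < 9) {
    warning("fewer than 9 MCs per HC: basket input reduced to all other MCs")
  }
  grid <- hex_grid(n_hc, cfg$hc_spacing)

  mc <- expand.grid(mc = seq_len(n_mc_per_hc), hc = seq_len(n_hc))
  pname <- function(type, hc, m) sprintf("%s_h%d_m%d", type, hc, m)
  mk_pops <- function(type, n_cells, par, rate = NA_real_,
                      cell_type = type) {
    xs <- lapply(mc$hc, function(h) rep(grid$x[h], n_cells))
    ys <- lapply(mc$hc, function(h) rep(grid$y[h], n_cells))
    tibble::tibble(
      name = pname(type, mc$hc, mc$mc),
      size = as.integer(n_cells), cell_type = cell_type,
      params = rep(list(par), nrow(mc)),
      rate = rate,
      x = xs, y = ys
    )
  }
  pops <- dplyr::bind_rows(
    mk_pops("PYR", n_pyr_per_mc, cfg$pyr),
    mk_pops("RSNP", 2L, cfg$rsnp),
    mk_pops("BAS", 1L, cfg$bas),
    mk_pops("L4", cfg$n_l4_per_mc, NULL, cell_type = "source"),
    mk_pops("noise", n_pyr_per_mc, NULL, rate = cfg$bg_rate,
            cell_type = "source")
  )

  ws <- pyr_weight_scale
  dly <- delay_distance(cfg$velocity, min = cfg$min_delay)
  dly0 <- delay_constant(cfg$min_delay)
  syn <- list(
    pyr_local = synapse_params(cfg$w_pyr_local * ws, 0, cfg$pyr$tau_e,
                               stp = cfg$stp_pyr),
    pyr_global = synapse_params(cfg$w_pyr_global * ws, 0, cfg$pyr$tau_e,
                                stp = cfg$stp_pyr),
    pyr_rsnp = synapse_params(cfg$w_pyr_rsnp * ws, 0, cfg$rsnp$tau_e,
                              stp = cfg$stp_pyr),
    pyr_bas = synapse_params(cfg$w_pyr_bas * ws, 0, cfg$bas$tau_e),
    bas_pyr = synapse_params(cfg$w_bas_pyr, cfg$pyr$e_i, cfg$pyr$tau_i),
    rsnp_pyr = synapse_params(cfg$w_rsnp_pyr, cfg$pyr$e_i, cfg$pyr$tau_i),
    l4_pyr = synapse_params(cfg$w_l4_pyr, 0, cfg$pyr$tau_e),
    bg = synapse_params(cfg$bg_weight, 0, cfg$pyr$tau_e)
  )

  # vectorized projection assembly: build all (source, target, ...) rows
  lab <- chr_s <- chr_t <- character()
  rules <- syns <- dlys <- list()
  ext <- logical()
  push <- function(label, s, t, rule, sy, dl, external = FALSE) {
    n <- length(s)
    lab <<- c(lab, rep(label, n)); chr_s <<- c(chr_s, s); chr_t <<- c(chr_t, t)
    rules <<- c(rules, rep(list(rule), n)); syns <<- c(syns, rep(list(sy), n))
    dlys <<- c(dlys, rep(list(dl), n)); ext <<- c(ext, rep(external, n))
  }

  for (h in seq_len(n_hc)) {
    for (m in seq_len(n_mc_per_hc)) {
      me_pyr <- pname("PYR", h, m)
      # recurrent PYR within the MC
      push("PYR->PYR(local)", me_pyr, me_pyr,
           rule_bernoulli(cfg$p_pyr_local), syn$pyr_local, dly0)
      # long-range PYR-PYR inside the pattern (same MC index, other HCs)
      oth <- setdiff(seq_len(n_hc), h)
      if (length(oth)) {
        push("PYR->PYR(global)", rep(me_pyr, length(oth)),
             pname("PYR", oth, m),
             rule_bernoulli(cfg$p_pyr_global), syn$pyr_global, dly)
      }
      # PYR -> RSNP of foreign patterns in foreign HCs
      if (length(oth) && n_mc_per_hc > 1) {
        tg <- expand.grid(hc = oth, mc = setdiff(seq_len(n_mc_per_hc), m))
        push("PYR->RSNP", rep(me_pyr, nrow(tg)),
             pname("RSNP", tg$hc, tg$mc),
             rule_bernoulli(cfg$p_pyr_rsnp), syn$pyr_rsnp, dly)
      }
      # RSNP inhibit their own MC's PYR
      push("RSNP->PYR", pname("RSNP", h, m), me_pyr,
           rule_bernoulli(cfg$p_rsnp_pyr), syn$rsnp_pyr, dly0)
      # BAS of this MC: driven by the 8 ring-closest other MCs
      if (n_mc_per_hc > 1) {
        ring <- setdiff(seq_len(n_mc_per_hc), m)
        rd <- pmin(abs(ring - m), n_mc_per_hc - abs(ring - m))
        near <- ring[order(rd, ring)][seq_len(min(8L, length(ring)))]
        push("PYR->BAS", pname("PYR", h, near), rep(pname("BAS", h, m),
             length(near)),
             rule_bernoulli(cfg$p_pyr_bas), syn$pyr_bas, dly0)
      }
      # BAS project to all PYR in the home HC
      push("BAS->PYR", rep(pname("BAS", h, m), n_mc_per_hc),
           pname("PYR", h, seq_len(n_mc_per_hc)),
           rule_bernoulli(cfg$p_bas_pyr), syn$bas_pyr, dly0)
      # layer 4 drive and diffuse background
      push("L4->PYR", pname("L4", h, m), me_pyr,
           rule_bernoulli(cfg$p_l4_pyr), syn$l4_pyr, dly0, external = TRUE)
      push("background", pname("noise", h, m), me_pyr,
           rule_one_to_one(), syn$bg, dly0, external = TRUE)
    }
  }
  prj <- tibble::tibble(label = lab, source = chr_s, target = chr_t,
                        rule = rules, syn = syns, delay = dlys,
                        external = ext)
  network_spec(pops, prj,
               meta = list(model = "l23", n_hc = n_hc,
                           n_mc_per_hc = n_mc_per_hc,
                           n_pyr_per_mc = n_pyr_per_mc, config = cfg,
                           pyr_weight_scale = pyr_weight_scale))
}

#' Pattern membership of a layer 2/3 network
#'
#' @param net A [build_l23()] network.
#' @return Tibble (`pattern`, `hc`, `mc`, `population`): the PYR population of
#'   each minicolumn, grouped by the orthogonal pattern it belongs to.
#' @export
l23_patterns <- function(net) {
  m <- net$meta
  g <- expand.grid(hc = seq_len(m$n_hc), mc = seq_len(m$n_mc_per_hc))
  tibble::tibble(pattern = g$mc, hc = g$hc, mc = g$mc,
                 population = sprintf("PYR_h%d_m%d", g$hc, g$mc))
}

# -- Self-sustained asynchronous-irregular network ---------------------------

#' Default configuration for the asynchronous-irregular torus network
#'
#' AdEx pyramidal (PY) and fast-spiking (INH) cells on a two-dimensional
#' torus with fixed in-degree, Gaussian distance-weighted connectivity and
#' distance-derived conduction delays. The spatial width and velocity defaults
#' put the mean conduction delay at 1.55 ms.
#'
#' @return Named list of defaults for [build_ai()].
#' @export
ai_config <- function() {
  list(
    py = adex_params(c_m = 0.2, g_l = 10, e_l = -60, v_t = -50, delta_t = 2.5,
                     a = 1, b = 20, tau_w = 600, v_reset = -60, v_spike = -40,
                     tau_ref = 2.5, tau_e = 5, tau_i = 10, e_e = 0, e_i = -80),
    inh = adex_params(c_m = 0.2, g_l = 10, e_l = -60, v_t = -50, delta_t = 2.5,
                      a = 1, b = 0, tau_w = 600, v_reset = -60, v_spike = -40,
                      tau_ref = 2.5, tau_e = 5, tau_i = 10, e_e = 0, e_i = -80),
    exc_fraction = 0.8,    # 4:1 excitatory to inhibitory
    k_exc = 63L,           # excitatory in-degree (per target, any type)
    k_inh = 16L,           # inhibitory in-degree
    g_exc = 9,             # nS
    g_inh = 90,            # nS
    torus_side = 2,        # mm
    sigma_space = 0.2437,  # mm; calibrated so the realized mean connected
                           # distance over v gives a 1.55 ms mean delay
    velocity = 0.2,        # mm/ms -> mean delay 1.55 ms
    min_delay = 0.1,       # ms
    stim_n = 100L,         # initial stimulation sources
    stim_sigma = 0.2,      # mm, spatial reach of the initial stimulus
    stim_k = 20L,          # expected targets per stimulus source
    stim_weight = 9        # nS
  )
}

#' Build the self-sustained asynchronous-irregular network
#'
#' Excitatory PY and inhibitory INH AdEx neurons are scattered uniformly on a
#' 2D torus. Every neuron draws a fixed number of excitatory and inhibitory
#' afferents, chosen with Gaussian distance weights (so in-degrees are exact
#' while connectivity remains local); conduction delays are torus distance
#' divided by the propagation velocity. A stimulus source population near the
#' torus origin kick-starts activity; there is no ongoing external drive.
#'
#' @param n_neurons Total PY + INH count (default 3920).
#' @param exc_fraction Fraction of excitatory neurons.
#' @param torus_side Torus side length (mm).
#' @param sigma_space Spatial width of the connection profile (mm).
#' @param velocity Conduction velocity (mm/ms); biological estimates span
#'   0.1-0.5 m/s.
#' @param g_exc,g_inh Excitatory / inhibitory synaptic weights (nS).
#' @param params Overrides for [ai_config()].
#' @param position_seed Seed for the neuron placement.
#' @return An (uninstantiated) `network_spec`.
#' @export
build_ai <- function(n_neurons = 3920, exc_fraction = NULL, torus_side = NULL,
                     sigma_space = NULL, velocity = NULL,
                     g_exc = NULL, g_inh = NULL, params = list(),
                     position_seed = 1L) {
  assert_that(n_neurons >= 2, "n_neurons must be >= 2")
  cfg <- utils::modifyList(ai_config(), params)
  for (nm in c("exc_fraction", "torus_side", "sigma_space", "velocity",
               "g_exc", "g_inh")) {
    v <- get(nm)
    if (!is.null(v)) cfg[[nm]] <- v
  }
  assert_that(cfg$torus_side > 0, "torus geometry must be positive")
  if (cfg$sigma_space >= cfg$torus_side / 2) {
    warning("sigma_space >= torus_side/2: connection profile is effectively uniform")
  }
  n_py <- round(n_neurons * cfg$exc_fraction)
  n_inh <- n_neurons - n_py
  assert_that(n_py >= 1 && n_inh >= 1, "both cell types must be non-empty")

  L <- cfg$torus_side
  pos <- with_seed(position_seed, {
    list(px = stats::runif(n_py, 0, L), py = stats::runif(n_py, 0, L),
         ix = stats::runif(n_inh, 0, L), iy = stats::runif(n_inh, 0, L),
         sx = stats::runif(cfg$stim_n, 0, cfg$stim_sigma),
         sy = stats::runif(cfg$stim_n, 0, cfg$stim_sigma))
  })
  torus_pos <- function(v) structure(v, torus_side = L)

  pops <- tibble::tibble(
    name = c("PY", "INH", "STIM"),
    size = c(n_py, n_inh, cfg$stim_n),
    cell_type = c("PY", "INH", "source"),
    params = list(cfg$py, cfg$inh, NULL),
    rate = NA_real_,
    x = list(torus_pos(pos$px), torus_pos(pos$ix), torus_pos(pos$sx)),
    y = list(torus_pos(pos$py), torus_pos(pos$iy), torus_pos(pos$sy))
  )

  syn_e <- synapse_params(cfg$g_exc, 0, cfg$py$tau_e)
  syn_i <- synapse_params(cfg$g_inh, cfg$py$e_i, cfg$py$tau_i)
  syn_s <- synapse_params(cfg$stim_weight, 0, cfg$py$tau_e)
  dly <- delay_distance(cfg$velocity, min = cfg$min_delay)
  rule_e <- rule_gaussian_in(cfg$k_exc, cfg$sigma_space)
  rule_i <- rule_gaussian_in(cfg$k_inh, cfg$sigma_space)

  prj <- dplyr::bind_rows(
    tibble::tibble(label = "PY->PY", source = "PY", target = "PY",
                   rule = list(rule_e), syn = list(syn_e), delay = list(dly),
                   external = FALSE),
    tibble::tibble(label = "PY->INH", source = "PY", target = "INH",
                   rule = list(rule_e), syn = list(syn_e), delay = list(dly),
                   external = FALSE),
    tibble::tibble(label = "INH->PY", source = "INH", target = "PY",
                   rule = list(rule_i), syn = list(syn_i), delay = list(dly),
                   external = FALSE),
    tibble::tibble(label = "INH->INH", source = "INH", target = "INH",
                   rule = list(rule_i), syn = list(syn_i), delay = list(dly),
                   external = FALSE),
    tibble::tibble(label = "STIM->PY", source = "STIM", target = "PY",
                   rule = list(rule_gaussian(cfg$stim_sigma, cfg$stim_k)),
                   syn = list(syn_s), delay = list(delay_constant(1)),
                   external = TRUE)
  )
  network_spec(pops, prj,
               meta = list(model = "ai", n_neurons = n_neurons, config = cfg,
                           position_seed = position_seed))
}

#' Initial stimulation spikes for the AI network
#'
#' Poisson activity of the stimulus sources during the first `t_stop` ms,
#' after which the network must sustain itself.
#'
#' @param net An AI `network_spec`.
#' @param rate Rate per stimulus source (Hz).
#' @param t_stop Stimulation end (ms).
#' @param seed Integer seed.
#' @export
ai_stimulus <- function(net, rate = 400, t_stop = 50, seed = 1L) {
  ids <- pop_ids(net, "STIM")
  sp <- poisson_sources(length(ids), rate, t_stop, seed = seed)
  tibble::tibble(time = sp$time, neuron = ids[sp$neuron])
}

#' Rescale a benchmark model while conserving fan-in
#'
#' Rebuilds one of the three benchmark networks at a different size under the
#' scaling rules that keep the average number of inputs per neuron type
#' constant:
#' * `ai`: neuron count changes, torus side grows with `sqrt(n)` (constant
#'   density), in-degrees and spatial profile are untouched.
#' * `synfire`: group sizes scale proportionally, feed-forward and inhibitory
#'   in-degrees stay fixed (capped at the population size).
#' * `l23`: hypercolumn/minicolumn grid is chosen to approximate the target
#'   size; with `rules$mode = "pyr_downscale"` the grid is kept and the PYR
#'   populations shrink instead, with PYR-sourced weights scaled up by the
#'   inverse factor so the total drive is preserved.
#'
#' @param model `"l23"`, `"synfire"` or `"ai"`.
#' @param target_n Desired total neuron count.
#' @param rules Optional list of scaling options (see above), plus `params`
#'   passed through to the builder.
#' @return An (uninstantiated) `network_spec`.
#' @export
scale_model <- function(model = c("l23", "synfire", "ai"), target_n,
                        rules = list()) {
  model <- match.arg(model)
  params <- rules$params %||% list()
  switch(model,
    ai = build_ai(n_neurons = target_n, params = params,
                  torus_side = sqrt(target_n / 3920) *
                    (utils::modifyList(ai_config(), params))$torus_side),
    synfire = {
      n_groups <- rules$n_groups %||% 6
      per_group <- target_n / n_groups
      n_rs <- max(1L, round(per_group * 0.8))
      n_fs <- max(1L, round(per_group * 0.2))
      assert_that(n_rs + n_fs >= 2, "target size infeasible")
      build_synfire(n_groups = n_groups, n_rs = n_rs, n_fs = n_fs,
                    params = params)
    },
    l23 = {
      if (identical(rules$mode, "pyr_downscale")) {
        n_hc <- rules$n_hc %||% 9
        n_mc <- rules$n_mc_per_hc %||% 9
        per_mc_other <- 3L # RSNP + BAS
        n_pyr <- round(target_n / (n_hc * n_mc)) - per_mc_other
        assert_that(n_pyr >= 1, "target size infeasible: empty PYR population")
        build_l23(n_hc, n_mc, n_pyr, params = params,
                  pyr_weight_scale = (rules$n_pyr_ref %||% 30) / n_pyr)
      } else {
        per_mc <- (rules$n_pyr_per_mc %||% 30) + 3L
        side <- max(1L, round(sqrt(target_n / per_mc)))
        build_l23(side, side, rules$n_pyr_per_mc %||% 30, params = params)
      }
    }
  )
}

#' Average fan-in per cell type
#'
#' Measured on the instantiated synapse table; used to verify the scaling
#' rules.
#'
#' @param net Instantiated `network_spec`.
#' @param internal_only Drop external-input synapses first.
#' @return Tibble (`cell_type`, `fan_in`).
#' @export
mean_fan_in <- function(net, internal_only = TRUE) {
  assert_that(!is.null(net$synapses), "network not instantiated")
  syn <- net$synapses
  if (internal_only) syn <- syn[!syn$external, ]
  pops <- net$populations[net$populations$cell_type != "source", ]
  counts <- tabulate(syn$target, nbins = max(pops$id_end))
  dplyr::bind_rows(lapply(split(pops, pops$cell_type), function(g) {
    ids <- unlist(lapply(seq_len(nrow(g)), function(i) {
      seq.int(g$id_start[i], g$id_end[i])
    }))
    tibble::tibble(cell_type = g$cell_type[1], fan_in = mean(counts[ids]))
  }))
}
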