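#' Distortion configuration
#'
#' Describes the three substrate-inspired distortion mechanisms applied to an
#' instantiated network: probabilistic synapse loss (global probability or a
#' per-projection-label map), multiplicative Gaussian weight noise clipped at
#' zero, and replacement of all delays by one uniform value.
#'
#' @param loss_p Deletion probability in \[0, 1\], or a named vector/list of
#'   per-projection probabilities.
#' @param exempt_external Keep synapses mediating external input untouched by
#'   loss (they can be prioritized when mapping a model to a substrate).
#' @param noise_ratio Standard-deviation-to-mean ratio of the weight noise
#'   (0-0.5 typical).
#' @param uniform_delay Uniform delay (ms), or `NULL` to leave delays alone.
#' @param recenter Divide noisy weights by the expected clipped-Gaussian mean
#'   shift so the mean is exactly preserved; off by default (the shift is
#'   0.425% at 50% noise and usually negligible).
#' @param frozen `TRUE` freezes weight noise with the network (fixed-pattern
#'   noise, redrawn only when the seed changes); `FALSE` models trial-to-trial
#'   variability (caller redraws per run). Iterative compensation requires the
#'   frozen mode.
#' @param seed Integer seed.
#' @return An object of class `distortion_config`.
#' @export
distortion_config <- function(loss_p = 0, exempt_external = TRUE,
                              noise_ratio = 0, uniform_delay = NULL,
                              recenter = FALSE, frozen = TRUE, seed = 1L) {
  lp <- unlist(loss_p)
  assert_that(all(lp >= 0 & lp <= 1), "loss_p must lie in [0, 1]")
  assert_that(noise_ratio >= 0, "noise_ratio must be >= 0")
  structure(list(loss_p = loss_p, exempt_external = exempt_external,
                 noise_ratio = noise_ratio, uniform_delay = uniform_delay,
                 recenter = recenter, frozen = frozen, seed = seed),
            class = "distortion_config")
}

loss_p_for <- function(cfg_loss, projection) {
  if (length(cfg_loss) == 1 && is.null(names(cfg_loss))) {
    rep(as.double(cfg_loss), length(projection))
  } else {
    p <- unlist(cfg_loss)[projection]
    p[is.na(p)] <- 0
    unname(p)
  }
}

#' Delete synapses probabilistically
#'
#' Each non-exempt synapse is deleted independently with its projection's
#' loss probability. A report of realized per-projection loss fractions is
#' attached as the `"loss_report"` attribute of the result.
#'
#' @param net Instantiated `network_spec`.
#' @param cfg A [distortion_config()] (its `loss_p`, `exempt_external` and
#'   `seed` fields are used).
#' @return The network with a thinned synapse table.
#' @export
apply_synapse_loss <- function(net, cfg) {
  assert_that(!is.null(net$synapses), "network not instantiated")
  syn <- net$synapses
  p <- loss_p_for(cfg$loss_p, syn$projection)
  if (isTRUE(cfg$exempt_external)) p[syn$external] <- 0
  keep <- with_seed(cfg$seed, stats::runif(nrow(syn)) >= p)
  report <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(projection = syn$projection, lost = !keep),
                    projection),
    n_before = dplyr::n(), n_lost = sum(lost),
    realized_loss = mean(lost), .groups = "drop"
  )
  net$synapses <- syn[keep, ]
  net$meta$distortions <- c(net$meta$distortions, list(
    list(type = "synapse_loss", loss_p = cfg$loss_p,
         exempt_external = cfg$exempt_external, seed = cfg$seed)
  ))
  attr(net, "loss_report") <- report
  net
}

#' Perturb synaptic weights with clipped Gaussian noise
#'
#' Each weight `w` is replaced by a draw from `N(w, (r w)^2)` clipped at zero
#' (a weight can weaken to nothing but never flip sign or receptor class).
#' Clipping raises the mean slightly; `cfg$recenter` divides by
#' [expected_clipped_mean_shift()] + 1 to undo this.
#'
#' @inheritParams apply_synapse_loss
#' @return The network with perturbed weights; realized relative mean shift in
#'   the `"noise_report"` attribute.
#' @export
apply_weight_noise <- function(net, cfg) {
  assert_that(!is.null(net$synapses), "network not instantiated")
  r <- cfg$noise_ratio
  if (r == 0) return(net)
  syn <- net$synapses
  w0 <- syn$weight
  w <- with_seed(cfg$seed, pmax(0, stats::rnorm(length(w0), w0, r * w0)))
  if (isTRUE(cfg$recenter)) w <- w / (1 + expected_clipped_mean_shift(r))
  net$synapses$weight <- w
  net$meta$distortions <- c(net$meta$distortions, list(
    list(type = "weight_noise", noise_ratio = r, frozen = cfg$frozen,
         recenter = isTRUE(cfg$recenter), seed = cfg$seed)
  ))
  attr(net, "noise_report") <- tibble::tibble(
    noise_ratio = r,
    mean_shift = sum(w) / sum(w0) - 1,
    expected_shift = if (isTRUE(cfg$recenter)) 0 else expected_clipped_mean_shift(r)
  )
  net
}

#' Replace all delays by one uniform value
#'
#' Models substrates whose propagation delays are not configurable. The
#' original delay distribution is kept in the `"delay_report"` attribute for
#' comparison.
#'
#' @param net Instantiated `network_spec`.
#' @param d Uniform delay (ms), `> 0`.
#' @return The network with constant delays.
#' @export
apply_uniform_delays <- function(net, d) {
  assert_that(!is.null(net$synapses), "network not instantiated")
  assert_that(d > 0, "d must be > 0")
  old <- net$synapses$delay
  attr(net, "delay_report") <- tibble::tibble(
    mean_before = mean(old), sd_before = stats::sd(old),
    min_before = min(old), max_before = max(old), uniform = d
  )
  net$synapses$delay <- rep(d, nrow(net$synapses))
  net$meta$distortions <- c(net$meta$distortions,
                            list(list(type = "uniform_delay", d = d)))
  net
}

#' Expected mean increase of a zero-clipped Gaussian weight distribution
#'
#' For weights drawn from `N(mu, (r mu)^2)` and clipped at zero, the relative
#' increase of the mean is `Phi(1/r) + r phi(1/r) - 1` — e.g. 0.425% at
#' r = 0.5. Used for documentation and for the optional re-centering of
#' [apply_weight_noise()].
#'
#' @param noise_ratio Standard-deviation-to-mean ratio (non-negative).
#' @return Relative mean increase (dimensionless).
#' @export
expected_clipped_mean_shift <- function(noise_ratio) {
  if (noise_ratio == 0) return(0)
  r <- noise_ratio
  stats::pnorm(1 / r) + r * stats::dnorm(1 / r) - 1
}

#' Apply a full distortion configuration
#'
#' Canonical order: synapse loss, then weight noise, then uniform delays.
#'
#' @inheritParams apply_synapse_loss
#' @return The distorted network.
#' @export
apply_distortions <- function(net, cfg) {
  if (any(unlist(cfg$loss_p) > 0)) {
    cl <- cfg; cl$seed <- derive_seed(cfg$seed, 1)
    net <- apply_synapse_loss(net, cl)
  }
  if (cfg$noise_ratio > 0) {
    cn <- cfg; cn$seed <- derive_seed(cfg$seed, 2)
    net <- apply_weight_noise(net, cn)
  }
  if (!is.null(cfg$uniform_delay)) net <- apply_uniform_delays(net, cfg$uniform_delay)
  net
}
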