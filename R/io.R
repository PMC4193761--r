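# Readers and writers for the package's external formats.

#' Write / read spike rasters as two-column text
#'
#' The raster format is whitespace-separated `time_ms neuron_id`, sorted by
#' time (the de-facto plain-text raster interchange format). Population
#' labels and the duration travel in an optional JSON side format, see
#' [write_spikes_json()].
#'
#' @param spikes Spike data.
#' @param path Output file.
#' @export
write_spikes <- function(spikes, path) {
  sp <- spikes[order(spikes$time, spikes$neuron), ]
  utils::write.table(data.frame(time = sp$time, neuron = sp$neuron),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @param duration Recording duration (ms) for the returned object.
#' @export
read_spikes <- function(path, duration) {
  d <- utils::read.table(path, col.names = c("time", "neuron"))
  spike_data(d$time, d$neuron, duration = duration)
}

#' Structured JSON spike container
#'
#' JSON object with `duration`, `time`, `neuron` and `population` arrays.
#'
#' @param spikes Spike data.
#' @param path Output file.
#' @export
write_spikes_json <- function(spikes, path) {
  jsonlite::write_json(
    list(duration = spike_duration(spikes), time = spikes$time,
         neuron = spikes$neuron, population = spikes$population),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_spikes_json
#' @export
read_spikes_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spike_data(x$time, x$neuron, population = x$population,
             duration = x$duration)
}

#' Write voltage traces as CSV
#'
#' One `time_ms` column plus one column per recorded neuron (`v<id>`).
#'
#' @param voltages Long voltage tibble (`time`, `neuron`, `v`).
#' @param path Output file.
#' @export
write_voltages <- function(voltages, path) {
  wide <- tidyr::pivot_wider(voltages, names_from = "neuron",
                             values_from = "v", names_prefix = "v")
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a network specification
#'
#' Populations, projection rules and metadata go to JSON; the expanded
#' synapse table (if instantiated) to a companion CSV
#' (`source,target,weight_nS,delay_ms,e_rev,tau_syn,projection,external`).
#'
#' @param net A `network_spec`.
#' @param path JSON output file.
#' @param synapse_csv Optional CSV path for the instantiated synapse table.
#' @export
write_network_json <- function(net, path, synapse_csv = NULL) {
  desc <- list(
    meta = net$meta[setdiff(names(net$meta), "config")],
    populations = lapply(seq_len(nrow(net$populations)), function(i) {
      p <- net$populations[i, ]
      list(name = p$name, size = p$size, cell_type = p$cell_type,
           rate = p$rate, params = unclass(p$params[[1]]))
    }),
    projections = lapply(seq_len(nrow(net$projections)), function(i) {
      p <- net$projections[i, ]
      s <- p$syn[[1]]
      list(label = p$label, source = p$source, target = p$target,
           rule = p$rule[[1]], delay = p$delay[[1]], external = p$external,
           weight = s$weight, e_rev = s$e_rev, tau_syn = s$tau_syn,
           stp = if (is.null(s$stp)) NULL else unclass(s$stp))
    })
  )
  jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(synapse_csv) && !is.null(net$synapses)) {
    syn <- net$synapses
    utils::write.csv(
      data.frame(source = syn$source, target = syn$target,
                 weight_nS = syn$weight, delay_ms = syn$delay,
                 e_rev = syn$e_rev, tau_syn = syn$tau_syn,
                 projection = syn$projection, external = syn$external),
      synapse_csv, row.names = FALSE
    )
  }
  invisible(path)
}

#' Load and validate a model configuration from YAML
#'
#' The YAML schema mirrors the `cfg` argument of [run_experiment()]: a
#' `model` block (name + builder arguments), optional `distortion` and
#' `compensation` blocks, optional `sweep` axes, `repetitions`.
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  assert_that(!is.null(cfg$model$name), "config must name a model")
  assert_that(cfg$model$name %in% c("synfire", "l23", "ai"),
              "model name must be one of synfire, l23, ai")
  if (!is.null(cfg$sweep)) {
    assert_that(all(nzchar(names(cfg$sweep))), "sweep axes must be named")
  }
  if (!is.null(cfg$repetitions)) {
    assert_that(cfg$repetitions >= 1, "repetitions must be >= 1")
  }
  if (!is.null(cfg$distortion)) {
    do.call(distortion_config, cfg$distortion) # validates
  }
  cfg
}

#' Write a functionality report as JSON
#'
#' Bundles per-criterion results with the configuration that produced them.
#'
#' @param report Named list or one-row tibble of criteria values.
#' @param path Output file.
#' @param config Optional provenance (config used, seeds).
#' @export
write_report_json <- function(report, path, config = NULL) {
  jsonlite::write_json(list(report = report, config = config),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
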