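#' Default run configuration
#'
#' A plain nested list holding every model constant (lattice and digit
#' partition, neuron and input model, synapse model, trial timing, protocol
#' schedule, seed).  Configurations round-trip losslessly through JSON (or
#' YAML) and their hash identifies a run.
#'
#' @param spec,neuron,plasticity,trial parameter objects to embed.
#' @param n_cycles,rf_every,patch_h,patch_w,track protocol settings.
#' @param seed integer seed for the run.
#' @return A `somato_config` list.
#' @export
default_config <- function(spec = lattice_spec(), neuron = neuron_params(),
                           plasticity = plasticity_params(),
                           trial = trial_spec(), n_cycles = 15L,
                           rf_every = 1L, patch_h = 7L, patch_w = 7L,
                           track = "experimental", seed = 1L) {
  structure(list(
    lattice = list(N = spec$N, M = spec$M, digit_rows = spec$digit_rows),
    neuron = unclass(neuron),
    plasticity = list(beta_w0 = plasticity$beta_w0,
                      alpha_beta = plasticity$alpha_beta,
                      tau_w = plasticity$tau_w,
                      resources = as.list(plasticity$resources),
                      beta_reset = plasticity$beta_reset),
    trial = unclass(trial),
    protocol = list(track = track, n_cycles = n_cycles, rf_every = rf_every,
                    patch_h = patch_h, patch_w = patch_w),
    seed = seed), class = "somato_config")
}

#' Materialize parameter objects from a configuration
#'
#' @param config a `somato_config` (e.g. from [load_config()]).
#' @return List with `spec`, `neuron`, `plasticity`, `trial`, `protocol`,
#'   `seed`.
#' @export
config_objects <- function(config) {
  lat <- config$lattice
  res <- unlist(config$plasticity$resources)
  list(
    spec = lattice_spec(lat$N, lat$M, unlist(lat$digit_rows)),
    neuron = neuron_params(config$neuron$tau_m, config$neuron$h,
                           config$neuron$beta_m, config$neuron$noise_amp,
                           config$neuron$mode),
    plasticity = plasticity_params(config$plasticity$beta_w0,
                                   config$plasticity$alpha_beta,
                                   config$plasticity$tau_w, res,
                                   isTRUE(config$plasticity$beta_reset)),
    trial = trial_spec(config$trial$total_ms, config$trial$prestim_ms,
                       config$trial$stim_ms, config$trial$stim_mag),
    protocol = config$protocol,
    seed = config$seed)
}

#' Read / write run configurations
#'
#' JSON by default; files ending in `.yml`/`.yaml` use YAML when the `yaml`
#' package is available.
#'
#' @param path file path.
#' @return For `load_config`, a validated `somato_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  required <- c("lattice", "neuron", "plasticity", "trial", "protocol")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config is missing section(s): ", paste(missing, collapse = ", "))
  class(cfg) <- "somato_config"
  config_objects(cfg)   # side effect: full validation of every field
  cfg
}

#' @rdname load_config
#' @param config a `somato_config`.
#' @export
save_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("writing YAML configs requires the 'yaml' package")
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Configuration hash
#'
#' MD5 of the canonical JSON serialization; recorded in every saved artifact
#' so outputs can be traced to the exact run settings.
#'
#' @param config a `somato_config`.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass(config),
                                           auto_unbox = TRUE, digits = NA)),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Save / load a network
#'
#' Text serialization of the full network state: `<stub>.json` holds the
#' configuration, adaptation state and history; `<stub>_weights.csv` holds
#' every weight slot at full precision (`%.17g`), so a save/load/save
#' round-trip is byte-identical.
#'
#' @param net a `somatonet`.
#' @param stub path stub (without extension).
#' @return `save_network` returns the stub invisibly; `load_network` returns
#'   the reconstructed `somatonet`.
#' @export
save_network <- function(net, stub) {
  cfg <- default_config(net$spec, net$neuron, net$plasticity, net$trial)
  meta <- list(format = "somatomap-net-1",
               config = unclass(cfg),
               config_hash = config_hash(cfg),
               beta_w = net$beta_w, cycle = net$cycle,
               history = net$history,
               weights_file = paste0(basename(stub), "_weights.csv"))
  jsonlite::write_json(meta, paste0(stub, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  con <- file(paste0(stub, "_weights.csv"), "w")
  on.exit(close(con))
  writeLines(c("# somatomap weight vector (cells x offsets x types, column-major)",
               sprintf("%.17g", as.numeric(net$weights))), con)
  invisible(stub)
}

#' @rdname save_network
#' @export
load_network <- function(stub) {
  meta <- jsonlite::fromJSON(paste0(stub, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "somatomap-net-1"))
    stop("unrecognized network file format: ", meta$format)
  cfg <- meta$config; class(cfg) <- "somato_config"
  ob <- config_objects(cfg)
  wfile <- file.path(dirname(stub), meta$weights_file)
  w <- scan(wfile, what = double(), comment.char = "#", quiet = TRUE)
  NC <- ob$spec$N^2; NO <- ob$spec$M^2
  if (length(w) != NC * NO * 4L)
    stop("weight file length mismatch: corrupt or wrong lattice")
  net <- structure(
    list(spec = ob$spec, neuron = ob$neuron, plasticity = ob$plasticity,
         trial = ob$trial, weights = array(w, c(NC, NO, 4L),
                                           list(NULL, NULL, CONN_TYPES)),
         beta_w = meta$beta_w, cycle = meta$cycle,
         history = if (is.data.frame(meta$history)) meta$history else
           data.frame(phase = character(), cycles = integer(),
                      trials = integer())),
    class = "somatonet")
  net
}

#' Export analysis tables as CSV
#'
#' `write_rf_map` writes the per-cell receptive-field table (1-based node
#' labels, response magnitude also in log10).  `write_divergence_grid`
#' writes the N x N intracolumnar E--I centroid divergence grid.
#' `write_count_map` writes a stimulation count grid with 1-based headers.
#'
#' @param map an [rf_map()].
#' @param path output file.
#' @export
write_rf_map <- function(map, path) {
  d <- as.data.frame(map)
  d$magnitude_log10 <- log10(d$magnitude)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rf_map
#' @export
write_divergence_grid <- function(map, path) {
  spec <- attr(map, "spec")
  div <- rf_divergence(map)
  g <- matrix(NA_real_, spec$N, spec$N)
  g[cbind(div$row, div$col)] <- div$divergence
  colnames(g) <- seq_len(spec$N)
  write.csv(cbind(row = seq_len(spec$N), g), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rf_map
#' @param counts matrix from [stimulation_count_map()].
#' @export
write_count_map <- function(counts, path) {
  colnames(counts) <- seq_len(ncol(counts))
  write.csv(cbind(row = seq_len(nrow(counts)), counts), path,
            row.names = FALSE)
  invisible(path)
}
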