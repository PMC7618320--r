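## Plain-text dataset store: a directory with CSV tables and JSON metadata.
## (An HDF5-style hierarchical store would be the natural container for the
## trial tensor; this environment carries no HDF5 bindings, so the tensor is
## serialized in long CSV form with its dimensions recorded in meta.json.)

#' Save / load a synthetic dataset directory
#'
#' Writes `cells.csv`, `connections.csv`, `stim.csv`, `trials.csv` (long
#' format: stim, rep, frame, cell, dff) and `meta.json` (seed, dimensions,
#' ensemble scalars). `load_dataset()` reverses the mapping and reattaches
#' the ensemble to the trial tensor.
#'
#' @param dataset List from [gen_dataset()].
#' @param dir Target directory (created if needed).
#' @return `save_dataset()`: the directory, invisibly. `load_dataset()`: a
#'   dataset list.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(dataset$cells, file.path(dir, "cells.csv"))
  data.table::fwrite(dataset$connections, file.path(dir, "connections.csv"))
  ens <- dataset$ensemble
  data.table::fwrite(ens$stim, file.path(dir, "stim.csv"))
  f <- dataset$trials
  dn <- dim(f)
  long <- data.table::data.table(
    stim = rep(seq_len(dn[1]), times = prod(dn[2:4])),
    rep = rep(rep(seq_len(dn[2]), each = dn[1]), times = prod(dn[3:4])),
    frame = rep(rep(seq_len(dn[3]), each = prod(dn[1:2])), times = dn[4]),
    cell = rep(seq_len(dn[4]), each = prod(dn[1:3])),
    dff = as.vector(f))
  data.table::fwrite(long, file.path(dir, "trials.csv"))
  meta <- list(seed = dataset$seed, dim = dn,
               directions = ens$directions,
               spatial_freqs = ens$spatial_freqs,
               temporal_freqs = ens$temporal_freqs,
               n_stationary_frames = ens$n_stationary_frames,
               n_moving_frames = ens$n_moving_frames,
               volume_rate = ens$volume_rate)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  ens <- stimulus_ensemble(directions = meta$directions,
                           spatial_freqs = meta$spatial_freqs,
                           temporal_freqs = meta$temporal_freqs,
                           n_stationary_frames = meta$n_stationary_frames,
                           n_moving_frames = meta$n_moving_frames,
                           volume_rate = meta$volume_rate)
  long <- data.table::fread(file.path(dir, "trials.csv"))
  f <- array(long$dff, dim = meta$dim)
  attr(f, "ensemble") <- ens
  list(cells = data.table::fread(file.path(dir, "cells.csv")),
       connections = data.table::fread(file.path(dir, "connections.csv")),
       trials = f, ensemble = ens, seed = meta$seed)
}
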