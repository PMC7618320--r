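#' Grating stimulus ensemble
#'
#' Describes the full-field drifting-grating battery used for tuning
#' characterization: all combinations of direction, spatial frequency (SF) and
#' temporal frequency (TF), each presented as a stationary phase followed by a
#' moving phase.
#'
#' @param directions Drift directions in degrees (default 8, every 45 deg).
#' @param spatial_freqs Spatial frequencies in cycles/deg (default 6,
#'   log2-spaced from 0.01 to 0.32).
#' @param temporal_freqs Temporal frequencies in Hz (default 6, log2-spaced
#'   from 0.5 to 16).
#' @param n_stationary_frames,n_moving_frames Imaging volumes per phase.
#' @param volume_rate Volumetric imaging rate in Hz.
#'
#' @return An object of class `stimulus_ensemble`: a list with the stimulus
#'   table (`stim`, one row per stimulus type), frame counts, the moving-phase
#'   frame window `moving_window = c(a, b)` (1-based, inclusive) and
#'   `n_stim`.
#' @export
#' @examples
#' ens <- stimulus_ensemble()
#' ens$n_stim  # 288
stimulus_ensemble <- function(directions = seq(0, 315, by = 45),
                              spatial_freqs = 0.01 * 2^seq(0, 5),
                              temporal_freqs = 0.5 * 2^seq(0, 5),
                              n_stationary_frames = 5,
                              n_moving_frames = 8,
                              volume_rate = 3.65) {
  stopifnot(n_stationary_frames >= 0, n_moving_frames >= 1, volume_rate > 0)
  stim <- expand.grid(direction = directions,
                      sf = spatial_freqs,
                      tf = temporal_freqs,
                      KEEP.OUT.ATTRS = FALSE)
  stim <- stim[order(stim$tf, stim$sf, stim$direction), , drop = FALSE]
  rownames(stim) <- NULL
  n_frames <- n_stationary_frames + n_moving_frames
  ens <- list(
    directions = directions,
    spatial_freqs = spatial_freqs,
    temporal_freqs = temporal_freqs,
    n_stationary_frames = n_stationary_frames,
    n_moving_frames = n_moving_frames,
    n_frames = n_frames,
    moving_window = c(n_stationary_frames + 1L, n_frames),
    volume_rate = volume_rate,
    stim = stim,
    n_stim = nrow(stim)
  )
  class(ens) <- "stimulus_ensemble"
  ens
}

#' @export
print.stimulus_ensemble <- function(x, ...) {
  cat(sprintf(
    "stimulus_ensemble: %d stimuli (%d dir x %d SF x %d TF), %d+%d frames @ %.2f Hz\n",
    x$n_stim, length(x$directions), length(x$spatial_freqs),
    length(x$temporal_freqs), x$n_stationary_frames, x$n_moving_frames,
    x$volume_rate))
  invisible(x)
}

## SF/TF are handled in octaves (log2 units) relative to the lowest probed
## value throughout the tuning code.
sf_octaves <- function(sf, ensemble) log2(sf / min(ensemble$spatial_freqs))
tf_octaves <- function(tf, ensemble) log2(tf / min(ensemble$temporal_freqs))
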