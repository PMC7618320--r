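# Small shared fixtures, built in code at test time.

small_ensemble <- function() {
  stimulus_ensemble(directions = seq(0, 315, by = 45),
                    spatial_freqs = 0.01 * 2^seq(0, 5),
                    temporal_freqs = 0.5 * 2^seq(0, 5),
                    n_stationary_frames = 2, n_moving_frames = 4)
}

# Noiseless trial tensor for one cell defined by `params`.
noiseless_tensor <- function(params, ensemble, n_rep = 2) {
  pred <- predict_response(params, ensemble$stim$direction,
                           sf_octaves(ensemble$stim$sf, ensemble),
                           tf_octaves(ensemble$stim$tf, ensemble))
  nf <- ensemble$n_frames
  mov <- seq(ensemble$moving_window[1], ensemble$moving_window[2])
  f <- array(params$b, dim = c(ensemble$n_stim, n_rep, nf))
  for (t in mov) f[, , t] <- array(rep(pred, n_rep),
                                   dim = c(ensemble$n_stim, n_rep))
  f
}

tiny_net_config <- function(N = 50, ...) {
  network_config(N = N, w_e = 10, w_i = 40, bg_weight = 1.5, ...)
}
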