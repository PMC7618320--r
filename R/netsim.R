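## Structured recurrent E/I spiking network: construction from von-Mises
## tuning-similarity kernels, LIF simulation (compiled integrator), stimulus
## battery, cohort perturbation, and conductance/stability analyses.

#' Network configuration
#'
#' Parameters of the structured E/I network. Class fractions, the E-to-I
#' weight factor `d_ie`, specificity parameters `s_e` (recurrent excitation)
#' and `s_i` (all connections involving inhibitory neurons), and the
#' concentration parameters `kappa` of the circular tuning kernel follow the
#' reference parameter set (N = 5000, f_I = 0.2, d_IE = 2, kappa_EE = 4,
#' others 0.5, D = 2, 2400 Hz background). Neuron and synapse constants are
#' standard conductance-LIF values. `w_e`, `w_i` (total output synaptic
#' weight per neuron, nS) and `bg_weight` must be calibrated per network size;
#' see [network_preset()].
#'
#' @param N Number of neurons.
#' @param f_i Inhibitory fraction (f_e = 1 - f_i).
#' @param w_e,w_i Total output synaptic weight of single E and I neurons (nS).
#' @param d_ie E-to-I weight scale factor (>= 1).
#' @param s_e Excitatory specificity in [0, 1].
#' @param s_i Inhibitory specificity in [-1, 1]; negative values switch the
#'   inhibitory-source kernels to the anti-tuned (lateral inhibition) variant.
#' @param kappa Named kernel concentrations `c(ee, ei, ie, ii)` (class A -> B
#'   stored as `ba`).
#' @param D Number of tuning dimensions.
#' @param bg_rate Background Poisson rate per neuron (Hz).
#' @param bg_weight Synaptic weight of one background event (nS).
#' @param dt Integration step (ms).
#' @param ... Overrides for neuron constants `C_m` (pF), `g_L` (nS), `E_L`,
#'   `V_th`, `V_reset`, `E_ex`, `E_in` (mV), `tau_ref`, `tau_E`, `tau_I`,
#'   `delay` (ms).
#' @return A `network_config` list.
#' @export
network_config <- function(N = 5000, f_i = 0.2, w_e = 100, w_i = 400,
                           d_ie = 2, s_e = 0, s_i = 0,
                           kappa = c(ee = 4, ei = 0.5, ie = 0.5, ii = 0.5),
                           D = 2, bg_rate = 2400, bg_weight = 0.006,
                           dt = 0.1, ...) {
  stopifnot(N >= 10, f_i > 0, f_i < 1, w_e > 0, w_i > 0, d_ie >= 1,
            s_e >= 0, s_e <= 1, s_i >= -1, s_i <= 1, D >= 1,
            all(kappa >= 0))
  neuron <- list(C_m = 200, g_L = 20, E_L = -70, V_th = -55, V_reset = -70,
                 E_ex = 0, E_in = -80, tau_ref = 2, tau_E = 0.5, tau_I = 1,
                 delay = 1)
  dots <- list(...)
  neuron[names(dots)] <- dots
  cfg <- c(list(N = N, f_e = 1 - f_i, f_i = f_i, w_e = w_e, w_i = w_i,
                d_ie = d_ie, s_e = s_e, s_i = s_i, kappa = kappa, D = D,
                bg_rate = bg_rate, bg_weight = bg_weight, dt = dt),
           neuron)
  if (dt > min(cfg$tau_E, cfg$tau_I) / 2)
    stop("dt too large for the synaptic time constants (stability guard)")
  class(cfg) <- "network_config"
  cfg
}

#' Calibrated scaled-down network presets
#'
#' Returns a [network_config()] with `w_e`, `w_i` and `bg_weight` calibrated
#' for the given network size so that the uniform network fires at a low
#' spontaneous rate (~2 Hz) and the specificity-driven regime transitions of
#' the full-size model are reproduced as labels. Calibrated once during
#' development; see the methods vignette.
#'
#' @param N Network size (500 and 1000 are the calibrated presets).
#' @param ... Passed to [network_config()] (e.g. `s_e`, `s_i`).
#' @export
network_preset <- function(N = 500, ...) {
  network_config(N = N, w_e = 3000, w_i = 16500, bg_weight = 1.2, ...)
}

#' Stimulus current used in scaled-down protocols
#'
#' The full-size model drives the excitatory population with currents scaled
#' to 12 pA; at reduced N the recurrent amplification is weaker, so scaled
#' runs use a stronger peak current (calibrated once, like the weights) to
#' obtain clearly evoked responses. All regime checks remain
#' direction-of-effect.
#'
#' @param N Network size.
#' @return Peak stimulus current in pA.
#' @export
preset_stim_pA <- function(N = 500) if (N >= 5000) 12 else 100

#' Assign preferred tuning values
#'
#' Each neuron receives, independently for each of the D feature dimensions, a
#' preferred value uniform on `[-pi, pi)`.
#'
#' @param config A [network_config()].
#' @param seed Integer seed.
#' @return `N x D` matrix of preferences (radians).
#' @export
assign_preferences <- function(config, seed = 1L) {
  set.seed(seed)
  matrix(stats::runif(config$N * config$D, -pi, pi), config$N, config$D)
}

#' Circular connection-tuning kernel
#'
#' `phi(gi, gj, kappa) = exp(kappa * cos(gi - gj))`: the von-Mises-shaped
#' factor by which tuning-preference similarity modulates connection weight.
#'
#' @param gamma_i,gamma_j Preferences (radians), vectorized.
#' @param kappa Concentration (>= 0).
#' @export
phi <- function(gamma_i, gamma_j, kappa) {
  stopifnot(kappa >= 0)
  exp(kappa * cos(gamma_i - gamma_j))
}

#' Specificity block between two populations
#'
#' Raw affinities are the product over dimensions of [phi()] between source
#' and target preferences (or `1 - prod(phi)` for the anti-tuned variant used
#' by negative inhibitory specificity). Each source neuron's affinities over
#' its available targets are then normalized to a probability density:
#' subtract the minimum, divide by the sum. Degenerate (constant) columns fall
#' back to the uniform density with a message.
#'
#' @param prefs_src,prefs_dst Preference matrices (rows = neurons, cols =
#'   dimensions).
#' @param kappa Kernel concentration for this block.
#' @param negative Use the `1 - prod(phi)` variant.
#' @param self_idx Optional integer vector: `self_idx[i]` is the row of
#'   `prefs_dst` that is the same neuron as source `i` (autapses excluded
#'   from the density).
#' @return Matrix `S[j, i]`: density over targets j for each source i
#'   (columns have min 0 and sum 1 over available targets).
#' @export
specificity_block <- function(prefs_src, prefs_dst, kappa, negative = FALSE,
                              self_idx = NULL) {
  n_src <- nrow(prefs_src); n_dst <- nrow(prefs_dst)
  M <- matrix(1, n_dst, n_src)
  for (d in seq_len(ncol(prefs_src))) {
    M <- M * exp(kappa * cos(outer(prefs_dst[, d], prefs_src[, d], "-")))
  }
  if (negative) M <- 1 - M
  if (!is.null(self_idx)) {
    M[cbind(self_idx, seq_len(n_src))] <- NA
  }
  uniform_fallback <- FALSE
  for (i in seq_len(n_src)) {
    col <- M[, i]
    avail <- !is.na(col)
    v <- col[avail] - min(col[avail])
    s <- sum(v)
    if (s <= 0) {
      v <- rep(1 / sum(avail), sum(avail))
      uniform_fallback <- TRUE
    } else {
      v <- v / s
    }
    col[avail] <- v
    col[!avail] <- 0
    M[, i] <- col
  }
  if (uniform_fallback)
    message("specificity_block: constant affinities; uniform density used")
  M
}

#' Build the signed block weight matrix
#'
#' Composes the four class blocks. For a source of class A with total output
#' weight `w_A,B` onto class B, per-target weights are
#' `w_A,B * (s * S[j,i] + (1 - s) * U[j,i])` with `S` the specificity density,
#' `U` the uniform density over available (non-self) targets, and `s` the
#' relevant specificity magnitude (`|s_e|` for E-to-E, `|s_i|` elsewhere).
#' Equivalent to the block equations
#' `W_EE = w_E [f_E(|s_E| S_EE) + (1 - |s_E|)/N]` etc., with autapses
#' excluded. Per-source output weight is conserved exactly for any
#' specificity.
#'
#' @param config A [network_config()].
#' @param prefs Preference matrix from [assign_preferences()].
#' @return A `network_model`: list with `W` (N x N magnitudes, `W[j, i]` =
#'   weight of connection i -> j, nS), `is_exc`, `prefs`, `config`.
#' @export
build_weights <- function(config, prefs) {
  N <- config$N
  n_e <- round(N * config$f_e); n_i <- N - n_e
  is_exc <- c(rep(TRUE, n_e), rep(FALSE, n_i))
  pe <- prefs[seq_len(n_e), , drop = FALSE]
  pi_ <- prefs[n_e + seq_len(n_i), , drop = FALSE]
  neg <- config$s_i < 0
  se <- abs(config$s_e); si <- abs(config$s_i)

  blk <- function(src, dst, kappa, s, negative, same_pop) {
    self <- if (same_pop) seq_len(nrow(src)) else NULL
    S <- specificity_block(src, dst, kappa, negative = negative,
                           self_idx = self)
    n_avail <- nrow(dst) - as.integer(same_pop)
    U <- matrix(1 / n_avail, nrow(dst), nrow(src))
    if (same_pop) U[cbind(self, seq_len(nrow(src)))] <- 0
    s * S + (1 - s) * U
  }
  W <- matrix(0, N, N)
  ie <- seq_len(n_e); ii <- n_e + seq_len(n_i)
  W[ie, ie] <- config$w_e * config$f_e *
    blk(pe, pe, config$kappa[["ee"]], se, FALSE, TRUE)
  W[ii, ie] <- config$w_e * config$d_ie * config$f_i *
    blk(pe, pi_, config$kappa[["ie"]], si, FALSE, FALSE)
  W[ie, ii] <- config$w_i * config$f_e *
    blk(pi_, pe, config$kappa[["ei"]], si, neg, FALSE)
  W[ii, ii] <- config$w_i * config$f_i *
    blk(pi_, pi_, config$kappa[["ii"]], si, neg, TRUE)
  model <- list(W = W, is_exc = is_exc, prefs = prefs, config = config,
                n_e = n_e, n_i = n_i)
  class(model) <- "network_model"
  model
}

#' Tuned feedforward input currents
#'
#' Input to excitatory neuron i is `u_i = prod_d phi(gamma_i^d, gamma_stim^d,
#' kappa_EE)`, min-max normalized over the excitatory population and scaled to
#' `max_current`. Inhibitory neurons receive no direct stimulus input.
#'
#' @param model A `network_model`.
#' @param gamma_stim Stimulus feature values (radians), length D.
#' @param max_current Peak current, pA (default 12).
#' @return Length-N current vector (pA).
#' @export
tuned_input <- function(model, gamma_stim, max_current = 12) {
  cfg <- model$config
  u <- rep(1, model$n_e)
  for (d in seq_len(cfg$D)) {
    u <- u * phi(model$prefs[seq_len(model$n_e), d], gamma_stim[d],
                 cfg$kappa[["ee"]])
  }
  rng <- range(u)
  cur <- numeric(cfg$N)
  if (diff(rng) == 0) {
    message("tuned_input: degenerate (constant) drive; zero input")
    return(cur)
  }
  cur[seq_len(model$n_e)] <- (u - rng[1]) / diff(rng) * max_current
  cur
}

#' Simulate the network
#'
#' Fixed-step exponential-Euler integration of conductance-based LIF neurons
#' with alpha-function synapses, independent Poisson background input, and a
#' protocol of piecewise-constant injected currents.
#'
#' @param model A `network_model` from [build_weights()].
#' @param protocol List with `t_max` (ms) and optionally `stim`: a list of
#'   events, each `list(start, end, current)` with `current` a length-N pA
#'   vector; `bg_rate` overriding the config background rate (scalar or
#'   per-neuron); `probe_idx` neurons whose conductances are recorded each
#'   step; `rate_bin` (ms, default 250).
#' @param seed Integer seed.
#' @return A `sim_result`: `spikes` (data.frame neuron/time), `rates`
#'   (neuron x bin Hz matrix), `g_e`/`g_i` (step x probe matrices), `probe_idx`,
#'   `protocol`, `t_max`.
#' @export
simulate_network <- function(model, protocol, seed = 1L) {
  cfg <- model$config
  t_max <- protocol$t_max
  stim <- protocol$stim %||% list()
  n_int <- length(stim)
  stim_cur <- matrix(0, cfg$N, max(n_int, 1))
  stim_start <- numeric(max(n_int, 1)); stim_end <- numeric(max(n_int, 1))
  if (n_int == 0) { stim_start[1] <- -2; stim_end[1] <- -1 }
  for (k in seq_len(n_int)) {
    stim_cur[, k] <- stim[[k]]$current
    stim_start[k] <- stim[[k]]$start
    stim_end[k] <- stim[[k]]$end
  }
  bg <- protocol$bg_rate %||% cfg$bg_rate
  bg <- rep_len(bg, cfg$N)
  probes <- protocol$probe_idx %||% integer(0)
  params <- cfg[c("C_m", "g_L", "E_L", "V_th", "V_reset", "E_ex", "E_in",
                  "tau_ref", "tau_E", "tau_I", "delay")]
  res <- lif_simulate_cpp(model$W, model$is_exc, cfg$dt, t_max, bg,
                          cfg$bg_weight, stim_cur, stim_start, stim_end,
                          as.integer(probes), params,
                          as.integer(seed %% 2147483647))
  bin <- protocol$rate_bin %||% 250
  n_bin <- max(1, floor(t_max / bin))
  rates <- matrix(0, cfg$N, n_bin)
  if (length(res$spike_time)) {
    bidx <- pmin(floor(res$spike_time / bin) + 1, n_bin)
    tab <- table(factor(res$spike_neuron, levels = seq_len(cfg$N)),
                 factor(bidx, levels = seq_len(n_bin)))
    rates <- unclass(tab) / (bin / 1000)
  }
  out <- list(spikes = data.frame(neuron = res$spike_neuron,
                                  time = res$spike_time),
              rates = rates, g_e = res$g_E, g_i = res$g_I,
              probe_idx = probes, protocol = protocol, t_max = t_max,
              dt = cfg$dt, is_exc = model$is_exc)
  class(out) <- "sim_result"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stimulus battery protocol
#'
#' Stimulates the network with 16 stimuli spanning both feature dimensions in
#' increments of pi/2 (400 ms on per 1 s cycle) and bins firing rates at
#' 250 ms. With `n_rep > 1` the battery is repeated with derived seeds and
#' rates are averaged. The pairwise I-to-E table contains cosine similarity
#' and Pearson correlation of the stimulus-period activity vectors,
#' preference differences per feature both from the ground-truth assignments
#' and as estimated from activity (rate-weighted circular mean, mirroring how
#' preferences are measured experimentally), and the model's connection
#' weights.
#'
#' @param model A `network_model`.
#' @param seed Integer seed.
#' @param n_rep Number of battery repeats averaged (default 1).
#' @param stim_ms,cycle_ms Stimulus-on and cycle durations (ms).
#' @param max_current Stimulus peak current (pA, default 12; see
#'   [preset_stim_pA()] for scaled networks).
#' @param probe_idx Optional conductance probes (recorded on the last repeat).
#' @param bg_rate Optional background override.
#' @return List: `sim` (the last repeat's `sim_result`), `stim_table`,
#'   `rates` (repeat-averaged), `stim_rates` (neuron x 16 mean stimulus-period
#'   rates), `est_prefs` (neuron x 2 estimated preferences), and `pairs`.
#' @export
stimulus_battery <- function(model, seed = 1L, n_rep = 1, stim_ms = 400,
                             cycle_ms = 1000, max_current = 12,
                             probe_idx = integer(0), bg_rate = NULL) {
  vals <- c(-pi, -pi / 2, 0, pi / 2)
  grid <- expand.grid(g1 = vals, g2 = vals)
  stim <- lapply(seq_len(nrow(grid)), function(k) {
    list(start = (k - 1) * cycle_ms, end = (k - 1) * cycle_ms + stim_ms,
         current = tuned_input(model, c(grid$g1[k], grid$g2[k]),
                               max_current))
  })
  proto <- list(t_max = nrow(grid) * cycle_ms, stim = stim,
                rate_bin = 250)
  if (!is.null(bg_rate)) proto$bg_rate <- bg_rate
  seeds <- derive_seeds(seed, n_rep)
  rates <- 0
  sim <- NULL
  for (r in seq_len(n_rep)) {
    proto$probe_idx <- if (r == n_rep) probe_idx else integer(0)
    sim <- simulate_network(model, proto, seed = seeds[r])
    rates <- rates + sim$rates
  }
  rates <- rates / n_rep

  bins_per_cycle <- cycle_ms / 250
  on_per_cycle <- max(1, floor(stim_ms / 250))
  on_bins <- sort(unlist(lapply(seq_len(nrow(grid)) - 1, function(k)
    k * bins_per_cycle + seq_len(on_per_cycle))))
  act <- rates[, on_bins, drop = FALSE]
  stim_rates <- vapply(seq_len(nrow(grid)) - 1, function(k)
    rowMeans(rates[, k * bins_per_cycle + seq_len(on_per_cycle),
                   drop = FALSE]), numeric(nrow(rates)))

  ## activity-estimated preference: rate-weighted circular mean per feature
  est_prefs <- vapply(c("g1", "g2"), function(feat) {
    g <- grid[[feat]]
    apply(stim_rates, 1, function(v) {
      if (sum(v) == 0) return(NA_real_)
      atan2(sum(v * sin(g)), sum(v * cos(g)))
    })
  }, numeric(nrow(rates)))

  ne <- model$n_e
  ii <- ne + seq_len(model$n_i)
  wrap_d <- function(a, b) {
    d <- abs(a - b) %% (2 * pi)
    pmin(d, 2 * pi - d)
  }
  pairs <- data.table::rbindlist(lapply(ii, function(i) {
    ri <- act[i, ]
    data.table::data.table(
      i_cell = i, e_cell = seq_len(ne),
      similarity = vapply(seq_len(ne), function(e)
        cosine(ri, act[e, ]), numeric(1)),
      correlation = vapply(seq_len(ne), function(e) {
        re <- act[e, ]
        if (stats::sd(ri) == 0 || stats::sd(re) == 0) NA_real_
        else stats::cor(ri, re)
      }, numeric(1)),
      d_pref1 = wrap_d(model$prefs[i, 1], model$prefs[seq_len(ne), 1]),
      d_pref2 = wrap_d(model$prefs[i, 2], model$prefs[seq_len(ne), 2]),
      d_est1 = wrap_d(est_prefs[i, 1], est_prefs[seq_len(ne), 1]),
      d_est2 = wrap_d(est_prefs[i, 2], est_prefs[seq_len(ne), 2]),
      w_ie = model$W[seq_len(ne), i],   # I -> E weight
      w_ei = model$W[i, seq_len(ne)])   # E -> I weight
  }))
  list(sim = sim, stim_table = grid, rates = rates, stim_rates = stim_rates,
       est_prefs = est_prefs, pairs = pairs)
}

#' Cohort perturbation protocol
#'
#' Elevates the background rate, selects the 11 excitatory neurons nearest in
#' feature-1 preference to a target (among those whose feature-2 preference
#' is within `tol` of its target), drives them with strong current pulses
#' (10 ms at 10 Hz), and compares each neuron's firing rate in the 20 ms
#' before each pulse with the 50 ms following pulse onset.
#'
#' @param model A `network_model`.
#' @param gamma_target Length-2 target preference (radians).
#' @param cohort_size Number of stimulated neurons (default 11).
#' @param tol Feature-2 matching tolerance (radians, default pi/16).
#' @param n_pulses Number of current pulses (default 8).
#' @param pulse_pA Pulse amplitude (pA; default 2e5 = 200 nA).
#' @param bg_rate Elevated background rate (Hz, default 3500).
#' @param seed Integer seed.
#' @return List: `cohort` (neuron indices), `table` (data.table: neuron,
#'   class, cohort flag, pre/post rates in Hz, `facilitated`), `sim`.
#' @export
perturb_cohort <- function(model, gamma_target = c(0, 0), cohort_size = 11,
                           tol = pi / 16, n_pulses = 8, pulse_pA = 2e5,
                           bg_rate = 3500, seed = 1L) {
  wrap_d <- function(a, b) {
    d <- abs(a - b) %% (2 * pi); pmin(d, 2 * pi - d)
  }
  ne <- model$n_e
  d2 <- wrap_d(model$prefs[seq_len(ne), 2], gamma_target[2])
  eligible <- which(d2 <= tol)
  if (length(eligible) < cohort_size)
    stop("only ", length(eligible), " excitatory neurons within tol = ",
         signif(tol, 3), " of the feature-2 target; need ", cohort_size)
  d1 <- wrap_d(model$prefs[eligible, 1], gamma_target[1])
  cohort <- eligible[order(d1)][seq_len(cohort_size)]

  period <- 100                      # 10 Hz
  t0 <- 200                          # settle time before first pulse
  cur <- numeric(model$config$N)
  cur[cohort] <- pulse_pA
  stim <- lapply(seq_len(n_pulses), function(k) {
    list(start = t0 + (k - 1) * period, end = t0 + (k - 1) * period + 10,
         current = cur)
  })
  t_max <- t0 + n_pulses * period
  sim <- simulate_network(model, list(t_max = t_max, stim = stim,
                                      bg_rate = bg_rate, rate_bin = 250),
                          seed = seed)
  sp <- sim$spikes
  count_in <- function(lo, hi) {
    sel <- sp$time >= lo & sp$time < hi
    tabulate(sp$neuron[sel], nbins = model$config$N)
  }
  pre <- post <- numeric(model$config$N)
  for (k in seq_len(n_pulses)) {
    on <- t0 + (k - 1) * period
    pre <- pre + count_in(on - 20, on)
    post <- post + count_in(on, on + 50)
  }
  pre_hz <- pre / (n_pulses * 0.020)
  post_hz <- post / (n_pulses * 0.050)
  tab <- data.table::data.table(
    neuron = seq_len(model$config$N),
    class = ifelse(model$is_exc, "E", "I"),
    cohort = seq_len(model$config$N) %in% cohort,
    pre_hz = pre_hz, post_hz = post_hz,
    facilitated = post_hz > pre_hz,
    d_pref1 = wrap_d(model$prefs[, 1], gamma_target[1]),
    d_pref2 = wrap_d(model$prefs[, 2], gamma_target[2]))
  list(cohort = cohort, table = tab, sim = sim)
}

#' Excitatory/inhibitory conductance co-tuning
#'
#' Per probed neuron, the Pearson correlation of its excitatory and inhibitory
#' conductance traces at the integration step (0.1 ms) resolution, plus
#' stimulus-averaged conductance tuning curves across the battery.
#'
#' @param sim A `sim_result` with conductance probes.
#' @param stim Optional list of stimulus events (from the battery protocol)
#'   over which to average conductances per stimulus.
#' @return List: `correlation` (per probe), `g_e_tuning`, `g_i_tuning`
#'   (probe x stimulus matrices, or NULL without `stim`).
#' @export
conductance_cotuning <- function(sim, stim = NULL) {
  stopifnot(length(sim$probe_idx) > 0)
  np <- length(sim$probe_idx)
  corr <- vapply(seq_len(np), function(k) {
    ge <- sim$g_e[, k]; gi <- sim$g_i[, k]
    if (stats::sd(ge) == 0 || stats::sd(gi) == 0) return(NA_real_)
    stats::cor(ge, gi)
  }, numeric(1))
  ge_t <- gi_t <- NULL
  if (!is.null(stim)) {
    ge_t <- gi_t <- matrix(NA_real_, np, length(stim))
    for (s in seq_along(stim)) {
      idx <- seq(floor(stim[[s]]$start / sim$dt) + 1,
                 min(floor(stim[[s]]$end / sim$dt), nrow(sim$g_e)))
      ge_t[, s] <- colMeans(sim$g_e[idx, , drop = FALSE])
      gi_t[, s] <- colMeans(sim$g_i[idx, , drop = FALSE])
    }
  }
  list(correlation = corr, g_e_tuning = ge_t, g_i_tuning = gi_t)
}

#' Stability index of a stimulated network
#'
#' For each stimulation cycle, the ratio of the population excitatory firing
#' rate in the last `off_tail` ms of the inter-stimulus (off) period to the
#' rate during stimulation. Persistent recurrent activity keeps the ratio
#' high; the network is labelled `"unstable"` if the ratio exceeds
#' `threshold` in a majority of cycles.
#'
#' @param sim A `sim_result` from a protocol with off periods.
#' @param stim The stimulus event list used (each with `start`, `end`).
#' @param cycle_ms Cycle length (ms).
#' @param off_tail Tail of the off period evaluated (ms, default 200).
#' @param threshold Ratio above which a cycle counts as unstable (default 0.5).
#' @return List: `ratios` per cycle, `index` (median ratio), `label`
#'   (`"stable"`/`"unstable"`).
#' @export
stability_index <- function(sim, stim, cycle_ms = 1000, off_tail = 200,
                            threshold = 0.5) {
  if (!length(stim)) stop("protocol has no stimulation events")
  e_idx <- which(sim$is_exc)
  sp <- sim$spikes[sim$spikes$neuron %in% e_idx, ]
  pop_rate <- function(lo, hi) {
    sum(sp$time >= lo & sp$time < hi) / ((hi - lo) / 1000) / length(e_idx)
  }
  ratios <- vapply(seq_along(stim), function(k) {
    on <- pop_rate(stim[[k]]$start, stim[[k]]$end)
    off_end <- stim[[k]]$start + cycle_ms
    off <- pop_rate(off_end - off_tail, off_end)
    if (on == 0) return(ifelse(off > 0, Inf, 0))
    off / on
  }, numeric(1))
  unstable <- mean(ratios > threshold) > 0.5
  list(ratios = ratios, index = stats::median(ratios),
       label = if (unstable) "unstable" else "stable")
}

#' Calibrate the background synaptic weight
#'
#' Bisects `bg_weight` so that an unconnected (W = 0) network fires
#' spontaneously at `target_hz`.
#'
#' @param config A [network_config()].
#' @param target_hz Target spontaneous rate (default 2 Hz).
#' @param t_max Calibration simulation length (ms).
#' @param seed Integer seed.
#' @return Calibrated `bg_weight` (nS).
#' @export
calibrate_background <- function(config, target_hz = 2, t_max = 2000,
                                 seed = 1L) {
  rate_at <- function(w) {
    cfg <- config; cfg$bg_weight <- w
    model <- list(W = matrix(0, cfg$N, cfg$N),
                  is_exc = rep(TRUE, cfg$N),
                  prefs = matrix(0, cfg$N, cfg$D), config = cfg,
                  n_e = cfg$N, n_i = 0)
    class(model) <- "network_model"
    sim <- simulate_network(model, list(t_max = t_max), seed = seed)
    nrow(sim$spikes) / cfg$N / (t_max / 1000)
  }
  lo <- 1e-3; hi <- 5
  for (k in 1:18) {
    mid <- sqrt(lo * hi)
    if (rate_at(mid) < target_hz) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}
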