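## Seeded synthetic-data generator: ground-truth cells, trial-resolved dF/F
## tensors, and paired-recording connectivity with configurable
## similarity-strength coupling. Stands in for the deposited two-photon +
## paired whole-cell dataset in every downstream test.

#' Default per-class tuning parameter sampling profiles
#'
#' PV+ cells are sampled with broader direction and SF/TF tuning and larger
#' null-direction responses than pyramidal (PV-) cells, reflecting their lower
#' stimulus selectivity. All draws respect the tuning-model bounds.
#'
#' @return Named list of per-class profiles; each profile gives `c(lo, hi)`
#'   uniform ranges per parameter plus response-gain and noise settings.
#' @export
default_selectivity_profiles <- function() {
  list(
    pyr = list(sigma_dir = c(15, 45), sigma_x = c(0.5, 1.5),
               sigma_y = c(0.5, 1.5), q = c(0, 0.5), alpha = c(0, 90),
               b = c(-0.02, 0.05), r_max_meanlog = log(1.0), r_max_sdlog = 0.4,
               noise_sd = 0.25),
    pv  = list(sigma_dir = c(50, 140), sigma_x = c(1.5, 3.5),
               sigma_y = c(1.5, 3.5), q = c(0.3, 1), alpha = c(0, 90),
               b = c(-0.02, 0.05), r_max_meanlog = log(0.8), r_max_sdlog = 0.4,
               noise_sd = 0.25)
  )
}

check_profile <- function(prof) {
  for (nm in c("sigma_dir", "sigma_x", "sigma_y", "q", "alpha", "b")) {
    rng <- prof[[nm]]
    if (length(rng) != 2 || rng[1] > rng[2])
      stop("invalid bounds for '", nm, "': low > high")
  }
  invisible(TRUE)
}

#' Generate ground-truth cells
#'
#' Samples PV+ and pyramidal cells with 3-D positions (x, y in a 350 um field
#' of view; z on 8 imaging planes 10 um apart) and ground-truth tuning
#' parameters drawn from per-class profiles.
#'
#' @param n_pv,n_pyr Cell counts (>= 0).
#' @param ensemble The [stimulus_ensemble()] (sets the SF/TF preference range).
#' @param profiles Per-class sampling profiles
#'   (default [default_selectivity_profiles()]).
#' @param seed Integer seed.
#' @return A data.table, one row per cell: `cell_id`, `cell_class`
#'   (`"pv"`/`"pyr"`), `x`, `y`, `z`, `plane`, the 9 tuning parameters,
#'   `noise_sd`.
#' @export
gen_cells <- function(n_pv, n_pyr, ensemble = stimulus_ensemble(),
                      profiles = default_selectivity_profiles(),
                      seed = 1L) {
  stopifnot(n_pv >= 0, n_pyr >= 0)
  lapply(profiles, check_profile)
  set.seed(seed)
  n <- n_pv + n_pyr
  cls <- rep(c("pv", "pyr"), c(n_pv, n_pyr))
  sf_hi <- max(sf_octaves(ensemble$spatial_freqs, ensemble))
  tf_hi <- max(tf_octaves(ensemble$temporal_freqs, ensemble))
  draw <- function(cell_class) {
    pr <- profiles[[cell_class]]
    u <- function(rng) stats::runif(1, rng[1], rng[2])
    data.table::data.table(
      b = u(pr$b),
      r_max = stats::rlnorm(1, pr$r_max_meanlog, pr$r_max_sdlog),
      sf_pref = stats::runif(1, 0, sf_hi),
      tf_pref = stats::runif(1, 0, tf_hi),
      alpha = u(pr$alpha),
      sigma_x = u(pr$sigma_x), sigma_y = u(pr$sigma_y),
      sigma_dir = u(pr$sigma_dir), q = u(pr$q),
      theta_pref = stats::runif(1, 0, 360),
      noise_sd = pr$noise_sd)
  }
  params <- data.table::rbindlist(lapply(cls, draw))
  plane <- sample.int(8, n, replace = TRUE)
  cells <- data.table::data.table(
    cell_id = seq_len(n), cell_class = cls,
    x = stats::runif(n, 0, 350), y = stats::runif(n, 0, 350),
    z = (plane - 1) * 10, plane = plane)
  cbind(cells, params)
}

cell_params <- function(cell_row) {
  do.call(tuning_params, as.list(cell_row[, c(
    "b", "r_max", "sf_pref", "tf_pref", "alpha", "sigma_x", "sigma_y",
    "sigma_dir", "q", "theta_pref")]))
}

#' Generate trial-resolved dF/F tensors
#'
#' Builds the forward model for every cell (baseline during the stationary
#' phase, tuning-model response during the moving phase), convolves the
#' stimulus-locked component with a causal single-exponential calcium kernel,
#' and adds i.i.d. Gaussian frame noise.
#'
#' @param cells Output of [gen_cells()].
#' @param ensemble The [stimulus_ensemble()].
#' @param n_rep Repeats (imaging segments) per stimulus, >= 2.
#' @param seed Integer seed.
#' @param calcium_tau Indicator decay time constant, seconds (default 0.7);
#'   `kernel = "none"` disables the convolution (traces then equal the
#'   noiseless forward model plus noise).
#' @param kernel `"exp"` or `"none"`.
#' @return 4-D array `f[stim, rep, frame, cell]` with the ensemble attached as
#'   attribute `"ensemble"`.
#' @export
gen_trials <- function(cells, ensemble = stimulus_ensemble(), n_rep = 8,
                       seed = 1L, calcium_tau = 0.7,
                       kernel = c("exp", "none")) {
  stopifnot(n_rep >= 2)
  kernel <- match.arg(kernel)
  set.seed(seed)
  nf <- ensemble$n_frames
  mov <- seq(ensemble$moving_window[1], ensemble$moving_window[2])
  k <- if (kernel == "exp") {
    kk <- exp(-(seq_len(nf) - 1) / (calcium_tau * ensemble$volume_rate))
    kk / sum(kk)
  } else c(1, rep(0, nf - 1))
  f <- array(0, dim = c(ensemble$n_stim, n_rep, nf, nrow(cells)))
  for (ci in seq_len(nrow(cells))) {
    row <- as.data.frame(cells)[ci, ]
    p <- cell_params(row)
    pred <- predict_ensemble(p, ensemble)
    drive <- matrix(0, ensemble$n_stim, nf)
    drive[, mov] <- pred - p$b
    conv <- t(apply(drive, 1, function(d) {
      stats::convolve(d, rev(k), type = "open")[seq_len(nf)]
    }))
    mean_trace <- conv + p$b
    noise <- array(stats::rnorm(ensemble$n_stim * n_rep * nf,
                                sd = row$noise_sd),
                   dim = c(ensemble$n_stim, n_rep, nf))
    f[, , , ci] <- aperm(array(mean_trace, dim = c(ensemble$n_stim, nf, n_rep)),
                         c(1, 3, 2)) + noise
  }
  attr(f, "ensemble") <- ensemble
  f
}

#' Default connectivity generator parameters
#'
#' @param n_pairs Number of tested PV/pyramidal pairs.
#' @param rates Category probabilities (reciprocal, IPSP-only, EPSP-only,
#'   unconnected); defaults to the observed 64/15/9/12 percent split.
#' @param amp_meanlog10,amp_sdlog10 Mean and SD of log10 PSP amplitude (mV).
#' @param rho_target Target Pearson correlation between response similarity
#'   and log10 amplitude, in (-1, 1).
#' @param reciprocal_rho Target correlation between log10 EPSP and log10 IPSP
#'   of reciprocally connected pairs (shared latent strength + shared
#'   slice-quality offset).
#' @param offset_frac Fraction of log-amplitude variance contributed by the
#'   per-PV-cell slice-quality offset.
#' @export
connectivity_params <- function(n_pairs = 138,
                                rates = c(recip = 0.64, ipsp_only = 0.15,
                                          epsp_only = 0.09, none = 0.12),
                                amp_meanlog10 = -0.3, amp_sdlog10 = 0.45,
                                rho_target = 0.43, reciprocal_rho = 0.6,
                                offset_frac = 0.2) {
  if (abs(sum(rates) - 1) > 1e-8) stop("category rates must sum to 1")
  if (rho_target <= -1 || rho_target >= 1)
    stop("rho_target must lie in (-1, 1)")
  list(n_pairs = n_pairs, rates = rates, amp_meanlog10 = amp_meanlog10,
       amp_sdlog10 = amp_sdlog10, rho_target = rho_target,
       reciprocal_rho = reciprocal_rho, offset_frac = offset_frac)
}

#' Generate directed synaptic connections for PV/pyramidal pairs
#'
#' Samples tested pairs, assigns each a connection category from the rate
#' table, and draws log10 amplitudes as
#' `beta * similarity + cell offset + shared latent + residual`, with `beta`
#' set so the realized similarity-log-amplitude correlation matches
#' `rho_target`, a per-PV-cell Gaussian "slice quality" offset shared by all of
#' that cell's connections, and a latent strength term shared within a
#' reciprocal pair so log-EPSP and log-IPSP are positively correlated.
#'
#' @param cells Output of [gen_cells()] (needs both classes).
#' @param trials Output of [gen_trials()] for the same cells (used to compute
#'   response similarity of each pair).
#' @param params [connectivity_params()].
#' @param seed Integer seed.
#' @return data.table, one row per directed tested pair: `pre_id`, `post_id`,
#'   `direction` (`"pv_pyr"` = IPSP, `"pyr_pv"` = EPSP), `connected`,
#'   `amplitude_mV` (NA when unconnected), `tau_r`, `tau_d`, `p`, `ppr`,
#'   `distance_um`, `similarity`.
#' @export
gen_connections <- function(cells, trials, params = connectivity_params(),
                            seed = 1L) {
  set.seed(seed)
  cells <- as.data.frame(cells)
  pv_ids <- cells$cell_id[cells$cell_class == "pv"]
  pyr_ids <- cells$cell_id[cells$cell_class == "pyr"]
  if (!length(pv_ids) || !length(pyr_ids))
    stop("need at least one PV and one pyramidal cell")
  combos <- expand.grid(pv = pv_ids, pyr = pyr_ids)
  np <- min(params$n_pairs, nrow(combos))
  pick <- combos[sample.int(nrow(combos), np), ]
  cat_lv <- c("recip", "ipsp_only", "epsp_only", "none")
  category <- cat_lv[apply(stats::rmultinom(np, 1, params$rates), 2,
                           which.max)]

  ## trial-average response vectors per cell, computed once (cells x features)
  ravg <- colMeans(aperm(trials, c(2, 1, 3, 4)))   # [stim, frame, cell]
  rmat <- matrix(ravg, ncol = dim(trials)[4])
  colnames(rmat) <- as.character(seq_len(dim(trials)[4]))
  sim <- vapply(seq_len(np), function(k) {
    cosine(rmat[, as.character(match(pick$pv[k], cells$cell_id))],
           rmat[, as.character(match(pick$pyr[k], cells$cell_id))])
  }, numeric(1))

  sig_t <- params$amp_sdlog10
  rho <- params$rho_target
  sig_s <- stats::sd(sim)
  shared_frac <- max(params$reciprocal_rho, rho^2)  # shared >= similarity part
  var_off <- params$offset_frac * sig_t^2
  var_lat <- max(0, (shared_frac - rho^2) * sig_t^2 - var_off)
  var_res <- max(1e-12, (1 - shared_frac) * sig_t^2)

  offset <- stats::rnorm(length(pv_ids), 0, sqrt(var_off))
  names(offset) <- as.character(pv_ids)
  latent <- stats::rnorm(np, 0, sqrt(var_lat))

  ## beta is calibrated against the realized noise draws so the realized
  ## similarity / log-amplitude correlation equals rho_target (per side);
  ## per-cell offsets cluster over PV cells, so a closed-form beta based on
  ## independence would leave cluster-level bias in the realized correlation.
  s_c <- sim - mean(sim)
  solve_beta <- function(noise) {
    if (sig_s == 0) return(0)
    f <- function(b) stats::cor(b * s_c + noise, s_c) - rho
    hi <- 50 * sig_t / sig_s
    tryCatch(stats::uniroot(f, c(-hi, hi))$root,
             error = function(e) rho * sig_t / sig_s)
  }
  noise_i <- offset[as.character(pick$pv)] + latent +
    stats::rnorm(np, 0, sqrt(var_res))
  noise_e <- offset[as.character(pick$pv)] + latent +
    stats::rnorm(np, 0, sqrt(var_res))
  logamp_i <- params$amp_meanlog10 + solve_beta(noise_i) * s_c + noise_i
  logamp_e <- params$amp_meanlog10 + solve_beta(noise_e) * s_c + noise_e

  xyz <- cells[, c("x", "y", "z")]
  dist_um <- sqrt(rowSums((xyz[match(pick$pv, cells$cell_id), ] -
                           xyz[match(pick$pyr, cells$cell_id), ])^2))

  has_i <- category %in% c("recip", "ipsp_only")
  has_e <- category %in% c("recip", "epsp_only")
  mk <- function(dirn, conn, la) {
    data.table::data.table(
      pre_id = if (dirn == "pv_pyr") pick$pv else pick$pyr,
      post_id = if (dirn == "pv_pyr") pick$pyr else pick$pv,
      direction = dirn, connected = conn,
      amplitude_mV = ifelse(conn, 10^la, NA_real_),
      tau_r = stats::rlnorm(np, log(1.5), 0.3),
      tau_d = stats::rlnorm(np, log(12), 0.35),
      p = stats::runif(np, 1, 3),
      ppr = stats::rlnorm(np, log(0.8), 0.25),
      distance_um = dist_um, similarity = sim, pair = seq_len(np))
  }
  out <- rbind(mk("pv_pyr", has_i, logamp_i), mk("pyr_pv", has_e, logamp_e))
  out[order(out$pair, out$direction, decreasing = c(FALSE, TRUE),
            method = "radix"), ]
}

#' Synthetic postsynaptic-potential trace
#'
#' Noiseless kernel `V(t) = Vmax (1 - exp(-t/tau_r))^p exp(-t/tau_d)` scaled
#' so the extremum magnitude equals `amplitude`; IPSPs are sign-flipped.
#' Multiple presynaptic spikes superpose linearly.
#'
#' @param amplitude Peak magnitude(s) in mV (> 0); recycled over spikes.
#' @param tau_r,tau_d Rise and decay time constants, ms (> 0).
#' @param p Onset shape exponent.
#' @param polarity `"epsp"` or `"ipsp"`.
#' @param noise_sd Gaussian noise SD in mV.
#' @param dt Sample interval, ms (> 0).
#' @param seed Seed for the noise.
#' @param spike_times Presynaptic spike times, ms.
#' @param duration Record length, ms.
#' @return A `psp_trace`: list with `time`, `voltage`, `spike_times`,
#'   `polarity`, `dt`.
#' @export
gen_psp_trace <- function(amplitude, tau_r, tau_d, p = 2,
                          polarity = c("epsp", "ipsp"), noise_sd = 0,
                          dt = 0.1, seed = 1L, spike_times = 10,
                          duration = 120) {
  polarity <- match.arg(polarity)
  if (dt <= 0) stop("dt must be positive")
  stopifnot(all(amplitude > 0), tau_r > 0, tau_d > 0)
  amplitude <- rep_len(amplitude, length(spike_times))
  tgrid <- seq(0, duration, by = dt)
  shape <- function(t) ifelse(t <= 0, 0, (1 - exp(-t / tau_r))^p *
                                exp(-t / tau_d))
  v <- numeric(length(tgrid))
  sgn <- if (polarity == "ipsp") -1 else 1
  for (s in seq_along(spike_times)) {
    kern <- shape(tgrid - spike_times[s])
    pk <- max(kern)  # normalize to the realized grid peak, not the
                     # continuous optimum, so the trace extremum is exact
    if (pk > 0) v <- v + sgn * amplitude[s] / pk * kern
  }
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  out <- list(time = tgrid, voltage = v, spike_times = spike_times,
              polarity = polarity, dt = dt)
  class(out) <- "psp_trace"
  out
}

#' Generate a complete synthetic paired dataset
#'
#' Convenience wrapper chaining [gen_cells()], [gen_trials()] and
#' [gen_connections()] from a single seed (fanned out deterministically to the
#' three stages).
#'
#' @param n_pv,n_pyr Cell counts.
#' @param ensemble The [stimulus_ensemble()].
#' @param n_rep Repeats per stimulus.
#' @param conn_params [connectivity_params()].
#' @param seed Master seed.
#' @param ... Passed to [gen_trials()].
#' @return List with `cells`, `trials`, `connections`, `ensemble`, `seed`.
#' @export
gen_dataset <- function(n_pv = 10, n_pyr = 40,
                        ensemble = stimulus_ensemble(), n_rep = 8,
                        conn_params = connectivity_params(), seed = 1L,
                        ...) {
  seeds <- derive_seeds(seed, 3)
  cells <- gen_cells(n_pv, n_pyr, ensemble, seed = seeds[1])
  trials <- gen_trials(cells, ensemble, n_rep = n_rep, seed = seeds[2], ...)
  conns <- gen_connections(cells, trials, conn_params, seed = seeds[3])
  list(cells = cells, trials = trials, connections = conns,
       ensemble = ensemble, seed = seed)
}

## Deterministic seed fan-out; keeps derived seeds inside 32-bit range.
derive_seeds <- function(seed, n) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * seq_len(n)) %% 2147483647)
}
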