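## PSP quantification and connectivity statistics: amplitudes, paired-pulse
## ratio, multiexponential kinetics, geometric-mean normalization and the
## within-cell permutation test, partial correlation, and the logistic
## connection-probability model.

#' PSP amplitude from a mean postsynaptic trace
#'
#' Subtracts the baseline (mean voltage in the 5 ms preceding the presynaptic
#' spike) and returns the post-spike extremum: minimum for IPSPs, maximum for
#' EPSPs. When a second, overlapping PSP follows, the search window is cut at
#' its onset so the first component's amplitude is recovered.
#'
#' @param trace A `psp_trace` (see [gen_psp_trace()]): `time`, `voltage`,
#'   `spike_times`, `polarity`.
#' @param second_psp_onset Optional time (ms) at which a second PSP begins.
#' @param baseline_ms Baseline window before the spike (default 5 ms).
#' @return Amplitude in mV (>= 0).
#' @export
psp_amplitude <- function(trace, second_psp_onset = NULL, baseline_ms = 5) {
  t0 <- trace$spike_times[1]
  bl_idx <- trace$time >= t0 - baseline_ms & trace$time < t0
  baseline <- if (any(bl_idx)) mean(trace$voltage[bl_idx]) else 0
  hi <- if (is.null(second_psp_onset)) max(trace$time) else second_psp_onset
  post <- trace$time >= t0 & trace$time <= hi
  if (!any(post)) stop("no post-spike samples in trace")
  v <- trace$voltage[post] - baseline
  if (identical(trace$polarity, "ipsp")) abs(min(v)) else max(v)
}

#' Paired-pulse ratio
#'
#' Amplitude of the response to the second of two presynaptic spikes (baseline
#' re-measured just before the second spike) divided by the first-pulse
#' amplitude.
#'
#' @param trace A `psp_trace` with >= 2 spike times.
#' @param baseline_ms Per-pulse baseline window, ms.
#' @return `amp2 / amp1`.
#' @export
paired_pulse_ratio <- function(trace, baseline_ms = 5) {
  if (length(trace$spike_times) < 2)
    stop("paired-pulse ratio requires at least two presynaptic spikes")
  t1 <- trace$spike_times[1]; t2 <- trace$spike_times[2]
  amp1 <- psp_amplitude(trace, second_psp_onset = t2,
                        baseline_ms = baseline_ms)
  bl2_idx <- trace$time >= t2 - baseline_ms & trace$time < t2
  baseline2 <- mean(trace$voltage[bl2_idx])
  t3 <- if (length(trace$spike_times) >= 3) trace$spike_times[3]
        else max(trace$time)
  post <- trace$time >= t2 & trace$time <= t3
  v <- trace$voltage[post] - baseline2
  amp2 <- if (identical(trace$polarity, "ipsp")) abs(min(v)) else max(v)
  amp2 / amp1
}

#' Multiexponential PSP kinetics fit
#'
#' Least-squares fit of `V(t) = Vmax (1 - exp(-t/tau_r))^p exp(-t/tau_d)` to
#' a baseline-subtracted mean PSP, excluding the first `skip_initial` ms after
#' the presynaptic spike (stimulation artefact), over multiple seeded starting
#' points, keeping the best SSE.
#'
#' @param trace A `psp_trace`.
#' @param n_restarts Number of optimizer starts (default 100).
#' @param skip_initial Initial response window to exclude, ms (default 5).
#' @param seed Integer seed.
#' @return List: `v_max`, `tau_r`, `tau_d`, `p`, `sse`, `converged`.
#' @export
fit_psp_kinetics <- function(trace, n_restarts = 100, skip_initial = 5,
                             seed = 1L) {
  t0 <- trace$spike_times[1]
  sel <- trace$time >= t0 + skip_initial
  tt <- trace$time[sel] - t0
  sgn <- if (identical(trace$polarity, "ipsp")) -1 else 1
  vv <- sgn * trace$voltage[sel]
  model <- function(par) {
    par["v_max"] * (1 - exp(-tt / par["tau_r"]))^par["p"] *
      exp(-tt / par["tau_d"])
  }
  obj <- function(par) sum((vv - model(par))^2)
  lower <- c(v_max = 1e-4, tau_r = 0.05, tau_d = 0.5, p = 0.5)
  upper <- c(v_max = 50, tau_r = 20, tau_d = 200, p = 6)
  set.seed(seed)
  best <- NULL
  for (k in seq_len(n_restarts)) {
    start <- if (k == 1) {
      c(v_max = max(vv, 0.1), tau_r = 2, tau_d = 20, p = 2)
    } else {
      lower * exp(stats::runif(4) * log(upper / lower))
    }
    ans <- tryCatch(
      stats::nlminb(start, obj, lower = lower, upper = upper,
                    control = list(iter.max = 500)),
      error = function(e) NULL)
    if (!is.null(ans) && (is.null(best) || ans$objective < best$objective))
      best <- ans
  }
  if (is.null(best))
    return(list(v_max = NA, tau_r = NA, tau_d = NA, p = NA, sse = Inf,
                converged = FALSE))
  out <- as.list(best$par)
  ## pure-noise guard: a fit that explains no variance is flagged
  tot <- sum((vv - mean(vv))^2)
  out$sse <- best$objective
  out$converged <- best$convergence == 0 && best$objective < tot
  out
}

#' Correlation of reciprocal EPSP and IPSP magnitudes
#'
#' Pearson correlation of log10 EPSP vs log10 IPSP amplitude over reciprocally
#' connected PV/pyramidal pairs.
#'
#' @param connections Connection table ([gen_connections()] format): needs
#'   `pair`, `direction`, `connected`, `amplitude_mV`.
#' @return List `r`, `p_value`, `n`.
#' @export
reciprocal_correlation <- function(connections) {
  rec <- reciprocal_table(connections)
  if (nrow(rec) < 3) stop("need >= 3 reciprocally connected pairs")
  ct <- stats::cor.test(log10(rec$ipsp), log10(rec$epsp))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(rec))
}

## One row per reciprocally connected pair: pv_id, ipsp, epsp, similarity.
reciprocal_table <- function(connections) {
  cx <- as.data.frame(connections)
  ip <- cx[cx$direction == "pv_pyr" & cx$connected, ]
  ep <- cx[cx$direction == "pyr_pv" & cx$connected, ]
  m <- merge(ip[, c("pair", "pre_id", "amplitude_mV", "similarity")],
             ep[, c("pair", "amplitude_mV")], by = "pair",
             suffixes = c("_i", "_e"))
  data.frame(pair = m$pair, pv_id = m$pre_id, ipsp = m$amplitude_mV_i,
             epsp = m$amplitude_mV_e, similarity = m$similarity)
}

#' Within-presynaptic-cell normalization of PSP magnitudes
#'
#' For each PV cell contributing at least `min_per_cell` reciprocal pairs,
#' divides each log10 amplitude by the cell's mean log10 amplitude (the ratio
#' of logs; equivalent to normalizing amplitudes by their geometric mean).
#' This removes per-recording ("slice quality") multiplicative offsets.
#' Cells whose mean log amplitude is within `eps` of zero are excluded with a
#' warning (the ratio is unstable there).
#'
#' @param values Positive amplitudes (mV).
#' @param group Grouping factor (PV cell id).
#' @param mean_kind `"geometric"` (ratio of log10s, as printed) or
#'   `"arithmetic"` (amplitudes divided by their arithmetic mean).
#' @param min_per_cell Minimum pairs per cell (default 2).
#' @param eps Exclusion threshold on |mean log10| (default 0.05).
#' @return data.frame `group`, `value`, `normalized` (excluded cells dropped).
#' @export
normalize_within_presyn <- function(values, group,
                                    mean_kind = c("geometric", "arithmetic"),
                                    min_per_cell = 2, eps = 0.05) {
  mean_kind <- match.arg(mean_kind)
  stopifnot(all(values > 0), length(values) == length(group))
  df <- data.frame(group = as.character(group), value = values)
  counts <- table(df$group)
  df <- df[df$group %in% names(counts)[counts >= min_per_cell], ]
  out <- lapply(split(df, df$group), function(d) {
    if (mean_kind == "geometric") {
      ml <- mean(log10(d$value))
      if (abs(ml) < eps) {
        warning("group '", d$group[1],
                "' excluded: mean log10 amplitude within eps of 0")
        return(NULL)
      }
      d$normalized <- log10(d$value) / ml
    } else {
      d$normalized <- d$value / mean(d$value)
    }
    d
  })
  out <- out[!vapply(out, is.null, logical(1))]
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aligned normalized reciprocal amplitudes
#'
#' Applies [normalize_within_presyn()] to the IPSP and EPSP magnitudes of a
#' reciprocal-pair table, keeping only PV cells with at least `min_per_cell`
#' pairs and dropping a cell entirely if either side is excluded, so the
#' returned vectors stay pair-aligned.
#'
#' @param rec data.frame with `pv_id`, `ipsp`, `epsp` (one row per
#'   reciprocally connected pair).
#' @param min_per_cell Minimum pairs per PV cell (default 2).
#' @param eps Mean-log exclusion threshold (see [normalize_within_presyn()]).
#' @return data.frame `pv_id`, `ipsp_norm`, `epsp_norm`.
#' @export
normalized_reciprocal <- function(rec, min_per_cell = 2, eps = 0.05) {
  counts <- table(rec$pv_id)
  rec <- rec[rec$pv_id %in% names(counts)[counts >= min_per_cell], ]
  out <- lapply(split(rec, rec$pv_id), function(d) {
    mi <- mean(log10(d$ipsp)); me <- mean(log10(d$epsp))
    if (abs(mi) < eps || abs(me) < eps) return(NULL)
    data.frame(pv_id = d$pv_id, ipsp_norm = log10(d$ipsp) / mi,
               epsp_norm = log10(d$epsp) / me)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Within-cell permutation test for normalized EPSP/IPSP correlation
#'
#' Computes the Pearson correlation `R_EI` of normalized IPSP and EPSP
#' magnitudes over reciprocal pairs, then randomly permutes the IPSP values
#' within each PV cell (destroying the pairing while preserving each cell's
#' amplitude set) and re-computes the correlation. The two-sided p value is
#' the exact proportion of shuffles whose |R| meets or exceeds the observed
#' |R| (ties count as exceedances; no add-one smoothing).
#'
#' @param ipsp_norm,epsp_norm Normalized magnitudes, one per reciprocal pair.
#' @param group PV-cell id per pair.
#' @param n_shuffles Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return List `r`, `p_value`, `n_pairs`, `n_cells`.
#' @export
permutation_test <- function(ipsp_norm, epsp_norm, group,
                             n_shuffles = 10000, seed = 1L) {
  stopifnot(length(ipsp_norm) == length(epsp_norm),
            length(group) == length(ipsp_norm))
  idx_by_g <- split(seq_along(group), as.character(group))
  sizes <- lengths(idx_by_g)
  if (sum(sizes >= 2) < 2)
    stop("need >= 2 PV cells with >= 2 pairs each for within-cell shuffling")
  if (all(sizes < 2)) stop("no group permits a non-trivial shuffle")
  r_obs <- suppressWarnings(stats::cor(ipsp_norm, epsp_norm))
  if (is.na(r_obs)) {
    ## permutation-invariant (constant) data: every shuffle ties the observed
    return(list(r = NA_real_, p_value = 1, n_pairs = length(group),
                n_cells = length(idx_by_g)))
  }
  set.seed(seed)
  ## shuffled-index matrix (n x n_shuffles), permuting within groups only
  n <- length(group)
  idx <- matrix(seq_len(n), n, n_shuffles)
  for (ix in idx_by_g) {
    if (length(ix) > 1)
      idx[ix, ] <- vapply(seq_len(n_shuffles), function(s) sample(ix),
                          integer(length(ix)))
  }
  X <- matrix(ipsp_norm[idx], n, n_shuffles)
  ## each column of X holds the same values, so means/sds are unchanged
  e <- epsp_norm - mean(epsp_norm)
  r_sh <- as.vector(crossprod(X, e)) /
    ((n - 1) * stats::sd(ipsp_norm) * stats::sd(epsp_norm))
  exceed <- sum(abs(r_sh) >= abs(r_obs))
  list(r = r_obs, p_value = exceed / n_shuffles,
       n_pairs = length(group), n_cells = length(idx_by_g))
}

#' Partial correlation controlling for a covariate
#'
#' Pearson correlation of the residuals of `x ~ covariate` and
#' `y ~ covariate` (ordinary least squares), with the two-sided p value of
#' that correlation. A constant covariate reduces to the plain correlation.
#'
#' @param x,y Numeric vectors (>= 4 values).
#' @param covariate Numeric vector, e.g. inter-cell distance.
#' @return List `r`, `p_value`, `n`.
#' @export
partial_correlation <- function(x, y, covariate) {
  stopifnot(length(x) == length(y), length(x) == length(covariate),
            length(x) >= 4)
  if (stats::sd(covariate) == 0) {
    message("constant covariate; returning plain correlation")
    rx <- x - mean(x); ry <- y - mean(y)
  } else {
    rx <- stats::residuals(stats::lm(x ~ covariate))
    ry <- stats::residuals(stats::lm(y ~ covariate))
  }
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12)
    stop("residuals have (near-)zero variance; partial correlation undefined")
  ct <- stats::cor.test(rx, ry)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Logistic model of connection probability vs similarity
#'
#' Maximum-likelihood logistic regression of the connected/unconnected flag on
#' response similarity, reporting the slope and its Wald p value. Complete or
#' quasi-complete separation is detected and flagged (slope and p are then
#' unreliable/undefined).
#'
#' @param similarity Numeric predictor.
#' @param connected Logical (or 0/1) outcome; both classes must be present.
#' @return List `slope`, `intercept`, `p_value`, `separation`, `n`.
#' @export
connection_probability_model <- function(similarity, connected) {
  connected <- as.logical(connected)
  stopifnot(length(similarity) == length(connected))
  if (!any(connected) || all(connected))
    stop("both connected and unconnected pairs are required")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(connected ~ similarity, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  separation <- sep_warn || abs(co["similarity", "Estimate"]) > 50
  list(slope = co["similarity", "Estimate"],
       intercept = co["(Intercept)", "Estimate"],
       p_value = if (separation) NA_real_ else co["similarity", "Pr(>|z|)"],
       separation = separation, n = length(connected))
}

#' Similarity-strength correlation for one connection direction
#'
#' Pearson correlation between response similarity and log10 PSP amplitude
#' over connected pairs of the given direction, the statistic relating in
#' vivo co-activity to synaptic weight.
#'
#' @param connections Connection table.
#' @param direction `"pv_pyr"` (IPSP) or `"pyr_pv"` (EPSP).
#' @return List `r`, `p_value`, `n`.
#' @export
similarity_strength_correlation <- function(connections,
                                            direction = c("pv_pyr",
                                                          "pyr_pv")) {
  direction <- match.arg(direction)
  cx <- as.data.frame(connections)
  cx <- cx[cx$direction == direction & cx$connected &
             is.finite(cx$similarity), ]
  ct <- stats::cor.test(cx$similarity, log10(cx$amplitude_mV))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(cx))
}
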