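## Responsiveness, selectivity, and the constrained direction x SF/TF tuning
## model. All SF/TF coordinates are in octaves (log2 units relative to the
## lowest value probed); directions are in degrees, converted to radians only
## inside the circular kernel.

#' Tuning model parameters
#'
#' The 9-parameter description of a cell's joint direction, spatial-frequency
#' and temporal-frequency tuning: a double Gaussian in direction space
#' (preferred and null direction) multiplied by a 2-D Gaussian with arbitrary
#' orientation in log-SF/log-TF space, plus an additive offset.
#'
#' @param b Response offset (dF/F units).
#' @param r_max Response at the preferred direction, SF and TF (above offset).
#' @param sf_pref,tf_pref Preferred SF and TF in octaves.
#' @param alpha Orientation of the SF/TF Gaussian, degrees in [0, 90].
#' @param sigma_x,sigma_y SF/TF tuning widths, octaves in [0.25, 4].
#' @param sigma_dir Direction tuning width, degrees in [0, 180].
#' @param q Relative amplitude of the null-direction response, in [0, 1].
#' @param theta_pref Preferred direction, degrees in [0, 360).
#' @return A `tuning_params` list.
#' @export
tuning_params <- function(b = 0, r_max = 1, sf_pref = 2, tf_pref = 2,
                          alpha = 0, sigma_x = 1, sigma_y = 1,
                          sigma_dir = 30, q = 0, theta_pref = 0) {
  p <- list(b = b, r_max = r_max, sf_pref = sf_pref, tf_pref = tf_pref,
            alpha = alpha, sigma_x = sigma_x, sigma_y = sigma_y,
            sigma_dir = sigma_dir, q = q, theta_pref = theta_pref)
  stopifnot(all(vapply(p, is.numeric, logical(1))))
  class(p) <- "tuning_params"
  p
}

.param_names <- c("b", "r_max", "sf_pref", "tf_pref", "alpha",
                  "sigma_x", "sigma_y", "sigma_dir", "q", "theta_pref")

## Squared wrapped angular difference, radians^2; maps any angle onto [0, pi]
## before squaring. Equivalent to min(|t|, |t + 2pi|, |t - 2pi|)^2 on
## [-2pi, 2pi] but valid for arbitrary inputs.
wrap_sq <- function(theta) {
  d <- abs(theta) %% (2 * pi)
  (pmin(d, 2 * pi - d))^2
}

#' Predicted response of the tuning model
#'
#' Evaluates the constrained direction x SF/TF model at given stimuli. The
#' direction term is `exp(-h(dtheta) / (2 sigma_dir^2))` with `h` the squared
#' wrapped angular difference (radians) and a second lobe of relative
#' amplitude `q` at the null direction; the SF/TF term is a bivariate Gaussian
#' in octave coordinates rotated by `alpha`.
#'
#' @param params A [tuning_params()] object.
#' @param direction Stimulus direction(s), degrees.
#' @param sf_oct,tf_oct Stimulus SF and TF in octaves.
#' @return Predicted response(s), same length as the stimulus vectors.
#' @export
predict_response <- function(params, direction, sf_oct, tf_oct) {
  a <- params$alpha * pi / 180
  dsf <- sf_oct - params$sf_pref
  dtf <- tf_oct - params$tf_pref
  x <- cos(a) * dsf + sin(a) * dtf
  y <- -sin(a) * dsf + cos(a) * dtf
  sd_rad <- max(params$sigma_dir, 1e-6) * pi / 180
  dth <- (direction - params$theta_pref) * pi / 180
  dir_term <- exp(-wrap_sq(dth) / (2 * sd_rad^2)) +
    params$q * exp(-wrap_sq(dth + pi) / (2 * sd_rad^2))
  freq_term <- exp(-(x^2 / (2 * params$sigma_x^2) +
                     y^2 / (2 * params$sigma_y^2)))
  params$r_max * dir_term * freq_term + params$b
}

## Predict on the ensemble's stimulus table (vector over stimulus types).
predict_ensemble <- function(params, ensemble) {
  st <- ensemble$stim
  predict_response(params, st$direction,
                   sf_octaves(st$sf, ensemble), tf_octaves(st$tf, ensemble))
}

#' Fraction of variance explained by the visual stimulus
#'
#' `R^2 = 1 - Var(f - fbar) / Var(f)` where `f(i,j,t)` is the single-trial
#' dF/F and `fbar(i,t)` the trial average, pooling all stimuli, repeats and
#' frames. Used as the responsiveness statistic: cells with R^2 > 0.15 are
#' classified responsive (more stringent than a one-way ANOVA at p < 0.05).
#'
#' @param f 3-D array `[stim, rep, frame]` of dF/F for one cell.
#' @return R^2 (can be negative for anti-reliable cells); `NA` with a warning
#'   if the trace has zero variance.
#' @export
variance_explained <- function(f) {
  stopifnot(length(dim(f)) == 3, dim(f)[2] >= 2)
  vtot <- stats::var(as.vector(f))
  if (!is.finite(vtot) || vtot == 0) {
    warning("zero total variance; responsiveness undefined")
    return(NA_real_)
  }
  fbar <- apply(f, c(1, 3), mean)                 # [stim, frame]
  resid <- sweep(f, c(1, 3), fbar, "-")
  1 - stats::var(as.vector(resid)) / vtot
}

#' @rdname variance_explained
#' @param threshold Responsiveness cutoff on R^2 (default 0.15).
#' @export
classify_responsive <- function(f, threshold = 0.15) {
  r2 <- variance_explained(f)
  isTRUE(r2 > threshold)
}

#' Trial-average responses
#'
#' Computes `r(i,t)`, the mean over repeats for each stimulus and frame, and
#' `rbar(i)`, the mean of `r(i,t)` over the moving-phase frames `a..b`.
#'
#' @param f 3-D array `[stim, rep, frame]`.
#' @param moving_window Integer pair `c(a, b)` of moving-phase frames.
#' @return List with matrix `r` (`[stim, frame]`) and vector `rbar`.
#' @export
stimulus_means <- function(f, moving_window) {
  stopifnot(length(dim(f)) == 3)
  a <- moving_window[1]; b <- moving_window[2]
  stopifnot(a >= 1, a <= b, b <= dim(f)[3])
  r <- apply(f, c(1, 3), mean)
  list(r = r, rbar = rowMeans(r[, a:b, drop = FALSE]))
}

## Single-trial moving-phase means r(i,j): the quantities the tuning model is
## fit to.
trial_means <- function(f, moving_window) {
  a <- moving_window[1]; b <- moving_window[2]
  apply(f[, , a:b, drop = FALSE], c(1, 2), mean)
}

#' Selectivity as response skewness
#'
#' Population skewness (1/N moment estimators) of the per-stimulus mean
#' responses; highly selective cells respond to few stimuli and have strongly
#' positive skewness.
#'
#' @param rbar Vector of per-stimulus mean responses.
#' @return Skewness `m3 / m2^(3/2)`; error if the responses have no variance.
#' @export
selectivity_skewness <- function(rbar) {
  stopifnot(length(rbar) >= 3)
  m <- mean(rbar)
  m2 <- mean((rbar - m)^2)
  if (m2 == 0) stop("zero variance across stimuli; skewness undefined")
  mean((rbar - m)^3) / m2^1.5
}

## Parameter bounds for the constrained fit. SF/TF preferences are allowed
## within 1 octave of the probed range; r_max upper bound is 2*max(r_ij).
tuning_bounds <- function(ensemble, rij) {
  sf_rng <- range(sf_octaves(ensemble$spatial_freqs, ensemble))
  tf_rng <- range(tf_octaves(ensemble$temporal_freqs, ensemble))
  rmax_hi <- max(2 * max(rij), 1e-6)
  spread <- max(diff(range(rij)), 1e-3)
  list(
    lower = c(b = min(rij) - spread, r_max = 1e-6,
              sf_pref = sf_rng[1] - 1, tf_pref = tf_rng[1] - 1,
              alpha = 0, sigma_x = 0.25, sigma_y = 0.25,
              sigma_dir = 0, q = 0, theta_pref = 0),
    upper = c(b = max(rij) + spread, r_max = rmax_hi,
              sf_pref = sf_rng[2] + 1, tf_pref = tf_rng[2] + 1,
              alpha = 90, sigma_x = 4, sigma_y = 4,
              sigma_dir = 180, q = 1, theta_pref = 360)
  )
}

#' Fit the constrained tuning model
#'
#' Bound-constrained nonlinear least squares of the 9-parameter model to
#' single-trial moving-phase mean responses `r(i,j)`, minimizing
#' `sum_ij (r(i,j) - rhat(i))^2` by multi-start local optimization
#' (`nlminb`): one data-driven start (peak stimulus) plus `n_restarts - 1`
#' seeded draws inside the bounds, keeping the best SSE.
#'
#' @param f 3-D array `[stim, rep, frame]` of dF/F, or a precomputed
#'   `[stim, rep]` matrix of moving-phase means (then `moving_window` is
#'   ignored).
#' @param ensemble The [stimulus_ensemble()].
#' @param n_restarts Number of optimizer starts (default 50).
#' @param seed Integer seed controlling the restart draws.
#' @return A `tuning_fit`: list with `params` ([tuning_params()]), `sse`,
#'   `r2_fit`, `converged`, plus FWHM features via [fwhm_features()].
#' @export
fit_tuning <- function(f, ensemble, n_restarts = 50, seed = 1L) {
  rij <- if (length(dim(f)) == 3) trial_means(f, ensemble$moving_window) else f
  stopifnot(nrow(rij) == ensemble$n_stim)
  bnd <- tuning_bounds(ensemble, rij)
  st <- ensemble$stim
  dir_v <- st$direction
  sf_v <- sf_octaves(st$sf, ensemble)
  tf_v <- tf_octaves(st$tf, ensemble)
  ybar <- rowMeans(rij)
  nrep <- ncol(rij)

  obj <- function(p) {
    pr <- predict_response(as_params(p), dir_v, sf_v, tf_v)
    ## sum over reps of (r_ij - rhat_i)^2 decomposes; only the mean term
    ## depends on parameters, but keep the full SSE for reporting.
    sum(nrep * (ybar - pr)^2)
  }
  as_params <- function(p) {
    p <- as.list(p); names(p) <- .param_names; class(p) <- "tuning_params"; p
  }

  ## data-driven start: peak stimulus sets theta/SF/TF preference
  ipk <- which.max(ybar)
  start0 <- c(b = stats::median(rij), r_max = max(ybar) - stats::median(rij),
              sf_pref = sf_v[ipk], tf_pref = tf_v[ipk], alpha = 10,
              sigma_x = 1, sigma_y = 1, sigma_dir = 40, q = 0.3,
              theta_pref = dir_v[ipk])
  start0 <- pmin(pmax(start0, bnd$lower), bnd$upper)

  set.seed(seed)
  starts <- list(start0)
  for (k in seq_len(max(n_restarts - 1, 0))) {
    starts[[k + 1]] <- bnd$lower +
      stats::runif(10) * (bnd$upper - bnd$lower)
  }

  best <- NULL
  for (s in starts) {
    ans <- tryCatch(
      stats::nlminb(s, obj, lower = bnd$lower, upper = bnd$upper,
                    control = list(eval.max = 2000, iter.max = 1000)),
      error = function(e) NULL)
    if (is.null(ans)) next
    if (is.null(best) || ans$objective < best$objective) best <- ans
  }
  if (is.null(best)) {
    fit <- list(params = as_params(start0), sse = Inf, converged = FALSE)
    class(fit) <- "tuning_fit"
    return(fit)
  }
  params <- as_params(best$par)
  pr <- predict_response(params, dir_v, sf_v, tf_v)
  sse <- sum((rij - pr)^2)  # full SSE incl. within-stimulus trial variance
  fit <- list(params = params, sse = sse,
              sse_mean = best$objective,
              r2_fit = 1 - best$objective / max(sum(nrep * (ybar - mean(ybar))^2), 1e-300),
              converged = TRUE)
  class(fit) <- "tuning_fit"
  c(fit, fwhm_features(fit, ensemble)) -> out
  class(out) <- "tuning_fit"
  out
}

#' @export
print.tuning_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "tuning_fit: theta_pref=%.1f deg, SF_pref=%.2f oct, TF_pref=%.2f oct, sse=%.4g\n",
    p$theta_pref, p$sf_pref, p$tf_pref, x$sse))
  if (!is.null(x$fwhm_dir))
    cat(sprintf("  FWHM dir=%.1f deg SF=%.2f oct TF=%.2f oct; tuned: %s/%s/%s\n",
                x$fwhm_dir, x$fwhm_sf, x$fwhm_tf,
                x$tuned_dir, x$tuned_sf, x$tuned_tf))
  invisible(x)
}

#' Tuning-curve widths and tuned/untuned classification
#'
#' Direction FWHM is `2.355 * sigma_dir`. SF and TF FWHMs are measured from
#' the model curve evaluated on a dense log2 grid over 0.0025–2.56 cycles/deg
#' and 0.125–16 Hz (the other coordinates held at preference), as the width
#' between the outermost half-maximum crossings, with half maximum taken
#' above the offset `b`. Cells are untuned for direction if FWHM > 180 deg
#' and untuned for SF/TF if FWHM > 6 octaves.
#'
#' @param fit A `tuning_fit` (or a list with element `params`).
#' @param ensemble The [stimulus_ensemble()].
#' @param grid_step Evaluation grid step in octaves (default 0.05).
#' @return List: `fwhm_dir`, `fwhm_sf`, `fwhm_tf` (degrees / octaves),
#'   logical `tuned_dir`, `tuned_sf`, `tuned_tf`, and `fwhm_clipped_*` flags
#'   set when a curve never reaches half maximum inside the range.
#' @export
fwhm_features <- function(fit, ensemble, grid_step = 0.05) {
  p <- fit$params
  fwhm_dir <- 2.355 * p$sigma_dir

  range_sf <- sf_octaves(c(0.0025, 2.56), ensemble)
  range_tf <- tf_octaves(c(0.125, 16), ensemble)

  curve_fwhm <- function(grid, feature) {
    v <- switch(feature,
      sf = predict_response(p, rep(p$theta_pref, length(grid)), grid,
                            rep(p$tf_pref, length(grid))),
      tf = predict_response(p, rep(p$theta_pref, length(grid)),
                            rep(p$sf_pref, length(grid)), grid))
    rel <- v - p$b
    pk <- max(rel)
    if (pk <= 0) return(list(w = diff(range(grid)), clipped = TRUE))
    above <- rel >= pk / 2
    idx <- range(which(above))
    clipped <- above[1] || above[length(above)]
    list(w = grid[idx[2]] - grid[idx[1]], clipped = clipped)
  }
  gs <- seq(range_sf[1], range_sf[2], by = grid_step)
  gt <- seq(range_tf[1], range_tf[2], by = grid_step)
  sfw <- curve_fwhm(gs, "sf")
  tfw <- curve_fwhm(gt, "tf")

  list(fwhm_dir = fwhm_dir, fwhm_sf = sfw$w, fwhm_tf = tfw$w,
       tuned_dir = fwhm_dir <= 180, tuned_sf = sfw$w <= 6,
       tuned_tf = tfw$w <= 6,
       fwhm_clipped_sf = sfw$clipped, fwhm_clipped_tf = tfw$clipped)
}
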