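## Pairwise functional-similarity metrics between cells' visual responses.

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Total similarity of single-trial traces
#'
#' For each imaging segment (repeat) j, the cosine of the two cells'
#' single-trial dF/F traces flattened over stimuli and frames; the metric is
#' the mean over segments. Sensitive to trial-to-trial co-fluctuations.
#' Zero-norm segments are skipped with a message.
#'
#' @param f,fp 3-D arrays `[stim, rep, frame]` for the two cells (same shape).
#' @return Scalar in `[-1, 1]`.
#' @export
total_similarity <- function(f, fp) {
  stopifnot(identical(dim(f), dim(fp)))
  vals <- vapply(seq_len(dim(f)[2]), function(j) {
    cosine(as.vector(f[, j, ]), as.vector(fp[, j, ]))
  }, numeric(1))
  if (anyNA(vals)) message("total_similarity: skipping zero-norm segment(s)")
  mean(vals, na.rm = TRUE)
}

#' Response similarity of trial-average responses
#'
#' Cosine of the trial-average response tensors `r(i,t)` flattened over
#' stimuli and frames. A pair with identical activity patterns scores 1; two
#' cells never active together score 0.
#'
#' @param r,rp Matrices `[stim, frame]` of trial-average dF/F (from
#'   [stimulus_means()]).
#' @return Scalar in `[-1, 1]`; `NA` when either norm is zero.
#' @export
response_similarity <- function(r, rp) cosine(as.vector(r), as.vector(rp))

#' Additional pairwise response metrics
#'
#' `signal_similarity_time_avg`: cosine of the time-averaged per-stimulus
#' responses `rbar(i)`. `total_correlation`: per-segment Pearson correlation
#' of single-trial traces, averaged over segments. `signal_correlation`:
#' Pearson correlation of the trial-average tensors `r(i,t)`.
#'
#' @param rbar,rbarp Per-stimulus mean-response vectors.
#' @return Scalar; `NA` for zero-variance/zero-norm inputs.
#' @export
signal_similarity_time_avg <- function(rbar, rbarp) cosine(rbar, rbarp)

#' @rdname signal_similarity_time_avg
#' @param f,fp 3-D arrays `[stim, rep, frame]`.
#' @export
total_correlation <- function(f, fp) {
  stopifnot(identical(dim(f), dim(fp)))
  vals <- vapply(seq_len(dim(f)[2]), function(j) {
    a <- as.vector(f[, j, ]); b <- as.vector(fp[, j, ])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' @rdname signal_similarity_time_avg
#' @param r,rp Matrices `[stim, frame]` of trial averages.
#' @export
signal_correlation <- function(r, rp) {
  a <- as.vector(r); b <- as.vector(rp)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Preferred-feature differences between two fitted cells
#'
#' Absolute differences of preferred SF, TF and speed (TF - SF, all in
#' octaves), and the orientation difference
#' `dOri = 90 - ||phi - phi'| - 90|` with `phi = theta_pref mod 180`.
#' Metrics are `NA` for features a cell is untuned for.
#'
#' @param fitA,fitB `tuning_fit` objects (or lists with `params` and tuned
#'   flags).
#' @return Named list `d_sf`, `d_tf`, `d_speed` (octaves), `d_ori` (deg,
#'   in `[0, 90]`).
#' @export
feature_deltas <- function(fitA, fitB) {
  pa <- fitA$params; pb <- fitB$params
  ok <- function(fit, flag) is.null(fit[[flag]]) || isTRUE(fit[[flag]])
  d_sf <- if (ok(fitA, "tuned_sf") && ok(fitB, "tuned_sf"))
    abs(pa$sf_pref - pb$sf_pref) else NA_real_
  d_tf <- if (ok(fitA, "tuned_tf") && ok(fitB, "tuned_tf"))
    abs(pa$tf_pref - pb$tf_pref) else NA_real_
  d_speed <- if (is.finite(d_sf) && is.finite(d_tf))
    abs((pa$tf_pref - pa$sf_pref) - (pb$tf_pref - pb$sf_pref)) else NA_real_
  d_ori <- if (ok(fitA, "tuned_dir") && ok(fitB, "tuned_dir")) {
    phi <- pa$theta_pref %% 180; phip <- pb$theta_pref %% 180
    90 - abs(abs(phi - phip) - 90)
  } else NA_real_
  list(d_sf = d_sf, d_tf = d_tf, d_speed = d_speed, d_ori = d_ori)
}

#' Correlations of marginal tuning curves
#'
#' For each stimulus feature, averages each cell's per-stimulus mean response
#' `rbar(i)` across the other two stimulus dimensions and correlates the
#' resulting marginal tuning curves between the two cells.
#'
#' @param rbarA,rbarB Per-stimulus mean-response vectors (ensemble order).
#' @param ensemble The [stimulus_ensemble()].
#' @return Named list `sf_corr`, `tf_corr`, `dir_corr` (`NA` for
#'   zero-variance marginals).
#' @export
marginal_tuning_correlations <- function(rbarA, rbarB, ensemble) {
  st <- ensemble$stim
  marg <- function(rbar, key) tapply(rbar, st[[key]], mean)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  list(sf_corr = safe_cor(marg(rbarA, "sf"), marg(rbarB, "sf")),
       tf_corr = safe_cor(marg(rbarA, "tf"), marg(rbarB, "tf")),
       dir_corr = safe_cor(marg(rbarA, "direction"), marg(rbarB, "direction")))
}

#' Proximity exclusion filter for cell pairs
#'
#' Fluorescence cross-talk between overlapping ROIs inflates similarity, so
#' pairs separated by less than `min_dist` micrometres in the same or
#' adjacent imaging planes are excluded.
#'
#' @param cells Cell table with `x`, `y`, `plane` columns.
#' @param id_a,id_b Vectors of cell ids forming the pairs.
#' @param min_dist Micrometre threshold (default 10).
#' @return Logical vector: TRUE = keep the pair.
#' @export
pair_distance_filter <- function(cells, id_a, id_b, min_dist = 10) {
  cells <- as.data.frame(cells)
  ia <- match(id_a, cells$cell_id); ib <- match(id_b, cells$cell_id)
  dxy <- sqrt((cells$x[ia] - cells$x[ib])^2 + (cells$y[ia] - cells$y[ib])^2)
  near_plane <- abs(cells$plane[ia] - cells$plane[ib]) <= 1
  !(near_plane & dxy < min_dist)
}

#' All pairwise similarity metrics for a dataset
#'
#' @param trials 4-D array `f[stim, rep, frame, cell]` from [gen_trials()].
#' @param cells The cell table.
#' @param pairs Two-column matrix/data.frame of cell-id pairs; default all
#'   PV x pyramidal combinations.
#' @return data.table with one row per pair and all metrics.
#' @export
pair_metrics <- function(trials, cells, pairs = NULL) {
  cells <- as.data.frame(cells)
  ens <- attr(trials, "ensemble")
  if (is.null(pairs)) {
    pairs <- expand.grid(a = cells$cell_id[cells$cell_class == "pv"],
                         b = cells$cell_id[cells$cell_class == "pyr"])
  }
  mw <- ens$moving_window
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    ia <- match(pairs[k, 1], cells$cell_id)
    ib <- match(pairs[k, 2], cells$cell_id)
    fa <- trials[, , , ia]; fb <- trials[, , , ib]
    sa <- stimulus_means(fa, mw); sb <- stimulus_means(fb, mw)
    data.table::data.table(
      id_a = cells$cell_id[ia], id_b = cells$cell_id[ib],
      response_similarity = response_similarity(sa$r, sb$r),
      total_similarity = total_similarity(fa, fb),
      signal_similarity_time_avg = signal_similarity_time_avg(sa$rbar, sb$rbar),
      total_correlation = total_correlation(fa, fb),
      signal_correlation = signal_correlation(sa$r, sb$r))
  })
  res <- data.table::rbindlist(out)
  res$keep <- pair_distance_filter(cells, res$id_a, res$id_b)
  res
}
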