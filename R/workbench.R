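## End-to-end pipeline orchestration: synth -> tuning -> similarity ->
## synaptic statistics -> report, with a reproducible manifest.

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Generates (or accepts) a dataset, fits tuning to every cell, computes pair
#' similarity metrics, runs the connectivity statistics, and assembles a
#' manifest recording every stage seed so the run is bit-reproducible.
#'
#' @param config List of options: `n_pv`, `n_pyr`, `n_rep`, `conn_params`
#'   ([connectivity_params()]), `fit_restarts` (tuning fit starts, default 10),
#'   `n_shuffles` (permutation test, default 1000).
#' @param seed Master seed; fanned out deterministically to the stages.
#' @param dataset Optional pre-generated dataset (skips the synth stage).
#' @param out_dir Optional directory: writes `tuning.csv`, `pairs.csv`,
#'   `stats.json`, `manifest.json`.
#' @return List: `dataset`, `tuning` (data.table), `pairs`, `stats`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = list(), seed = 1L, dataset = NULL,
                         out_dir = NULL) {
  cfg <- utils::modifyList(
    list(n_pv = 8, n_pyr = 30, n_rep = 6,
         conn_params = connectivity_params(n_pairs = 138),
         fit_restarts = 10, n_shuffles = 1000), config)
  seeds <- derive_seeds(seed, 5)
  if (is.null(dataset)) {
    dataset <- gen_dataset(cfg$n_pv, cfg$n_pyr, n_rep = cfg$n_rep,
                           conn_params = cfg$conn_params, seed = seeds[1])
  }
  ens <- dataset$ensemble
  cells <- as.data.frame(dataset$cells)

  tuning <- data.table::rbindlist(lapply(seq_len(nrow(cells)), function(ci) {
    f <- dataset$trials[, , , ci]
    r2 <- variance_explained(f)
    sm <- stimulus_means(f, ens$moving_window)
    gam <- tryCatch(selectivity_skewness(sm$rbar), error = function(e) NA)
    fit <- fit_tuning(f, ens, n_restarts = cfg$fit_restarts,
                      seed = seeds[2] + ci)
    data.table::data.table(
      cell_id = cells$cell_id[ci], cell_class = cells$cell_class[ci],
      r2 = r2, responsive = isTRUE(r2 > 0.15), skewness = gam,
      data.table::as.data.table(unclass(fit$params)),
      sse = fit$sse, fwhm_dir = fit$fwhm_dir, fwhm_sf = fit$fwhm_sf,
      fwhm_tf = fit$fwhm_tf, tuned_dir = fit$tuned_dir,
      tuned_sf = fit$tuned_sf, tuned_tf = fit$tuned_tf)
  }))

  pairs <- pair_metrics(dataset$trials, cells)

  conns <- as.data.frame(dataset$connections)
  stats_out <- list()
  ip <- conns[conns$direction == "pv_pyr", ]  # all tested pairs, both classes
  stats_out$ipsp_similarity <- tryCatch(
    similarity_strength_correlation(conns, "pv_pyr"), error = function(e) NULL)
  stats_out$epsp_similarity <- tryCatch(
    similarity_strength_correlation(conns, "pyr_pv"), error = function(e) NULL)
  stats_out$reciprocal <- tryCatch(reciprocal_correlation(conns),
                                   error = function(e) NULL)
  rec <- reciprocal_table(conns)
  stats_out$permutation <- tryCatch({
    nr <- normalized_reciprocal(rec)
    permutation_test(nr$ipsp_norm, nr$epsp_norm, nr$pv_id,
                     n_shuffles = cfg$n_shuffles, seed = seeds[3])
  }, error = function(e) NULL)
  stats_out$logistic <- tryCatch(
    connection_probability_model(ip$similarity, ip$connected),
    error = function(e) NULL)
  cats <- connection_categories(conns)
  stats_out$categories <- cats

  manifest <- list(seed = seed, stage_seeds = as.list(seeds),
                   config = cfg[c("n_pv", "n_pyr", "n_rep", "fit_restarts",
                                  "n_shuffles")],
                   timestamp = format(Sys.time(), tz = "UTC"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(tuning, file.path(out_dir, "tuning.csv"))
    data.table::fwrite(pairs, file.path(out_dir, "pairs.csv"))
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, force = TRUE)
  }
  list(dataset = dataset, tuning = tuning, pairs = pairs, stats = stats_out,
       manifest = manifest)
}

#' Connection-category percentages
#'
#' Classifies each tested pair as reciprocal, IPSP-only, EPSP-only or
#' unconnected and reports counts and percentages.
#'
#' @param connections Connection table (both directions per tested pair).
#' @return List with `n_pairs`, `counts`, `percent` (named vectors).
#' @export
connection_categories <- function(connections) {
  cx <- as.data.frame(connections)
  sp <- split(cx, cx$pair)
  cat1 <- vapply(sp, function(d) {
    has_i <- any(d$direction == "pv_pyr" & d$connected)
    has_e <- any(d$direction == "pyr_pv" & d$connected)
    if (has_i && has_e) "recip" else if (has_i) "ipsp_only"
    else if (has_e) "epsp_only" else "none"
  }, character(1))
  lv <- c("recip", "ipsp_only", "epsp_only", "none")
  counts <- table(factor(cat1, levels = lv))
  list(n_pairs = length(cat1), counts = as.list(counts),
       percent = as.list(100 * counts / length(cat1)))
}

#' Human-readable summary of pipeline statistics
#'
#' @param stats The `stats` element of a [run_pipeline()] result.
#' @return Character vector of report lines (also printed).
#' @export
report <- function(stats) {
  fmt <- function(x) if (is.null(x) || !is.finite(x)) "undefined"
                     else sprintf("%.3g", x)
  lines <- character(0)
  cats <- stats$categories
  if (!is.null(cats)) {
    if (cats$n_pairs == 0) {
      lines <- c(lines, "connectivity: zero tested pairs")
    } else {
      lines <- c(lines, sprintf(
        "connectivity (n=%d pairs): %.0f%% reciprocal, %.0f%% IPSP-only, %.0f%% EPSP-only, %.0f%% unconnected",
        cats$n_pairs, cats$percent$recip, cats$percent$ipsp_only,
        cats$percent$epsp_only, cats$percent$none))
    }
  }
  if (!is.null(stats$ipsp_similarity))
    lines <- c(lines, sprintf(
      "IPSP strength vs response similarity: R=%s (p=%s, n=%d)",
      fmt(stats$ipsp_similarity$r), fmt(stats$ipsp_similarity$p_value),
      stats$ipsp_similarity$n))
  if (!is.null(stats$epsp_similarity))
    lines <- c(lines, sprintf(
      "EPSP strength vs response similarity: R=%s (p=%s, n=%d)",
      fmt(stats$epsp_similarity$r), fmt(stats$epsp_similarity$p_value),
      stats$epsp_similarity$n))
  if (!is.null(stats$reciprocal))
    lines <- c(lines, sprintf(
      "reciprocal log-EPSP vs log-IPSP: R=%s (p=%s, n=%d)",
      fmt(stats$reciprocal$r), fmt(stats$reciprocal$p_value),
      stats$reciprocal$n))
  if (!is.null(stats$permutation))
    lines <- c(lines, sprintf(
      "normalized E/I correlation: R=%s (permutation p=%s, %d pairs, %d cells)",
      fmt(stats$permutation$r), fmt(stats$permutation$p_value),
      stats$permutation$n_pairs, stats$permutation$n_cells))
  if (!is.null(stats$logistic))
    lines <- c(lines, sprintf(
      "connection probability ~ similarity: slope=%s (p=%s%s)",
      fmt(stats$logistic$slope), fmt(stats$logistic$p_value),
      if (isTRUE(stats$logistic$separation)) ", separation" else ""))
  cat(lines, sep = "\n")
  invisible(lines)
}
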