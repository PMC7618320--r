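test_that("gen_cells: classes, determinism, and PV breadth", {
  ens <- small_ensemble()
  # empty PV class
  cells <- gen_cells(0, 5, ens, seed = 1)
  expect_equal(nrow(cells), 5)
  expect_true(all(cells$cell_class == "pyr"))
  # determinism
  a <- gen_cells(3, 4, ens, seed = 99)
  b <- gen_cells(3, 4, ens, seed = 99)
  expect_identical(a, b)
  # PV+ cells are more broadly tuned on the median
  big <- gen_cells(200, 200, ens, seed = 5)
  med <- tapply(big$sigma_dir, big$cell_class, median)
  expect_gt(med[["pv"]], med[["pyr"]])
  medx <- tapply(big$sigma_x, big$cell_class, median)
  expect_gt(medx[["pv"]], medx[["pyr"]])
  # invalid bounds rejected
  bad <- default_selectivity_profiles()
  bad$pv$sigma_dir <- c(100, 10)
  expect_error(gen_cells(1, 1, ens, profiles = bad), "invalid bounds")
})

test_that("gen_trials: noiseless traces equal the forward model", {
  ens <- small_ensemble()
  cells <- gen_cells(1, 1, ens, seed = 2)
  cells$noise_sd <- 0
  tr <- gen_trials(cells, ens, n_rep = 3, seed = 3, kernel = "none")
  f <- tr[, , , 1]
  # all repetitions identical to the trial average
  expect_equal(f[, 1, ], apply(f, c(1, 3), mean), tolerance = 1e-12)
  # moving-phase mean equals the tuning prediction
  p <- pvcircuit:::cell_params(as.data.frame(cells)[1, ])
  pred <- predict_response(p, ens$stim$direction,
                           sf_octaves(ens$stim$sf, ens),
                           tf_octaves(ens$stim$tf, ens))
  mw <- ens$moving_window
  expect_equal(rowMeans(f[, 1, mw[1]:mw[2]]), pred, tolerance = 1e-12)
  # flat cell: r_max = 0 leaves baseline everywhere
  flat <- cells
  flat$r_max <- 0
  trf <- gen_trials(flat, ens, n_rep = 2, seed = 4, kernel = "none")
  expect_equal(as.vector(trf[, , , 1]),
               rep(flat$b[1], length(trf[, , , 1])), tolerance = 1e-12)
  # determinism
  expect_identical(gen_trials(cells, ens, n_rep = 2, seed = 7),
                   gen_trials(cells, ens, n_rep = 2, seed = 7))
})

test_that("responsiveness statistic separates tuned from flat cells", {
  ens <- small_ensemble()
  cells <- gen_cells(0, 6, ens, seed = 11)
  cells$noise_sd <- 0.2
  cells$r_max <- c(2, 2, 2, 0, 0, 0)   # high-gain vs silent cells
  tr <- gen_trials(cells, ens, n_rep = 10, seed = 12)
  r2 <- sapply(1:6, function(i) variance_explained(tr[, , , i]))
  expect_true(all(r2[1:3] > 0.15))
  expect_true(all(r2[4:6] < 0.15))
})

test_that("gen_connections: categories, correlation target, structure", {
  ens <- small_ensemble()
  cells <- gen_cells(6, 30, ens, seed = 21)
  tr <- gen_trials(cells, ens, n_rep = 3, seed = 22)
  cp <- connectivity_params(n_pairs = 138, rho_target = 0.43)
  conns <- gen_connections(cells, tr, cp, seed = 23)
  # two directed rows per tested pair; conservation of the multinomial draw
  expect_equal(nrow(conns), 2 * 138)
  expect_equal(length(unique(conns$pair)), 138)
  # every connection references existing cells of the correct classes
  cdf <- as.data.frame(conns)
  pv <- cells$cell_id[cells$cell_class == "pv"]
  expect_true(all(cdf$pre_id[cdf$direction == "pv_pyr"] %in% pv))
  expect_true(all(!(cdf$post_id[cdf$direction == "pv_pyr"] %in% pv)))
  expect_true(all(cdf$amplitude_mV[cdf$connected] > 0))
  expect_true(all(is.na(cdf$amplitude_mV[!cdf$connected])))
  expect_error(connectivity_params(rho_target = 1.2), "rho_target")
})

test_that("gen_connections hits the similarity-strength correlation target", {
  ens <- small_ensemble()
  cells <- gen_cells(10, 60, ens, seed = 31)
  tr <- gen_trials(cells, ens, n_rep = 3, seed = 32)
  # all pairs connected so n is large
  cp <- connectivity_params(n_pairs = 500,
                            rates = c(recip = 1, ipsp_only = 0,
                                      epsp_only = 0, none = 0),
                            rho_target = 0.43)
  conns <- gen_connections(cells, tr, cp, seed = 33)
  r <- similarity_strength_correlation(conns, "pv_pyr")$r
  expect_gt(r, 0.35)
  expect_lt(r, 0.51)
  # null generator
  cp0 <- connectivity_params(n_pairs = 500,
                             rates = c(recip = 1, ipsp_only = 0,
                                       epsp_only = 0, none = 0),
                             rho_target = 0)
  conns0 <- gen_connections(cells, tr, cp0, seed = 34)
  expect_lt(abs(similarity_strength_correlation(conns0, "pv_pyr")$r), 0.1)
})

test_that("gen_psp_trace construction and time-to-peak oracle", {
  tr <- gen_psp_trace(0.5, 2, 20, p = 2, dt = 0.01)
  expect_equal(max(abs(tr$voltage)), 0.5, tolerance = 1e-9)
  ip <- gen_psp_trace(1, 2, 20, polarity = "ipsp", dt = 0.01)
  expect_equal(min(ip$voltage), -1, tolerance = 1e-9)
  # time of peak matches a dense grid search of the kernel
  tg <- seq(0, 200, 0.001)
  shape <- (1 - exp(-tg / 2))^2 * exp(-tg / 20)
  t_peak_oracle <- tg[which.max(shape)]
  t_peak <- tr$time[which.max(tr$voltage)] - tr$spike_times[1]
  expect_equal(t_peak, t_peak_oracle, tolerance = 0.02)
  expect_error(gen_psp_trace(1, 2, 20, dt = 0), "dt")
})

test_that("gen_dataset is byte-identical under a fixed seed", {
  d1 <- gen_dataset(3, 8, small_ensemble(), n_rep = 2,
                    conn_params = connectivity_params(n_pairs = 10), seed = 5)
  d2 <- gen_dataset(3, 8, small_ensemble(), n_rep = 2,
                    conn_params = connectivity_params(n_pairs = 10), seed = 5)
  expect_identical(d1$cells, d2$cells)
  expect_identical(d1$trials, d2$trials)
  expect_identical(d1$connections, d2$connections)
})
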