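test_that("phi kernel values and properties", {
  expect_equal(phi(0, 0, 4), exp(4))
  expect_equal(phi(pi, 0, 4), exp(-4))
  expect_equal(phi(0.3, 1.1, 0), 1)
  g <- runif(10, -pi, pi)
  expect_equal(phi(g, 0.5, 2), phi(0.5, g, 2))           # symmetric
  expect_equal(phi(g, 0.5, 2), phi(g + 2 * pi, 0.5, 2))  # periodic
  expect_error(phi(0, 0, -1), "kappa")
})

test_that("assign_preferences is uniform and deterministic", {
  cfg <- tiny_net_config(N = 5000)
  p <- assign_preferences(cfg, seed = 3)
  expect_equal(dim(p), c(5000, 2))
  expect_gt(ks.test(p[, 1], "punif", -pi, pi)$p.value, 0.01)
  expect_identical(p, assign_preferences(cfg, seed = 3))
  cfg1 <- tiny_net_config(N = 100, D = 1)
  expect_equal(ncol(assign_preferences(cfg1, seed = 1)), 1)
})

test_that("specificity_block: normalization contract and brute-force oracle", {
  set.seed(4)
  src <- matrix(runif(40, -pi, pi), 20, 2)
  dst <- matrix(runif(40, -pi, pi), 20, 2)
  S <- specificity_block(src, dst, kappa = 4)
  expect_equal(apply(S, 2, min), rep(0, 20), tolerance = 1e-12)
  expect_equal(colSums(S), rep(1, 20), tolerance = 1e-12)
  # brute-force per-pair oracle
  for (i in c(1, 7, 20)) {
    raw <- vapply(seq_len(20), function(j) {
      prod(exp(4 * cos(src[i, ] - dst[j, ])))
    }, numeric(1))
    expect_equal(S[, i], (raw - min(raw)) / sum(raw - min(raw)),
                 tolerance = 1e-9)
    # argmax target = smallest combined wrapped distance under the kernel
    expect_equal(which.max(S[, i]), which.max(raw))
  }
  # negative variant reverses the target ordering
  Sn <- specificity_block(src, dst, kappa = 4, negative = TRUE)
  for (i in 1:20) {
    expect_equal(order(Sn[, i]), rev(order(S[, i])))
  }
  # kappa = 0: constant affinities -> uniform fallback
  expect_message(S0 <- specificity_block(src, dst, kappa = 0), "uniform")
  expect_equal(S0, matrix(1 / 20, 20, 20))
})

test_that("build_weights conserves per-source output weight exactly", {
  cfg0 <- tiny_net_config(N = 50)
  prefs <- assign_preferences(cfg0, seed = 2)
  for (s_e in c(0, 0.48, 0.55, 1)) {
    for (s_i in c(0, 0.8, -0.8)) {
      cfg <- tiny_net_config(N = 50, s_e = s_e, s_i = s_i)
      m <- build_weights(cfg, prefs)
      ne <- m$n_e
      # E source: weight onto E targets and I targets
      expect_equal(colSums(m$W[1:ne, 1:ne]), rep(cfg$w_e * cfg$f_e, ne),
                   tolerance = 1e-9)
      expect_equal(colSums(m$W[(ne + 1):50, 1:ne]),
                   rep(cfg$w_e * cfg$d_ie * cfg$f_i, ne), tolerance = 1e-9)
      # I source
      expect_equal(colSums(m$W[1:ne, (ne + 1):50]),
                   rep(cfg$w_i * cfg$f_e, 50 - ne), tolerance = 1e-9)
      expect_equal(colSums(m$W[(ne + 1):50, (ne + 1):50]),
                   rep(cfg$w_i * cfg$f_i, 50 - ne), tolerance = 1e-9)
      # no autapses
      expect_equal(diag(m$W), rep(0, 50))
      # sign structure is carried by class, magnitudes nonnegative
      expect_true(all(m$W >= 0))
    }
  }
  # s_e = 0: E->E block is exactly uniform over non-self targets
  mu <- build_weights(tiny_net_config(N = 50, s_e = 0), prefs)
  off_diag <- mu$W[1:40, 1:40][row(matrix(0, 40, 40)) != col(matrix(0, 40, 40))]
  expect_equal(off_diag, rep(tiny_net_config(N = 50)$w_e * 0.8 / 39,
                             length(off_diag)), tolerance = 1e-12)
})

test_that("tuned_input scaling and class restriction", {
  cfg <- tiny_net_config(N = 50, kappa = c(ee = 4, ei = 0.5, ie = 0.5,
                                           ii = 0.5))
  prefs <- assign_preferences(cfg, seed = 6)
  prefs[1, ] <- c(0, 0)       # neuron at the stimulus
  prefs[2, ] <- c(pi, pi)     # antipodal neuron
  m <- build_weights(cfg, prefs)
  cur <- tuned_input(m, c(0, 0), max_current = 12)
  expect_equal(cur[1], 12)
  expect_equal(cur[2], 0)
  expect_true(all(cur[(m$n_e + 1):50] == 0))  # inhibitory neurons: none
})

test_that("simulate_network: silence, determinism, and spiking", {
  cfg <- tiny_net_config(N = 40)
  prefs <- assign_preferences(cfg, seed = 1)
  m <- build_weights(cfg, prefs)
  # zero background, no stimulus: no spikes
  s0 <- simulate_network(m, list(t_max = 200, bg_rate = 0), seed = 1)
  expect_equal(nrow(s0$spikes), 0)
  # same seed, identical spike trains
  s1 <- simulate_network(m, list(t_max = 300), seed = 9)
  s2 <- simulate_network(m, list(t_max = 300), seed = 9)
  expect_identical(s1$spikes, s2$spikes)
  expect_gt(nrow(s1$spikes), 0)
  # rates are nonnegative and times inside the window
  expect_true(all(s1$spikes$time > 0 & s1$spikes$time <= 300))
  expect_true(all(s1$rates >= 0))
  # stability guard
  expect_error(network_config(N = 50, dt = 5), "stability guard")
})

test_that("unconnected network fires near the calibrated background rate", {
  cfg <- network_preset(200)
  model <- build_weights(cfg, assign_preferences(cfg, seed = 2))
  model$W[] <- 0
  sim <- simulate_network(model, list(t_max = 2000), seed = 3)
  hz <- nrow(sim$spikes) / cfg$N / 2
  expect_gt(hz, 0.5)   # calibrated for ~2 Hz; allow Poisson + finite-size slop
  expect_lt(hz, 8)
})

test_that("stability_index flags persistent activity", {
  # synthetic sim_result: active during stim, silent after -> stable
  mk <- function(off_spikes) {
    sp <- data.frame(neuron = rep(1:10, 20), time = runif(200, 0, 400))
    if (off_spikes > 0)
      sp <- rbind(sp, data.frame(neuron = rep(1:10, off_spikes / 10),
                                 time = runif(off_spikes, 800, 1000)))
    list(spikes = sp, is_exc = rep(TRUE, 10))
  }
  stim <- list(list(start = 0, end = 400))
  expect_equal(stability_index(mk(0), stim)$label, "stable")
  expect_equal(stability_index(mk(0), stim)$ratios, 0)
  expect_equal(stability_index(mk(400), stim)$label, "unstable")
  expect_error(stability_index(mk(0), list()), "no stimulation")
})

test_that("conductance correlation is near zero in an uncoupled network", {
  cfg <- network_preset(100)
  model <- build_weights(cfg, assign_preferences(cfg, seed = 4))
  model$W[] <- 0
  sim <- simulate_network(model, list(t_max = 1000, probe_idx = 1:10),
                          seed = 5)
  ct <- conductance_cotuning(sim)
  # no inhibitory input at all -> g_I constant -> NA, excluded
  expect_true(all(is.na(ct$correlation)))
})

test_that("perturb_cohort selects the requested cohort and drives it", {
  cfg <- network_preset(300, s_e = 0.55, s_i = 0.8)
  prefs <- assign_preferences(cfg, seed = 11)
  m <- build_weights(cfg, prefs)
  pc <- perturb_cohort(m, gamma_target = c(0, 0), cohort_size = 11,
                       tol = pi / 4, n_pulses = 3, seed = 12)
  expect_length(pc$cohort, 11)
  expect_true(all(pc$cohort <= m$n_e))
  tb <- pc$table
  coh <- tb[tb$cohort == TRUE, ]
  expect_gt(mean(coh$post_hz), mean(coh$pre_hz))  # direct drive
  expect_error(perturb_cohort(m, tol = 1e-5), "within tol")
})
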