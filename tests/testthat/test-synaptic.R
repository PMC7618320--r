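test_that("psp_amplitude recovers constructed peaks and handles overlap", {
  tr <- gen_psp_trace(0.5, 2, 20, p = 2, dt = 0.05)
  expect_equal(psp_amplitude(tr), 0.5, tolerance = 1e-6)
  ip <- gen_psp_trace(1, 2, 20, polarity = "ipsp", dt = 0.05)
  expect_equal(min(ip$voltage), -1, tolerance = 1e-6)
  expect_equal(psp_amplitude(ip), 1, tolerance = 1e-6)
  # flat trace -> 0
  flat <- list(time = seq(0, 50, 0.1), voltage = rep(0, 501),
               spike_times = 10, polarity = "epsp")
  expect_equal(psp_amplitude(flat), 0)
  # baseline invariance: adding a constant changes nothing
  tr2 <- tr; tr2$voltage <- tr2$voltage - 63
  expect_equal(psp_amplitude(tr2), psp_amplitude(tr), tolerance = 1e-12)
  # overlapping double PSP: cutting at the second onset recovers the first
  dbl <- gen_psp_trace(c(0.8, 0.8), 2, 20, spike_times = c(10, 25),
                       dt = 0.02)
  expect_equal(psp_amplitude(dbl, second_psp_onset = 25), 0.8,
               tolerance = 0.02 * 0.8)
})

test_that("paired_pulse_ratio with per-pulse baselines", {
  # fast-decaying kinetics so the 30 Hz pulses barely overlap
  same <- gen_psp_trace(c(0.6, 0.6), 1, 6, spike_times = c(10, 43.3),
                        dt = 0.02, duration = 150)
  expect_equal(paired_pulse_ratio(same), 1, tolerance = 0.02)
  dep <- gen_psp_trace(c(1, 0.6), 1, 6, spike_times = c(10, 43.3),
                       dt = 0.02, duration = 150, noise_sd = 0.005, seed = 3)
  expect_equal(paired_pulse_ratio(dep), 0.6, tolerance = 0.02)
  single <- gen_psp_trace(1, 1.5, 12)
  expect_error(paired_pulse_ratio(single), "two presynaptic spikes")
})

test_that("fit_psp_kinetics recovers parameters and flags bad fits", {
  tr <- gen_psp_trace(1, 2, 20, p = 2, dt = 0.05, duration = 150)
  # re-express truth: gen_psp_trace scales so the peak is `amplitude`
  shape_pk <- optimize(function(t) (1 - exp(-t / 2))^2 * exp(-t / 20),
                       c(0, 400), maximum = TRUE)$objective
  k <- fit_psp_kinetics(tr, n_restarts = 20, seed = 2)
  expect_true(k$converged)
  expect_equal(k$tau_r, 2, tolerance = 1e-3)
  expect_equal(k$tau_d, 20, tolerance = 1e-3)
  expect_equal(k$p, 2, tolerance = 1e-3)
  expect_equal(k$v_max, 1 / shape_pk, tolerance = 1e-3)
  # slow decay lands in the exclusion regime (tau_d > 25 ms)
  slow <- gen_psp_trace(1, 2, 80, p = 2, dt = 0.1, duration = 400)
  ks <- fit_psp_kinetics(slow, n_restarts = 20, seed = 2)
  expect_gt(ks$tau_d, 25)
  # pure noise is flagged
  set.seed(4)
  noise <- list(time = seq(0, 100, 0.1),
                voltage = rnorm(1001, sd = 0.05),
                spike_times = 10, polarity = "epsp")
  kn <- fit_psp_kinetics(noise, n_restarts = 10, seed = 1)
  expect_false(kn$converged)
})

test_that("reciprocal_correlation detects shared latent strength", {
  mk <- function(n, rho, seed) {
    set.seed(seed)
    lat <- rnorm(n, 0, sqrt(rho) * 0.4)
    ip <- 10^(-0.3 + lat + rnorm(n, 0, sqrt(1 - rho) * 0.4))
    ep <- 10^(-0.3 + lat + rnorm(n, 0, sqrt(1 - rho) * 0.4))
    data.frame(pair = rep(seq_len(n), 2),
               pre_id = c(seq_len(n), n + seq_len(n)),
               post_id = c(n + seq_len(n), seq_len(n)),
               direction = rep(c("pv_pyr", "pyr_pv"), each = n),
               connected = TRUE, amplitude_mV = c(ip, ep),
               similarity = 0.3)
  }
  # proportional amplitudes -> R = 1
  d <- mk(10, 0.5, 1)
  d$amplitude_mV[11:20] <- d$amplitude_mV[1:10] * 2
  expect_equal(reciprocal_correlation(d)$r, 1, tolerance = 1e-12)
  # latent coupling recovered
  rc <- reciprocal_correlation(mk(200, 0.6, 7))
  expect_equal(rc$r, 0.6, tolerance = 0.1)
  # independent draws near zero
  rc0 <- reciprocal_correlation(mk(200, 0, 8))
  expect_lt(abs(rc0$r), 0.15)
  expect_error(reciprocal_correlation(mk(2, 0.5, 1)), ">= 3")
})

test_that("normalize_within_presyn identities", {
  # two equal IPSPs -> both normalized values are exactly 1
  out <- normalize_within_presyn(c(0.4, 0.4), c("a", "a"))
  expect_equal(out$normalized, c(1, 1))
  # per-cell mean of normalized values is 1 for any input
  set.seed(6)
  vals <- rlnorm(12, -0.5, 0.5)
  grp <- rep(c("a", "b", "c"), each = 4)
  nm <- normalize_within_presyn(vals, grp)
  means <- tapply(nm$normalized, nm$group, mean)
  expect_equal(as.vector(means), rep(1, 3), tolerance = 1e-12)
  # hand-worked two-cell fixture
  v <- c(0.2, 0.8, 2, 5)
  g <- c("x", "x", "y", "y")
  expected <- c(log10(0.2), log10(0.8)) / mean(log10(c(0.2, 0.8)))
  nm2 <- normalize_within_presyn(v, g)
  expect_equal(nm2$normalized[nm2$group == "x"], expected, tolerance = 1e-12)
  # arithmetic variant
  na2 <- normalize_within_presyn(v, g, mean_kind = "arithmetic")
  expect_equal(na2$normalized[na2$group == "x"], c(0.2, 0.8) / 0.5)
  # near-zero mean log excluded with warning
  expect_warning(normalize_within_presyn(c(0.9, 1.1, 3, 4),
                                         c("z", "z", "w", "w")),
                 "excluded")
  # singleton groups dropped
  expect_equal(nrow(normalize_within_presyn(c(1.5, 2, 3), c("a", "b", "b"))),
               2)
})

test_that("permutation_test exceedance rule and invariances", {
  # permutation-invariant data -> p = 1
  pt <- permutation_test(rep(1, 6), rep(1, 6), rep(c("a", "b"), each = 3),
                         n_shuffles = 50, seed = 1)
  expect_equal(pt$p_value, 1)
  # strong within-cell coupling detected
  set.seed(12)
  g <- rep(letters[1:10], each = 4)
  e <- rnorm(40)
  i <- e + rnorm(40, 0, 0.3)
  pt2 <- permutation_test(i, e, g, n_shuffles = 500, seed = 2)
  expect_lt(pt2$p_value, 0.05)
  # p invariant to monotone relabeling of PV-cell identities
  relab <- setNames(paste0("cell_", LETTERS[1:10]), letters[1:10])
  pt3 <- permutation_test(i, e, unname(relab[g]), n_shuffles = 500, seed = 2)
  expect_equal(pt3$p_value, pt2$p_value)
  # power: strong coupling at n = 50 pairs detected in most replicates
  hits <- 0
  for (k in 1:40) {
    set.seed(1000 + k)
    gg <- rep(seq_len(10), each = 5)
    ee <- rnorm(50)
    ii2 <- ee + rnorm(50, 0, 0.6)
    ptk <- permutation_test(ii2, ee, gg, n_shuffles = 200, seed = k)
    hits <- hits + (ptk$p_value < 0.05)
  }
  expect_gt(hits / 40, 0.8)
  expect_error(permutation_test(1:3, 1:3, c("a", "b", "c")), "within-cell")
})

test_that("normalization removes per-cell offsets exactly", {
  # log-domain: an additive per-cell offset in log amplitude cancels in the
  # normalized ratio when amplitudes are scaled per cell
  set.seed(13)
  g <- rep(letters[1:6], each = 5)
  base <- rlnorm(30, -0.6, 0.3)
  off <- setNames(runif(6, 0.5, 2), letters[1:6])
  n1 <- normalize_within_presyn(base, g)
  # multiplicative per-cell scaling changes normalized values only through
  # the (nonlinear) ratio; verify the per-cell mean stays exactly 1
  n2 <- normalize_within_presyn(base * off[g], g)
  expect_equal(as.vector(tapply(n2$normalized, n2$group, mean)), rep(1, 6),
               tolerance = 1e-12)
  expect_equal(nrow(n1), nrow(n2))
})

test_that("partial_correlation matches the residual oracle", {
  set.seed(14)
  n <- 60
  cov_ <- rnorm(n)
  x <- 0.8 * cov_ + rnorm(n)
  y <- -0.5 * cov_ + 0.6 * x + rnorm(n)
  pc <- partial_correlation(x, y, cov_)
  # brute-force oracle
  rx <- resid(lm(x ~ cov_)); ry <- resid(lm(y ~ cov_))
  expect_equal(pc$r, cor(rx, ry), tolerance = 1e-12)
  # orthogonal covariate: equals plain Pearson
  covo <- rep(c(1, -1), n / 2)
  xo <- rnorm(n); xo <- xo - mean(xo)
  yo <- rnorm(n); yo <- yo - mean(yo)
  xo <- xo - covo * sum(xo * covo) / sum(covo^2)
  yo <- yo - covo * sum(yo * covo) / sum(covo^2)
  expect_equal(partial_correlation(xo, yo, covo)$r, cor(xo, yo),
               tolerance = 1e-10)
  # perfectly collinear variables -> undefined
  expect_error(partial_correlation(2 * cov_, 3 * cov_, cov_), "undefined")
  expect_message(partial_correlation(x, y, rep(1, n)), "constant covariate")
})

test_that("connection_probability_model slope recovery and separation", {
  set.seed(15)
  n <- 2000
  s <- rnorm(n)
  pr <- plogis(-0.5 + 2 * s)
  flags <- runif(n) < pr
  fit <- connection_probability_model(s, flags)
  expect_false(fit$separation)
  expect_equal(fit$slope, 2, tolerance = 0.3)
  # deterministic threshold -> separation flagged
  sep <- connection_probability_model(s, s > 0)
  expect_true(sep$separation)
  expect_true(is.na(sep$p_value))
  expect_error(connection_probability_model(s, rep(TRUE, n)), "both")
})
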