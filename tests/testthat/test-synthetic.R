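test_that("target sampling covers the task geometry uniformly", {
  cfg <- sim_config(n_trials = 300, n_units = 1, acq_rate = 166.667)
  tr <- generate_behavior(cfg, seed = 101)
  expect_true(all(tr$target_r >= 100 & tr$target_r <= 400))
  expect_true(all(tr$target_theta >= -40 & tr$target_theta <= 40))
  expect_gt(suppressWarnings(
    stats::ks.test((tr$target_r - 100) / 300, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(
    stats::ks.test((tr$target_theta + 40) / 80, "punif"))$p.value, 0.01)
  # target visible for 300 ms; speed caps honored
  expect_true(all(abs(tr$t_target_off - tr$t_target_on - 0.3) < 1e-9))
  caps_ok <- vapply(tr$trajectory, function(x) {
    max(x$lin_vel) <= 200 + 1e-6 && max(abs(x$ang_vel)) <= 90 + 1e-6
  }, logical(1))
  expect_true(all(caps_ok))
  # reward only within the 60 cm boundary
  kept <- tr[!is.na(tr$endpoint_r), ]
  err <- sqrt((kept$endpoint_r * sinpi(kept$endpoint_theta / 180) -
                 kept$target_r * sinpi(kept$target_theta / 180))^2 +
              (kept$endpoint_r * cospi(kept$endpoint_theta / 180) -
                 kept$target_r * cospi(kept$target_theta / 180))^2)
  expect_true(all(err[kept$rewarded] <= 60 + 1e-6))
  expect_true(all(err[!kept$rewarded] > 60 - 1e-6))
  # inter-trial delays within the truncated-exponential range
  gaps <- tr$t_start[-1] - (tr$t_start + tr$duration)[-nrow(tr)]
  expect_true(all(gaps >= 0.2 - 1e-9 & gaps <= 2.0 + 1e-9))
  expect_lt(abs(mean(gaps) - 0.5), 0.08)
})

test_that("unbiased gains with no noise reward every trial with slope 1", {
  cfg <- sim_config(n_trials = 30, n_units = 1,
                    gains = c(radial = 1, angular = 1),
                    noise_sd = c(radial = 0, angular = 0),
                    fraction_no_stop = 0, fraction_near_origin = 0,
                    acq_rate = 166.667)
  tr <- generate_behavior(cfg, seed = 102)
  expect_true(all(tr$rewarded))
  sl <- bias_slopes(tr)
  expect_equal(sl$slope_radial, 1, tolerance = 1e-6)
  expect_equal(sl$slope_angular, 1, tolerance = 1e-4)
})

test_that("planted undershoot gains are recovered by the behavior module", {
  cfg <- sim_config(n_trials = 250, n_units = 1,
                    gains = c(radial = 0.9, angular = 0.8),
                    fraction_no_stop = 0.05, fraction_near_origin = 0.02,
                    acq_rate = 166.667)
  tr <- generate_behavior(cfg, seed = 103)
  sl <- bias_slopes(exclude_trials(tr)$kept)
  expect_lt(abs(sl$slope_radial - 0.9), 0.035)
  expect_lt(abs(sl$slope_angular - 0.8), 0.05)
})

test_that("gaze tracking quality maps onto the measured index", {
  trials <- small_trials()[1:8, ]
  # quality 1: measured index exactly 1
  g1 <- generate_gaze(trials, 1)
  idx1 <- vapply(seq_len(nrow(g1)),
                 function(i) navgam:::trial_tracking_index(g1[i, ])["whole"],
                 numeric(1))
  expect_equal(unname(idx1), rep(1, nrow(g1)))
  # quality 0: near-zero correspondence
  g0 <- generate_gaze(trials, 0, seed = 104)
  idx0 <- vapply(seq_len(nrow(g0)),
                 function(i) navgam:::trial_tracking_index(g0[i, ])["whole"],
                 numeric(1))
  expect_lt(mean(idx0), 0.1)
  # sweep is strictly increasing
  means <- vapply(c(0.2, 0.5, 0.8), function(q) {
    g <- generate_gaze(trials, q, seed = 105)
    mean(vapply(seq_len(nrow(g)),
                function(i) navgam:::trial_tracking_index(g[i, ])["whole"],
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(max(abs(means - c(0.2, 0.5, 0.8))), 0.05)
  expect_error(generate_gaze(trials, 1.2), "tracking_quality")
})

test_that("flat ground truth produces Poisson spiking at the set rate", {
  ss <- small_session()
  gt <- make_ground_truth(sim_config(n_trials = 24, n_units = 1,
                                     areas = "MSTd"), seed = 106)
  gt$tuning[[1]] <- list()
  gt$history[[1]] <- rep(0, 6)
  gt$units$intercept[1] <- log(0.06)   # 10 Hz at 6 ms bins
  out <- generate_spikes(ss, gt, seed = 107)
  y <- out$counts[, 1]
  expect_lt(abs(mean(y) / 0.06 - 1), 0.05)
  expect_lt(abs(var(y) / mean(y) - 1), 0.05)   # Fano factor ~ 1
})

test_that("refractory spike-history kernels produce refractoriness", {
  ss <- small_session()
  gt <- make_ground_truth(sim_config(n_trials = 24, n_units = 1,
                                     areas = "MSTd"), seed = 108)
  gt$tuning[[1]] <- list()
  gt$units$intercept[1] <- log(50 * 0.006)   # high rate to expose history
  gt$history[[1]] <- c(-4, -2, -0.5, 0, 0, 0)
  with_h <- generate_spikes(ss, gt, seed = 109)$counts[, 1]
  gt$history[[1]] <- rep(0, 6)
  no_h <- generate_spikes(ss, gt, seed = 109)$counts[, 1]
  # successive-bin co-activation is suppressed relative to memoryless
  co <- function(y) mean(y[-1] * y[-length(y)]) / mean(y)^2
  expect_lt(co(with_h), 0.5 * co(no_h))
})

test_that("planted phase locking shows up in spike-phase histograms", {
  ss <- small_session()
  gt <- make_ground_truth(sim_config(n_trials = 24, n_units = 1,
                                     areas = "MSTd"), seed = 110)
  gt$tuning[[1]] <- list(
    lfp_beta = list(type = "cosine", params = list(amp = 1, center = 0.8)))
  gt$history[[1]] <- rep(0, 6)
  gt$units$intercept[1] <- log(20 * 0.006)
  out <- generate_spikes(ss, gt, seed = 111)
  ph <- out$lfp$lfp_beta_MSTd
  y <- out$counts[, 1]
  # circular-statistics oracle: resultant of spike phases points at the
  # planted preferred phase
  C <- sum(y * cos(ph)); S <- sum(y * sin(ph))
  pref <- atan2(S, C)
  expect_lt(abs(navgam:::wrap_rad(pref - 0.8)), 0.15)
  expect_gt(sqrt(C^2 + S^2) / sum(y), 0.2)   # strong locking
})

test_that("sessions are reproducible from config plus seed", {
  cfg <- sim_config(n_trials = 6, n_units = 3, coupling_pairs = 2,
                    acq_rate = 166.667)
  s1 <- simulate_session(cfg, seed = 112)
  s2 <- simulate_session(cfg, seed = 112)
  expect_identical(s1$counts, s2$counts)
  expect_equal(s1$bins, s2$bins)
  s3 <- simulate_session(cfg, seed = 113)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("coupled generation respects the planted directed kernels", {
  cfg <- sim_config(n_trials = 16, n_units = 2, areas = "MSTd",
                    coupling_pairs = 0, acq_rate = 166.667)
  ss <- simulate_session(cfg, seed = 114)
  gt <- ss$ground_truth
  gt$tuning <- list(u001 = list(), u002 = list())
  gt$history <- list(u001 = rep(0, 6), u002 = rep(0, 6))
  names(gt$history) <- gt$units$unit_id
  gt$units$intercept <- log(c(40, 15) * 0.006)
  gt$coupling <- tibble::tibble(sender = "u001", receiver = "u002",
                                kernel = list(c(1.2, 0.8, 0.3, 0, 0, 0)))
  out <- generate_spikes(ss, gt, seed = 115)
  y1 <- out$counts[, "u001"]; y2 <- out$counts[, "u002"]
  # receiver rate is elevated right after sender spikes (lag 1), not before
  after <- mean(y2[which(y1[-length(y1)] > 0) + 1])
  before <- mean(y2[which(y1[-1] > 0)])
  expect_gt(after, 1.5 * before)
})
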