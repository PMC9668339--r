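test_that("trial exclusion applies the near-origin and no-stop rules", {
  tr <- tibble::tibble(endpoint_r = c(40, 120, NA, 300, 49.9),
                       endpoint_theta = 0)
  ex <- exclude_trials(tr)
  expect_equal(nrow(ex$kept), 2L)
  expect_equal(ex$report$fraction_no_stop, 0.2)
  expect_equal(ex$report$fraction_excluded_near_origin, 0.4)
})

test_that("planted exclusion rates are recovered on synthetic sessions", {
  cfg <- sim_config(n_trials = 400, n_units = 1, fraction_no_stop = 0.13,
                    fraction_near_origin = 0.05, acq_rate = 166.667)
  tr <- generate_behavior(cfg, seed = 99)
  ex <- exclude_trials(tr)
  expect_lt(abs(ex$report$fraction_no_stop - 0.13), 0.045)
  expect_lt(abs(ex$report$fraction_excluded_near_origin - 0.05), 0.03)
})

test_that("bias slopes recover multiplicative gains", {
  set.seed(21)
  tg <- tibble::tibble(target_r = runif(100, 100, 400),
                       target_theta = runif(100, -40, 40))
  exact <- dplyr::mutate(tg, endpoint_r = 0.9 * target_r,
                         endpoint_theta = 0.9 * target_theta)
  sl <- bias_slopes(exact)
  expect_equal(sl$slope_radial, 0.9, tolerance = 1e-12)
  expect_equal(sl$r2_radial, 1, tolerance = 1e-12)
  ident <- dplyr::mutate(tg, endpoint_r = target_r,
                         endpoint_theta = target_theta)
  expect_equal(bias_slopes(ident)$slope_radial, 1, tolerance = 1e-12)
  expect_equal(bias_slopes(ident)$slope_angular, 1, tolerance = 1e-12)
  # gain 0.85 with 30 cm noise on 500 trials: sampling distribution check
  set.seed(22)
  tg5 <- tibble::tibble(target_r = runif(500, 100, 400),
                        target_theta = runif(500, -40, 40))
  noisy <- dplyr::mutate(tg5,
                         endpoint_r = 0.85 * target_r + rnorm(500, 0, 30),
                         endpoint_theta = 0.85 * target_theta)
  expect_lt(abs(bias_slopes(noisy)$slope_radial - 0.85), 0.02)
  expect_error(bias_slopes(exact[1:5, ]), ">= 10")
  same <- tibble::tibble(target_r = rep(200, 20), target_theta = rep(0, 20),
                         endpoint_r = rep(190, 20), endpoint_theta = 0)
  expect_error(bias_slopes(same), "degenerate")
})

test_that("gaze prediction follows ground-plane perspective geometry", {
  # far target straight ahead: azimuth ~ 0, elevation small and negative
  still <- tibble::tibble(t = 0, x = 0, y = 0, heading = 0)
  far <- predict_gaze(still, 400, 0)
  expect_lt(abs((far$lh + far$rh) / 2), 0.5)
  expect_lt(far$lv, 0)
  expect_gt(far$lv, -2)
  # halving the ground distance doubles tan(|elevation|) (similar triangles)
  near <- predict_gaze(still, 200, 0)
  expect_equal(tanpi(-near$lv / 180) / tanpi(-far$lv / 180), 2,
               tolerance = 1e-3)
  # over a steered approach the eyes decline and the azimuth centers
  appr <- navgam:::steer_trial(350 * sinpi(15 / 180), 350 * cospi(15 / 180),
                               200)
  pg <- predict_gaze(appr, 350, 15)
  ok <- pg$valid
  expect_lt(tail(pg$lv[ok], 1), pg$lv[1])            # lower at the end
  cyc <- (pg$lh + pg$rh) / 2
  expect_lt(abs(tail(cyc[ok], 1)), abs(cyc[1]))      # less eccentric
  expect_true(all(diff(pg$lv[ok]) < 1e-9))           # monotone decline
  # target behind the observer is flagged invalid
  behind <- predict_gaze(tibble::tibble(t = 0, x = 0, y = 500, heading = 0),
                         300, 0)
  expect_false(behind$valid)
})

test_that("tracking index hits its analytic endpoints", {
  tt <- seq(0, 2, by = 0.005)
  traj <- tibble::tibble(t = tt, x = 10 * tt, y = 140 * tt,
                         heading = 4 * tt)
  pred <- predict_gaze(traj, 320, 10)
  # exact fixation
  expect_equal(tracking_index(pred, pred), 1)
  # observed = predicted + noise at SNR 1 -> index ~ sqrt(0.5)
  set.seed(31)
  obs <- pred
  for (cc in c("lh", "lv", "rh", "rv")) {
    obs[[cc]] <- pred[[cc]] + rnorm(nrow(pred), 0, sd(pred[[cc]]))
  }
  expect_lt(abs(tracking_index(obs, pred) - sqrt(0.5)), 0.08)
  # rigid rotation applied to both leaves the index unchanged
  rot <- function(g, a) {
    within(as.data.frame(g), {
      h <- lh * cos(a) - lv * sin(a); v <- lh * sin(a) + lv * cos(a)
      lh <- h; lv <- v
      h <- rh * cos(a) - rv * sin(a); v <- rh * sin(a) + rv * cos(a)
      rh <- h; rv <- v
    })
  }
  expect_equal(tracking_index(rot(obs, 0.7), rot(pred, 0.7)),
               tracking_index(obs, pred), tolerance = 1e-10)
  # constant observed gaze is undefined
  const <- pred
  for (cc in c("lh", "lv", "rh", "rv")) const[[cc]] <- 1
  expect_warning(ti <- tracking_index(const, pred), "constant")
  expect_true(is.na(ti))
})

test_that("bimodality coefficient matches its analytic limits", {
  set.seed(41)
  expect_lt(abs(bimodality_coefficient(runif(2e5)) - 5 / 9), 0.01)
  expect_lt(abs(bimodality_coefficient(rnorm(2e5)) - 1 / 3), 0.01)
  mix <- c(rnorm(1e4, -4), rnorm(1e4, 4))
  expect_gt(bimodality_coefficient(mix), 5 / 9)
  expect_error(bimodality_coefficient(rep(2, 10)), "variance")
  expect_error(bimodality_coefficient(1:3), "n >= 4")
})

test_that("stop detection finds the sustained-stillness onset", {
  tt <- seq(0, 3, by = 0.01)
  v <- ifelse(tt < 0.4, 0, ifelse(tt < 2, 100, 0))
  traj <- tibble::tibble(t = tt, lin_vel = v, ang_vel = 0)
  expect_equal(detect_stop(traj), 2, tolerance = 0.02)
  # never stops
  traj2 <- tibble::tibble(t = tt, lin_vel = 50, ang_vel = 0)
  expect_true(is.na(detect_stop(traj2)))
  # brief dip below threshold does not count
  v3 <- v; v3[tt >= 2 & tt < 2.1] <- 0; v3[tt >= 2.1] <- 80
  expect_true(is.na(detect_stop(tibble::tibble(t = tt, lin_vel = v3,
                                               ang_vel = 0))))
})

test_that("worse target tracking goes with stronger steering bias", {
  # sessions where the same internal noise degrades both gaze and steering:
  # the session-level analysis should see tracking index and |1 - slope|
  # negatively correlated
  qs <- seq(0.25, 0.95, length.out = 8)
  stats <- purrr::map_dfr(seq_along(qs), function(i) {
    cfg <- sim_config(n_trials = 14, n_units = 1,
                      gains = c(radial = 1 - 0.35 * (1 - qs[i]),
                                angular = 1 - 0.35 * (1 - qs[i])),
                      fraction_no_stop = 0, fraction_near_origin = 0,
                      acq_rate = 166.667)
    tr <- generate_behavior(cfg, seed = 300 + i)
    tr <- generate_gaze(tr, qs[i])
    bs <- behavior_summary(tr, session_id = i)
    tibble::tibble(tracking = bs$tracking_index_mean,
                   bias = abs(1 - bs$slope_radial))
  })
  expect_lt(cor(stats$tracking, stats$bias), -0.5)
})

test_that("behavior summary ties gaze quality to planted gains", {
  trials <- small_trials()
  bs <- behavior_summary(trials)
  expect_true(all(c("slope_radial", "slope_angular",
                    "tracking_index_mean") %in% names(bs)))
  expect_gt(bs$tracking_index_mean, 0.6)
  expect_true(bs$slope_radial > 0.6 && bs$slope_radial < 1.15)
  expect_true(bs$fraction_rewarded >= 0 && bs$fraction_rewarded <= 1)
})
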