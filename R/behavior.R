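#' Exclude invalid trials before behavioral analysis
#'
#' Drops trials where the animal stopped within 0.5 m of the origin and trials
#' with no stop within the maximum trial duration (7 s), reporting the
#' per-category fractions.
#'
#' @param trials Trial tibble (one row per trial with `endpoint_r`).
#' @return List with `kept` (filtered tibble) and `report` (tibble of
#'   exclusion fractions).
#' @export
exclude_trials <- function(trials) {
  no_stop <- is.na(trials$endpoint_r)
  near_origin <- !no_stop & trials$endpoint_r < 50
  kept <- trials[!(no_stop | near_origin), , drop = FALSE]
  list(kept = kept,
       report = tibble::tibble(
         n_trials = nrow(trials),
         fraction_no_stop = mean(no_stop),
         fraction_excluded_near_origin = mean(near_origin),
         fraction_kept = nrow(kept) / nrow(trials)))
}

#' Multiplicative-gain bias slopes of endpoints on targets
#'
#' Fits the no-intercept regression of response on target separately for the
#' radial and angular components. A slope of 1 indicates unbiased steering;
#' slopes below 1 indicate undershooting.
#'
#' @param trials Trial tibble with `target_r`, `target_theta`, `endpoint_r`,
#'   `endpoint_theta` (excluded trials already removed).
#' @return Tibble with `slope_radial`, `slope_angular`, `r2_radial`,
#'   `r2_angular`, `n_trials`.
#' @export
bias_slopes <- function(trials) {
  if (nrow(trials) < 10L) stop("need >= 10 kept trials for bias slopes")
  if (sd(trials$target_r) < 1e-8 || sd(trials$target_theta) < 1e-8) {
    stop("degenerate target spread")
  }
  fr <- lm(endpoint_r ~ 0 + target_r, data = trials)
  fa <- lm(endpoint_theta ~ 0 + target_theta, data = trials)
  tibble::tibble(slope_radial = unname(coef(fr)),
                 slope_angular = unname(coef(fa)),
                 r2_radial = suppressWarnings(summary(fr)$r.squared),
                 r2_angular = suppressWarnings(summary(fa)$r.squared),
                 n_trials = nrow(trials))
}

#' Predicted binocular gaze under perfect fixation on the target
#'
#' Projects the target center into eye-centered visual angles for each eye,
#' assuming the observer's eyes sit `eye_height` above the ground plane and
#' fixation is maintained on the (ground-level) target center throughout the
#' trajectory. As the target is approached, the predicted elevation becomes
#' more negative (the eyes drop) and the azimuth less eccentric.
#'
#' @param trajectory Tibble with `t`, `x`, `y` (cm), `heading` (deg).
#' @param target_r,target_theta Target polar position (cm, deg) at trial start.
#' @param eye_height Eye height above the ground plane in cm (default 10).
#' @param interocular Interocular distance in cm (default 3.5).
#' @param near_clip Targets closer than this ground distance, or behind the
#'   observer, are flagged invalid (default 5 cm).
#' @return Tibble `t`, `lh`, `lv`, `rh`, `rv` (deg; h = azimuth, rightward
#'   positive; v = elevation, negative below the horizon), `valid`.
#' @export
predict_gaze <- function(trajectory, target_r, target_theta,
                         eye_height = 10, interocular = 3.5, near_clip = 5) {
  tx <- target_r * sinpi(target_theta / 180)
  ty <- target_r * cospi(target_theta / 180)
  ex <- tx - trajectory$x
  ey <- ty - trajectory$y
  phi <- trajectory$heading * pi / 180
  fwd <- ex * sin(phi) + ey * cos(phi)
  lat <- ex * cos(phi) - ey * sin(phi)
  eye <- function(offset) {
    le <- lat - offset
    gd <- sqrt(fwd^2 + le^2)
    list(h = atan2(le, fwd) * 180 / pi,
         v = atan2(-eye_height, gd) * 180 / pi)
  }
  l <- eye(-interocular / 2)
  r <- eye(interocular / 2)
  tibble::tibble(t = trajectory$t, lh = l$h, lv = l$v, rh = r$h, rv = r$v,
                 valid = fwd > near_clip)
}

#' Target-tracking index
#'
#' The square root of the fraction of variance in the observed eye position
#' explained by the perfect-fixation prediction. Components (horizontal and
#' vertical) are pooled within each eye before the variance ratio, then the
#' index is averaged across eyes. An index of 1 means the gaze followed the
#' target center exactly; values near 0 mean no correspondence. The explained
#' fraction is computed against the prediction directly (no free gain or
#' offset) and rectified at 0 before the square root; set `fit_gain = TRUE`
#' for a variant that allows a common gain.
#'
#' @param observed,predicted Gaze tibbles with columns `lh`, `lv`, `rh`, `rv`
#'   (deg), aligned sample-by-sample. Single-eye tibbles with `h`, `v` also
#'   work.
#' @param fit_gain Allow a fitted gain between prediction and observation.
#' @return Tracking index in `[0, 1]`; `NA` (with a warning) if the observed
#'   gaze is constant.
#' @export
tracking_index <- function(observed, predicted, fit_gain = FALSE) {
  eyes <- if (all(c("lh", "lv", "rh", "rv") %in% names(observed))) {
    list(c("lh", "lv"), c("rh", "rv"))
  } else {
    list(c("h", "v"))
  }
  per_eye <- vapply(eyes, function(cols) {
    obs <- cbind(observed[[cols[1]]], observed[[cols[2]]])
    prd <- cbind(predicted[[cols[1]]], predicted[[cols[2]]])
    ok <- complete.cases(obs) & complete.cases(prd)
    obs <- obs[ok, , drop = FALSE]; prd <- prd[ok, , drop = FALSE]
    ss_tot <- sum(sweep(obs, 2, colMeans(obs))^2)
    if (ss_tot < 1e-12) return(NA_real_)
    if (fit_gain) {
      g <- sum(obs * prd) / sum(prd * prd)
      prd <- g * prd
    }
    ss_res <- sum((obs - prd)^2)
    sqrt(max(0, 1 - ss_res / ss_tot))
  }, numeric(1))
  if (all(is.na(per_eye))) {
    warning("constant observed gaze: tracking index undefined")
    return(NA_real_)
  }
  mean(per_eye, na.rm = TRUE)
}

#' Sarle's bimodality coefficient
#'
#' `(skewness^2 + 1) / (kurtosis + 3 (n-1)^2 / ((n-2)(n-3)))` with
#' bias-corrected sample skewness and excess kurtosis. Large uniform samples
#' give ~5/9 (0.556), large Gaussian samples ~1/3; values above the uniform
#' null suggest bimodality.
#'
#' @param samples Numeric vector, `n >= 4`.
#' @return Bimodality coefficient in `(0, 1]`.
#' @export
bimodality_coefficient <- function(samples) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 4L) stop("bimodality coefficient needs n >= 4")
  if (sd(samples) < 1e-12) stop("zero variance: bimodality undefined")
  g1 <- e1071::skewness(samples, type = 2)
  g2 <- e1071::kurtosis(samples, type = 2)
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Detect the stopping time from a trial's velocity traces
#'
#' The first time both linear and angular speed stay below threshold for a
#' sustained window counts as the stop; trials that never meet the criterion
#' (or only at the very start, before movement onset) return `NA`.
#'
#' @param trajectory Trajectory tibble (`t`, `lin_vel`, `ang_vel`).
#' @param lin_thresh,ang_thresh Speed thresholds (cm/s, deg/s; default 1).
#' @param min_duration Sustained-stop window in seconds (default 0.2).
#' @param after Ignore stillness before this time (default 0.3 s, the
#'   target-visibility window).
#' @return Stop time in seconds from trial start, or `NA`.
#' @export
detect_stop <- function(trajectory, lin_thresh = 1, ang_thresh = 1,
                        min_duration = 0.2, after = 0.3) {
  still <- abs(trajectory$lin_vel) < lin_thresh &
    abs(trajectory$ang_vel) < ang_thresh & trajectory$t >= after
  if (!any(still)) return(NA_real_)
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  step <- median(diff(trajectory$t))
  ok <- which(r$values & r$lengths * step >= min_duration)
  if (!length(ok)) return(NA_real_)
  trajectory$t[starts[ok[1]]]
}

## Tracking index for one trial row (list-column trajectory/gaze), with
## whole-trial and first-second variants.
trial_tracking_index <- function(trial, eye_height = 10, interocular = 3.5) {
  traj <- trial$trajectory[[1]]
  gaze <- trial$gaze[[1]]
  pred <- predict_gaze(traj, trial$target_r, trial$target_theta,
                       eye_height = eye_height, interocular = interocular)
  ok <- pred$valid
  whole <- tracking_index(gaze[ok, ], pred[ok, ])
  first <- ok & traj$t <= 1
  first_s <- if (sum(first) > 10) tracking_index(gaze[first, ], pred[first, ])
             else NA_real_
  c(whole = whole, first_second = first_s)
}

#' Session-level behavioral summary
#'
#' Applies the trial exclusion rules, fits the multiplicative-gain bias
#' slopes, and averages the per-trial target-tracking index (whole-trial and
#' first-second variants).
#'
#' @param trials Trial tibble with trajectory/gaze list-columns.
#' @param session_id Optional identifier.
#' @return One-row tibble (slopes, fit quality, exclusion fractions, reward
#'   fraction, mean tracking indices).
#' @export
behavior_summary <- function(trials, session_id = "session") {
  ex <- exclude_trials(trials)
  sl <- bias_slopes(ex$kept)
  ti <- t(vapply(seq_len(nrow(ex$kept)),
                 function(i) trial_tracking_index(ex$kept[i, ]),
                 numeric(2)))
  tibble::tibble(
    session_id = session_id,
    slope_radial = sl$slope_radial, slope_angular = sl$slope_angular,
    r2_radial = sl$r2_radial, r2_angular = sl$r2_angular,
    fraction_excluded_near_origin = ex$report$fraction_excluded_near_origin,
    fraction_no_stop = ex$report$fraction_no_stop,
    fraction_rewarded = mean(ex$kept$rewarded),
    tracking_index_mean = mean(ti[, "whole"], na.rm = TRUE),
    tracking_index_first_second = mean(ti[, "first_second"], na.rm = TRUE))
}
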