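#' Configuration for synthetic firefly sessions
#'
#' Bundles the generator's study conditions: task geometry (targets uniform
#' over 1--4 m and +/-40 deg), joystick caps (2 m/s, 90 deg/s), 300 ms target
#' visibility, 0.6 m reward boundary, truncated-exponential inter-trial
#' delays (0.2--2 s, mean 0.5 s), behavioral undershoot gains, gaze tracking
#' quality, and the neural cohort (area composition and tuning-probability
#' profiles).
#'
#' @param n_trials Number of trials (default 300).
#' @param n_units Number of units (default 40).
#' @param gains Radial/angular multiplicative endpoint gains
#'   (default `c(radial = 0.89, angular = 0.79)`).
#' @param noise_sd Endpoint noise SDs (cm, deg).
#' @param fraction_no_stop,fraction_near_origin Planted rates of trials with
#'   no stop within 7 s and of stops within 0.5 m of the origin.
#' @param tracking_quality Expected target-tracking index of generated gaze.
#' @param acq_rate Acquisition rate of behavioral streams (Hz).
#' @param dt Model bin width (s).
#' @param areas Area label per unit (recycled from the default mix).
#' @param mean_rate_hz Range of baseline firing rates.
#' @param coupling_pairs Number of directed coupled pairs to plant.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_trials = 300, n_units = 40,
                       gains = c(radial = 0.89, angular = 0.79),
                       noise_sd = c(radial = 40, angular = 5),
                       fraction_no_stop = 0.13,
                       fraction_near_origin = 0.05,
                       tracking_quality = 0.8,
                       acq_rate = 833.33, dt = 0.006,
                       areas = NULL,
                       mean_rate_hz = c(5, 20),
                       coupling_pairs = 0L) {
  if (is.null(areas)) {
    mix <- c("MSTd", "7a", "7a", "dlPFC")
    areas <- rep_len(mix, n_units)
  }
  structure(list(n_trials = n_trials, n_units = n_units, gains = gains,
                 noise_sd = noise_sd, fraction_no_stop = fraction_no_stop,
                 fraction_near_origin = fraction_near_origin,
                 tracking_quality = tracking_quality, acq_rate = acq_rate,
                 dt = dt, areas = rep_len(areas, n_units),
                 mean_rate_hz = mean_rate_hz,
                 coupling_pairs = as.integer(coupling_pairs)),
            class = "sim_config")
}

## Truncated-exponential sampler with prescribed truncated mean.
rtrunc_exp <- function(n, lo = 0.2, hi = 2.0, mean = 0.5) {
  tmean <- function(r) {
    1 / r + (lo * exp(-r * lo) - hi * exp(-r * hi)) /
      (exp(-r * lo) - exp(-r * hi))
  }
  r <- stats::uniroot(function(r) tmean(r) - mean, c(0.2, 50))$root
  u <- runif(n)
  stats::qexp(stats::pexp(lo, r) + u * (stats::pexp(hi, r) -
                                          stats::pexp(lo, r)), r)
}

## Quadratic Bezier from the origin (initial heading straight ahead) to P,
## with dense arc-length table for reparameterization.
bezier_path <- function(px, py, n_dense = 600) {
  d <- sqrt(px^2 + py^2)
  bx <- 0; by <- 0.4 * d
  u <- seq(0, 1, length.out = n_dense)
  x <- (1 - u)^2 * 0 + 2 * (1 - u) * u * bx + u^2 * px
  y <- (1 - u)^2 * 0 + 2 * (1 - u) * u * by + u^2 * py
  dx <- 2 * (1 - u) * bx + 2 * u * (px - bx)
  dy <- 2 * (1 - u) * (by - 0) + 2 * u * (py - by)
  arc <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  list(u = u, x = x, y = y, heading = atan2(dx, dy) * 180 / pi,
       arc = arc, length = arc[n_dense])
}

## One steered trial: raised-cosine speed profile along a Bezier arc ending
## exactly at the planned endpoint; re-tried with a longer movement time if a
## speed cap would be violated.
steer_trial <- function(px, py, acq_rate, v_max = 200, w_max = 90) {
  bz <- bezier_path(px, py)
  t_mv <- max(0.9, bz$length / 110)
  for (try in 1:6) {
    v_pk <- 2 * bz$length / t_mv
    step <- 1 / acq_rate
    tt <- seq(0, t_mv, by = step)
    s <- bz$length * (tt / t_mv - sin(2 * pi * tt / t_mv) / (2 * pi))
    ui <- approx(bz$arc, bz$u, xout = pmin(s, bz$length), rule = 2)$y
    x <- approx(bz$u, bz$x, xout = ui)$y
    y <- approx(bz$u, bz$y, xout = ui)$y
    heading <- approx(bz$u, bz$heading, xout = ui)$y
    lin_vel <- v_pk * sin(pi * tt / t_mv)^2
    ang_vel <- c(0, wrap_deg(diff(heading))) / step
    if (v_pk <= v_max * 0.98 && max(abs(ang_vel)) <= w_max * 0.98) {
      return(tibble::tibble(t = tt, x = x, y = y, heading = heading,
                            lin_vel = lin_vel, ang_vel = ang_vel))
    }
    t_mv <- t_mv * 1.35
  }
  stop("could not steer to endpoint within speed caps (infeasible gains?)")
}

#' Generate firefly-task behavior with known ground truth
#'
#' Targets are uniform over 1--4 m and +/-40 deg; trajectories follow a smooth
#' steering controller honoring the 2 m/s and 90 deg/s caps; endpoints are
#' `gain x target + noise`; reward is delivered when the endpoint falls within
#' 0.6 m of the target center. Configurable fractions of near-origin-stop and
#' no-stop (7 s timeout) trials are planted.
#'
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return Trial tibble: one row per trial with target/endpoint polar
#'   coordinates, event times (s from trial start), reward flag, session-clock
#'   `t_start`, `duration`, and a `trajectory` list-column at the acquisition
#'   rate. (Gaze is added by [generate_gaze()].)
#' @export
generate_behavior <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  step <- 1 / config$acq_rate
  target_r <- runif(n, 100, 400)
  target_theta <- runif(n, -40, 40)
  kind <- sample(c("normal", "near_origin", "no_stop"), n, replace = TRUE,
                 prob = c(1 - config$fraction_near_origin -
                            config$fraction_no_stop,
                          config$fraction_near_origin,
                          config$fraction_no_stop))
  delays <- rtrunc_exp(n)
  reward_wait <- rtrunc_exp(n, 0.1, 0.6, 0.25)
  rows <- vector("list", n)
  t_start <- 0
  for (i in seq_len(n)) {
    if (kind[i] == "no_stop") {
      tt <- seq(0, 7, by = step)
      v <- 60 + 20 * sin(2 * pi * tt / 7)
      heading <- 0.8 * target_theta[i] * pmin(tt / 3, 1)
      ang_vel <- c(0, wrap_deg(diff(heading))) / step
      xy_step <- v * step
      x <- cumsum(xy_step * sinpi(heading / 180))
      y <- cumsum(xy_step * cospi(heading / 180))
      traj <- tibble::tibble(t = tt, x = c(0, x[-length(x)]),
                             y = c(0, y[-length(y)]), heading = heading,
                             lin_vel = v, ang_vel = ang_vel)
      ep_r <- NA_real_; ep_th <- NA_real_
      t_move_on <- 0.25; t_move_off <- NA_real_; rewarded <- FALSE
      duration <- 7
    } else {
      if (kind[i] == "near_origin") {
        ep_r <- runif(1, 10, 45)
        ep_th <- target_theta[i] + rnorm(1, 0, config$noise_sd["angular"])
      } else {
        ep_r <- max(20, config$gains["radial"] * target_r[i] +
                      rnorm(1, 0, config$noise_sd["radial"]))
        ep_th <- config$gains["angular"] * target_theta[i] +
          rnorm(1, 0, config$noise_sd["angular"])
      }
      mv <- steer_trial(ep_r * sinpi(ep_th / 180), ep_r * cospi(ep_th / 180),
                        config$acq_rate)
      t_move_on <- round(runif(1, 0.1, 0.4) / step) * step
      post <- 0.8
      pre_t <- seq(0, t_move_on - step, by = step)
      post_t <- seq(step, post, by = step)
      traj <- dplyr::bind_rows(
        tibble::tibble(t = pre_t, x = 0, y = 0, heading = 0,
                       lin_vel = 0, ang_vel = 0),
        dplyr::mutate(mv, t = .data$t + t_move_on),
        tibble::tibble(t = post_t + t_move_on + max(mv$t),
                       x = mv$x[nrow(mv)], y = mv$y[nrow(mv)],
                       heading = mv$heading[nrow(mv)],
                       lin_vel = 0, ang_vel = 0))
      t_move_off <- t_move_on + max(mv$t)
      duration <- max(traj$t)
      tx <- target_r[i] * sinpi(target_theta[i] / 180)
      ty <- target_r[i] * cospi(target_theta[i] / 180)
      err <- sqrt((traj$x[nrow(traj)] - tx)^2 + (traj$y[nrow(traj)] - ty)^2)
      rewarded <- err <= 60
    }
    rows[[i]] <- tibble::tibble(
      trial_id = i, target_r = target_r[i], target_theta = target_theta[i],
      endpoint_r = ep_r, endpoint_theta = ep_th,
      t_target_on = 0, t_target_off = 0.3,
      t_move_on = t_move_on, t_move_off = t_move_off,
      t_reward = if (rewarded) t_move_off + reward_wait[i] else NA_real_,
      rewarded = rewarded, t_start = t_start, duration = duration,
      trajectory = list(traj))
    t_start <- t_start + duration + delays[i]
  }
  dplyr::bind_rows(rows)
}

#' Generate gaze traces with a target tracking quality
#'
#' Observed gaze is the perfect-fixation prediction mixed with smooth AR(1)
#' drift noise, scaled per trial so the measured target-tracking index equals
#' `tracking_quality`; at quality 0, gaze is independent white noise with
#' matched variance (no correspondence with the prediction).
#'
#' @param trials Trial tibble from [generate_behavior()].
#' @param tracking_quality Value in `[0, 1]`.
#' @param seed Optional RNG seed.
#' @return `trials` with a `gaze` list-column added.
#' @export
generate_gaze <- function(trials, tracking_quality = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- tracking_quality
  if (q < 0 || q > 1) stop("tracking_quality must be in [0, 1]")
  phi <- 0.95
  gaze <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    traj <- trials$trajectory[[i]]
    pred <- predict_gaze(traj, trials$target_r[i], trials$target_theta[i])
    g <- pred[c("t", "lh", "lv", "rh", "rv")]
    n <- nrow(pred)
    cols <- c("lh", "lv", "rh", "rv")
    if (q >= 1) {
      gaze[[i]] <- g
      next
    }
    if (q <= 0) {
      for (col in cols) {
        p <- pred[[col]]
        g[[col]] <- mean(p) + rnorm(n, 0, sqrt(max(var(p), 1e-6)))
      }
      gaze[[i]] <- g
      next
    }
    ## AR(1) drift per component, then one common scale chosen so the
    ## trial's measured tracking index equals q
    eps <- lapply(cols, function(col) {
      p <- pred[[col]]
      sd_m <- sqrt(max(var(p), 1e-6) * (1 - q^2) / max(q^2, 1e-6))
      e <- rnorm(n, 0, sd_m * sqrt(1 - phi^2))
      as.numeric(stats::filter(e, phi, method = "recursive"))
    })
    names(eps) <- cols
    ok <- pred$valid
    idx_at <- function(cc) {
      for (col in cols) g[[col]] <- pred[[col]] + cc * eps[[col]]
      tracking_index(g[ok, ], pred[ok, ])
    }
    cc <- tryCatch(
      stats::uniroot(function(cc) idx_at(cc) - q, c(1e-6, 50),
                     extendInt = "downX", tol = 1e-4)$root,
      error = function(e) 1)
    for (col in cols) g[[col]] <- pred[[col]] + cc * eps[[col]]
    gaze[[i]] <- g
  }
  trials$gaze <- gaze
  trials
}

## Band-limited oscillator phases: advance at band-center frequency with
## phase diffusion, wrapped to (-pi, pi].
gen_lfp_phases <- function(duration, acq_rate, diffusion = 1.5,
                           centers = c(theta = 6, alpha = 10, beta = 21)) {
  step <- 1 / acq_rate
  tt <- seq(0, duration, by = step)
  n <- length(tt)
  out <- tibble::tibble(t = tt)
  for (b in names(centers)) {
    dphi <- 2 * pi * centers[[b]] * step +
      rnorm(n, 0, diffusion * sqrt(step))
    out[[b]] <- wrap_rad(runif(1, -pi, pi) + cumsum(dphi))
  }
  out
}

## ---- ground truth ------------------------------------------------------

true_shape <- function(type, params) {
  switch(type,
    bump = function(x) params$amp *
      exp(-(x - params$center)^2 / (2 * params$width^2)),
    sigmoid = function(x) params$amp /
      (1 + exp(-(x - params$center) / params$width)),
    cosine = function(x) params$amp * cos(x - params$center),
    spline = function(x) {
      as.numeric(bspline_basis(x, params$knots) %*% params$beta)
    },
    stop("unknown tuning shape ", type))
}

#' Spline-class ground-truth tuning for a session covariate
#'
#' Projects a parametric shape onto the encoding model's own spline family
#' (cubic B-splines on equi-probable knots of the session's covariate), so
#' the generated log rate lies exactly in the fitted model class -- the
#' generator's tuning functions are genuine P-GAM tuning functions.
#'
#' @param session A `binned_session`.
#' @param variable Continuous covariate name.
#' @param shape A `list(type, params)` parametric shape to project.
#' @param n_knots Knots (default 15, matching the model default).
#' @return A `list(type = "spline", params = list(knots, beta))` tuning spec.
#' @export
spline_truth <- function(session, variable, shape, n_knots = 15L) {
  x <- session$bins[[variable]]
  knots <- suppressWarnings(place_knots(x, n_knots))
  st <- smooth_term(variable, "continuous", knots = knots)
  B <- eval_basis(st, x)
  f <- eval_true_tuning(shape,
                        pmin(pmax(x, knots[1]), knots[length(knots)]))
  beta <- qr.solve(crossprod(B) + 1e-8 * diag(ncol(B)), crossprod(B, f))
  list(type = "spline",
       params = list(knots = knots, beta = as.numeric(beta)))
}

#' Draw a ground-truth encoding cohort
#'
#' Each unit gets a baseline rate, a subset of tuned task variables with
#' parametric tuning shapes (bumps and sigmoids on continuous variables,
#' cosine phase-locking on LFP phases, decaying kernels on events), a
#' refractory spike-history kernel, and optionally directed coupling kernels
#' between units. Tuning probabilities follow qualitative area profiles
#' (MSTd eye-heavy, 7a sensorimotor/LFP-heavy, dlPFC latent-heavy).
#'
#' @param config A [sim_config()].
#' @param covariate_ranges Named list of covariate ranges used to place bump
#'   centers (defaults cover the task geometry).
#' @param seed Optional RNG seed.
#' @return List of class `ground_truth` with `units` (tibble: unit_id, area,
#'   electrode_x, intercept), `tuning` (per-unit named list of
#'   `list(type, params)`), `history` (per-unit lag kernels), `coupling`
#'   (tibble of edges with kernel list-column).
#' @export
make_ground_truth <- function(config = sim_config(),
                              covariate_ranges = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(covariate_ranges)) {
    covariate_ranges <- list(
      lin_vel = c(0, 200), ang_vel = c(-90, 90), lin_acc = c(-250, 250),
      ang_acc = c(-200, 200), dist_origin = c(0, 400),
      ang_origin = c(-45, 45), dist_target = c(0, 400),
      ang_target = c(-60, 60), eye_hori = c(-30, 30), eye_vert = c(-35, 0))
  }
  profiles <- list(
    MSTd  = c(lin_vel = .5, ang_vel = .5, lin_acc = .2, ang_acc = .2,
              dist_origin = .2, ang_origin = .2, dist_target = .45,
              ang_target = .45, eye_hori = .65, eye_vert = .6,
              target_on = .5, move_on = .3, move_off = .3, reward = .3,
              lfp_theta = .2, lfp_alpha = .25, lfp_beta = .25),
    `7a`  = c(lin_vel = .7, ang_vel = .65, lin_acc = .5, ang_acc = .5,
              dist_origin = .45, ang_origin = .4, dist_target = .2,
              ang_target = .2, eye_hori = .25, eye_vert = .25,
              target_on = .4, move_on = .55, move_off = .55, reward = .35,
              lfp_theta = .45, lfp_alpha = .5, lfp_beta = .6),
    dlPFC = c(lin_vel = .35, ang_vel = .3, lin_acc = .25, ang_acc = .25,
              dist_origin = .5, ang_origin = .5, dist_target = .55,
              ang_target = .55, eye_hori = .55, eye_vert = .5,
              target_on = .45, move_on = .3, move_off = .3, reward = .4,
              lfp_theta = .25, lfp_alpha = .25, lfp_beta = .35))
  cn <- task_covariate_names()
  n <- config$n_units
  units <- tibble::tibble(
    unit_id = sprintf("u%03d", seq_len(n)),
    area = config$areas,
    electrode_x = round(runif(n, 0, 3600) / 400) * 400,
    intercept = log(runif(n, config$mean_rate_hz[1],
                          config$mean_rate_hz[2]) * config$dt))
  tuning <- vector("list", n)
  history <- vector("list", n)
  names(tuning) <- names(history) <- units$unit_id
  for (i in seq_len(n)) {
    pr <- profiles[[units$area[i]]]
    tuned <- names(pr)[runif(length(pr)) < pr]
    tl <- list()
    for (v in tuned) {
      if (v %in% cn$continuous) {
        rg <- covariate_ranges[[v]]
        type <- sample(c("bump", "sigmoid"), 1, prob = c(0.7, 0.3))
        tl[[v]] <- list(type = type, params = list(
          amp = runif(1, 0.5, 1.2) * sample(c(-1, 1), 1),
          center = runif(1, rg[1] + 0.15 * diff(rg), rg[2] - 0.15 * diff(rg)),
          width = runif(1, 0.08, 0.2) * diff(rg)))
      } else if (v %in% cn$lfp) {
        tl[[v]] <- list(type = "cosine", params = list(
          amp = runif(1, 0.25, 0.6), center = runif(1, -pi, pi)))
      } else {                       # event kernel over lags
        L <- 25L
        lag <- seq_len(L)
        amp <- runif(1, 0.6, 1.4) * sample(c(-1, 1), 1, prob = c(.25, .75))
        peak <- sample(2:8, 1)
        tl[[v]] <- list(type = "event_kernel", params = list(
          kernel = amp * exp(-(lag - peak)^2 / (2 * 2.5^2))))
      }
    }
    tuning[[i]] <- tl
    history[[i]] <- c(-2.5, -1.0, -0.3, -0.1, 0, 0)   # refractory, 36 ms
  }
  coupling <- tibble::tibble(sender = character(), receiver = character(),
                             kernel = list())
  if (config$coupling_pairs > 0L && n >= 2L) {
    pairs <- matrix(nrow = 0, ncol = 2)
    while (nrow(pairs) < config$coupling_pairs) {
      p <- sample(n, 2)
      pairs <- unique(rbind(pairs, p))
    }
    kern <- lapply(seq_len(nrow(pairs)), function(k) {
      s <- pairs[k, 1]; r <- pairs[k, 2]
      L <- if (units$area[s] == units$area[r]) 6L else 100L
      lag <- seq_len(L)
      peak <- if (L == 6L) 2 else sample(3:15, 1)
      runif(1, 0.5, 1.0) * sample(c(-1, 1), 1, prob = c(.3, .7)) *
        exp(-(lag - peak)^2 / (2 * (L / 8)^2))
    })
    coupling <- tibble::tibble(sender = units$unit_id[pairs[, 1]],
                               receiver = units$unit_id[pairs[, 2]],
                               kernel = kern)
  }
  structure(list(units = units, tuning = tuning, history = history,
                 coupling = coupling, config = config),
            class = "ground_truth")
}

#' Evaluate a ground-truth tuning function
#'
#' @param spec A `list(type, params)` entry from [make_ground_truth()].
#' @param x Covariate values (continuous/circular shapes only).
#' @return Log-rate contribution at `x`.
#' @export
eval_true_tuning <- function(spec, x) true_shape(spec$type, spec$params)(x)

#' Generate spike counts (and attach them) from ground truth
#'
#' Composes each unit's log rate from its intercept, tuning functions of the
#' binned covariates, event kernels (causal convolution), and -- sequentially
#' in time -- spike-history and partner-coupling contributions, then draws
#' per-bin Poisson counts. Rates are capped at `max_rate` spikes per bin.
#'
#' @param session A `binned_session` (counts may be empty).
#' @param ground_truth A [make_ground_truth()] object.
#' @param max_rate Cap on the per-bin Poisson mean (default 4).
#' @param seed Optional RNG seed.
#' @return The session with `counts`, `units` and `ground_truth` filled in.
#' @export
generate_spikes <- function(session, ground_truth, max_rate = 4,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gt <- ground_truth
  cn <- task_covariate_names()
  Tn <- nrow(session$bins)
  U <- nrow(gt$units)
  eta0 <- matrix(rep(gt$units$intercept, each = Tn), Tn, U)
  for (i in seq_len(U)) {
    tl <- gt$tuning[[i]]
    area <- gt$units$area[i]
    for (v in names(tl)) {
      spec <- tl[[v]]
      if (spec$type == "event_kernel") {
        z <- session$bins[[v]]
        k <- spec$params$kernel
        contr <- stats::filter(z, filter = c(0, k), sides = 1)
        contr[is.na(contr)] <- 0
        eta0[, i] <- eta0[, i] + as.numeric(contr)
      } else if (v %in% cn$lfp) {
        band <- sub("lfp_", "", v)
        col <- paste0("lfp_", band, "_", area)
        ph <- if (!is.null(session$lfp) && col %in% names(session$lfp)) {
          session$lfp[[col]]
        } else stop("session lacks LFP phases for area ", area)
        eta0[, i] <- eta0[, i] + eval_true_tuning(spec, ph)
      } else {
        eta0[, i] <- eta0[, i] + eval_true_tuning(spec, session$bins[[v]])
      }
    }
  }
  if (any(!is.finite(eta0))) stop("non-finite log rate; offending unit: ",
                                  gt$units$unit_id[which(!is.finite(
                                    colSums(eta0)))[1]])
  hist_mat <- do.call(cbind, gt$history)
  ids <- gt$units$unit_id
  E <- nrow(gt$coupling)
  if (E > 0L) {
    Lk <- max(vapply(gt$coupling$kernel, length, integer(1)))
    edge_k <- vapply(gt$coupling$kernel,
                     function(k) c(k, rep(0, Lk - length(k))), numeric(Lk))
    edge_k <- matrix(edge_k, nrow = Lk)
    es <- match(gt$coupling$sender, ids) - 1L
    er <- match(gt$coupling$receiver, ids) - 1L
  } else {
    edge_k <- matrix(0, 1, 0); es <- integer(0); er <- integer(0)
  }
  counts <- gen_spikes_seq(eta0, hist_mat, es, er, edge_k, max_rate)
  colnames(counts) <- ids
  session$counts <- counts
  session$units <- gt$units[c("unit_id", "area", "electrode_x")]
  session$ground_truth <- gt
  session
}

#' Spike times consistent with binned counts
#'
#' Spreads each bin's count uniformly within the bin (sorted), giving a
#' spike-time list usable by [unit_qc()].
#'
#' @param session A `binned_session` with counts.
#' @param seed Optional RNG seed.
#' @return Named list of per-unit spike-time vectors.
#' @export
spike_times_from_counts <- function(session, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- session$dt
  lapply(setNames(seq_len(ncol(session$counts)),
                  colnames(session$counts)), function(i) {
    ct <- session$counts[, i]
    nz <- which(ct > 0L)
    sort(rep((nz - 1L) * dt, ct[nz]) + runif(sum(ct[nz]), 0, dt))
  })
}

#' Simulate a complete firefly session with known ground truth
#'
#' Runs the full generative chain: behavior, gaze, LFP phases, binning at the
#' model resolution, and ground-truth spiking. Identical `config` and `seed`
#' reproduce the session exactly.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (single integer; governs all stages).
#' @param ground_truth Optional pre-built [make_ground_truth()].
#' @return A `binned_session` with `ground_truth` attached.
#' @export
simulate_session <- function(config = sim_config(), seed = 1,
                             ground_truth = NULL) {
  set.seed(seed)
  trials <- generate_behavior(config)
  trials <- generate_gaze(trials, config$tracking_quality)
  t_end <- max(trials$t_start + trials$duration) + 0.1
  lfp_areas <- unique(config$areas)
  lfp <- lapply(setNames(lfp_areas, lfp_areas),
                function(a) gen_lfp_phases(t_end, config$acq_rate))
  session <- bin_session(trials, spikes = list(), lfp = lfp,
                         unit_meta = NULL, dt = config$dt)
  if (is.null(ground_truth)) ground_truth <- make_ground_truth(config)
  generate_spikes(session, ground_truth)
}
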