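#' Canonical task-covariate names
#'
#' The encoding model's task inputs: eight continuous sensorimotor/latent
#' variables, two eye-position signals, four discrete task events, and the
#' ongoing LFP phase in three frequency bands -- 17 inputs in total.
#'
#' @return Named list with elements `continuous`, `events`, `lfp` and `all`.
#' @export
task_covariate_names <- function() {
  continuous <- c("lin_vel", "ang_vel", "lin_acc", "ang_acc",
                  "dist_origin", "ang_origin", "dist_target", "ang_target",
                  "eye_hori", "eye_vert")
  events <- c("target_on", "move_on", "move_off", "reward")
  lfp <- c("lfp_theta", "lfp_alpha", "lfp_beta")
  list(continuous = continuous, events = events, lfp = lfp,
       all = c(continuous, events, lfp))
}

wrap_deg <- function(a) ((a + 180) %% 360) - 180
wrap_rad <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Latent navigation covariates along one trial trajectory
#'
#' From a trajectory (position, heading, speeds) and the trial's target
#' location, computes the four latent variables of the task: distance
#' travelled from the origin (arc length), cumulative heading change from the
#' initial heading, and the Euclidean distance / signed egocentric angle to
#' the (hidden) target. All four reset at trial start by construction.
#'
#' @param trajectory Tibble with columns `t` (s), `x`, `y` (cm; `x` rightward,
#'   `y` forward from the trial-start pose), `heading` (deg, rightward
#'   positive), `lin_vel` (cm/s), `ang_vel` (deg/s).
#' @param target_r,target_theta Target polar coordinates (cm, deg).
#' @return The trajectory tibble with columns `dist_origin`, `ang_origin`,
#'   `dist_target`, `ang_target` added.
#' @export
compute_latent_covariates <- function(trajectory, target_r, target_theta) {
  if (is.na(target_r) || is.na(target_theta)) stop("missing target location")
  tr <- trajectory
  n <- nrow(tr)
  step <- diff(tr$t)
  ds <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  tr$dist_origin <- c(0, cumsum(ds))
  tr$ang_origin <- cumsum(c(0, wrap_deg(diff(tr$heading))))
  tx <- target_r * sinpi(target_theta / 180)
  ty <- target_r * cospi(target_theta / 180)
  ex <- tx - tr$x
  ey <- ty - tr$y
  tr$dist_target <- sqrt(ex^2 + ey^2)
  bearing <- atan2(ex, ey) * 180 / pi
  tr$ang_target <- wrap_deg(bearing - tr$heading)
  tr
}

#' Spike-train isolation quality control
#'
#' Inter-spike-interval violations (ISIv) are the fraction of spikes occurring
#' within 1 ms of the previous spike; presence rate (PR) is 1 minus the
#' fraction of 1-minute bins containing no spike. A unit passes when
#' ISIv < 0.20 and PR > 0.90.
#'
#' @param spike_times Numeric vector of spike times (seconds), sorted.
#' @param session_duration Session duration in seconds.
#' @return Tibble with `isi_violation_fraction`, `presence_rate`, `pass`.
#' @export
unit_qc <- function(spike_times, session_duration) {
  if (length(spike_times) < 1L) {
    return(tibble::tibble(isi_violation_fraction = NA_real_,
                          presence_rate = 0, pass = FALSE))
  }
  if (is.unsorted(spike_times)) stop("non-monotonic spike times")
  isiv <- if (length(spike_times) < 2L) 0 else {
    sum(diff(spike_times) <= 0.001) / length(spike_times)
  }
  n_min <- max(1L, ceiling(session_duration / 60))
  occupied <- unique(pmin(floor(spike_times / 60), n_min - 1L))
  pr <- length(occupied) / n_min
  tibble::tibble(isi_violation_fraction = isiv, presence_rate = pr,
                 pass = isiv < 0.20 & pr > 0.90)
}

## Average samples into model bins; returns numeric vector of length n_bins
## with NA where a bin received no sample.
bin_average <- function(ts, vals, dt, n_bins) {
  idx <- pmin(pmax(floor(ts / dt) + 1L, 1L), n_bins)
  s <- rowsum(vals, idx)
  n <- rowsum(rep(1, length(idx)), idx)
  out <- rep(NA_real_, n_bins)
  out[as.integer(rownames(s))] <- s / n
  out
}

fill_locf <- function(v, default = 0) {
  if (all(is.na(v))) return(rep(default, length(v)))
  i <- cummax(ifelse(is.na(v), 0L, seq_along(v)))
  out <- ifelse(i == 0L, NA, v[pmax(i, 1L)])
  # leading NAs: back-fill with first observed value
  out[is.na(out)] <- v[which(!is.na(v))[1]]
  out
}

#' Bin a session of trials, spikes and LFP phases at the model resolution
#'
#' Concatenates trials (inter-trial intervals retained and flagged), counts
#' spikes per bin with no baseline correction, averages continuous covariates
#' within each bin, marks the bin containing each event time, and resamples
#' LFP band phases. Latent covariates reset at each trial start.
#'
#' @param trials Trial tibble as produced by [generate_behavior()]:
#'   one row per trial with scalar fields and `trajectory` / `gaze`
#'   list-columns sampled at the acquisition rate.
#' @param spikes Named list of per-unit spike-time vectors (session clock, s).
#' @param lfp Optional named list (per area) of tibbles `t`, `theta`, `alpha`,
#'   `beta` giving band phases (radians) at the acquisition rate.
#' @param unit_meta Tibble with `unit_id`, `area`, `electrode_x` (micrometres).
#' @param dt Bin width in seconds (default 0.006).
#' @param lfp_binning `"center"` takes the phase at the bin center sample;
#'   `"circular_mean"` takes the per-bin circular mean of phases.
#' @return A `binned_session`: list with `dt`, `bins` (tibble: time, trial,
#'   intertrial flag, continuous covariates, event indicators), `lfp` (tibble
#'   of per-area band phases), `counts` (bins x units matrix), `units`,
#'   `trials`.
#' @export
bin_session <- function(trials, spikes, lfp = NULL, unit_meta = NULL,
                        dt = 0.006,
                        lfp_binning = c("center", "circular_mean")) {
  lfp_binning <- match.arg(lfp_binning)
  stopifnot(nrow(trials) >= 1L)
  t_end <- max(trials$t_start + trials$duration)
  n_bins <- as.integer(ceiling(t_end / dt))
  bin_time <- (seq_len(n_bins) - 0.5) * dt
  cn <- task_covariate_names()

  ## spike counts
  units <- names(spikes)
  if (is.null(units)) {
    units <- if (length(spikes)) paste0("u", seq_along(spikes)) else
      character(0)
  }
  counts <- matrix(0L, n_bins, length(spikes),
                   dimnames = list(NULL, units))
  for (i in seq_along(spikes)) {
    st <- spikes[[i]]
    if (is.unsorted(st)) stop("non-monotonic spike times for unit ", units[i])
    st <- st[st >= 0 & st < n_bins * dt]
    if (length(st)) {
      tab <- tabulate(floor(st / dt) + 1L, nbins = n_bins)
      counts[, i] <- tab
    }
  }

  ## continuous covariates, concatenated across trials
  cont <- matrix(NA_real_, n_bins, length(cn$continuous),
                 dimnames = list(NULL, cn$continuous))
  trial_of_bin <- rep(NA_integer_, n_bins)
  for (k in seq_len(nrow(trials))) {
    tr <- trials$trajectory[[k]]
    gz <- trials$gaze[[k]]
    if (nrow(tr) > 1L) {
      gap <- max(diff(tr$t))
      if (gap > dt + 1e-9) {
        stop("covariate gap of ", signif(gap, 3), " s (> one bin) in trial ",
             trials$trial_id[k])
      }
    }
    tr <- compute_latent_covariates(tr, trials$target_r[k],
                                    trials$target_theta[k])
    step <- if (nrow(tr) > 1L) median(diff(tr$t)) else dt
    tr$lin_acc <- c(0, diff(tr$lin_vel)) / step
    tr$ang_acc <- c(0, diff(tr$ang_vel)) / step
    ts <- tr$t + trials$t_start[k]
    keep <- ts < n_bins * dt
    for (v in c("lin_vel", "ang_vel", "lin_acc", "ang_acc",
                "dist_origin", "ang_origin", "dist_target", "ang_target")) {
      bv <- bin_average(ts[keep], tr[[v]][keep], dt, n_bins)
      cont[, v] <- ifelse(is.na(cont[, v]), bv, cont[, v])
    }
    # binocular gaze averaged over eyes
    gh <- (gz$lh + gz$rh) / 2
    gv <- (gz$lv + gz$rv) / 2
    gts <- gz$t + trials$t_start[k]
    gkeep <- gts < n_bins * dt
    bh <- bin_average(gts[gkeep], gh[gkeep], dt, n_bins)
    bv <- bin_average(gts[gkeep], gv[gkeep], dt, n_bins)
    cont[, "eye_hori"] <- ifelse(is.na(cont[, "eye_hori"]), bh,
                                 cont[, "eye_hori"])
    cont[, "eye_vert"] <- ifelse(is.na(cont[, "eye_vert"]), bv,
                                 cont[, "eye_vert"])
    b0 <- max(1L, floor(trials$t_start[k] / dt) + 1L)
    b1 <- min(n_bins, ceiling((trials$t_start[k] + trials$duration[k]) / dt))
    trial_of_bin[b0:b1] <- trials$trial_id[k]
  }
  for (v in c("lin_vel", "ang_vel", "lin_acc", "ang_acc")) {
    cont[is.na(cont[, v]), v] <- 0   # stationary between trials
  }
  for (v in c("dist_origin", "ang_origin", "dist_target", "ang_target",
              "eye_hori", "eye_vert")) {
    cont[, v] <- fill_locf(cont[, v])
  }

  ## events: mark the bin containing each event time
  ev <- matrix(0L, n_bins, length(cn$events),
               dimnames = list(NULL, cn$events))
  mark <- function(col, tt) {
    tt <- tt[!is.na(tt) & tt >= 0 & tt < n_bins * dt]
    ev[floor(tt / dt) + 1L, col] <<- 1L
  }
  mark("target_on", trials$t_start + trials$t_target_on)
  mark("move_on", trials$t_start + trials$t_move_on)
  mark("move_off", trials$t_start + trials$t_move_off)
  mark("reward", trials$t_start + trials$t_reward)

  bins <- tibble::as_tibble(cbind(as.data.frame(cont), as.data.frame(ev)))
  bins <- dplyr::mutate(bins, time = bin_time, trial = trial_of_bin,
                        intertrial = is.na(trial_of_bin), .before = 1L)

  ## LFP phases per area and band
  lfp_tbl <- NULL
  if (!is.null(lfp)) {
    cols <- list()
    for (area in names(lfp)) {
      la <- lfp[[area]]
      for (band in c("theta", "alpha", "beta")) {
        ph <- unwrap_then_bin(la$t, la[[band]], dt, n_bins, lfp_binning)
        cols[[paste0("lfp_", band, "_", area)]] <- ph
      }
    }
    lfp_tbl <- tibble::as_tibble(cols)
  }

  if (is.null(unit_meta)) {
    unit_meta <- tibble::tibble(unit_id = units, area = "MSTd",
                                electrode_x = 0)
  }
  structure(list(dt = dt, bins = bins, lfp = lfp_tbl, counts = counts,
                 units = unit_meta, trials = trials),
            class = "binned_session")
}

## Resample a phase series to the bin grid. Phases are unwrapped, interpolated
## or averaged, then wrapped back to (-pi, pi].
unwrap_then_bin <- function(ts, phase, dt, n_bins, method) {
  un <- cumsum(c(phase[1], wrap_rad(diff(phase))))
  if (method == "center") {
    centers <- (seq_len(n_bins) - 0.5) * dt
    v <- approx(ts, un, xout = centers, rule = 2)$y
  } else {
    v <- fill_locf(bin_average(ts, un, dt, n_bins))
  }
  wrap_rad(v)
}

#' @export
print.binned_session <- function(x, ...) {
  cat("<binned_session> ", nrow(x$bins), " bins of ", x$dt * 1000, " ms, ",
      ncol(x$counts), " units, ", nrow(x$trials), " trials\n", sep = "")
  invisible(x)
}

#' Serialize / load a binned session as a directory of plain-text files
#'
#' Writes `trials.csv` (one row per trial, scalar fields), `units.csv`,
#' `bins.csv` (continuous covariates + event trains), `counts.csv`,
#' `lfp.csv`, and a `session.json` manifest (bin width, covariate names,
#' band definitions). All CSVs are RFC-4180 UTF-8.
#'
#' @param session A `binned_session`.
#' @param dir Directory to write to (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- dplyr::select(session$trials, -dplyr::any_of(c("trajectory", "gaze")))
  readr::write_csv(tr, file.path(dir, "trials.csv"))
  readr::write_csv(session$units, file.path(dir, "units.csv"))
  readr::write_csv(session$bins, file.path(dir, "bins.csv"))
  readr::write_csv(tibble::as_tibble(session$counts),
                   file.path(dir, "counts.csv"))
  if (!is.null(session$lfp)) {
    readr::write_csv(session$lfp, file.path(dir, "lfp.csv"))
  }
  jsonlite::write_json(
    list(dt = session$dt, covariates = task_covariate_names(),
         bands = list(theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30)),
         n_bins = nrow(session$bins), n_units = ncol(session$counts)),
    file.path(dir, "session.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "session.json"))
  need <- c("trials.csv", "units.csv", "bins.csv", "counts.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("session directory is missing stream(s): ",
         paste(missing, collapse = ", "))
  }
  bins <- readr::read_csv(file.path(dir, "bins.csv"),
                          show_col_types = FALSE, progress = FALSE)
  counts <- as.matrix(readr::read_csv(file.path(dir, "counts.csv"),
                                      show_col_types = FALSE,
                                      progress = FALSE))
  lfp <- NULL
  if (file.exists(file.path(dir, "lfp.csv"))) {
    lfp <- readr::read_csv(file.path(dir, "lfp.csv"),
                           show_col_types = FALSE, progress = FALSE)
  }
  structure(list(dt = manifest$dt, bins = bins, lfp = lfp, counts = counts,
                 units = readr::read_csv(file.path(dir, "units.csv"),
                                         show_col_types = FALSE,
                                         progress = FALSE),
                 trials = readr::read_csv(file.path(dir, "trials.csv"),
                                          show_col_types = FALSE,
                                          progress = FALSE)),
            class = "binned_session")
}
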