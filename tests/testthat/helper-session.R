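# Shared small synthetic fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

small_trials <- function() {
  if (is.null(.fixtures$trials)) {
    cfg <- sim_config(n_trials = 24, n_units = 2)
    set.seed(42)
    tr <- generate_behavior(cfg)
    .fixtures$trials <- generate_gaze(tr, cfg$tracking_quality)
    .fixtures$cfg <- cfg
  }
  .fixtures$trials
}

small_session <- function() {
  if (is.null(.fixtures$session)) {
    trials <- small_trials()
    cfg <- .fixtures$cfg
    t_end <- max(trials$t_start + trials$duration) + 0.1
    set.seed(43)
    lfp <- list(MSTd = gen_lfp_phases(t_end, cfg$acq_rate),
                `7a` = gen_lfp_phases(t_end, cfg$acq_rate))
    .fixtures$session <- bin_session(trials, spikes = list(), lfp = lfp,
                                     dt = cfg$dt)
  }
  .fixtures$session
}

# One fitted unit (2 true + 2 null covariates), reused across tests.
small_fit <- function() {
  if (is.null(.fixtures$fit)) {
    ss <- small_session()
    gt <- make_ground_truth(sim_config(n_trials = 24, n_units = 1,
                                       areas = "MSTd"), seed = 7)
    gt$tuning[[1]] <- list(
      lin_vel = list(type = "bump",
                     params = list(amp = 1.1, center = 120, width = 45)),
      eye_hori = list(type = "sigmoid",
                      params = list(amp = 0.8, center = 0, width = 8)))
    gt$history[[1]] <- rep(0, 6)
    gt$units$intercept[1] <- log(12 * 0.006)
    ss <- generate_spikes(ss, gt, seed = 8)
    spec <- pgam_spec(continuous = c("lin_vel", "eye_hori", "ang_vel",
                                     "dist_target"),
                      events = "target_on", lfp = "lfp_theta",
                      n_knots = 8, n_phase_basis = 6, event_filter = 0.12,
                      spike_history = FALSE)
    des <- suppressWarnings(assemble_design(ss, "u001", spec))
    .fixtures$fit <- fit_pgam(des, folds = 4, seed = 1)
    .fixtures$design <- des
    .fixtures$truth <- gt
    .fixtures$spiking_session <- ss
  }
  list(fit = .fixtures$fit, design = .fixtures$design,
       truth = .fixtures$truth, session = .fixtures$spiking_session)
}
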