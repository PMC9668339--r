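# Synthetic candidate-edge table with a planted distance-dependent
# probability of significant coupling.
planted_edges <- function(n, prob_fn, seed = 1) {
  set.seed(seed)
  d <- sample(seq(100, 3600, by = 100), n, replace = TRUE)
  tibble::tibble(distance_um = d,
                 significant = runif(n) < prob_fn(d))
}

test_that("a planted sender-receiver kernel is detected, never a self edge", {
  cfg <- sim_config(n_trials = 30, n_units = 3, areas = "MSTd",
                    coupling_pairs = 0, acq_rate = 166.667)
  ss <- simulate_session(cfg, seed = 151)
  gt <- ss$ground_truth
  for (i in 1:3) gt$tuning[[i]] <- list()
  gt$units$intercept <- log(c(25, 15, 12) * 0.006)
  gt$coupling <- tibble::tibble(sender = "u001", receiver = "u002",
                                kernel = list(c(1.0, 0.6, 0.2, 0, 0, 0)))
  ss <- generate_spikes(ss, gt, seed = 152)
  spec <- pgam_spec(continuous = c("lin_vel", "eye_hori"),
                    events = "target_on", lfp = character(0),
                    n_knots = 6, event_filter = 0.12, coupling = "all")
  fits <- lapply(colnames(ss$counts), function(u) {
    des <- suppressWarnings(assemble_design(ss, u, spec))
    fit_pgam(des, folds = 4, seed = 1, outer_iter = 1)
  })
  graph <- extract_couplings(fits, ss$units)
  expect_true(all(graph$edges$sender != graph$edges$receiver))
  planted <- graph$edges[graph$edges$sender == "u001" &
                           graph$edges$receiver == "u002", ]
  expect_true(planted$significant)
  expect_equal(planted$sign, 1)
  expect_lte(planted$peak_lag_s, 0.018)
  # non-planted pairs mostly stay quiet
  others <- graph$edges[!(graph$edges$sender == "u001" &
                            graph$edges$receiver == "u002"), ]
  expect_lte(sum(others$significant), 1)
  # fractions are directional
  fr <- coupling_fractions(graph)
  expect_equal(nrow(fr), 1L)   # single area: 1x1 grid
  expect_gt(fr$fraction, 0)
})

test_that("distance-flat truth yields a flat corrected probability", {
  e <- planted_edges(600, function(d) rep(0.2, length(d)), seed = 2)
  dm <- distance_corrected_probability(e, seed = 1)
  expect_lt(abs(dm$p_ref - 0.2), 0.06)
  grid <- seq(200, 3000, by = 200)
  expect_lt(diff(range(dm$predict(grid))), 0.12)
  expect_true(all(dm$predict(grid) > 0 & dm$predict(grid) < 1))
})

test_that("planted exponential decay is recovered at the 500 um reference", {
  e <- planted_edges(3000, function(d) 0.3 * exp(-d / 400), seed = 3)
  dm <- distance_corrected_probability(e, seed = 1)
  truth <- 0.3 * exp(-500 / 400)
  expect_lt(abs(dm$p_ref - truth), 0.05)
  # fitted curve is decreasing over the bulk of the data range
  grid <- seq(200, 2500, by = 100)
  pr <- dm$predict(grid)
  expect_lt(pr[length(pr)], pr[1])
  expect_lt(mean(diff(pr) > 0.003), 0.2)
  expect_error(distance_corrected_probability(e[1:20, ]), ">= 50")
  same_d <- tibble::tibble(distance_um = rep(400, 100),
                           significant = runif(100) < 0.25)
  expect_warning(dm2 <- distance_corrected_probability(same_d),
                 "distinct distances")
  expect_lt(abs(dm2$p_ref - 0.25), 0.12)
})

test_that("session-level coupling-tracking correlations are detected", {
  set.seed(161)
  n <- 20
  ti <- runif(n, 0.4, 0.9)
  tbl <- dplyr::bind_rows(
    tibble::tibble(session_id = 1:n, sender_area = "MSTd",
                   receiver_area = "dlPFC",
                   fraction = 0.05 + 0.4 * ti + rnorm(n, 0, 0.03),
                   tracking_index = ti),
    tibble::tibble(session_id = 1:n, sender_area = "7a",
                   receiver_area = "7a",
                   fraction = runif(n, 0, 0.3), tracking_index = ti),
    tibble::tibble(session_id = 1:n, sender_area = "dlPFC",
                   receiver_area = "7a",
                   fraction = 0.1, tracking_index = ti))
  res <- coupling_behavior_correlation(tbl)
  planted <- res[res$sender_area == "MSTd", ]
  expect_gt(planted$slope, 0)
  expect_gt(planted$r2, 0.5)
  expect_lt(planted$p, 0.01)
  null_cell <- res[res$sender_area == "7a", ]
  expect_gt(null_cell$p, 0.01)
  # constant fraction: flagged, not crashed
  const <- res[res$sender_area == "dlPFC", ]
  expect_true(is.na(const$p) || const$r2 < 1e-10)
  expect_true(all(res$p_bonferroni >= res$p, na.rm = TRUE))
})

test_that("like-to-like connectivity is seen as a rank correlation", {
  set.seed(171)
  n_units <- 40
  shapes <- matrix(rnorm(n_units * 30), n_units)
  ids <- sprintf("u%03d", seq_len(n_units))
  pairs <- expand.grid(s = seq_len(n_units), r = seq_len(n_units))
  pairs <- pairs[pairs$s != pairs$r, ]
  sim <- vapply(seq_len(nrow(pairs)),
                function(i) cor(shapes[pairs$s[i], ], shapes[pairs$r[i], ]),
                numeric(1))
  meta <- tibble::tibble(unit_id = ids, area = "MSTd", electrode_x = 0)
  stacked <- list(shapes = shapes, unit_id = ids, area = rep("MSTd", n_units))
  mk_graph <- function(sig) {
    structure(list(edges = tibble::tibble(
      sender = ids[pairs$s], receiver = ids[pairs$r],
      sender_area = "MSTd", receiver_area = "MSTd",
      p_value = ifelse(sig, 1e-4, 0.5), significant = sig),
      alpha = 0.01, unit_meta = meta), class = "coupling_graph")
  }
  # perfect like-to-like: couple iff similarity above the top-quintile edge
  thr <- quantile(sim, 0.8)
  step <- tuning_similarity_vs_coupling(mk_graph(sim > thr), stacked,
                                        n_perm = 200, seed = 1)
  expect_gt(step$rho, 0.3)
  expect_lt(step$p_perm, 0.01)
  expect_equal(unname(tail(step$profile$rate, 1)), 1)
  expect_equal(unname(step$profile$rate[1]), 0)
  # graded like-to-like
  graded <- tuning_similarity_vs_coupling(
    mk_graph(runif(length(sim)) < plogis(4 * sim - 2)), stacked,
    n_perm = 200, seed = 1)
  expect_gt(graded$rho, 0)
  expect_lt(graded$p_perm, 0.05)
  # independent coupling: flat profile
  null <- tuning_similarity_vs_coupling(
    mk_graph(runif(length(sim)) < 0.15), stacked, n_perm = 200, seed = 1)
  expect_gt(null$p_perm, 0.05)
})

test_that("coupling graphs export as plain-text edge lists", {
  meta <- tibble::tibble(unit_id = c("a", "b"), area = c("MSTd", "dlPFC"),
                         electrode_x = c(0, 400))
  g <- structure(list(edges = tibble::tibble(
    sender = "a", receiver = "b", p_value = 0.001, significant = TRUE,
    peak_lag_s = 0.012, sign = 1, filter = list(1:5),
    sender_area = "MSTd", receiver_area = "dlPFC",
    distance_um = NA_real_), alpha = 0.01, unit_meta = meta),
    class = "coupling_graph")
  dir <- withr::local_tempdir()
  write_coupling_graph(g, dir)
  expect_true(all(file.exists(file.path(dir, c("edges.csv",
                                               "coupling_fractions.csv",
                                               "coupling_summary.json")))))
})
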