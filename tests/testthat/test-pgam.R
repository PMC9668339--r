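test_that("design assembly matches per-term construction", {
  sf <- small_fit()
  ss <- sf$session
  des <- sf$design
  # intercept column
  expect_true(all(des$X[, 1] == 1))
  # continuous block: centered spline basis of the covariate
  tm <- des$terms$lin_vel
  B <- eval_basis(tm$basis, ss$bins$lin_vel) %*% tm$basis$Z
  expect_equal(unname(des$X[, tm$cols]), unname(B))
  expect_lt(max(abs(colMeans(des$X[, tm$cols]))), 1e-10)
  # event block: causal convolution oracle
  te <- des$terms$target_on
  z <- ss$bins$target_on
  oracle <- matrix(0, length(z), te$basis$n_basis)
  for (t in seq_along(z)) {
    for (l in te$basis$lag_bins) {
      if (t - l >= 1) {
        oracle[t, ] <- oracle[t, ] + te$basis$lag_basis[l, ] * z[t - l]
      }
    }
  }
  expect_equal(unname(des$X[, te$cols]), oracle)
  # circular block evaluates the area's phase
  tc <- des$terms$lfp_theta
  Bc <- eval_basis(tc$basis, ss$lfp$lfp_theta_MSTd) %*% tc$basis$Z
  expect_equal(unname(des$X[, tc$cols]), unname(Bc))
  expect_error(assemble_design(ss, "nope"), "not present")
})

test_that("the default model carries the full 17-input task census", {
  ss <- small_session()
  set.seed(71)
  gt <- make_ground_truth(sim_config(n_trials = 24, n_units = 1,
                                     areas = "MSTd"))
  ss <- generate_spikes(ss, gt, seed = 72)
  des <- suppressWarnings(assemble_design(
    ss, "u001", pgam_spec(n_knots = 6, spike_history = FALSE)))
  task_kinds <- vapply(des$terms, `[[`, "", "kind")
  expect_equal(sum(task_kinds %in% c("continuous", "circular", "event")),
               17L)
  # a unit with no partners gets task + LFP (+ history) blocks only
  expect_false(any(task_kinds == "coupling"))
})

test_that("fitting recovers planted tuning and satisfies score equations", {
  sf <- small_fit()
  fit <- sf$fit
  expect_true(fit$converged)
  # intercept score equation: fitted mean matches observed mean on train
  mu <- fit$fitted_rate[!fit$is_test]
  y <- sf$design$y[!fit$is_test]
  expect_lt(abs(sum(mu) / sum(y) - 1), 1e-6)
  # rates strictly positive, posterior covariance symmetric PSD
  expect_true(all(fit$fitted_rate > 0))
  expect_equal(fit$posterior_cov, t(fit$posterior_cov), tolerance = 1e-10)
  ev <- eigen(fit$posterior_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  # planted terms detected, planted-null terms not
  td <- tidy(fit)
  expect_lt(td$p_value[td$term == "lin_vel"], 1e-6)
  expect_lt(td$p_value[td$term == "eye_hori"], 1e-6)
  expect_gt(min(td$p_value[td$term %in% c("ang_vel", "lfp_theta")]), 0.01)
})

test_that("penalized log-likelihood is monotone across IRLS iterations", {
  sf <- small_fit()
  des <- sf$design
  X <- des$X; y <- des$y
  S <- navgam:::penalty_at(des$terms, rep(10, length(des$terms)), ncol(X))
  # run IRLS step by step and track the penalized log-likelihood
  beta <- numeric(ncol(X)); beta[1] <- log(mean(y))
  pll <- function(b) {
    eta <- pmin(as.numeric(X %*% b), 30)
    sum(y * eta - exp(eta)) - 0.5 * sum(b * (S %*% b))
  }
  lls <- pll(beta)
  for (it in 1:8) {
    eta <- pmin(as.numeric(X %*% beta), 30)
    mu <- exp(eta); w <- mu; z <- eta + (y - mu) / mu
    A <- crossprod(X * sqrt(w)) + S
    bnew <- solve(A, crossprod(X, w * z))
    step <- 1
    while (pll(beta + step * (bnew - beta)) < lls[length(lls)] &&
           step > 1e-4) step <- step / 2
    beta <- beta + step * (bnew - beta)
    lls <- c(lls, pll(beta))
  }
  expect_true(all(diff(lls) > -1e-8))
})

test_that("forcing lambda to infinity collapses smooths to the null space", {
  sf <- small_fit()
  des <- sf$design
  fit_big <- fit_pgam(des, folds = 4, seed = 1,
                      lambda_grid = 1e12, outer_iter = 1)
  # with an extreme penalty every smooth flattens toward its affine null
  # space and the deviance approaches the null model's
  tf <- extract_tuning(fit_big, "lin_vel", n_grid = 30)
  curv <- diff(diff(log(tf$response)))
  tf0 <- extract_tuning(sf$fit, "lin_vel", n_grid = 30)
  curv0 <- diff(diff(log(tf0$response)))
  expect_lt(max(abs(curv)), 1e-3)
  expect_lt(max(abs(curv)), 0.05 * max(abs(curv0)))
  expect_lt(fit_big$pseudo_r2_train, sf$fit$pseudo_r2_train)
})

test_that("zero-spike units yield a flagged degenerate fit", {
  sf <- small_fit()
  des <- sf$design
  des$y <- rep(0, length(des$y))
  f <- fit_pgam(des, folds = 4, seed = 1)
  expect_true(f$degenerate)
  expect_equal(f$reason, "zero-spike unit")
  expect_equal(nrow(tidy(f)), 0L)
})

test_that("reduced refit keeps exactly the selected terms", {
  sf <- small_fit()
  red <- reduce_and_refit(sf$fit, sf$design, alpha = 0.01)
  expect_setequal(names(red$terms), selected_terms(sf$fit, 0.01))
  expect_true(all(c("lin_vel", "eye_hori") %in% names(red$terms)))
  # cross-validated fit quality is preserved by the reduction
  expect_lt(abs(red$pseudo_r2_test - sf$fit$pseudo_r2_test), 0.02)
  # with an absurdly strict threshold the model collapses to the intercept
  none <- reduce_and_refit(sf$fit, sf$design, alpha = 1e-300)
  expect_length(none$terms, 0L)
  expect_lt(abs(none$pseudo_r2_train), 0.01)
})

test_that("a penalized Poisson spline fit agrees with an independent GAM", {
  skip_if_not_installed("mgcv")
  # one smooth covariate, moderate data; compare fitted curves, not engines
  set.seed(81)
  n <- 6000
  x <- runif(n, 0, 1)
  f <- 1.2 * exp(-(x - 0.4)^2 / 0.02)
  y <- rpois(n, exp(log(0.2) + f))
  knots <- place_knots(x, 10)
  st <- smooth_term("x", "continuous", knots = knots)
  B <- eval_basis(st, x)
  cc <- center_constraint(B, st$penalty)
  X <- cbind(1, cc$X)
  S <- matrix(0, ncol(X), ncol(X))
  S[-1, -1] <- 20 * cc$S / mean(diag(cc$S))
  ours <- navgam:::pirls(X, y, S + diag(1e-8, ncol(X)))
  gam_fit <- mgcv::gam(y ~ s(x, k = 12), family = stats::poisson(),
                       method = "REML")
  grid <- seq(0.05, 0.95, length.out = 50)
  ours_mu <- as.numeric(exp(cbind(1, eval_basis(st, grid) %*% cc$Z)
                            %*% ours$beta))
  gam_mu <- as.numeric(predict(gam_fit, newdata = data.frame(x = grid),
                               type = "response"))
  expect_gt(cor(as.numeric(ours_mu), as.numeric(gam_mu)), 0.99)
  expect_lt(max(abs(log(ours_mu) - log(gam_mu))), 0.25)
})

test_that("fold assignment is seeded and fits are reproducible", {
  sf <- small_fit()
  f2 <- fit_pgam(sf$design, folds = 4, seed = 1)
  expect_equal(f2$beta, sf$fit$beta)
  expect_equal(tidy(f2)$p_value, tidy(sf$fit)$p_value)
  f3 <- fit_pgam(sf$design, folds = 4, seed = 2)
  expect_false(identical(f3$is_test, sf$fit$is_test))
})
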