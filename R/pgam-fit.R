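#' Model specification for the Poisson GAM encoding model
#'
#' Declares which task covariates enter the model and the basis sizes and
#' filter durations for each family. The default covers all 17 task inputs
#' (10 continuous, 4 events, 3 LFP bands) plus the unit's spike-history
#' filter; unit-to-unit coupling filters are added per partner with 36 ms
#' (within-area) or 600 ms (across-area) durations.
#'
#' @param continuous,events,lfp Character vectors of covariate names (defaults
#'   from [task_covariate_names()]).
#' @param n_knots Knots per continuous covariate (default 15, equi-probable
#'   from the 2nd to the 98th percentile).
#' @param n_phase_basis Basis functions for periodic LFP-phase terms.
#' @param event_filter,history_filter Filter durations in seconds.
#' @param within_filter,across_filter Coupling filter durations in seconds.
#' @param spike_history Include the unit's own causal spike-history filter.
#' @param coupling Character vector of partner unit ids, `"all"` for all
#'   simultaneously recorded units, or `NULL` for none.
#' @return A list of class `pgam_spec`.
#' @export
pgam_spec <- function(continuous = task_covariate_names()$continuous,
                      events = task_covariate_names()$events,
                      lfp = task_covariate_names()$lfp,
                      n_knots = 15L, n_phase_basis = 8L,
                      event_filter = 0.6, history_filter = 0.036,
                      within_filter = 0.036, across_filter = 0.6,
                      spike_history = TRUE, coupling = NULL) {
  structure(list(continuous = continuous, events = events, lfp = lfp,
                 n_knots = as.integer(n_knots),
                 n_phase_basis = as.integer(n_phase_basis),
                 event_filter = event_filter,
                 history_filter = history_filter,
                 within_filter = within_filter,
                 across_filter = across_filter,
                 spike_history = spike_history, coupling = coupling),
            class = "pgam_spec")
}

#' Assemble the design matrix for one unit
#'
#' Continuous covariates contribute centered spline-basis columns; LFP phases
#' contribute periodic spline columns; events, the unit's own spike history
#' (lag >= 1) and partner spike trains contribute causally convolved
#' temporal-filter columns. Column blocks are labeled by term. Each term's
#' curvature penalty is normalized to unit mean diagonal so smoothness scales
#' are comparable across terms.
#'
#' @param session A `binned_session`.
#' @param unit_id Unit to model (column name of `session$counts`).
#' @param spec A [pgam_spec()].
#' @return List of class `pgam_design`: `X` (T x p, first column intercept),
#'   `y`, `terms` (per-term metadata: kind, columns, penalty, basis), `trial`
#'   (per-bin trial index for fold construction), `unit_id`.
#' @export
assemble_design <- function(session, unit_id, spec = pgam_spec()) {
  stopifnot(inherits(session, "binned_session"))
  if (!unit_id %in% colnames(session$counts)) {
    stop("unit ", unit_id, " not present in session")
  }
  y <- as.numeric(session$counts[, unit_id])
  bins <- session$bins
  Tn <- nrow(bins)
  area <- session$units$area[match(unit_id, session$units$unit_id)]
  blocks <- list(matrix(1, Tn, 1))
  terms <- list()
  p_next <- 2L

  add_term <- function(name, kind, Xb, S, basis_obj) {
    cols <- seq.int(p_next, p_next + ncol(Xb) - 1L)
    terms[[name]] <<- list(name = name, kind = kind, cols = cols,
                           penalty = S / mean(diag(S) + 1e-300),
                           basis = basis_obj,
                           col_means = colMeans(Xb))
    blocks[[length(blocks) + 1L]] <<- Xb
    p_next <<- p_next + ncol(Xb)
  }

  for (v in spec$continuous) {
    x <- bins[[v]]
    if (is.null(x)) stop("covariate ", v, " absent from session")
    if (sd(x) < 1e-10) {
      warning("dropping constant covariate ", v)
      next
    }
    knots <- place_knots(x, spec$n_knots)
    st <- smooth_term(v, "continuous", knots = knots)
    B <- eval_basis(st, x)
    cc <- center_constraint(B, st$penalty)
    st$Z <- cc$Z
    add_term(v, "continuous", cc$X, cc$S, st)
  }
  for (v in spec$lfp) {
    band <- sub("lfp_", "", v)
    col <- paste0("lfp_", band, "_", area)
    ph <- if (!is.null(session$lfp) && col %in% names(session$lfp)) {
      session$lfp[[col]]
    } else next
    st <- smooth_term(v, "circular", n_basis = spec$n_phase_basis)
    B <- eval_basis(st, ph)
    cc <- center_constraint(B, st$penalty)
    st$Z <- cc$Z
    add_term(v, "circular", cc$X, cc$S, st)
  }
  for (v in spec$events) {
    z <- bins[[v]]
    if (is.null(z) || sum(z) == 0) {
      warning("dropping event ", v, " with no occurrences")
      next
    }
    st <- temporal_basis(spec$event_filter, session$dt, name = v)
    add_term(v, "event", convolve_basis(z, st), st$penalty, st)
  }
  if (isTRUE(spec$spike_history)) {
    st <- temporal_basis(spec$history_filter, session$dt,
                         name = "spike_history")
    add_term("spike_history", "history", convolve_basis(y, st),
             st$penalty, st)
  }
  partners <- spec$coupling
  if (!is.null(partners)) {
    if (identical(partners, "all")) {
      partners <- setdiff(colnames(session$counts), unit_id)
    }
    for (pu in partners) {
      if (identical(pu, unit_id)) next
      if (!pu %in% colnames(session$counts)) {
        warning("coupling partner ", pu, " absent; skipped")
        next
      }
      p_area <- session$units$area[match(pu, session$units$unit_id)]
      dur <- if (identical(p_area, area)) spec$within_filter else
        spec$across_filter
      st <- temporal_basis(dur, session$dt, name = paste0("coupling:", pu))
      add_term(paste0("coupling:", pu), "coupling",
               convolve_basis(as.numeric(session$counts[, pu]), st),
               st$penalty, st)
    }
  }
  trial <- bins$trial
  if (anyNA(trial)) trial <- fill_locf(trial, default = 1)
  structure(list(X = do.call(cbind, blocks), y = y, terms = terms,
                 trial = as.integer(trial), unit_id = unit_id,
                 dt = session$dt, area = area, spec = spec),
            class = "pgam_design")
}

## Full penalty matrix at a given per-term lambda vector (+ small ridge).
penalty_at <- function(terms, lambda, p, ridge = 1e-7) {
  S <- diag(ridge, p)
  for (i in seq_along(terms)) {
    cols <- terms[[i]]$cols
    S[cols, cols] <- S[cols, cols] + lambda[i] * terms[[i]]$penalty
  }
  S
}

clamp_eta <- function(eta, lim = 30) pmin(pmax(eta, -lim), lim)

## Penalized IRLS for the Poisson log link. Returns beta, convergence flag,
## and the final weighted cross-products.
pirls <- function(X, y, S, beta0 = NULL, maxit = 60L, tol = 1e-8) {
  p <- ncol(X)
  if (is.null(beta0)) {
    beta <- numeric(p)
    beta[1] <- log(max(mean(y), 1e-4))
  } else beta <- beta0
  pen_ll <- function(b, eta) {
    sum(y * eta - exp(clamp_eta(eta))) - 0.5 * sum(b * (S %*% b))
  }
  eta <- clamp_eta(as.numeric(X %*% beta))
  ll <- pen_ll(beta, eta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- exp(clamp_eta(eta))
    w <- mu
    z <- eta + (y - mu) / mu
    sw <- sqrt(w)
    A <- crossprod(X * sw) + S
    b <- crossprod(X, w * z)
    beta_new <- tryCatch(solve(A, b), error = function(e) {
      solve(A + diag(1e-6, p), b)
    })
    step <- 1
    repeat {
      cand <- beta + step * (beta_new - beta)
      eta_c <- clamp_eta(as.numeric(X %*% cand))
      ll_c <- pen_ll(cand, eta_c)
      if (is.finite(ll_c) && ll_c >= ll - 1e-10) break
      step <- step / 2
      if (step < 1e-4) break
    }
    moved <- sqrt(sum((cand - beta)^2) / max(1e-12, sum(beta^2)))
    beta <- cand; eta <- eta_c
    if (abs(ll_c - ll) < tol * (abs(ll) + 1)) {
      ll <- ll_c; converged <- TRUE; break
    }
    ll <- ll_c
    if (moved < 1e-9) { converged <- TRUE; break }
  }
  mu <- exp(clamp_eta(eta))
  list(beta = as.numeric(beta), eta = eta, mu = mu,
       XtWX = crossprod(X * sqrt(mu)), converged = converged, pll = ll)
}

## Contiguous trial blocks -> fold id per bin.
trial_folds <- function(trial, folds) {
  ut <- unique(trial)
  fold_of_trial <- ceiling(seq_along(ut) / (length(ut) / folds))
  fold_of_trial[match(trial, ut)]
}

## Held-out negative Poisson log-likelihood (up to y! terms).
holdout_nll <- function(eta, y) sum(exp(clamp_eta(eta)) - y * clamp_eta(eta))

#' Fit the penalized Poisson encoding model for one unit
#'
#' Maximizes the penalized Poisson log-likelihood by iteratively reweighted
#' least squares, alternating with smoothness selection: per-term smoothness
#' scales are chosen to minimize the k-fold cross-validated held-out deviance
#' (folds are contiguous trial blocks). A seeded 20% of trials is held out as
#' a test set for the cross-validated pseudo-R-squared; smoothness selection
#' and the final fit use training trials only.
#'
#' @param design A [assemble_design()] result.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Seed governing the train/test trial split (the fit itself is
#'   deterministic).
#' @param lambda_grid Candidate smoothness scales (log-spaced).
#' @param outer_iter Outer alternations between coefficient and smoothness
#'   updates.
#' @param test_fraction Fraction of trials held out for testing (default 0.2).
#' @return Object of class `pgam_fit`: per-term coefficients, smoothness
#'   scales, inclusion p-values and effective degrees of freedom, posterior
#'   covariance, train/test pseudo-R-squared, convergence flag.
#' @export
fit_pgam <- function(design, folds = 5L, seed = 1L,
                     lambda_grid = 10^seq(-3, 5, by = 1),
                     outer_iter = 2L, test_fraction = 0.2) {
  X <- design$X; y <- design$y; terms <- design$terms
  p <- ncol(X); nt <- length(terms)
  if (sum(y) == 0) {
    return(degenerate_fit(design, reason = "zero-spike unit"))
  }
  ut <- unique(design$trial)
  n_test <- max(1L, round(test_fraction * length(ut)))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  test_trials <- sample(ut, n_test)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  is_test <- design$trial %in% test_trials
  Xtr <- X[!is_test, , drop = FALSE]; ytr <- y[!is_test]
  fold_id <- trial_folds(design$trial[!is_test], folds)

  lambda <- rep(1, nt)
  fit <- pirls(Xtr, ytr, penalty_at(terms, lambda, p))
  for (outer in seq_len(max(1L, outer_iter))) {
    ## performance iteration: freeze weights/working response, select lambda
    mu <- fit$mu
    z <- clamp_eta(fit$eta) + (ytr - mu) / mu
    sw <- sqrt(mu)
    A_fold <- list(); b_fold <- list(); rows_fold <- list()
    for (f in seq_len(folds)) {
      rf <- fold_id == f
      A_fold[[f]] <- crossprod(Xtr[rf, , drop = FALSE] * sw[rf])
      b_fold[[f]] <- crossprod(Xtr[rf, , drop = FALSE], (mu * z)[rf])
      rows_fold[[f]] <- rf
    }
    A_all <- Reduce(`+`, A_fold); b_all <- Reduce(`+`, b_fold)
    cv_score <- function(lam) {
      S <- penalty_at(terms, lam, p)
      sc <- 0
      for (f in seq_len(folds)) {
        bt <- tryCatch(solve(A_all - A_fold[[f]] + S, b_all - b_fold[[f]]),
                       error = function(e) NULL)
        if (is.null(bt)) return(Inf)
        eta_ho <- as.numeric(Xtr[rows_fold[[f]], , drop = FALSE] %*% bt)
        sc <- sc + holdout_nll(eta_ho, ytr[rows_fold[[f]]])
      }
      sc
    }
    ## shared-lambda pass
    shared <- vapply(lambda_grid, function(l) cv_score(rep(l, nt)),
                     numeric(1))
    lambda <- rep(lambda_grid[which.min(shared)], nt)
    best <- min(shared)
    ## per-term coordinate passes
    for (pass in 1:2) {
      for (i in seq_len(nt)) {
        cand <- vapply(lambda_grid, function(l) {
          lam <- lambda; lam[i] <- l; cv_score(lam)
        }, numeric(1))
        if (min(cand) < best - 1e-9) {
          lambda[i] <- lambda_grid[which.min(cand)]
          best <- min(cand)
        }
      }
    }
    fit <- pirls(Xtr, ytr, penalty_at(terms, lambda, p), beta0 = fit$beta)
  }

  finalize_fit(design, fit, lambda, is_test, seed = seed, folds = folds)
}

## Shared epilogue for full and reduced fits: posterior covariance, per-term
## edf and inclusion p-values, pseudo-R2 on train and held-out trials.
##
## Inclusion p-values come from a parallel lightly-penalized refit: heavy
## CV-selected smoothing biases the true tuning functions, and with the
## task's correlated covariates that bias leaks systematic signal into other
## terms' coefficient blocks, inflating their test statistics. A zero block
## has no smoothing bias, so testing on a near-unpenalized fit restores
## standard GLM block-Wald calibration while the CV-smoothed fit is kept for
## tuning curves and prediction.
finalize_fit <- function(design, fit, lambda, is_test, seed, folds,
                         lambda_test = 1e-2) {
  X <- design$X; y <- design$y; terms <- design$terms
  p <- ncol(X)
  S <- penalty_at(terms, lambda, p)
  H <- fit$XtWX + S
  V <- tryCatch(solve(H), error = function(e) solve(H + diag(1e-6, p)))
  V <- (V + t(V)) / 2
  Fmat <- V %*% fit$XtWX
  edf <- diag(Fmat)
  nt <- length(terms)
  if (nt) {
    Xtr <- X[!is_test, , drop = FALSE]
    S_t <- penalty_at(terms, rep(lambda_test, nt), p)
    tfit <- pirls(Xtr, y[!is_test], S_t, beta0 = fit$beta)
    Ht <- tfit$XtWX + S_t
    Vt <- tryCatch(solve(Ht), error = function(e) solve(Ht + diag(1e-5, p)))
    Ve <- Vt %*% tfit$XtWX %*% Vt   # sandwich covariance of the estimator
    Ve <- (Ve + t(Ve)) / 2
  }
  for (i in seq_along(terms)) {
    cols <- terms[[i]]$cols
    terms[[i]]$beta <- fit$beta[cols]
    terms[[i]]$lambda <- lambda[i]
    terms[[i]]$edf <- sum(edf[cols])
    terms[[i]]$p_value <- wald_block_p(tfit$beta[cols],
                                       Ve[cols, cols, drop = FALSE])
  }
  eta_all <- clamp_eta(as.numeric(X %*% fit$beta))
  mu_all <- exp(eta_all)
  r2_tr <- pseudo_r2(y[!is_test], mu_all[!is_test])
  r2_te <- if (any(is_test)) pseudo_r2(y[is_test], mu_all[is_test]) else NA
  structure(list(
    unit_id = design$unit_id, area = design$area, terms = terms,
    beta = fit$beta, intercept = fit$beta[1], lambda = lambda,
    posterior_cov = V, edf = edf, converged = fit$converged,
    pseudo_r2_train = r2_tr, pseudo_r2_test = r2_te,
    is_test = is_test, seed = seed, folds = folds, dt = design$dt,
    fitted_rate = mu_all, degenerate = FALSE),
    class = "pgam_fit")
}

degenerate_fit <- function(design, reason) {
  structure(list(unit_id = design$unit_id, area = design$area,
                 terms = design$terms, beta = NULL,
                 intercept = -Inf, lambda = NULL, posterior_cov = NULL,
                 converged = TRUE, pseudo_r2_train = NA_real_,
                 pseudo_r2_test = NA_real_, degenerate = TRUE,
                 reason = reason, dt = design$dt),
            class = "pgam_fit")
}

## Wald-type quadratic form on a term's coefficient block against the
## frequentist covariance of the penalized estimator. Under the null the
## penalized estimate of a zero block is unbiased, so the quadratic form is
## chi-square with the covariance's numerical rank; directions whose
## variance is numerically zero (fully shrunk) carry no evidence and are
## dropped from both statistic and degrees of freedom.
wald_block_p <- function(beta_f, V_f) {
  eg <- eigen(V_f, symmetric = TRUE)
  keep <- eg$values > max(eg$values[1], 1e-300) * 1e-8
  r <- sum(keep)
  if (r == 0L) return(1)
  proj <- crossprod(eg$vectors[, keep, drop = FALSE], beta_f)
  stat <- sum(proj^2 / eg$values[keep])
  pchisq(stat, df = r, lower.tail = FALSE)
}

#' Per-term inclusion test
#'
#' p-value for the null hypothesis that a term's contribution to the log rate
#' is indistinguishable from zero, from the Wald-type quadratic form of the
#' term's coefficient block against its posterior covariance. A term is
#' declared tuned at `p < 0.01`.
#'
#' @param fit A `pgam_fit`.
#' @param term Term name.
#' @return The p-value.
#' @export
inclusion_test <- function(fit, term) {
  if (!term %in% names(fit$terms)) stop("term ", term, " not in fit")
  fit$terms[[term]]$p_value
}

#' Selected (tuned) terms of a fit
#'
#' @param fit A `pgam_fit`.
#' @param alpha Significance level (default 0.01).
#' @return Character vector of term names with `p < alpha`.
#' @export
selected_terms <- function(fit, alpha = 0.01) {
  ps <- vapply(fit$terms, function(t) t$p_value %||% NA_real_, numeric(1))
  names(ps)[!is.na(ps) & ps < alpha]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Refit the model keeping only significant terms
#'
#' Drops all terms with inclusion p-value `>= alpha` and refits the reduced
#' model on the same training trials (smoothness scales of surviving terms
#' are kept). With no surviving terms an intercept-only model is returned.
#'
#' @param fit A full `pgam_fit`.
#' @param design The [assemble_design()] object the fit came from.
#' @param alpha Significance level (default 0.01).
#' @return A reduced `pgam_fit`.
#' @export
reduce_and_refit <- function(fit, design, alpha = 0.01) {
  keep <- selected_terms(fit, alpha)
  terms_red <- design$terms[keep]
  cols <- c(1L, unlist(lapply(terms_red, `[[`, "cols"), use.names = FALSE))
  Xr <- design$X[, cols, drop = FALSE]
  idx_new <- 2L
  for (nm in names(terms_red)) {
    k <- length(terms_red[[nm]]$cols)
    terms_red[[nm]]$cols <- seq.int(idx_new, idx_new + k - 1L)
    idx_new <- idx_new + k
  }
  design_red <- design
  design_red$X <- Xr
  design_red$terms <- terms_red
  lambda_red <- if (length(keep)) fit$lambda[match(keep, names(fit$terms))]
                else numeric(0)
  is_test <- fit$is_test
  pr <- pirls(Xr[!is_test, , drop = FALSE], design$y[!is_test],
              penalty_at(terms_red, lambda_red, ncol(Xr)))
  out <- finalize_fit(design_red, pr, lambda_red, is_test,
                      seed = fit$seed, folds = fit$folds)
  out$reduced_from <- fit$unit_id
  out
}

#' Export a fitted encoding model as JSON
#'
#' Writes the per-term metadata (kind, knots, smoothness scale, effective
#' degrees of freedom, inclusion p-value), coefficient vector, and posterior
#' covariance to one JSON file per unit.
#'
#' @param fit A `pgam_fit`.
#' @param path Output file path.
#' @export
write_pgam_fit <- function(fit, path) {
  terms <- lapply(fit$terms, function(t) {
    list(name = t$name, kind = t$kind, cols = t$cols,
         knots = t$basis$knots, lambda = t$lambda %||% NA,
         edf = t$edf %||% NA, p_value = t$p_value %||% NA,
         beta = t$beta)
  })
  jsonlite::write_json(
    list(unit_id = fit$unit_id, area = fit$area,
         degenerate = fit$degenerate, intercept = fit$intercept,
         pseudo_r2_train = fit$pseudo_r2_train,
         pseudo_r2_test = fit$pseudo_r2_test,
         converged = fit$converged %||% NA, terms = terms,
         beta = fit$beta, posterior_cov = fit$posterior_cov),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.pgam_fit <- function(x, ...) {
  cat("<pgam_fit> unit ", x$unit_id, " (", x$area, ")\n", sep = "")
  if (x$degenerate) {
    cat("  degenerate: ", x$reason, "\n", sep = "")
    return(invisible(x))
  }
  cat("  ", length(x$terms), " terms, pseudo-R2 train ",
      signif(x$pseudo_r2_train, 3), " / test ",
      signif(x$pseudo_r2_test, 3), "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted encoding model
#'
#' One row per model term with its kind, smoothness scale, effective degrees
#' of freedom and inclusion p-value.
#'
#' @param x A `pgam_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pgam_fit <- function(x, ...) {
  if (x$degenerate) return(tibble::tibble())
  tibble::tibble(
    unit_id = x$unit_id, area = x$area,
    term = names(x$terms),
    kind = vapply(x$terms, `[[`, "", "kind"),
    edf = vapply(x$terms, function(t) t$edf %||% NA_real_, numeric(1)),
    lambda = vapply(x$terms, function(t) t$lambda %||% NA_real_, numeric(1)),
    p_value = vapply(x$terms, function(t) t$p_value %||% NA_real_,
                     numeric(1)))
}

#' One-row fit summary
#'
#' @param x A `pgam_fit`.
#' @param ... Unused.
#' @return A tibble with unit, area, convergence, pseudo-R-squared and term
#'   counts.
#' @export
glance.pgam_fit <- function(x, ...) {
  tibble::tibble(unit_id = x$unit_id, area = x$area,
                 converged = x$converged %||% NA,
                 degenerate = x$degenerate,
                 n_terms = length(x$terms),
                 n_selected = if (x$degenerate) NA_integer_ else
                   length(selected_terms(x)),
                 pseudo_r2_train = x$pseudo_r2_train,
                 pseudo_r2_test = x$pseudo_r2_test)
}
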