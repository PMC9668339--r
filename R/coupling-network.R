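#' Extract the directed coupling graph from a cohort of fits
#'
#' One candidate edge per fitted coupling filter: sender (partner unit) to
#' receiver (modeled unit), with the filter's inclusion p-value, significance
#' at `alpha`, peak lag and sign, and the electrode distance for within-area
#' pairs (cross-area electrode distance is undefined and never used).
#'
#' @param fits List of `pgam_fit` objects (fitted with coupling terms).
#' @param unit_meta Tibble `unit_id`, `area`, `electrode_x`.
#' @param alpha Significance level (default 0.01).
#' @return List of class `coupling_graph`: `edges` tibble and `alpha`.
#' @export
extract_couplings <- function(fits, unit_meta, alpha = 0.01) {
  edges <- purrr::map_dfr(fits, function(f) {
    if (f$degenerate) return(tibble::tibble())
    cp <- f$terms[vapply(f$terms, function(t) t$kind == "coupling",
                         logical(1))]
    purrr::map_dfr(cp, function(tm) {
      sender <- sub("^coupling:", "", tm$name)
      kern <- as.numeric(tm$basis$lag_basis %*% tm$beta)
      pk <- which.max(abs(kern))
      tibble::tibble(sender = sender, receiver = f$unit_id,
                     p_value = tm$p_value,
                     significant = tm$p_value < alpha,
                     peak_lag_s = pk * f$dt,
                     sign = sign(kern[pk]),
                     filter = list(kern))
    })
  })
  if (nrow(edges)) {
    edges <- edges[edges$sender != edges$receiver, , drop = FALSE]
    m <- function(u, col) unit_meta[[col]][match(u, unit_meta$unit_id)]
    edges$sender_area <- m(edges$sender, "area")
    edges$receiver_area <- m(edges$receiver, "area")
    edges$distance_um <- ifelse(
      edges$sender_area == edges$receiver_area,
      abs(m(edges$sender, "electrode_x") - m(edges$receiver, "electrode_x")),
      NA_real_)
  }
  structure(list(edges = edges, alpha = alpha, unit_meta = unit_meta),
            class = "coupling_graph")
}

#' Area-pair coupling fractions
#'
#' For each sender-receiver area pair: the fraction of sender-area units with
#' at least one significant edge to the receiver area (default), or the edge
#' density (significant / candidate edges) with `mode = "edge"`. Fractions
#' are directional.
#'
#' @param graph A `coupling_graph`.
#' @param mode `"unit"` (default) or `"edge"`.
#' @return Tibble: sender_area, receiver_area, fraction, n.
#' @export
coupling_fractions <- function(graph, mode = c("unit", "edge")) {
  mode <- match.arg(mode)
  e <- graph$edges
  areas <- unique(graph$unit_meta$area)
  grid <- tidyr::expand_grid(sender_area = areas, receiver_area = areas)
  purrr::pmap_dfr(grid, function(sender_area, receiver_area) {
    sub <- e[e$sender_area == sender_area &
               e$receiver_area == receiver_area, , drop = FALSE]
    if (mode == "edge") {
      tibble::tibble(sender_area, receiver_area,
                     fraction = if (nrow(sub)) mean(sub$significant)
                                else NA_real_,
                     n = nrow(sub))
    } else {
      senders <- unique(graph$unit_meta$unit_id[
        graph$unit_meta$area == sender_area])
      evaluated <- senders[senders %in% sub$sender]
      hit <- vapply(evaluated, function(u) {
        any(sub$significant[sub$sender == u])
      }, logical(1))
      tibble::tibble(sender_area, receiver_area,
                     fraction = if (length(evaluated)) mean(hit)
                                else NA_real_,
                     n = length(evaluated))
    }
  })
}

## Penalized logistic IRLS (spline-expanded predictor).
pirls_logistic <- function(X, y, S, maxit = 50L, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  eta <- as.numeric(X %*% beta)
  pll <- function(b, eta) {
    sum(y * eta - log1p(exp(pmin(eta, 30)))) - 0.5 * sum(b * (S %*% b))
  }
  ll <- pll(beta, eta)
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    A <- crossprod(X * sqrt(w)) + S
    bb <- crossprod(X, w * z)
    beta_new <- solve(A + diag(1e-9, p), bb)
    step <- 1
    repeat {
      cand <- beta + step * (beta_new - beta)
      eta_c <- as.numeric(X %*% cand)
      ll_c <- pll(cand, eta_c)
      if (is.finite(ll_c) && ll_c >= ll - 1e-10) break
      step <- step / 2
      if (step < 1e-4) break
    }
    done <- abs(ll_c - ll) < tol * (abs(ll) + 1)
    beta <- cand; eta <- eta_c; ll <- ll_c
    if (done) break
  }
  list(beta = as.numeric(beta), eta = eta)
}

#' Electrode-distance-corrected coupling probability
#'
#' Fits, per area, a penalized logistic model expressing the probability of a
#' significant within-area coupling as a nonlinear (spline) function of
#' electrode distance, `p(c = 1) = logit^-1(f(d))`, and reports the model
#' prediction at a reference distance (500 um) -- the distance-corrected
#' coupling probability.
#'
#' @param edges Within-area candidate-edge tibble (`significant`,
#'   `distance_um`), e.g. one area's rows of a `coupling_graph`.
#' @param n_knots Spline knots over distance (default 5).
#' @param lambda_grid Smoothness candidates chosen by 5-fold deviance.
#' @param ref_distance Reference distance in micrometres (default 500).
#' @param seed Seed for fold assignment.
#' @return List of class `distance_model`: `predict(d)`, `p_ref`,
#'   `ref_distance`, `knots`.
#' @export
distance_corrected_probability <- function(edges, n_knots = 5L,
                                           lambda_grid = 10^seq(-1, 4),
                                           ref_distance = 500,
                                           seed = 1L) {
  d <- edges$distance_um
  c01 <- as.numeric(edges$significant)
  ok <- is.finite(d)
  d <- d[ok]; c01 <- c01[ok]
  if (length(d) < 50L) stop("need >= 50 candidate pairs")
  if (length(unique(d)) < 3L) {
    warning("fewer than 3 distinct distances: falling back to the raw ",
            "coupling proportion")
    pr <- mean(c01)
    return(structure(list(predict = function(x) rep(pr, length(x)),
                          p_ref = pr, ref_distance = ref_distance,
                          knots = NULL), class = "distance_model"))
  }
  n_knots <- min(n_knots, length(unique(d)))
  knots <- if (length(unique(d)) >= n_knots + 2L) {
    place_knots(d, n_knots)
  } else sort(unique(d))
  st <- smooth_term("distance", "continuous", knots = knots)
  B <- eval_basis(st, d)
  cc <- center_constraint(B, st$penalty)
  X <- cbind(1, cc$X)
  p <- ncol(X)
  Sf <- matrix(0, p, p)
  Sf[-1, -1] <- cc$S / mean(diag(cc$S) + 1e-300)
  set.seed(seed)
  fold <- sample(rep_len(1:5, length(d)))
  cv <- vapply(lambda_grid, function(l) {
    sc <- 0
    for (f in 1:5) {
      tr <- fold != f
      fit <- pirls_logistic(X[tr, , drop = FALSE], c01[tr], l * Sf)
      eta <- as.numeric(X[!tr, , drop = FALSE] %*% fit$beta)
      sc <- sc - sum(c01[!tr] * eta - log1p(exp(pmin(eta, 30))))
    }
    sc
  }, numeric(1))
  lambda <- lambda_grid[which.min(cv)]
  fit <- pirls_logistic(X, c01, lambda * Sf)
  pred <- function(x) {
    Bx <- eval_basis(st, x) %*% cc$Z
    stats::plogis(as.numeric(cbind(1, Bx) %*% fit$beta))
  }
  structure(list(predict = pred, p_ref = pred(ref_distance),
                 ref_distance = ref_distance, knots = knots,
                 lambda = lambda, beta = fit$beta),
            class = "distance_model")
}

#' Across-session correlation between coupling and target tracking
#'
#' Ordinary least-squares r-squared and p-value relating each sender-receiver
#' area pair's coupling fraction to the sessions' target-tracking index
#' (averaged across the whole trial and then across trials). p-values are
#' reported raw and Bonferroni-corrected across the area-pair grid. Sessions
#' should already be filtered to well-fit ones (mean pseudo-R-squared > 0.05,
#' at least two units in each of two areas); fewer than 5 qualifying sessions
#' flags the cell as underpowered.
#'
#' @param session_table Tibble with `session_id`, `sender_area`,
#'   `receiver_area`, `fraction`, `tracking_index`.
#' @return Tibble per area pair: slope, r2, p, p_bonferroni, n, underpowered.
#' @export
coupling_behavior_correlation <- function(session_table) {
  cells <- dplyr::distinct(session_table, .data$sender_area,
                           .data$receiver_area)
  res <- purrr::pmap_dfr(cells, function(sender_area, receiver_area) {
    sub <- session_table[session_table$sender_area == sender_area &
                           session_table$receiver_area == receiver_area, ]
    sub <- sub[is.finite(sub$fraction) & is.finite(sub$tracking_index), ]
    n <- nrow(sub)
    if (n < 3L || sd(sub$tracking_index) < 1e-12 ||
        sd(sub$fraction) < 1e-12) {
      return(tibble::tibble(sender_area, receiver_area, slope = NA_real_,
                            r2 = NA_real_, p = NA_real_, n = n,
                            underpowered = TRUE))
    }
    fit <- lm(fraction ~ tracking_index, data = sub)
    sm <- summary(fit)
    tibble::tibble(sender_area, receiver_area,
                   slope = coef(fit)[["tracking_index"]],
                   r2 = sm$r.squared,
                   p = sm$coefficients["tracking_index", 4],
                   n = n, underpowered = n < 5L)
  })
  res$p_bonferroni <- pmin(res$p * nrow(res), 1)
  res
}

#' Tuning similarity versus coupling probability
#'
#' Pairwise similarity of stacked tuning shapes (Pearson correlation) for
#' every candidate directed pair, the coupling rate within similarity bins,
#' and a rank-correlation statistic with a permutation p-value -- positive
#' association means like-to-like connectivity.
#'
#' @param graph A `coupling_graph`.
#' @param stacked Result of [stack_tuning_profiles()] covering the units.
#' @param n_bins Similarity bins for the profile (default 5).
#' @param n_perm Permutations for the p-value (default 500).
#' @param seed RNG seed.
#' @return List: `profile` (per-bin coupling rate), `rho` (rank correlation),
#'   `p_perm`.
#' @export
tuning_similarity_vs_coupling <- function(graph, stacked, n_bins = 5L,
                                          n_perm = 500L, seed = 1L) {
  e <- graph$edges
  si <- match(e$sender, stacked$unit_id)
  ri <- match(e$receiver, stacked$unit_id)
  ok <- !is.na(si) & !is.na(ri)
  e <- e[ok, ]; si <- si[ok]; ri <- ri[ok]
  sim <- vapply(seq_along(si), function(i) {
    a <- stacked$shapes[si[i], ]; b <- stacked$shapes[ri[i], ]
    if (sd(a) < 1e-12 || sd(b) < 1e-12) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  keep <- is.finite(sim)
  sim <- sim[keep]
  cpl <- as.numeric(e$significant[keep])
  if (!length(sim)) stop("no candidate pairs with defined tuning similarity")
  br <- quantile(sim, probs = seq(0, 1, length.out = n_bins + 1L))
  bins <- cut(sim, unique(br), include.lowest = TRUE)
  profile <- tibble::tibble(bin = levels(bins)) |>
    dplyr::mutate(rate = vapply(.data$bin, function(b) {
      mean(cpl[bins == b])
    }, numeric(1)),
    n = vapply(.data$bin, function(b) sum(bins == b), numeric(1)))
  rho <- cor(sim, cpl, method = "spearman")
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    cor(sim, sample(cpl), method = "spearman")
  }, numeric(1))
  list(profile = profile, rho = rho,
       p_perm = (1 + sum(abs(null) >= abs(rho))) / (n_perm + 1))
}

#' Export a coupling graph as plain-text files
#'
#' Edge list CSV (sender, receiver, areas, p, peak lag, sign) and a JSON
#' adjacency summary with per-area-pair fractions.
#'
#' @param graph A `coupling_graph`.
#' @param dir Output directory.
#' @export
write_coupling_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(dplyr::select(graph$edges, -dplyr::any_of("filter")),
                   file.path(dir, "edges.csv"))
  fr <- coupling_fractions(graph)
  readr::write_csv(fr, file.path(dir, "coupling_fractions.csv"))
  jsonlite::write_json(
    list(alpha = graph$alpha,
         n_edges = nrow(graph$edges),
         n_significant = sum(graph$edges$significant),
         fractions = fr),
    file.path(dir, "coupling_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
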