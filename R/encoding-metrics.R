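#' Poisson pseudo-R-squared
#'
#' Likelihood-based goodness of fit for spike-count models:
#' `1 - (L(y) - L(yhat)) / (L(y) - L(ybar))`, with `L(y)` the saturated
#' Poisson log-likelihood, `L(yhat)` the model's, and `L(ybar)` a constant
#' mean-rate null model. The score is 0 when the model is no better than the
#' null, 1 when it matches the data perfectly, and can be negative on
#' held-out data when overfitting occurs.
#'
#' @param counts Observed spike counts (non-negative integers).
#' @param predicted_rates Model's predicted mean counts per bin.
#' @param null_rate Null model's constant rate (default: mean of `counts`).
#' @return The pseudo-R-squared (NaN, flagged with a warning, when the counts
#'   are constant so the null and saturated likelihoods coincide).
#' @export
pseudo_r2 <- function(counts, predicted_rates, null_rate = mean(counts)) {
  if (is.null(null_rate) || !is.finite(null_rate) || null_rate <= 0) {
    stop("null_rate must be positive")
  }
  mu <- pmax(predicted_rates, 1e-12)
  l_sat <- sum(dpois(counts, pmax(counts, 1e-12), log = TRUE))
  l_hat <- sum(dpois(counts, mu, log = TRUE))
  l_null <- sum(dpois(counts, null_rate, log = TRUE))
  denom <- l_sat - l_null
  if (abs(denom) < 1e-12) {
    warning("constant counts: pseudo-R2 undefined")
    return(NaN)
  }
  1 - (l_sat - l_hat) / denom
}

## Entropy (bits) of a Poisson(lambda) count distribution, truncated at the
## 1 - 1e-10 quantile.
poisson_entropy_bits <- function(lambda) {
  if (lambda <= 0) return(0)
  # truncate beyond the 1 - 1e-10 quantile, with a safety margin so the
  # neglected tail cannot move the entropy at the 1e-10 level
  kmax <- qpois(1e-14, lambda, lower.tail = FALSE) + 10L
  k <- 0:kmax
  p <- dpois(k, lambda)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between spike counts and a discretized stimulus
#'
#' `I(Y, S) = H(Y) - H(Y|S)`, computed assuming counts are Poisson: the
#' marginal entropy uses the unit's mean firing rate, and the conditional
#' entropy averages per-stimulus Poisson entropies over the stimulus
#' distribution. Sums are truncated at the `1 - 1e-10` Poisson quantile and
#' reported in bits.
#'
#' @param rates Firing rate (Hz) per stimulus bin.
#' @param probs Stimulus probability per bin (empty bins dropped with
#'   renormalization).
#' @param dt Counting-window width in seconds.
#' @return Tibble with `mi_bits`, `h_y`, `h_y_given_s` and list-columns of
#'   the stimulus pmf and conditional rates.
#' @export
mi_poisson <- function(rates, probs, dt) {
  stopifnot(length(rates) == length(probs))
  keep <- probs > 0 & is.finite(rates)
  rates <- rates[keep]
  probs <- probs[keep] / sum(probs[keep])
  mean_rate <- sum(probs * rates)
  h_y <- poisson_entropy_bits(mean_rate * dt)
  h_ys <- sum(probs * vapply(rates * dt, poisson_entropy_bits, numeric(1)))
  tibble::tibble(mi_bits = max(h_y - h_ys, 0), h_y = h_y,
                 h_y_given_s = h_ys,
                 stimulus_pmf = list(probs), conditional_rates = list(rates))
}

#' @describeIn mi_poisson Mutual information from a fitted tuning function
#'   and raw stimulus samples. The stimulus is discretized on the tuning
#'   grid; its distribution is the empirical pmf, or a moment-matched
#'   binomial when `stimulus_pmf = "binomial"`.
#' @param tuning A tuning tibble from [extract_tuning()].
#' @param stimulus_samples Raw covariate samples.
#' @param stimulus_pmf `"empirical"` (default) or `"binomial"`.
#' @export
mutual_information <- function(tuning, stimulus_samples, dt,
                               stimulus_pmf = c("empirical", "binomial")) {
  stimulus_pmf <- match.arg(stimulus_pmf)
  grid <- tuning$grid
  edges <- c(-Inf, (grid[-1] + grid[-length(grid)]) / 2, Inf)
  idx <- cut(stimulus_samples, edges, labels = FALSE)
  counts <- tabulate(idx, nbins = length(grid))
  probs <- if (stimulus_pmf == "empirical") {
    counts / sum(counts)
  } else {
    m <- length(grid) - 1L
    phat <- sum(counts * (seq_along(grid) - 1L)) / (sum(counts) * m)
    stats::dbinom(0:m, m, phat)
  }
  mi_poisson(tuning$response, probs, dt)
}

#' Speed / direction discrimination index (DDI)
#'
#' `DDI = (Rmax - Rmin) / (Rmax - Rmin + 2 sqrt(SSE / (N - M)))`, where
#' `Rmax`/`Rmin` are the extreme mean responses across stimulus bins, `SSE`
#' is the pooled sum of squared errors around the per-bin means, `M` the
#' number of stimulus bins and `N` the total number of observations. The
#' recording is divided into contiguous equal-duration segments; each
#' segment contributes one observation per stimulus bin.
#'
#' @param responses Segments x stimulus-bins matrix of mean responses (use
#'   [ddi_from_session()] to build one from binned data).
#' @return Tibble with `ddi`, `r_max`, `r_min`, `sse`, `n`, `m`.
#' @export
ddi <- function(responses) {
  responses <- as.matrix(responses)
  M <- ncol(responses)
  N <- sum(is.finite(responses))
  if (N <= M) stop("DDI undefined: need more observations than stimulus bins")
  bin_means <- colMeans(responses, na.rm = TRUE)
  r_max <- max(bin_means); r_min <- min(bin_means)
  sse <- sum(sweep(responses, 2, bin_means)^2, na.rm = TRUE)
  d <- (r_max - r_min) / (r_max - r_min + 2 * sqrt(sse / (N - M)))
  if (!is.finite(d)) d <- 0   # flat tuning with zero variance
  tibble::tibble(ddi = d, r_max = r_max, r_min = r_min, sse = sse,
                 n = N, m = M)
}

#' @describeIn ddi Build the segments x bins response matrix for one unit and
#'   covariate from a binned session (`segments` contiguous equal-duration
#'   segments, `m` equi-probable stimulus bins) and compute the DDI.
#' @param session A `binned_session`.
#' @param unit_id Unit column name.
#' @param variable Continuous covariate name.
#' @param m Number of stimulus bins (default 15).
#' @param segments Number of recording segments (default 80).
#' @export
ddi_from_session <- function(session, unit_id, variable, m = 15L,
                             segments = 80L) {
  y <- session$counts[, unit_id] / session$dt
  x <- session$bins[[variable]]
  n <- length(y)
  seg <- ceiling(seq_along(y) / (n / segments))
  edges <- unique(quantile(x, probs = seq(0, 1, length.out = m + 1L)))
  sbin <- cut(x, edges, labels = FALSE, include.lowest = TRUE)
  resp <- matrix(NA_real_, segments, length(edges) - 1L)
  agg <- aggregate(y, by = list(seg = seg, sbin = sbin), FUN = mean)
  resp[cbind(agg$seg, agg$sbin)] <- agg$x
  ddi(resp)
}

#' Extract a tuning function from a fitted model
#'
#' Evaluates the model rate along one covariate (the others held at their
#' session reference: centered smooth terms contribute zero, temporal-filter
#' terms their session-mean contribution), with pointwise confidence bounds
#' from the posterior covariance of the term's coefficient block. The
#' preferred value is the abscissa of the response peak.
#'
#' @param fit A `pgam_fit`.
#' @param variable Term name (continuous or circular).
#' @param n_grid Grid resolution (default 100).
#' @param level Confidence level for the bounds (default 0.95).
#' @return Tibble of class `navgam_tuning`: `grid`, `response` (Hz),
#'   `ci_low`, `ci_high`, plus attributes `preferred`, `p_value`,
#'   `monotone_flag`.
#' @export
extract_tuning <- function(fit, variable, n_grid = 100L, level = 0.95) {
  if (!variable %in% names(fit$terms)) {
    stop("term ", variable, " not present in fit")
  }
  tm <- fit$terms[[variable]]
  if (!tm$kind %in% c("continuous", "circular")) {
    stop("tuning curves are defined for continuous/circular terms")
  }
  st <- tm$basis
  grid <- if (st$periodic) {
    seq(st$domain[1], st$domain[2], length.out = n_grid)
  } else {
    seq(st$knots[1], st$knots[length(st$knots)], length.out = n_grid)
  }
  B <- eval_basis(st, grid) %*% st$Z
  eta_f <- as.numeric(B %*% tm$beta)
  ## baseline: intercept + mean contribution of every other term
  base <- fit$intercept
  for (ot in fit$terms) {
    if (ot$name == variable) next
    base <- base + sum(ot$col_means * ot$beta)
  }
  V_f <- fit$posterior_cov[tm$cols, tm$cols, drop = FALSE]
  se <- sqrt(pmax(rowSums((B %*% V_f) * B), 0))
  zq <- qnorm(1 - (1 - level) / 2)
  resp <- exp(base + eta_f) / fit$dt
  out <- tibble::tibble(grid = grid, response = resp,
                        ci_low = exp(base + eta_f - zq * se) / fit$dt,
                        ci_high = exp(base + eta_f + zq * se) / fit$dt)
  pk <- which.max(eta_f)
  attr(out, "unit_id") <- fit$unit_id
  attr(out, "variable") <- variable
  attr(out, "preferred") <- grid[pk]
  attr(out, "p_value") <- tm$p_value %||% NA_real_
  attr(out, "monotone_flag") <- pk %in% c(1L, n_grid)
  class(out) <- c("navgam_tuning", class(out))
  out
}

#' Subset a binned session to a set of trials
#'
#' Keeps the bins belonging to the given trials (inter-trial bins follow the
#' preceding trial), e.g. for odd/even-trial cross-validated tuning.
#'
#' @param session A `binned_session`.
#' @param trial_ids Trials to keep.
#' @return A `binned_session` restricted to those bins.
#' @export
subset_session <- function(session, trial_ids) {
  tr <- session$bins$trial
  tr_filled <- as.integer(fill_locf(tr, default = tr[!is.na(tr)][1]))
  keep <- tr_filled %in% trial_ids
  session$bins <- session$bins[keep, , drop = FALSE]
  session$counts <- session$counts[keep, , drop = FALSE]
  if (!is.null(session$lfp)) {
    session$lfp <- session$lfp[keep, , drop = FALSE]
  }
  session$trials <- session$trials[session$trials$trial_id %in% trial_ids, ,
                                   drop = FALSE]
  session
}
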