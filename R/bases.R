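#' Place equi-probable spline knots over a covariate's sampled range
#'
#' Knots are located at empirical quantiles with probabilities spaced linearly
#' from 0.02 to 0.98, so that each inter-knot interval carries the same
#' probability mass and the spline support covers the 2nd--98th percentile of
#' the data. Duplicate quantiles (probability atoms) are collapsed with a
#' warning.
#'
#' @param x Numeric vector of covariate samples.
#' @param n_knots Number of knots requested (default 15).
#' @return Strictly increasing numeric vector of knots (length `<= n_knots`).
#' @export
place_knots <- function(x, n_knots = 15) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < n_knots) {
    stop("fewer distinct sample values (", length(unique(x)),
         ") than requested knots (", n_knots, ")")
  }
  probs <- seq(0.02, 0.98, length.out = n_knots)
  k <- unname(quantile(x, probs = probs, type = 7, names = FALSE))
  ku <- unique(k)
  if (length(ku) < 2L) {
    stop("degenerate knot placement: all quantiles coincide at ", ku[1])
  }
  if (length(ku) < length(k)) {
    warning("collapsed ", length(k) - length(ku),
            " duplicate knots (probability atoms in the covariate)")
  }
  ku
}

## Full (clamped) knot vector: boundary knots repeated so the basis spans
## exactly [min(knots), max(knots)].
full_knot_vector <- function(knots, order) {
  c(rep(knots[1], order - 1), knots, rep(knots[length(knots)], order - 1))
}

## Evaluate a clamped B-spline basis; values outside the knot span are clamped
## to the boundary (no spline extrapolation).
bspline_basis <- function(x, knots, order = 4L, derivs = 0L) {
  xc <- pmin(pmax(x, knots[1]), knots[length(knots)])
  splines::splineDesign(full_knot_vector(knots, order), xc, ord = order,
                        derivs = rep(derivs, length(xc)), outer.ok = FALSE)
}

## Periodic (wrapped) uniform B-spline basis on [a, b] with period b - a.
## n_basis columns; b(a) == b(b) to machine precision at any derivative order.
periodic_basis <- function(x, n_basis, order = 4L, a = -pi, b = pi,
                           derivs = 0L) {
  period <- b - a
  xw <- ((x - a) %% period) + a
  h <- period / n_basis
  full <- seq(a - (order - 1) * h, b + (order - 1) * h, by = h)
  B <- splines::splineDesign(full, xw, ord = order,
                             derivs = rep(derivs, length(xw)), outer.ok = TRUE)
  # fold the wrap-around columns
  for (j in seq_len(order - 1L)) {
    B[, j] <- B[, j] + B[, j + n_basis]
  }
  B[, seq_len(n_basis), drop = FALSE]
}

## 3-point Gauss-Legendre nodes/weights on [-1, 1]; exact for degree <= 5,
## more than enough for products of piecewise-linear second derivatives of
## cubic splines.
gl3_nodes <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
gl3_weights <- c(5 / 9, 8 / 9, 5 / 9)

#' Curvature penalty matrix of a spline basis
#'
#' Computes `S[i, j] = integral of b_i''(x) b_j''(x) dx` over the knot span by
#' per-interval Gauss--Legendre quadrature (exact for the polynomial degrees
#' involved). The null space of `S` is the set of coefficient vectors whose
#' spline is affine over the span.
#'
#' @param term A `smooth_term` object.
#' @return Symmetric positive semi-definite penalty matrix.
#' @export
penalty_matrix <- function(term) {
  stopifnot(inherits(term, "smooth_term"))
  if (term$order < 3L) stop("curvature penalty needs spline order >= 3")
  if (term$periodic) {
    a <- term$domain[1]; b <- term$domain[2]
    breaks <- seq(a, b, length.out = term$n_basis + 1L)
    d2 <- function(x) periodic_basis(x, term$n_basis, term$order, a, b,
                                     derivs = 2L)
  } else {
    breaks <- unique(term$knots)
    d2 <- function(x) bspline_basis(x, term$knots, term$order, derivs = 2L)
  }
  p <- term$n_basis
  S <- matrix(0, p, p)
  for (i in seq_len(length(breaks) - 1L)) {
    lo <- breaks[i]; hi <- breaks[i + 1L]
    if (hi <= lo) next
    half <- (hi - lo) / 2
    xs <- (hi + lo) / 2 + half * gl3_nodes
    B2 <- d2(xs)
    S <- S + half * crossprod(B2 * sqrt(gl3_weights), B2 * sqrt(gl3_weights))
  }
  (S + t(S)) / 2
}

#' Construct a smooth term for one model covariate
#'
#' A `smooth_term` bundles a covariate's spline basis, knots, curvature
#' penalty, and (after fitting) its coefficients and smoothness scale.
#'
#' @param name Covariate identifier.
#' @param kind One of `"continuous"`, `"circular"`, `"temporal_filter"`.
#' @param knots Knot vector (continuous terms). Ignored for circular terms.
#' @param order Spline order (4 = cubic, the default).
#' @param n_basis Number of basis functions for circular terms (default 8).
#' @param domain Domain for circular terms, default `c(-pi, pi)`.
#' @return An object of class `smooth_term`.
#' @export
smooth_term <- function(name, kind = c("continuous", "circular",
                                       "temporal_filter"),
                        knots = NULL, order = 4L, n_basis = 8L,
                        domain = c(-pi, pi)) {
  kind <- match.arg(kind)
  term <- list(name = name, kind = kind, order = as.integer(order),
               periodic = kind == "circular", domain = domain,
               beta = NULL, lambda = NA_real_)
  if (kind == "circular") {
    term$n_basis <- as.integer(n_basis)
    term$knots <- seq(domain[1], domain[2], length.out = n_basis + 1L)
  } else {
    if (is.null(knots) || length(knots) < 2L) {
      stop("continuous smooth terms need >= 2 knots")
    }
    term$knots <- sort(knots)
    term$n_basis <- length(term$knots) + order - 2L
  }
  class(term) <- "smooth_term"
  term$penalty <- penalty_matrix(term)
  term
}

#' Evaluate the basis of a smooth term at covariate values
#'
#' @param term A `smooth_term`.
#' @param x Covariate values (for temporal filters: lag times in seconds).
#' @return Matrix with `length(x)` rows and `term$n_basis` columns.
#' @export
eval_basis <- function(term, x) {
  if (term$periodic) {
    periodic_basis(x, term$n_basis, term$order, term$domain[1], term$domain[2])
  } else {
    bspline_basis(x, term$knots, term$order)
  }
}

#' Causal temporal-filter basis over event/spike lags
#'
#' Builds a lag-domain spline basis covering `(0, duration]` at the model bin
#' width. Convolving an event train with each basis column yields the design
#' columns for that event's temporal filter. Short filters (<= 72 ms) use
#' linearly spaced lag knots; long filters use log-spaced knots so early lags
#' get finer resolution.
#'
#' @param duration Filter duration in seconds (positive multiple of `dt`).
#' @param dt Bin width in seconds (default 0.006).
#' @param n_knots Number of lag knots (default: 3 for short filters, 8 for
#'   long ones).
#' @param spacing `"linear"` or `"log"` (default chosen from `duration`).
#' @param name Term name.
#' @return A `smooth_term` of kind `"temporal_filter"` with elements
#'   `lag_bins` (integer lags, starting at 1) and `lag_basis` (lags x basis
#'   matrix).
#' @export
temporal_basis <- function(duration, dt = 0.006, n_knots = NULL,
                           spacing = NULL, name = "filter") {
  if (duration < dt) stop("filter duration shorter than one bin")
  n_lag <- as.integer(round(duration / dt))
  if (abs(n_lag * dt - duration) > 1e-9) {
    stop("duration must be a positive multiple of dt")
  }
  if (is.null(spacing)) spacing <- if (duration <= 0.072) "linear" else "log"
  if (is.null(n_knots)) n_knots <- if (spacing == "linear") 3L else 8L
  lag_t <- seq_len(n_lag) * dt
  knots <- if (spacing == "linear") {
    seq(dt, duration, length.out = n_knots)
  } else {
    exp(seq(log(dt), log(duration), length.out = n_knots))
  }
  knots <- unique(knots)
  term <- smooth_term(name, "continuous", knots = knots, order = 4L)
  term$kind <- "temporal_filter"
  term$lag_bins <- seq_len(n_lag)
  term$lag_basis <- eval_basis(term, lag_t)
  term
}

#' Convolve a binary event / spike-count train with a temporal-filter basis
#'
#' Strictly causal: the design column at bin `t` depends on the train at bins
#' `t - 1, ..., t - L` only (lag 0 excluded, as required for spike-history
#' filters). Bins earlier than the first lag are zero-padded.
#'
#' @param z Numeric train (events 0/1 or spike counts) along the bin axis.
#' @param term A temporal-filter `smooth_term` from [temporal_basis()].
#' @return Matrix `length(z)` x `n_basis` of convolved design columns.
#' @export
convolve_basis <- function(z, term) {
  stopifnot(term$kind == "temporal_filter")
  L <- length(term$lag_bins)
  Tn <- length(z)
  out <- matrix(0, Tn, term$n_basis)
  for (j in seq_len(term$n_basis)) {
    v <- stats::filter(z, filter = c(0, term$lag_basis[, j]), sides = 1)
    v[is.na(v)] <- 0
    # stats::filter pads only the start; recompute the first L bins exactly
    out[, j] <- as.numeric(v)
  }
  if (Tn >= 1L) {
    for (t in seq_len(min(L, Tn))) {
      lags <- seq_len(t - 1L)
      out[t, ] <- if (length(lags)) {
        colSums(term$lag_basis[lags, , drop = FALSE] * z[t - lags])
      } else 0
    }
  }
  out
}

## Sum-to-zero (centering) constraint: reparameterize a basis block so the
## fitted smooth is orthogonal to the intercept over the observed data.
## Returns list(Z, X, S): Z the (p x p-1) constraint null-space basis,
## X = B %*% Z, S = t(Z) %*% S0 %*% Z.
center_constraint <- function(B, S0) {
  C <- matrix(colMeans(B), nrow = 1L)
  qrC <- qr(t(C))
  Z <- qr.Q(qrC, complete = TRUE)[, -1L, drop = FALSE]
  list(Z = Z, X = B %*% Z, S = crossprod(Z, S0 %*% Z))
}

#' Export a smooth term's definition as JSON
#'
#' Serializes knots, order, kind and penalty matrix so a basis can be rebuilt
#' or audited outside the package.
#'
#' @param term A `smooth_term`.
#' @param path Output file path.
#' @export
write_smooth_term <- function(term, path) {
  jsonlite::write_json(
    list(name = term$name, kind = term$kind, order = term$order,
         periodic = term$periodic, knots = term$knots,
         n_basis = term$n_basis, domain = term$domain,
         penalty = term$penalty),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
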