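#' Per-area fraction of units tuned to a task variable
#'
#' Binomial proportion of units with inclusion p-value below `alpha`, with an
#' exact 99% confidence interval per area. Cells with fewer than 5 units are
#' flagged as wide.
#'
#' @param term_table Long tibble of per-unit, per-term results (as stacked
#'   [tidy.pgam_fit()] rows: `unit_id`, `area`, `term`, `p_value`).
#' @param variable Task variable (term name); `NULL` for all.
#' @param alpha Tuning threshold (default 0.01).
#' @param conf Confidence level of the interval (default 0.99).
#' @return Tibble: area, variable, n, fraction, ci_low, ci_high, wide_flag.
#' @export
fraction_tuned <- function(term_table, variable = NULL, alpha = 0.01,
                           conf = 0.99) {
  tt <- term_table
  if (!is.null(variable)) tt <- dplyr::filter(tt, .data$term %in% variable)
  tt |>
    dplyr::group_by(.data$area, .data$term) |>
    dplyr::summarise(n = dplyr::n(),
                     n_tuned = sum(.data$p_value < alpha, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::rowwise() |>
    dplyr::mutate(fraction = .data$n_tuned / .data$n,
                  ci_low = binom.test(.data$n_tuned, .data$n,
                                      conf.level = conf)$conf.int[1],
                  ci_high = binom.test(.data$n_tuned, .data$n,
                                       conf.level = conf)$conf.int[2],
                  wide_flag = .data$n < 5L) |>
    dplyr::ungroup()
}

#' Pairwise area contrasts with Cohen's d on a modulation metric
#'
#' @param term_table As in [fraction_tuned()], with a numeric `metric` column
#'   (e.g. effective degrees of freedom or tuning-curve modulation depth).
#' @param variable Term to contrast.
#' @param metric Column name of the modulation metric (default `"edf"`).
#' @return Tibble of area pairs with mean difference and Cohen's d.
#' @export
area_contrasts <- function(term_table, variable, metric = "edf") {
  tt <- dplyr::filter(term_table, .data$term == variable)
  areas <- unique(tt$area)
  pairs <- utils::combn(areas, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- tt[[metric]][tt$area == pr[1]]
    b <- tt[[metric]][tt$area == pr[2]]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    tibble::tibble(variable = variable, area_1 = pr[1], area_2 = pr[2],
                   diff = mean(a) - mean(b),
                   cohens_d = (mean(a) - mean(b)) / sp)
  })
}

#' Binary tuning profiles of a cohort of fits
#'
#' One row per unit; 17 logical columns marking tuning (reduced-model
#' membership / inclusion `p < alpha`) per task variable.
#'
#' @param fits List of `pgam_fit` objects.
#' @param alpha Tuning threshold (default 0.01).
#' @return Tibble with `unit_id`, `area` and one logical column per task
#'   variable.
#' @export
tuning_profiles <- function(fits, alpha = 0.01) {
  vars <- task_covariate_names()$all
  purrr::map_dfr(fits, function(f) {
    sel <- if (f$degenerate) character(0) else selected_terms(f, alpha)
    row <- as.list(setNames(vars %in% sel, vars))
    tibble::as_tibble(c(list(unit_id = f$unit_id, area = f$area), row))
  })
}

## Pairwise Jaccard distance between binary row vectors (both-empty rows have
## distance 0).
jaccard_distance <- function(M) {
  M <- matrix(as.numeric(M), nrow = nrow(M))
  inter <- tcrossprod(M)
  sizes <- rowSums(M)
  uni <- outer(sizes, sizes, `+`) - inter
  D <- 1 - inter / pmax(uni, 1e-300)
  D[uni == 0] <- 0
  diag(D) <- 0
  D
}

#' Spectral clustering of binary tuning profiles under the Jaccard metric
#'
#' Builds the similarity graph `1 - Jaccard distance`, takes the leading k
#' eigenvectors of the normalized graph Laplacian, row-normalizes, and
#' partitions k ways with k-means. Deterministic given `seed`.
#'
#' @param profiles Units x variables logical/0-1 matrix (or the tibble from
#'   [tuning_profiles()]).
#' @param k Number of clusters (default 7).
#' @param seed RNG seed for the k-means step.
#' @return List of class `cluster_assignment`: `labels` (integer per unit),
#'   `method`, `k`.
#' @export
jaccard_spectral_cluster <- function(profiles, k = 7L, seed = 1L) {
  M <- profile_matrix(profiles)
  if (nrow(unique(as.data.frame(M))) < k) {
    if (nrow(unique(as.data.frame(M))) == 1L) {
      warning("all profiles identical: single cluster")
      return(structure(list(labels = rep(1L, nrow(M)),
                            method = "jaccard_spectral", k = 1L),
                       class = "cluster_assignment"))
    }
    stop("fewer distinct profiles than clusters")
  }
  W <- 1 - jaccard_distance(M)
  diag(W) <- 0
  dg <- pmax(rowSums(W), 1e-12)
  Ln <- sweep(sweep(W, 1, sqrt(dg), `/`), 2, sqrt(dg), `/`)
  eg <- eigen(Ln, symmetric = TRUE)
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  km <- kmeans(U, centers = k, nstart = 25, iter.max = 100)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  structure(list(labels = km$cluster, method = "jaccard_spectral",
                 k = k), class = "cluster_assignment")
}

profile_matrix <- function(profiles) {
  if (is.data.frame(profiles)) {
    as.matrix(dplyr::select(profiles,
                            -dplyr::any_of(c("unit_id", "area")))) * 1
  } else as.matrix(profiles) * 1
}

#' Robustness sweep over the number of spectral clusters
#'
#' Repeats the Jaccard-spectral clustering over a range of k and reports,
#' for each k, each area's majority-cluster fraction and the agreement
#' (Rand index) between consecutive k -- the check that conclusions do not
#' hinge on one k.
#'
#' @param profiles Profile tibble/matrix (see [tuning_profiles()]).
#' @param areas Area labels (taken from the tibble if present).
#' @param ks Values of k to sweep (default 3:8).
#' @param seed RNG seed.
#' @return Tibble: k, area, majority_fraction, rand_vs_prev.
#' @export
cluster_k_sweep <- function(profiles, areas = NULL, ks = 3:8, seed = 1L) {
  if (is.null(areas) && is.data.frame(profiles)) areas <- profiles$area
  M <- profile_matrix(profiles)
  rand_index <- function(a, b) {
    n <- length(a)
    ca <- outer(a, a, `==`); cb <- outer(b, b, `==`)
    up <- upper.tri(ca)
    mean(ca[up] == cb[up])
  }
  prev <- NULL
  purrr::map_dfr(ks, function(k) {
    cl <- jaccard_spectral_cluster(M, k = k, seed = seed)
    r <- if (is.null(prev)) NA_real_ else rand_index(cl$labels, prev)
    prev <<- cl$labels
    tibble::tibble(k = k, area = unique(areas)) |>
      dplyr::rowwise() |>
      dplyr::mutate(majority_fraction =
                      max(table(cl$labels[areas == .data$area])) /
                      sum(areas == .data$area),
                    rand_vs_prev = r) |>
      dplyr::ungroup()
  })
}

#' Majority-cluster fractions with subsampling to a reference count
#'
#' Repeats the Jaccard-spectral clustering while subsampling (without
#' replacement) the larger areas down to `n_per_area` units, and reports each
#' area's mean fraction of units in its majority cluster across draws --
#' the control for unequal area sizes.
#'
#' @param profiles Profile tibble/matrix.
#' @param areas Area label per unit (taken from the tibble if present).
#' @param k Number of clusters.
#' @param n_per_area Subsample size (default: smallest area count).
#' @param n_draws Number of subsampling draws.
#' @param seed RNG seed.
#' @return Tibble: area, mean/quantile majority-cluster fraction.
#' @export
cluster_subsample_control <- function(profiles, areas = NULL, k = 7L,
                                      n_per_area = NULL, n_draws = 50L,
                                      seed = 1L) {
  if (is.null(areas) && is.data.frame(profiles)) areas <- profiles$area
  M <- profile_matrix(profiles)
  tab <- table(areas)
  if (is.null(n_per_area)) n_per_area <- min(tab)
  set.seed(seed)
  draws <- purrr::map_dfr(seq_len(n_draws), function(d) {
    idx <- unlist(lapply(names(tab), function(a) {
      ia <- which(areas == a)
      if (length(ia) > n_per_area) sample(ia, n_per_area) else ia
    }))
    cl <- jaccard_spectral_cluster(M[idx, , drop = FALSE], k = k,
                                   seed = seed + d)
    tibble::tibble(draw = d, area = areas[idx], label = cl$labels) |>
      dplyr::group_by(.data$area) |>
      dplyr::summarise(majority = max(table(.data$label)) / dplyr::n(),
                       .groups = "drop")
  })
  draws |>
    dplyr::group_by(.data$area) |>
    dplyr::summarise(majority_fraction = mean(.data$majority),
                     q05 = quantile(.data$majority, 0.05),
                     q95 = quantile(.data$majority, 0.95),
                     .groups = "drop")
}

#' Stack and normalize tuning-curve shapes across variables
#'
#' Evaluates each unit's tuning curve on a fixed grid for every continuous /
#' circular variable, z-scores each curve (so high-rate units do not dominate
#' the PCA), and concatenates them into one shape vector per unit. Untuned or
#' missing terms contribute flat (zero) segments.
#'
#' @param fits List of `pgam_fit` objects.
#' @param variables Variables to stack (default: all continuous + LFP terms).
#' @param n_grid Grid points per variable (default 20).
#' @return List with `shapes` (units x sum(n_i) matrix), `blocks` (column
#'   index per variable), `unit_id`, `area`.
#' @export
stack_tuning_profiles <- function(fits, variables = NULL, n_grid = 20L) {
  cn <- task_covariate_names()
  if (is.null(variables)) variables <- c(cn$continuous, cn$lfp)
  rows <- lapply(fits, function(f) {
    unlist(lapply(variables, function(v) {
      if (f$degenerate || !v %in% names(f$terms)) return(rep(0, n_grid))
      tf <- extract_tuning(f, v, n_grid = n_grid)
      r <- log(pmax(tf$response, 1e-12))
      s <- sd(r)
      if (s < 1e-10) rep(0, n_grid) else (r - mean(r)) / s
    }))
  })
  shapes <- do.call(rbind, rows)
  blocks <- rep(variables, each = n_grid)
  list(shapes = shapes, blocks = blocks,
       unit_id = vapply(fits, `[[`, "", "unit_id"),
       area = vapply(fits, `[[`, "", "area"))
}

## Neighborhood radius from the sorted k-distance curve: the upper bend of
## the curve, located where the core-point distances end and the sparse tail
## begins (90th percentile; the geometric chord knee sits below the last
## dense shelf when cluster densities differ, over-fragmenting clusters).
kdist_eps <- function(D, k = 4L) {
  kd <- sort(apply(D, 1, function(r) sort(r)[k + 1L]))
  unname(quantile(kd, 0.90))
}

## Density-based clustering (DBSCAN) on a distance matrix. Label 0 = noise.
dbscan_labels <- function(D, eps, min_pts = 5L) {
  n <- nrow(D)
  labels <- rep(NA_integer_, n)
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (is.na(labels[j]) || labels[j] == 0L) {
        newly <- is.na(labels[j])
        labels[j] <- cl
        if (newly && core[j]) queue <- union(queue, setdiff(nb[[j]], j))
      }
    }
  }
  labels[is.na(labels)] <- 0L
  labels
}

#' Embed stacked tuning shapes in 2D and cluster by density
#'
#' Reduces the stacked-shape matrix by PCA to the smallest number of
#' components explaining more than 90% of the variance, projects those scores
#' onto a 2D neighborhood-preserving spectral (Laplacian eigenmap) embedding,
#' and clusters the embedding by density (DBSCAN with the neighborhood radius
#' at the knee of the k-distance curve, which determines the number of
#' clusters automatically). Deterministic given `seed`.
#'
#' @param shapes Units x features matrix (see [stack_tuning_profiles()]).
#' @param pca_var Variance threshold for the PCA step (default 0.90).
#' @param n_neighbors Neighborhood size of the embedding graph (default 10).
#' @param min_pts DBSCAN core-point threshold (default 5).
#' @param seed RNG seed.
#' @return List of class `cluster_assignment`: `labels` (0 = noise),
#'   `embedding` (n x 2), `m` (PCs kept), `method`.
#' @export
shape_embed_cluster <- function(shapes, pca_var = 0.90, n_neighbors = 10L,
                                min_pts = 5L, seed = 1L) {
  if (nrow(shapes) < 10L) stop("need >= 10 units to embed and cluster")
  ## exact duplicates collapse to one representative (and share its label):
  ## keeps the neighborhood graph well defined and the pipeline equivariant
  key <- apply(shapes, 1, function(r) paste(signif(r, 12), collapse = ","))
  rep_idx <- match(key, key)
  uniq <- !duplicated(key)
  map <- match(rep_idx, which(uniq))
  shapes <- shapes[uniq, , drop = FALSE]
  n <- nrow(shapes)
  keep <- apply(shapes, 2, sd) > 0
  pc <- prcomp(shapes[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  m <- which(cum > pca_var)[1]
  scores <- pc$x[, seq_len(m), drop = FALSE]
  D <- as.matrix(dist(scores))
  ## symmetric kNN graph with heat-kernel weights
  sigma <- median(apply(D, 1, function(r) sort(r)[n_neighbors + 1L]))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nn <- setdiff(order(D[i, ]), i)[seq_len(n_neighbors)]
    W[i, nn] <- exp(-D[i, nn]^2 / (2 * sigma^2))
  }
  W <- pmax(W, t(W))
  dg <- pmax(rowSums(W), 1e-12)
  Ln <- diag(n) - sweep(sweep(W, 1, sqrt(dg), `/`), 2, sqrt(dg), `/`)
  eg <- eigen(Ln, symmetric = TRUE)
  emb <- eg$vectors[, c(n - 1L, n - 2L), drop = FALSE]
  emb <- sweep(emb, 1, sqrt(dg), `*`)   # back to the random-walk scaling
  De <- as.matrix(dist(emb))
  eps <- kdist_eps(De, k = min_pts - 1L)
  labels <- dbscan_labels(De, eps = eps, min_pts = min_pts)[map]
  emb <- emb[map, , drop = FALSE]
  structure(list(labels = labels, embedding = emb, m = m,
                 method = "shape_embedding_density",
                 eps = eps, k = length(setdiff(unique(labels), 0L))),
            class = "cluster_assignment")
}

#' Ratio of centroid distances between areas in an embedding
#'
#' `dist(ref, area_b) / dist(ref, area_a)`: how much closer the reference
#' area's centroid is to `area_a` than to `area_b`. A subsampled version
#' (equal units per area) gives a percentile confidence interval.
#'
#' @param embedding n x 2 matrix of embedded units.
#' @param areas Area label per unit.
#' @param ref_area,area_a,area_b Area names.
#' @param n_sub If not `NULL`, subsample size per area for the CI.
#' @param n_draws Subsampling draws (default 100).
#' @param seed RNG seed.
#' @return Tibble with `ratio` (and `ci_low`, `ci_high` when subsampling).
#' @export
centroid_distance_ratio <- function(embedding, areas, ref_area, area_a,
                                    area_b, n_sub = NULL, n_draws = 100L,
                                    seed = 1L) {
  for (a in c(ref_area, area_a, area_b)) {
    if (sum(areas == a) < 2L) stop("need >= 2 units in area ", a)
  }
  one_ratio <- function(idx) {
    cen <- function(a) colMeans(embedding[idx[areas[idx] == a], ,
                                          drop = FALSE])
    cr <- cen(ref_area)
    sqrt(sum((cr - cen(area_b))^2)) / sqrt(sum((cr - cen(area_a))^2))
  }
  out <- tibble::tibble(ref_area = ref_area, area_a = area_a,
                        area_b = area_b,
                        ratio = one_ratio(seq_len(nrow(embedding))))
  if (!is.null(n_sub)) {
    set.seed(seed)
    draws <- vapply(seq_len(n_draws), function(d) {
      idx <- unlist(lapply(unique(areas), function(a) {
        ia <- which(areas == a)
        if (length(ia) > n_sub) sample(ia, n_sub) else ia
      }))
      one_ratio(idx)
    }, numeric(1))
    out$ratio_sub <- mean(draws)
    out$ci_low <- quantile(draws, 0.025)
    out$ci_high <- quantile(draws, 0.975)
  }
  out
}
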