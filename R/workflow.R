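#' Pipeline configuration
#'
#' One place for every stage's settings and seeds: the synthetic-session
#' conditions, the encoding-model spec and fitting options, and the
#' downstream analysis parameters.
#'
#' @param sim A [sim_config()].
#' @param spec A [pgam_spec()] (smaller bases than the session default keep
#'   cohort fits fast).
#' @param folds Cross-validation folds for smoothness selection.
#' @param alpha Inclusion significance level.
#' @param stages Stages to run, in dependency order.
#' @param cluster_k Clusters for the Jaccard-spectral step.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(n_trials = 60, n_units = 18),
                            spec = pgam_spec(n_knots = 6L,
                                             n_phase_basis = 6L,
                                             event_filter = 0.12),
                            folds = 5L, alpha = 0.01,
                            stages = c("simulate", "behavior", "fit",
                                       "metrics", "population", "coupling"),
                            cluster_k = 3L) {
  structure(list(sim = sim, spec = spec, folds = folds, alpha = alpha,
                 stages = stages, cluster_k = cluster_k),
            class = "pipeline_config")
}

#' Run the full synthetic-session analysis pipeline
#'
#' Executes simulate, behavior, fit, metrics, population, and coupling stages
#' in dependency order, producing the tuned-fraction table, preferred-value
#' distributions, cluster reports and the coupling-fraction grid on the
#' synthetic cohort. A stage failure is recorded in the manifest and
#' downstream stages are skipped. Deterministic given config and seed.
#'
#' @param config A [pipeline_config()].
#' @param seed Master seed.
#' @param out_dir Optional directory; stage outputs are written as CSV/JSON.
#' @return List of class `navgam_run`: `manifest` plus per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = NULL) {
  res <- list(manifest = tibble::tibble(stage = character(),
                                        status = character(),
                                        seconds = numeric()))
  ok <- TRUE
  stage <- function(name, fun) {
    if (!name %in% config$stages || !ok) {
      status <- if (!name %in% config$stages) "disabled" else "skipped"
      res$manifest <<- dplyr::bind_rows(
        res$manifest, tibble::tibble(stage = name, status = status,
                                     seconds = 0))
      return(invisible(NULL))
    }
    t0 <- proc.time()[3]
    out <- tryCatch(fun(), error = function(e) e)
    el <- proc.time()[3] - t0
    if (inherits(out, "error")) {
      ok <<- FALSE
      res$manifest <<- dplyr::bind_rows(
        res$manifest, tibble::tibble(stage = name,
                                     status = paste("failed:",
                                                    conditionMessage(out)),
                                     seconds = el))
    } else {
      res[[name]] <<- out
      res$manifest <<- dplyr::bind_rows(
        res$manifest, tibble::tibble(stage = name, status = "ok",
                                     seconds = el))
    }
    invisible(NULL)
  }

  stage("simulate", function() simulate_session(config$sim, seed = seed))
  stage("behavior", function() {
    behavior_summary(res$simulate$trials, session_id = "synthetic")
  })
  stage("fit", function() {
    session <- res$simulate
    fits <- lapply(colnames(session$counts), function(u) {
      des <- assemble_design(session, u, config$spec)
      fit <- fit_pgam(des, folds = config$folds, seed = seed)
      red <- reduce_and_refit(fit, des, alpha = config$alpha)
      list(full = fit, reduced = red)
    })
    names(fits) <- colnames(session$counts)
    fits
  })
  stage("metrics", function() {
    full <- lapply(res$fit, `[[`, "full")
    term_table <- purrr::map_dfr(full, tidy)
    summary <- purrr::map_dfr(full, glance)
    preferred <- purrr::map_dfr(full, function(f) {
      if (f$degenerate) return(tibble::tibble())
      vars <- intersect(selected_terms(f),
                        c(task_covariate_names()$continuous))
      purrr::map_dfr(vars, function(v) {
        tf <- extract_tuning(f, v, n_grid = 50)
        tibble::tibble(unit_id = f$unit_id, area = f$area, variable = v,
                       preferred = attr(tf, "preferred"),
                       monotone = attr(tf, "monotone_flag"))
      })
    })
    list(term_table = term_table, summary = summary, preferred = preferred)
  })
  stage("population", function() {
    full <- lapply(res$fit, `[[`, "full")
    profiles <- tuning_profiles(full, alpha = config$alpha)
    k <- min(config$cluster_k,
             nrow(unique(profile_matrix(profiles))))
    jac <- jaccard_spectral_cluster(profiles, k = max(2L, k), seed = seed)
    stacked <- stack_tuning_profiles(full)
    emb <- tryCatch(shape_embed_cluster(stacked$shapes, seed = seed),
                    error = function(e) NULL)
    fractions <- fraction_tuned(res$metrics$term_table,
                                alpha = config$alpha)
    list(profiles = profiles, jaccard = jac, stacked = stacked,
         embedding = emb, tuned_fractions = fractions)
  })
  stage("coupling", function() {
    full <- lapply(res$fit, `[[`, "full")
    has_coupling <- any(vapply(full, function(f) {
      any(vapply(f$terms, function(t) t$kind == "coupling", logical(1)))
    }, logical(1)))
    if (!has_coupling) {
      return(list(graph = NULL, note = "no coupling terms in spec"))
    }
    graph <- extract_couplings(full, res$simulate$units,
                               alpha = config$alpha)
    list(graph = graph, fractions = coupling_fractions(graph))
  })

  if (!is.null(out_dir)) write_run(res, out_dir)
  class(res) <- "navgam_run"
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(res$manifest, file.path(out_dir, "manifest.csv"))
  if (!is.null(res$behavior)) {
    readr::write_csv(res$behavior, file.path(out_dir, "behavior.csv"))
  }
  if (!is.null(res$metrics)) {
    readr::write_csv(res$metrics$term_table,
                     file.path(out_dir, "terms.csv"))
    readr::write_csv(res$metrics$summary, file.path(out_dir, "units.csv"))
    readr::write_csv(res$metrics$preferred,
                     file.path(out_dir, "preferred.csv"))
  }
  if (!is.null(res$population)) {
    readr::write_csv(res$population$tuned_fractions,
                     file.path(out_dir, "tuned_fractions.csv"))
    readr::write_csv(
      tibble::tibble(unit_id = res$population$profiles$unit_id,
                     area = res$population$profiles$area,
                     cluster = res$population$jaccard$labels),
      file.path(out_dir, "clusters.csv"))
  }
  if (!is.null(res$coupling$graph)) {
    write_coupling_graph(res$coupling$graph, file.path(out_dir, "coupling"))
  }
  invisible(out_dir)
}

#' @export
print.navgam_run <- function(x, ...) {
  cat("<navgam_run>\n")
  print(x$manifest)
  invisible(x)
}
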