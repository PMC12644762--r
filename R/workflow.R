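#' Run a named end-to-end workflow and write its artifacts
#'
#' Convenience driver reproducing the figure-level analyses with desk-scale
#' defaults: each workflow writes CSV outputs plus a JSON manifest (inputs,
#' seeds, package version, runtimes) to `out_dir`, and returns the result
#' invisibly. Workflows: `"steady"` (stationary states + eigenstructure),
#' `"landscape"`, `"transitions"` (first-passage ensemble), `"perturb"`
#' (degradation scan + transition assay), `"table1"` (full
#' attractor-geometry report), `"cohort"` (repeated correlations),
#' `"calibrate"` (self-consistency refit on model-generated targets).
#'
#' @param name Workflow name.
#' @param out_dir Output directory (created if missing).
#' @param config Named list of overrides (`seed`, `n_cells`, `horizon`,
#'   `n_sims`, `factors`, `reps`, ...).
#' @param params Parameter set (default [grn_params()]).
#' @return The workflow result, invisibly.
#' @export
run_workflow <- function(name = c("steady", "landscape", "transitions",
                                  "perturb", "table1", "cohort",
                                  "calibrate"),
                         out_dir = "nfkbgrn-out", config = list(),
                         params = grn_params()) {
  name <- match.arg(name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(
    list(seed = 1L, n_cells = 120L, horizon = 30 * MINUTES_PER_DAY,
         n_sims = 1e4, bins = 100, factors = c(0.975, 1.05), reps = 100L,
         record_interval = 250),
    config
  )
  t0 <- Sys.time()
  net <- build_network(params)
  result <- switch(
    name,
    steady = {
      rep <- find_stationary_states(net, seed = cfg$seed)
      utils::write.csv(rep$states, file.path(out_dir, "stationary_states.csv"),
                       row.names = FALSE)
      eig <- purrr::map_dfr(seq_along(rep$eigen), function(i)
        tibble::tibble(state = rep$states$state[i],
                       eigenvalue_re = Re(rep$eigen[[i]]$values),
                       eigenvalue_im = Im(rep$eigen[[i]]$values)))
      utils::write.csv(eig, file.path(out_dir, "eigenvalues.csv"),
                       row.names = FALSE)
      rep
    },
    landscape = {
      ls <- build_landscape(net, n_sims = cfg$n_sims, bins = cfg$bins,
                            seed = cfg$seed)
      utils::write.csv(ls, file.path(out_dir, "landscape.csv"),
                       row.names = FALSE)
      ls
    },
    transitions = {
      rep <- find_stationary_states(net, seed = cfg$seed)
      rec <- first_passage_ensemble(net, rep, n_cells = cfg$n_cells,
                                    horizon = cfg$horizon,
                                    base_seed = cfg$seed)
      utils::write.csv(rec, file.path(out_dir, "transitions.csv"),
                       row.names = FALSE)
      utils::write.csv(transition_curve(rec),
                       file.path(out_dir, "transition_curve.csv"),
                       row.names = FALSE)
      rec
    },
    perturb = {
      res <- purrr::map(cfg$factors, function(f)
        scan_degradation(params, f, n_starts = 60, seed = cfg$seed))
      tbl <- purrr::map_dfr(res, function(r) {
        if (is.null(r$distances)) return(tibble::tibble(factor = r$factor))
        dplyr::bind_cols(tibble::tibble(factor = r$factor), r$distances)
      })
      utils::write.csv(tbl, file.path(out_dir, "perturbation.csv"),
                       row.names = FALSE)
      res
    },
    table1 = {
      rep1 <- degradation_report(params, factors = cfg$factors,
                                 seed = cfg$seed)
      utils::write.csv(rep1$levels, file.path(out_dir, "table1_levels.csv"),
                       row.names = FALSE)
      utils::write.csv(rep1$variation,
                       file.path(out_dir, "table1_variation.csv"),
                       row.names = FALSE)
      utils::write.csv(rep1$distances,
                       file.path(out_dir, "table1_distances.csv"),
                       row.names = FALSE)
      rep1
    },
    cohort = {
      rep <- find_stationary_states(net, seed = cfg$seed)
      ens <- run_ensemble(net, n_cells = min(cfg$n_cells, 60L),
                          horizon = cfg$horizon, init = "HER2", report = rep,
                          record_interval = cfg$record_interval,
                          base_seed = cfg$seed)
      cor_res <- repeated_correlation(ens, rep, reps = cfg$reps,
                                      seed = cfg$seed)
      utils::write.csv(cor_res$summary,
                       file.path(out_dir, "cohort_correlations.csv"),
                       row.names = FALSE)
      cor_res
    },
    calibrate = {
      targets <- stationary_rna_targets(params, seed = cfg$seed)
      utils::write.csv(targets, file.path(out_dir, "calibration_targets.csv"),
                       row.names = FALSE)
      obj <- steady_state_objective(params, targets)
      list(targets = targets, objective_at_reference = obj)
    }
  )
  manifest <- list(
    workflow = name,
    config = cfg,
    package_version = as.character(utils::packageVersion("nfkbgrn")),
    r_version = R.version.string,
    runtime_seconds = as.numeric(Sys.time() - t0, units = "secs"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(result)
}
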