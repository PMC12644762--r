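#' Euclidean basin distance in the (p50, p65) protein plane
#'
#' Distance between two states using only their p50 and p65 protein
#' coordinates — the metric in which the attractor-basin sizes are
#' reported.
#'
#' @param state_a,state_b States: named vectors or one-row data frames
#'   exposing `P_p50` and `P_p65`.
#' @return Nonnegative scalar.
#' @export
basin_distance <- function(state_a, state_b) {
  get2 <- function(s) {
    if (is.data.frame(s)) return(c(s$P_p50[1], s$P_p65[1]))
    as.numeric(c(s[["P_p50"]], s[["P_p65"]]))
  }
  a <- get2(state_a); b <- get2(state_b)
  sqrt(sum((a - b)^2))
}

#' Scan the p65 protein degradation rate
#'
#' Multiplies the p65 protein degradation rate by `factor` (FBXW2-type
#' mutations or targeted protein degradation change p65 availability),
#' recomputes the stationary states, and reports per-species percentage
#' changes at each state together with the HER2-to-unstable and
#' TNBC-to-unstable basin distances and their percentage changes.
#'
#' @param params A `grn_params` object (wild type).
#' @param factor Positive multiplier on the p65 protein degradation rate.
#' @param report_wt Optional precomputed wild-type `stability_report`
#'   (computed when missing).
#' @param ... Passed to [find_stationary_states()].
#' @return A `perturbation_result`: list with `factor`, `states` (the
#'   perturbed `stability_report`), `pct_change` (tibble: state x species),
#'   `distances` (tibble with wild-type and perturbed distances and their
#'   percentage changes), and `monostable` flag.
#' @export
scan_degradation <- function(params, factor, report_wt = NULL, ...) {
  stopifnot(inherits(params, "grn_params"), factor > 0)
  net_wt <- build_network(params)
  if (is.null(report_wt)) report_wt <- find_stationary_states(net_wt, ...)
  net_mut <- build_network(scale_p65_degradation(params, factor))
  report_mut <- find_stationary_states(net_mut, ...)

  monostable <- sum(report_mut$states$classification == "stable") < 2
  sp <- intersect(names(report_wt$states), net_wt$species$name)
  pct <- NULL
  dist_tbl <- NULL
  if (!monostable && nrow(report_mut$states) == nrow(report_wt$states)) {
    wt <- report_wt$states
    mut <- report_mut$states
    pct <- purrr::map_dfr(seq_len(nrow(wt)), function(i) {
      vals <- 100 * (unlist(mut[i, sp]) / unlist(wt[i, sp]) - 1)
      dplyr::bind_cols(tibble::tibble(state = wt$state[i]),
                       tibble::as_tibble(as.list(vals)))
    })
    d_wt <- basin_distances(report_wt)
    d_mut <- basin_distances(report_mut)
    dist_tbl <- tibble::tibble(
      pair = c("HER2_to_unstable", "TNBC_to_unstable"),
      wild_type = c(d_wt$her2, d_wt$tnbc),
      perturbed = c(d_mut$her2, d_mut$tnbc),
      pct_change = 100 * (c(d_mut$her2, d_mut$tnbc) /
                            c(d_wt$her2, d_wt$tnbc) - 1)
    )
  }
  structure(list(factor = factor, states = report_mut, pct_change = pct,
                 distances = dist_tbl, monostable = monostable,
                 wild_type = report_wt),
            class = "perturbation_result")
}

basin_distances <- function(report) {
  st <- report$states
  uns <- st[st$classification != "stable", ][1, ]
  stab <- st[st$classification == "stable", ]
  stab <- stab[order(stab$NFKB), ]
  list(her2 = basin_distance(stab[1, ], uns),
       tnbc = basin_distance(stab[2, ], uns))
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("<perturbation_result> p65 degradation x %.4g%s\n", x$factor,
              if (x$monostable) " (monostable after perturbation)" else ""))
  if (!is.null(x$pct_change)) {
    print(dplyr::select(x$pct_change, "state",
                        dplyr::any_of(c("P_p50", "P_p65", "NFKB",
                                        "RNA_p50", "RNA_p65"))))
    print(x$distances)
  }
  invisible(x)
}

#' Attractor-geometry report across degradation factors
#'
#' Runs [scan_degradation()] for each factor and assembles a table of
#' stationary molecule numbers, percentage variations and basin distances —
#' stationary states in columns, conditions side by side.
#'
#' @param params Wild-type `grn_params`.
#' @param factors Degradation multipliers to scan.
#' @param ... Passed to [find_stationary_states()].
#' @return List with `levels` (molecule numbers per state and condition),
#'   `variation` (percent change vs wild type), `distances` (basin
#'   distances and their percent changes).
#' @export
degradation_report <- function(params, factors = c(0.975, 1.05), ...) {
  net <- build_network(params)
  wt <- find_stationary_states(net, ...)
  species <- c("P_p50", "P_p65", "NFKB", "RNA_p50", "RNA_p65")
  lev_wt <- dplyr::bind_cols(
    tibble::tibble(condition = "wild_type", state = wt$states$state),
    wt$states[, species])
  scans <- purrr::map(factors, function(f)
    scan_degradation(params, f, report_wt = wt, ...))
  levels <- dplyr::bind_rows(
    lev_wt,
    purrr::map_dfr(seq_along(factors), function(k) {
      st <- scans[[k]]$states$states
      dplyr::bind_cols(
        tibble::tibble(condition = sprintf("factor_%g", factors[k]),
                       state = st$state),
        st[, species])
    })
  )
  variation <- purrr::map_dfr(seq_along(factors), function(k) {
    pc <- scans[[k]]$pct_change
    if (is.null(pc)) return(tibble::tibble())
    dplyr::bind_cols(
      tibble::tibble(condition = sprintf("factor_%g", factors[k])),
      pc[, c("state", species)])
  })
  d_wt <- basin_distances(wt)
  distances <- dplyr::bind_rows(
    tibble::tibble(condition = "wild_type",
                   pair = c("HER2_to_unstable", "TNBC_to_unstable"),
                   distance = c(d_wt$her2, d_wt$tnbc),
                   pct_change = c(0, 0)),
    purrr::map_dfr(seq_along(factors), function(k) {
      dt <- scans[[k]]$distances
      if (is.null(dt)) return(tibble::tibble())
      tibble::tibble(condition = sprintf("factor_%g", factors[k]),
                     pair = dt$pair, distance = dt$perturbed,
                     pct_change = dt$pct_change)
    })
  )
  list(levels = levels, variation = variation, distances = distances,
       reports = c(list(wild_type = wt),
                   stats::setNames(purrr::map(scans, "states"),
                                   sprintf("factor_%g", factors))))
}

#' Stochastic transition assay under perturbed p65 degradation
#'
#' Couples [scan_degradation()] with the first-passage machinery: simulates
#' `n_cells` tau-leaping cells from the HER2 stationary state of the
#' perturbed model and summarises the transition curve.
#'
#' @param params Wild-type `grn_params`.
#' @param factor Degradation multiplier.
#' @param n_cells Ensemble size.
#' @param horizon Per-cell horizon (model minutes).
#' @param base_seed Seed base; cell i uses `base_seed + i`.
#' @param dwell Dwell-confirmation window (minutes).
#' @param report_wt Optional wild-type report (for reuse).
#' @param ... Passed to [find_stationary_states()].
#' @return List with `records` (per-cell first passages), `curve`
#'   (transition curve), `fraction_transitioned`, `max_first_passage`.
#' @export
perturbed_transition_assay <- function(params, factor, n_cells = 120,
                                       horizon = 30 * MINUTES_PER_DAY,
                                       base_seed = 1L, dwell = 4320,
                                       report_wt = NULL, ...) {
  pm <- scale_p65_degradation(params, factor)
  net <- build_network(pm)
  report <- find_stationary_states(net, ...)
  rec <- first_passage_ensemble(net, report, n_cells = n_cells,
                                horizon = horizon, start = "HER2",
                                base_seed = base_seed, dwell = dwell)
  curve <- transition_curve(rec, horizon = horizon)
  list(records = rec, curve = curve,
       fraction_transitioned = mean(rec$transitioned),
       max_first_passage = if (any(rec$transitioned))
         max(rec$first_passage_time, na.rm = TRUE) else NA_real_)
}
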