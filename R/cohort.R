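#' Labelled single-cell ensemble for cohort sampling
#'
#' Simulates `n_cells` independent tau-leaping cells from the HER2
#' stationary state, recording at `record_interval`, and stops each cell
#' early once it has resided in the TNBC basin for `tn_window` minutes
#' (untransitioned cells run to `horizon`). Both subtypes thereby
#' contribute recorded moments at a fraction of the cost of running every
#' cell to the full horizon — TNBC-basin simulation is several-fold more
#' expensive per model minute than HER2-basin simulation, and moments
#' beyond a long post-transition window add little new information about
#' the basin. Cells are simulated in chunks; chunk `k` of cell `i` uses
#' seed `base_seed + 1009 * i + k`.
#'
#' @param network A `grn_network`.
#' @param report A `stability_report` for it.
#' @param n_cells Number of cells.
#' @param horizon Maximum simulated time per cell (model minutes).
#' @param tn_window Post-transition residence recorded before stopping.
#' @param record_interval Snapshot interval (minutes).
#' @param base_seed Seed base.
#' @param chunk Chunk length (minutes).
#' @return A `grn_ensemble` tibble (`cell`, `time`, species columns).
#' @export
cohort_ensemble <- function(network, report, n_cells = 51,
                            horizon = 1.3e5, tn_window = 2e4,
                            record_interval = 250, base_seed = 1L,
                            chunk = 10000) {
  sp_names <- network$species$name
  row <- report$states[report$states$state == "HER2", , drop = FALSE]
  init0 <- round_state(network, row[, sp_names])
  cells <- purrr::map(seq_len(n_cells), function(i) {
    t_now <- 0
    init <- init0
    segs <- list()
    first_tn <- NA_real_
    k <- 0
    while (t_now < horizon) {
      k <- k + 1
      len <- min(chunk, horizon - t_now)
      tr <- tau_leap(network, init, horizon = len,
                     seed = base_seed + 1009L * i + k,
                     record_interval = record_interval)
      tr$time <- tr$time + t_now
      if (t_now > 0) tr <- tr[-1, , drop = FALSE]  # drop duplicated joint
      segs[[k]] <- tr
      last <- tr[nrow(tr), ]
      init <- round_state(network, unlist(last[, sp_names]))
      t_now <- t_now + len
      if (is.na(first_tn) &&
          assign_basin(last, report, "hyperplane") == "TNBC") {
        first_tn <- t_now
      }
      if (!is.na(first_tn) && t_now - first_tn >= tn_window) break
    }
    dplyr::bind_cols(tibble::tibble(cell = i), dplyr::bind_rows(segs))
  })
  out <- dplyr::bind_rows(cells)
  structure(out, class = c("grn_ensemble", class(out)),
            base_seed = base_seed, n_cells = n_cells, horizon = horizon)
}

#' Sample a pseudo-cohort of (p50 RNA, p65 RNA) pairs from an ensemble
#'
#' Emulates cohort construction from single-cell simulations: `n` distinct
#' cells are drawn without replacement and one recorded timepoint is drawn
#' uniformly per cell; the (RNA_p50, RNA_p65) pair at that moment is the
#' cohort sample, labelled by the attractor basin occupied at that time.
#' When `subtype` is given, the timepoint for each cell is drawn among the
#' moments carrying that basin label, and only cells possessing such
#' moments are eligible.
#'
#' @param ensemble A `grn_ensemble` from [run_ensemble()].
#' @param n Number of cells to draw.
#' @param report A `stability_report` (for basin labelling).
#' @param subtype Optional label filter (`"HER2"` or `"TNBC"`).
#' @param seed RNG seed.
#' @return Tibble (`cell`, `time`, `p50_rna`, `p65_rna`, `subtype`).
#' @export
sample_simulated_cohort <- function(ensemble, n, report, subtype = NULL,
                                    seed = 1) {
  lab <- assign_basin(ensemble, report, method = "hyperplane")
  df <- tibble::tibble(cell = ensemble$cell, time = ensemble$time,
                       p50_rna = ensemble$RNA_p50,
                       p65_rna = ensemble$RNA_p65, subtype = lab)
  if (!is.null(subtype)) {
    df <- df[df$subtype == subtype, , drop = FALSE]
  }
  eligible <- unique(df$cell)
  if (length(eligible) < n) {
    stop("only ", length(eligible), " cells carry ",
         if (is.null(subtype)) "recorded" else subtype,
         " timepoints; cannot draw ", n, call. = FALSE)
  }
  with_seed(seed, {
    cells <- sample(eligible, n)
    purrr::map_dfr(cells, function(cl) {
      rows <- df[df$cell == cl, , drop = FALSE]
      rows[sample.int(nrow(rows), 1), ]
    })
  })
}

#' Spearman rank correlation with p-value
#'
#' Mid-rank-tied Spearman correlation and two-sided p-value via
#' [stats::cor.test()].
#'
#' @param pairs Two-column data frame or matrix (x, y); `n >= 3` required.
#' @return Tibble (`rho`, `p_value`, `n`, `ok`); `ok = FALSE` with `NA`
#'   statistics when either margin is constant.
#' @export
spearman_with_p <- function(pairs) {
  m <- as.matrix(pairs[, 1:2])
  if (nrow(m) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(m[, 1]) == 0 || stats::sd(m[, 2]) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                          n = nrow(m), ok = FALSE))
  }
  ct <- suppressWarnings(
    stats::cor.test(m[, 1], m[, 2], method = "spearman", exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(m), ok = TRUE)
}

#' Repeated cohort-correlation procedure
#'
#' Repeats the pseudo-cohort sampling `reps` times: each repeat draws
#' `n_her2` HER2-labelled and `n_tnbc` TNBC-labelled (p50 RNA, p65 RNA)
#' pairs from distinct cells, computes the Spearman correlation per subtype
#' set, and keeps only sets whose correlation p-value is below
#' `p_threshold`. Reported are the mean correlation over accepted sets and
#' the acceptance count, per subtype.
#'
#' @param ensemble A `grn_ensemble`.
#' @param report A `stability_report`.
#' @param n_her2,n_tnbc Cohort sizes per subtype.
#' @param reps Number of repeats.
#' @param p_threshold Acceptance threshold on the correlation p-value.
#' @param seed RNG seed (each repeat derives its own stream).
#' @return List with `summary` (tibble: `subtype`, `mean_rho`, `n_accepted`,
#'   `reps`) and `draws` (per-repeat tibble of `subtype`, `rho`, `p_value`,
#'   `accepted`).
#' @export
repeated_correlation <- function(ensemble, report, n_her2 = 17, n_tnbc = 34,
                                 reps = 100, p_threshold = 5e-3, seed = 1) {
  draws <- purrr::map_dfr(seq_len(reps), function(r) {
    purrr::map_dfr(
      list(list(st = "HER2", n = n_her2), list(st = "TNBC", n = n_tnbc)),
      function(cfg) {
        smp <- tryCatch(
          sample_simulated_cohort(ensemble, cfg$n, report,
                                  subtype = cfg$st,
                                  seed = seed * 100003L + r),
          error = function(e) NULL
        )
        if (is.null(smp)) {
          return(tibble::tibble(rep = r, subtype = cfg$st, rho = NA_real_,
                                p_value = NA_real_, accepted = FALSE))
        }
        sc <- spearman_with_p(smp[, c("p50_rna", "p65_rna")])
        tibble::tibble(rep = r, subtype = cfg$st, rho = sc$rho,
                       p_value = sc$p_value,
                       accepted = isTRUE(sc$ok && sc$p_value < p_threshold))
      })
  })
  summary <- dplyr::summarise(
    dplyr::group_by(draws, .data$subtype),
    mean_rho = mean(.data$rho[.data$accepted]),
    n_accepted = sum(.data$accepted),
    reps = dplyr::n(),
    .groups = "drop"
  )
  list(summary = summary, draws = draws)
}
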