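#' Relative expression by the delta-delta-Ct method
#'
#' `fold = 2^-ddCt` with
#' `ddCt = (Ct_gene - Ct_ref)_sample - (Ct_gene - Ct_ref)_calibrator`.
#' Inputs may be triplicate vectors; means are taken first.
#'
#' @param sample_ct,sample_ref_ct Ct values of the gene of interest and the
#'   reference gene(s) in the sample.
#' @param calibrator_ct,calibrator_ref_ct The same in the calibrator sample.
#' @return Fold expression of the sample relative to the calibrator.
#' @examples
#' ddct_fold(20, 15, 21, 15) # one cycle earlier than calibrator -> fold 2
#' @export
ddct_fold <- function(sample_ct, sample_ref_ct,
                      calibrator_ct, calibrator_ref_ct) {
  d_sample <- mean(sample_ct) - mean(sample_ref_ct)
  d_cal <- mean(calibrator_ct) - mean(calibrator_ref_ct)
  2^(-(d_sample - d_cal))
}

#' Convert fold expression to absolute molecule numbers
#'
#' Scales a relative expression level by the typical per-cell RNA abundance
#' of the reference transcript in a mammalian cell.
#'
#' @param fold Fold expression (relative to the calibrator).
#' @param reference_abundance RNA molecules per cell for the calibrator
#'   condition.
#' @return Estimated RNA molecule count (real-valued).
#' @export
fold_to_molecules <- function(fold, reference_abundance) {
  if (any(reference_abundance <= 0)) {
    stop("reference abundance must be positive", call. = FALSE)
  }
  fold * reference_abundance
}

#' Ct table to calibration targets
#'
#' Summarises a tidy qPCR Ct table (columns `gene`, `subtype`, `ct`, with
#' reference genes among `ref_genes`) into per-gene per-subtype RNA molecule
#' targets via the delta-delta-Ct method, using the given calibrator
#' subtype and per-gene reference abundances.
#'
#' @param ct_table Tidy Ct table (`gene`, `subtype`, `ct`).
#' @param reference_abundance Named vector: RNA molecules per cell of each
#'   gene in the calibrator subtype.
#' @param calibrator Subtype used as the calibrator (default `"HER2"`).
#' @param ref_genes Reference (housekeeping) gene names.
#' @return Tibble (`gene`, `subtype`, `fold`, `rna_count`).
#' @export
qpcr_to_targets <- function(ct_table, reference_abundance,
                            calibrator = "HER2",
                            ref_genes = c("ACTB", "GAPDH")) {
  ct <- dplyr::group_by(ct_table, .data$gene, .data$subtype)
  ct <- dplyr::summarise(ct, ct = mean(.data$ct), .groups = "drop")
  refs <- dplyr::filter(ct, .data$gene %in% ref_genes)
  refs <- dplyr::group_by(refs, .data$subtype)
  refs <- dplyr::summarise(refs, ref_ct = mean(.data$ct), .groups = "drop")
  goi <- dplyr::filter(ct, !.data$gene %in% ref_genes)
  goi <- dplyr::left_join(goi, refs, by = "subtype")
  cal <- dplyr::filter(goi, .data$subtype == calibrator)
  cal <- dplyr::select(cal, "gene", cal_ct = "ct", cal_ref_ct = "ref_ct")
  goi <- dplyr::left_join(goi, cal, by = "gene")
  goi <- dplyr::mutate(
    goi,
    fold = 2^(-((.data$ct - .data$ref_ct) - (.data$cal_ct - .data$cal_ref_ct))),
    rna_count = unname(fold_to_molecules(
      .data$fold, reference_abundance[.data$gene]))
  )
  dplyr::select(goi, "gene", "subtype", "fold", "rna_count")
}

#' Stationary-state calibration objective
#'
#' Sum over genes and both stable states of the squared log-ratio between
#' the model's stationary RNA counts and the calibration targets. Parameter
#' sets under which the model is not bistable receive a large penalty.
#'
#' @param params A `grn_params` proposal.
#' @param targets Tibble (`gene`, `subtype` in `"HER2"`/`"TNBC"`,
#'   `rna_count`).
#' @param penalty Value returned when fewer than 3 stationary states exist.
#' @param n_starts Multistart budget for the inner stationary-state solve
#'   (kept small for speed; the three basins are well separated).
#' @return Nonnegative scalar; 0 iff the model matches every target.
#' @export
steady_state_objective <- function(params, targets, penalty = 1e6,
                                   n_starts = 40) {
  net <- build_network(params)
  rep <- tryCatch(
    find_stationary_states(net, n_starts = n_starts, seed = 7),
    error = function(e) NULL
  )
  if (is.null(rep) || nrow(rep$states) < 3 ||
      sum(rep$states$classification == "stable") != 2) {
    return(penalty)
  }
  stable <- rep$states[rep$states$classification == "stable", ]
  stable <- stable[order(stable$NFKB), ]
  rownames_map <- c(HER2 = 1, TNBC = 2)
  obj <- 0
  for (i in seq_len(nrow(targets))) {
    row <- rownames_map[[targets$subtype[i]]]
    model_rna <- stable[[paste0("RNA_", targets$gene[i])]][row]
    if (is.null(model_rna) || !is.finite(model_rna) || model_rna <= 0) {
      return(penalty)
    }
    obj <- obj + log(model_rna / targets$rna_count[i])^2
  }
  obj
}

#' Stationary RNA targets implied by a parameter set
#'
#' Convenience for self-consistency experiments: the model's own stationary
#' RNA counts at the two stable states, shaped as a calibration target
#' table.
#'
#' @param params A `grn_params`.
#' @param genes Genes to include.
#' @param ... Passed to [find_stationary_states()].
#' @return Tibble (`gene`, `subtype`, `rna_count`).
#' @export
stationary_rna_targets <- function(params, genes = c("p50", "p65"), ...) {
  rep <- find_stationary_states(build_network(params), ...)
  stable <- rep$states[rep$states$classification == "stable", ]
  stable <- stable[order(stable$NFKB), ]
  purrr::map_dfr(seq_along(genes), function(i) {
    tibble::tibble(
      gene = genes[i],
      subtype = c("HER2", "TNBC"),
      rna_count = stable[[paste0("RNA_", genes[i])]]
    )
  })
}

#' Multistart local optimisation of a calibration objective
#'
#' Wraps [stats::optim()] (Nelder-Mead by default) in a seeded multistart
#' over log-scaled parameters and records the evaluation trace.
#'
#' @param objective Function of a numeric parameter vector.
#' @param start Named numeric start vector (positive values; optimised on
#'   the log scale).
#' @param lower,upper Box bounds on the original scale.
#' @param n_starts Number of random restarts (the first start is `start`).
#' @param seed RNG seed.
#' @param method Passed to [stats::optim()].
#' @param control Passed to [stats::optim()].
#' @return List with `par` (best parameters, original scale), `value`,
#'   `trace` (tibble of all evaluations), `converged`.
#' @export
fit_parameters <- function(objective, start, lower = start / 10,
                           upper = start * 10, n_starts = 5, seed = 1,
                           method = "Nelder-Mead",
                           control = list(maxit = 400, reltol = 1e-10)) {
  stopifnot(all(start > 0), all(lower > 0), all(upper >= lower))
  trace <- new.env()
  trace$rows <- list()
  wrapped <- function(th) {
    par <- exp(th)
    par <- pmin(pmax(par, lower), upper)
    val <- objective(par)
    trace$rows[[length(trace$rows) + 1]] <- c(par, value = val)
    val
  }
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      th0 <- if (s == 1) log(start)
             else log(start) + stats::rnorm(length(start), 0, 0.5)
      th0 <- pmin(pmax(th0, log(lower)), log(upper))
      o <- tryCatch(stats::optim(th0, wrapped, method = method,
                                 control = control),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
  })
  if (is.null(best)) stop("optimizer failed from every start", call. = FALSE)
  par <- pmin(pmax(exp(best$par), lower), upper)
  names(par) <- names(start)
  list(par = par, value = best$value,
       trace = tibble::as_tibble(do.call(rbind, trace$rows)),
       converged = isTRUE(best$convergence == 0))
}

#' Deterministic NF-kB inhibitor (DHMEQ-style) recovery time course
#'
#' Simulates transient inhibition of NF-kB activity followed by release,
#' for a cell sitting in a given stationary state. Two inhibition modes are
#' supported: `"zero_binding"` sets all NF-kB-to-DNA binding rates to zero
#' for the treatment duration (default), `"deplete_dimer"` instead removes
#' the free dimer pool at release time. RNA levels are reported at the
#' requested times after release.
#'
#' @param params A `grn_params`.
#' @param report A `stability_report` (wild type).
#' @param subtype `"HER2"` or `"TNBC"`: which stationary state is treated.
#' @param mode Inhibition mode.
#' @param duration Treatment duration (model minutes; default 24 h).
#' @param sample_times Times after release at which RNA levels are reported
#'   (default 0 to 48 h, including the 8 h point).
#' @return Tibble (`subtype`, `gene`, `time_h`, `rna`).
#' @export
simulate_dhmeq_recovery <- function(params, report, subtype = "HER2",
                                    mode = c("zero_binding", "deplete_dimer"),
                                    duration = 1440,
                                    sample_times = c(0, 60, 120, 240, 480,
                                                     720, 1440, 2880)) {
  mode <- match.arg(mode)
  net <- build_network(params)
  row <- report$states[report$states$state == subtype, , drop = FALSE]
  if (nrow(row) != 1) stop("no stationary state named ", subtype,
                           call. = FALSE)
  x0 <- as_state(net, row[, net$species$name])

  if (mode == "zero_binding") {
    p_inh <- params
    p_inh$genes$kon <- 0
    net_inh <- build_network(p_inh)
    if (duration > 0) {
      sol <- integrate_ode(net_inh, x0, times = c(0, duration))
      x0 <- unlist(sol[nrow(sol), -1])
    }
  } else {
    x0[net$species$name == "NFKB"] <- 0
  }
  sol <- integrate_ode(net, x0, times = sample_times)
  rna_cols <- grep("^RNA_", names(sol), value = TRUE)
  out <- tidyr::pivot_longer(sol[, c("time", rna_cols)], cols = -"time",
                             names_to = "gene", values_to = "rna")
  out$gene <- sub("^RNA_", "", out$gene)
  tibble::tibble(subtype = subtype, gene = out$gene,
                 time_h = out$time / 60, rna = out$rna)
}
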