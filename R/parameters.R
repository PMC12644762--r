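#' Kinetic parameter set for the five-gene NF-kB circuit
#'
#' Builds the full kinetic parameterisation of the network: per-gene rate
#' constants for NF-kB binding/unbinding at the regulatory region,
#' bound-state transcription, constitutive RNA synthesis, RNA degradation
#' and (for translated genes) translation and protein degradation, plus the
#' p50:p65 dimerisation constants. All rates are per minute and per
#' molecule-count (mass action on molecule numbers); two copies of every
#' gene are assumed.
#'
#' The default values are the package's calibrated reference set. The
#' stationary structure (three stationary states whose p50/p65/NF-kB protein
#' and RNA levels correspond to the HER2-positive and triple-negative
#' expression phenotypes) is fixed by the rate *ratios*; the absolute time
#' scales were calibrated so that the weak Jacobian eigenvalues at the
#' stationary states fall at the few-per-thousand-per-minute scale
#' (hour-scale relaxation) and so that stochastic simulations exhibit rare,
#' irreversible HER2-to-TNBC basin transitions.
#'
#' @param genes Data frame of per-gene rate constants. Columns: `gene`,
#'   `kon`, `koff`, `ktx`, `kbasal`, `kdR`, `ktl`, `kdP`, `translated`.
#'   Defaults to the calibrated set for p50, p65, TWIST1, SLUG, SIP1.
#' @param ka Association rate of p50 + p65 -> NF-kB (per molecule pair per
#'   minute).
#' @param kd_dimer Dissociation rate of the NF-kB dimer (per minute).
#' @param kdP_dimer Degradation rate of the intact dimer; 0 by default (the
#'   dimer decays via its subunits after dissociation).
#' @param gene_copies Integer number of copies of each gene (2).
#' @param time_unit Declared model time unit label (`"minute"`).
#' @param translate_targets If `TRUE`, the EMT target genes TWIST1, SLUG and
#'   SIP1 are also translated into protein; by default they are tracked at
#'   the RNA level only, which matches the reported protein species (p50,
#'   p65, NF-kB) and keeps the dynamical core nine-dimensional.
#'
#' @return An object of class `grn_params`: a list with elements `genes`
#'   (tibble), `ka`, `kd_dimer`, `kdP_dimer`, `gene_copies`, `time_unit`.
#' @examples
#' p <- grn_params()
#' p$genes
#' @export
grn_params <- function(genes = NULL,
                       ka = 1.436197173e-07,
                       kd_dimer = 0.09150636935,
                       kdP_dimer = 0,
                       gene_copies = 2L,
                       time_unit = "minute",
                       translate_targets = FALSE) {
  if (is.null(genes)) {
    genes <- default_gene_table(translate_targets)
  } else {
    genes <- tibble::as_tibble(genes)
  }
  required <- c("gene", "kon", "koff", "ktx", "kbasal", "kdR", "ktl", "kdP",
                "translated")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop("`genes` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rate_cols <- c("kon", "koff", "ktx", "kbasal", "kdR")
  for (col in rate_cols) {
    bad <- !is.finite(genes[[col]]) | genes[[col]] < 0
    if (any(bad)) {
      stop("missing or negative rate constant `", col, "` for gene ",
           paste(genes$gene[bad], collapse = ", "), call. = FALSE)
    }
  }
  tr <- genes$translated
  for (col in c("ktl", "kdP")) {
    bad <- tr & (!is.finite(genes[[col]]) | genes[[col]] < 0)
    if (any(bad)) {
      stop("missing or negative rate constant `", col,
           "` for translated gene ", paste(genes$gene[bad], collapse = ", "),
           call. = FALSE)
    }
  }
  if (!all(c("p50", "p65") %in% genes$gene)) {
    stop("parameter set must contain genes p50 and p65", call. = FALSE)
  }
  stopifnot(ka >= 0, kd_dimer >= 0, kdP_dimer >= 0, gene_copies >= 1)
  structure(
    list(genes = genes, ka = ka, kd_dimer = kd_dimer, kdP_dimer = kdP_dimer,
         gene_copies = as.integer(gene_copies), time_unit = time_unit),
    class = "grn_params"
  )
}

# Calibrated reference rate constants (per minute, molecule-count units).
default_gene_table <- function(translate_targets = FALSE) {
  g <- tibble::tribble(
    ~gene,     ~kon,            ~koff,        ~ktx,         ~kbasal,       ~kdR,  ~ktl,           ~kdP,
    "p50",     2.215913089e-04, 20.34962145,  109.5661305,  18.099495,     0.3,   9.616708639,    0.03089288719,
    "p65",     1.0e-04,         11.77262466,  156.4163505,  25.583292,     0.3,   64.70456818,    0.0755813609,
    "TWIST1",  1.0e-05,         1.0,          15.0,         2.0,           0.1,   NA_real_,       NA_real_,
    "SLUG",    1.0e-05,         1.0,          15.0,         2.0,           0.1,   NA_real_,       NA_real_,
    "SIP1",    1.0e-05,         1.0,          15.0,         2.0,           0.1,   NA_real_,       NA_real_
  )
  g$translated <- g$gene %in% c("p50", "p65")
  if (translate_targets) {
    idx <- !g$translated
    # generic turnover for target proteins when requested
    g$ktl[idx] <- 10
    g$kdP[idx] <- 0.01
    g$translated <- TRUE
  }
  g
}

#' @export
print.grn_params <- function(x, ...) {
  cat("<grn_params> five-gene NF-kB circuit, time unit:", x$time_unit, "\n")
  cat(sprintf("  dimer: ka = %.4g, kd = %.4g, kdP = %.4g; gene copies = %d\n",
              x$ka, x$kd_dimer, x$kdP_dimer, x$gene_copies))
  print(x$genes)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a parameter set into a long tibble
#'
#' @param x A `grn_params` object.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `gene`, `value`.
#' @export
tidy.grn_params <- function(x, ...) {
  per_gene <- tidyr::pivot_longer(x$genes, cols = -c("gene", "translated"),
                                  names_to = "parameter",
                                  values_to = "value")
  per_gene <- dplyr::select(per_gene, "parameter", "gene", "value")
  global <- tibble::tibble(
    parameter = c("ka", "kd_dimer", "kdP_dimer", "gene_copies"),
    gene = NA_character_,
    value = c(x$ka, x$kd_dimer, x$kdP_dimer, as.numeric(x$gene_copies))
  )
  dplyr::bind_rows(per_gene, global)
}

#' Scale the p65 protein degradation rate
#'
#' Convenience used by the perturbation module: returns a copy of the
#' parameter set with `kdP` of p65 multiplied by `factor` (mimicking
#' FBXW2-type mutations or targeted protein degradation).
#'
#' @param params A `grn_params` object.
#' @param factor Positive multiplier applied to the p65 protein degradation
#'   rate.
#' @return A modified `grn_params` object.
#' @export
scale_p65_degradation <- function(params, factor) {
  stopifnot(inherits(params, "grn_params"), factor > 0)
  i <- params$genes$gene == "p65"
  params$genes$kdP[i] <- params$genes$kdP[i] * factor
  params
}
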