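#' Synthetic qPCR Ct table with known fold structure
#'
#' Generates triplicate Ct values for a set of genes in two subtypes such
#' that the delta-delta-Ct fold of each gene (TNBC relative to the HER2
#' calibrator) equals the supplied profile in expectation. Reference genes
#' ACTB and GAPDH are included at a fixed Ct.
#'
#' @param profiles Tibble (`gene`, `fold`): TNBC/HER2 fold per gene.
#' @param noise_sd Gaussian Ct noise standard deviation (cycles).
#' @param reps Technical replicates per gene and subtype.
#' @param seed RNG seed.
#' @param base_ct Mean Ct of each gene in the calibrator subtype.
#' @param ref_ct Mean Ct of the reference genes.
#' @return Tidy tibble (`gene`, `subtype`, `replicate`, `ct`).
#' @export
synth_qpcr <- function(profiles, noise_sd = 0.15, reps = 3, seed = 1,
                       base_ct = 24, ref_ct = 16) {
  stopifnot(all(profiles$fold > 0))
  genes <- c(profiles$gene, "ACTB", "GAPDH")
  mean_ct <- function(gene, subtype) {
    if (gene %in% c("ACTB", "GAPDH")) return(ref_ct)
    if (subtype == "HER2") return(base_ct)
    base_ct - log2(profiles$fold[profiles$gene == gene])
  }
  grid <- tidyr::expand_grid(gene = genes, subtype = c("HER2", "TNBC"),
                             replicate = seq_len(reps))
  with_seed(seed, {
    grid$ct <- vapply(seq_len(nrow(grid)), function(i) {
      mean_ct(grid$gene[i], grid$subtype[i]) + stats::rnorm(1, 0, noise_sd)
    }, numeric(1))
  })
  grid
}

#' Synthetic expression cohort with a target Spearman correlation
#'
#' Draws `n` (p50, p65) expression pairs from a Gaussian copula whose
#' latent correlation is chosen so that the population Spearman correlation
#' equals `target_rho`, with either log-normal marginals (bulk cohorts) or
#' negative-binomial marginals (single-cell UMI-style integer counts).
#'
#' @param n Number of samples.
#' @param target_rho Population Spearman correlation (|rho| <= 1).
#' @param marginal_means Length-2 means of the (p50, p65) marginals.
#' @param dispersion Log-normal sdlog (bulk) or negative-binomial size
#'   parameter (single cell).
#' @param mode `"bulk_lognormal"` or `"sc_negative_binomial"`.
#' @param seed RNG seed.
#' @return Tibble (`sample_id`, `p50`, `p65`, `source`).
#' @export
synth_cohort <- function(n, target_rho, marginal_means = c(100, 130),
                         dispersion = 0.5,
                         mode = c("bulk_lognormal", "sc_negative_binomial"),
                         seed = 1) {
  mode <- match.arg(mode)
  stopifnot(abs(target_rho) <= 1)
  # Gaussian-copula latent correlation giving the requested Spearman rho
  rho_z <- 2 * sin(pi * target_rho / 6)
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * stats::rnorm(n)
    u1 <- stats::pnorm(z1); u2 <- stats::pnorm(z2)
    if (mode == "bulk_lognormal") {
      p50 <- stats::qlnorm(u1, meanlog = log(marginal_means[1]),
                           sdlog = dispersion)
      p65 <- stats::qlnorm(u2, meanlog = log(marginal_means[2]),
                           sdlog = dispersion)
    } else {
      if (dispersion <= 0) stop("infeasible dispersion", call. = FALSE)
      p50 <- stats::qnbinom(u1, mu = marginal_means[1], size = dispersion)
      p65 <- stats::qnbinom(u2, mu = marginal_means[2], size = dispersion)
    }
    tibble::tibble(sample_id = seq_len(n), p50 = p50, p65 = p65,
                   source = "synthetic")
  })
}

#' Constructed basin-switching trajectory
#'
#' Piecewise-stationary noisy trajectory that sits at `pre_state` until
#' `t_switch` and at `post_state` afterwards, with independent Gaussian
#' jitter proportional to the square root of the local mean (Poisson-scale
#' noise). Used as a ground-truth fixture for transition detection.
#'
#' @param network A `grn_network` (defines the species set).
#' @param t_switch Switch time (model minutes).
#' @param pre_state,post_state Full species states (e.g. rows of a
#'   `stability_report`).
#' @param jitter Noise multiplier (0 disables noise).
#' @param horizon Trajectory length (minutes).
#' @param record_interval Sampling interval (minutes).
#' @param seed RNG seed.
#' @return A `grn_trajectory`-shaped tibble.
#' @export
synth_transition_trajectory <- function(network, t_switch, pre_state,
                                        post_state, jitter = 1,
                                        horizon = 2 * t_switch,
                                        record_interval = 10, seed = 1) {
  pre <- as_state(network, pre_state)
  post <- as_state(network, post_state)
  times <- seq(0, horizon, by = record_interval)
  base <- t(vapply(times, function(tm) if (tm < t_switch) pre else post,
                   numeric(length(pre))))
  with_seed(seed, {
    noise <- matrix(stats::rnorm(length(base), 0, 1), nrow(base)) *
      jitter * sqrt(pmax(base, 0))
    # gene-copy species stay exact: jitter would break their conservation
    gene_cols <- grepl("^N[01]_", network$species$name)
    noise[, gene_cols] <- 0
    x <- pmax(base + noise, 0)
    out <- tibble::as_tibble(as.data.frame(round(x)))
    names(out) <- network$species$name
    out <- dplyr::bind_cols(tibble::tibble(time = times), out)
    structure(out, class = c("grn_trajectory", class(out)),
              method = "synthetic", seed = seed, truncated = FALSE)
  })
}
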