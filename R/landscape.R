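#' Grid of initial conditions over the (p50, p65) protein plane
#'
#' Lays the p50/p65 protein counts of `n` starting states evenly over the
#' given ranges. The remaining species are set either to the conditional
#' quasi-equilibrium given the clamped proteins (gene occupancies, RNAs and
#' the dimer at their fixed point conditional on the protein pair; default)
#' or to a generic baseline (`"zero"`: free genes, zero RNA/dimer).
#'
#' @param network A `grn_network`.
#' @param n Number of start points (rounded down to a full grid).
#' @param p50_range,p65_range Protein-count intervals covered by the grid.
#' @param fill_rule `"quasi_equilibrium"` or `"zero"`.
#' @return Tibble of integer-valued initial states, one row per start.
#' @export
grid_initial_conditions <- function(network, n,
                                    p50_range = c(0, 1.8e5),
                                    p65_range = c(0, 6.0e5),
                                    fill_rule = c("quasi_equilibrium",
                                                  "zero")) {
  fill_rule <- match.arg(fill_rule)
  if (diff(p50_range) <= 0 || diff(p65_range) <= 0) {
    stop("empty protein range", call. = FALSE)
  }
  n_side <- max(floor(sqrt(n)), 1)
  p50s <- seq(p50_range[1], p50_range[2], length.out = n_side + 1)[-(n_side + 1)]
  p65s <- seq(p65_range[1], p65_range[2], length.out = n_side + 1)[-(n_side + 1)]
  grid <- tidyr::expand_grid(P_p50 = p50s, P_p65 = p65s)
  sp <- network$species
  states <- purrr::pmap(grid, function(P_p50, P_p65) {
    x <- initial_state(network)
    x["P_p50"] <- P_p50
    x["P_p65"] <- P_p65
    if (fill_rule == "quasi_equilibrium") {
      x <- conditional_equilibrium(network, x)
    }
    round_state(network, x)
  })
  out <- tibble::as_tibble(do.call(rbind, states))
  names(out) <- sp$name
  out
}

# Fixed point of the gene/RNA/dimer subsystem with the p50/p65 proteins
# clamped: dimer from the binding equilibrium, gene occupancies from the
# dimer level, RNA from the occupancy balance.
conditional_equilibrium <- function(network, x) {
  p <- network$params
  g <- p$genes
  copies <- p$gene_copies
  denom <- p$kd_dimer + p$kdP_dimer
  nf <- if (denom > 0) p$ka * x[["P_p50"]] * x[["P_p65"]] / denom else 0
  x["NFKB"] <- nf
  for (i in seq_len(nrow(g))) {
    gene <- g$gene[i]
    occ <- copies * g$kon[i] * nf / (g$koff[i] + g$kon[i] * nf)
    x[paste0("N1_", gene)] <- occ
    x[paste0("N0_", gene)] <- copies - occ
    x[paste0("RNA_", gene)] <- (g$ktx[i] * occ + g$kbasal[i]) / g$kdR[i]
  }
  x
}

#' Quasi-potential attractor landscape from short stochastic simulations
#'
#' Launches `n_sims` tau-leaping simulations of length `sim_length` from
#' initial conditions distributed over a uniform grid in the (p50, p65)
#' protein plane, bins the endpoints, and converts the endpoint occupancy
#' into a quasi-potential `U = -ln(P + pseudocount-normalised)`. The surface
#' exhibits one well per attractor basin; the wells contain the stable
#' stationary states.
#'
#' @param network A `grn_network`.
#' @param n_sims Number of simulations (default 1e4; the desk-scale
#'   default — increase for smoother surfaces).
#' @param sim_length Length of each simulation (model minutes; default 30).
#' @param bins Number of bins per axis.
#' @param pseudocount Occupancy pseudocount guaranteeing a finite potential.
#' @param seed RNG seed.
#' @param p50_range,p65_range Grid ranges (protein counts).
#' @param fill_rule Passed to [grid_initial_conditions()].
#' @param accumulate `"endpoint"` (default) or `"path"`: whether only the
#'   final state or all recorded states of each simulation enter the
#'   occupancy.
#' @param record_interval Recording interval when `accumulate = "path"`.
#' @param epsilon Tau-leaping control parameter.
#' @return A `grn_landscape`: tibble with bin centres (`p50`, `p65`),
#'   `occupancy`, `probability` and `potential`; attributes carry the bin
#'   edges and the call settings.
#' @export
build_landscape <- function(network, n_sims = 1e4, sim_length = 30,
                            bins = 100, pseudocount = 0.5, seed = 1L,
                            p50_range = c(0, 1.8e5), p65_range = c(0, 6.0e5),
                            fill_rule = "quasi_equilibrium",
                            accumulate = c("endpoint", "path"),
                            record_interval = 5, epsilon = 1e-3) {
  accumulate <- match.arg(accumulate)
  inits <- grid_initial_conditions(network, n_sims, p50_range, p65_range,
                                   fill_rule)
  im <- as.matrix(inits)
  storage.mode(im) <- "integer"
  sp_names <- network$species$name
  i50 <- match("P_p50", sp_names); i65 <- match("P_p65", sp_names)
  if (accumulate == "endpoint") {
    ends <- with_seed(seed, endpoints_cpp(network$stoich, network$reactants,
                                          network$reactions$rate, im,
                                          sim_length, epsilon, 1e10, 10))
    pts <- cbind(ends[, i50], ends[, i65])
  } else {
    pts <- with_seed(seed, {
      acc <- list()
      for (s in seq_len(nrow(im))) {
        res <- tau_leap_cpp(network$stoich, network$reactants,
                            network$reactions$rate, im[s, ], sim_length,
                            record_interval, epsilon, 1e10, 10)
        acc[[s]] <- res$states[, c(i50, i65), drop = FALSE]
      }
      do.call(rbind, acc)
    })
  }
  e50 <- seq(p50_range[1], max(p50_range[2], max(pts[, 1]) + 1),
             length.out = bins + 1)
  e65 <- seq(p65_range[1], max(p65_range[2], max(pts[, 2]) + 1),
             length.out = bins + 1)
  b50 <- pmin(pmax(findInterval(pts[, 1], e50, rightmost.closed = TRUE), 1),
              bins)
  b65 <- pmin(pmax(findInterval(pts[, 2], e65, rightmost.closed = TRUE), 1),
              bins)
  occ <- matrix(0, bins, bins)
  for (k in seq_along(b50)) occ[b50[k], b65[k]] <- occ[b50[k], b65[k]] + 1
  if (sum(occ > 0) <= 1) {
    warning("degenerate landscape: all endpoints fall in one bin")
  }
  prob <- occ / sum(occ)
  pot <- -log((occ + pseudocount) / sum(occ + pseudocount))
  centre <- function(e) (e[-1] + e[-length(e)]) / 2
  out <- tidyr::expand_grid(p50 = centre(e50), p65 = centre(e65))
  ij <- as.matrix(tidyr::expand_grid(i = seq_len(bins), j = seq_len(bins)))
  out$occupancy <- occ[ij]
  out$probability <- prob[ij]
  out$potential <- pot[ij]
  structure(out, class = c("grn_landscape", class(out)),
            p50_edges = e50, p65_edges = e65, n_sims = nrow(im),
            sim_length = sim_length, pseudocount = pseudocount, seed = seed)
}

#' Locate the wells (local minima) of a quasi-potential landscape
#'
#' Finds bins whose potential is a local minimum over their 8-neighbourhood
#' and that carry genuine occupancy, ranked by depth.
#'
#' @param landscape A `grn_landscape`.
#' @param n_minima Maximum number of wells to report.
#' @param min_separation Minimum separation between reported wells, as a
#'   fraction of the grid diagonal.
#' @param smooth Half-width (in bins) of a moving-average filter applied to
#'   the occupancy before well detection; suppresses bin-level sampling
#'   noise at moderate simulation counts.
#' @return Tibble of wells (`p50`, `p65`, `potential`, `occupancy`).
#' @export
landscape_minima <- function(landscape, n_minima = 2,
                             min_separation = 0.15, smooth = 1) {
  bins50 <- length(attr(landscape, "p50_edges")) - 1
  bins65 <- length(attr(landscape, "p65_edges")) - 1
  pot <- matrix(landscape$potential, bins50, bins65, byrow = TRUE)
  occ <- matrix(landscape$occupancy, bins50, bins65, byrow = TRUE)
  if (smooth > 0) {
    pc <- attr(landscape, "pseudocount")
    occ_s <- smooth_matrix(occ, smooth)
    pot <- -log((occ_s + pc) / sum(occ_s + pc))
    occ <- occ_s
  }
  cand <- list()
  for (i in seq_len(bins50)) {
    for (j in seq_len(bins65)) {
      if (occ[i, j] == 0) next
      nb <- pot[max(1, i - 1):min(bins50, i + 1),
                max(1, j - 1):min(bins65, j + 1)]
      if (pot[i, j] <= min(nb)) {
        cand[[length(cand) + 1]] <- c(i = i, j = j, pot = pot[i, j],
                                      occ = occ[i, j])
      }
    }
  }
  if (length(cand) == 0) return(tibble::tibble())
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, "pot"]), , drop = FALSE]
  c50 <- (attr(landscape, "p50_edges")[-1] +
            utils::head(attr(landscape, "p50_edges"), -1)) / 2
  c65 <- (attr(landscape, "p65_edges")[-1] +
            utils::head(attr(landscape, "p65_edges"), -1)) / 2
  diag_len <- sqrt(diff(range(c50))^2 + diff(range(c65))^2)
  picked <- list()
  for (k in seq_len(nrow(cand))) {
    pt <- c(c50[cand[k, "i"]], c65[cand[k, "j"]])
    too_close <- any(vapply(picked, function(q)
      sqrt(sum((q$xy - pt)^2)) < min_separation * diag_len, logical(1)))
    if (!too_close) {
      picked[[length(picked) + 1]] <- list(xy = pt, pot = cand[k, "pot"],
                                           occ = cand[k, "occ"])
    }
    if (length(picked) >= n_minima) break
  }
  purrr::map_dfr(picked, function(q)
    tibble::tibble(p50 = q$xy[1], p65 = q$xy[2], potential = q$pot,
                   occupancy = q$occ))
}

# moving-average smoothing with edge truncation
smooth_matrix <- function(m, hw) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  cs <- matrix(0, n1 + 1, n2 + 1)
  cs[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum)
  # cs is transposed by the second apply; recompute directly instead
  cs <- matrix(0, n1 + 1, n2 + 1)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      cs[i + 1, j + 1] <- m[i, j] + cs[i, j + 1] + cs[i + 1, j] - cs[i, j]
    }
  }
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      i0 <- max(1, i - hw); i1 <- min(n1, i + hw)
      j0 <- max(1, j - hw); j1 <- min(n2, j + hw)
      s <- cs[i1 + 1, j1 + 1] - cs[i0, j1 + 1] - cs[i1 + 1, j0] + cs[i0, j0]
      out[i, j] <- s / ((i1 - i0 + 1) * (j1 - j0 + 1))
    }
  }
  out
}

#' @export
autoplot.grn_landscape <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p50, y = .data$p65,
                                       fill = .data$potential)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "p50 protein (molecules)",
                  y = "p65 protein (molecules)",
                  fill = "quasi-potential U")
}
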