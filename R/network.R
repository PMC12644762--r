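#' Build the mass-action reaction network for the NF-kB circuit
#'
#' Expands a parameter set into the explicit reaction network. Gene
#' activation follows a three-step scheme per gene X: a reversible binding
#' of the NF-kB dimer to the free regulatory region (`NFKB + N0_X <-> N1_X`)
#' and irreversible RNA (`N1_X -> N1_X + RNA_X`) and, for translated genes,
#' protein (`RNA_X -> RNA_X + P_X`) synthesis. Constitutive RNA synthesis
#' and first-order RNA/protein decay complete each gene module, and
#' `P_p50 + P_p65 <-> NFKB` couples the two subunits into the dimer.
#'
#' @param params A [grn_params()] object.
#' @return An object of class `grn_network`: list with
#'   * `species`: tibble (`name`, `kind`, `gene`),
#'   * `reactions`: tibble (`name`, `rate_name`, `rate`),
#'   * `stoich`: integer species-by-reaction stoichiometry matrix,
#'   * `reactants`: integer species-by-reaction reactant-multiplicity matrix,
#'   * `conservation`: list of conservation laws (coefficient vector, total),
#'   * `params`: the parameter set used.
#' @examples
#' net <- build_network(grn_params())
#' net$species
#' @export
build_network <- function(params = grn_params()) {
  stopifnot(inherits(params, "grn_params"))
  g <- params$genes

  species <- list()
  add_sp <- function(name, kind, gene) {
    species[[length(species) + 1]] <<- tibble::tibble(
      name = name, kind = kind, gene = gene)
  }
  for (i in seq_len(nrow(g))) {
    gene <- g$gene[i]
    add_sp(paste0("N0_", gene), "gene_free", gene)
    add_sp(paste0("N1_", gene), "gene_bound", gene)
    add_sp(paste0("RNA_", gene), "rna", gene)
  }
  for (i in seq_len(nrow(g))) {
    if (g$translated[i]) add_sp(paste0("P_", g$gene[i]), "protein", g$gene[i])
  }
  add_sp("NFKB", "dimer", NA_character_)
  species <- dplyr::bind_rows(species)
  sp_index <- stats::setNames(seq_len(nrow(species)), species$name)

  rx <- list()
  add_rx <- function(name, rate_name, rate, reactants, products) {
    rx[[length(rx) + 1]] <<- list(name = name, rate_name = rate_name,
                                  rate = rate, reactants = reactants,
                                  products = products)
  }
  for (i in seq_len(nrow(g))) {
    gene <- g$gene[i]
    n0 <- paste0("N0_", gene); n1 <- paste0("N1_", gene)
    rna <- paste0("RNA_", gene)
    add_rx(paste0("bind_", gene), paste0("kon_", gene), g$kon[i],
           c("NFKB", n0), n1)
    add_rx(paste0("unbind_", gene), paste0("koff_", gene), g$koff[i],
           n1, c("NFKB", n0))
    add_rx(paste0("tx_", gene), paste0("ktx_", gene), g$ktx[i],
           n1, c(n1, rna))
    add_rx(paste0("basal_", gene), paste0("kbasal_", gene), g$kbasal[i],
           character(0), rna)
    add_rx(paste0("degR_", gene), paste0("kdR_", gene), g$kdR[i],
           rna, character(0))
    if (g$translated[i]) {
      prot <- paste0("P_", gene)
      add_rx(paste0("tl_", gene), paste0("ktl_", gene), g$ktl[i],
             rna, c(rna, prot))
      add_rx(paste0("degP_", gene), paste0("kdP_", gene), g$kdP[i],
             prot, character(0))
    }
  }
  add_rx("dimer_assoc", "ka", params$ka, c("P_p50", "P_p65"), "NFKB")
  add_rx("dimer_dissoc", "kd_dimer", params$kd_dimer, "NFKB",
         c("P_p50", "P_p65"))
  if (params$kdP_dimer > 0) {
    add_rx("degP_NFKB", "kdP_NFKB", params$kdP_dimer, "NFKB", character(0))
  }

  n_sp <- nrow(species); n_rx <- length(rx)
  S <- matrix(0L, n_sp, n_rx, dimnames = list(species$name, NULL))
  RM <- matrix(0L, n_sp, n_rx, dimnames = list(species$name, NULL))
  for (j in seq_len(n_rx)) {
    for (s in rx[[j]]$reactants) {
      RM[sp_index[[s]], j] <- RM[sp_index[[s]], j] + 1L
      S[sp_index[[s]], j] <- S[sp_index[[s]], j] - 1L
    }
    for (s in rx[[j]]$products) S[sp_index[[s]], j] <- S[sp_index[[s]], j] + 1L
  }
  reactions <- tibble::tibble(
    name = vapply(rx, `[[`, character(1), "name"),
    rate_name = vapply(rx, `[[`, character(1), "rate_name"),
    rate = vapply(rx, `[[`, numeric(1), "rate")
  )
  colnames(S) <- reactions$name
  colnames(RM) <- reactions$name

  net <- structure(
    list(species = species, reactions = reactions, stoich = S,
         reactants = RM, conservation = list(), params = params),
    class = "grn_network"
  )
  net$conservation <- conservation_laws(net)
  net
}

#' @export
print.grn_network <- function(x, ...) {
  cat(sprintf("<grn_network> %d species, %d reactions, %d conservation laws\n",
              nrow(x$species), nrow(x$reactions), length(x$conservation)))
  cat("  species:", paste(x$species$name, collapse = " "), "\n")
  invisible(x)
}

#' Detect linear conservation laws of a reaction network
#'
#' Computes an integer basis of the left null space of the stoichiometry
#' matrix. For this circuit the laws are the gene-copy constraints
#' `N0_X + N1_X = 2` for each of the five genes.
#'
#' @param network A `grn_network`.
#' @param tol Numerical tolerance on singular values.
#' @return A list of conservation laws, each a list with `coefficients`
#'   (named integer vector over species) and `total` (the conserved total
#'   implied by the default initial state, when determinable).
#' @export
conservation_laws <- function(network, tol = 1e-9) {
  S <- network$stoich
  sv <- svd(t(S), nu = 0, nv = ncol(t(S)))
  null_idx <- which(sv$d < tol * max(sv$d))
  rank <- sum(sv$d >= tol * max(sv$d))
  V <- sv$v[, setdiff(seq_len(ncol(sv$v)), seq_len(rank)), drop = FALSE]
  laws <- list()
  # Prefer the sparse, interpretable gene-copy basis when it spans the space.
  genes <- unique(network$species$gene[network$species$kind == "gene_free"])
  copies <- network$params$gene_copies
  for (gene in genes) {
    v <- stats::setNames(numeric(nrow(S)), rownames(S))
    v[paste0("N0_", gene)] <- 1
    v[paste0("N1_", gene)] <- 1
    if (max(abs(v %*% S)) < tol) {
      laws[[length(laws) + 1]] <- list(
        coefficients = v, total = copies,
        label = paste0("N0_", gene, " + N1_", gene, " = ", copies))
    }
  }
  if (length(laws) != ncol(V)) {
    # fall back to the raw numerical basis for any remaining directions
    known <- do.call(cbind, lapply(laws, `[[`, "coefficients"))
    for (k in seq_len(ncol(V))) {
      v <- V[, k]
      if (!is.null(known)) {
        proj <- known %*% solve(crossprod(known), crossprod(known, v))
        v <- v - as.numeric(proj)
      }
      if (sqrt(sum(v^2)) > tol * 10) {
        v <- v / max(abs(v))
        laws[[length(laws) + 1]] <- list(
          coefficients = stats::setNames(v, rownames(S)), total = NA_real_,
          label = "numerical conservation direction")
      }
    }
  }
  laws
}

#' Reaction propensities / deterministic rates
#'
#' Mass-action rate of every reaction at a given state. Under the
#' stochastic convention a reactant entering with multiplicity m
#' contributes the falling factorial `x (x-1) ... (x-m+1)`; under the
#' deterministic convention it contributes `x^m`.
#'
#' @param network A `grn_network`.
#' @param state Named or positional numeric vector of species counts
#'   (length and order of `network$species`).
#' @param convention `"stochastic"` (falling factorials) or
#'   `"deterministic"` (plain powers).
#' @return Numeric vector of propensities, one per reaction, named.
#' @export
propensities <- function(network, state,
                         convention = c("stochastic", "deterministic")) {
  convention <- match.arg(convention)
  state <- as_state(network, state)
  if (any(state < 0)) stop("negative species count", call. = FALSE)
  a <- propensities_cpp(network$reactants, network$reactions$rate, state,
                        convention == "stochastic")
  stats::setNames(as.numeric(a), network$reactions$name)
}

#' Deterministic right-hand side of the ODE system
#'
#' `d state / dt = S %*% propensities(state)` under the deterministic
#' mass-action convention. Every conservation law `v` satisfies
#' `v . rhs = 0` identically.
#'
#' @inheritParams propensities
#' @return Named numeric vector, one entry per species.
#' @export
ode_rhs <- function(network, state) {
  state <- as_state(network, state)
  a <- propensities(network, state, convention = "deterministic")
  stats::setNames(as.numeric(network$stoich %*% a), network$species$name)
}

# Coerce a state supplied as a named vector, full positional vector or
# one-row data frame into the canonical positional vector.
as_state <- function(network, state) {
  nms <- network$species$name
  if (is.data.frame(state)) {
    state <- unlist(state[1, intersect(names(state), nms)])
  }
  if (!is.null(names(state)) && all(nms %in% names(state))) {
    state <- state[nms]
  } else if (length(state) != length(nms)) {
    stop("state dimension (", length(state),
         ") does not match network species count (", length(nms), ")",
         call. = FALSE)
  }
  as.numeric(state)
}

#' Default initial state
#'
#' All genes free (`N0_X = gene_copies`), optionally with RNA/protein counts
#' supplied; used as a generic starting point for simulations.
#'
#' @param network A `grn_network`.
#' @param ... Named species counts overriding the zero default.
#' @return Named numeric vector satisfying the gene-copy conservation laws.
#' @export
initial_state <- function(network, ...) {
  x <- stats::setNames(numeric(nrow(network$species)), network$species$name)
  x[grepl("^N0_", names(x))] <- network$params$gene_copies
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(x)) stop("unknown species: ", nm, call. = FALSE)
    x[nm] <- dots[[nm]]
  }
  x
}
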