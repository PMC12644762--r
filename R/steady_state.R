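#' Analytic Jacobian of the mass-action ODE system
#'
#' @param network A `grn_network`.
#' @param state Species counts (named or positional).
#' @return Square numeric matrix (species x species) with dimnames.
#' @export
jacobian <- function(network, state) {
  state <- as_state(network, state)
  S <- network$stoich
  RM <- network$reactants
  rates <- network$reactions$rate
  n_sp <- nrow(S); n_rx <- ncol(S)
  # dA[j, i] = d a_j / d x_i  for a_j = k_j prod_i x_i^{m_ij}
  dA <- matrix(0, n_rx, n_sp)
  for (j in seq_len(n_rx)) {
    m <- RM[, j]
    idx <- which(m > 0)
    for (i in idx) {
      others <- prod(state[setdiff(idx, i)]^m[setdiff(idx, i)])
      dA[j, i] <- rates[j] * m[i] * state[i]^(m[i] - 1) * others
    }
  }
  J <- S %*% dA
  dimnames(J) <- list(network$species$name, network$species$name)
  J
}

# species forming the p50/p65/NF-kB feedback core
core_species <- function(network) {
  intersect(c("N0_p50", "N1_p50", "N0_p65", "N1_p65",
              "RNA_p50", "RNA_p65", "P_p50", "P_p65", "NFKB"),
            network$species$name)
}

#' Eigenanalysis and stability classification at a stationary state
#'
#' Computes eigenvalues/eigenvectors of the Jacobian restricted to either
#' the nine-species dynamical core (the p50/p65/NF-kB feedback loop; the
#' EMT target genes are feed-forward) or the full system, and classifies
#' the state. Null eigenvalues arising from the gene-copy conservation laws
#' are identified with threshold `null_tol * max(|lambda|)`.
#'
#' @param network A `grn_network`.
#' @param state Stationary state (species counts).
#' @param subsystem `"core"` (default) or `"full"`.
#' @param null_tol Relative threshold below which an eigenvalue is treated
#'   as a conservation null.
#' @param check_stationary If `TRUE`, error when `ode_rhs` at `state` is not
#'   numerically zero.
#' @param tol Residual tolerance used by the stationarity check (relative to
#'   typical flux magnitudes).
#' @return List with `values` (complex eigenvalues, sorted by decreasing
#'   real part), `vectors`, `n_positive`, `n_negative`, `n_null`, and
#'   `classification` (`"stable"`, `"saddle"` for exactly one unstable
#'   direction, `"unstable"` otherwise).
#' @export
eigen_analysis <- function(network, state, subsystem = c("core", "full"),
                           null_tol = 1e-9, check_stationary = TRUE,
                           tol = 1e-6) {
  subsystem <- match.arg(subsystem)
  state <- as_state(network, state)
  if (check_stationary) {
    r <- ode_rhs(network, state)
    scale <- max(propensities(network, state, "deterministic"), 1)
    if (max(abs(r)) > tol * scale) {
      stop("state is not stationary (max |rhs| = ", signif(max(abs(r)), 3),
           ")", call. = FALSE)
    }
  }
  J <- jacobian(network, state)
  keep <- if (subsystem == "core") core_species(network)
          else network$species$name
  Jsub <- J[keep, keep, drop = FALSE]
  e <- eigen(Jsub)
  ord <- order(Re(e$values), decreasing = TRUE)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  rownames(vectors) <- keep
  mx <- max(abs(values), 1e-300)
  is_null <- abs(values) < null_tol * mx
  n_pos <- sum(Re(values) > 0 & !is_null)
  n_neg <- sum(Re(values) < 0 & !is_null)
  classification <- if (n_pos == 0) "stable"
                    else if (n_pos == 1) "saddle" else "unstable"
  list(values = values, vectors = vectors,
       n_positive = n_pos, n_negative = n_neg, n_null = sum(is_null),
       classification = classification, subsystem = subsystem)
}

#' Enumerate stationary states by multistart damped Newton iteration
#'
#' Solves `ode_rhs = 0` on the conservation-reduced system (the free
#' gene-copy species `N0_X` are eliminated through `N0_X = copies - N1_X`)
#' from `n_starts` log-uniform random starting points, deduplicates the
#' converged roots, and classifies each root through [eigen_analysis()].
#' With the default calibrated parameters the circuit is bistable: two
#' stable states (low-NF-kB, the HER2-positive phenotype, and high-NF-kB,
#' the triple-negative phenotype) separated by a saddle.
#'
#' @param network A `grn_network`.
#' @param n_starts Number of random multistart points.
#' @param seed RNG seed for the start points.
#' @param tol Convergence tolerance on the maximum absolute residual.
#' @param dedup_tol Relative distance below which two roots are merged.
#' @param max_iter Newton iteration budget per start.
#' @param bounds Optional 2-row matrix of lower/upper bounds for the random
#'   starts (columns = reduced species); a broad default covering the
#'   biologically plausible count ranges is used when `NULL`.
#' @return A `stability_report`: list with `states` (tibble of per-state
#'   species counts, residual norms and classifications, ordered by
#'   ascending NF-kB), `eigen` (list of [eigen_analysis()] results),
#'   `network`, and `core_dimension`.
#' @examples
#' \donttest{
#' rep <- find_stationary_states(build_network(grn_params()))
#' rep$states
#' }
#' @export
find_stationary_states <- function(network, n_starts = 200, seed = 1,
                                   tol = 1e-8, dedup_tol = 1e-4,
                                   max_iter = 200, bounds = NULL) {
  sp <- network$species
  copies <- network$params$gene_copies
  elim <- which(sp$kind == "gene_free")
  paired <- match(paste0("N1_", sp$gene[elim]), sp$name)
  free <- setdiff(seq_len(nrow(sp)), elim)

  expand <- function(y) {
    x <- numeric(nrow(sp))
    x[free] <- y
    x[elim] <- copies - y[match(paired, free)]
    x
  }
  resid <- function(y) ode_rhs(network, expand(y))[free]
  red_jac <- function(y) {
    J <- jacobian(network, expand(y))
    Jr <- J[free, free, drop = FALSE]
    # moving N1 moves the eliminated N0 in the opposite direction
    for (k in seq_along(elim)) {
      col_n1 <- match(paired[k], free)
      Jr[, col_n1] <- Jr[, col_n1] - J[free, elim[k]]
    }
    Jr
  }

  if (is.null(bounds)) {
    lo <- hi <- stats::setNames(numeric(length(free)), sp$name[free])
    for (k in seq_along(free)) {
      kind <- sp$kind[free[k]]
      rng <- switch(kind,
                    gene_bound = c(1e-3, copies),
                    rna = c(1, 5e3),
                    protein = c(1e2, 5e6),
                    dimer = c(10, 1e6),
                    c(1e-3, 1e6))
      lo[k] <- rng[1]; hi[k] <- rng[2]
    }
  } else {
    lo <- bounds[1, ]; hi <- bounds[2, ]
  }

  newton <- function(y) {
    for (it in seq_len(max_iter)) {
      r <- resid(y)
      if (max(abs(r)) < tol) return(list(y = y, ok = TRUE))
      Jr <- red_jac(y)
      step <- tryCatch(solve(Jr, -r), error = function(e) NULL)
      if (is.null(step)) return(list(ok = FALSE))
      lam <- 1
      repeat {
        y_new <- y + lam * step
        # keep within the physical region
        y_new <- pmax(y_new, 0)
        n1_idx <- match(paired, free)
        y_new[n1_idx] <- pmin(y_new[n1_idx], copies)
        r_new <- tryCatch(resid(y_new), error = function(e) NULL)
        if (!is.null(r_new) && all(is.finite(r_new)) &&
            max(abs(r_new)) < max(abs(r))) break
        lam <- lam / 2
        if (lam < 1e-10) return(list(ok = FALSE))
      }
      y <- y_new
    }
    list(ok = FALSE)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)

  roots <- list()
  for (s in seq_len(n_starts)) {
    y0 <- exp(stats::runif(length(free), log(lo), log(hi)))
    n1_idx <- match(paired, free)
    y0[n1_idx] <- stats::runif(length(n1_idx), 0, copies)
    sol <- newton(y0)
    if (!sol$ok) next
    x <- expand(sol$y)
    if (any(x < -1e-9)) next
    dup <- FALSE
    for (r0 in roots) {
      rel <- sqrt(sum((x - r0)^2)) / max(sqrt(sum(r0^2)), 1)
      if (rel < dedup_tol) { dup <- TRUE; break }
    }
    if (!dup) roots[[length(roots) + 1]] <- x
  }
  if (length(roots) == 0) {
    stop("no stationary state found; widen bounds or increase n_starts",
         call. = FALSE)
  }

  nf <- vapply(roots, function(x) x[match("NFKB", sp$name)], numeric(1))
  roots <- roots[order(nf)]
  eig <- lapply(roots, function(x)
    eigen_analysis(network, x, subsystem = "core", check_stationary = FALSE))
  cls <- vapply(eig, `[[`, character(1), "classification")
  labels <- if (length(roots) == 3 && identical(cls, c("stable", "saddle",
                                                       "stable"))) {
    c("HER2", "unstable", "TNBC")
  } else {
    paste0("state_", seq_along(roots))
  }
  if (length(roots) > 3) {
    warning(length(roots), " stationary states found; reporting all")
  }
  res <- vapply(roots, function(x) max(abs(ode_rhs(network, x))), numeric(1))
  root_mat <- do.call(rbind, roots)
  colnames(root_mat) <- sp$name
  states <- tibble::as_tibble(root_mat)
  states <- dplyr::bind_cols(
    tibble::tibble(state = labels, classification = cls,
                   residual_norm = res),
    states
  )
  structure(
    list(states = states, eigen = eig, network = network,
         core_dimension = length(core_species(network))),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d stationary state(s), core dimension %d\n",
              nrow(x$states), x$core_dimension))
  print(dplyr::select(x$states, "state", "classification", "residual_norm",
                      dplyr::any_of(c("P_p50", "P_p65", "NFKB",
                                      "RNA_p50", "RNA_p65"))))
  invisible(x)
}

#' Tidy stationary states into a long tibble
#' @param x A `stability_report`.
#' @param ... Unused.
#' @return Tibble with columns `state`, `classification`, `species`, `count`.
#' @export
tidy.stability_report <- function(x, ...) {
  tidyr::pivot_longer(x$states,
                      cols = -c("state", "classification", "residual_norm"),
                      names_to = "species", values_to = "count")
}

#' One-row summary of a stability report
#' @param x A `stability_report`.
#' @param ... Unused.
#' @return Tibble with state counts and the leading unstable eigenvalue.
#' @export
glance.stability_report <- function(x, ...) {
  cls <- x$states$classification
  lead <- NA_real_
  i <- which(cls == "saddle")
  if (length(i) >= 1) lead <- max(Re(x$eigen[[i[1]]]$values))
  tibble::tibble(
    n_states = nrow(x$states),
    n_stable = sum(cls == "stable"),
    n_saddle = sum(cls == "saddle"),
    bistable = sum(cls == "stable") == 2,
    unstable_eigenvalue = lead
  )
}

#' Separatrix anchor point and crossing direction
#'
#' Returns the (p50, p65) protein coordinates of the unstable state together
#' with the unit vector pointing from the HER2 stable state to the TNBC
#' stable state in that plane. The hyperplane through the point with this
#' normal is the fast basin classifier used by the transition module.
#'
#' @param report A `stability_report` with three states.
#' @return List with `point` (length-2 named vector) and `direction`
#'   (unit length-2 vector).
#' @export
separatrix_normal <- function(report) {
  st <- report$states
  if (nrow(st) != 3) {
    stop("separatrix_normal requires a report with exactly 3 states",
         call. = FALSE)
  }
  cls <- st$classification
  uns <- st[cls != "stable", , drop = FALSE]
  stab <- st[cls == "stable", , drop = FALSE]
  if (nrow(uns) != 1 || nrow(stab) != 2) {
    stop("expected two stable states and one saddle", call. = FALSE)
  }
  a <- c(stab$P_p50[1], stab$P_p65[1])
  b <- c(stab$P_p50[2], stab$P_p65[2])
  # direction from the low-NF-kB (HER2) state to the high-NF-kB (TNBC) state
  if (stab$NFKB[1] > stab$NFKB[2]) { tmp <- a; a <- b; b <- tmp }
  d <- b - a
  nd <- sqrt(sum(d^2))
  if (nd < .Machine$double.eps * 100) {
    stop("stable states coincide in the (p50, p65) plane", call. = FALSE)
  }
  list(point = c(p50 = uns$P_p50[1], p65 = uns$P_p65[1]),
       direction = d / nd)
}

#' Integrate the deterministic ODE system
#'
#' Thin wrapper around [deSolve::lsoda()] with the analytic Jacobian.
#'
#' @param network A `grn_network`.
#' @param init Initial species counts.
#' @param times Output times (model minutes).
#' @param ... Passed to [deSolve::lsoda()].
#' @return Tibble with a `time` column and one column per species.
#' @export
integrate_ode <- function(network, init, times, ...) {
  init <- as_state(network, init)
  names(init) <- network$species$name
  # clamp transient negative excursions of the stiff solver at zero
  f <- function(t, y, parms) list(ode_rhs(network, pmax(y, 0)))
  jf <- function(t, y, parms) jacobian(network, pmax(y, 0))
  out <- deSolve::lsoda(init, times, f, parms = NULL, jacfunc = jf,
                        jactype = "fullusr", rtol = 1e-8, atol = 1e-6, ...)
  tibble::as_tibble(as.data.frame(out))
}
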