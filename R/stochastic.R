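#' Exact stochastic simulation (Gillespie direct method)
#'
#' Simulates the network as a continuous-time Markov jump process and
#' records the state at fixed intervals. Statistically exact; used as the
#' reference for the tau-leaping approximation.
#'
#' @param network A `grn_network`.
#' @param init Integer initial counts (named or positional); must satisfy
#'   the gene-copy conservation laws.
#' @param horizon Simulated time span (model minutes).
#' @param seed Integer RNG seed; identical seeds give identical
#'   trajectories.
#' @param record_interval Interval between recorded snapshots.
#' @param max_steps Event budget; the trajectory is truncated (with a
#'   warning and `truncated` attribute) if exhausted.
#' @return A `grn_trajectory`: tibble with `time` and one column per
#'   species, and attributes `method`, `seed`, `truncated`, `nsteps`.
#' @export
ssa <- function(network, init, horizon, seed = 1L, record_interval = 1,
                max_steps = 1e8) {
  init <- check_init(network, init)
  res <- with_seed(seed, ssa_cpp(network$stoich, network$reactants,
                                 network$reactions$rate, init, horizon,
                                 record_interval, max_steps))
  as_trajectory(network, res, method = "ssa", seed = seed)
}

#' Tau-leaping stochastic simulation
#'
#' Approximate stochastic simulation using Poisson leaps whose length is
#' chosen by the species-based bounded-relative-change criterion with
#' control parameter `epsilon` (default 1.0e-3). When the selected leap is
#' shorter than `ssa_factor` expected single-reaction waiting times, the
#' simulator falls back to exact SSA steps; candidate leaps that would
#' drive any count negative are rejected and retried with half the step.
#'
#' @inheritParams ssa
#' @param epsilon Relative propensity-change bound per leap.
#' @param ssa_factor Fall back to exact steps when
#'   `tau < ssa_factor / total_propensity`.
#' @return A `grn_trajectory` tibble (see [ssa()]), `method = "tau_leap"`.
#' @export
tau_leap <- function(network, init, horizon, epsilon = 1e-3, seed = 1L,
                     record_interval = 1, max_steps = 1e8, ssa_factor = 10) {
  stopifnot(epsilon > 0)
  init <- check_init(network, init)
  res <- with_seed(seed, tau_leap_cpp(network$stoich, network$reactants,
                                      network$reactions$rate, init, horizon,
                                      record_interval, epsilon, max_steps,
                                      ssa_factor))
  as_trajectory(network, res, method = "tau_leap", seed = seed)
}

check_init <- function(network, init) {
  x <- as_state(network, init)
  if (any(x < 0)) stop("negative initial count", call. = FALSE)
  xi <- as.integer(round(x))
  if (max(abs(xi - x)) > 1e-6) {
    stop("stochastic simulation requires integer initial counts",
         call. = FALSE)
  }
  copies <- network$params$gene_copies
  sp <- network$species
  for (gene in unique(sp$gene[sp$kind == "gene_free"])) {
    tot <- xi[match(paste0("N0_", gene), sp$name)] +
      xi[match(paste0("N1_", gene), sp$name)]
    if (tot != copies) {
      stop("initial state violates gene-copy conservation for ", gene,
           call. = FALSE)
    }
  }
  xi
}

as_trajectory <- function(network, res, method, seed) {
  out <- tibble::as_tibble(as.data.frame(res$states))
  names(out) <- network$species$name
  out <- dplyr::bind_cols(tibble::tibble(time = res$times), out)
  if (isTRUE(res$truncated)) {
    warning("step budget exhausted; trajectory truncated at t = ",
            signif(max(res$times), 4))
  }
  structure(out,
            class = c("grn_trajectory", class(out)),
            method = method, seed = seed,
            truncated = isTRUE(res$truncated), nsteps = res$nsteps)
}

#' Round a (possibly fractional) state to valid integer counts
#'
#' Rounds all species and restores exact gene-copy conservation by setting
#' `N0_X = copies - N1_X`.
#'
#' @param network A `grn_network`.
#' @param state Species counts.
#' @return Named integer-valued numeric vector.
#' @export
round_state <- function(network, state) {
  x <- round(as_state(network, state))
  sp <- network$species
  copies <- network$params$gene_copies
  for (gene in unique(sp$gene[sp$kind == "gene_free"])) {
    i0 <- match(paste0("N0_", gene), sp$name)
    i1 <- match(paste0("N1_", gene), sp$name)
    x[i1] <- min(max(x[i1], 0), copies)
    x[i0] <- copies - x[i1]
  }
  stats::setNames(x, sp$name)
}

#' Simulate an ensemble of independent single cells
#'
#' Runs `n_cells` tau-leaping simulations from a common initial state; cell
#' `i` uses seed `base_seed + i`, so ensembles are reproducible and cells
#' are independent.
#'
#' @param network A `grn_network`.
#' @param n_cells Number of cells.
#' @param horizon Simulated time per cell (model minutes).
#' @param init Initial state: species counts or the name of a stationary
#'   state (`"HER2"`, `"TNBC"`) looked up in `report`.
#' @param report Optional `stability_report` used to resolve a named `init`.
#' @param record_interval Snapshot interval (model minutes).
#' @param base_seed Base RNG seed.
#' @param epsilon Tau-leaping control parameter.
#' @param max_steps Per-cell step budget.
#' @return A `grn_ensemble`: tibble with `cell` and trajectory columns.
#' @export
run_ensemble <- function(network, n_cells, horizon, init = "HER2",
                         report = NULL, record_interval = 60,
                         base_seed = 1L, epsilon = 1e-3, max_steps = 1e8) {
  stopifnot(n_cells >= 1, horizon > 0)
  if (is.character(init)) {
    if (is.null(report)) {
      stop("`report` is required when `init` names a stationary state",
           call. = FALSE)
    }
    row <- report$states[report$states$state == init, , drop = FALSE]
    if (nrow(row) != 1) stop("no state named ", init, call. = FALSE)
    init <- round_state(network, row[, network$species$name])
  }
  cells <- purrr::map(seq_len(n_cells), function(i) {
    tr <- tau_leap(network, init, horizon, epsilon = epsilon,
                   seed = base_seed + i, record_interval = record_interval,
                   max_steps = max_steps)
    dplyr::bind_cols(tibble::tibble(cell = i), tr)
  })
  out <- dplyr::bind_rows(cells)
  structure(out, class = c("grn_ensemble", class(out)),
            base_seed = base_seed, n_cells = n_cells, horizon = horizon)
}

#' Plot a stochastic trajectory in time or phase space
#'
#' @param object A `grn_trajectory`.
#' @param species Character vector of species to draw (default the p50/p65
#'   proteins and the dimer).
#' @param phase If `TRUE`, draw the (P_p50, P_p65) phase-plane path instead
#'   of time courses.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grn_trajectory <- function(object,
                                    species = c("P_p50", "P_p65", "NFKB"),
                                    phase = FALSE, ...) {
  if (phase) {
    return(
      ggplot2::ggplot(object, ggplot2::aes(x = .data$P_p50,
                                           y = .data$P_p65)) +
        ggplot2::geom_path(alpha = 0.6, colour = "#6a3d9a") +
        ggplot2::labs(x = "p50 protein (molecules)",
                      y = "p65 protein (molecules)")
    )
  }
  long <- tidyr::pivot_longer(
    dplyr::select(object, "time", dplyr::all_of(species)),
    cols = -"time", names_to = "species", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$count,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (model minutes)", y = "molecule count")
}
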