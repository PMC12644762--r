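#' Assign points to attractor basins
#'
#' Labels states as belonging to the HER2 (low NF-kB) or TNBC (high NF-kB)
#' basin. Two methods are provided: `"hyperplane"` classifies by the side
#' of the plane through the unstable state with normal along the
#' HER2-to-TNBC direction in the (p50, p65) protein plane (fast, used for
#' per-sample labelling), and `"relaxation"` integrates the deterministic
#' ODE system to convergence and labels by the nearest stable state (the
#' slower oracle).
#'
#' @param points A data frame with `P_p50` and `P_p65` columns (hyperplane)
#'   or full species counts (relaxation), or a single state vector.
#' @param report A `stability_report` with three states.
#' @param method `"hyperplane"` or `"relaxation"`.
#' @param t_max Integration budget for the relaxation oracle (minutes).
#' @param conv_tol Convergence criterion: relative distance to a stable
#'   state at which relaxation stops.
#' @return Character vector of basin labels (`"HER2"` / `"TNBC"`).
#' @export
assign_basin <- function(points, report,
                         method = c("hyperplane", "relaxation"),
                         t_max = 2e6, conv_tol = 0.02) {
  method <- match.arg(method)
  if (!is.data.frame(points)) {
    points <- tibble::as_tibble(as.list(points))
  }
  if (method == "hyperplane") {
    cls <- basin_classifier(report)
    sp_names <- report$network$species$name
    if (all(sp_names %in% names(points))) {
      h <- as.matrix(points[, sp_names]) %*% cls$w_full - cls$b_full
    } else {
      h <- (points$P_p50 - cls$point[["P_p50"]]) * cls$w2[1] +
        (points$P_p65 - cls$point[["P_p65"]]) * cls$w2[2]
    }
    return(ifelse(as.numeric(h) >= 0, "TNBC", "HER2"))
  }
  net <- report$network
  stable <- report$states[report$states$classification == "stable", ]
  stable <- stable[order(stable$NFKB), ]
  targets <- as.matrix(stable[, net$species$name])
  vapply(seq_len(nrow(points)), function(i) {
    x <- as_state(net, points[i, , drop = FALSE])
    t_now <- 0; dt <- 5000
    repeat {
      sol <- integrate_ode(net, x, times = c(0, dt))
      x <- unlist(sol[nrow(sol), -1])
      t_now <- t_now + dt
      d <- sqrt(rowSums((targets - rep(x, each = 2))^2)) /
        sqrt(rowSums(targets^2))
      if (min(d) < conv_tol) {
        return(c("HER2", "TNBC")[which.min(d)])
      }
      if (t_now >= t_max) {
        stop("relaxation did not converge within t_max", call. = FALSE)
      }
    }
  }, character(1))
}

# Linearised separatrix classifier: the boundary between basins is the
# stable manifold of the saddle; its normal at the saddle is the left
# eigenvector of the Jacobian for the positive eigenvalue. h > 0 is the
# TNBC side. w2/b2 give the projection onto the (p50, p65) protein plane
# for points known only by their protein coordinates.
basin_classifier <- function(report) {
  net <- report$network
  sp <- net$species$name
  st <- report$states
  i_saddle <- which(st$classification != "stable")[1]
  stable <- which(st$classification == "stable")
  if (is.na(i_saddle) || length(stable) != 2) {
    stop("basin classification requires two stable states and a saddle",
         call. = FALSE)
  }
  xs <- unlist(st[i_saddle, sp])
  J <- jacobian(net, xs)
  e <- eigen(t(J))
  l <- Re(e$vectors[, which.max(Re(e$values))])
  names(l) <- sp
  x_tn <- unlist(st[stable[which.max(st$NFKB[stable])], sp])
  if (sum(l * (x_tn - xs)) < 0) l <- -l
  w2 <- c(l[["P_p50"]], l[["P_p65"]])
  w2 <- w2 / sqrt(sum(w2^2))
  list(point = xs, w_full = l, b_full = sum(l * xs), w2 = w2)
}

#' Detect the first confirmed basin transition in a trajectory
#'
#' Finds the first time the basin label flips away from the starting basin
#' and remains flipped for at least `dwell` model minutes (the dwell window
#' suppresses flicker at the separatrix).
#'
#' @param trajectory A `grn_trajectory` (or any tibble with `time`, `P_p50`,
#'   `P_p65`).
#' @param report A `stability_report` with three states.
#' @param dwell Dwell-confirmation window (model minutes; default 10 days).
#' @return One-row tibble: `first_passage_time` (NA when no confirmed
#'   transition), `direction` (`"HER2_to_TNBC"`, `"TNBC_to_HER2"`, or
#'   `"none"`), `dwell_confirmed`.
#' @export
detect_transition <- function(trajectory, report, dwell = 14400) {
  lab <- assign_basin(trajectory, report, method = "hyperplane")
  t <- trajectory$time
  start <- lab[1]
  flipped <- lab != start
  if (!any(flipped)) {
    return(tibble::tibble(first_passage_time = NA_real_,
                          direction = "none", dwell_confirmed = FALSE))
  }
  runs <- rle(flipped)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    t0 <- t[starts[k]]
    t1 <- if (k == length(runs$values)) t[length(t)] else t[ends[k]]
    if (t1 - t0 >= dwell) {
      dir <- if (start == "HER2") "HER2_to_TNBC" else "TNBC_to_HER2"
      return(tibble::tibble(first_passage_time = t0, direction = dir,
                            dwell_confirmed = TRUE))
    }
  }
  tibble::tibble(first_passage_time = NA_real_, direction = "none",
                 dwell_confirmed = FALSE)
}

#' First-passage times for an ensemble of cells (online detection)
#'
#' Runs `n_cells` independent tau-leaping simulations from a stationary
#' state and detects, online, the first time each cell crosses the
#' separatrix hyperplane and stays on the far side for at least `dwell`
#' minutes. This avoids storing year-scale trajectories when only the
#' transition times are of interest.
#'
#' @param network A `grn_network` (possibly perturbed).
#' @param report A `stability_report` for `network` (three states).
#' @param n_cells Number of cells.
#' @param horizon Simulation horizon per cell (model minutes).
#' @param start `"HER2"` or `"TNBC"` starting stationary state.
#' @param base_seed Cell `i` uses seed `base_seed + i`.
#' @param dwell Dwell-confirmation window (minutes).
#' @param check_interval How often the classifier is evaluated (minutes).
#' @param epsilon,max_steps Tau-leaping controls.
#' @return Tibble with one row per cell: `cell`, `first_passage_time`,
#'   `transitioned`, `direction`, `truncated`.
#' @export
first_passage_ensemble <- function(network, report, n_cells = 120,
                                   horizon = MINUTES_PER_YEAR,
                                   start = "HER2", base_seed = 1L,
                                   dwell = 14400, check_interval = 50,
                                   epsilon = 1e-3, max_steps = 1e10) {
  cls <- basin_classifier(report)
  sp_names <- network$species$name
  w <- cls$w_full[sp_names]
  b <- cls$b_full
  row <- report$states[report$states$state == start, , drop = FALSE]
  if (nrow(row) != 1) stop("no stationary state named ", start, call. = FALSE)
  init <- as.integer(round_state(network, row[, sp_names]))
  dir_label <- if (start == "HER2") "HER2_to_TNBC" else "TNBC_to_HER2"
  rows <- purrr::map(seq_len(n_cells), function(i) {
    fp <- with_seed(base_seed + i,
      first_passage_cpp(network$stoich, network$reactants,
                        network$reactions$rate, init, horizon,
                        check_interval, epsilon, max_steps, 10, w, b, dwell))
    tibble::tibble(
      cell = i,
      first_passage_time = if (fp$transitioned) fp$first_passage else NA_real_,
      transitioned = fp$transitioned,
      direction = if (fp$transitioned) dir_label else "none",
      truncated = isTRUE(fp$truncated)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("transition_records", class(out)),
            horizon = horizon, start = start, base_seed = base_seed)
}

#' Transition records for a stored ensemble
#'
#' Applies [detect_transition()] to every cell of a [run_ensemble()] result.
#'
#' @param ensemble A `grn_ensemble`.
#' @param report A `stability_report`.
#' @param dwell Dwell window (minutes).
#' @return Tibble with one row per cell (`cell`, `first_passage_time`,
#'   `direction`, `dwell_confirmed`).
#' @export
ensemble_transitions <- function(ensemble, report, dwell = 14400) {
  out <- dplyr::group_modify(
    dplyr::group_by(ensemble, .data$cell),
    function(df, key) detect_transition(df, report, dwell = dwell)
  )
  horizon <- attr(ensemble, "horizon")
  out <- dplyr::ungroup(out)
  out$transitioned <- !is.na(out$first_passage_time)
  structure(out, class = c("transition_records", class(out)),
            horizon = horizon)
}

#' Cumulative transition-fraction curve
#'
#' @param records A tibble of transition records (`first_passage_time`).
#' @param horizon Ensemble horizon (minutes); defaults to the records'
#'   attribute.
#' @param grid Optional vector of evaluation times; defaults to 200 points
#'   spanning the horizon.
#' @return Tibble with `time` and `fraction_transitioned` (nondecreasing,
#'   in `[0, 1]`).
#' @export
transition_curve <- function(records, horizon = NULL, grid = NULL) {
  if (nrow(records) == 0) stop("empty ensemble", call. = FALSE)
  if (is.null(horizon)) horizon <- attr(records, "horizon")
  if (is.null(grid)) grid <- seq(0, horizon, length.out = 201)
  fpt <- records$first_passage_time
  frac <- vapply(grid, function(g) mean(!is.na(fpt) & fpt <= g), numeric(1))
  structure(tibble::tibble(time = grid, fraction_transitioned = frac),
            class = c("transition_curve", "tbl_df", "tbl", "data.frame"))
}

#' Tissue-composition snapshots
#'
#' Fraction of cells in each basin at the requested times, given per-cell
#' first-passage records from a HER2-initialised ensemble.
#'
#' @param records Transition records.
#' @param times Vector of snapshot times (model minutes).
#' @return Tibble with `time`, `fraction_HER2`, `fraction_TNBC`
#'   (summing to 1).
#' @export
snapshot_composition <- function(records, times) {
  fpt <- records$first_passage_time
  purrr::map_dfr(times, function(tm) {
    f_tn <- mean(!is.na(fpt) & fpt <= tm)
    tibble::tibble(time = tm, fraction_HER2 = 1 - f_tn, fraction_TNBC = f_tn)
  })
}

#' @export
autoplot.transition_curve <- function(object, time_unit = "year", ...) {
  df <- dplyr::mutate(object,
                      t = convert_time(.data$time, "minute", time_unit))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t,
                                   y = .data$fraction_transitioned)) +
    ggplot2::geom_step(colour = "#1f78b4") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = paste0("time (", time_unit, "s)"),
                  y = "fraction transitioned")
}
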