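test_that("zero-rate networks yield constant trajectories to the horizon", {
  net <- toy_network("X", list(list(re = "X", pr = character(0), k = 0)))
  tr <- ssa(net, c(X = 7L), horizon = 10, seed = 1, record_interval = 1)
  expect_equal(tr$X, rep(7, 11))
  expect_equal(max(tr$time), 10)
  tr2 <- tau_leap(net, c(X = 7L), horizon = 10, seed = 1,
                  record_interval = 1)
  expect_equal(tr2$X, rep(7, 11))
})

test_that("identical seeds give bitwise-identical trajectories", {
  net <- birth_death()
  a <- ssa(net, c(X = 0L), horizon = 50, seed = 99)
  b <- ssa(net, c(X = 0L), horizon = 50, seed = 99)
  expect_identical(a$X, b$X)
  c1 <- tau_leap(net, c(X = 0L), horizon = 50, seed = 99)
  c2 <- tau_leap(net, c(X = 0L), horizon = 50, seed = 99)
  expect_identical(c1$X, c2$X)
})

test_that("SSA long-run mean of birth-death matches k/gamma within 3 SE", {
  net <- birth_death(k = 10, gamma = 0.1)  # analytic stationary mean 100
  means <- vapply(1:50, function(s) {
    tr <- ssa(net, c(X = 100L), horizon = 60, seed = 1000 + s,
              record_interval = 2)
    mean(tr$X)
  }, numeric(1))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 100), 3 * se + 1e-9)
})

test_that("tau-leap agrees with SSA on birth-death means within 3 SE", {
  net <- birth_death(k = 10, gamma = 0.1)
  m_ssa <- vapply(1:40, function(s) {
    mean(ssa(net, c(X = 100L), horizon = 60, seed = 2000 + s,
             record_interval = 2)$X)
  }, numeric(1))
  m_tau <- vapply(1:40, function(s) {
    mean(tau_leap(net, c(X = 100L), horizon = 60, seed = 3000 + s,
                  record_interval = 2)$X)
  }, numeric(1))
  se <- sqrt(stats::var(m_ssa) / 40 + stats::var(m_tau) / 40)
  expect_lt(abs(mean(m_ssa) - mean(m_tau)), 3 * se + 1e-9)
})

test_that("SSA and tau-leap agree in mean and variance on a 3-species
           cascade", {
  # X -> X + Y (translation-like), Y -> 0, plus X birth-death
  net <- toy_network(c("X", "Y"), list(
    list(re = character(0), pr = "X", k = 2),
    list(re = "X", pr = character(0), k = 0.1),
    list(re = "X", pr = c("X", "Y"), k = 1),
    list(re = "Y", pr = character(0), k = 0.2)
  ))
  stats_of <- function(fun, seeds) {
    t(vapply(seeds, function(s) {
      tr <- fun(s)
      c(mean(tr$Y), stats::var(tr$Y))
    }, numeric(2)))
  }
  s_ssa <- stats_of(function(s)
    ssa(net, c(X = 20L, Y = 100L), horizon = 80, seed = s,
        record_interval = 1), 1:60)
  s_tau <- stats_of(function(s)
    tau_leap(net, c(X = 20L, Y = 100L), horizon = 80, seed = 500 + s,
             record_interval = 1), 1:60)
  for (col in 1:2) {
    se <- sqrt(stats::var(s_ssa[, col]) / 60 + stats::var(s_tau[, col]) / 60)
    expect_lt(abs(mean(s_ssa[, col]) - mean(s_tau[, col])), 3 * se)
  }
})

test_that("gene-copy conservation is exact along stochastic trajectories", {
  net <- core_network()
  rep <- core_report()
  init <- round_state(net, unlist(rep$states[1, net$species$name]))
  tr <- tau_leap(net, init, horizon = 500, seed = 17, record_interval = 1)
  expect_true(all(tr$N0_p50 + tr$N1_p50 == 2))
  expect_true(all(tr$N0_p65 + tr$N1_p65 == 2))
  expect_true(all(as.matrix(tr[, -1]) >= 0))
  tr2 <- ssa(net, init, horizon = 2, seed = 18, record_interval = 0.1)
  expect_true(all(tr2$N0_p50 + tr2$N1_p50 == 2))
})

test_that("stochastic simulation requires valid integer initial states", {
  net <- default_network()
  x <- initial_state(net)
  x["RNA_p50"] <- 1.4
  expect_error(tau_leap(net, x, horizon = 1), "integer")
  x2 <- initial_state(net)
  x2["N0_p50"] <- 1  # breaks N0 + N1 = 2
  expect_error(tau_leap(net, x2, horizon = 1), "conservation")
})

test_that("ensembles are reproducible, indexed by cell, and independent", {
  net <- core_network()
  rep <- core_report()
  ens <- run_ensemble(net, n_cells = 3, horizon = 30, init = "HER2",
                      report = rep, record_interval = 5, base_seed = 7)
  expect_setequal(unique(ens$cell), 1:3)
  # cell i reproduces a direct tau_leap call with seed base_seed + i
  init <- round_state(net, unlist(rep$states[1, net$species$name]))
  direct <- tau_leap(net, init, horizon = 30, seed = 8, record_interval = 5)
  cell1 <- ens[ens$cell == 1, names(direct)]
  expect_equal(as.matrix(as.data.frame(cell1)),
               as.matrix(as.data.frame(direct)), ignore_attr = TRUE)
  # distinct seeds give distinct trajectories
  m <- tidyr::pivot_wider(ens[, c("cell", "time", "NFKB")],
                          names_from = "cell", values_from = "NFKB")
  expect_false(identical(m$`1`, m$`2`))
  expect_false(identical(m$`2`, m$`3`))
})
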