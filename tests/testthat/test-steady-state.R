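test_that("analytic Jacobian matches central finite differences", {
  net <- default_network()
  set.seed(3)
  for (k in 1:3) {
    x <- initial_state(net)
    x[] <- stats::runif(length(x), 1, 1e4)
    J <- jacobian(net, x)
    h <- 1e-3
    for (i in sample(length(x), 6)) {
      xp <- x; xm <- x
      xp[i] <- x[i] * (1 + h) + h
      xm[i] <- x[i] * (1 - h) - h
      fd <- (ode_rhs(net, xp) - ode_rhs(net, xm)) / (xp[i] - xm[i])
      scale <- pmax(abs(J[, i]), max(abs(J[, i])) * 1e-8, 1e-12)
      expect_lt(max(abs(J[, i] - fd) / scale), 1e-5)
    }
  }
})

test_that("Jacobian of a linear birth-death system is [-gamma]", {
  net <- birth_death(k = 5, gamma = 0.25)
  J <- jacobian(net, c(X = 40))
  expect_equal(unname(J[1, 1]), -0.25)
})

test_that("conservation vectors annihilate the Jacobian rows", {
  net <- default_network()
  set.seed(4)
  x <- initial_state(net)
  x[] <- stats::runif(length(x), 1, 1e5)
  J <- jacobian(net, x)
  for (law in net$conservation) {
    expect_lt(max(abs(law$coefficients %*% J)), 1e-8 * max(abs(J)))
  }
})

test_that("the calibrated circuit has exactly three stationary states", {
  rep <- default_report()
  expect_equal(nrow(rep$states), 3)
  expect_equal(rep$states$classification, c("stable", "saddle", "stable"))
  expect_true(all(rep$states$residual_norm < 1e-6))
  # the saddle lies between the stable states along both protein axes
  st <- rep$states
  expect_true(st$P_p50[1] < st$P_p50[2] && st$P_p50[2] < st$P_p50[3])
  expect_true(st$P_p65[1] < st$P_p65[2] && st$P_p65[2] < st$P_p65[3])
  gl <- glance(rep)
  expect_true(gl$bistable)
  expect_equal(gl$n_states, 3)
})

test_that("stable states reconverge from perturbed starts", {
  net <- default_network()
  rep <- default_report()
  for (i in c(1, 3)) {
    x <- unlist(rep$states[i, net$species$name])
    x_pert <- round_state(net, x * 1.03)
    sol <- integrate_ode(net, x_pert, times = c(0, 5e4))
    xf <- unlist(sol[nrow(sol), -1])
    expect_lt(sqrt(sum((xf - x)^2)) / sqrt(sum(x^2)), 0.01)
  }
})

test_that("zero synthesis rates give a single all-off stationary state", {
  g <- grn_params()$genes
  g$ktx <- 0
  g$kbasal <- 0
  net <- build_network(grn_params(genes = g))
  rep <- find_stationary_states(net, n_starts = 60, seed = 2)
  expect_equal(nrow(rep$states), 1)
  rna_prot <- unlist(rep$states[1, grep("^(RNA_|P_|NFKB)",
                                        names(rep$states))])
  expect_true(all(abs(rna_prot) < 1e-6))
})

test_that("core eigenstructure: 7 negative + 2 null at stable states, one
           positive direction at the saddle", {
  rep <- default_report()
  for (i in c(1, 3)) {
    e <- rep$eigen[[i]]
    expect_equal(e$n_negative, 7)
    expect_equal(e$n_null, 2)
    expect_equal(e$n_positive, 0)
  }
  e_mid <- rep$eigen[[2]]
  expect_equal(e_mid$n_positive, 1)
  expect_equal(e_mid$n_null, 2)
})

test_that("eigen_analysis rejects non-stationary input", {
  net <- default_network()
  x <- initial_state(net, NFKB = 100, RNA_p50 = 50)
  expect_error(eigen_analysis(net, x), "not stationary")
})

test_that("deterministic trajectories converge to a stable state, never to
           the saddle", {
  net <- default_network()
  rep <- default_report()
  stable <- as.matrix(rep$states[c(1, 3), net$species$name])
  saddle <- unlist(rep$states[2, net$species$name])
  starts <- grid_initial_conditions(net, 9, p50_range = c(1e4, 1.7e5),
                                    p65_range = c(5e4, 5.5e5))
  for (i in seq_len(nrow(starts))) {
    sol <- integrate_ode(net, unlist(starts[i, ]), times = c(0, 2e5))
    xf <- unlist(sol[nrow(sol), -1])
    d_stable <- apply(stable, 1, function(s)
      sqrt(sum((xf - s)^2)) / sqrt(sum(s^2)))
    d_saddle <- sqrt(sum((xf - saddle)^2)) / sqrt(sum(saddle^2))
    expect_lt(min(d_stable), 0.02)
    expect_gt(d_saddle, 0.05)
  }
})

test_that("separatrix anchor sits at the saddle with a unit direction", {
  rep <- default_report()
  sep <- separatrix_normal(rep)
  expect_equal(unname(sep$point),
               c(rep$states$P_p50[2], rep$states$P_p65[2]))
  expect_equal(sqrt(sum(sep$direction^2)), 1, tolerance = 1e-12)
  # direction points from HER2 towards TNBC
  expect_true(all(sep$direction > 0))
})
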