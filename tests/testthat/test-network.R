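test_that("the default network has the expected gene-module structure", {
  net <- default_network()
  sp <- net$species
  genes <- c("p50", "p65", "TWIST1", "SLUG", "SIP1")
  for (g in genes) {
    expect_true(all(c(paste0("N0_", g), paste0("N1_", g),
                      paste0("RNA_", g)) %in% sp$name))
  }
  # proteins exist only for the translated subunits plus the dimer
  expect_setequal(sp$name[sp$kind == "protein"], c("P_p50", "P_p65"))
  expect_true("NFKB" %in% sp$name)
  expect_false(any(duplicated(sp$name)))
  # per-gene three-step activation: bind, unbind, transcribe (+ basal/decay)
  expect_true(all(paste0(c("bind_", "unbind_", "tx_", "basal_", "degR_"),
                         rep(genes, each = 5)) %in% net$reactions$name))
  # stoichiometry columns equal products minus reactants by construction;
  # verify one explicitly for the p50 binding reaction
  j <- match("bind_p50", net$reactions$name)
  expected <- stats::setNames(numeric(nrow(sp)), sp$name)
  expected[c("NFKB", "N0_p50")] <- -1
  expected["N1_p50"] <- 1
  expect_equal(net$stoich[, j], expected[sp$name], ignore_attr = TRUE)
})

test_that("gene-copy conservation laws are detected for all five genes", {
  net <- default_network()
  expect_length(net$conservation, 5)
  for (law in net$conservation) {
    expect_equal(law$total, 2)
    expect_lt(max(abs(law$coefficients %*% net$stoich)), 1e-9)
    on_species <- names(law$coefficients)[law$coefficients != 0]
    expect_length(on_species, 2)
    expect_true(all(grepl("^N[01]_", on_species)))
  }
})

test_that("missing rate constants raise configuration errors naming them", {
  g <- grn_params()$genes
  g$koff[g$gene == "SLUG"] <- NA_real_
  expect_error(grn_params(genes = g), "koff.*SLUG")
  g2 <- grn_params()$genes
  g2$ktl[g2$gene == "p65"] <- -1
  expect_error(grn_params(genes = g2), "ktl.*p65")
})

test_that("propensities follow mass action with the stochastic convention", {
  # bimolecular: kon * NFKB * N0 (distinct species, plain product)
  net <- default_network()
  x <- initial_state(net, NFKB = 10)
  x["N0_p50"] <- 2
  a <- propensities(net, x)
  kon <- grn_params()$genes$kon[1]
  expect_equal(unname(a[["bind_p50"]]), kon * 10 * 2)
  # zero-count reactant gives zero propensity
  x["NFKB"] <- 0
  expect_equal(unname(propensities(net, x)[["bind_p50"]]), 0)
  expect_error(propensities(net, x - 5), "negative")
})

test_that("propensities match a hand-expanded oracle on random small states", {
  # toy network exercising orders 0-3, including multiplicity > 1
  net <- toy_network(c("A", "B", "C"), list(
    list(re = character(0), pr = "A", k = 2.5),          # 0 -> A
    list(re = c("A", "B"), pr = "C", k = 0.3),           # A + B -> C
    list(re = c("A", "A"), pr = "B", k = 0.7),           # 2A -> B
    list(re = c("C", "C", "C"), pr = "A", k = 0.1)       # 3C -> A
  ))
  set.seed(42)
  for (i in 1:20) {
    x <- stats::setNames(sample(0:6, 3, replace = TRUE), c("A", "B", "C"))
    a <- propensities(net, x)
    expect_equal(unname(a), c(
      2.5,
      0.3 * x[["A"]] * x[["B"]],
      0.7 * x[["A"]] * (x[["A"]] - 1),
      0.1 * x[["C"]] * (x[["C"]] - 1) * (x[["C"]] - 2)
    ), tolerance = 1e-12)
    d <- propensities(net, x, convention = "deterministic")
    expect_equal(unname(d), c(
      2.5, 0.3 * x[["A"]] * x[["B"]], 0.7 * x[["A"]]^2, 0.1 * x[["C"]]^3
    ), tolerance = 1e-12)
  }
})

test_that("ode_rhs equals stoichiometry times propensities and conserves", {
  net <- default_network()
  # all counts zero: RNA synthesis proceeds at the basal rate
  x0 <- stats::setNames(numeric(nrow(net$species)), net$species$name)
  r <- ode_rhs(net, x0)
  g <- grn_params()$genes
  for (i in seq_len(nrow(g))) {
    expect_equal(unname(r[[paste0("RNA_", g$gene[i])]]), g$kbasal[i])
  }
  # conservation holds identically at random states
  set.seed(1)
  for (k in 1:10) {
    x <- initial_state(net)
    x[] <- stats::runif(length(x), 0, 1e4)
    r <- ode_rhs(net, x)
    for (law in net$conservation) {
      expect_lt(abs(sum(law$coefficients * r)), 1e-6 * max(abs(r)))
    }
  }
})

test_that("degenerate all-zero rates give a valid network with zero flux", {
  g <- grn_params()$genes
  g[, c("kon", "koff", "ktx", "kbasal", "kdR", "ktl", "kdP")] <- 0
  net <- build_network(grn_params(genes = g, ka = 0, kd_dimer = 0))
  x <- initial_state(net, NFKB = 50, RNA_p50 = 10)
  expect_true(all(propensities(net, x) == 0))
  expect_true(all(ode_rhs(net, x) == 0))
})

test_that("parameters tidy into a long table", {
  td <- tidy(grn_params())
  expect_true(all(c("parameter", "gene", "value") %in% names(td)))
  expect_equal(sum(td$parameter == "kon"), 5)
})
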