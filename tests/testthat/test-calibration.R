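test_that("delta-delta-Ct folds follow the textbook identities", {
  expect_equal(ddct_fold(20, 15, 20, 15), 1)    # ddCt = 0
  expect_equal(ddct_fold(19, 15, 20, 15), 2)    # one cycle earlier
  expect_equal(ddct_fold(20 + 3.3219, 15, 20, 15), 0.1, tolerance = 1e-4)
  # triplicates are averaged
  expect_equal(ddct_fold(c(19, 19.5, 18.5), c(15, 15, 15), 20, 15), 2)
  # scale invariance: adding a constant to every Ct leaves the fold alone
  expect_equal(ddct_fold(22, 17, 23, 18), ddct_fold(20, 15, 21, 16))
})

test_that("fold-to-molecule conversion is linear with guarded inputs", {
  expect_equal(fold_to_molecules(1, 250), 250)
  expect_equal(fold_to_molecules(0, 250), 0)
  expect_equal(fold_to_molecules(c(0.5, 2), 100), c(50, 200))
  expect_error(fold_to_molecules(1, 0), "positive")
})

test_that("qpcr_to_targets reconstructs known folds from a Ct table", {
  profiles <- tibble::tibble(gene = c("p50", "p65"), fold = c(4, 0.5))
  tab <- synth_qpcr(profiles, noise_sd = 0, seed = 1)
  targets <- qpcr_to_targets(tab, reference_abundance = c(p50 = 100,
                                                          p65 = 130))
  got <- targets[targets$subtype == "TNBC", ]
  expect_equal(got$fold[got$gene == "p50"], 4, tolerance = 1e-10)
  expect_equal(got$rna_count[got$gene == "p50"], 400, tolerance = 1e-10)
  expect_equal(got$rna_count[got$gene == "p65"], 65, tolerance = 1e-10)
})

test_that("the objective vanishes on self-generated targets and scores a
           doubled target as (ln 2)^2", {
  params <- grn_params()
  targets <- stationary_rna_targets(params)
  expect_lt(steady_state_objective(params, targets), 1e-6)
  targets2 <- targets
  targets2$rna_count[1] <- 2 * targets2$rna_count[1]
  expect_equal(steady_state_objective(params, targets2), log(2)^2,
               tolerance = 1e-3)
})

test_that("non-bistable parameter proposals are penalised", {
  params <- scale_p65_degradation(grn_params(), 1.5)  # monostable regime
  targets <- stationary_rna_targets(grn_params())
  expect_equal(steady_state_objective(params, targets), 1e6)
})

test_that("fit_parameters recovers the minimum of a quadratic objective", {
  obj <- function(p) sum((log(p) - log(c(2, 5)))^2)
  fit <- fit_parameters(obj, start = c(a = 1, b = 1),
                        lower = c(0.1, 0.1), upper = c(50, 50),
                        n_starts = 3, seed = 2)
  expect_equal(unname(fit$par), c(2, 5), tolerance = 1e-4)
  expect_lt(fit$value, 1e-6)
  # deterministic under a fixed seed
  fit2 <- fit_parameters(obj, start = c(a = 1, b = 1),
                         lower = c(0.1, 0.1), upper = c(50, 50),
                         n_starts = 3, seed = 2)
  expect_identical(fit$par, fit2$par)
})

test_that("perturbed rate constants are recovered from synthetic targets", {
  truth <- grn_params()
  targets <- stationary_rna_targets(truth)
  # perturb two rates and refit them against the targets; the bistable
  # regime is only a few percent wide in these directions (larger
  # perturbations abolish one basin and land on the penalty plateau), so
  # the perturbation is +/- 5%
  scale0 <- c(kbasal_p50 = 1.05, ktx_p65 = 0.95)
  apply_rates <- function(params, r) {
    params$genes$kbasal[params$genes$gene == "p50"] <-
      truth$genes$kbasal[truth$genes$gene == "p50"] * r[["kbasal_p50"]]
    params$genes$ktx[params$genes$gene == "p65"] <-
      truth$genes$ktx[truth$genes$gene == "p65"] * r[["ktx_p65"]]
    params
  }
  obj <- function(r) {
    names(r) <- names(scale0)
    steady_state_objective(apply_rates(truth, r), targets, n_starts = 12)
  }
  fit <- fit_parameters(obj, start = scale0,
                        lower = rep(0.85, 2), upper = rep(1.15, 2),
                        n_starts = 1, seed = 4,
                        control = list(maxit = 200, reltol = 1e-10))
  expect_lt(max(abs(fit$par - 1)), 0.05)
  expect_lt(fit$value, 1e-8)
})

test_that("inhibitor recovery returns to the originating state's RNA levels", {
  params <- grn_params()
  rep <- default_report()
  for (subtype in c("HER2", "TNBC")) {
    rec <- simulate_dhmeq_recovery(params, rep, subtype = subtype,
                                   duration = 30,
                                   sample_times = c(0, 120, 480, 1440, 4320))
    st <- rep$states[rep$states$state == subtype, ]
    for (gene in c("p50", "p65")) {
      target <- st[[paste0("RNA_", gene)]]
      curve <- rec[rec$gene == gene, ]
      final <- curve$rna[which.max(curve$time_h)]
      expect_equal(final, target, tolerance = 0.02)
      # recovery approaches the target monotonically after the initial dip
      errs <- abs(curve$rna - target)
      expect_true(all(diff(errs) <= errs[-length(errs)] * 0.05 + 1e-6))
    }
  }
})

test_that("zero-duration zero-binding treatment leaves the state unchanged", {
  params <- grn_params()
  rep <- default_report()
  rec <- simulate_dhmeq_recovery(params, rep, subtype = "HER2",
                                 duration = 0, sample_times = c(0, 60, 120))
  st <- rep$states[rep$states$state == "HER2", ]
  for (gene in c("p50", "p65")) {
    expect_equal(rec$rna[rec$gene == gene],
                 rep(st[[paste0("RNA_", gene)]], 3), tolerance = 1e-4)
  }
})
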