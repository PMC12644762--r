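test_that("basin assignment labels the stationary states correctly", {
  rep <- default_report()
  st <- rep$states
  expect_equal(assign_basin(st[1, ], rep), "HER2")
  expect_equal(assign_basin(st[3, ], rep), "TNBC")
  # reference TNBC protein coordinates
  expect_equal(assign_basin(data.frame(P_p50 = 150491, P_p65 = 535271), rep),
               "TNBC")
  expect_equal(assign_basin(data.frame(P_p50 = 32491, P_p65 = 115566), rep),
               "HER2")
})

test_that("hyperplane classifier agrees with the relaxation oracle", {
  net <- default_network()
  rep <- default_report()
  set.seed(11)
  pts <- grid_initial_conditions(net, 16, p50_range = c(5e3, 1.75e5),
                                 p65_range = c(2e4, 5.9e5))
  hyp <- assign_basin(pts, rep, method = "hyperplane")
  rel <- assign_basin(pts, rep, method = "relaxation")
  expect_gte(mean(hyp == rel), 0.95)
})

test_that("constructed switching trajectories are detected at the right time", {
  net <- default_network()
  rep <- default_report()
  pre <- unlist(rep$states[1, net$species$name])
  post <- unlist(rep$states[3, net$species$name])
  # clean switch at t = 5000
  tr <- synth_transition_trajectory(net, t_switch = 5000, pre_state = pre,
                                    post_state = post, jitter = 0,
                                    horizon = 20000, record_interval = 10,
                                    seed = 1)
  det <- detect_transition(tr, rep, dwell = 1000)
  expect_true(det$dwell_confirmed)
  expect_equal(det$direction, "HER2_to_TNBC")
  expect_equal(det$first_passage_time, 5000, tolerance = 1e-9)
  # noisy switch recovered within the jitter/recording scale
  trn <- synth_transition_trajectory(net, t_switch = 5000, pre_state = pre,
                                     post_state = post, jitter = 1,
                                     horizon = 20000, record_interval = 10,
                                     seed = 2)
  detn <- detect_transition(trn, rep, dwell = 1000)
  expect_true(detn$dwell_confirmed)
  expect_lt(abs(detn$first_passage_time - 5000), 200)
  # no switch: stays at the HER2 state
  tr0 <- synth_transition_trajectory(net, t_switch = 1e9, pre_state = pre,
                                     post_state = post, jitter = 1,
                                     horizon = 20000, record_interval = 10,
                                     seed = 3)
  det0 <- detect_transition(tr0, rep, dwell = 1000)
  expect_equal(det0$direction, "none")
  expect_true(is.na(det0$first_passage_time))
  # reverse direction is reported as such
  trr <- synth_transition_trajectory(net, t_switch = 5000, pre_state = post,
                                     post_state = pre, jitter = 0,
                                     horizon = 20000, record_interval = 10,
                                     seed = 4)
  expect_equal(detect_transition(trr, rep, dwell = 1000)$direction,
               "TNBC_to_HER2")
})

test_that("dwell confirmation suppresses separatrix flicker", {
  net <- default_network()
  rep <- default_report()
  pre <- unlist(rep$states[1, net$species$name])
  post <- unlist(rep$states[3, net$species$name])
  # visit the far basin for 300 minutes, return, then switch for good
  t <- seq(0, 20000, by = 10)
  mk <- function(tm) if ((tm >= 3000 && tm < 3300) || tm >= 9000) post else pre
  states <- t(vapply(t, mk, numeric(length(pre))))
  tr <- tibble::as_tibble(as.data.frame(states))
  names(tr) <- net$species$name
  tr <- dplyr::bind_cols(tibble::tibble(time = t), tr)
  det <- detect_transition(tr, rep, dwell = 1000)
  expect_equal(det$first_passage_time, 9000)
})

test_that("transition curves are monotone step functions in [0, 1]", {
  rec <- tibble::tibble(cell = 1:5,
                        first_passage_time = c(NA, 100, 400, 400, NA),
                        transitioned = c(FALSE, TRUE, TRUE, TRUE, FALSE))
  cv <- transition_curve(rec, horizon = 1000)
  expect_true(all(diff(cv$fraction_transitioned) >= 0))
  expect_true(all(cv$fraction_transitioned >= 0 &
                    cv$fraction_transitioned <= 1))
  expect_equal(max(cv$fraction_transitioned), 0.6)
  # all transitions at t = 1: step to 1 at t = 1
  rec2 <- tibble::tibble(first_passage_time = rep(1, 4))
  cv2 <- transition_curve(rec2, horizon = 10, grid = c(0.5, 1, 2))
  expect_equal(cv2$fraction_transitioned, c(0, 1, 1))
  # no transitions: constant zero
  rec3 <- tibble::tibble(first_passage_time = rep(NA_real_, 4))
  expect_true(all(transition_curve(rec3, horizon = 10)$fraction_transitioned
                  == 0))
  expect_error(transition_curve(rec3[0, ], horizon = 10), "empty")
})

test_that("snapshot compositions are proper fractions that sum to one", {
  rec <- tibble::tibble(first_passage_time = c(NA, 50, 150, 250))
  snap <- snapshot_composition(rec, times = c(0, 100, 300))
  expect_equal(snap$fraction_HER2 + snap$fraction_TNBC, rep(1, 3))
  expect_equal(snap$fraction_HER2[1], 1)
  expect_equal(snap$fraction_TNBC[2], 0.25)
  expect_equal(snap$fraction_TNBC[3], 0.75)
})

test_that("online first-passage detection matches trajectory-based detection", {
  net <- core_network()
  rep <- core_report()
  # a fast-transitioning condition keeps this cheap: 2.5% lower p65
  # degradation shrinks the HER2 basin
  g <- grn_params()
  net_p <- build_network(scale_p65_degradation(g, 0.975))
  rep_p <- find_stationary_states(net_p, n_starts = 60, seed = 3)
  rec <- first_passage_ensemble(net_p, rep_p, n_cells = 4, horizon = 43200,
                                base_seed = 900, dwell = 4320)
  expect_true(all(rec$transitioned))
  expect_true(all(rec$first_passage_time <= 43200))
  expect_equal(rec$direction, rep("HER2_to_TNBC", 4))
})
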