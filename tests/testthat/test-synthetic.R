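test_that("identical seeds give bit-identical sessions, different seeds differ", {
  g1 <- generate_session(quick_config(6, seed = 5, render = TRUE))
  g2 <- generate_session(quick_config(6, seed = 5, render = TRUE))
  expect_identical(g1$session$tracks, g2$session$tracks)
  expect_identical(g1$truth$labels, g2$truth$labels)
  g3 <- generate_session(quick_config(6, seed = 6))
  expect_false(identical(g1$truth$labels, g3$truth$labels))
})

test_that("a degenerate forward chain yields the canonical sequence every trial", {
  P <- matrix(0, 7, 7, dimnames = list(MOTIFS, MOTIFS))
  P["NoReach", "Lift"] <- 1
  for (i in 2:6) P[MOTIFS[i], MOTIFS[i + 1]] <- 1
  P["Drink", "NoReach"] <- 1
  gen <- generate_session(quick_config(12, seed = 2, reach_prob = 1,
                                       transition = P))
  b <- gen$truth$bouts
  for (tr in unique(b$trial)) {
    seqv <- b$motif[b$trial == tr]
    expect_equal(seqv[seq_len(6)], 1:6)
  }
})

test_that("bout list concatenates exactly to the frame label sequence", {
  gen <- generate_session(quick_config(10, seed = 9))
  b <- gen$truth$bouts
  lab <- gen$truth$labels
  for (i in seq_len(nrow(b))) {
    fr <- (b$start_frame[i] + 1L):b$end_frame[i]
    expect_true(all(lab[fr] == b$motif[i]))
  }
  # frames outside bouts are NoReach
  covered <- unlist(lapply(seq_len(nrow(b)), function(i)
    (b$start_frame[i] + 1L):b$end_frame[i]))
  expect_true(all(lab[setdiff(seq_along(lab), covered)] == 0L))
})

test_that("trial structure respects the configured response window and ITI", {
  cfg <- quick_config(25, seed = 4)
  gen <- generate_session(cfg)
  ev <- gen$session$events
  expect_equal(nrow(ev), 25)
  iti <- diff(ev$water_time) - cfg$response_window
  expect_true(all(iti >= cfg$iti_range[1] - 1e-9))
  expect_true(all(iti <= cfg$iti_range[2] + 1e-9))
})

test_that("non-stochastic transition matrices are rejected", {
  P <- default_transition_matrix()
  P["Lift", "Reach"] <- 0.5   # row no longer sums to 1
  expect_error(generator_config(transition = P), "row-stochastic")
})

test_that("empirical bout transitions recover the configured probabilities", {
  P <- default_transition_matrix()
  P["Reach", "Open"] <- 0.8; P["Reach", "NoReach"] <- 0.2
  gen <- generate_session(quick_config(200, seed = 12, reach_prob = 1,
                                       transition = P))
  b <- gen$truth$bouts
  est <- transition_matrix(split(b$motif, b$trial))
  expect_lt(abs(est["Reach", "Open"] - 0.8), 0.05)
})

test_that("null calcium coupling gives flat corrected dF/F", {
  cfg <- quick_config(6, seed = 8,
                      photometry = list(coupling_gain = 0, motion_sd = 0))
  gen <- generate_session(cfg)
  gn <- attach_neural(gen$session, gen$truth, cfg)
  ph <- gn$session$photometry$left
  d <- isosbestic_dff(ph$f470, ph$f410)
  expect_lt(max(abs(d$dff)), 1e-8)
})

test_that("noise-free population traces are kernel-smoothed kinematic copies", {
  W <- diag(4)
  cfg <- quick_config(6, seed = 8,
                      population = list(n_neurons = 4, W = W, noise_sd = 0,
                                        tau_s = 0))
  gen <- generate_session(cfg)
  gn <- attach_neural(gen$session, gen$truth, cfg)
  K <- gn$truth$kin_neural
  for (i in 1:4) {
    expect_gt(cor(gn$session$population$traces[i, ], K[, i]), 0.999)
  }
})

test_that("null excite perturbation leaves kinematics untouched", {
  cfg <- quick_config(10, seed = 3,
                      perturbation = list(p_stim = 0.5, velocity_scale = 1,
                                          schedule = "motif_pulse",
                                          pulse_ms = 300))
  gen <- generate_session(cfg)
  before <- gen$truth$centroid
  gp <- apply_perturbation(gen$session, gen$truth, cfg)
  expect_equal(gp$truth$centroid, before)
  expect_true(any(gp$session$events$condition == "stim"))
})

test_that("4 s inhibition at water onset abolishes within-laser reaching", {
  cfg <- quick_config(20, seed = 13,
                      perturbation = list(p_stim = 0.5, mode = "inhibit_abort",
                                          schedule = "water_onset",
                                          duration_s = 4, rebound_gain = 0,
                                          effect_lag_ms = 0))
  gen <- generate_session(cfg)
  gp <- apply_perturbation(gen$session, gen$truth, cfg)
  ev <- gp$session$events
  stim <- which(ev$condition == "stim")
  expect_gt(length(stim), 0)
  fs <- cfg$fs_behavior
  for (i in stim) {
    fr <- (floor(ev$laser_on[i] * fs) + 2L):(floor(ev$laser_off[i] * fs))
    expect_true(all(gp$session$labels[fr] == 0L))
  }
})

test_that("excite scaling multiplies within-window speed by the configured factor", {
  cfg <- quick_config(40, seed = 21,
                      perturbation = list(p_stim = 0.5, velocity_scale = 1.5,
                                          schedule = "motif_pulse",
                                          pulse_ms = 300, effect_lag_ms = 0))
  gen <- generate_session(cfg)
  base_kin <- kin_from_centroid(gen$truth$centroid, 500)
  gp <- apply_perturbation(gen$session, gen$truth, cfg)
  kin <- kin_from_centroid(gp$truth$centroid, 500)
  ev <- gp$session$events
  ratios <- c()
  for (i in which(ev$condition == "stim")) {
    fr <- (floor(ev$laser_on[i] * 500) + 3L):(floor(ev$laser_off[i] * 500) - 2L)
    ratios <- c(ratios, mean(kin$speed[fr]) / mean(base_kin$speed[fr]))
  }
  expect_equal(mean(ratios), 1.5, tolerance = 0.05)
})
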