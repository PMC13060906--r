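excite_perturbation <- function(scale = 1.5, pulse_ms = 300, p_stim = 0.5) {
  list(p_stim = p_stim, mode = "excite_scale", velocity_scale = scale,
       schedule = "motif_pulse", pulse_ms = pulse_ms, effect_lag_ms = 0)
}

test_that("pseudo-laser offsets are a permutation of stim offsets when counts match", {
  cfg <- quick_config(20, seed = 81,
                      perturbation = excite_perturbation(p_stim = 0.5))
  gen <- generate_session(cfg)
  gp <- apply_perturbation(gen$session, gen$truth, cfg)
  ev <- gp$session$events
  # force equal counts by trimming to the smaller group
  stim <- which(ev$condition == "stim")
  ctrl <- which(ev$condition != "stim")
  k <- min(length(stim), length(ctrl))
  keep <- sort(c(stim[seq_len(k)], ctrl[seq_len(k)]))
  s2 <- gp$session
  s2$events <- ev[keep, ]
  s2$events$trial_index <- seq_len(nrow(s2$events))
  s2 <- assign_pseudo_laser(s2, seed = 4)
  ev2 <- s2$events
  stim_off <- ev2$laser_on[ev2$condition == "stim"] -
    ev2$water_time[ev2$condition == "stim"]
  pseudo_off <- ev2$pseudo_on[ev2$condition != "stim"] -
    ev2$water_time[ev2$condition != "stim"]
  expect_equal(sort(pseudo_off), sort(stim_off), tolerance = 1e-12)
})

test_that("pseudo assignment resamples from the stim set, never alters stim trials, and is seed-stable", {
  cfg <- quick_config(24, seed = 82,
                      perturbation = excite_perturbation(p_stim = 0.25))
  gen <- generate_session(cfg)
  gp <- apply_perturbation(gen$session, gen$truth, cfg)
  before <- gp$session$events
  s1 <- assign_pseudo_laser(gp$session, seed = 9)
  s2 <- assign_pseudo_laser(gp$session, seed = 9)
  expect_identical(s1$events, s2$events)
  stim_rows <- before$condition == "stim"
  expect_identical(s1$events[stim_rows, c("laser_on", "laser_off")],
                   before[stim_rows, c("laser_on", "laser_off")])
  offs <- s1$events$pseudo_on[!stim_rows] - s1$events$water_time[!stim_rows]
  stim_offs <- before$laser_on[stim_rows] - before$water_time[stim_rows]
  expect_true(all(vapply(offs, function(o)
    any(abs(o - stim_offs) < 1e-9), TRUE)))
  expect_error(assign_pseudo_laser(gen$session), "no stim trials")
})

test_that("pseudo offsets match the stim offset distribution across sessions", {
  all_stim <- c(); all_pseudo <- c()
  for (s in 1:25) {
    bd <- quick_bundle(400 + s, n_trials = 16,
                       perturbation = excite_perturbation(scale = 1))
    ev <- bd$events
    all_stim <- c(all_stim, ev$laser_on[ev$condition == "stim"] -
                    ev$water_time[ev$condition == "stim"])
    all_pseudo <- c(all_pseudo, ev$pseudo_on[ev$condition != "stim"] -
                      ev$water_time[ev$condition != "stim"])
  }
  ks <- suppressWarnings(stats::ks.test(all_stim, all_pseudo))
  expect_gt(ks$p.value, 0.05)
})

test_that("identical conditions produce zero paired differences", {
  bd <- quick_bundle(83, n_trials = 16,
                     perturbation = excite_perturbation(scale = 1))
  # duplicate the same trials as stim and control with identical windows
  ev <- bd$events
  stim <- which(ev$condition == "stim")
  bd2 <- bd
  bd2$events <- rbind(ev[stim, ], transform(ev[stim, ],
                                            condition = "control",
                                            pseudo_on = ev$laser_on[stim],
                                            pseudo_off = ev$laser_off[stim]))
  means <- session_condition_means(bd2, "within_laser",
                                   c("reach_probability", "mean_speed"))
  expect_equal(means$control, means$stim, tolerance = 1e-12)
})

test_that("transition difference maps are antisymmetric with zero-sum defined rows", {
  bd <- quick_bundle(84, n_trials = 20,
                     perturbation = excite_perturbation(scale = 1))
  sb <- onset_bout_lists(bd, "stim")
  cb <- onset_bout_lists(bd, "control")
  D <- transition_difference(sb, cb)
  D2 <- transition_difference(cb, sb)
  expect_equal(unclass(D), -unclass(D2), ignore_attr = TRUE)
  def <- attr(D, "rows_defined")
  for (r in which(def)) expect_equal(sum(D[r, ]), 0, tolerance = 1e-9)
  # identical bout sets -> zero matrix
  D0 <- transition_difference(sb, sb)
  expect_true(all(D0 == 0))
})

test_that("inhibition shifts transition mass off the superdiagonal into NoReach", {
  bundles <- lapply(1:4, function(s)
    quick_bundle(500 + s, n_trials = 30,
                 perturbation = list(p_stim = 0.5, mode = "inhibit_abort",
                                     schedule = "motif_pulse", pulse_ms = 100,
                                     rebound_gain = 0, effect_lag_ms = 0)))
  sb <- unlist(lapply(bundles, onset_bout_lists, "stim"), recursive = FALSE)
  cb <- unlist(lapply(bundles, onset_bout_lists, "control"), recursive = FALSE)
  D <- transition_difference(sb, cb)
  super <- mean(c(D["Lift", "Reach"], D["Reach", "Open"], D["Open", "Grasp"],
                  D["Grasp", "Retract"]), na.rm = TRUE)
  into_noreach <- mean(D[c("Lift", "Reach", "Open", "Grasp"), "NoReach"],
                       na.rm = TRUE)
  expect_lt(super, 0)
  expect_gt(into_noreach, 0)
})

test_that("coincident-motif grouping matches the schedule and partitions cleanly", {
  gen <- generate_session(quick_config(12, seed = 85))
  b <- gen$truth$bouts
  mv <- b[b$motif %in% MOVEMENT_MOTIFS, ]
  take <- mv[seq(1, nrow(mv), length.out = 10), ]
  onsets <- (take$start_frame + 1.5) / 500   # mid-bout (bouts are > 15 frames)
  ids <- seq_len(nrow(take))                 # one id per scheduled pulse
  g <- group_by_coincident_motif(ids, onsets, gen$session$labels, 500)
  for (m in names(g)) {
    expect_true(all(take$motif[ids %in% g[[m]]] == motif_code(m)))
  }
  expect_equal(sort(unname(unlist(g))), ids)         # disjoint cover
  expect_equal(sum(attr(g, "excluded")), 0)
  # NoReach-coincident onsets are excluded with counts
  g2 <- group_by_coincident_motif(1L, 0.05, gen$session$labels, 500)
  expect_equal(unname(attr(g2, "excluded")["NoReach"]), 1)
})

test_that("dose-response recovers a monotone effect with trend rho = 1", {
  # fixed-duration (4 s at water onset) stimulation, intensity-dependent
  # velocity scaling -- the varying-intensity protocol
  mk_level <- function(seed, scale, level) {
    bd <- quick_bundle(seed, n_trials = 16,
                       perturbation = list(p_stim = 0.5, mode = "excite_scale",
                                           velocity_scale = scale,
                                           schedule = "water_onset",
                                           duration_s = 4, effect_lag_ms = 0))
    bd$events$laser_intensity_mW[bd$events$condition == "stim"] <- level
    bd
  }
  levels <- c(1.25, 2.5, 5, 10)
  scales <- c(1.0, 1.5, 2.0, 2.5)
  bundles <- list()
  for (s in 1:4) {   # 4 sessions, each with all levels (concatenated events)
    parts <- lapply(seq_along(levels), function(li)
      mk_level(600 + 10 * s + li, scales[li], levels[li]))
    # treat each (session, level) pair via a merged bundle per session:
    # append level bundles' events/bouts with frame offsets is complex, so
    # simulate paired sessions by merging metric tables instead
    bundles[[s]] <- parts
  }
  # flatten: one bundle per (session, level); dose_response needs levels
  # within a session, so merge each session's parts by stacking trials
  merged <- lapply(bundles, function(parts) {
    bd <- parts[[1]]
    for (k in 2:length(parts)) {
      p <- parts[[k]]
      fshift <- length(bd$labels)
      shift <- fshift / 500          # keep frame and time axes consistent
      ev <- p$events
      for (col in c("water_time", "laser_on", "laser_off", "pseudo_on",
                    "pseudo_off")) ev[[col]] <- ev[[col]] + shift
      bd$events <- rbind(bd$events, ev)
      pb <- p$bouts
      pb$start_frame <- pb$start_frame + fshift
      pb$end_frame <- pb$end_frame + fshift
      bd$bouts <- rbind(bd$bouts, pb)
      pk <- p$kin; pk$t <- pk$t + shift
      bd$kin <- rbind(bd$kin, pk)
      bd$labels <- c(bd$labels, p$labels)
    }
    bd$events$trial_index <- seq_len(nrow(bd$events))
    bd
  })
  dr <- dose_response(merged, "laser_intensity_mW", "mean_speed",
                      window_kind = "within_laser")
  expect_equal(dr$mean_speed$trend_rho, 1)
  expect_lt(dr$mean_speed$friedman_p, 0.05)
  per <- colMeans(dr$mean_speed$per_level)
  expect_true(all(diff(per) > 0))
})

test_that("two-level dose-response agrees with the paired Wilcoxon decision", {
  set.seed(7)
  tab <- matrix(c(rnorm(8, 10), rnorm(8, 12)), 8, 2)
  fp <- stats::friedman.test(tab)$p.value
  wp <- stats::wilcox.test(tab[, 1], tab[, 2], paired = TRUE, exact = FALSE,
                           correct = FALSE)$p.value
  expect_equal(fp < 0.05, wp < 0.05)
})

test_that("trial history partitions control trials by predecessor only", {
  bd <- quick_bundle(86, n_trials = 20,
                     perturbation = excite_perturbation(scale = 1))
  ev <- bd$events
  # alternating schedule: every control trial follows a stim trial
  ev$condition <- rep(c("stim", "control"), length.out = nrow(ev))
  ev$laser_on[ev$condition != "stim"] <- NA
  ev$laser_off[ev$condition != "stim"] <- NA
  ev$laser_on[ev$condition == "stim"] <- ev$water_time[ev$condition == "stim"] + 1
  ev$laser_off[ev$condition == "stim"] <- ev$laser_on[ev$condition == "stim"] + 0.3
  bd$events <- ev
  res <- trial_history(list(bd, bd, bd), metrics = "reach_probability")
  expect_s3_class(res, "comparison_result")
  # no-carry-over generator: session means should be close, p not tiny
  bundles <- lapply(1:6, function(s)
    quick_bundle(700 + s, n_trials = 24, perturbation = excite_perturbation()))
  res2 <- trial_history(bundles, metrics = c("reach_probability", "mean_speed"))
  expect_true(all(abs(res2$stim_mean - res2$control_mean) <
                    0.25 * pmax(res2$control_mean, 0.2)))
})

test_that("rebound analysis detects gain > 1 and stays null at gain 1", {
  mk_reb <- function(seed, gain) {
    quick_bundle(seed, n_trials = 24,
                 perturbation = list(p_stim = 0.4, mode = "inhibit_abort",
                                     schedule = "water_onset", duration_s = 2,
                                     rebound_gain = gain, effect_lag_ms = 0))
  }
  hi <- rebound_analysis(lapply(1:8, function(s) mk_reb(800 + s, 1.6)))
  expect_lt(hi$speed_comparison$p, 0.05)
  expect_gt(hi$speed_comparison$rebound_mean, hi$speed_comparison$control_mean)
  expect_true(all(hi$per_duration$reach_probability > 0.5))

  null <- rebound_analysis(lapply(1:8, function(s) mk_reb(900 + s, 1.0)))
  expect_lt(abs(null$speed_comparison$rebound_mean /
                  null$speed_comparison$control_mean - 1), 0.25)
})
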