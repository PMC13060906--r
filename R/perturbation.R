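#' Assign pseudo-laser windows to control trials
#'
#' Control trials receive laser on/off offsets (relative to water delivery)
#' resampled from the session's stimulation trials so that sham windows
#' match the temporal distribution of real stimulation: a seeded
#' permutation when the counts match (the pseudo offsets are then exactly
#' the stim multiset), otherwise sampling with replacement. Stimulation
#' trials are never altered.
#'
#' @param session `reach_session` with at least one stim trial.
#' @param seed RNG seed; identical seeds give identical assignments.
#' @return the session with `pseudo_on` / `pseudo_off` filled on control
#'   trials.
#' @export
assign_pseudo_laser <- function(session, seed = 1L) {
  ev <- session$events
  stim <- which(ev$condition == "stim" & !is.na(ev$laser_on))
  ctrl <- which(ev$condition != "stim")
  if (!length(stim)) stop("no stim trials in session; cannot assign pseudo-laser")
  on_off <- cbind(ev$laser_on[stim] - ev$water_time[stim],
                  ev$laser_off[stim] - ev$water_time[stim])
  set.seed(seed)
  pick <- if (length(ctrl) == length(stim)) {
    sample(length(stim))
  } else {
    sample(length(stim), length(ctrl), replace = TRUE)
  }
  ev$pseudo_on[ctrl] <- ev$water_time[ctrl] + on_off[pick, 1]
  ev$pseudo_off[ctrl] <- ev$water_time[ctrl] + on_off[pick, 2]
  session$events <- ev
  session
}

#' Build an analysis bundle from a session
#'
#' Perturbation analyses operate on a light-weight bundle: events, frame
#' labels, the bout table and a kinematic series. Kinematics come from the
#' rendered tracks, or from supplied ground-truth centroid coordinates.
#'
#' @param session a `reach_session` with labels.
#' @param kin optional precomputed `kinematic_series`.
#' @param centroid optional n x 3 true centroid (used when the session has
#'   no rendered tracks).
#' @return list `(events, labels, bouts, kin, fs)`.
#' @export
session_bundle <- function(session, kin = NULL, centroid = NULL) {
  if (is.null(session$labels)) stop("session has no labels")
  fs <- session$fs_behavior
  if (is.null(kin)) {
    if (!is.null(centroid)) {
      kin <- kin_from_centroid(centroid, fs, session$spout_xyz)
    } else if (length(session$tracks)) {
      kin <- session_kinematics(session)$kin
    } else {
      stop("supply kin or centroid for a session without tracks")
    }
  }
  bouts <- segment_bouts(session$labels, kin, fs)
  list(events = session$events, labels = session$labels, bouts = bouts,
       kin = kin, fs = fs)
}

# minimal kinematic series from a known 3D centroid path
kin_from_centroid <- function(centroid, fs, spout_xyz = NULL) {
  vel <- central_diff(centroid) * fs
  speed <- sqrt(rowSums(vel^2))
  acc <- sqrt(rowSums((central_diff(vel) * fs)^2))
  out <- data.frame(
    t = (seq_len(nrow(centroid)) - 1) / fs,
    x = centroid[, 1], y = centroid[, 2], z = centroid[, 3],
    speed = speed, accel = acc,
    dist_to_spout = if (is.null(spout_xyz)) NA_real_ else
      sqrt(colSums((t(centroid) - spout_xyz)^2)),
    inter_digit_dist = NA_real_, inter_digit_speed = NA_real_)
  class(out) <- c("kinematic_series", "data.frame")
  out
}

# per-trial analysis window bounds (absolute s)
trial_window <- function(ev_row, kind) {
  w <- ev_row$water_time
  t_end <- w + ev_row$response_window
  is_stim <- identical(ev_row$condition, "stim")
  on <- if (is_stim) ev_row$laser_on else ev_row$pseudo_on
  off <- if (is_stim) ev_row$laser_off else ev_row$pseudo_off
  switch(kind,
         whole_trial = c(w, t_end),
         within_laser = c(on, off),
         after_laser = c(off, t_end),
         stop("unknown window kind: ", kind))
}

# per-trial metric values over a clipped bout table
window_trial_values <- function(b, metrics) {
  mv <- b[b$motif %in% MOVEMENT_MOTIFS, , drop = FALSE]
  vals <- c(
    reach_probability = as.numeric(length(lift_reach_starts(b)) > 0),
    success_probability = as.numeric(any(b$motif == 6L & b$duration_s > 0.6)),
    motif_count = nrow(mv),
    total_duration = if (nrow(mv)) sum(mv$duration_s) else 0,
    total_distance = if (nrow(mv) && "distance_mm" %in% names(mv))
      sum(mv$distance_mm) else NA_real_,
    mean_speed = if (nrow(mv) && "mean_speed" %in% names(mv))
      mean(mv$mean_speed) else NA_real_,
    peak_speed = if (nrow(mv) && "peak_speed" %in% names(mv))
      mean(mv$peak_speed) else NA_real_)
  vals[metrics]
}

PERTURBATION_METRICS <- c("reach_probability", "success_probability",
                          "motif_count", "total_duration", "total_distance",
                          "mean_speed", "peak_speed")

# per-session condition means of the windowed metrics
session_condition_means <- function(bundle, window_kind, metrics) {
  ev <- bundle$events
  out <- list()
  for (cond in c("control", "stim")) {
    rows <- which((ev$condition == "stim") == (cond == "stim"))
    vals <- matrix(NA_real_, length(rows), length(metrics),
                   dimnames = list(NULL, metrics))
    for (k in seq_along(rows)) {
      i <- rows[k]
      wnd <- trial_window(ev[i, ], window_kind)
      if (anyNA(wnd)) next
      b <- clip_bouts(bundle$bouts, wnd[1], wnd[2], bundle$fs, bundle$kin)
      vals[k, ] <- window_trial_values(b, metrics)
    }
    out[[cond]] <- colMeans(vals, na.rm = TRUE)
  }
  out
}

#' Stimulation-vs-control comparison over an analysis window
#'
#' Metrics are computed per trial on bouts clipped to the requested window
#' (Within-Laser, After-Laser or Whole-trial; control trials use their
#' pseudo-laser windows), averaged per session and condition, and compared
#' across sessions with a paired two-sided Wilcoxon signed-rank test.
#' Fewer than 5 paired sessions flags the p-values as underpowered.
#'
#' @param bundles list of [session_bundle()]s with pseudo-laser assigned.
#' @param window_kind one of `"within_laser"`, `"after_laser"`,
#'   `"whole_trial"`.
#' @param metrics metric names (subset of
#'   reach_probability, success_probability, motif_count, total_duration,
#'   total_distance, mean_speed, peak_speed).
#' @return `comparison_result` data.frame: per metric the session-mean
#'   control/stim values, Wilcoxon V and p, effect `direction`,
#'   `n_sessions`, `underpowered`.
#' @export
windowed_comparison <- function(bundles, window_kind = "whole_trial",
                                metrics = PERTURBATION_METRICS) {
  per_sess <- lapply(bundles, function(bd) {
    ev <- bd$events
    if (!any(ev$condition == "stim") || all(ev$condition == "stim")) {
      return(NULL)   # session missing a condition: dropped
    }
    session_condition_means(bd, window_kind, metrics)
  })
  per_sess <- Filter(Negate(is.null), per_sess)
  n <- length(per_sess)
  if (!n) stop("no sessions with both conditions")
  ctrl <- do.call(rbind, lapply(per_sess, `[[`, "control"))
  stim <- do.call(rbind, lapply(per_sess, `[[`, "stim"))
  rows <- lapply(metrics, function(m) {
    x <- ctrl[, m]; y <- stim[, m]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) >= 3 && any(x[ok] != y[ok])) {
      wt <- suppressWarnings(stats::wilcox.test(x[ok], y[ok], paired = TRUE,
                                                exact = FALSE))
      v <- unname(wt$statistic); p <- wt$p.value
    } else {
      v <- NA_real_; p <- if (sum(ok) >= 3) 1 else NA_real_
    }
    data.frame(metric = m, control_mean = mean(x, na.rm = TRUE),
               stim_mean = mean(y, na.rm = TRUE), statistic = v, p = p,
               direction = sign(mean(y - x, na.rm = TRUE)),
               n_sessions = sum(ok), underpowered = sum(ok) < 5)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_result", "data.frame")
  out
}

# onset time of the (pseudo-)laser for each trial; NA when absent
trial_onsets <- function(ev) {
  ifelse(ev$condition == "stim", ev$laser_on, ev$pseudo_on)
}

#' Laser-onset-aligned kinematic traces and segment statistics
#'
#' Aligns the kinematic variables (x, y, z, dist_to_spout, speed) to the
#' (pseudo-)laser onset of every included trial. Inclusion filter: a
#' movement motif (Lift through Retract) must be ongoing at onset. For each
#' analysis segment, per-trial mean and max/min are computed, averaged per
#' session and condition, and compared with a paired Wilcoxon signed-rank
#' test across session means.
#'
#' @param bundles list of [session_bundle()]s with pseudo-laser assigned.
#' @param window alignment window around onset, s (default -0.2 to 0.8).
#' @param segments named list of `c(t0, t1)` segments (s, relative to
#'   onset); must lie within `window`.
#' @param fs_out resampled rate for the aligned traces (Hz).
#' @param vars kinematic variables to align.
#' @return list: `time`, per-condition mean +/- SEM traces (`traces`),
#'   `segment_stats` (per var x segment x stat comparison), `n_trials`.
#' @export
laser_aligned_kinematics <- function(bundles, window = c(-0.2, 0.8),
                                     segments = list(seg1 = c(0.1, 0.3),
                                                     seg2 = c(0.3, 0.4)),
                                     fs_out = 100,
                                     vars = c("x", "y", "z", "dist_to_spout",
                                              "speed")) {
  for (sg in segments) {
    if (sg[1] < window[1] || sg[2] > window[2]) {
      stop("segment [", sg[1], ", ", sg[2], "] outside alignment window")
    }
  }
  grid <- seq(window[1], window[2], by = 1 / fs_out)
  sess_stats <- list(); cond_traces <- list(control = list(), stim = list())
  n_trials <- c(control = 0, stim = 0)
  for (bd in bundles) {
    ev <- bd$events
    onsets <- trial_onsets(ev)
    lab_at <- label_at_time(bd$labels, onsets, bd$fs)
    include <- which(is.finite(onsets) & lab_at %in% MOVEMENT_MOTIFS)
    if (!length(include)) next
    per_cond <- list()
    for (cond in c("control", "stim")) {
      rows <- include[(ev$condition[include] == "stim") == (cond == "stim")]
      if (!length(rows)) next
      n_trials[cond] <- n_trials[cond] + length(rows)
      st <- list()
      for (v in vars) {
        M <- t(vapply(onsets[rows], function(o)
          resample_peri(bd$kin$t, bd$kin[[v]], o, grid),
          numeric(length(grid))))
        cond_traces[[cond]][[v]] <- rbind(cond_traces[[cond]][[v]], M)
        for (sn in names(segments)) {
          sel <- grid >= segments[[sn]][1] & grid <= segments[[sn]][2]
          st[[paste(v, sn, "mean", sep = ".")]] <-
            mean(rowMeans(M[, sel, drop = FALSE], na.rm = TRUE), na.rm = TRUE)
          st[[paste(v, sn, "max", sep = ".")]] <-
            mean(apply(M[, sel, drop = FALSE], 1, max, na.rm = TRUE))
          st[[paste(v, sn, "min", sep = ".")]] <-
            mean(apply(M[, sel, drop = FALSE], 1, min, na.rm = TRUE))
        }
      }
      per_cond[[cond]] <- unlist(st)
    }
    if (length(per_cond) == 2) sess_stats[[length(sess_stats) + 1]] <- per_cond
  }
  if (!length(sess_stats)) stop("no sessions with included trials in both conditions")
  ctrl <- do.call(rbind, lapply(sess_stats, `[[`, "control"))
  stim <- do.call(rbind, lapply(sess_stats, `[[`, "stim"))
  seg_rows <- lapply(colnames(ctrl), function(cn) {
    x <- ctrl[, cn]; y <- stim[, cn]
    ok <- is.finite(x) & is.finite(y)
    p <- if (sum(ok) >= 3 && any(x[ok] != y[ok])) {
      suppressWarnings(stats::wilcox.test(x[ok], y[ok], paired = TRUE,
                                          exact = FALSE)$p.value)
    } else NA_real_
    data.frame(stat = cn, control = mean(x, na.rm = TRUE),
               stim = mean(y, na.rm = TRUE), p = p, n_sessions = sum(ok))
  })
  traces <- lapply(cond_traces, function(tl) lapply(tl, function(M) {
    list(mean = colMeans(M, na.rm = TRUE),
         sem = apply(M, 2, stats::sd, na.rm = TRUE) / sqrt(nrow(M)))
  }))
  list(time = grid, traces = traces,
       segment_stats = do.call(rbind, seg_rows), n_trials = n_trials)
}

label_at_time <- function(labels, times, fs) {
  fr <- floor(times * fs) + 1L
  out <- rep(NA_integer_, length(times))
  ok <- is.finite(times) & fr >= 1 & fr <= length(labels)
  out[ok] <- labels[fr[ok]]
  out
}

#' Onset-window transition-matrix difference map
#'
#' Transition matrices are computed from per-trial bout sequences clipped
#' to a window around the (pseudo-)laser onset, and the element-wise
#' difference (stimulation - control) is returned. Rows with no transitions
#' in either condition are flagged.
#'
#' @param stim_bouts,control_bouts lists of per-trial bout tables, already
#'   clipped to the analysis window (see [onset_bout_lists()]).
#' @return 7x7 difference matrix with attributes `stim`, `control`
#'   (the two transition matrices) and `rows_defined`.
#' @export
transition_difference <- function(stim_bouts, control_bouts) {
  Ps <- transition_matrix(stim_bouts)
  Pc <- transition_matrix(control_bouts)
  D <- Ps - Pc
  attr(D, "stim") <- Ps
  attr(D, "control") <- Pc
  attr(D, "rows_defined") <- attr(Ps, "populated") & attr(Pc, "populated")
  D
}

#' Per-trial bout sequences clipped to a peri-onset window
#'
#' @param bundle a [session_bundle()] with pseudo-laser assigned.
#' @param condition `"stim"` or `"control"`.
#' @param window window around onset, s (default -40 ms to 260 ms).
#' @return list of bout tables, one per trial with a defined onset.
#' @export
onset_bout_lists <- function(bundle, condition = "stim",
                             window = c(-0.040, 0.260)) {
  ev <- bundle$events
  onsets <- trial_onsets(ev)
  rows <- which((ev$condition == "stim") == (condition == "stim") &
                  is.finite(onsets))
  lapply(rows, function(i)
    clip_bouts(bundle$bouts, onsets[i] + window[1], onsets[i] + window[2],
               bundle$fs))
}

#' Group trials by the motif ongoing at pulse onset
#'
#' Partition over the movement motifs (Lift, Reach, Open, Grasp, Retract).
#' Trials whose onset frame is NoReach or Drink, or falls outside the
#' labeled range, are excluded with counts reported.
#'
#' @param trials trial indices to group.
#' @param onsets per-trial pulse onset times (s), aligned with `trials`.
#' @param labels session frame labels.
#' @param fs frame rate, Hz.
#' @return list of trial-index vectors named by motif, with attribute
#'   `excluded` (named counts: NoReach, Drink, unlabeled).
#' @export
group_by_coincident_motif <- function(trials, onsets, labels, fs = 500) {
  lab <- label_at_time(labels, onsets, fs)
  groups <- lapply(MOVEMENT_MOTIFS, function(m) trials[which(lab == m)])
  names(groups) <- MOTIFS[MOVEMENT_MOTIFS + 1]
  attr(groups, "excluded") <- c(NoReach = sum(lab == 0L, na.rm = TRUE),
                                Drink = sum(lab == 6L, na.rm = TRUE),
                                unlabeled = sum(is.na(lab)))
  groups
}

#' Dose-response analysis across stimulation levels
#'
#' Per-session, per-level means of the requested metrics on stim trials
#' (window `whole_trial` by default), a Friedman test across levels over
#' sessions with all levels (listwise deletion otherwise), and a Spearman
#' rank correlation of level versus session mean as the monotonic-trend
#' statistic.
#'
#' @param bundles list of [session_bundle()]s whose events carry the level
#'   column.
#' @param level_key one of `"laser_intensity_mW"`, `"laser_frequency_Hz"`,
#'   `"laser_pulse_ms"`.
#' @param metrics metric names (see [windowed_comparison()]).
#' @param window_kind analysis window for the metrics.
#' @return list per metric: `per_level` (session x level means),
#'   `friedman_chisq`, `friedman_p`, `trend_rho`, `trend_p`.
#' @export
dose_response <- function(bundles, level_key = "laser_intensity_mW",
                          metrics = c("reach_probability", "mean_speed"),
                          window_kind = "whole_trial") {
  lv_all <- sort(unique(unlist(lapply(bundles, function(bd)
    bd$events[[level_key]][bd$events$condition == "stim"]))))
  lv_all <- lv_all[is.finite(lv_all)]
  if (length(lv_all) < 2) stop("need >= 2 stimulation levels")
  res <- list()
  for (m in metrics) {
    tab <- matrix(NA_real_, length(bundles), length(lv_all),
                  dimnames = list(NULL, paste0("level_", lv_all)))
    for (si in seq_along(bundles)) {
      bd <- bundles[[si]]
      ev <- bd$events
      for (li in seq_along(lv_all)) {
        rows <- which(ev$condition == "stim" & ev[[level_key]] == lv_all[li])
        if (!length(rows)) next
        vals <- vapply(rows, function(i) {
          wnd <- trial_window(ev[i, ], window_kind)
          b <- clip_bouts(bd$bouts, wnd[1], wnd[2], bd$fs, bd$kin)
          window_trial_values(b, m)
        }, 0)
        tab[si, li] <- mean(vals, na.rm = TRUE)
      }
    }
    complete <- stats::complete.cases(tab)
    fr_chisq <- fr_p <- NA_real_
    if (sum(complete) >= 2) {
      ft <- stats::friedman.test(tab[complete, , drop = FALSE])
      fr_chisq <- unname(ft$statistic); fr_p <- ft$p.value
    }
    # monotonic trend: session means are ranked within each session (so
    # between-session baseline differences cancel) and the pooled ranks are
    # Spearman-correlated with the level
    ranks <- t(apply(tab, 1, rank, na.last = "keep"))
    lv_rep <- rep(lv_all, each = nrow(tab))
    vals <- as.numeric(ranks)
    ok <- is.finite(vals)
    tr <- if (sum(ok) >= 3) suppressWarnings(
      stats::cor.test(lv_rep[ok], vals[ok], method = "spearman")) else NULL
    res[[m]] <- list(per_level = tab, levels = lv_all,
                     friedman_chisq = fr_chisq, friedman_p = fr_p,
                     trend_rho = if (is.null(tr)) NA_real_ else unname(tr$estimate),
                     trend_p = if (is.null(tr)) NA_real_ else tr$p.value,
                     n_complete_sessions = sum(complete))
  }
  res
}

#' Trial-history comparison (Post-Stim vs Post-Ctr control trials)
#'
#' Control trials are partitioned by the condition of the immediately
#' preceding trial (the first trial is excluded); whole-trial metrics are
#' averaged per session and partition and compared with a paired Wilcoxon
#' signed-rank test across sessions.
#'
#' @param bundles list of [session_bundle()]s.
#' @param metrics metric names (see [windowed_comparison()]).
#' @return `comparison_result` data.frame (control_mean = Post-Ctr,
#'   stim_mean = Post-Stim).
#' @export
trial_history <- function(bundles, metrics = PERTURBATION_METRICS) {
  per_sess <- lapply(bundles, function(bd) {
    ev <- bd$events
    n <- nrow(ev)
    if (n < 2) return(NULL)
    is_ctrl <- ev$condition != "stim"
    prev_stim <- c(NA, ev$condition[-n] == "stim")
    post_stim <- which(is_ctrl & prev_stim %in% TRUE)
    post_ctrl <- which(is_ctrl & prev_stim %in% FALSE)
    if (!length(post_stim)) stop("no Post-Stim control trials in session")
    mk <- function(rows) {
      vals <- vapply(rows, function(i) {
        wnd <- trial_window(ev[i, ], "whole_trial")
        b <- clip_bouts(bd$bouts, wnd[1], wnd[2], bd$fs, bd$kin)
        window_trial_values(b, metrics)
      }, numeric(length(metrics)))
      vals <- matrix(vals, nrow = length(metrics))
      rowMeans(vals, na.rm = TRUE)
    }
    list(control = mk(post_ctrl), stim = mk(post_stim))
  })
  per_sess <- Filter(Negate(is.null), per_sess)
  ctrl <- do.call(rbind, lapply(per_sess, `[[`, "control"))
  stim <- do.call(rbind, lapply(per_sess, `[[`, "stim"))
  colnames(ctrl) <- colnames(stim) <- metrics
  rows <- lapply(metrics, function(m) {
    x <- ctrl[, m]; y <- stim[, m]
    ok <- is.finite(x) & is.finite(y)
    p <- if (sum(ok) >= 3 && any(x[ok] != y[ok])) {
      suppressWarnings(stats::wilcox.test(x[ok], y[ok], paired = TRUE,
                                          exact = FALSE)$p.value)
    } else NA_real_
    data.frame(metric = m, control_mean = mean(x, na.rm = TRUE),
               stim_mean = mean(y, na.rm = TRUE), statistic = NA_real_, p = p,
               direction = sign(mean(y - x, na.rm = TRUE)),
               n_sessions = sum(ok), underpowered = sum(ok) < 5)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Rebound reaching after inhibition offset
#'
#' For each inhibition duration, the probability of a reach initiated
#' within `post_window_s` of laser offset, its latency from offset, and the
#' velocity of rebound reaches, compared against the reaches of control
#' trials (aligned to pseudo-laser offsets) across session means.
#'
#' @param bundles list of [session_bundle()]s with pseudo-laser assigned.
#' @param post_window_s window after laser offset searched for a rebound
#'   reach (default 1.0 s).
#' @return list: `per_duration` (per laser duration: n, rebound reach
#'   probability, mean latency), `speed_comparison` (rebound vs control
#'   mean speed; Wilcoxon over session means), `excluded` trials whose
#'   laser offset falls outside the trial.
#' @export
rebound_analysis <- function(bundles, post_window_s = 1.0) {
  dur_rows <- list()
  sess_speed <- list()
  excluded <- 0L
  for (bd in bundles) {
    ev <- bd$events
    reb_speeds <- c(); ctl_speeds <- c()
    for (i in seq_len(nrow(ev))) {
      is_stim <- ev$condition[i] == "stim"
      off <- if (is_stim) ev$laser_off[i] else ev$pseudo_off[i]
      if (!is.finite(off)) next
      t_end <- ev$water_time[i] + ev$response_window[i]
      if (off >= t_end) { excluded <- excluded + 1L; next }
      b <- clip_bouts(bd$bouts, off, min(off + post_window_s, t_end), bd$fs,
                      bd$kin)
      lr <- lift_reach_starts(b)
      got <- length(lr) > 0
      lat <- if (got) b$start_frame[lr[1]] / bd$fs - off else NA_real_
      spd <- if (got) {
        mv <- b[b$motif %in% MOVEMENT_MOTIFS, ]
        mean(mv$mean_speed, na.rm = TRUE)
      } else NA_real_
      if (is_stim) {
        dur_rows[[length(dur_rows) + 1]] <- data.frame(
          duration_s = round(ev$laser_off[i] - ev$laser_on[i], 3),
          reached = got, latency_s = lat)
        if (got) reb_speeds <- c(reb_speeds, spd)
      } else if (got) {
        ctl_speeds <- c(ctl_speeds, spd)
      }
    }
    if (length(reb_speeds) && length(ctl_speeds)) {
      sess_speed[[length(sess_speed) + 1]] <-
        c(rebound = mean(reb_speeds), control = mean(ctl_speeds))
    }
  }
  dr <- do.call(rbind, dur_rows)
  per_dur <- if (!is.null(dr)) do.call(rbind, lapply(split(dr, dr$duration_s),
    function(d) data.frame(duration_s = d$duration_s[1], n = nrow(d),
                           reach_probability = mean(d$reached),
                           mean_latency_s = mean(d$latency_s, na.rm = TRUE))))
  sp <- do.call(rbind, sess_speed)
  cmp <- NULL
  if (!is.null(sp) && nrow(sp) >= 3) {
    wt <- suppressWarnings(stats::wilcox.test(sp[, "rebound"],
                                              sp[, "control"],
                                              paired = TRUE, exact = FALSE))
    cmp <- data.frame(rebound_mean = mean(sp[, "rebound"]),
                      control_mean = mean(sp[, "control"]),
                      p = wt$p.value, n_sessions = nrow(sp))
  }
  list(per_duration = per_dur, speed_comparison = cmp,
       session_speeds = sp, excluded = excluded)
}
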