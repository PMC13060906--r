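# Shared builders for synthetic fixtures. Everything is generated in code;
# sizes here are deliberately small so the default run stays fast.

quick_config <- function(n_trials = 10, seed = 1, render = FALSE, ...) {
  generator_config(n_trials = n_trials, seed = seed, render_tracks = render,
                   ...)
}

# generated session + ground-truth-driven kinematics (no rendering)
quick_bundle <- function(seed, n_trials = 16, perturbation = NULL,
                         pseudo_seed = seed + 7) {
  cfg <- if (is.null(perturbation)) {
    quick_config(n_trials, seed)
  } else {
    quick_config(n_trials, seed, perturbation = perturbation)
  }
  gen <- generate_session(cfg)
  if (!is.null(perturbation)) {
    gen <- apply_perturbation(gen$session, gen$truth, cfg)
    gen$session <- assign_pseudo_laser(gen$session, seed = pseudo_seed)
  }
  bd <- session_bundle(gen$session, centroid = gen$truth$centroid)
  bd$truth <- gen$truth
  bd
}

# classifier training data: rendered session, features over peri-trial
# windows (water - 0.2 s .. water + 2.8 s), per-frame trial groups
classifier_data <- function(n_trials, seed, fs = 500) {
  cfg <- generator_config(n_trials = n_trials, seed = seed)
  gen <- generate_session(cfg)
  sk <- session_kinematics(gen$session)
  fb <- build_features(sk$tracks3d, fs)
  ev <- gen$session$events
  sel <- integer(0); grp <- integer(0)
  for (i in seq_len(nrow(ev))) {
    fr <- (floor((ev$water_time[i] - 0.2) * fs)):
      (floor((ev$water_time[i] + 2.8) * fs) - 1L)
    sel <- c(sel, fr); grp <- c(grp, rep(i, length(fr)))
  }
  list(x = fb$x[sel + 1L, ], y = gen$session$labels[sel + 1L], groups = grp,
       session = gen$session, truth = gen$truth, norm = fb$norm_stats)
}

# small deterministic pose-table CSV in the 3-row-header tracker dialect
write_pose_csv <- function(path, n = 50, bodyparts = REQUIRED_BODYPARTS,
                           conf = NULL) {
  set.seed(99)
  cols <- list(frame = 0:(n - 1))
  bp_row <- c("scorer"); co_row <- c("coords")
  for (bp in bodyparts) {
    cols[[paste0(bp, "_x")]] <- round(stats::runif(n, 0, 100), 3)
    cols[[paste0(bp, "_y")]] <- round(stats::runif(n, 0, 100), 3)
    cols[[paste0(bp, "_l")]] <- if (is.null(conf)) rep(0.99, n) else conf
    bp_row <- c(bp_row, rep(bp, 3))
    co_row <- c(co_row, "x", "y", "likelihood")
  }
  dat <- as.data.frame(cols)
  lines <- c(paste(rep("tracker", ncol(dat)), collapse = ","),
             paste(bp_row, collapse = ","),
             paste(co_row, collapse = ","),
             apply(dat, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
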