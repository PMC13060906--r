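#' Default bout-level motif transition matrix
#'
#' Row-stochastic 7x7 matrix over (NoReach, Lift, Reach, Open, Grasp,
#' Retract, Drink). Mass sits on the forward superdiagonal
#' (Lift -> Reach -> Open -> Grasp -> Retract -> Drink) with a small abort
#' probability into NoReach, NoReach re-initiates with a Lift, and Drink
#' terminates the sequence.
#'
#' @return 7x7 numeric matrix with motif dimnames.
#' @export
default_transition_matrix <- function() {
  P <- matrix(0, 7, 7, dimnames = list(MOTIFS, MOTIFS))
  P["NoReach", "Lift"] <- 1
  P["Lift", "Reach"] <- 0.95;   P["Lift", "NoReach"] <- 0.05
  P["Reach", "Open"] <- 0.95;   P["Reach", "NoReach"] <- 0.05
  P["Open", "Grasp"] <- 0.95;   P["Open", "NoReach"] <- 0.05
  P["Grasp", "Retract"] <- 0.95; P["Grasp", "NoReach"] <- 0.05
  P["Retract", "Drink"] <- 0.95; P["Retract", "NoReach"] <- 0.05
  P["Drink", "NoReach"] <- 1
  P
}

default_templates <- function() {
  list(
    Lift    = list(direction = c(0, 0, 1),  peak_speed = 150, curvature = 0),
    Reach   = list(direction = "spout",     peak_speed = 350, curvature = 0.1),
    Open    = list(direction = "spout",     peak_speed = 80,  curvature = 0),
    Grasp   = list(direction = c(0, 0, -1), peak_speed = 100, curvature = 0),
    Retract = list(direction = "mouth",     peak_speed = 300, curvature = 0.1),
    Drink   = list(direction = c(1, 0, 0),  peak_speed = 40,  curvature = 0)
  )
}

default_durations <- function() {
  data.frame(
    motif   = MOTIFS,
    mean_ms = c(300, 80, 120, 90, 110, 150, 800),
    sd_ms   = c(120, 15, 20, 15, 20, 25, 150),
    min_ms  = c(60, 30, 40, 30, 40, 50, 300),
    row.names = MOTIFS
  )
}

#' Synthetic-session generator configuration
#'
#' Defines the simulated study conditions: trial structure (7 s response
#' window, inter-trial intervals uniform on 2--15 s, 500 Hz cameras), the
#' bout-level semi-Markov motif chain, per-motif kinematic velocity
#' templates, keypoint pixel noise, photometry artifact model, a linearly
#' encoding neural population, and optogenetic perturbation effects.
#'
#' @param n_trials number of trials.
#' @param reach_prob probability a trial contains a reach sequence.
#' @param transition 7x7 row-stochastic bout-level transition matrix.
#' @param durations per-motif duration distribution (`mean_ms`, `sd_ms`,
#'   `min_ms`; truncated Gaussian).
#' @param templates per-motif velocity-profile parameters (`direction`,
#'   `peak_speed` in mm/s, `curvature`).
#' @param speed_scale_sd s.d. of the log-normal per-trial vigor factor
#'   multiplying template speeds (trial-to-trial movement vigor
#'   variability; default 0.2).
#' @param keypoint_noise_px s.d. of pixel noise added to rendered views.
#' @param spout_xyz 3D water-spout coordinate, mm.
#' @param response_window s, default 7.
#' @param iti_range inter-trial interval range, s, default `c(2, 15)`.
#' @param fs_behavior camera frame rate, Hz.
#' @param rt_shape,rt_scale,rt_min Gamma reaction-time parameters (s).
#' @param photometry list: `bleach_tau_s`, `motion_sd`, `coupling_gain`,
#'   `fs_photo`, `tau_s` (calcium kernel decay).
#' @param population list: `n_neurons`, `W` (neurons x 4 weights onto
#'   x, y, z, velocity; NULL for random), `noise_sd`, `fs_neural`, `tau_s`,
#'   and optional motif modulation (`mod_motif`, `n_excited`, `n_inhibited`,
#'   `effect_z`).
#' @param perturbation list: `p_stim`, `mode` (`inhibit_abort` or
#'   `excite_scale`), `velocity_scale`, `effect_lag_ms`, `rebound_gain`,
#'   `schedule` (`water_onset` or `motif_pulse`), `duration_s`, `pulse_ms`,
#'   `pulse_latency_s` (pulse onset latency after water delivery, with
#'   uniform `pulse_latency_jitter_s`), `rebound_latency_ms`,
#'   `intensity_mW`, `frequency_Hz`.
#' @param render_tracks if FALSE, camera views are not rendered (ground
#'   truth and labels only; much faster for label-level simulations).
#' @param seed integer RNG seed; identical seeds give bit-identical sessions.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_trials = 60, reach_prob = 0.9,
                             transition = default_transition_matrix(),
                             durations = default_durations(),
                             templates = default_templates(),
                             speed_scale_sd = 0.2,
                             keypoint_noise_px = 1,
                             spout_xyz = c(25, 0, 18),
                             response_window = 7, iti_range = c(2, 15),
                             fs_behavior = 500,
                             rt_shape = 4, rt_scale = 0.175, rt_min = 0.1,
                             photometry = list(),
                             population = list(),
                             perturbation = list(),
                             render_tracks = TRUE, seed = 1L) {
  photometry <- utils::modifyList(list(
    bleach_tau_s = 600, motion_sd = 0.02, coupling_gain = 0.5,
    fs_photo = 100, tau_s = 0.5), photometry)
  population <- utils::modifyList(list(
    n_neurons = 100, W = NULL, noise_sd = 1, fs_neural = 20, tau_s = 0.5,
    mod_motif = NULL, n_excited = 0, n_inhibited = 0, effect_z = 1), population)
  perturbation <- utils::modifyList(list(
    p_stim = 0.33, mode = "excite_scale", velocity_scale = 1.5,
    effect_lag_ms = 10, rebound_gain = 1, schedule = "water_onset",
    duration_s = 4, pulse_ms = 300, pulse_latency_s = 1.0,
    pulse_latency_jitter_s = 0.25,
    rebound_latency_ms = 150, intensity_mW = 5, frequency_Hz = NA_real_),
    perturbation)
  cfg <- structure(list(
    n_trials = as.integer(n_trials), reach_prob = reach_prob,
    transition = transition, durations = durations, templates = templates,
    speed_scale_sd = speed_scale_sd,
    keypoint_noise_px = keypoint_noise_px, spout_xyz = spout_xyz,
    response_window = response_window, iti_range = iti_range,
    fs_behavior = fs_behavior,
    rt_shape = rt_shape, rt_scale = rt_scale, rt_min = rt_min,
    photometry = photometry, population = population,
    perturbation = perturbation,
    render_tracks = isTRUE(render_tracks), seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  P <- cfg$transition
  if (!is.matrix(P) || !all(dim(P) == c(7, 7))) {
    stop("transition must be a 7x7 matrix")
  }
  rs <- rowSums(P)
  active <- rs > 0
  if (any(abs(rs[active] - 1) > 1e-8) || any(P < 0)) {
    stop("transition matrix must be row-stochastic (rows sum to 1)")
  }
  if (any(cfg$durations$mean_ms <= 0) || any(cfg$durations$min_ms <= 0)) {
    stop("motif durations must be > 0")
  }
  for (fs in c(cfg$fs_behavior, cfg$photometry$fs_photo,
               cfg$population$fs_neural)) {
    if (!is.finite(fs) || fs <= 0) stop("sampling rates must be > 0")
  }
  if (cfg$perturbation$velocity_scale <= 0) stop("velocity_scale must be > 0")
  if (cfg$reach_prob < 0 || cfg$reach_prob > 1) stop("reach_prob must be in [0,1]")
  invisible(cfg)
}

# fixed body-plan offsets (mm) around the forelimb centroid; the three digit
# offsets plus the paw offset sum to zero so the rendered part mean tracks
# the designed path up to the Open/Grasp digit spread.
PART_OFFSETS <- list(
  digit2 = c(1.2, 1.0, 0.4),
  digit3 = c(1.6, 0.0, 0.5),
  digit4 = c(1.2, -1.0, 0.4),
  paw    = c(-4.0, 0.0, -1.3)
)
MOUTH_POS <- c(-5, 0, 8)
NOSE_POS <- c(-2, 0, 14)
REST_POS <- c(0, 0, 0)

# temporally correlated noise: AR(1) with correlation time `sd_frames`
# samples, scaled to stationary s.d. `sd`; O(n)
smooth_noise <- function(n, sd, sd_frames) {
  if (sd <= 0) return(numeric(n))
  a <- exp(-1 / sd_frames)
  burn <- min(5L * ceiling(sd_frames), 1000L)
  x <- stats::rnorm(n + burn)
  y <- stats::filter(x, a, method = "recursive")
  as.numeric(y)[(burn + 1):(burn + n)] * sd * sqrt(1 - a^2)
}

# draw one bout plan (motifs + durations in s) for a reaching trial
plan_bouts <- function(cfg, t_avail) {
  P <- cfg$transition
  dur <- cfg$durations
  draw_dur <- function(m) {
    max(dur[m, "min_ms"], stats::rnorm(1, dur[m, "mean_ms"], dur[m, "sd_ms"])) / 1000
  }
  motifs <- character(0); durs <- numeric(0)
  state <- "Lift"; t_used <- 0
  repeat {
    d <- draw_dur(state)
    motifs <- c(motifs, state); durs <- c(durs, d)
    t_used <- t_used + d
    if (t_used >= t_avail) break
    nxt <- sample(MOTIFS, 1, prob = P[state, ])
    if (state == "Drink" || (state == "NoReach" && nxt == "NoReach")) break
    if (nxt == "NoReach" && state != "Drink") {
      # abort into background; chain may re-initiate from the NoReach row
      state <- "NoReach"
      d <- draw_dur("NoReach")
      motifs <- c(motifs, "NoReach"); durs <- c(durs, d)
      t_used <- t_used + d
      if (t_used >= t_avail - 0.5) break
      nxt2 <- sample(MOTIFS, 1, prob = P["NoReach", ])
      if (nxt2 == "NoReach") break
      state <- nxt2
    } else if (nxt == "NoReach" && state == "Drink") {
      break
    } else {
      state <- nxt
    }
  }
  # clip to the available time
  keep <- cumsum(durs) - durs < t_avail
  motifs <- motifs[keep]; durs <- durs[keep]
  n <- length(durs)
  if (n > 0 && sum(durs) > t_avail) {
    durs[n] <- t_avail - (sum(durs) - durs[n])
  }
  list(motifs = motifs, durs = durs)
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

template_direction <- function(tpl, pos, cfg) {
  d <- tpl$direction
  if (identical(d, "spout")) return(unit3(cfg$spout_xyz - pos))
  if (identical(d, "mouth")) return(unit3(MOUTH_POS - pos))
  unit3(as.numeric(d))
}

# positions for one motif bout starting at p0: half-sine speed profile along
# the template direction plus an optional perpendicular curvature arc;
# `vigor` scales the template speed (per-trial vigor factor)
bout_path <- function(motif, nfr, p0, cfg, vigor = 1) {
  if (nfr <= 0) return(matrix(numeric(0), 0, 3))
  fs <- cfg$fs_behavior
  if (motif == "NoReach") {
    # exponential relaxation toward the rest posture
    tau <- 0.3
    w <- exp(-(seq_len(nfr) / fs) / tau)
    sweep(outer(w, p0 - REST_POS), 2, REST_POS, "+")
  } else {
    tpl <- cfg$templates[[motif]]
    dir <- template_direction(tpl, p0, cfg)
    u <- seq_len(nfr) / nfr
    speed <- vigor * tpl$peak_speed * sin(pi * (u - 0.5 / nfr))
    disp <- cumsum(speed) / fs
    path <- outer(disp, dir)
    if (tpl$curvature > 0) {
      perp <- unit3(pracma_cross(dir, c(0, 0, 1)))
      if (all(abs(perp) < 1e-9)) perp <- c(1, 0, 0)
      path <- path + outer(tpl$curvature * disp[nfr] * sin(pi * u), perp)
    }
    sweep(path, 2, p0, "+")
  }
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a complete synthetic session with ground truth
#'
#' Simulates the water-reaching paradigm: each trial opens a response window
#' at water delivery; with probability `reach_prob` a bout sequence is drawn
#' from the bout-level semi-Markov chain starting at Lift, the 3D forelimb
#' centroid follows the per-motif velocity templates, and two orthogonal
#' camera views (side -> x,z; front -> y,z) are rendered with pixel noise.
#' Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return list with elements `session` (a `reach_session`) and `truth`
#'   (frame labels, true bout table, true part/centroid paths, per-trial
#'   reaction times).
#' @export
generate_session <- function(cfg) {
  validate_generator_config(cfg)
  set.seed(cfg$seed)
  fs <- cfg$fs_behavior
  nt <- cfg$n_trials

  iti <- stats::runif(nt, cfg$iti_range[1], cfg$iti_range[2])
  water <- numeric(nt)
  water[1] <- 1 + iti[1]
  if (nt > 1) {
    for (i in 2:nt) water[i] <- water[i - 1] + cfg$response_window + iti[i]
  }
  t_end <- water[nt] + cfg$response_window + 1
  nfr <- as.integer(round(t_end * fs))

  labels <- integer(nfr)           # 0 = NoReach
  reaches <- stats::runif(nt) < cfg$reach_prob
  rts <- ifelse(reaches,
                cfg$rt_min + stats::rgamma(nt, cfg$rt_shape, scale = cfg$rt_scale),
                NA_real_)

  bout_trial <- integer(0); bout_motif <- integer(0)
  bout_start <- integer(0); bout_end <- integer(0)
  plans <- vector("list", nt)
  for (i in seq_len(nt)) {
    if (!reaches[i]) next
    t0 <- water[i] + rts[i]
    t_avail <- water[i] + cfg$response_window - t0
    if (t_avail < 0.3) { reaches[i] <- FALSE; rts[i] <- NA_real_; next }
    plan <- plan_bouts(cfg, t_avail)
    plans[[i]] <- plan
    f0 <- as.integer(floor(t0 * fs))
    nfrs <- pmax(1L, as.integer(round(plan$durs * fs)))
    ends <- f0 + cumsum(nfrs)
    starts <- c(f0, ends[-length(ends)])
    keep <- starts < nfr
    starts <- starts[keep]; ends <- pmin(ends[keep], nfr)
    codes <- motif_code(plan$motifs)[keep]
    for (k in seq_along(starts)) {
      labels[(starts[k] + 1L):ends[k]] <- codes[k]
    }
    bout_trial <- c(bout_trial, rep(i, length(starts)))
    bout_motif <- c(bout_motif, codes)
    bout_start <- c(bout_start, starts)
    bout_end <- c(bout_end, ends)
  }
  bouts <- data.frame(trial = bout_trial, motif = bout_motif,
                      start_frame = bout_start, end_frame = bout_end)

  # per-trial vigor: log-normal speed factor shared by all motifs in a trial
  vigor <- exp(stats::rnorm(nt, 0, cfg$speed_scale_sd))

  # centroid path: walk the label segments, keeping positional continuity
  centroid <- matrix(0, nfr, 3)
  r <- rle(labels)
  seg_end <- cumsum(r$lengths); seg_start <- seg_end - r$lengths + 1L
  pos <- REST_POS
  spread <- rep(1, nfr)
  for (k in seq_along(r$values)) {
    rows <- seg_start[k]:seg_end[k]
    m <- MOTIFS[r$values[k] + 1L]
    tr_k <- findInterval((seg_start[k] - 1) / fs, water)
    vg <- if (tr_k >= 1 && tr_k <= nt) vigor[tr_k] else 1
    pth <- bout_path(m, length(rows), pos, cfg, vg)
    centroid[rows, ] <- pth
    pos <- pth[nrow(pth), ]
    if (m == "Open")  spread[rows] <- seq(1, 1.8, length.out = length(rows))
    if (m == "Grasp") spread[rows] <- seq(1.8, 1, length.out = length(rows))
  }
  # slow postural jitter so background frames have realistic nonzero speed
  for (j in 1:3) centroid[, j] <- centroid[, j] + smooth_noise(nfr, 0.25, 25)

  parts <- list()
  for (bp in names(PART_OFFSETS)) {
    off <- PART_OFFSETS[[bp]]
    sp <- if (bp == "paw") rep(1, nfr) else spread
    parts[[bp]] <- centroid + outer(sp, off)
  }
  parts$mouth <- matrix(rep(MOUTH_POS, each = nfr), nfr, 3) +
    cbind(smooth_noise(nfr, 0.1, 25), smooth_noise(nfr, 0.1, 25),
          smooth_noise(nfr, 0.1, 25))
  parts$nose <- matrix(rep(NOSE_POS, each = nfr), nfr, 3) +
    cbind(smooth_noise(nfr, 0.1, 25), smooth_noise(nfr, 0.1, 25),
          smooth_noise(nfr, 0.1, 25))

  events <- as_events(data.frame(water_time = water,
                                 response_window = cfg$response_window,
                                 condition = "control"))
  truth <- list(labels = labels, bouts = bouts,
                centroid = rowMeans3(parts[c("digit2", "digit3", "digit4", "paw")]),
                parts = parts, rts = rts, reached = reaches, vigor = vigor,
                config = cfg)
  session <- new_session(
    session_id = sprintf("synthetic-seed%d", cfg$seed), fs_behavior = fs,
    tracks = if (cfg$render_tracks) render_views(parts, cfg) else list(),
    events = events, labels = labels, spout_xyz = cfg$spout_xyz,
    meta = list(synthetic = TRUE, seed = cfg$seed)
  )
  list(session = session, truth = truth)
}

rowMeans3 <- function(mats) {
  out <- mats[[1]]
  for (k in 2:length(mats)) out <- out + mats[[k]]
  out / length(mats)
}

# orthogonal-projection camera model: side view images (x, z), front view
# images (y, z); mm and px coincide for synthetic data
render_views <- function(parts, cfg) {
  nfr <- nrow(parts[[1]])
  noise <- cfg$keypoint_noise_px
  mk <- function(u, v) data.frame(
    x = u + if (noise > 0) stats::rnorm(nfr, 0, noise) else 0,
    y = v + if (noise > 0) stats::rnorm(nfr, 0, noise) else 0,
    confidence = stats::runif(nfr, 0.9, 1))
  side <- lapply(parts, function(p) mk(p[, 1], p[, 3]))
  front <- lapply(parts, function(p) mk(p[, 2], p[, 3]))
  list(side = side, front = front)
}

# exponential-decay kernel convolution (causal), kernel normalized to sum 1
exp_smooth <- function(x, tau_s, fs) {
  if (tau_s <= 0) return(x)
  n <- length(x)
  L <- min(n, ceiling(5 * tau_s * fs))
  k <- exp(-(0:(L - 1)) / (tau_s * fs))
  k <- k / sum(k)
  y <- stats::filter(c(rep(x[1], L), x), k, sides = 1)
  as.numeric(y)[(L + 1):(L + n)]
}

# average x (sampled at fs_in) within the sample bins of a slower grid
bin_average <- function(x, fs_in, t_out) {
  idx <- pmin(length(x), pmax(1L, floor(t_out * fs_in) + 1L))
  nb <- length(t_out)
  bin <- findInterval(seq_along(x) / fs_in, c(t_out, Inf))
  keep <- bin >= 1 & bin <= nb
  out <- rep(NA_real_, nb)
  agg <- tapply(x[keep], bin[keep], mean)
  out[as.integer(names(agg))] <- agg
  # bins with no sample (fs_out > fs_in) fall back to nearest sample
  miss <- is.na(out)
  out[miss] <- x[idx[miss]]
  out
}

#' Attach synthetic neural recordings to a generated session
#'
#' Photometry: the 470 nm channel is
#' `bleach(t) * (1 + coupling_gain * c(t)) + motion(t)` where `c(t)` is the
#' forelimb speed convolved with an exponential calcium kernel, and the
#' 410 nm isosbestic channel shares the bleaching and motion components but
#' carries no calcium signal. Population: neuron i follows
#' `[W (x, y, z, v)](i)` passed through the calcium kernel plus Gaussian
#' noise, sampled at `fs_neural`, optionally with additive per-motif
#' excitation/inhibition effects, then z-scored.
#'
#' @param session a generated `reach_session`.
#' @param truth matching ground truth from [generate_session()].
#' @param cfg the [generator_config()] used.
#' @return list `(session, truth)` with photometry + population attached and
#'   `truth$calcium`, `truth$W`, `truth$mod_sign` recorded.
#' @export
attach_neural <- function(session, truth, cfg) {
  fs <- cfg$fs_behavior
  cen <- truth$centroid
  nfr <- nrow(cen)
  speed <- centroid_speed(cen, fs)

  # --- photometry ---
  ph <- cfg$photometry
  t_ph <- seq(0, (nfr - 1) / fs, by = 1 / ph$fs_photo)
  sp_ph <- bin_average(speed, fs, t_ph)
  c_t <- exp_smooth(sp_ph, ph$tau_s, ph$fs_photo)
  if (max(c_t) > 0) c_t <- c_t / max(c_t)
  bleach <- 1.5 * exp(-t_ph / ph$bleach_tau_s) + 0.5
  motion <- smooth_noise(length(t_ph), ph$motion_sd, 0.2 * ph$fs_photo)
  f470 <- bleach * (1 + ph$coupling_gain * c_t) + motion
  f410 <- 0.7 * bleach + motion
  session$photometry <- list(left = list(t = t_ph, f470 = f470, f410 = f410,
                                         fs = ph$fs_photo, hemisphere = "ipsi"))
  truth$calcium <- c_t

  # --- single-cell population ---
  po <- cfg$population
  n <- po$n_neurons
  if (n > 0) {
    t_ne <- seq(0, (nfr - 1) / fs, by = 1 / po$fs_neural)
    K <- cbind(x = bin_average(cen[, 1], fs, t_ne),
               y = bin_average(cen[, 2], fs, t_ne),
               z = bin_average(cen[, 3], fs, t_ne),
               velocity = bin_average(speed, fs, t_ne))
    W <- po$W
    if (is.null(W)) W <- matrix(stats::rnorm(n * 4, 0, 0.2), n, 4)
    if (nrow(W) != n || ncol(W) != 4) {
      stop("population weight matrix W must be n_neurons x 4")
    }
    Kz <- scale(K)
    drive <- Kz %*% t(W)          # time x neurons
    if (po$tau_s > 0) drive <- apply(drive, 2, exp_smooth, po$tau_s, po$fs_neural)
    drive <- matrix(drive, ncol = n)
    mod_sign <- integer(n)
    if (!is.null(po$mod_motif) && (po$n_excited + po$n_inhibited) > 0) {
      mod_sign[seq_len(po$n_excited)] <- 1L
      if (po$n_inhibited > 0) {
        mod_sign[po$n_excited + seq_len(po$n_inhibited)] <- -1L
      }
      lab_ne <- truth$labels[pmin(nfr, floor(t_ne * fs) + 1L)]
      on <- as.numeric(lab_ne %in% motif_code(po$mod_motif))
      drive <- drive + outer(on, mod_sign * po$effect_z)
    }
    traces <- t(drive) + matrix(stats::rnorm(n * length(t_ne), 0, po$noise_sd),
                                n, length(t_ne))
    traces <- t(scale(t(traces)))
    session$population <- list(traces = traces, t = t_ne, fs = po$fs_neural,
                               neuron_ids = seq_len(n))
    truth$W <- W
    truth$mod_sign <- mod_sign
    truth$kin_neural <- K
  }
  list(session = session, truth = truth)
}

centroid_speed <- function(cen, fs) {
  d <- central_diff(cen) * fs
  sqrt(rowSums(d^2))
}

#' Apply an optogenetic perturbation to a generated session
#'
#' Stimulation trials receive laser windows per the experimental design
#' (`water_onset`: a fixed-duration laser starting at water delivery;
#' `motif_pulse`: a brief pulse timed to coincide with an ongoing movement
#' motif). `excite_scale` multiplies within-window velocity by
#' `velocity_scale` (the accumulated spatial protrusion decays back over
#' ~150 ms after offset); `inhibit_abort` freezes progression into NoReach
#' after `effect_lag_ms` and, upon laser offset, triggers a rebound reach
#' whose velocity is scaled by `rebound_gain`. Ground truth records what was
#' applied; camera views of modified frames are re-rendered.
#'
#' @param session,truth output of [generate_session()].
#' @param cfg the [generator_config()] (its `perturbation` entry is used).
#' @return list `(session, truth)` with laser events, modified kinematics
#'   and `truth$perturbation` (per-trial record).
#' @export
apply_perturbation <- function(session, truth, cfg) {
  pc <- cfg$perturbation
  fs <- cfg$fs_behavior
  ev <- session$events
  nt <- nrow(ev)
  nfr <- length(truth$labels)
  stim <- stats::runif(nt) < pc$p_stim

  rec <- data.frame(trial = seq_len(nt), stim = stim,
                    on = NA_real_, off = NA_real_, mode = pc$mode)
  for (i in which(stim)) {
    if (pc$schedule == "water_onset") {
      on <- ev$water_time[i]
      off <- on + pc$duration_s
    } else {
      # brief pulses at a calibrated latency relative to water delivery
      # (plus jitter), timed to intercept the reaching sequence; whether a
      # movement motif actually coincides is decided post-hoc, exactly as
      # in the analysis
      on <- ev$water_time[i] + pc$pulse_latency_s +
        stats::runif(1, -pc$pulse_latency_jitter_s, pc$pulse_latency_jitter_s)
      off <- on + pc$pulse_ms / 1000
    }
    trial_end <- ev$water_time[i] + ev$response_window[i]
    if (on >= trial_end) {
      stop("pulse scheduled outside the trial response window (trial ", i, ")")
    }
    if (off > trial_end) off <- trial_end
    ev$laser_on[i] <- on; ev$laser_off[i] <- off
    ev$laser_intensity_mW[i] <- pc$intensity_mW
    ev$laser_frequency_Hz[i] <- pc$frequency_Hz
    ev$laser_pulse_ms[i] <- (off - on) * 1000
    ev$condition[i] <- "stim"
    rec$on[i] <- on; rec$off[i] <- off

    f_on <- as.integer(floor((on + pc$effect_lag_ms / 1000) * fs)) + 1L
    f_off <- min(nfr, as.integer(floor(off * fs)) + 1L)
    f_trial_end <- min(nfr, as.integer(floor(trial_end * fs)))
    if (f_on >= f_off || f_on >= nfr) next

    if (pc$mode == "excite_scale" && pc$velocity_scale != 1) {
      truth <- scale_window_velocity(truth, f_on, f_off, pc$velocity_scale, fs)
    } else if (pc$mode == "inhibit_abort") {
      truth <- abort_and_rebound(truth, i, f_on, f_off, f_trial_end, cfg)
    }
  }
  truth$centroid <- rowMeans3(truth$parts[c("digit2", "digit3", "digit4", "paw")])
  truth$perturbation <- rec
  session$events <- ev
  session$labels <- truth$labels
  if (cfg$render_tracks) session$tracks <- render_views(truth$parts, cfg)
  list(session = session, truth = truth)
}

# multiply frame-to-frame displacement inside [f_on, f_off) by `scale`; the
# accumulated extra displacement decays back to the unperturbed path after
# the window (elastic return over ~150 ms)
scale_window_velocity <- function(truth, f_on, f_off, scale, fs) {
  decay_fr <- round(0.15 * fs)
  for (bp in c("digit2", "digit3", "digit4", "paw")) {
    P <- truth$parts[[bp]]
    win <- f_on:(f_off - 1L)
    inc <- diff(P[c(win[1] - 1L, win), , drop = FALSE])
    extra <- matrix(apply(inc * (scale - 1), 2, cumsum), ncol = 3)
    P[win, ] <- P[win, ] + extra
    tail_n <- min(decay_fr, nrow(P) - f_off + 1L)
    if (tail_n > 0) {
      w <- exp(-(seq_len(tail_n)) / (0.05 * fs))
      rows <- (f_off - 1L) + seq_len(tail_n)
      P[rows, ] <- P[rows, ] + outer(w, extra[nrow(extra), ])
    }
    truth$parts[[bp]] <- P
  }
  truth
}

# inhibit_abort: velocity collapses at laser onset, labels fall into NoReach
# until offset; a rebound reach (velocity scaled by rebound_gain) is
# re-initiated shortly after offset if the response window allows
abort_and_rebound <- function(truth, trial, f_on, f_off, f_trial_end, cfg) {
  fs <- cfg$fs_behavior
  pc <- cfg$perturbation
  nfr <- length(truth$labels)
  # freeze: relax all forelimb parts toward their position at onset
  hold <- f_on:f_trial_end
  for (bp in c("digit2", "digit3", "digit4", "paw")) {
    P <- truth$parts[[bp]]
    p0 <- P[f_on, ]
    relax <- bout_path("NoReach", length(hold), p0 - REST_POS + REST_POS, cfg)
    P[hold, ] <- relax
    truth$parts[[bp]] <- P
  }
  truth$labels[hold] <- 0L
  truth$bouts <- drop_bout_frames(truth$bouts, trial, f_on, nfr)

  f_reb <- f_off + as.integer(round(pc$rebound_latency_ms / 1000 * fs))
  t_avail <- (f_trial_end - f_reb) / fs
  if (pc$rebound_gain > 0 && t_avail > 0.5) {
    plan <- plan_bouts(cfg, t_avail)
    nfrs <- pmax(1L, as.integer(round(plan$durs * fs)))
    ends <- pmin(f_reb + cumsum(nfrs), f_trial_end)
    starts <- c(f_reb, ends[-length(ends)])
    keep <- starts < ends
    starts <- starts[keep]; ends <- ends[keep]
    codes <- motif_code(plan$motifs)[keep]
    # rebuild centroid-level path with velocity scaled by rebound_gain
    pos <- truth$parts$digit3[f_reb, ] - PART_OFFSETS$digit3
    cfg_reb <- cfg
    for (m in names(cfg_reb$templates)) {
      cfg_reb$templates[[m]]$peak_speed <-
        cfg_reb$templates[[m]]$peak_speed * pc$rebound_gain
    }
    for (k in seq_along(starts)) {
      rows <- (starts[k] + 1L):ends[k]
      m <- MOTIFS[codes[k] + 1L]
      pth <- bout_path(m, length(rows), pos, cfg_reb)
      pos <- pth[nrow(pth), ]
      for (bp in c("digit2", "digit3", "digit4", "paw")) {
        truth$parts[[bp]][rows, ] <- sweep(pth, 2, PART_OFFSETS[[bp]], "+")
      }
      truth$labels[rows] <- codes[k]
    }
    truth$bouts <- rbind(truth$bouts,
                         data.frame(trial = trial, motif = codes,
                                    start_frame = starts, end_frame = ends))
    truth$bouts <- truth$bouts[order(truth$bouts$start_frame), ]
  }
  truth
}

drop_bout_frames <- function(bouts, trial, f_on, nfr) {
  sel <- bouts$trial == trial & bouts$end_frame > f_on
  bouts$end_frame[sel] <- pmin(bouts$end_frame[sel], f_on)
  bouts[bouts$end_frame > bouts$start_frame, ]
}
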