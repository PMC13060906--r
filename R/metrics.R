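#' Segment a label sequence into motif bouts
#'
#' A bout is a maximal constant-label run (NoReach runs included). When a
#' kinematic series is supplied, per-bout kinematics are computed over
#' `[start, end)`: distance travelled is the cumulative 3D path length (sum
#' of the `end - start - 1` inter-frame steps), mean/peak speed summarize
#' the per-frame speed within the bout.
#'
#' @param labels integer motif codes per frame.
#' @param kin optional `kinematic_series` aligned with `labels`.
#' @param fs frame rate, Hz.
#' @return data.frame of bouts: `motif`, `start_frame`, `end_frame`
#'   (half-open, 0-based), `duration_s`, and (if `kin` given) `distance_mm`,
#'   `mean_speed`, `peak_speed`.
#' @export
segment_bouts <- function(labels, kin = NULL, fs = 500) {
  if (!length(labels)) {
    return(data.frame(motif = integer(), start_frame = integer(),
                      end_frame = integer(), duration_s = numeric(),
                      distance_mm = numeric(), mean_speed = numeric(),
                      peak_speed = numeric()))
  }
  if (!is.null(kin) && nrow(kin) != length(labels)) {
    stop("labels and kinematics must be aligned")
  }
  r <- rle(as.integer(labels))
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  out <- data.frame(motif = r$values, start_frame = start, end_frame = end,
                    duration_s = r$lengths / fs)
  if (!is.null(kin)) {
    pos <- cbind(kin$x, kin$y, kin$z)
    step <- sqrt(rowSums(diff(pos)^2))       # step i = frame i -> i+1
    cstep <- c(0, cumsum(step))
    # path length within [start, end): steps start..end-2 (0-based frames)
    out$distance_mm <- cstep[pmax(out$end_frame, 1)] - cstep[out$start_frame + 1L]
    out$distance_mm[out$end_frame - out$start_frame < 2] <- 0
    out$mean_speed <- vapply(seq_len(nrow(out)), function(i)
      mean(kin$speed[(out$start_frame[i] + 1L):out$end_frame[i]]), 0)
    out$peak_speed <- vapply(seq_len(nrow(out)), function(i)
      max(kin$speed[(out$start_frame[i] + 1L):out$end_frame[i]]), 0)
  }
  out
}

# clip a bout table to a time window [t0, t1] (s), keeping overlap;
# kinematic fields are recomputed proportionally is not attempted -- bouts
# are clipped frame-wise and durations follow the clipped frames
clip_bouts <- function(bouts, t0, t1, fs, kin = NULL) {
  if (!nrow(bouts)) return(bouts)
  f0 <- as.integer(floor(t0 * fs)); f1 <- as.integer(ceiling(t1 * fs))
  sel <- bouts$end_frame > f0 & bouts$start_frame < f1
  b <- bouts[sel, , drop = FALSE]
  if (!nrow(b)) return(b)
  b$start_frame <- pmax(b$start_frame, f0)
  b$end_frame <- pmin(b$end_frame, f1)
  b$duration_s <- (b$end_frame - b$start_frame) / fs
  if (!is.null(kin) && "distance_mm" %in% names(bouts)) {
    pos <- cbind(kin$x, kin$y, kin$z)
    step <- sqrt(rowSums(diff(pos)^2))
    cstep <- c(0, cumsum(step))
    b$distance_mm <- cstep[pmax(b$end_frame, 1)] - cstep[b$start_frame + 1L]
    b$distance_mm[b$end_frame - b$start_frame < 2] <- 0
    b$mean_speed <- vapply(seq_len(nrow(b)), function(i)
      mean(kin$speed[(b$start_frame[i] + 1L):b$end_frame[i]]), 0)
    b$peak_speed <- vapply(seq_len(nrow(b)), function(i)
      max(kin$speed[(b$start_frame[i] + 1L):b$end_frame[i]]), 0)
  }
  rownames(b) <- NULL
  b
}

# indices (into bouts rows) of the first Lift of each Lift-Reach sequence:
# a Lift bout whose next non-NoReach bout is a Reach, with at most max_gap
# seconds of intervening NoReach
lift_reach_starts <- function(bouts, max_gap = 0.040) {
  n <- nrow(bouts)
  hits <- integer(0)
  for (i in seq_len(n)) {
    if (bouts$motif[i] != 1L) next           # Lift
    j <- i + 1L
    gap <- 0
    while (j <= n && bouts$motif[j] == 0L) {
      gap <- gap + bouts$duration_s[j]
      j <- j + 1L
    }
    if (j <= n && bouts$motif[j] == 2L && gap <= max_gap) hits <- c(hits, i)
  }
  hits
}

#' Per-trial motif and latency metrics
#'
#' Bouts are restricted (clipped) to the trial's response window
#' `[water_time, water_time + response_window]`. For each motif the
#' occurrence count, latency of the first occurrence from water delivery,
#' mean single-occurrence duration, total duration, distance travelled and
#' mean/peak velocity are computed, occurrence values averaged within the
#' trial. A trial `reached` when it contains a Lift-Reach sequence (a Lift
#' whose next non-NoReach bout is a Reach within `max_gap`); it `succeeded`
#' when a Drink bout strictly longer than 0.6 s starts at or after the
#' first Lift-Reach sequence. `latency_to_success` runs from the first Lift
#' of the first Lift-Reach sequence to that Drink's start.
#'
#' @param bouts session bout table from [segment_bouts()].
#' @param event one-row trial event (or list with `water_time`,
#'   `response_window`).
#' @param fs frame rate, Hz.
#' @param kin optional `kinematic_series` for clipped-bout kinematics.
#' @param max_gap maximum NoReach gap inside a Lift-Reach sequence, s.
#' @param success_min_s success threshold on Drink duration (strict `>`).
#' @return one-row data.frame of trial metrics (per-motif columns prefixed
#'   by the motif name) plus `reached`, `succeeded`, `latency_to_reach_s`,
#'   `latency_to_success_s`.
#' @export
trial_metrics <- function(bouts, event, fs = 500, kin = NULL,
                          max_gap = 0.040, success_min_s = 0.6) {
  w <- event$water_time
  b <- clip_bouts(bouts, w, w + event$response_window, fs, kin)
  out <- list()
  has_kin <- "distance_mm" %in% names(b)
  for (m in 1:6) {
    sel <- b$motif == m
    nm <- MOTIFS[m + 1]
    out[[paste0(nm, "_count")]] <- sum(sel)
    out[[paste0(nm, "_latency_s")]] <-
      if (any(sel)) min(b$start_frame[sel]) / fs - w else NA_real_
    out[[paste0(nm, "_duration_s")]] <-
      if (any(sel)) mean(b$duration_s[sel]) else NA_real_
    out[[paste0(nm, "_total_duration_s")]] <-
      if (any(sel)) sum(b$duration_s[sel]) else NA_real_
    if (has_kin) {
      out[[paste0(nm, "_distance_mm")]] <-
        if (any(sel)) mean(b$distance_mm[sel]) else NA_real_
      out[[paste0(nm, "_mean_speed")]] <-
        if (any(sel)) mean(b$mean_speed[sel]) else NA_real_
      out[[paste0(nm, "_peak_speed")]] <-
        if (any(sel)) mean(b$peak_speed[sel]) else NA_real_
    }
  }
  lr <- lift_reach_starts(b, max_gap)
  reached <- length(lr) > 0
  out$reached <- reached
  out$latency_to_reach_s <-
    if (reached) b$start_frame[lr[1]] / fs - w else NA_real_
  succeeded <- FALSE; lat_succ <- NA_real_
  if (reached) {
    first_lift_frame <- b$start_frame[lr[1]]
    drink <- which(b$motif == 6L & b$duration_s > success_min_s &
                     b$start_frame >= first_lift_frame)
    if (length(drink)) {
      succeeded <- TRUE
      lat_succ <- (b$start_frame[drink[1]] - first_lift_frame) / fs
    }
  }
  out$succeeded <- succeeded
  out$latency_to_success_s <- lat_succ
  as.data.frame(out)
}

#' Per-trial metrics for every trial of a session
#'
#' @param bouts session bout table.
#' @param events trial event table.
#' @param ... passed to [trial_metrics()].
#' @return data.frame with one row per trial (`trial_index` first).
#' @export
session_trial_metrics <- function(bouts, events, ...) {
  rows <- lapply(seq_len(nrow(events)), function(i)
    trial_metrics(bouts, events[i, ], ...))
  cbind(trial_index = events$trial_index, do.call(rbind, rows))
}

#' Session-level summary
#'
#' Reach probability is the fraction of trials containing at least one
#' Lift-Reach sequence; success probability is the fraction of *reaching*
#' trials that contain a qualifying Drink; per-motif probability is the
#' fraction of trials with at least one occurrence of the motif. Metric
#' columns are averaged over the trials where they are defined.
#'
#' @param trials output of [session_trial_metrics()].
#' @return list with `reach_probability`, `success_probability` (NA and
#'   flagged when no trial reached), `motif_probability` (named length-6),
#'   `means` (per-metric trial means), `n_trials`.
#' @export
session_summary <- function(trials) {
  if (!nrow(trials)) stop("need at least one trial")
  reach_p <- mean(trials$reached)
  n_reached <- sum(trials$reached)
  success_p <- if (n_reached > 0) sum(trials$succeeded) / n_reached else NA_real_
  motif_p <- vapply(1:6, function(m)
    mean(trials[[paste0(MOTIFS[m + 1], "_count")]] > 0), 0)
  names(motif_p) <- MOTIFS[2:7]
  num <- vapply(trials, is.numeric, TRUE)
  means <- colMeans(trials[, num, drop = FALSE], na.rm = TRUE)
  list(reach_probability = reach_p, success_probability = success_p,
       no_reaching_trials = n_reached == 0,
       motif_probability = motif_p, means = means, n_trials = nrow(trials))
}

#' Bout-level motif transition matrix
#'
#' Counts consecutive bout pairs within each trial's bout sequence (trial
#' boundaries are never counted) and normalizes rows. Rows with no outgoing
#' transitions are left all-zero and flagged in the `populated` attribute.
#'
#' @param bout_lists list of per-trial bout tables (or integer motif
#'   sequences) in temporal order.
#' @return 7x7 row-stochastic matrix (rows = from, cols = to) with
#'   attribute `populated` (logical per row) and `counts`.
#' @export
transition_matrix <- function(bout_lists) {
  counts <- matrix(0, 7, 7, dimnames = list(MOTIFS, MOTIFS))
  for (b in bout_lists) {
    seqv <- if (is.data.frame(b)) b$motif else as.integer(b)
    if (any(seqv < 0 | seqv > 6)) stop("unknown state label in bout sequence")
    if (length(seqv) < 2) next
    from <- seqv[-length(seqv)] + 1L
    to <- seqv[-1] + 1L
    for (k in seq_along(from)) counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
  }
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, 1)
  attr(P, "populated") <- rs > 0
  attr(P, "counts") <- counts
  P
}

#' Event-aligned motif ethogram
#'
#' For each time bin relative to the alignment event and each motif, the
#' fraction of trials whose label at that bin equals the motif. Bins inside
#' every trial's labeled range sum to 1 over the 7 states.
#'
#' @param labels integer frame labels for the session.
#' @param align_times per-trial alignment times (s); trials with `NA`
#'   alignment are dropped (count reported in the `dropped` attribute).
#' @param window `c(t_min, t_max)` around the alignment time, s.
#' @param fs frame rate, Hz.
#' @param bin_ms bin width, ms.
#' @return 7 x n_bins probability matrix with attributes `time` (bin
#'   centers), `raster` (trials x bins label matrix), `dropped`.
#' @export
ethogram <- function(labels, align_times, window = c(-1, 2), fs = 500,
                     bin_ms = 10) {
  keep <- is.finite(align_times)
  dropped <- sum(!keep)
  align_times <- align_times[keep]
  if (!length(align_times)) stop("no trials with an alignment time")
  centers <- seq(window[1] + bin_ms / 2000, window[2] - bin_ms / 2000 + 1e-12,
                 by = bin_ms / 1000)
  raster <- matrix(NA_integer_, length(align_times), length(centers))
  nfr <- length(labels)
  for (i in seq_along(align_times)) {
    fr <- floor((align_times[i] + centers) * fs) + 1L
    ok <- fr >= 1 & fr <= nfr
    raster[i, ok] <- labels[fr[ok]]
  }
  P <- vapply(0:6, function(m) colMeans(raster == m, na.rm = TRUE),
              numeric(length(centers)))
  P <- t(P)
  dimnames(P) <- list(MOTIFS, NULL)
  attr(P, "time") <- centers
  attr(P, "raster") <- raster
  attr(P, "dropped") <- dropped
  P
}

#' Time of the first occurrence of a motif in each trial
#'
#' @param bouts session bout table.
#' @param events trial event table.
#' @param motif motif name or code (default "Open", the alignment motif of
#'   the session ethograms).
#' @param fs frame rate, Hz.
#' @return numeric vector of alignment times (s), NA for trials without the
#'   motif in their response window.
#' @export
first_motif_times <- function(bouts, events, motif = "Open", fs = 500) {
  m <- if (is.character(motif)) motif_code(motif) else as.integer(motif)
  vapply(seq_len(nrow(events)), function(i) {
    w <- events$water_time[i]
    b <- clip_bouts(bouts, w, w + events$response_window[i], fs)
    sel <- b$motif == m
    if (any(sel)) min(b$start_frame[sel]) / fs else NA_real_
  }, 0)
}

# restrict a session bout table to per-trial sequences (list of bout tables,
# one per trial, clipped to each response window)
trial_bout_lists <- function(bouts, events, fs = 500, kin = NULL) {
  lapply(seq_len(nrow(events)), function(i) {
    w <- events$water_time[i]
    clip_bouts(bouts, w, w + events$response_window[i], fs, kin)
  })
}
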