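#' Isosbestic-corrected fractional fluorescence change
#'
#' The calcium-independent 410 nm channel is fitted to the 470 nm channel
#' by least-squares affine regression `f_fit = a * f410 + b`, and
#' `dff = (f470 - f_fit) / f_fit`. The fit absorbs bleaching and shared
#' motion artifacts carried by both channels.
#'
#' @param f470,f410 numeric traces of equal length (>= 2 samples).
#' @return list with `dff` and `fit_params` (`slope`, `intercept`).
#' @export
isosbestic_dff <- function(f470, f410) {
  if (length(f470) != length(f410)) stop("f470/f410 length mismatch")
  if (length(f470) < 2) stop("need at least 2 samples")
  if (stats::sd(f410) < 1e-12) stop("f410 is constant; cannot fit isosbestic")
  fit <- stats::lm.fit(cbind(1, f410), f470)
  a <- fit$coefficients[2]; b <- fit$coefficients[1]
  f_fit <- a * f410 + b
  if (any(f_fit <= 0)) {
    stop("fitted baseline is non-positive; detrend the channels first")
  }
  list(dff = (f470 - f_fit) / f_fit,
       fit_params = c(slope = unname(a), intercept = unname(b)))
}

#' Z-score a trace
#'
#' @param x numeric trace.
#' @param scope normalization scope; `"session"` uses the whole recording's
#'   mean and s.d.
#' @return z-scored trace.
#' @export
zscore_trace <- function(x, scope = c("session")) {
  scope <- match.arg(scope)
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) stop("zero-variance trace cannot be z-scored")
  (x - mean(x)) / s
}

#' Full photometry preprocessing for one recording
#'
#' @param rec list with `t`, `f470`, `f410`, `fs`.
#' @return `rec` with `dff`, `z`, `fit_params` added.
#' @export
process_photometry <- function(rec) {
  d <- isosbestic_dff(rec$f470, rec$f410)
  rec$dff <- d$dff
  rec$fit_params <- d$fit_params
  rec$z <- zscore_trace(d$dff)
  rec
}

# linear resampling of (t, x) onto a peri-event grid for one event time
resample_peri <- function(t, x, event_time, grid) {
  stats::approx(t - event_time, x, xout = grid, rule = 1)$y
}

#' Trial-aligned photometry matrix with reaction-time stratification
#'
#' Resamples the z-scored trace onto a uniform peri-event grid around each
#' water delivery, stratifies reaching trials by reaction time (fastest vs
#' slowest `fraction`, sizes `ceiling(fraction * n)`), and reports the
#' group-mean traces and their peak latencies within a search window.
#'
#' @param z z-scored trace; `t` its timestamps (s).
#' @param t timestamps of `z`.
#' @param events trial event table.
#' @param reaction_times per-trial latency to reach (s; NA = no reach;
#'   non-reaching trials are excluded from stratification but kept in the
#'   matrix).
#' @param window peri-event window `c(t_min, t_max)` (s); must lie within
#'   the recording for at least one trial.
#' @param fraction stratified fraction per tail (default 0.3).
#' @param fs_out resampled rate (Hz, default 50).
#' @param peak_window search window for group-mean peak latency (s).
#' @return list: `matrix` (trials x bins), `time`, `fast_idx`, `slow_idx`,
#'   `fast_mean`, `slow_mean`, `fast_peak_s`, `slow_peak_s`, `sort_order`.
#' @export
align_and_stratify <- function(z, t, events, reaction_times,
                               window = c(-2, 5), fraction = 0.3,
                               fs_out = 50, peak_window = c(0, 3)) {
  if (window[1] < t[1] - max(events$water_time) ||
      window[2] > max(t) - min(events$water_time)) {
    if (min(events$water_time) + window[1] < t[1] - 1e-9 ||
        min(events$water_time) + window[2] > max(t) + 1e-9) {
      stop("peri-event window extends beyond the recording")
    }
  }
  grid <- seq(window[1], window[2], by = 1 / fs_out)
  M <- t(vapply(events$water_time, function(w) resample_peri(t, z, w, grid),
                numeric(length(grid))))
  rt <- reaction_times
  reachers <- which(is.finite(rt))
  ns <- ceiling(fraction * length(reachers))
  ord <- reachers[order(rt[reachers])]
  fast_idx <- utils::head(ord, ns)
  slow_idx <- utils::tail(ord, ns)
  gm <- function(idx) if (length(idx)) colMeans(M[idx, , drop = FALSE]) else
    rep(NA_real_, length(grid))
  fast_mean <- gm(fast_idx); slow_mean <- gm(slow_idx)
  pk <- function(m) {
    sel <- grid >= peak_window[1] & grid <= peak_window[2]
    if (!any(sel) || all(is.na(m[sel]))) return(NA_real_)
    grid[sel][which.max(m[sel])]
  }
  list(matrix = M, time = grid,
       fast_idx = fast_idx, slow_idx = slow_idx,
       fast_mean = fast_mean, slow_mean = slow_mean,
       fast_peak_s = pk(fast_mean), slow_peak_s = pk(slow_mean),
       sort_order = order(rt))
}

#' Per-bout photometry activity paired with bout kinematics
#'
#' Mean and peak z-scored calcium for each motif bout occurrence, paired
#' with the bout's kinematics (distance travelled, mean and peak speed).
#'
#' @param z z-scored trace; `t` its timestamps.
#' @param t timestamps of `z`.
#' @param bouts bout table with kinematic columns (see [segment_bouts()]).
#' @param fs behavioral frame rate (converts bout frames to seconds).
#' @return data.frame: `motif`, `mean_z`, `peak_z`, `distance_mm`,
#'   `mean_speed`, `peak_speed`.
#' @export
motif_activity <- function(z, t, bouts, fs = 500) {
  b <- bouts[bouts$motif != 0L, , drop = FALSE]
  n <- nrow(b)
  mean_z <- peak_z <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sel <- t >= b$start_frame[i] / fs & t < b$end_frame[i] / fs
    if (any(sel)) {
      mean_z[i] <- mean(z[sel])
      peak_z[i] <- max(z[sel])
    }
  }
  data.frame(motif = b$motif, mean_z = mean_z, peak_z = peak_z,
             distance_mm = b$distance_mm, mean_speed = b$mean_speed,
             peak_speed = b$peak_speed)
}

#' Spearman correlation of motif activity with motif kinematics
#'
#' For every combination of motif, kinematic feature (distance, mean speed,
#' peak speed) and activity measure (mean z, peak z), the Spearman rank
#' correlation over bout occurrences. Cells with fewer than `min_n` paired
#' occurrences are flagged and left NA.
#'
#' @param act output of [motif_activity()].
#' @param min_n minimum paired occurrences per cell (default 5).
#' @return data.frame: `motif`, `feature`, `measure`, `rho`, `p`, `n`,
#'   `insufficient`.
#' @export
kinematic_correlation <- function(act, min_n = 5) {
  feats <- c("distance_mm", "mean_speed", "peak_speed")
  meas <- c("mean_z", "peak_z")
  rows <- list()
  for (m in sort(unique(act$motif))) {
    sub <- act[act$motif == m, ]
    for (f in feats) for (a in meas) {
      ok <- is.finite(sub[[f]]) & is.finite(sub[[a]])
      n <- sum(ok)
      if (n >= min_n) {
        ct <- suppressWarnings(
          stats::cor.test(sub[[f]][ok], sub[[a]][ok], method = "spearman"))
        rho <- unname(ct$estimate); p <- ct$p.value
      } else {
        rho <- NA_real_; p <- NA_real_
      }
      rows[[length(rows) + 1]] <- data.frame(
        motif = MOTIFS[m + 1], feature = f, measure = a,
        rho = rho, p = p, n = n, insufficient = n < min_n)
    }
  }
  do.call(rbind, rows)
}
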