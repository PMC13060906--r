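# ---- hand-written toy-session fixture --------------------------------------
# fs = 100 Hz, one trial per 10 s, water at 1 s into each trial slot.
# Each trial is specified as runs of (motif, duration s) starting at water.
# Edge cases: Drink exactly 600 ms, NoReach gaps above/below the Lift-Reach
# tolerance, bouts clipped at the window edge, Reach without Lift, Drink
# without a reach, multiple Lift-Reach sequences, multiple Drinks, a Lift
# straddling water, and the 0.10/0.20/0.30 Reach-duration enumeration case.

FS <- 100
RW <- 7

toy_trials <- list(
  t01_clean = list(c("NoReach", 1.0), c("Lift", 0.10), c("Reach", 0.12),
                   c("Open", 0.09), c("Grasp", 0.11), c("Retract", 0.15),
                   c("Drink", 0.80)),
  t02_drink_600ms = list(c("NoReach", 0.5), c("Lift", 0.10), c("Reach", 0.12),
                         c("Drink", 0.60)),
  t03_gap_too_long = list(c("NoReach", 0.5), c("Lift", 0.10),
                          c("NoReach", 0.10), c("Reach", 0.12),
                          c("Drink", 0.90)),
  t04_gap_ok = list(c("NoReach", 0.5), c("Lift", 0.10), c("NoReach", 0.03),
                    c("Reach", 0.12), c("Drink", 0.70)),
  t05_no_reach = list(c("NoReach", 6.0)),
  t06_two_sequences = list(c("NoReach", 0.4), c("Lift", 0.08), c("Reach", 0.10),
                           c("NoReach", 0.6), c("Lift", 0.09), c("Reach", 0.11),
                           c("Open", 0.09), c("Drink", 0.75)),
  t07_drink_clipped = list(c("NoReach", 0.2), c("Lift", 0.10), c("Reach", 0.12),
                           c("NoReach", 6.08), c("Drink", 1.00)),
  t08_reach_no_lift = list(c("NoReach", 0.5), c("Reach", 0.20),
                           c("Drink", 0.80)),
  t09_drink_no_reach = list(c("NoReach", 0.5), c("Drink", 0.70)),
  t10_two_drinks = list(c("NoReach", 0.3), c("Lift", 0.10), c("Reach", 0.10),
                        c("Drink", 0.40), c("NoReach", 0.20), c("Drink", 0.90)),
  t11_lift_at_edge = list(c("Lift", 0.12), c("Reach", 0.10), c("Drink", 0.65)),
  t12_three_reaches = list(c("NoReach", 0.5), c("Lift", 0.10), c("Reach", 0.10),
                           c("NoReach", 0.3), c("Reach", 0.20),
                           c("NoReach", 0.3), c("Reach", 0.30),
                           c("Drink", 0.70))
)

build_toy_session <- function(trials = toy_trials) {
  nt <- length(trials)
  nfr <- nt * 10 * FS
  labels <- rep(0L, nfr)
  water <- 10 * (seq_len(nt) - 1) + 1
  for (i in seq_len(nt)) {
    t <- water[i]
    if (names(trials)[i] == "t11_lift_at_edge") t <- t - 0.05  # straddle water
    for (run in trials[[i]]) {
      dur <- as.numeric(run[2])
      f0 <- round(t * FS); f1 <- round((t + dur) * FS)
      labels[(f0 + 1):f1] <- motif_code(run[1])
      t <- t + dur
    }
  }
  # deterministic speed profile: moving frames get a varying positive speed
  idx <- seq_len(nfr)
  speed <- ifelse(labels > 0, 40 + 10 * sin(idx / 5), 0)
  kin <- data.frame(t = (idx - 1) / FS,
                    x = cumsum(speed) / FS, y = 0, z = 0,
                    speed = speed, accel = 0, dist_to_spout = NA_real_,
                    inter_digit_dist = NA_real_, inter_digit_speed = NA_real_)
  events <- as_events(data.frame(water_time = water, response_window = RW))
  list(labels = labels, kin = kin, events = events)
}

# ---- independent brute-force oracle -----------------------------------------
# frame-level loops only; no shared code with the package implementation
oracle_trial <- function(labels, kin, w, fs = FS, rw = RW,
                         max_gap = 0.040) {
  f0 <- floor(w * fs); f1 <- ceiling((w + rw) * fs)
  fr <- (f0 + 1):min(f1, length(labels))
  lab <- labels[fr]
  # enumerate runs by scanning
  runs <- list(); cur <- lab[1]; start <- 1
  for (i in seq_along(lab)[-1]) {
    if (lab[i] != cur) {
      runs[[length(runs) + 1]] <- c(cur, start, i - 1)
      cur <- lab[i]; start <- i
    }
  }
  runs[[length(runs) + 1]] <- c(cur, start, length(lab))
  R <- do.call(rbind, runs)      # motif, first, last (local 1-based)
  out <- list()
  for (m in 1:6) {
    rows <- which(R[, 1] == m)
    nm <- MOTIFS[m + 1]
    out[[paste0(nm, "_count")]] <- length(rows)
    if (length(rows)) {
      durs <- (R[rows, 3] - R[rows, 2] + 1) / fs
      lat <- (R[rows[1], 2] - 1 + f0) / fs - w
      dist <- msp <- psp <- numeric(0)
      for (r in rows) {
        gidx <- (R[r, 2]:R[r, 3]) + f0
        d <- 0
        if (length(gidx) > 1) {
          for (k in 2:length(gidx)) d <- d + abs(kin$x[gidx[k]] - kin$x[gidx[k - 1]])
        }
        dist <- c(dist, d)
        msp <- c(msp, mean(kin$speed[gidx]))
        psp <- c(psp, max(kin$speed[gidx]))
      }
      out[[paste0(nm, "_latency_s")]] <- lat
      out[[paste0(nm, "_duration_s")]] <- mean(durs)
      out[[paste0(nm, "_total_duration_s")]] <- sum(durs)
      out[[paste0(nm, "_distance_mm")]] <- mean(dist)
      out[[paste0(nm, "_mean_speed")]] <- mean(msp)
      out[[paste0(nm, "_peak_speed")]] <- mean(psp)
    } else {
      for (sfx in c("latency_s", "duration_s", "total_duration_s",
                    "distance_mm", "mean_speed", "peak_speed")) {
        out[[paste0(nm, "_", sfx)]] <- NA_real_
      }
    }
  }
  # Lift-Reach sequences
  lr <- integer(0)
  for (r in seq_len(nrow(R))) {
    if (R[r, 1] != 1) next
    j <- r + 1; gap <- 0
    while (j <= nrow(R) && R[j, 1] == 0) {
      gap <- gap + (R[j, 3] - R[j, 2] + 1) / fs
      j <- j + 1
    }
    if (j <= nrow(R) && R[j, 1] == 2 && gap <= max_gap) lr <- c(lr, r)
  }
  out$reached <- length(lr) > 0
  out$latency_to_reach_s <-
    if (out$reached) (R[lr[1], 2] - 1 + f0) / fs - w else NA_real_
  out$succeeded <- FALSE; out$latency_to_success_s <- NA_real_
  if (out$reached) {
    lift_f <- R[lr[1], 2]
    for (r in seq_len(nrow(R))) {
      if (R[r, 1] == 6 && (R[r, 3] - R[r, 2] + 1) / fs > 0.6 &&
          R[r, 2] >= lift_f) {
        out$succeeded <- TRUE
        out$latency_to_success_s <- (R[r, 2] - lift_f) / fs
        break
      }
    }
  }
  out
}

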