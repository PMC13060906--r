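#' Per-neuron motif modulation test
#'
#' For every neuron and motif: per trial, the baseline mean z-score (over a
#' predefined pre-delivery window, default -2.0 s to -0.4 s relative to
#' water delivery) and the mean z-score over that trial's motif occurrences
#' are paired; `delta_z` is the mean over trials of (motif - baseline), and
#' significance comes from a two-sided Wilcoxon signed-rank test on the
#' paired per-trial values. A neuron is `excited`/`inhibited` when
#' `p < alpha` with positive/negative `delta_z`, else `unchanged`.
#'
#' @param pop population recording: `list(traces, t, fs, neuron_ids)` with
#'   `traces` a neurons x time z-scored matrix.
#' @param bouts session bout table (behavioral frames).
#' @param events trial event table.
#' @param fs_behavior behavioral frame rate, Hz.
#' @param baseline_window `c(lo, hi)` relative to water delivery, s.
#' @param alpha significance level (two-sided).
#' @param motifs motif codes to test (default 1:6).
#' @param min_trials minimum trials with both baseline and motif samples.
#' @param p_adjust optional multiple-testing correction method passed to
#'   [stats::p.adjust()] (default "none", matching per-cell reporting).
#' @return data.frame per neuron x motif: `neuron`, `motif`, `delta_z`,
#'   `p`, `class`, `n_trials`; attribute `proportions` has per-motif
#'   fractions excited/inhibited/unchanged.
#' @export
motif_modulation <- function(pop, bouts, events, fs_behavior = 500,
                             baseline_window = c(-2.0, -0.4), alpha = 0.05,
                             motifs = 1:6, min_trials = 6,
                             p_adjust = "none") {
  tr <- pop$traces
  tt <- pop$t
  nn <- nrow(tr)
  nt <- nrow(events)

  base_idx <- lapply(seq_len(nt), function(i) {
    w <- events$water_time[i]
    which(tt >= w + baseline_window[1] & tt < w + baseline_window[2])
  })
  bout_by_trial <- trial_bout_lists(bouts, events, fs_behavior)

  rows <- list()
  for (m in motifs) {
    motif_idx <- lapply(seq_len(nt), function(i) {
      b <- bout_by_trial[[i]]
      b <- b[b$motif == m, , drop = FALSE]
      if (!nrow(b)) return(integer(0))
      unlist(lapply(seq_len(nrow(b)), function(k)
        which(tt >= b$start_frame[k] / fs_behavior &
                tt < b$end_frame[k] / fs_behavior)))
    })
    usable <- which(vapply(base_idx, length, 1L) > 0 &
                      vapply(motif_idx, length, 1L) > 0)
    if (length(usable) < min_trials) {
      rows[[length(rows) + 1]] <- data.frame(
        neuron = pop$neuron_ids, motif = m, delta_z = NA_real_, p = NA_real_,
        class = "undefined", n_trials = length(usable))
      next
    }
    base_mat <- vapply(usable, function(i)
      rowMeans(tr[, base_idx[[i]], drop = FALSE]), numeric(nn))
    mot_mat <- vapply(usable, function(i)
      rowMeans(tr[, motif_idx[[i]], drop = FALSE]), numeric(nn))
    diff_mat <- mot_mat - base_mat       # neurons x trials
    delta <- rowMeans(diff_mat)
    p <- apply(diff_mat, 1, function(d) {
      if (all(d == 0)) return(1)
      suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
    })
    rows[[length(rows) + 1]] <- data.frame(
      neuron = pop$neuron_ids, motif = m, delta_z = delta, p = p,
      class = "unchanged", n_trials = length(usable))
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none") out$p <- stats::p.adjust(out$p, method = p_adjust)
  def <- out$class != "undefined"
  out$class[def & out$p < alpha & out$delta_z > 0] <- "excited"
  out$class[def & out$p < alpha & out$delta_z < 0] <- "inhibited"
  prop <- do.call(rbind, lapply(split(out, out$motif), function(d) {
    n <- sum(d$class != "undefined")
    data.frame(motif = MOTIFS[d$motif[1] + 1],
               excited = sum(d$class == "excited") / max(n, 1),
               inhibited = sum(d$class == "inhibited") / max(n, 1),
               unchanged = sum(d$class == "unchanged") / max(n, 1))
  }))
  attr(out, "proportions") <- prop
  out
}

#' Order neurons by modulation magnitude during one motif
#'
#' Descending `delta_z`; ties broken by neuron id; neurons with undefined
#' modulation come last. The result is a permutation of the neuron ids.
#'
#' @param mod output of [motif_modulation()].
#' @param motif motif name or code (default "Retract").
#' @return integer vector of neuron ids in display order.
#' @export
sort_by_modulation <- function(mod, motif = "Retract") {
  m <- if (is.character(motif)) motif_code(motif) else as.integer(motif)
  d <- mod[mod$motif == m, ]
  if (!nrow(d)) stop("motif not present in modulation table")
  ord <- order(is.na(d$delta_z), -ifelse(is.na(d$delta_z), 0, d$delta_z),
               d$neuron)
  d$neuron[ord]
}

# kinematic series averaged within each neural frame interval
# (anti-aliasing resampling onto the neural clock)
kin_to_neural <- function(kin, fs_behavior, t_neural) {
  cbind(x = bin_average(kin$x, fs_behavior, t_neural),
        y = bin_average(kin$y, fs_behavior, t_neural),
        z = bin_average(kin$z, fs_behavior, t_neural),
        velocity = bin_average(kin$speed, fs_behavior, t_neural))
}

#' Linear population decoding of 3D kinematics
#'
#' Ordinary least squares (with intercept) from the neural population to
#' each kinematic target (x, y, z, velocity), cross-validated over
#' contiguous time blocks. R^2 = 1 - SS_res/SS_tot is computed on the
#' concatenated held-out predictions; reported weights come from a
#' full-data refit, and normalized weights divide by the largest absolute
#' weight per target.
#'
#' @param pop population recording (`traces` neurons x time).
#' @param kin kinematic targets: time x 4 matrix (columns x, y, z,
#'   velocity) on the neural clock, e.g. from a `kinematic_series` resampled
#'   with the internal bin-averaging (see [decode_session()]).
#' @param k number of contiguous CV folds (default 5, >= 2).
#' @param ridge fallback ridge penalty for rank-deficient designs.
#' @return `decoding_result`: data.frame `r2` per target, `weights`
#'   (neurons x 4), `normalized_weights`, `predicted` (time x 4), `folds`.
#' @export
decode_kinematics <- function(pop, kin, k = 5, ridge = 1e-6) {
  X <- t(pop$traces)                     # time x neurons
  Y <- as.matrix(kin)
  stopifnot(nrow(X) == nrow(Y), ncol(Y) == 4, k >= 2)
  ok <- stats::complete.cases(X) & stats::complete.cases(Y)
  X <- X[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
  n <- nrow(X)
  fold <- as.integer(cut(seq_len(n), breaks = k, labels = FALSE))

  fit_ols <- function(Xtr, Ytr) {
    A <- cbind(1, Xtr)
    XtX <- crossprod(A)
    coefs <- tryCatch(solve(XtX, crossprod(A, Ytr)), error = function(e) NULL)
    if (is.null(coefs) || qr(A)$rank < ncol(A)) {
      warning("rank-deficient design; using ridge fallback")
      coefs <- solve(XtX + diag(ridge, ncol(A)), crossprod(A, Ytr))
    }
    coefs
  }

  pred <- matrix(NA_real_, n, 4, dimnames = list(NULL, colnames(Y)))
  for (f in seq_len(k)) {
    te <- fold == f
    coefs <- fit_ols(X[!te, , drop = FALSE], Y[!te, , drop = FALSE])
    pred[te, ] <- cbind(1, X[te, , drop = FALSE]) %*% coefs
  }
  r2 <- vapply(1:4, function(j) {
    ss_res <- sum((Y[, j] - pred[, j])^2)
    ss_tot <- sum((Y[, j] - mean(Y[, j]))^2)
    1 - ss_res / ss_tot
  }, 0)
  coefs_full <- fit_ols(X, Y)
  W <- coefs_full[-1, , drop = FALSE]    # neurons x 4
  rownames(W) <- pop$neuron_ids
  colnames(W) <- colnames(Y)
  Wn <- sweep(W, 2, apply(abs(W), 2, max), "/")
  structure(list(
    r2 = data.frame(target = colnames(Y), r2 = r2),
    weights = W, normalized_weights = Wn,
    predicted = pred, folds = fold), class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> held-out R^2:\n")
  print(x$r2, row.names = FALSE)
  invisible(x)
}

#' Decode kinematics directly from a session
#'
#' Resamples the behavioral kinematic series onto the neural clock
#' (averaging within neural frame intervals) and runs
#' [decode_kinematics()].
#'
#' @param session `reach_session` with a population recording.
#' @param kin `kinematic_series` at the behavioral frame rate.
#' @param k number of contiguous CV folds (see [decode_kinematics()]).
#' @param ... passed to [decode_kinematics()].
#' @return a `decoding_result`.
#' @export
decode_session <- function(session, kin, k = 5, ...) {
  if (is.null(session$population)) stop("session has no population recording")
  K <- kin_to_neural(kin, session$fs_behavior, session$population$t)
  decode_kinematics(session$population, K, k = k, ...)
}
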