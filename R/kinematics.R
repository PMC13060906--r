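# central differences with edge replication: d[i] = (x[i+1] - x[i-1]) / 2
central_diff <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, central_diff))
  n <- length(x)
  if (n < 2) return(rep(0, n))
  d <- (c(x[-1], x[n]) - c(x[1], x[-n])) / c(1, rep(2, n - 2), 1)
  d
}

#' Fuse two orthogonal camera views into 3D tracks
#'
#' The side view images the (x, z) plane and the front view the (y, z)
#' plane (ideal orthogonal projection). The shared vertical axis z is the
#' confidence-weighted mean of the two views; the fused per-frame confidence
#' is the minimum of the two views. With noiseless projections the fused
#' coordinates reproduce the true 3D positions exactly.
#'
#' @param side,front per-bodypart track lists as returned by
#'   [read_pose_table()] (columns `x`, `y`, `confidence`; the track `y`
#'   column is the image vertical, i.e. world z).
#' @param axis_map which world axes the two views image; only the default
#'   `list(side = c("x", "z"), front = c("y", "z"))` is supported.
#' @return named list of per-bodypart data.frames `x`, `y`, `z`,
#'   `confidence` (mm if the views are metric).
#' @export
fuse_views <- function(side, front,
                       axis_map = list(side = c("x", "z"), front = c("y", "z"))) {
  if (!identical(axis_map, list(side = c("x", "z"), front = c("y", "z")))) {
    stop("only the side->(x,z), front->(y,z) axis map is supported")
  }
  bps <- intersect(names(side), names(front))
  if (!length(bps)) stop("no common bodyparts between views")
  out <- list()
  for (bp in bps) {
    a <- side[[bp]]; b <- front[[bp]]
    if (nrow(a) != nrow(b)) {
      stop(sprintf("frame count mismatch for %s: side %d vs front %d",
                   bp, nrow(a), nrow(b)))
    }
    wa <- a$confidence; wb <- b$confidence
    wsum <- wa + wb
    z <- ifelse(wsum > 0, (wa * a$y + wb * b$y) / wsum, (a$y + b$y) / 2)
    out[[bp]] <- data.frame(x = a$x, y = b$x, z = z,
                            confidence = pmin(wa, wb))
  }
  out
}

#' Project fused 3D tracks back onto the two camera planes
#'
#' Inverse of [fuse_views()] for the ideal orthogonal camera model; used to
#' check the fusion round-trip.
#'
#' @param tracks3d output of [fuse_views()].
#' @return list with `side` and `front` per-bodypart track lists.
#' @export
project_views <- function(tracks3d) {
  side <- lapply(tracks3d, function(tr)
    data.frame(x = tr$x, y = tr$z, confidence = tr$confidence))
  front <- lapply(tracks3d, function(tr)
    data.frame(x = tr$y, y = tr$z, confidence = tr$confidence))
  list(side = side, front = front)
}

#' Derive the kinematic series from fused 3D tracks
#'
#' The forelimb centroid is the mean of digits 2--4 and the paw. Speed is
#' the norm of the central-difference derivative of the centroid times the
#' frame rate (mm/s); acceleration is computed analogously on the velocity
#' components; `dist_to_spout` is the Euclidean distance from the centroid
#' to the spout; `inter_digit_dist` is the mean pairwise distance among
#' digits 2--4 and `inter_digit_speed` its derivative. Optional
#' Savitzky-Golay smoothing (off by default) is applied to coordinates
#' before differentiation.
#'
#' @param tracks3d per-bodypart 3D tracks from [fuse_views()].
#' @param fs frame rate, Hz.
#' @param spout_xyz spout coordinate (mm); `NULL` skips `dist_to_spout`.
#' @param smooth list(`enabled`, `window` frames, `order`); default off,
#'   window 11, order 3.
#' @return data.frame of class `kinematic_series`: `t`, `x`, `y`, `z`,
#'   `speed`, `accel`, `dist_to_spout`, `inter_digit_dist`,
#'   `inter_digit_speed`.
#' @export
derive_series <- function(tracks3d, fs, spout_xyz = NULL,
                          smooth = list(enabled = FALSE, window = 11, order = 3)) {
  if (fs <= 0) stop("fs must be > 0")
  digits <- c("digit2", "digit3", "digit4")
  core <- c(digits, "paw")
  miss <- setdiff(core, names(tracks3d))
  if (length(miss)) stop("missing bodypart(s): ", paste(miss, collapse = ", "))
  for (bp in core) {
    if (all(is.na(tracks3d[[bp]]$x))) stop("bodypart all-missing: ", bp)
  }
  sm <- function(v) {
    if (isTRUE(smooth$enabled)) {
      signal::sgolayfilt(v, p = smooth$order, n = smooth$window)
    } else v
  }
  xyz <- function(bp) cbind(sm(tracks3d[[bp]]$x), sm(tracks3d[[bp]]$y),
                            sm(tracks3d[[bp]]$z))
  P <- lapply(core, xyz)
  cen <- (P[[1]] + P[[2]] + P[[3]] + P[[4]]) / 4
  n <- nrow(cen)
  vel <- central_diff(cen) * fs
  speed <- sqrt(rowSums(vel^2))
  acc_vec <- central_diff(vel) * fs
  accel <- sqrt(rowSums(acc_vec^2))

  D <- lapply(1:3, function(i) xyz(digits[i]))
  pd <- function(a, b) sqrt(rowSums((a - b)^2))
  idd <- (pd(D[[1]], D[[2]]) + pd(D[[1]], D[[3]]) + pd(D[[2]], D[[3]])) / 3
  ids <- central_diff(idd) * fs

  out <- data.frame(
    t = (seq_len(n) - 1) / fs,
    x = cen[, 1], y = cen[, 2], z = cen[, 3],
    speed = speed, accel = accel,
    dist_to_spout = if (is.null(spout_xyz)) NA_real_ else
      sqrt((cen[, 1] - spout_xyz[1])^2 + (cen[, 2] - spout_xyz[2])^2 +
             (cen[, 3] - spout_xyz[3])^2),
    inter_digit_dist = idd, inter_digit_speed = ids
  )
  class(out) <- c("kinematic_series", "data.frame")
  out
}

#' Build the classifier feature matrix
#'
#' Features are the augmented per-frame set: per-bodypart 3D coordinates
#' (6 bodyparts x 3 = 18), all pairwise inter-bodypart distances
#' (C(6,2) = 15), per-bodypart speeds (6), and centroid acceleration
#' magnitude (1) -- 40 features. Columns are z-normalized using `norm_stats`
#' when provided (training statistics reused at prediction time), otherwise
#' by the matrix's own statistics, which are returned for reuse.
#'
#' @param tracks3d per-bodypart 3D tracks (imputed; no missing values).
#' @param fs frame rate, Hz.
#' @param norm_stats optional list(`mean`, `sd`, `names`) from a previous
#'   call.
#' @return list with `x` (frames x features matrix), `names`, and
#'   `norm_stats`.
#' @export
build_features <- function(tracks3d, fs, norm_stats = NULL) {
  bps <- intersect(c(REQUIRED_BODYPARTS), names(tracks3d))
  if (length(bps) < 2) stop("need at least two bodyparts")
  P <- lapply(bps, function(bp) as.matrix(tracks3d[[bp]][, c("x", "y", "z")]))
  names(P) <- bps
  n <- nrow(P[[1]])

  cols <- list(); cn <- character(0)
  for (bp in bps) {
    cols[[length(cols) + 1]] <- P[[bp]]
    cn <- c(cn, paste0(bp, "_", c("x", "y", "z")))
  }
  for (i in seq_along(bps)) for (j in seq_along(bps)) {
    if (j <= i) next
    cols[[length(cols) + 1]] <- sqrt(rowSums((P[[i]] - P[[j]])^2))
    cn <- c(cn, paste0("dist_", bps[i], "_", bps[j]))
  }
  for (bp in bps) {
    v <- central_diff(P[[bp]]) * fs
    cols[[length(cols) + 1]] <- sqrt(rowSums(v^2))
    cn <- c(cn, paste0(bp, "_speed"))
  }
  core <- intersect(c("digit2", "digit3", "digit4", "paw"), bps)
  cen <- Reduce(`+`, P[core]) / length(core)
  acc <- central_diff(central_diff(cen) * fs) * fs
  cols[[length(cols) + 1]] <- sqrt(rowSums(acc^2))
  cn <- c(cn, "centroid_accel")

  x <- do.call(cbind, cols)
  colnames(x) <- cn
  if (any(!is.finite(x))) {
    bad <- which(rowSums(!is.finite(x)) > 0)
    stop("non-finite feature values at frame(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (is.null(norm_stats)) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv < 1e-12] <- 1
    norm_stats <- list(mean = mu, sd = sdv, names = cn)
  } else {
    if (!identical(norm_stats$names, cn)) {
      stop("feature names differ from norm_stats: ",
           paste(symdiff_chr(norm_stats$names, cn), collapse = ", "))
    }
  }
  x <- sweep(sweep(x, 2, norm_stats$mean), 2, norm_stats$sd, "/")
  list(x = x, names = cn, norm_stats = norm_stats)
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' Fuse a session's two-camera tracks and derive kinematics
#'
#' Convenience wrapper: impute low-confidence keypoints, fuse views, derive
#' the kinematic series against the session spout.
#'
#' @param session a `reach_session` with `side` and `front` tracks.
#' @param impute apply [impute_track()] first (default TRUE).
#' @param ... passed to [derive_series()].
#' @return list with `tracks3d` and `kin` (a `kinematic_series`).
#' @export
session_kinematics <- function(session, impute = TRUE, ...) {
  tr <- session$tracks
  if (!all(c("side", "front") %in% names(tr))) {
    stop("session needs side and front camera tracks")
  }
  if (impute) {
    tr <- lapply(tr, function(cam) lapply(cam, impute_track))
  }
  t3 <- fuse_views(tr$side, tr$front)
  kin <- derive_series(t3, session$fs_behavior, session$spout_xyz, ...)
  list(tracks3d = t3, kin = kin)
}
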