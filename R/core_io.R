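#' Construct a behavioral session object
#'
#' A `reach_session` bundles everything recorded in one water-reaching
#' session: two-camera keypoint tracks, the trial event table, optional
#' frame-wise motif labels, and optional neural recordings (fiber photometry
#' and/or a single-cell calcium population). Time is in seconds with 0 at
#' session start; frames are 0-based; trial-relative time is 0 at water
#' delivery.
#'
#' @param session_id character identifier.
#' @param fs_behavior behavioral frame rate in Hz (default 500).
#' @param tracks named list of cameras (`side`, `front`), each a named list of
#'   bodypart data.frames with columns `x`, `y`, `confidence`.
#' @param events trial event data.frame, see [read_events()].
#' @param labels optional integer vector of per-frame motif codes (0--6).
#' @param photometry optional named list (per hemisphere) of photometry
#'   recordings: `list(t, f470, f410, fs)`.
#' @param population optional population recording:
#'   `list(traces, t, fs, neuron_ids)` with `traces` a neurons x time matrix.
#' @param spout_xyz numeric length-3 target coordinate (mm).
#' @param meta free-form provenance list.
#' @return object of class `reach_session`.
#' @export
new_session <- function(session_id, fs_behavior = 500, tracks = list(),
                        events = empty_events(), labels = NULL,
                        photometry = NULL, population = NULL,
                        spout_xyz = c(25, 0, 18), meta = list()) {
  s <- structure(list(
    session_id = as.character(session_id),
    fs_behavior = as.numeric(fs_behavior),
    tracks = tracks,
    events = events,
    labels = if (is.null(labels)) NULL else as.integer(labels),
    photometry = photometry,
    population = population,
    spout_xyz = as.numeric(spout_xyz),
    meta = meta
  ), class = "reach_session")
  validate_session(s)
  s
}

#' @export
print.reach_session <- function(x, ...) {
  nf <- session_n_frames(x)
  cat(sprintf("<reach_session '%s'>  %d trials, %s frames @ %g Hz\n",
              x$session_id, nrow(x$events),
              if (is.na(nf)) "?" else format(nf), x$fs_behavior))
  if (!is.null(x$labels)) cat("  labels: present\n")
  if (!is.null(x$photometry))
    cat("  photometry:", paste(names(x$photometry), collapse = ", "), "\n")
  if (!is.null(x$population))
    cat("  population:", nrow(x$population$traces), "neurons\n")
  invisible(x)
}

session_n_frames <- function(s) {
  if (length(s$tracks)) {
    nrow(s$tracks[[1]][[1]])
  } else if (!is.null(s$labels)) {
    length(s$labels)
  } else NA_integer_
}

#' Validate a session's structural invariants
#'
#' Checks the type invariants: per-camera tracks share one frame count,
#' labels (if present) share it too, `fs_behavior > 0`, water times strictly
#' increasing, laser off >= on. Errors name the offending field.
#'
#' @param s a `reach_session`.
#' @return `s` invisibly.
#' @export
validate_session <- function(s) {
  if (!is.finite(s$fs_behavior) || s$fs_behavior <= 0) {
    stop("fs_behavior must be > 0")
  }
  nf <- NA_integer_
  for (cam in names(s$tracks)) {
    for (bp in names(s$tracks[[cam]])) {
      tr <- s$tracks[[cam]][[bp]]
      if (!all(c("x", "y", "confidence") %in% names(tr))) {
        stop(sprintf("track %s/%s lacks x/y/confidence columns", cam, bp))
      }
      if (is.na(nf)) nf <- nrow(tr)
      if (nrow(tr) != nf) {
        stop(sprintf("track %s/%s has %d frames, expected %d", cam, bp,
                     nrow(tr), nf))
      }
    }
  }
  if (!is.null(s$labels)) {
    if (!is.na(nf) && length(s$labels) != nf) {
      stop(sprintf("labels length %d does not match track frame count %d",
                   length(s$labels), nf))
    }
    bad <- s$labels[!is.na(s$labels)]
    if (length(bad) && (min(bad) < 0L || max(bad) > 6L)) {
      stop("labels must be motif codes in 0..6")
    }
  }
  validate_events(s$events)
  invisible(s)
}

#' Empty trial event table
#' @return zero-row events data.frame with the canonical columns.
#' @export
empty_events <- function() {
  data.frame(trial_index = integer(), water_time = numeric(),
             response_window = numeric(), condition = character(),
             laser_on = numeric(), laser_off = numeric(),
             laser_intensity_mW = numeric(), laser_frequency_Hz = numeric(),
             laser_pulse_ms = numeric(),
             pseudo_on = numeric(), pseudo_off = numeric(),
             stringsAsFactors = FALSE)
}

validate_events <- function(ev) {
  if (nrow(ev) == 0) return(invisible(ev))
  if (any(!is.finite(ev$water_time))) stop("water_time must be finite")
  if (is.unsorted(ev$water_time, strictly = TRUE)) {
    stop("water_time must be strictly increasing across trials")
  }
  if (any(ev$response_window <= 0, na.rm = TRUE)) {
    stop("response_window must be > 0")
  }
  has_on <- !is.na(ev$laser_on)
  has_off <- !is.na(ev$laser_off)
  if (any(has_on & has_off & ev$laser_off < ev$laser_on)) {
    stop("laser_off must be >= laser_on")
  }
  # intensity etc. given but window incomplete -> refuse
  partial <- (!is.na(ev$laser_intensity_mW) | !is.na(ev$laser_frequency_Hz) |
                !is.na(ev$laser_pulse_ms) | has_on) & !has_off
  partial <- partial | (has_off & !has_on)
  if (any(partial)) {
    stop("laser fields present without complete laser_on/laser_off window ",
         "(trials ", paste(which(partial), collapse = ", "), ")")
  }
  invisible(ev)
}

REQUIRED_BODYPARTS <- c("digit2", "digit3", "digit4", "paw", "mouth", "nose")

#' Read a keypoint-tracker pose table for one camera
#'
#' Accepts the de-facto keypoint-tracker export dialect (CSV with a 3-row
#' header: tracker scorer, bodypart, coordinate in x/y/likelihood) or a plain
#' long-format CSV with columns `frame, bodypart, x, y, confidence`.
#' Confidence values are clamped to `[0, 1]` (with a warning when clamping
#' occurred); missing required bodyparts raise a format error naming them.
#'
#' @param path CSV file path.
#' @param camera_id identifier stored on the result (`side` or `front`).
#' @param required character vector of bodyparts that must be present.
#' @return named list of per-bodypart data.frames (`x`, `y`, `confidence`)
#'   of uniform length, with attribute `camera_id`.
#' @export
read_pose_table <- function(path, camera_id,
                            required = REQUIRED_BODYPARTS) {
  if (!file.exists(path)) stop("pose file does not exist: ", path)
  head3 <- readLines(path, n = 3L)
  multi <- length(head3) >= 3 &&
    all(strsplit(head3[3], ",")[[1]][-1] %in% c("x", "y", "likelihood",
                                                "confidence"))
  tracks <- if (multi) {
    bp_row <- strsplit(head3[2], ",")[[1]][-1]
    co_row <- strsplit(head3[3], ",")[[1]][-1]
    dat <- utils::read.csv(path, skip = 3, header = FALSE)
    dat <- dat[, -1, drop = FALSE]  # frame index column
    if (ncol(dat) != length(bp_row)) {
      stop("ragged pose table: ", ncol(dat), " data columns for ",
           length(bp_row), " header columns")
    }
    out <- list()
    for (bp in unique(bp_row)) {
      sel <- which(bp_row == bp)
      cols <- co_row[sel]
      if (!all(c("x", "y") %in% cols)) {
        stop("bodypart ", bp, " lacks x/y columns")
      }
      conf_col <- sel[cols %in% c("likelihood", "confidence")]
      out[[bp]] <- data.frame(
        x = as.numeric(dat[[sel[cols == "x"]]]),
        y = as.numeric(dat[[sel[cols == "y"]]]),
        confidence = if (length(conf_col)) as.numeric(dat[[conf_col[1]]]) else 1
      )
    }
    out
  } else {
    dat <- utils::read.csv(path)
    need <- c("frame", "bodypart", "x", "y", "confidence")
    if (!all(need %in% names(dat))) {
      stop("long-format pose table must have columns: ",
           paste(need, collapse = ", "))
    }
    nper <- table(dat$bodypart)
    if (length(unique(nper)) != 1) stop("ragged pose table: unequal rows per bodypart")
    out <- lapply(split(dat, dat$bodypart), function(d) {
      d <- d[order(d$frame), ]
      data.frame(x = d$x, y = d$y, confidence = d$confidence)
    })
    out
  }
  missing_bp <- setdiff(required, names(tracks))
  if (length(missing_bp)) {
    stop("pose table missing required bodypart(s): {",
         paste(missing_bp, collapse = ", "), "}")
  }
  n <- unique(vapply(tracks, nrow, 1L))
  if (length(n) != 1) stop("ragged pose table: bodyparts differ in length")
  clamped <- FALSE
  tracks <- lapply(tracks, function(tr) {
    if (any(tr$confidence < 0 | tr$confidence > 1, na.rm = TRUE)) clamped <<- TRUE
    tr$confidence <- pmin(pmax(tr$confidence, 0), 1)
    tr
  })
  if (clamped) warning("confidence values outside [0, 1] were clamped")
  attr(tracks, "camera_id") <- camera_id
  tracks
}

#' Read a trial event table
#'
#' One row per trial from CSV (or JSON if the path ends in `.json` and
#' jsonlite is available). Recognized columns: `water_time` (required),
#' `response_window` (default 7 s), `condition`, `laser_on`, `laser_off`,
#' `laser_intensity_mW`, `laser_frequency_Hz`, `laser_pulse_ms`. Trials with
#' no laser fields default to condition `control`. Non-monotonic water times
#' or inverted/incomplete laser windows raise validation errors.
#'
#' @param path file path.
#' @return events data.frame sorted by `water_time`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file does not exist: ", path)
  dat <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite is required to read JSON event tables")
    }
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path)
  }
  as_events(dat)
}

#' Coerce a data.frame to a canonical trial event table
#'
#' @param dat data.frame with at least `water_time`.
#' @return validated events data.frame with all canonical columns.
#' @export
as_events <- function(dat) {
  if (!"water_time" %in% names(dat)) stop("events need a water_time column")
  ev <- empty_events()[seq_len(nrow(dat)), ]
  rownames(ev) <- NULL
  ev$water_time <- as.numeric(dat$water_time)
  ev$response_window <- if ("response_window" %in% names(dat)) {
    as.numeric(dat$response_window)
  } else 7
  for (col in c("laser_on", "laser_off", "laser_intensity_mW",
                "laser_frequency_Hz", "laser_pulse_ms",
                "pseudo_on", "pseudo_off")) {
    ev[[col]] <- if (col %in% names(dat)) as.numeric(dat[[col]]) else NA_real_
  }
  ev$condition <- if ("condition" %in% names(dat)) {
    as.character(dat$condition)
  } else {
    ifelse(is.na(ev$laser_on), "control", "stim")
  }
  ord <- order(ev$water_time)
  ev <- ev[ord, ]
  ev$trial_index <- seq_len(nrow(ev))
  rownames(ev) <- NULL
  validate_events(ev)
  ev
}

SESSION_SCHEMA_VERSION <- 1L

#' Persist / restore a session
#'
#' `write_session()` serializes the whole session (all groups: tracks,
#' events, labels, neural recordings, metadata) into a single versioned
#' container file; `read_session()` restores it with a round-trip that is
#' bit-identical for every numeric field. A schema-version mismatch or a
#' corrupted container raises an explicit error rather than a silent partial
#' load.
#'
#' @param session a `reach_session`.
#' @param path container file path.
#' @return `read_session()` returns the `reach_session`;
#'   `write_session()` returns `path` invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "reach_session"))
  envelope <- list(format = "reachmotif-session",
                   schema_version = SESSION_SCHEMA_VERSION,
                   session = unclass(session))
  saveRDS(envelope, path, version = 3)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("session container does not exist: ", path)
  envelope <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupted session container (", conditionMessage(e), ")")
  })
  if (!is.list(envelope) || !identical(envelope$format, "reachmotif-session")) {
    stop("corrupted session container: not a reachmotif session file")
  }
  if (!identical(envelope$schema_version, SESSION_SCHEMA_VERSION)) {
    stop("session container schema version ", envelope$schema_version,
         " does not match supported version ", SESSION_SCHEMA_VERSION)
  }
  s <- structure(envelope$session, class = "reach_session")
  validate_session(s)
  s
}

#' Mark low-confidence keypoints missing and interpolate short gaps
#'
#' Coordinates whose confidence falls below `threshold` are set to `NA`,
#' then gaps of at most `max_gap` frames are filled by linear interpolation;
#' longer gaps are left missing so downstream operations can skip those
#' frames. Standard pose-tracking hygiene.
#'
#' @param track data.frame with `x`, `y`, `confidence`.
#' @param threshold confidence threshold (default 0.6).
#' @param max_gap maximum gap length to interpolate, in frames (default 10).
#' @return track with low-confidence coordinates interpolated or `NA`.
#' @export
impute_track <- function(track, threshold = 0.6, max_gap = 10L) {
  bad <- track$confidence < threshold
  for (col in c("x", "y")) {
    v <- track[[col]]
    v[bad] <- NA_real_
    track[[col]] <- fill_gaps(v, max_gap)
  }
  track
}

# linear interpolation of NA runs no longer than max_gap
fill_gaps <- function(v, max_gap) {
  if (!anyNA(v)) return(v)
  idx <- which(!is.na(v))
  if (length(idx) < 2) return(v)
  filled <- stats::approx(idx, v[idx], xout = seq_along(v), rule = 1)$y
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep_na <- r$values & r$lengths > max_gap
  for (k in which(keep_na)) filled[starts[k]:ends[k]] <- NA_real_
  ifelse(is.na(v), filled, v)
}
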