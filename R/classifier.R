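#' Motif classifier configuration
#'
#' @param hidden_units GRU hidden-layer size (default 256).
#' @param chunk_len training chunk length in frames (default 1000); the
#'   hidden state is reset at every chunk boundary, and chunks never cross
#'   trial boundaries when frame groups are supplied.
#' @param batch_size chunks per gradient step.
#' @param epochs maximum training epochs.
#' @param learning_rate Adam learning rate.
#' @param patience early-stopping patience on held-out loss.
#' @param val_fraction fraction of trials held out (split by whole trials,
#'   never by frames).
#' @param class_weights optional length-7 positive weights; default
#'   inverse-frequency (NoReach dominates the frame count).
#' @param min_bout_ms post-hoc smoothing threshold: predicted bouts shorter
#'   than this are absorbed into the longer neighbouring bout.
#' @param seed RNG seed for initialization and batch order.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(hidden_units = 256, chunk_len = 1000,
                              batch_size = 8, epochs = 20,
                              learning_rate = 2e-3, patience = 5,
                              val_fraction = 0.2, class_weights = NULL,
                              min_bout_ms = 20, seed = 1L) {
  stopifnot(hidden_units > 0, chunk_len > 0, min_bout_ms >= 0)
  structure(list(hidden_units = as.integer(hidden_units),
                 n_classes = 7L, chunk_len = as.integer(chunk_len),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 val_fraction = val_fraction, class_weights = class_weights,
                 min_bout_ms = min_bout_ms, seed = as.integer(seed)),
            class = "classifier_config")
}

# split frames into fixed-length chunks that never cross group boundaries;
# short tails are padded with zero features and ignore-label -1
make_chunks <- function(x, y, groups, chunk_len) {
  n <- nrow(x)
  if (is.null(groups)) groups <- rep(1L, n)
  stopifnot(length(y) == n, length(groups) == n)
  runs <- rle(as.integer(groups))
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  idx_list <- list(); grp <- integer(0)
  for (k in seq_along(starts)) {
    fr <- starts[k]:ends[k]
    nchunk <- ceiling(length(fr) / chunk_len)
    for (c0 in seq_len(nchunk)) {
      lo <- (c0 - 1L) * chunk_len + 1L
      hi <- min(c0 * chunk_len, length(fr))
      idx_list[[length(idx_list) + 1]] <- fr[lo:hi]
      grp <- c(grp, runs$values[k])
    }
  }
  nc <- length(idx_list)
  X <- array(0, dim = c(chunk_len, ncol(x), nc))
  Y <- matrix(-1L, chunk_len, nc)
  for (c0 in seq_len(nc)) {
    fr <- idx_list[[c0]]
    X[seq_along(fr), , c0] <- x[fr, ]
    Y[seq_along(fr), c0] <- y[fr]
  }
  list(X = X, Y = Y, chunk_group = grp, frame_index = idx_list)
}

#' Train the GRU motif classifier
#'
#' Unidirectional recurrent network (input -> GRU -> per-frame linear ->
#' softmax) trained with class-weighted cross-entropy on fixed-length
#' chunks, Adam optimization and early stopping on held-out loss. The
#' held-out split is by whole trials. Deterministic given `config$seed`.
#'
#' @param x frames x features matrix (z-normalized; see [build_features()]).
#' @param y integer motif codes 0--6 per frame.
#' @param config a [classifier_config()].
#' @param groups optional per-frame trial identifier; chunks and the
#'   held-out split respect these boundaries.
#' @return object of class `motif_gru`: fitted `params`, `feature_names`,
#'   `history` (per-epoch losses and held-out accuracy), `config`.
#' @export
train_motif_classifier <- function(x, y, config = classifier_config(),
                                   groups = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.integer(y)
  if (any(y < 0 | y > 6, na.rm = TRUE)) stop("labels must be motif codes 0..6")
  y[is.na(y)] <- -1L
  present <- sort(unique(y[y >= 0]))
  if (length(present) < 1) stop("no labeled frames")

  cw <- config$class_weights
  if (is.null(cw)) {
    # square-root inverse-frequency: counteracts the NoReach frame majority
    # without the rare-class overcalling that full inverse weighting causes
    counts <- tabulate(y[y >= 0] + 1L, nbins = 7L)
    cw <- ifelse(counts > 0, sqrt(sum(counts) / (7 * pmax(counts, 1))), 0)
  }
  if (any(cw == 0)) {
    warning("class(es) absent from training data get zero weight: ",
            paste(MOTIFS[cw == 0], collapse = ", "))
  }
  cw <- cw / mean(cw[cw > 0])

  ch <- make_chunks(x, y, groups, config$chunk_len)
  nc <- dim(ch$X)[3]
  set.seed(config$seed)
  ug <- unique(ch$chunk_group)
  nval <- if (length(ug) > 1) max(1L, floor(config$val_fraction * length(ug))) else 0L
  val_groups <- if (nval > 0) sample(ug, nval) else integer(0)
  val_idx <- which(ch$chunk_group %in% val_groups) - 1L
  train_idx <- which(!ch$chunk_group %in% val_groups) - 1L

  H <- config$hidden_units; Fd <- ncol(x)
  r1 <- 1 / sqrt(Fd); r2 <- 1 / sqrt(H)
  params <- list(
    Wx = matrix(stats::runif(Fd * 3 * H, -r1, r1), Fd, 3 * H),
    Wh = matrix(stats::runif(H * 3 * H, -r2, r2), H, 3 * H),
    b = rep(0, 3 * H),
    Wo = matrix(stats::runif(H * 7, -r2, r2), H, 7),
    bo = rep(0, 7))
  order <- t(vapply(seq_len(config$epochs),
                    function(e) sample(seq_along(train_idx)) - 1L,
                    integer(length(train_idx))))

  fit <- gru_train_cpp(params, ch$X, ch$Y, train_idx, val_idx, order, cw,
                       config$batch_size, config$learning_rate,
                       config$patience)
  if (any(!is.finite(unlist(fit$train_loss)))) {
    stop("training diverged: non-finite loss (history: ",
         paste(signif(unlist(fit$train_loss), 4), collapse = ", "), ")")
  }
  structure(list(
    params = fit$params,
    feature_names = colnames(x),
    class_weights = cw,
    config = config,
    history = data.frame(epoch = seq_along(fit$train_loss),
                         train_loss = unlist(fit$train_loss),
                         val_loss = unlist(fit$val_loss),
                         val_accuracy = unlist(fit$val_accuracy)),
    best_epoch = fit$best_epoch,
    val_groups = val_groups
  ), class = "motif_gru")
}

#' @export
print.motif_gru <- function(x, ...) {
  cat(sprintf("<motif_gru> %d hidden units, %d features, best epoch %d\n",
              x$config$hidden_units, length(x$feature_names), x$best_epoch))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final val loss %.4f, val accuracy %.3f\n",
                last$val_loss, last$val_accuracy))
  }
  invisible(x)
}

#' Predict per-frame motif labels
#'
#' Returns per-frame class probabilities (rows summing to 1), their argmax
#' labels, and smoothed labels in which predicted bouts shorter than
#' `min_bout_ms` are absorbed into the longer neighbouring bout.
#'
#' @param model a `motif_gru`.
#' @param x frames x features matrix with the training feature columns.
#' @param groups optional per-frame trial identifier (hidden state resets
#'   at boundaries).
#' @param fs frame rate, used to convert `min_bout_ms` to frames.
#' @return list with `prob` (frames x 7), `labels`, `smoothed`.
#' @export
predict_motifs <- function(model, x, groups = NULL, fs = 500) {
  stopifnot(inherits(model, "motif_gru"))
  if (!identical(colnames(x), model$feature_names)) {
    stop("feature names differ from training: ",
         paste(symdiff_chr(colnames(x), model$feature_names), collapse = ", "))
  }
  ch <- make_chunks(x, rep(0L, nrow(x)), groups, model$config$chunk_len)
  pr <- gru_predict_cpp(model$params, ch$X)
  prob <- matrix(NA_real_, nrow(x), 7)
  for (c0 in seq_len(dim(pr)[3])) {
    fr <- ch$frame_index[[c0]]
    prob[fr, ] <- pr[seq_along(fr), , c0]
  }
  colnames(prob) <- MOTIFS
  labels <- max.col(prob, ties.method = "first") - 1L
  min_frames <- ceiling(model$config$min_bout_ms / 1000 * fs)
  smoothed <- smooth_labels(labels, min_frames, groups)
  list(prob = prob, labels = labels, smoothed = smoothed)
}

#' Absorb label bouts shorter than a threshold
#'
#' Repeatedly merges the shortest run below `min_frames` into its longer
#' neighbour (ties and edges merge into the preceding run) until every run
#' reaches the threshold. Idempotent. When `groups` is supplied, smoothing
#' is applied within each group independently.
#'
#' @param labels integer label vector.
#' @param min_frames minimum run length to keep.
#' @param groups optional per-frame group (trial) identifier.
#' @return smoothed integer labels.
#' @export
smooth_labels <- function(labels, min_frames, groups = NULL) {
  if (min_frames <= 1) return(labels)
  if (!is.null(groups)) {
    out <- labels
    for (g in unique(groups)) {
      sel <- groups == g
      out[sel] <- smooth_labels(labels[sel], min_frames)
    }
    return(out)
  }
  r <- rle(labels)
  vals <- r$values; lens <- r$lengths
  while (length(lens) > 1) {
    short <- which(lens < min_frames)
    if (!length(short)) break
    i <- short[which.min(lens[short])]
    left <- if (i > 1) lens[i - 1] else -Inf
    right <- if (i < length(lens)) lens[i + 1] else -Inf
    j <- if (left >= right) i - 1L else i + 1L
    # absorb run i into run j, then collapse any equal-valued neighbours
    lens[j] <- lens[j] + lens[i]
    vals <- vals[-i]; lens <- lens[-i]
    k <- 1L
    while (k < length(vals)) {
      if (vals[k] == vals[k + 1]) {
        lens[k] <- lens[k] + lens[k + 1]
        vals <- vals[-(k + 1)]; lens <- lens[-(k + 1)]
      } else k <- k + 1L
    }
  }
  inverse.rle(list(values = vals, lengths = lens))
}

#' Evaluate frame-wise predictions against reference labels
#'
#' @param pred,truth integer label vectors of equal length.
#' @param k boundary tolerance in frames: a frame counts as
#'   boundary-tolerant-correct when the predicted label occurs in the
#'   reference within +/- `k` frames.
#' @return list: `accuracy`, `boundary_accuracy`, `confusion` (7x7,
#'   reference rows x prediction columns), `per_class` (precision, recall,
#'   F1 per motif).
#' @export
evaluate_motifs <- function(pred, truth, k = 5L) {
  if (length(pred) != length(truth)) {
    stop("length mismatch: pred ", length(pred), " vs truth ", length(truth))
  }
  n <- length(pred)
  lv <- 0:6
  confusion <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  dimnames(confusion) <- list(truth = MOTIFS, pred = MOTIFS)
  acc <- mean(pred == truth)
  ok <- pred == truth
  for (off in setdiff(-k:k, 0)) {
    if (off > 0) {
      ok[1:(n - off)] <- ok[1:(n - off)] |
        (pred[1:(n - off)] == truth[(1 + off):n])
    } else {
      ok[(1 - off):n] <- ok[(1 - off):n] |
        (pred[(1 - off):n] == truth[1:(n + off)])
    }
  }
  tp <- diag(confusion)
  prec <- tp / pmax(colSums(confusion), 1)
  rec <- tp / pmax(rowSums(confusion), 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = acc, boundary_accuracy = mean(ok),
       confusion = confusion,
       per_class = data.frame(motif = MOTIFS, precision = as.numeric(prec),
                              recall = as.numeric(rec), f1 = as.numeric(f1)))
}
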