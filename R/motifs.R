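#' Motif label set
#'
#' The water-reaching sequence is segmented into six stereotyped motor motifs
#' (Lift, Reach, Open, Grasp, Retract, Drink) plus a background NoReach state.
#' Labels are stored as integer codes 0--6 with NoReach = 0.
#'
#' @format Character vector of the seven state names, in code order.
#' @export
MOTIFS <- c("NoReach", "Lift", "Reach", "Open", "Grasp", "Retract", "Drink")

#' Number of motif classes (including NoReach)
#' @export
N_MOTIFS <- 7L

#' Convert between motif codes and names
#'
#' @param x integer codes 0--6 or character names.
#' @return `motif_name()` returns character names for integer codes;
#'   `motif_code()` returns integer codes for names.
#' @examples
#' motif_name(0:6)
#' motif_code(c("Lift", "Drink"))
#' @export
motif_name <- function(x) {
  stopifnot(is.numeric(x))
  if (any(!is.na(x) & (x < 0 | x > 6))) stop("motif codes must be in 0..6")
  MOTIFS[as.integer(x) + 1L]
}

#' @rdname motif_name
#' @export
motif_code <- function(x) {
  i <- match(x, MOTIFS)
  if (anyNA(i) && !anyNA(x)) {
    stop("unknown motif name(s): ", paste(unique(x[is.na(i)]), collapse = ", "))
  }
  i - 1L
}

# movement motifs eligible for pulse-coincidence grouping (Lift..Retract)
MOVEMENT_MOTIFS <- 1:5
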