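# Posture normalization and the triadic score colormap.
#
# The latent model is trained on joint vectors mapped to the unit interval
# by an invertible per-dimension min-max function fn; maps invert it before
# scoring decoded postures. Two sources of ranges: fixed joint limits
# (task-independent, always invertible) or calibration over a dataset.

#' Posture normalization specification
#'
#' @param lo,hi per-dimension lower/upper bounds (radians), equal length.
#' @param location_max optional named per-location maxima for local-score
#'   normalization.
#' @return object of class `lem_norm` with `fn` and `fn_inv` semantics via
#'   [normalize_postures()] / [denormalize_postures()].
#' @export
norm_spec <- function(lo, hi, location_max = NULL) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (length(lo) != length(hi)) stop("lo and hi must have equal length")
  if (any(!(hi > lo))) stop("each dimension must have max > min")
  structure(list(lo = lo, hi = hi, location_max = location_max),
            class = "lem_norm")
}

#' @export
print.lem_norm <- function(x, ...) {
  cat("Posture normalization over", length(x$lo), "dimensions\n")
  invisible(x)
}

#' Fixed normalization from joint range of motion
#'
#' Uses the documented joint limits ([joint_limit_table()]) as per-dimension
#' bounds; task-independent and always invertible.
#'
#' @param model a `lem_skeleton` (human layout).
#' @return a `lem_norm` over the model's joint vector.
#' @export
joint_limit_normalization <- function(model = lemr_model()) {
  lim <- joint_limit_table()
  lo <- numeric(model$n_dof); hi <- numeric(model$n_dof)
  for (i in seq_len(nrow(lim))) {
    base <- model$q_start[match(lim$name[i], model$names)]
    lo[base + 1:3] <- c(lim$flex_lo[i], lim$abd_lo[i], lim$rot_lo[i])
    hi[base + 1:3] <- c(lim$flex_hi[i], lim$abd_hi[i], lim$rot_hi[i])
  }
  norm_spec(lo * pi / 180, hi * pi / 180)
}

#' Calibrate a normalization from data
#'
#' Offline calibration: per-dimension min/max over a posture dataset, and
#' per-location maxima of local scores when provided. Dimensions that do
#' not move in the dataset (range below `eps`) are widened symmetrically by
#' `pad` radians so the spec stays invertible; a dataset of fewer than two
#' postures is rejected.
#'
#' @param Q n x n_dof matrix of joint vectors (radians).
#' @param local optional data.frame of local scores ([local_scores()]).
#' @param pad widening applied to degenerate dimensions (radians).
#' @param eps degeneracy threshold on the per-dimension range.
#' @return a `lem_norm`.
#' @export
calibrate_normalization <- function(Q, local = NULL, pad = 0.01,
                                    eps = 1e-8) {
  if (is.null(dim(Q))) Q <- matrix(Q, 1)
  if (nrow(Q) < 2)
    stop("calibration needs at least two postures (degenerate min = max)")
  lo <- apply(Q, 2, min); hi <- apply(Q, 2, max)
  deg <- which(hi - lo < eps)
  if (length(deg) > 0) {
    warning(length(deg), " static dimensions widened by +/-", pad, " rad")
    lo[deg] <- lo[deg] - pad; hi[deg] <- hi[deg] + pad
  }
  lm <- if (!is.null(local)) vapply(local, max, 0) else NULL
  norm_spec(lo, hi, location_max = lm)
}

#' Normalize / denormalize joint vectors
#'
#' `normalize_postures` applies fn(q) = (q - lo) / (hi - lo) per dimension;
#' `denormalize_postures` is its exact inverse.
#'
#' @param Q n x n_dof matrix (or single vector) of joint angles (radians)
#'   resp. normalized values.
#' @param spec a `lem_norm`.
#' @return matrix of the same shape.
#' @export
normalize_postures <- function(Q, spec) {
  single <- is.null(dim(Q))
  if (single) Q <- matrix(Q, 1)
  out <- sweep(sweep(Q, 2, spec$lo, "-"), 2, spec$hi - spec$lo, "/")
  if (single) out[1, ] else out
}

#' @rdname normalize_postures
#' @export
denormalize_postures <- function(Q, spec) {
  single <- is.null(dim(Q))
  if (single) Q <- matrix(Q, 1)
  out <- sweep(sweep(Q, 2, spec$hi - spec$lo, "*"), 2, spec$lo, "+")
  if (single) out[1, ] else out
}

#' Normalize local scores by task maxima
#'
#' Maps each location's score to [0, 1] with the RULA floor 1 as minimum
#' and the calibrated task maximum for that location as maximum; scores
#' above the calibration maximum clamp to 1.
#'
#' @param scores data.frame of local scores ([local_scores()]).
#' @param spec a `lem_norm` whose `location_max` covers the columns.
#' @return data.frame of values in [0, 1].
#' @export
normalize_scores <- function(scores, spec) {
  if (is.null(spec$location_max)) stop("spec carries no location maxima")
  out <- scores
  for (nm in names(scores)) {
    mx <- spec$location_max[[nm]]
    if (is.null(mx) || is.na(mx)) stop("no maximum for location ", nm)
    if (mx <= 1) stop("location maximum must exceed the score floor 1")
    out[[nm]] <- pmin(pmax((scores[[nm]] - 1) / (mx - 1), 0), 1)
  }
  out
}

#' Triadic score colormap
#'
#' Piecewise-linear green-yellow-red map on [0, 1]: 0 is pure green
#' (0,255,0), 0.5 pure yellow (255,255,0), 1 pure red (255,0,0).
#'
#' @param v numeric vector in [0, 1] (values outside clamp).
#' @return integer matrix n x 3 (R, G, B in 0..255).
#' @export
score_to_color <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  r <- round(255 * pmin(2 * v, 1))
  g <- round(255 * pmin(2 * (1 - v), 1))
  cbind(R = as.integer(r), G = as.integer(g), B = 0L)
}
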