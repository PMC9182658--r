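# Synthetic whole-body motion generator.
#
# Keyframed archetypes of industrial activities (pick-and-place, stooped
# lifting, squatting, overhead work, carrying, walking) interpolated with
# cubic ease-in/ease-out segments (zero velocity at keyframes), plus
# truncated Gaussian angle noise. The keyframe angles are chosen to land
# squarely inside named RULA bands (stoop: 70 deg trunk flexion, past the
# >60 deg top band; squat: 90 deg knees; overhead: 150 deg shoulder
# flexion, past the >90 deg top band) so the generated data carries the
# ergonomic contrast the latent map must learn. This generator stands in
# for recorded motion-capture data in all tests and examples.

keyframe_angles <- function() {
  list(
    neutral = c(),
    stoop = c(l5.flex = 30, l3.flex = 20, t12.flex = 20, neck.flex = 15,
              thigh_r.flex = 40, thigh_l.flex = 40, shank_r.flex = 10,
              shank_l.flex = 10, upperarm_r.flex = 30, upperarm_l.flex = 30,
              forearm_r.flex = 20, forearm_l.flex = 20),
    squat = c(thigh_r.flex = 90, thigh_l.flex = 90, shank_r.flex = 90,
              shank_l.flex = 90, l5.flex = 10, l3.flex = 10,
              upperarm_r.flex = 40, upperarm_l.flex = 40,
              forearm_r.flex = 30, forearm_l.flex = 30,
              foot_r.flex = -20, foot_l.flex = -20),
    overhead = c(upperarm_r.flex = 150, upperarm_l.flex = 150,
                 clavicle_r.abd = -15, clavicle_l.abd = 15,
                 forearm_r.flex = 10, forearm_l.flex = 10,
                 neck.flex = -15, l5.flex = -5),
    carry = c(forearm_r.flex = 90, forearm_l.flex = 90,
              upperarm_r.flex = 15, upperarm_l.flex = 15, l5.flex = 5),
    walk_a = c(thigh_r.flex = 25, shank_r.flex = 15, thigh_l.flex = -10,
               shank_l.flex = 5, upperarm_r.flex = -15,
               upperarm_l.flex = 20, forearm_r.flex = 15,
               forearm_l.flex = 15),
    walk_b = c(thigh_l.flex = 25, shank_l.flex = 15, thigh_r.flex = -10,
               shank_r.flex = 5, upperarm_l.flex = -15,
               upperarm_r.flex = 20, forearm_l.flex = 15,
               forearm_r.flex = 15)
  )
}

#' Canonical posture keyframes
#'
#' Named archetype postures used by the motion generator: `neutral`
#' standing, `stoop` (70 deg total trunk flexion), `squat` (90 deg knees),
#' `overhead` (150 deg shoulder flexion), `carry` (elbows at 90 deg),
#' and the `walk_a` / `walk_b` stride pair.
#'
#' @param model a `lem_skeleton` (joint layout).
#' @return named list of `lem_posture` objects.
#' @export
keyframe_library <- function(model = lemr_model()) {
  lapply(keyframe_angles(), function(a) {
    q <- numeric(model$n_dof)
    if (length(a) > 0) {
      parts <- strsplit(names(a), ".", fixed = TRUE)
      for (i in seq_along(a)) {
        q[q_index(model, parts[[i]][1], parts[[i]][2])] <- a[[i]] * pi / 180
      }
    }
    posture(q)
  })
}

activity_cycles <- function() {
  list(
    neutral = c("neutral", "neutral"),
    stoop = c("neutral", "stoop", "stoop", "neutral"),
    squat = c("neutral", "squat", "squat", "neutral"),
    overhead = c("neutral", "overhead", "overhead", "neutral"),
    carry = c("neutral", "carry", "carry", "neutral"),
    pick_place = c("neutral", "stoop", "carry", "overhead", "neutral"),
    walk = c("walk_a", "walk_b", "walk_a", "walk_b", "walk_a")
  )
}

#' Names of the generated activities
#' @return character vector.
#' @export
activities <- function() names(activity_cycles())

# clamp a joint matrix to the joint limits (radians)
clamp_to_limits <- function(Q, model) {
  lim <- joint_limit_table()
  for (i in seq_len(nrow(lim))) {
    b <- model$q_start[match(lim$name[i], model$names)]
    lohj <- rbind(c(lim$flex_lo[i], lim$flex_hi[i]),
                  c(lim$abd_lo[i], lim$abd_hi[i]),
                  c(lim$rot_lo[i], lim$rot_hi[i])) * pi / 180
    for (k in 1:3)
      Q[, b + k] <- pmin(pmax(Q[, b + k], lohj[k, 1]), lohj[k, 2])
  }
  Q
}

#' Generate a synthetic motion sequence
#'
#' Interpolates the activity's keyframe cycle with cubic ease-in/ease-out
#' segments (zero velocity at every keyframe) sampled at a uniform rate,
#' and adds zero-mean joint-angle noise truncated at three standard
#' deviations, clamped to the joint limits. Seeded and reproducible.
#'
#' @param activity one of [activities()].
#' @param duration sequence duration (s).
#' @param rate sampling rate (Hz).
#' @param noise_std joint angle noise standard deviation (rad).
#' @param seed integer seed.
#' @param model a `lem_skeleton`.
#' @return object of class `lem_motion`: `time` (s), `Q` (T x n_dof,
#'   rad), `base_pos`, `base_rpy` (T x 3), `activity`, `rate`.
#' @export
#' @examples
#' seq <- generate_sequence("stoop", duration = 4, rate = 25, seed = 2)
#' nrow(seq$Q)  # 100 frames
generate_sequence <- function(activity, duration = 10, rate = 50,
                              noise_std = 0.02, seed = 1,
                              model = lemr_model()) {
  cyc <- activity_cycles()[[activity]]
  if (is.null(cyc)) stop("unknown activity: ", activity)
  if (duration <= 0) stop("duration must be positive")
  keys <- keyframe_library(model)
  K <- do.call(rbind, lapply(keys[cyc], function(p) p$q))
  nk <- nrow(K)
  TT <- max(round(duration * rate), 1)
  tt <- (seq_len(TT) - 1) / rate
  tk <- seq(0, tt[TT], length.out = nk)
  Q <- matrix(0, TT, model$n_dof)
  seg <- pmin(findInterval(tt, tk, rightmost.closed = TRUE), nk - 1)
  u <- (tt - tk[seg]) / (tk[seg + 1] - tk[seg])
  s <- 3 * u^2 - 2 * u^3            # cubic smoothstep: zero end-velocity
  Q <- K[seg, , drop = FALSE] * (1 - s) + K[seg + 1, , drop = FALSE] * s
  if (noise_std > 0) {
    set.seed(as.integer(seed))
    noise <- matrix(rnorm(length(Q), 0, noise_std), TT)
    noise <- pmin(pmax(noise, -3 * noise_std), 3 * noise_std)
    Q <- clamp_to_limits(Q + noise, model)
  }
  structure(list(time = tt, Q = Q,
                 base_pos = matrix(0, TT, 3), base_rpy = matrix(0, TT, 3),
                 activity = activity, rate = rate, seed = as.integer(seed)),
            class = "lem_motion")
}

#' @export
print.lem_motion <- function(x, ...) {
  cat("Motion sequence: ", length(x$time), " frames @ ", x$rate, " Hz (",
      x$activity %||% "unlabelled", ")\n", sep = "")
  invisible(x)
}

#' Mirror postures left-right
#'
#' Swaps the left/right joint triplets and negates the abduction and axial
#' rotation components of every joint (the model's abduction/rotation axes
#' are defined identically on both sides, so the sagittal-plane mirror is
#' exactly this sign flip). An involution: mirroring twice recovers the
#' input.
#'
#' @param Q posture matrix (n x n_dof) or single joint vector.
#' @param model a `lem_skeleton`.
#' @return mirrored matrix of the same shape.
#' @export
mirror_postures <- function(Q, model = lemr_model()) {
  single <- is.null(dim(Q))
  if (single) Q <- matrix(Q, 1)
  out <- Q
  for (i in seq_along(model$names)) {
    if (model$ndof_seg[i] == 0) next
    nm <- model$names[i]
    tgt <- if (grepl("_r$", nm)) sub("_r$", "_l", nm)
           else if (grepl("_l$", nm)) sub("_l$", "_r", nm) else nm
    j <- match(tgt, model$names)
    cols_src <- model$q_start[j] + seq_len(model$ndof_seg[j])
    cols_dst <- model$q_start[i] + seq_len(model$ndof_seg[i])
    out[, cols_dst] <- Q[, cols_src, drop = FALSE]
    # negate abduction (2) and rotation (3)
    out[, cols_dst[2:3]] <- -out[, cols_dst[2:3], drop = FALSE]
  }
  if (single) out[1, ] else out
}

#' Augment a posture sequence
#'
#' Adds the left-right mirrored copy of every posture and the pairwise
#' midpoints of temporally adjacent postures: n input rows become
#' 2n + (n - 1) rows.
#'
#' @param Q posture matrix (n x n_dof), rows in temporal order.
#' @param model a `lem_skeleton`.
#' @return augmented posture matrix.
#' @export
augment_postures <- function(Q, model = lemr_model()) {
  if (is.null(dim(Q))) Q <- matrix(Q, 1)
  if (nrow(Q) == 0) stop("empty posture set")
  mid <- if (nrow(Q) > 1)
    (Q[-nrow(Q), , drop = FALSE] + Q[-1, , drop = FALSE]) / 2
  else NULL
  rbind(Q, mirror_postures(Q, model), mid)
}

#' Build a normalized training set of postures and scores
#'
#' Generates noisy sequences of every activity (equal shares), augments
#' them with mirrored and intermediate postures, normalizes the joint
#' vectors to the unit interval and pairs each posture with its RULA-C
#' score scaled to (0, 1] by the maximum grand score 7.
#'
#' @param n number of postures in the returned set.
#' @param seed integer seed.
#' @param norm a `lem_norm` (default: fixed joint-limit normalization).
#' @param noise_std generator noise (rad).
#' @param model a `lem_skeleton`.
#' @return list: `X` (n x n_dof normalized postures), `eps` (unit-scaled
#'   RULA-C), `Q` (raw angles, rad), `activity` (labels), `norm`.
#' @export
make_training_set <- function(n, seed = 1, norm = NULL, noise_std = 0.02,
                              model = lemr_model()) {
  if (n < 1) stop("n must be at least 1")
  if (is.null(norm)) norm <- joint_limit_normalization(model)
  acts <- activities()
  per <- ceiling(n / length(acts))
  # each activity contributes `per` rows after augmentation (3f - 1 rows
  # from f frames)
  frames <- max(20, ceiling((per + 1) / 3))
  set.seed(as.integer(seed))
  Qs <- list(); labs <- character(0)
  for (k in seq_along(acts)) {
    sq <- generate_sequence(acts[k], duration = frames / 25, rate = 25,
                            noise_std = noise_std,
                            seed = seed + 13 * k, model = model)
    Qa <- augment_postures(sq$Q, model)
    keep <- sample.int(nrow(Qa), min(per, nrow(Qa)))
    Qs[[k]] <- Qa[keep, , drop = FALSE]
    labs <- c(labs, rep(acts[k], length(keep)))
  }
  Q <- do.call(rbind, Qs)
  if (nrow(Q) > n) {
    keep <- sort(sample.int(nrow(Q), n))
    Q <- Q[keep, , drop = FALSE]; labs <- labs[keep]
  }
  X <- normalize_postures(Q, norm)
  X <- pmin(pmax(X, 0), 1)
  eps <- rula_c(Q, model = model) / 7
  list(X = X, eps = eps, Q = Q, activity = labs, norm = norm)
}
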