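# Rapid Upper Limb Assessment (RULA).
#
# The worksheet maps banded joint angles to sub-scores, combines the arm
# sub-scores through Table A and the neck/trunk/legs sub-scores through
# Table B, adds muscle-use and force/load scores, and reads the grand score
# (1-7) from Table C. Both arms are scored; the worse side is used for the
# grand score.

#' RULA worksheet tables and band definitions
#'
#' Returns the published RULA lookup tables (A: upper arm x lower arm x
#' wrist x wrist-twist; B: neck x trunk x legs; C: wrist/arm score x
#' neck/trunk/legs score) together with the joint-angle band definitions
#' (degrees) and the angle thresholds used for the posture-adjustment
#' checkboxes (shoulder raised, upper arm abducted, arm across the midline,
#' wrist deviated, neck/trunk twist and side-bend). Band edges follow the
#' worksheet; the adjustment thresholds are package choices documented here
#' because the worksheet expresses them as observer checkboxes, not angles.
#'
#' @return a list of class `rula_tables` with elements `A` (6x3x4x2 array),
#'   `B` (6x6x2 array), `C` (8x7 matrix), `bands` (per scored joint:
#'   `breaks`, `scores`, `domain`), and `adjust` (named thresholds in
#'   degrees).
#' @export
rula_tables <- function() {
  A <- array(0L, c(6, 3, 4, 2))
  fill_a <- function(ua, la, vals) {
    A[ua, la, , 1] <<- vals[c(1, 3, 5, 7)]
    A[ua, la, , 2] <<- vals[c(2, 4, 6, 8)]
  }
  fill_a(1, 1, c(1, 2, 2, 2, 2, 3, 3, 3))
  fill_a(1, 2, c(2, 2, 2, 2, 3, 3, 3, 3))
  fill_a(1, 3, c(2, 3, 3, 3, 3, 3, 4, 4))
  fill_a(2, 1, c(2, 3, 3, 3, 3, 4, 4, 4))
  fill_a(2, 2, c(3, 3, 3, 3, 3, 4, 4, 4))
  fill_a(2, 3, c(3, 4, 4, 4, 4, 4, 5, 5))
  fill_a(3, 1, c(3, 3, 4, 4, 4, 4, 5, 5))
  fill_a(3, 2, c(3, 4, 4, 4, 4, 4, 5, 5))
  fill_a(3, 3, c(4, 4, 4, 4, 4, 5, 5, 5))
  fill_a(4, 1, c(4, 4, 4, 4, 4, 5, 5, 5))
  fill_a(4, 2, c(4, 4, 4, 4, 4, 5, 5, 5))
  fill_a(4, 3, c(4, 4, 4, 5, 5, 5, 6, 6))
  fill_a(5, 1, c(5, 5, 5, 5, 5, 6, 6, 7))
  fill_a(5, 2, c(5, 6, 6, 6, 6, 7, 7, 7))
  fill_a(5, 3, c(6, 6, 6, 7, 7, 7, 7, 8))
  fill_a(6, 1, c(7, 7, 7, 7, 7, 8, 8, 9))
  fill_a(6, 2, c(8, 8, 8, 8, 8, 9, 9, 9))
  fill_a(6, 3, c(9, 9, 9, 9, 9, 9, 9, 9))

  B <- array(0L, c(6, 6, 2))
  fill_b <- function(neck, vals) {
    B[neck, , 1] <<- vals[c(1, 3, 5, 7, 9, 11)]
    B[neck, , 2] <<- vals[c(2, 4, 6, 8, 10, 12)]
  }
  fill_b(1, c(1, 3, 2, 3, 3, 4, 5, 5, 6, 6, 7, 7))
  fill_b(2, c(2, 3, 2, 3, 4, 5, 5, 5, 6, 7, 7, 7))
  fill_b(3, c(3, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7, 7))
  fill_b(4, c(5, 5, 5, 6, 6, 7, 7, 7, 7, 7, 8, 8))
  fill_b(5, c(7, 7, 7, 7, 7, 8, 8, 8, 8, 8, 8, 8))
  fill_b(6, c(8, 8, 8, 8, 8, 8, 8, 9, 9, 9, 9, 9))

  C <- matrix(c(1, 2, 3, 3, 4, 5, 5,
                2, 2, 3, 4, 4, 5, 5,
                3, 3, 3, 4, 4, 5, 6,
                3, 3, 3, 4, 5, 6, 6,
                4, 4, 4, 5, 6, 7, 7,
                4, 4, 5, 6, 6, 7, 7,
                5, 5, 6, 6, 7, 7, 7,
                5, 5, 6, 7, 7, 7, 7), 8, 7, byrow = TRUE)

  bands <- list(
    upper_arm = list(breaks = c(-20, 20, 45, 90),
                     scores = c(2, 1, 2, 3, 4), domain = c(-60, 180)),
    lower_arm = list(breaks = c(60, 100),
                     scores = c(2, 1, 2), domain = c(0, 150)),
    wrist = list(breaks = c(-15, -5, 5, 15),
                 scores = c(3, 2, 1, 2, 3), domain = c(-70, 70)),
    wrist_twist = list(breaks = c(-30, 30),
                       scores = c(2, 1, 2), domain = c(-90, 90)),
    neck = list(breaks = c(-5, 10, 20),
                scores = c(4, 1, 2, 3), domain = c(-40, 50)),
    trunk = list(breaks = c(-5, 5, 20, 60),
                 scores = c(2, 1, 2, 3, 4), domain = c(-30, 90)),
    legs = list(breaks = c(30), scores = c(1, 2), domain = c(0, 60))
  )
  storage.mode(A) <- "integer"
  storage.mode(B) <- "integer"
  storage.mode(C) <- "integer"
  adjust <- c(shoulder_raised = 10, upper_arm_abducted = 30,
              arm_across_midline = 10, wrist_deviated = 10,
              neck_twist = 20, neck_side = 20,
              trunk_twist = 20, trunk_side = 20)
  structure(list(A = A, B = B, C = C, bands = bands, adjust = adjust),
            class = "rula_tables")
}

# findInterval-based band score; angles in degrees, vectorized.
band_score <- function(x, band) {
  band$scores[findInterval(x, band$breaks) + 1L]
}

#' Scored joint angles of a posture
#'
#' Extracts from the joint vector the angle quantities the RULA worksheet
#' scores, in degrees: upper-arm flexion and outward abduction and shoulder
#' elevation per side, elbow flexion per side, wrist flexion / deviation /
#' twist per side, neck and trunk flexion / twist / side-bend (spine levels
#' summed), knee flexion per side and the stance asymmetry used for the legs
#' score. Accepts a single posture or a matrix of joint vectors.
#'
#' @param Q a `lem_posture`, a joint vector, or an n x n_dof matrix.
#' @param model a `lem_skeleton` providing the joint layout.
#' @return data.frame with one row per posture.
#' @export
rula_angles <- function(Q, model = lemr_model()) {
  if (inherits(Q, "lem_posture")) Q <- matrix(Q$q, 1)
  if (is.null(dim(Q))) Q <- matrix(Q, 1)
  if (ncol(Q) != model$n_dof) stop("joint matrix does not match model")
  deg <- 180 / pi
  qi <- function(seg, comp) Q[, q_index(model, seg, comp), drop = TRUE] * deg
  # abduction is positive toward the subject's left for every joint, so the
  # outward direction flips sign between sides; same for clavicle elevation.
  data.frame(
    ua_flex_r = qi("upperarm_r", "flex"),
    ua_flex_l = qi("upperarm_l", "flex"),
    ua_abd_out_r = -qi("upperarm_r", "abd"),
    ua_abd_out_l = qi("upperarm_l", "abd"),
    elev_r = -qi("clavicle_r", "abd"),
    elev_l = qi("clavicle_l", "abd"),
    elbow_r = qi("forearm_r", "flex"),
    elbow_l = qi("forearm_l", "flex"),
    wrist_r = qi("hand_r", "flex"),
    wrist_l = qi("hand_l", "flex"),
    wrist_dev_r = qi("hand_r", "abd"),
    wrist_dev_l = qi("hand_l", "abd"),
    wrist_twist_r = qi("hand_r", "rot"),
    wrist_twist_l = qi("hand_l", "rot"),
    neck_flex = qi("neck", "flex") + qi("head", "flex"),
    neck_rot = qi("neck", "rot") + qi("head", "rot"),
    neck_side = qi("neck", "abd") + qi("head", "abd"),
    trunk_flex = qi("l5", "flex") + qi("l3", "flex") + qi("t12", "flex") +
      qi("t8", "flex"),
    trunk_rot = qi("l5", "rot") + qi("l3", "rot") + qi("t12", "rot") +
      qi("t8", "rot"),
    trunk_side = qi("l5", "abd") + qi("l3", "abd") + qi("t12", "abd") +
      qi("t8", "abd"),
    knee_r = qi("shank_r", "flex"),
    knee_l = qi("shank_l", "flex")
  )
}

# Discrete sub-scores (with adjustments) for a batch of angle rows.
rula_subscores <- function(ang, tables) {
  b <- tables$bands; adj <- tables$adjust
  ua <- function(flex, abd_out, elev) {
    s <- band_score(flex, b$upper_arm) +
      (elev > adj[["shoulder_raised"]]) +
      (abd_out > adj[["upper_arm_abducted"]])
    pmin(s, 6L)
  }
  la <- function(flex, abd_out) {
    pmin(band_score(flex, b$lower_arm) +
           (abd_out < -adj[["arm_across_midline"]]), 3L)
  }
  wr <- function(flex, dev) {
    pmin(band_score(flex, b$wrist) +
           (abs(dev) > adj[["wrist_deviated"]]), 4L)
  }
  list(
    ua_r = ua(ang$ua_flex_r, ang$ua_abd_out_r, ang$elev_r),
    ua_l = ua(ang$ua_flex_l, ang$ua_abd_out_l, ang$elev_l),
    la_r = la(ang$elbow_r, ang$ua_abd_out_r),
    la_l = la(ang$elbow_l, ang$ua_abd_out_l),
    wr_r = wr(ang$wrist_r, ang$wrist_dev_r),
    wr_l = wr(ang$wrist_l, ang$wrist_dev_l),
    wt_r = band_score(ang$wrist_twist_r, b$wrist_twist),
    wt_l = band_score(ang$wrist_twist_l, b$wrist_twist),
    neck = pmin(band_score(ang$neck_flex, b$neck) +
                  (abs(ang$neck_rot) > adj[["neck_twist"]]) +
                  (abs(ang$neck_side) > adj[["neck_side"]]), 6L),
    trunk = pmin(band_score(ang$trunk_flex, b$trunk) +
                   (abs(ang$trunk_rot) > adj[["trunk_twist"]]) +
                   (abs(ang$trunk_side) > adj[["trunk_side"]]), 6L),
    legs = band_score(abs(ang$knee_r - ang$knee_l), b$legs)
  )
}

#' Force/load score of the RULA worksheet
#'
#' @param load handled load in kg.
#' @param static `TRUE` if the load is held statically or the action is
#'   repeated (4x/min or more).
#' @return integer score 0-3.
#' @export
rula_load_score <- function(load, static = FALSE) {
  s <- ifelse(load < 2, 0L, ifelse(load <= 10, ifelse(static, 2L, 1L), 3L))
  as.integer(s)
}

#' Discrete RULA assessment of a posture
#'
#' Scores a whole-body posture with the published RULA worksheet. Both arms
#' are scored through Table A and the worse side is carried to the grand
#' score; muscle-use and force/load scores default to a static, unloaded
#' task.
#'
#' @param post a `lem_posture` (or joint vector / matrix of joint vectors).
#' @param load handled load in kg (applies the worksheet force/load score).
#' @param static load held statically / action highly repeated.
#' @param muscle muscle-use score (0 or 1), default 0.
#' @param model a `lem_skeleton` for the joint layout.
#' @param tables a `rula_tables` object.
#' @return for a single posture, a list of class `lem_assessment` with
#'   `grand_score`, `score_a` (per side), `score_b`, `wrist_arm`,
#'   `neck_trunk_leg` and the per-joint `sub_scores`; for a matrix input,
#'   the vector of grand scores.
#' @export
#' @examples
#' model <- lemr_model()
#' p <- neutral_posture(model)
#' p$q[q_index(model, "forearm_r", "flex")] <- 80 * pi / 180
#' p$q[q_index(model, "forearm_l", "flex")] <- 80 * pi / 180
#' rula(p)$grand_score  # 1: all bands at their best
rula <- function(post, load = 0, static = FALSE, muscle = 0,
                 model = lemr_model(), tables = rula_tables()) {
  single <- inherits(post, "lem_posture") ||
    (is.null(dim(post)) && length(post) == model$n_dof)
  ang <- rula_angles(post, model)
  sc <- rula_subscores(ang, tables)
  fs <- rula_load_score(load, static) + as.integer(muscle)
  a_r <- tables$A[cbind(sc$ua_r, sc$la_r, sc$wr_r, sc$wt_r)]
  a_l <- tables$A[cbind(sc$ua_l, sc$la_l, sc$wr_l, sc$wt_l)]
  score_a <- pmax(a_r, a_l)
  score_b <- tables$B[cbind(sc$neck, sc$trunk, sc$legs)]
  wrist_arm <- pmin(score_a + fs, 8L)
  ntl <- pmin(score_b + fs, 7L)
  grand <- tables$C[cbind(pmax(wrist_arm, 1L), pmax(ntl, 1L))]
  if (!single) return(as.integer(grand))
  structure(list(grand_score = as.integer(grand),
                 score_a = c(right = a_r, left = a_l),
                 score_b = score_b,
                 wrist_arm = wrist_arm, neck_trunk_leg = ntl,
                 load_score = fs,
                 sub_scores = lapply(sc, as.integer),
                 angles = ang),
            class = "lem_assessment")
}

#' @export
print.lem_assessment <- function(x, ...) {
  cat("RULA assessment: grand score", x$grand_score, "\n")
  cat("  A (arm):", x$score_a["right"], "(R)", x$score_a["left"], "(L);",
      "B (neck/trunk/legs):", x$score_b, "; load score:", x$load_score, "\n")
  invisible(x)
}

# Cached canonical human model (joint layout provider for scoring).
.lemr_env <- new.env(parent = emptyenv())

#' Canonical digital human model
#'
#' A cached default model (1.75 m, 70 kg) used wherever only the joint
#' layout matters (scoring, motion generation).
#' @param height,mass anthropometrics; the cache is keyed on them.
#' @return a `lem_skeleton`.
#' @export
lemr_model <- function(height = 1.75, mass = 70) {
  key <- sprintf("model_%.3f_%.3f", height, mass)
  if (is.null(.lemr_env[[key]]))
    .lemr_env[[key]] <- build_skeleton(height, mass)
  .lemr_env[[key]]
}
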