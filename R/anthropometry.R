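#' Anthropometric segment table
#'
#' Returns the per-segment anthropometric coefficient table used to scale the
#' digital human model to a subject's stature and body mass. The segment set
#' follows the layout of inertial motion-capture skeletons (pelvis, five
#' spine/neck levels, head, and symmetric clavicle-arm-hand and
#' thigh-shank-foot-toe chains): 23 segments, of which 22 carry a triplet of
#' revolute joints, giving 66 actuated degrees of freedom.
#'
#' Relative segment masses are adult whole-body coefficients in the style of
#' the classical photogrammetric anthropometry literature (trunk mass split
#' across the pelvis and four spine levels); they are renormalized at build
#' time so that they sum to exactly one. Segment lengths and joint offsets
#' are fractions of stature; the stacked leg-trunk-head chain sums to 1.0 so
#' a standing model spans the subject height. Each segment is a homogeneous
#' geometric primitive (parallelepiped, cylinder or sphere) whose dimensions
#' are also stature fractions; inertia tensors follow from the primitive
#' formulas.
#'
#' Offsets are expressed in the parent segment frame with the world
#' convention x forward, y to the subject's left, z up, and the model
#' standing in the rest pose (all joint angles zero, arms hanging).
#'
#' @return A data.frame with one row per segment: `name`, `parent` (name or
#'   `NA` for the pelvis root), offset coefficients `off_x`, `off_y`,
#'   `off_z` (fractions of stature), `length_coeff`, `mass_coeff`, `shape`
#'   (`"box"`, `"cylinder"`, `"sphere"`), shape dimension coefficients
#'   `dim1`, `dim2`, `dim3`, shape axis `shape_axis`, and COM direction
#'   coefficients `com_x`, `com_y`, `com_z` (fractions of stature).
#' @export
#' @examples
#' tab <- human_segment_table()
#' nrow(tab)        # 23 segments
#' sum(tab$mass_coeff)
human_segment_table <- function() {
  seg <- function(name, parent, off, len, mass, shape, dims, axis, com) {
    data.frame(name = name, parent = parent,
               off_x = off[1], off_y = off[2], off_z = off[3],
               length_coeff = len, mass_coeff = mass, shape = shape,
               dim1 = dims[1], dim2 = dims[2], dim3 = dims[3],
               shape_axis = axis, com_x = com[1], com_y = com[2],
               com_z = com[3], stringsAsFactors = FALSE)
  }
  rows <- list(
    seg("pelvis", NA, c(0, 0, 0), 0.090, 0.1120, "box",
        c(0.11, 0.19, 0.09), "z", c(0, 0, 0.045)),
    seg("l5", "pelvis", c(0, 0, 0.078), 0.050, 0.0810, "box",
        c(0.11, 0.17, 0.05), "z", c(0, 0, 0.025)),
    seg("l3", "l5", c(0, 0, 0.050), 0.050, 0.0810, "box",
        c(0.11, 0.17, 0.05), "z", c(0, 0, 0.025)),
    seg("t12", "l3", c(0, 0, 0.050), 0.050, 0.0810, "box",
        c(0.11, 0.17, 0.05), "z", c(0, 0, 0.025)),
    seg("t8", "t12", c(0, 0, 0.050), 0.060, 0.0720, "box",
        c(0.12, 0.18, 0.06), "z", c(0, 0, 0.030)),
    seg("neck", "t8", c(0, 0, 0.060), 0.052, 0.0120, "cylinder",
        c(0.028, 0.052, 0), "z", c(0, 0, 0.026)),
    seg("head", "neck", c(0, 0, 0.052), 0.130, 0.0490, "sphere",
        c(0.065, 0, 0), "z", c(0, 0, 0.065)),
    # right arm chain
    seg("clavicle_r", "t8", c(0, -0.023, 0.055), 0.106, 0.0050, "cylinder",
        c(0.015, 0.106, 0), "y", c(0, -0.053, 0)),
    seg("upperarm_r", "clavicle_r", c(0, -0.106, 0), 0.186, 0.0270,
        "cylinder", c(0.028, 0.186, 0), "z", c(0, 0, -0.093)),
    seg("forearm_r", "upperarm_r", c(0, 0, -0.186), 0.146, 0.0160,
        "cylinder", c(0.025, 0.146, 0), "z", c(0, 0, -0.073)),
    seg("hand_r", "forearm_r", c(0, 0, -0.146), 0.108, 0.0060, "cylinder",
        c(0.020, 0.108, 0), "z", c(0, 0, -0.054)),
    # left arm chain (mirror of the right about the x-z plane)
    seg("clavicle_l", "t8", c(0, 0.023, 0.055), 0.106, 0.0050, "cylinder",
        c(0.015, 0.106, 0), "y", c(0, 0.053, 0)),
    seg("upperarm_l", "clavicle_l", c(0, 0.106, 0), 0.186, 0.0270,
        "cylinder", c(0.028, 0.186, 0), "z", c(0, 0, -0.093)),
    seg("forearm_l", "upperarm_l", c(0, 0, -0.186), 0.146, 0.0160,
        "cylinder", c(0.025, 0.146, 0), "z", c(0, 0, -0.073)),
    seg("hand_l", "forearm_l", c(0, 0, -0.146), 0.108, 0.0060, "cylinder",
        c(0.020, 0.108, 0), "z", c(0, 0, -0.054)),
    # right leg chain
    seg("thigh_r", "pelvis", c(0, -0.050, 0), 0.245, 0.1416, "cylinder",
        c(0.052, 0.245, 0), "z", c(0, 0, -0.1225)),
    seg("shank_r", "thigh_r", c(0, 0, -0.245), 0.246, 0.0433, "cylinder",
        c(0.036, 0.246, 0), "z", c(0, 0, -0.123)),
    seg("foot_r", "shank_r", c(0, 0, -0.246), 0.152, 0.0107, "box",
        c(0.10, 0.05, 0.039), "x", c(0.035, 0, -0.020)),
    seg("toe_r", "foot_r", c(0.10, 0, -0.039), 0.050, 0.0030, "box",
        c(0.05, 0.05, 0.02), "x", c(0.020, 0, 0)),
    # left leg chain
    seg("thigh_l", "pelvis", c(0, 0.050, 0), 0.245, 0.1416, "cylinder",
        c(0.052, 0.245, 0), "z", c(0, 0, -0.1225)),
    seg("shank_l", "thigh_l", c(0, 0, -0.245), 0.246, 0.0433, "cylinder",
        c(0.036, 0.246, 0), "z", c(0, 0, -0.123)),
    seg("foot_l", "shank_l", c(0, 0, -0.246), 0.152, 0.0107, "box",
        c(0.10, 0.05, 0.039), "x", c(0.035, 0, -0.020)),
    seg("toe_l", "foot_l", c(0.10, 0, -0.039), 0.050, 0.0030, "box",
        c(0.05, 0.05, 0.02), "x", c(0.020, 0, 0))
  )
  do.call(rbind, rows)
}

# Inertia tensor (3x3, about the COM, segment frame) of a homogeneous
# primitive. dims are absolute metres: box = full edge lengths (x, y, z);
# cylinder = (radius, length, unused) with `axis` its symmetry axis;
# sphere = (radius, -, -).
primitive_inertia <- function(shape, dims, axis, mass) {
  if (shape == "box") {
    a <- dims[1]; b <- dims[2]; c <- dims[3]
    return(diag(mass / 12 * c(b^2 + c^2, a^2 + c^2, a^2 + b^2)))
  }
  if (shape == "cylinder") {
    r <- dims[1]; h <- dims[2]
    i_perp <- mass * (3 * r^2 + h^2) / 12
    i_ax <- mass * r^2 / 2
    v <- switch(axis,
                x = c(i_ax, i_perp, i_perp),
                y = c(i_perp, i_ax, i_perp),
                z = c(i_perp, i_perp, i_ax))
    return(diag(v))
  }
  if (shape == "sphere") {
    return(diag(rep(2 / 5 * mass * dims[1]^2, 3)))
  }
  stop("unknown primitive shape: ", shape)
}

#' Joint range-of-motion table
#'
#' Per-segment joint limits (degrees) for the flexion, abduction and axial
#' rotation components of each joint triplet. Values are conservative adult
#' ranges of motion; they bound the synthetic motion generator, define the
#' default fixed normalization of postures to the unit interval, and supply
#' the domain over which the continuous score polynomials are fitted.
#'
#' Sign conventions follow the model axes: flexion is positive bending
#' forward for the spine/neck/head, positive raising the limb forward for
#' arms and thighs, positive knee bend for the shank, positive toes-up for
#' foot and toes. Abduction is positive toward the subject's left for all
#' joints (so outward abduction of the right limbs is negative), which makes
#' left-right mirroring a plain sign flip.
#'
#' @return data.frame with columns `name`, `flex_lo`, `flex_hi`, `abd_lo`,
#'   `abd_hi`, `rot_lo`, `rot_hi` (degrees), one row per jointed segment.
#' @export
joint_limit_table <- function() {
  lim <- function(name, flex, abd, rot) {
    data.frame(name = name, flex_lo = flex[1], flex_hi = flex[2],
               abd_lo = abd[1], abd_hi = abd[2], rot_lo = rot[1],
               rot_hi = rot[2], stringsAsFactors = FALSE)
  }
  spine <- c(-20, 35)
  rows <- list(
    lim("l5", spine, c(-20, 20), c(-25, 25)),
    lim("l3", spine, c(-20, 20), c(-25, 25)),
    lim("t12", spine, c(-20, 20), c(-25, 25)),
    lim("t8", spine, c(-20, 20), c(-25, 25)),
    lim("neck", c(-40, 50), c(-35, 35), c(-60, 60)),
    lim("head", c(-30, 30), c(-30, 30), c(-40, 40)),
    lim("clavicle_r", c(-20, 20), c(-30, 30), c(-20, 20)),
    lim("upperarm_r", c(-60, 180), c(-150, 150), c(-90, 90)),
    lim("forearm_r", c(0, 150), c(-10, 10), c(-90, 90)),
    lim("hand_r", c(-70, 70), c(-25, 25), c(-35, 35)),
    lim("clavicle_l", c(-20, 20), c(-30, 30), c(-20, 20)),
    lim("upperarm_l", c(-60, 180), c(-150, 150), c(-90, 90)),
    lim("forearm_l", c(0, 150), c(-10, 10), c(-90, 90)),
    lim("hand_l", c(-70, 70), c(-25, 25), c(-35, 35)),
    lim("thigh_r", c(-20, 120), c(-45, 45), c(-45, 45)),
    lim("shank_r", c(0, 140), c(-5, 5), c(-30, 30)),
    lim("foot_r", c(-45, 25), c(-20, 20), c(-15, 15)),
    lim("toe_r", c(-30, 60), c(-5, 5), c(-5, 5)),
    lim("thigh_l", c(-20, 120), c(-45, 45), c(-45, 45)),
    lim("shank_l", c(0, 140), c(-5, 5), c(-30, 30)),
    lim("foot_l", c(-45, 25), c(-20, 20), c(-15, 15)),
    lim("toe_l", c(-30, 60), c(-5, 5), c(-5, 5))
  )
  do.call(rbind, rows)
}
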