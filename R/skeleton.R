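# Rigid multi-body digital human model: construction and kinematics.
#
# A skeleton is a topologically ordered list of segments. Every non-root
# segment carries a joint at its origin: a chain of 1-DoF revolute joints
# (typically three: flexion, abduction, axial rotation) whose axes are given
# in the parent frame at the rest pose. The root (pelvis) is attached to the
# world through the unactuated 6-DoF floating base.

# Rodrigues rotation about a unit axis.
rot_axis <- function(a, th) {
  ct <- cos(th); st <- sin(th)
  ax <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * ct + st * ax + (1 - ct) * tcrossprod(a)
}

skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

# Extrinsic XYZ Euler angles (file convention) -> rotation matrix.
euler_xyz_to_mat <- function(e) {
  rot_axis(c(0, 0, 1), e[3]) %*% rot_axis(c(0, 1, 0), e[2]) %*%
    rot_axis(c(1, 0, 0), e[1])
}

# Standard joint axis triplet (rows: flexion, abduction, rotation) for a
# named segment under the package sign conventions (see joint_limit_table).
standard_axes <- function(name) {
  flex_neg <- c("clavicle_r", "upperarm_r", "forearm_r", "hand_r",
                "clavicle_l", "upperarm_l", "forearm_l", "hand_l",
                "thigh_r", "thigh_l", "foot_r", "foot_l", "toe_r", "toe_l")
  fl <- if (name %in% flex_neg) c(0, -1, 0) else c(0, 1, 0)
  rbind(fl, c(1, 0, 0), c(0, 0, 1))
}

#' Construct a skeleton from explicit segment specifications
#'
#' Low-level constructor used both by [build_skeleton()] and by tests that
#' need small bespoke kinematic chains (planar pendulums, two-link arms).
#'
#' @param segments list of segment specs; each a list with `name`,
#'   `parent` (name or `NA`), `offset` (3-vector, metres, in the parent
#'   frame), `axes` (k x 3 matrix of unit joint axes in the parent rest
#'   frame; k = 0 for an unjointed root), `mass` (kg), `com` (3-vector,
#'   metres, segment frame), `inertia` (3x3, kg m^2, about the COM).
#' @param height,mass subject stature (m) and body mass (kg), stored for
#'   reference.
#' @return an object of class `lem_skeleton`.
#' @export
new_skeleton <- function(segments, height = NA_real_, mass = NA_real_) {
  n <- length(segments)
  names <- vapply(segments, `[[`, "", "name")
  if (anyDuplicated(names)) stop("duplicate segment names")
  parent <- integer(n)
  for (i in seq_len(n)) {
    p <- segments[[i]]$parent
    if (is.na(p) || is.null(p)) {
      parent[i] <- 0L
    } else {
      j <- match(p, names)
      if (is.na(j)) stop("unknown parent segment: ", p)
      if (j >= i) stop("segments must be in topological order")
      parent[i] <- j
    }
    ax <- segments[[i]]$axes
    if (is.null(ax)) ax <- matrix(0, 0, 3)
    if (!is.matrix(ax)) ax <- matrix(ax, ncol = 3, byrow = TRUE)
    nrm <- sqrt(rowSums(ax^2))
    if (any(abs(nrm - 1) > 1e-9)) stop("joint axes must be unit vectors")
    segments[[i]]$axes <- ax
  }
  ndof_seg <- vapply(segments, function(s) nrow(s$axes), 0L)
  q_start <- cumsum(c(0L, ndof_seg))[seq_len(n)]
  total_mass <- sum(vapply(segments, `[[`, 0, "mass"))
  obj <- list(segments = segments, names = names, parent = parent,
              ndof_seg = ndof_seg, q_start = q_start,
              n_dof = sum(ndof_seg), height = height, mass = mass,
              total_mass = total_mass)
  class(obj) <- "lem_skeleton"
  obj
}

#' Build the anthropometric digital human model
#'
#' Scales the embedded anthropometric coefficient table
#' ([human_segment_table()]) to a subject: segment lengths and offsets are
#' fractions of stature, segment masses fractions of body mass (renormalized
#' so they sum to exactly the input mass), and inertia tensors follow from
#' homogeneous-density geometric primitives. The result is a 23-segment tree
#' with 22 joint triplets (66 revolute DoF) on a floating base.
#'
#' @param height subject stature in metres, in (1.0, 2.5).
#' @param mass subject body mass in kg, in (20, 200).
#' @return an object of class `lem_skeleton` with `n_dof = 66`.
#' @export
#' @examples
#' model <- build_skeleton(1.75, 70)
#' model$n_dof
#' sum(sapply(model$segments, `[[`, "mass"))
build_skeleton <- function(height, mass) {
  if (!is.finite(height) || height <= 1.0 || height >= 2.5)
    stop("height must be in (1.0, 2.5) m")
  if (!is.finite(mass) || mass <= 20 || mass >= 200)
    stop("mass must be in (20, 200) kg")
  tab <- human_segment_table()
  mc <- tab$mass_coeff / sum(tab$mass_coeff)  # renormalize to exactly 1
  segments <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    m_i <- mc[i] * mass
    dims <- c(r$dim1, r$dim2, r$dim3) * height
    segments[[i]] <- list(
      name = r$name,
      parent = if (is.na(r$parent)) NA_character_ else r$parent,
      offset = c(r$off_x, r$off_y, r$off_z) * height,
      axes = if (is.na(r$parent)) matrix(0, 0, 3) else standard_axes(r$name),
      mass = m_i,
      com = c(r$com_x, r$com_y, r$com_z) * height,
      inertia = primitive_inertia(r$shape, dims, r$shape_axis, m_i),
      length = r$length_coeff * height,
      shape = r$shape)
  }
  new_skeleton(segments, height = height, mass = mass)
}

#' @export
print.lem_skeleton <- function(x, ...) {
  cat("Digital human model: ", length(x$segments), " segments, ",
      x$n_dof, " actuated DoF (+6 floating base)\n", sep = "")
  if (!is.na(x$height))
    cat(sprintf("  stature %.2f m, body mass %.1f kg (segments sum %.3f kg)\n",
                x$height, x$mass, x$total_mass))
  invisible(x)
}

#' Create a whole-body posture
#'
#' A posture is the extended configuration of the model: the 6-DoF floating
#' base pose of the pelvis plus the joint angle vector.
#'
#' @param q joint angles (radians), length equal to the model's `n_dof`
#'   (66 for the human model).
#' @param base_pos pelvis position in the world frame (m).
#' @param base_rpy pelvis orientation as extrinsic XYZ Euler angles (rad).
#' @return object of class `lem_posture`.
#' @export
posture <- function(q, base_pos = c(0, 0, 0), base_rpy = c(0, 0, 0)) {
  q <- as.numeric(q)
  if (!all(is.finite(q)) || !all(is.finite(base_pos)) ||
      !all(is.finite(base_rpy)))
    stop("posture entries must be finite")
  if (length(base_pos) != 3 || length(base_rpy) != 3)
    stop("base pose must have 3 position and 3 orientation entries")
  structure(list(q = q, base_pos = as.numeric(base_pos),
                 base_rpy = as.numeric(base_rpy)), class = "lem_posture")
}

#' @export
print.lem_posture <- function(x, ...) {
  cat("Posture: ", length(x$q), " joint angles, base at (",
      paste(sprintf("%.3f", x$base_pos), collapse = ", "), ") m\n", sep = "")
  invisible(x)
}

#' Neutral (rest) posture of a model
#' @param model a `lem_skeleton`.
#' @return `lem_posture` with all joint angles zero and identity base.
#' @export
neutral_posture <- function(model) posture(rep(0, model$n_dof))

check_posture <- function(model, post) {
  if (!inherits(post, "lem_posture")) stop("not a lem_posture")
  if (length(post$q) != model$n_dof)
    stop("posture has ", length(post$q), " joint angles; model expects ",
         model$n_dof)
}

#' Index of a joint angle in the q vector
#'
#' @param model a `lem_skeleton`.
#' @param segment segment name (e.g. `"upperarm_r"`).
#' @param component one of `"flex"`, `"abd"`, `"rot"` (or an integer
#'   axis number).
#' @return integer position in `q`.
#' @export
q_index <- function(model, segment, component = "flex") {
  i <- match(segment, model$names)
  if (is.na(i)) stop("unknown segment: ", segment)
  k <- if (is.character(component))
    match(component, c("flex", "abd", "rot")) else as.integer(component)
  if (is.na(k) || k < 1 || k > model$ndof_seg[i])
    stop("invalid joint component for segment ", segment)
  model$q_start[i] + k
}

#' Forward kinematics
#'
#' Computes the world pose of every segment frame. The pelvis (root) pose
#' equals the floating-base pose; child frames are composed through the
#' fixed rest offsets and the revolute joint rotations.
#'
#' @param model a `lem_skeleton`.
#' @param post a `lem_posture` matching the model.
#' @return list with `p` (n x 3 matrix of frame origins, metres) and `R`
#'   (list of 3x3 world rotation matrices), plus `axes_w` (per segment, the
#'   world direction of each joint axis, used by Jacobians and dynamics).
#' @export
forward_kinematics <- function(model, post) {
  check_posture(model, post)
  n <- length(model$segments)
  p <- matrix(0, n, 3)
  R <- vector("list", n)
  axes_w <- vector("list", n)
  R0 <- euler_xyz_to_mat(post$base_rpy)
  for (i in seq_len(n)) {
    s <- model$segments[[i]]
    if (model$parent[i] == 0L) {
      Rp <- R0
      p[i, ] <- post$base_pos + as.numeric(Rp %*% s$offset)
    } else {
      j <- model$parent[i]
      Rp <- R[[j]]
      p[i, ] <- p[j, ] + as.numeric(Rp %*% s$offset)
    }
    k <- model$ndof_seg[i]
    Ri <- Rp
    aw <- matrix(0, k, 3)
    # R_i = R_p * prod_m rot(axis_m, q_m); the world axis of sub-joint m
    # rotates with the partial product up to m-1.
    for (m in seq_len(k)) {
      aw[m, ] <- as.numeric(Ri %*% s$axes[m, ])
      Ri <- Ri %*% rot_axis(s$axes[m, ], post$q[model$q_start[i] + m])
    }
    R[[i]] <- Ri
    axes_w[[i]] <- aw
  }
  list(p = p, R = R, axes_w = axes_w)
}

# Indices of segments on the path root -> link (inclusive).
path_to_root <- function(model, link) {
  path <- integer(0)
  i <- link
  while (i != 0L) {
    path <- c(i, path)
    i <- model$parent[i]
  }
  path
}

#' Spatial Jacobian of a segment frame
#'
#' Maps the extended velocity (base linear velocity, base angular velocity,
#' joint rates) to the spatial velocity of the segment frame origin:
#' rows 1-3 linear (m/s), rows 4-6 angular (rad/s). Columns are the 6 base
#' coordinates followed by the `n_dof` joint coordinates; columns of joints
#' not on the root-to-link path are zero.
#'
#' @param model a `lem_skeleton`.
#' @param post a `lem_posture`.
#' @param link segment index or name.
#' @param fk optional precomputed [forward_kinematics()] result.
#' @param point_offset point of interest on the link, as an offset from
#'   the link frame origin expressed in the link frame (default: the
#'   frame origin itself).
#' @return 6 x (6 + n_dof) matrix.
#' @export
link_jacobian <- function(model, post, link, fk = NULL,
                          point_offset = c(0, 0, 0)) {
  if (is.character(link)) link <- match(link, model$names)
  if (is.na(link) || link < 1 || link > length(model$segments))
    stop("invalid link")
  if (is.null(fk)) fk <- forward_kinematics(model, post)
  J <- matrix(0, 6, 6 + model$n_dof)
  pL <- fk$p[link, ] + as.numeric(fk$R[[link]] %*% point_offset)
  # floating base: v_L = v_b + w_b x (p_L - p_b)
  p_base <- post$base_pos
  J[1:3, 1:3] <- diag(3)
  J[1:3, 4:6] <- -skew(pL - p_base)
  J[4:6, 4:6] <- diag(3)
  for (i in path_to_root(model, link)) {
    k <- model$ndof_seg[i]
    if (k == 0) next
    pj <- fk$p[i, ]
    for (m in seq_len(k)) {
      a <- fk$axes_w[[i]][m, ]
      col <- 6L + model$q_start[i] + m
      J[1:3, col] <- crossprod3(a, pL - pj)
      J[4:6, col] <- a
    }
  }
  J
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Export / import a skeleton as a YAML configuration
#'
#' Writes the segment tree (names, parents, offsets, masses, COMs, inertias,
#' joint axes) to a human-readable YAML file, and reads it back into an
#' identical model.
#'
#' @param model a `lem_skeleton`.
#' @param path file path.
#' @return `read_skeleton_yaml` returns a `lem_skeleton`.
#' @export
write_skeleton_yaml <- function(model, path) {
  segs <- lapply(model$segments, function(s) {
    list(name = s$name,
         parent = if (is.na(s$parent) || is.null(s$parent)) NULL else s$parent,
         offset = as.numeric(s$offset),
         axes = if (nrow(s$axes) > 0) lapply(seq_len(nrow(s$axes)),
                                             function(m) as.numeric(s$axes[m, ]))
                else list(),
         mass = s$mass,
         com = as.numeric(s$com),
         inertia = as.numeric(s$inertia))
  })
  yaml::write_yaml(list(height = model$height, mass = model$mass,
                        segments = segs), path, precision = 15)
  invisible(path)
}

#' @rdname write_skeleton_yaml
#' @export
read_skeleton_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  segs <- lapply(cfg$segments, function(s) {
    ax <- if (length(s$axes) > 0)
      do.call(rbind, lapply(s$axes, as.numeric)) else matrix(0, 0, 3)
    list(name = s$name,
         parent = if (is.null(s$parent)) NA_character_ else s$parent,
         offset = as.numeric(s$offset), axes = ax, mass = as.numeric(s$mass),
         com = as.numeric(s$com),
         inertia = matrix(as.numeric(s$inertia), 3, 3))
  })
  new_skeleton(segs, height = cfg$height %||% NA_real_,
               mass = cfg$mass %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
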