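# Floating-base inverse dynamics and manipulability.
#
# Joint torques solve M(q)q.. + C(q,q.)q. + G(q) = S't + sum_i Jpi' f_i for
# the actuated coordinates t, with external wrenches f_i applied at segment
# frame origins in the world frame. Rather than assembling M, C and G
# explicitly, torques are computed with a recursive Newton-Euler pass over
# the tree (O(n)); equivalence with the Lagrangian form is established in
# the test suite against closed-form planar-chain oracles.

#' Extended dynamic state
#'
#' @param post a `lem_posture`.
#' @param velocity extended velocity: base linear velocity (m/s, world),
#'   base angular velocity (rad/s, world), then joint rates (rad/s).
#'   Length 6 + n_dof. Defaults to rest.
#' @param acceleration extended acceleration, same layout. Defaults to rest.
#' @return object of class `lem_state`.
#' @export
dyn_state <- function(post, velocity = NULL, acceleration = NULL) {
  n <- length(post$q) + 6L
  if (is.null(velocity)) velocity <- numeric(n)
  if (is.null(acceleration)) acceleration <- numeric(n)
  if (length(velocity) != n || length(acceleration) != n)
    stop("velocity and acceleration must have length 6 + n_dof = ", n)
  if (!all(is.finite(velocity)) || !all(is.finite(acceleration)))
    stop("non-finite state")
  structure(list(posture = post, velocity = as.numeric(velocity),
                 acceleration = as.numeric(acceleration)),
            class = "lem_state")
}

#' External wrench applied to a segment
#'
#' Force and moment in the world frame, applied at the segment frame origin.
#'
#' @param link segment name or index.
#' @param force 3-vector (N).
#' @param moment 3-vector (N m).
#' @return object of class `lem_wrench`.
#' @export
wrench <- function(link, force = c(0, 0, 0), moment = c(0, 0, 0)) {
  if (!all(is.finite(force)) || !all(is.finite(moment)))
    stop("wrench entries must be finite")
  structure(list(link = link, force = as.numeric(force),
                 moment = as.numeric(moment)), class = "lem_wrench")
}

#' Gravitational foot-wrench approximation
#'
#' Approximates the ground reaction at the feet by the body weight: vertical
#' upward forces at the foot frame origins summing to `mass * g`, zero
#' moments. The weight is split equally when both feet are within `tol` of
#' the lowest foot (double stance); otherwise the lower foot carries all of
#' it.
#'
#' @param model a `lem_skeleton` with `foot_r` and `foot_l` segments.
#' @param post a `lem_posture`.
#' @param g gravitational acceleration magnitude (m/s^2).
#' @param tol double-stance height tolerance (m).
#' @return list of two `lem_wrench` objects (right, left).
#' @export
foot_wrench_approximation <- function(model, post, g = 9.81, tol = 0.02) {
  ir <- match("foot_r", model$names)
  il <- match("foot_l", model$names)
  if (is.na(ir) || is.na(il)) stop("model has no foot segments")
  fk <- forward_kinematics(model, post)
  zr <- fk$p[ir, 3]; zl <- fk$p[il, 3]
  w <- model$total_mass * g
  if (abs(zr - zl) <= tol) {
    fr <- w / 2; fl <- w / 2
  } else if (zr < zl) {
    fr <- w; fl <- 0
  } else {
    fr <- 0; fl <- w
  }
  list(wrench("foot_r", c(0, 0, fr)), wrench("foot_l", c(0, 0, fl)))
}

#' Inverse dynamics of the floating-base model
#'
#' Computes the actuated joint torques for a given extended state and set of
#' external wrenches by a recursive Newton-Euler sweep over the segment
#' tree. The gravitational foot wrenches from [foot_wrench_approximation()]
#' are appended by default; robot interaction wrenches (e.g. from
#' [impedance_wrench()]) can be supplied at the hand segments.
#'
#' @param model a `lem_skeleton`.
#' @param state a `lem_state` (or a `lem_posture`, treated as static).
#' @param wrenches list of `lem_wrench` objects.
#' @param include_foot_wrench append the body-weight foot approximation.
#' @param quasi_static if `TRUE`, velocities and accelerations are ignored
#'   (gravity and external wrenches only).
#' @param gravity gravity vector (m/s^2, world frame).
#' @return numeric torque vector of length `n_dof` (N m).
#' @export
inverse_dynamics <- function(model, state, wrenches = list(),
                             include_foot_wrench = TRUE,
                             quasi_static = FALSE,
                             gravity = c(0, 0, -9.81)) {
  if (inherits(state, "lem_posture")) state <- dyn_state(state)
  if (!inherits(state, "lem_state")) stop("state must be a lem_state")
  post <- state$posture
  check_posture(model, post)
  if (length(wrenches) > 0 &&
      (inherits(wrenches, "lem_wrench"))) wrenches <- list(wrenches)
  if (include_foot_wrench &&
      all(c("foot_r", "foot_l") %in% model$names)) {
    g_mag <- sqrt(sum(gravity^2))
    wrenches <- c(wrenches,
                  foot_wrench_approximation(model, post, g = g_mag))
  }
  vel <- state$velocity
  acc <- state$acceleration
  if (quasi_static) {
    vel[] <- 0; acc[] <- 0
  }
  n <- length(model$segments)
  fk <- forward_kinematics(model, post)
  # external wrench per segment
  f_ext <- matrix(0, n, 3); m_ext <- matrix(0, n, 3)
  for (w in wrenches) {
    if (!inherits(w, "lem_wrench")) stop("wrenches must be lem_wrench")
    i <- if (is.character(w$link)) match(w$link, model$names) else w$link
    if (is.na(i) || i < 1 || i > n) stop("wrench references invalid link")
    f_ext[i, ] <- f_ext[i, ] + w$force
    m_ext[i, ] <- m_ext[i, ] + w$moment
  }
  # forward pass: velocities/accelerations of segment frames
  omega <- matrix(0, n, 3); alpha <- matrix(0, n, 3)
  a_o <- matrix(0, n, 3)            # linear acceleration of frame origin
  v_o <- matrix(0, n, 3)
  Fi <- matrix(0, n, 3); Ni <- matrix(0, n, 3); r_c <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    s <- model$segments[[i]]
    if (model$parent[i] == 0L) {
      w_p <- vel[4:6]; al_p <- acc[4:6]
      v_p <- vel[1:3]; a_p <- acc[1:3]
      r <- fk$p[i, ] - post$base_pos
    } else {
      j <- model$parent[i]
      w_p <- omega[j, ]; al_p <- alpha[j, ]
      v_p <- v_o[j, ]; a_p <- a_o[j, ]
      r <- fk$p[i, ] - fk$p[j, ]
    }
    v_i <- v_p + crossprod3(w_p, r)
    a_i <- a_p + crossprod3(al_p, r) + crossprod3(w_p, crossprod3(w_p, r))
    w_i <- w_p; al_i <- al_p
    k <- model$ndof_seg[i]
    for (m in seq_len(k)) {
      a_ax <- fk$axes_w[[i]][m, ]
      qd <- vel[6L + model$q_start[i] + m]
      qdd <- acc[6L + model$q_start[i] + m]
      al_i <- al_i + a_ax * qdd + crossprod3(w_i, a_ax * qd)
      w_i <- w_i + a_ax * qd
    }
    omega[i, ] <- w_i; alpha[i, ] <- al_i
    v_o[i, ] <- v_i; a_o[i, ] <- a_i
    rc <- as.numeric(fk$R[[i]] %*% s$com)
    r_c[i, ] <- rc
    a_c <- a_i + crossprod3(al_i, rc) + crossprod3(w_i, crossprod3(w_i, rc))
    I_w <- fk$R[[i]] %*% s$inertia %*% t(fk$R[[i]])
    Fi[i, ] <- s$mass * (a_c - gravity)
    Ni[i, ] <- as.numeric(I_w %*% al_i) +
      crossprod3(w_i, as.numeric(I_w %*% w_i))
  }
  # backward pass: joint wrenches and torques
  f <- matrix(0, n, 3); nn <- matrix(0, n, 3)
  tau <- numeric(model$n_dof)
  for (i in rev(seq_len(n))) {
    fi <- Fi[i, ] - f_ext[i, ]
    ni <- Ni[i, ] + crossprod3(r_c[i, ], Fi[i, ]) - m_ext[i, ]
    kids <- which(model$parent == i)
    for (cdx in kids) {
      fi <- fi + f[cdx, ]
      ni <- ni + nn[cdx, ] + crossprod3(fk$p[cdx, ] - fk$p[i, ], f[cdx, ])
    }
    f[i, ] <- fi; nn[i, ] <- ni
    k <- model$ndof_seg[i]
    for (m in seq_len(k)) {
      tau[model$q_start[i] + m] <- sum(fk$axes_w[[i]][m, ] * ni)
    }
  }
  tau
}

#' Manipulability of a kinematic chain
#'
#' Yoshikawa's manipulability of the chain endpoint: the product of the
#' singular values of the positional Jacobian restricted to the joints on
#' the path from the chain root to the endpoint. It measures the volume of
#' the endpoint velocity ellipsoid — the capacity of the limb to produce
#' endpoint velocity (and, reciprocally, force) in its current
#' configuration; it vanishes at singular (e.g. fully extended)
#' configurations.
#'
#' @param model a `lem_skeleton`.
#' @param post a `lem_posture`.
#' @param endpoint segment name or index of the chain endpoint (e.g.
#'   `"hand_r"`).
#' @param from segment name or index at which the chain starts (its own
#'   joint excluded); defaults to the root, so all joints between root and
#'   endpoint contribute.
#' @param tip point of interest on the endpoint segment, in its frame;
#'   defaults to the segment tip (twice the COM offset of the homogeneous
#'   primitive), e.g. the fingertip end of a hand segment.
#' @return non-negative scalar (units m^k for k effective DoF).
#' @export
manipulability <- function(model, post, endpoint, from = NULL,
                           tip = NULL) {
  if (is.character(endpoint)) endpoint <- match(endpoint, model$names)
  if (is.na(endpoint) || endpoint < 1 || endpoint > length(model$segments))
    stop("invalid chain endpoint")
  path <- path_to_root(model, endpoint)
  if (!is.null(from)) {
    if (is.character(from)) from <- match(from, model$names)
    if (!(from %in% path)) stop("`from` is not on the chain to the endpoint")
    path <- path[seq(which(path == from) + 1L, length(path))]
  }
  cols <- unlist(lapply(path, function(i) {
    if (model$ndof_seg[i] == 0) integer(0)
    else 6L + model$q_start[i] + seq_len(model$ndof_seg[i])
  }))
  if (length(cols) == 0) return(0)
  if (is.null(tip)) tip <- 2 * model$segments[[endpoint]]$com
  J <- link_jacobian(model, post, endpoint,
                     point_offset = tip)[1:3, cols, drop = FALSE]
  sv <- svd(J)$d
  prod(sv[seq_len(min(3, length(cols)))])
}
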