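# Cartesian impedance wrench source.
#
# Task-space impedance law: the interaction wrench applied to the human
# hand is D (xd_dot - x_dot) + K (xd - x), with diagonal stiffness K and
# damping D. The damping follows the factorization design D = 2 zeta
# sqrt(K) per axis (mass-normalized), default damping ratio 0.7. This is
# the synthetic stand-in for the wrench a torque-sensing collaborative
# robot exerts through a shared object.

#' Cartesian impedance parameters
#'
#' @param K stiffness, a scalar (N/m, applied to all six axes), a
#'   6-vector, or a 6x6 diagonal matrix.
#' @param zeta damping ratio used by the factorization design
#'   `D = 2 zeta sqrt(K)`; ignored when `D` is given.
#' @param D optional damping (scalar, 6-vector or diagonal matrix,
#'   N s/m).
#' @param link hand segment that receives the wrench.
#' @return list of class `impedance_params` with 6x6 diagonal `K`, `D`.
#' @export
impedance_params <- function(K = 500, zeta = 0.7, D = NULL,
                             link = "hand_r") {
  as_diag6 <- function(v) {
    if (is.matrix(v)) {
      if (any(v[row(v) != col(v)] != 0)) stop("matrix must be diagonal")
      v <- diag(v)
    }
    if (length(v) == 1) v <- rep(v, 6)
    if (length(v) != 6) stop("need a scalar, 6-vector or 6x6 diagonal")
    if (any(v < 0)) stop("gains must be non-negative")
    diag(v)
  }
  K <- as_diag6(K)
  D <- if (is.null(D)) 2 * zeta * sqrt(K) else as_diag6(D)
  structure(list(K = K, D = D, zeta = zeta, link = link),
            class = "impedance_params")
}

#' Impedance interaction wrench
#'
#' Evaluates the task-space impedance law
#' `w = D (xd_dot - x_dot) + K (xd - x)` for a 6-DoF pose error and
#' returns it as a wrench at the configured hand link.
#'
#' @param params an [impedance_params()].
#' @param x current hand pose (6-vector: position m, orientation rad).
#' @param x_dot current hand twist (6-vector).
#' @param x_d,xd_dot desired pose and twist.
#' @return a `lem_wrench` at the hand link.
#' @export
#' @examples
#' ip <- impedance_params(K = 500)
#' # 1 cm static displacement along x -> 5 N restoring force
#' impedance_wrench(ip, x = c(0.01, 0, 0, 0, 0, 0))$force[1]
impedance_wrench <- function(params, x, x_dot = numeric(6),
                             x_d = numeric(6), xd_dot = numeric(6)) {
  w <- as.numeric(params$D %*% (xd_dot - x_dot) +
                    params$K %*% (x_d - x))
  wrench(params$link, force = w[1:3], moment = w[4:6])
}
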