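# RULA-C: a continuous relaxation of RULA.
#
# Two ingredients: (i) per scored joint, second-degree polynomial segments
# interpolate intermediate scores between the worksheet bands: each band
# contributes a parabola with its vertex at the band midpoint (value = the
# discrete band score) that meets the neighbouring band at the band edge,
# where the value is the mean of the two adjacent scores; beyond the
# outermost midpoints the extreme band score is held. The interpolant is
# continuous everywhere and exact at band midpoints. (ii) The combination
# tables A, B and C are replaced by ordinary least-squares linear models
# with intercept fitted to every cell of the corresponding table. The
# worksheet's posture-adjustment checkboxes enter as continuous ramps.
# The grand score is clamped to the RULA range [1, 7].

# Anchor points for one banded joint: each band midpoint paired with its
# score, interior band edges paired with the mean of the adjacent scores.
# Open-ended extreme bands use midpoint = edge +/- half the width of the
# adjacent band, clipped to the joint's angular domain.
band_anchors <- function(band) {
  br <- band$breaks; sc <- band$scores; dom <- band$domain
  nb <- length(sc)
  mids <- numeric(nb)
  if (nb == 2 && length(br) == 1) {
    w <- diff(dom) / 2
    mids <- c(br[1] - w / 2, br[1] + w / 2)
  } else {
    for (i in seq_len(nb)) {
      lo <- if (i == 1) br[1] - (br[2] - br[1]) / 2 else br[i - 1]
      hi <- if (i == nb) br[nb - 1] + (br[nb - 1] - br[nb - 2]) / 2
            else br[i]
      mids[i] <- (lo + hi) / 2
    }
  }
  mids <- pmin(pmax(mids, dom[1]), dom[2])
  x <- c(mids, br)
  y <- c(sc, (sc[-nb] + sc[-1]) / 2)
  list(x = x, y = y)
}

# Piecewise-quadratic band interpolant: list(E = edges, M = midpoints,
# s = band scores).
fit_quad <- function(band) {
  a <- band_anchors(band)
  nb <- length(band$scores)
  list(E = band$breaks, M = a$x[seq_len(nb)], s = band$scores)
}

# Evaluate the interpolant; vectorized in x.
quad_eval <- function(jf, x) {
  E <- jf$E; M <- jf$M; s <- jf$s
  nb <- length(s)
  i <- findInterval(x, E) + 1L
  v <- s[i]
  left <- x <= M[i]
  # rising/falling half-parabola toward the adjacent band edge
  use_l <- left & i > 1L
  if (any(use_l)) {
    ii <- i[use_l]
    vL <- (s[ii - 1L] + s[ii]) / 2
    t <- (x[use_l] - M[ii]) / (E[ii - 1L] - M[ii])
    v[use_l] <- s[ii] + (vL - s[ii]) * t^2
  }
  use_r <- !left & i < nb
  if (any(use_r)) {
    ii <- i[use_r]
    vR <- (s[ii] + s[ii + 1L]) / 2
    t <- (x[use_r] - M[ii]) / (E[ii] - M[ii])
    v[use_r] <- s[ii] + (vR - s[ii]) * t^2
  }
  v
}

#' Fit the continuous RULA model (RULA-C)
#'
#' Builds (i) the per-joint second-degree polynomial interpolants of the
#' worksheet bands (one parabola segment per band, vertex at the band
#' midpoint, meeting adjacent bands at the edge mean — exact at midpoints,
#' continuous everywhere) and (ii) ordinary-least-squares linear models
#' with intercept over all cells of worksheet Tables A, B and C
#' (sub-scores as regressors). The fitted object evaluates a continuous
#' grand score via [rula_c()].
#'
#' @param tables a [rula_tables()] object.
#' @return list of class `rula_c_model`: `quad` (named list of per-joint
#'   interpolants: band edges `E`, midpoints `M`, scores `s`; angle in
#'   degrees), `wa`, `wb`, `wc` (linear-model coefficient vectors),
#'   `score_range` per joint, and the fit residual summaries `resid_a`,
#'   `resid_b`, `resid_c` (max absolute residual over table cells; for C,
#'   of the range-clamped model as evaluated).
#' @export
fit_rula_c <- function(tables = rula_tables()) {
  quad <- lapply(tables$bands, fit_quad)
  rng <- lapply(tables$bands, function(b) range(b$scores))

  # least squares anchored at the worksheet's neutral cell: the fitted
  # model is constrained to return exactly 1 when every regressor is at
  # its best value 1, so the relaxation preserves the neutral reference
  # (an unconstrained plane overshoots the best corner of the saturating
  # tables and lifts the floor of the continuous score).
  cls <- function(X, y, c0) {
    G <- crossprod(X)
    w0 <- solve(G, crossprod(X, y))
    gc <- solve(G, c0)
    as.numeric(w0 + gc * (1 - sum(c0 * w0)) / sum(c0 * gc))
  }
  g <- expand.grid(ua = 1:6, la = 1:3, w = 1:4, wt = 1:2)
  ya <- tables$A[as.matrix(g)]
  Xa <- cbind(1, g$ua, g$la, g$w, g$wt)
  wa <- cls(Xa, ya, rep(1, 5))

  g <- expand.grid(neck = 1:6, trunk = 1:6, legs = 1:2)
  yb <- tables$B[as.matrix(g)]
  Xb <- cbind(1, g$neck, g$trunk, g$legs)
  wb <- cls(Xb, yb, rep(1, 4))

  g <- expand.grid(a = 1:8, b = 1:7)
  yc <- tables$C[as.matrix(g)]
  Xc <- cbind(1, g$a, g$b)
  wc <- cls(Xc, yc, rep(1, 3))
  # residual of the model as evaluated: the grand score is clamped to the
  # RULA range, which absorbs the plane's overshoot at saturated cells
  resid_c <- max(abs(pmin(pmax(Xc %*% wc, 1), 7) - yc))

  structure(list(quad = quad, wa = wa, wb = wb, wc = wc,
                 score_range = rng,
                 resid_a = max(abs(Xa %*% wa - ya)),
                 resid_b = max(abs(Xb %*% wb - yb)),
                 resid_c = resid_c,
                 tables = tables),
            class = "rula_c_model")
}

#' @export
print.rula_c_model <- function(x, ...) {
  cat("RULA-C model: 7 joint quadratics + linear table models\n")
  cat(sprintf("  max |residual|: Table A %.2f, Table B %.2f, Table C %.2f\n",
              x$resid_a, x$resid_b, x$resid_c))
  invisible(x)
}

# Continuous sub-score of one joint: quadratic evaluated at the angle,
# plus continuous versions of the worksheet adjustments, clamped to the
# joint's discrete score range (keeps the linear table models inside their
# fitted domain; clamping preserves continuity).
cont_sub <- function(fit, joint, x, adj = 0, hi = NULL) {
  r <- fit$score_range[[joint]]
  if (is.null(hi)) hi <- r[2]
  pmin(pmax(quad_eval(fit$quad[[joint]], x) + adj, r[1]), hi)
}

# Continuous stand-in for a worksheet checkbox: ramps 0 -> 1 over `w`
# degrees centered on the discrete threshold (value 0.5 at the threshold).
adj_ramp <- function(x, thr, w = 10) {
  pmin(pmax((x - (thr - w / 2)) / w, 0), 1)
}

rula_c_subscores <- function(ang, fit) {
  thr <- fit$tables$adjust
  ua_adj <- function(abd_out, elev)
    adj_ramp(elev, thr[["shoulder_raised"]]) +
      adj_ramp(abd_out, thr[["upper_arm_abducted"]])
  la_adj <- function(abd_out)
    adj_ramp(-abd_out, thr[["arm_across_midline"]])
  wr_adj <- function(dev) adj_ramp(abs(dev), thr[["wrist_deviated"]])
  nt_adj <- function(rot, side, k)
    adj_ramp(abs(rot), thr[[paste0(k, "_twist")]]) +
      adj_ramp(abs(side), thr[[paste0(k, "_side")]])
  list(
    ua_r = cont_sub(fit, "upper_arm", ang$ua_flex_r,
                    ua_adj(ang$ua_abd_out_r, ang$elev_r), hi = 6),
    ua_l = cont_sub(fit, "upper_arm", ang$ua_flex_l,
                    ua_adj(ang$ua_abd_out_l, ang$elev_l), hi = 6),
    la_r = cont_sub(fit, "lower_arm", ang$elbow_r,
                    la_adj(ang$ua_abd_out_r), hi = 3),
    la_l = cont_sub(fit, "lower_arm", ang$elbow_l,
                    la_adj(ang$ua_abd_out_l), hi = 3),
    wr_r = cont_sub(fit, "wrist", ang$wrist_r, wr_adj(ang$wrist_dev_r),
                    hi = 4),
    wr_l = cont_sub(fit, "wrist", ang$wrist_l, wr_adj(ang$wrist_dev_l),
                    hi = 4),
    wt_r = cont_sub(fit, "wrist_twist", ang$wrist_twist_r),
    wt_l = cont_sub(fit, "wrist_twist", ang$wrist_twist_l),
    neck = cont_sub(fit, "neck", ang$neck_flex,
                    nt_adj(ang$neck_rot, ang$neck_side, "neck"), hi = 6),
    trunk = cont_sub(fit, "trunk", ang$trunk_flex,
                     nt_adj(ang$trunk_rot, ang$trunk_side, "trunk"), hi = 6),
    legs = cont_sub(fit, "legs", abs(ang$knee_r - ang$knee_l))
  )
}

#' Continuous RULA score (RULA-C)
#'
#' Evaluates the continuous grand score of one or many postures: quadratic
#' per-joint sub-scores, linear Table A model per arm (worse side kept),
#' linear Table B model, force/load score added to both, linear Table C
#' model, clamped to [1, 7]. Continuous in the joint angles (the posture
#' adjustment checkboxes of the discrete worksheet are step functions and
#' are deliberately excluded).
#'
#' @inheritParams rula
#' @param fit a [fit_rula_c()] model.
#' @return numeric vector of continuous grand scores in [1, 7].
#' @export
rula_c <- function(post, load = 0, static = FALSE, muscle = 0,
                   model = lemr_model(), fit = rula_c_fit()) {
  ang <- rula_angles(post, model)
  sc <- rula_c_subscores(ang, fit)
  fs <- rula_load_score(load, static) + muscle
  wa <- fit$wa; wb <- fit$wb; wc <- fit$wc
  a_r <- wa[1] + wa[2] * sc$ua_r + wa[3] * sc$la_r + wa[4] * sc$wr_r +
    wa[5] * sc$wt_r
  a_l <- wa[1] + wa[2] * sc$ua_l + wa[3] * sc$la_l + wa[4] * sc$wr_l +
    wa[5] * sc$wt_l
  a <- pmax(a_r, a_l) + fs
  b <- wb[1] + wb[2] * sc$neck + wb[3] * sc$trunk + wb[4] * sc$legs + fs
  g <- wc[1] + wc[2] * a + wc[3] * b
  pmin(pmax(g, 1), 7)
}

#' Cached default RULA-C fit
#' @return a `rula_c_model` fitted to the standard tables.
#' @export
rula_c_fit <- function() {
  if (is.null(.lemr_env$rula_c_fit))
    .lemr_env$rula_c_fit <- fit_rula_c(rula_tables())
  .lemr_env$rula_c_fit
}

#' Continuous local (per body-location) scores
#'
#' Per-location partial scores used to color spheres at relevant joints of
#' the digital human model: shoulders from the upper-arm sub-score, elbows
#' from the lower-arm sub-score, back from the trunk sub-score, torso from
#' the mean of trunk and neck, knees from a continuous knee-flexion ramp
#' (the worksheet has no per-knee band) and ankles from the legs sub-score.
#'
#' @inheritParams rula_c
#' @return data.frame with columns `shoulder_r`, `shoulder_l`, `elbow_r`,
#'   `elbow_l`, `back`, `torso`, `knee_r`, `knee_l`, `ankle_r`, `ankle_l`;
#'   one row per posture.
#' @export
local_scores <- function(post, model = lemr_model(), fit = rula_c_fit()) {
  ang <- rula_angles(post, model)
  sc <- rula_c_subscores(ang, fit)
  knee <- function(k) pmin(pmax(1 + k / 90, 1), 2)
  data.frame(
    shoulder_r = sc$ua_r, shoulder_l = sc$ua_l,
    elbow_r = sc$la_r, elbow_l = sc$la_l,
    back = sc$trunk, torso = (sc$trunk + sc$neck) / 2,
    knee_r = knee(ang$knee_r), knee_l = knee(ang$knee_l),
    ankle_r = sc$legs, ankle_l = sc$legs
  )
}
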