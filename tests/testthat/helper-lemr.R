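# Shared fixtures: bespoke test chains, closed-form oracles, an
# independently hand-entered copy of the RULA worksheet, uniform random
# postures, and cached reference trainings (built once per test run).

.test_cache <- new.env(parent = emptyenv())

# ---- planar chains -------------------------------------------------------

# n-link planar pendulum hanging along -z, one flexion DoF (about +y) per
# link, motion in the x-z plane; COM mid-link, thin-rod inertia.
planar_chain <- function(lengths, masses) {
  n <- length(lengths)
  segs <- lapply(seq_len(n), function(i) {
    list(name = paste0("link", i),
         parent = if (i == 1) NA_character_ else paste0("link", i - 1),
         offset = if (i == 1) c(0, 0, 0) else c(0, 0, -lengths[i - 1]),
         axes = matrix(c(0, 1, 0), 1, 3),
         mass = masses[i], com = c(0, 0, -lengths[i] / 2),
         inertia = diag(c(masses[i] * lengths[i]^2 / 12,
                          masses[i] * lengths[i]^2 / 12, 1e-9)))
  })
  new_skeleton(segs)
}

# Closed-form inverse dynamics of the planar pendulum via the Lagrangian
# (analytic COM Jacobians and accelerations): an oracle independent of the
# package's recursive Newton-Euler implementation.
planar_tau <- function(lengths, masses, q, qd, qdd, g = 9.81) {
  n <- length(q)
  th <- cumsum(q); thd <- cumsum(qd); thdd <- cumsum(qdd)
  tau <- numeric(n)
  for (j in seq_len(n)) {
    lm <- c(lengths[seq_len(j - 1)], lengths[j] / 2)
    ax <- sum(lm * (cos(th[1:j]) * thdd[1:j] - sin(th[1:j]) * thd[1:j]^2))
    az <- sum(lm * (sin(th[1:j]) * thdd[1:j] + cos(th[1:j]) * thd[1:j]^2))
    Ij <- masses[j] * lengths[j]^2 / 12
    for (k in 1:j) {
      Jx <- sum(lm[k:j] * cos(th[k:j]))
      Jz <- sum(lm[k:j] * sin(th[k:j]))
      tau[k] <- tau[k] + masses[j] * (Jx * ax + Jz * (az + g)) +
        Ij * thdd[j]
    }
  }
  tau
}

# ---- independently hand-entered RULA worksheet ---------------------------

# The three lookup tables typed in afresh, row by row as they appear on
# the published worksheet (wrist columns left to right, each split by
# wrist twist; trunk columns split by legs), parsed from strings.
rula_tables_reference <- function() {
  parse_rows <- function(txt) {
    rows <- strsplit(trimws(strsplit(txt, "\n")[[1]]), "\\s+")
    t(vapply(rows, as.integer, integer(length(rows[[1]]))))
  }
  a_txt <- "1 2 2 2 2 3 3 3
            2 2 2 2 3 3 3 3
            2 3 3 3 3 3 4 4
            2 3 3 3 3 4 4 4
            3 3 3 3 3 4 4 4
            3 4 4 4 4 4 5 5
            3 3 4 4 4 4 5 5
            3 4 4 4 4 4 5 5
            4 4 4 4 4 5 5 5
            4 4 4 4 4 5 5 5
            4 4 4 4 4 5 5 5
            4 4 4 5 5 5 6 6
            5 5 5 5 5 6 6 7
            5 6 6 6 6 7 7 7
            6 6 6 7 7 7 7 8
            7 7 7 7 7 8 8 9
            8 8 8 8 8 9 9 9
            9 9 9 9 9 9 9 9"
  am <- parse_rows(a_txt)
  A <- array(0L, c(6, 3, 4, 2))
  for (ua in 1:6) for (la in 1:3) {
    r <- am[(ua - 1) * 3 + la, ]
    A[ua, la, , 1] <- r[c(1, 3, 5, 7)]
    A[ua, la, , 2] <- r[c(2, 4, 6, 8)]
  }
  b_txt <- "1 3 2 3 3 4 5 5 6 6 7 7
            2 3 2 3 4 5 5 5 6 7 7 7
            3 3 3 4 4 5 5 6 6 7 7 7
            5 5 5 6 6 7 7 7 7 7 8 8
            7 7 7 7 7 8 8 8 8 8 8 8
            8 8 8 8 8 8 8 9 9 9 9 9"
  bm <- parse_rows(b_txt)
  B <- array(0L, c(6, 6, 2))
  for (nk in 1:6) {
    B[nk, , 1] <- bm[nk, c(1, 3, 5, 7, 9, 11)]
    B[nk, , 2] <- bm[nk, c(2, 4, 6, 8, 10, 12)]
  }
  c_txt <- "1 2 3 3 4 5 5
            2 2 3 4 4 5 5
            3 3 3 4 4 5 6
            3 3 3 4 5 6 6
            4 4 4 5 6 7 7
            4 4 5 6 6 7 7
            5 5 6 6 7 7 7
            5 5 6 7 7 7 7"
  list(A = A, B = B, C = parse_rows(c_txt))
}

# ---- posture generators --------------------------------------------------

# uniform draws from the joint range-of-motion box
random_postures <- function(n, seed, model = lemr_model()) {
  set.seed(seed)
  lim <- joint_limit_table()
  Q <- matrix(0, n, model$n_dof)
  for (i in seq_len(nrow(lim))) {
    b <- model$q_start[match(lim$name[i], model$names)]
    Q[, b + 1] <- runif(n, lim$flex_lo[i], lim$flex_hi[i]) * pi / 180
    Q[, b + 2] <- runif(n, lim$abd_lo[i], lim$abd_hi[i]) * pi / 180
    Q[, b + 3] <- runif(n, lim$rot_lo[i], lim$rot_hi[i]) * pi / 180
  }
  Q
}

set_deg <- function(p, model, seg, comp, deg) {
  p$q[q_index(model, seg, comp)] <- deg * pi / 180
  p
}

# neutral posture with the elbows inside their best band (60-100 deg)
best_band_posture <- function(model = lemr_model()) {
  p <- neutral_posture(model)
  p <- set_deg(p, model, "forearm_r", "flex", 80)
  set_deg(p, model, "forearm_l", "flex", 80)
}

# ---- cached trainings ----------------------------------------------------

# small VAE for structural map tests (seconds)
quick_vae <- function() {
  if (is.null(.test_cache$quick)) {
    ts <- make_training_set(800, seed = 5)
    p <- vae_train(ts$X, ts$eps, vae_config(epochs = 40, seed = 5))
    .test_cache$quick <- list(p = p, ts = ts)
  }
  .test_cache$quick
}

# reference training at the study scale: 5,000 training postures plus a
# 500-posture held-out set, default configuration
ref_vae <- function() {
  if (is.null(.test_cache$ref)) {
    ts <- make_training_set(5500, seed = 11)
    set.seed(99)
    idx <- sample.int(5500, 5000)
    p <- vae_train(ts$X[idx, ], ts$eps[idx],
                   vae_config(alpha = 0.2, epochs = 300, seed = 7))
    .test_cache$ref <- list(
      p = p, norm = ts$norm,
      train = list(X = ts$X[idx, ], eps = ts$eps[idx]),
      holdout = list(X = ts$X[-idx, ], eps = ts$eps[-idx],
                     Q = ts$Q[-idx, ]))
  }
  .test_cache$ref
}
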