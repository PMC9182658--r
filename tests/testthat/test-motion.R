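test_that("sequence generation is seeded, sized, and hits its keyframes", {
  s1 <- generate_sequence("squat", duration = 5, rate = 20, seed = 7)
  s2 <- generate_sequence("squat", duration = 5, rate = 20, seed = 7)
  expect_identical(s1$Q, s2$Q)
  s3 <- generate_sequence("squat", duration = 5, rate = 20, seed = 8)
  expect_false(identical(s1$Q, s3$Q))
  expect_equal(nrow(generate_sequence("walk", 10, 50, seed = 1)$Q), 500)
  expect_error(generate_sequence("juggling"), "unknown activity")
  expect_error(generate_sequence("walk", duration = -1), "duration")
  # noiseless stoop reaches the top trunk band (> 60 deg flexion)
  m <- lemr_model()
  sq <- generate_sequence("stoop", duration = 4, rate = 25, noise_std = 0,
                          seed = 1, model = m)
  ang <- rula_angles(sq$Q, m)
  expect_equal(max(ang$trunk_flex), 70, tolerance = 1e-9)
  tb <- rula_tables()
  expect_equal(lemr:::band_score(max(ang$trunk_flex), tb$bands$trunk), 4)
  # generated postures respect the joint limits
  lim <- joint_limit_normalization(m)
  sqn <- generate_sequence("pick_place", 6, 25, noise_std = 0.1, seed = 2)
  X <- normalize_postures(sqn$Q, lim)
  expect_true(all(X >= -1e-9 & X <= 1 + 1e-9))
})

test_that("mirroring is an involution and a true geometric reflection", {
  m <- lemr_model()
  Q <- random_postures(10, 23)
  expect_equal(mirror_postures(mirror_postures(Q, m), m), Q,
               tolerance = 1e-15)
  # a bilaterally symmetric posture is a fixed point
  p <- neutral_posture(m)
  p <- set_deg(p, m, "upperarm_r", "flex", 90)
  p <- set_deg(p, m, "upperarm_l", "flex", 90)
  p <- set_deg(p, m, "l5", "flex", 30)
  expect_equal(mirror_postures(p$q, m), p$q, tolerance = 1e-15)
  # FK of the mirrored posture is the y-reflection of the original
  q <- random_postures(1, 29)[1, ]
  f1 <- forward_kinematics(m, posture(q))
  f2 <- forward_kinematics(m, posture(mirror_postures(q, m)))
  for (i in seq_along(m$names)) {
    nm <- m$names[i]
    j <- match(if (grepl("_r$", nm)) sub("_r$", "_l", nm)
               else if (grepl("_l$", nm)) sub("_l$", "_r", nm) else nm,
               m$names)
    expect_equal(f2$p[j, ], f1$p[i, ] * c(1, -1, 1), tolerance = 1e-9)
  }
})

test_that("augmentation adds mirrors and adjacent midpoints", {
  m <- lemr_model()
  Q <- random_postures(8, 31)
  A <- augment_postures(Q, m)
  expect_equal(nrow(A), 2 * 8 + 7)
  expect_equal(A[1:8, ], Q)
  expect_equal(A[9:16, ], mirror_postures(Q, m))
  expect_equal(A[17, ], (Q[1, ] + Q[2, ]) / 2)
  expect_error(augment_postures(Q[0, , drop = FALSE]), "empty")
})

test_that("impedance wrench implements the task-space law", {
  ip <- impedance_params(K = 500)
  # equilibrium: zero wrench
  w0 <- impedance_wrench(ip, x = numeric(6))
  expect_equal(w0$force, c(0, 0, 0))
  expect_equal(w0$moment, c(0, 0, 0))
  # 1 cm static displacement at K = 500 N/m -> 5 N restoring force
  w1 <- impedance_wrench(ip, x = c(0.01, 0, 0, 0, 0, 0))
  expect_equal(w1$force[1], -5)
  expect_equal(abs(w1$force[1]), 500 * 0.01)
  # the stiff variant doubles the force
  w2 <- impedance_wrench(impedance_params(K = 1000),
                         x = c(0.01, 0, 0, 0, 0, 0))
  expect_equal(w2$force[1], 2 * w1$force[1])
  # damping factorization D = 2 zeta sqrt(K)
  expect_equal(diag(ip$D), rep(2 * 0.7 * sqrt(500), 6))
  expect_error(impedance_params(K = -5), "non-negative")
})

test_that("factorized damping keeps the step response near critical", {
  # unit-mass 1-DoF step response under K, D = 2 zeta sqrt(K), zeta = 0.7
  K <- 500; D <- 2 * 0.7 * sqrt(K)
  x <- 0; v <- 0; dt <- 1e-4; xd <- 0.1
  xs <- numeric(20000)
  for (i in seq_along(xs)) {
    acc1 <- function(x, v) K * (xd - x) - D * v
    # RK4
    k1x <- v; k1v <- acc1(x, v)
    k2x <- v + dt / 2 * k1v; k2v <- acc1(x + dt / 2 * k1x, v + dt / 2 * k1v)
    k3x <- v + dt / 2 * k2v; k3v <- acc1(x + dt / 2 * k2x, v + dt / 2 * k2v)
    k4x <- v + dt * k3v; k4v <- acc1(x + dt * k3x, v + dt * k3v)
    x <- x + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
    v <- v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    xs[i] <- x
  }
  overshoot <- (max(xs) - xd) / xd
  expect_lte(overshoot, 0.05)
  expect_equal(xs[length(xs)], xd, tolerance = 1e-6)
})

test_that("training sets are normalized, balanced, and ergonomically spread", {
  ts <- make_training_set(1400, seed = 3)
  expect_equal(nrow(ts$X), 1400)
  expect_true(all(ts$X >= 0 & ts$X <= 1))
  expect_equal(length(ts$eps), 1400)
  # every activity contributes at least 10%
  shares <- table(ts$activity) / length(ts$activity)
  expect_true(all(shares >= 0.10))
  expect_setequal(names(shares), activities())
  # the score span covers low and high RULA bands
  expect_lte(min(ts$eps), 1.5 / 7)
  expect_gte(max(ts$eps), 5 / 7)
  # awkward activities score at least one RULA unit above neutral frames
  rc <- ts$eps * 7
  sep <- mean(rc[ts$activity %in% c("stoop", "overhead")]) -
    mean(rc[ts$activity == "neutral"])
  expect_gte(sep, 1.0)
  # reproducible
  ts2 <- make_training_set(1400, seed = 3)
  expect_identical(ts$X, ts2$X)
})
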