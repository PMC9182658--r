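test_that("inverse dynamics matches the closed-form planar-chain Lagrangian", {
  ls3 <- c(0.4, 0.3, 0.25); ms3 <- c(2, 1.5, 1)
  ch <- planar_chain(ls3, ms3)
  set.seed(42)
  for (k in 1:100) {
    q <- runif(3, -pi, pi); qd <- runif(3, -3, 3); qdd <- runif(3, -5, 5)
    st <- dyn_state(posture(q), c(rep(0, 6), qd), c(rep(0, 6), qdd))
    tau <- inverse_dynamics(ch, st, include_foot_wrench = FALSE)
    expect_lt(max(abs(tau - planar_tau(ls3, ms3, q, qd, qdd))), 1e-6)
  }
  # double pendulum as well
  ls2 <- c(0.5, 0.35); ms2 <- c(1.2, 0.8)
  ch2 <- planar_chain(ls2, ms2)
  for (k in 1:20) {
    q <- runif(2, -pi, pi); qd <- runif(2, -3, 3); qdd <- runif(2, -5, 5)
    st <- dyn_state(posture(q), c(rep(0, 6), qd), c(rep(0, 6), qdd))
    tau <- inverse_dynamics(ch2, st, include_foot_wrench = FALSE)
    expect_lt(max(abs(tau - planar_tau(ls2, ms2, q, qd, qdd))), 1e-6)
  }
})

test_that("no gravity, no motion, no wrench gives zero torque", {
  m <- build_skeleton(1.75, 70)
  q <- random_postures(1, 8)[1, ]
  tau <- inverse_dynamics(m, dyn_state(posture(q)),
                          include_foot_wrench = FALSE,
                          gravity = c(0, 0, 0))
  expect_equal(tau, rep(0, 66))
})

test_that("static torques equal the potential-energy gradient", {
  m <- build_skeleton(1.75, 70)
  q <- random_postures(1, 17)[1, ]
  tau <- inverse_dynamics(m, dyn_state(posture(q)),
                          include_foot_wrench = FALSE)
  # potential energy V(q) = sum_i m_i g z_ci; static torque = dV/dq
  V <- function(qv) {
    fk <- forward_kinematics(m, posture(qv))
    sum(vapply(seq_along(m$segments), function(i) {
      zc <- fk$p[i, 3] + (fk$R[[i]] %*% m$segments[[i]]$com)[3]
      m$segments[[i]]$mass * 9.81 * zc
    }, 0))
  }
  h <- 1e-6
  set.seed(18)
  for (cc in sample(66, 12)) {
    qp <- q; qm <- q
    qp[cc] <- qp[cc] + h; qm[cc] <- qm[cc] - h
    expect_equal(tau[cc], (V(qp) - V(qm)) / (2 * h), tolerance = 1e-4)
  }
})

test_that("horizontal arm shoulder torque equals the hand-computed gravity moment", {
  m <- build_skeleton(1.75, 70)
  # right arm straight out to the side: abduction -90 (outward)
  p <- set_deg(neutral_posture(m), m, "upperarm_r", "abd", -90)
  tau <- inverse_dynamics(m, dyn_state(p), include_foot_wrench = FALSE)
  # moment of arm segment weights about the shoulder: sum m_i g d_i with
  # d_i the horizontal lever of each COM, from the coefficient table
  H <- 1.75
  l_ua <- 0.186 * H; l_fa <- 0.146 * H
  segs <- m$segments
  nm <- m$names
  mass_of <- function(s) segs[[match(s, nm)]]$mass
  mom <- mass_of("upperarm_r") * 9.81 * (l_ua / 2) +
    mass_of("forearm_r") * 9.81 * (l_ua + l_fa / 2) +
    mass_of("hand_r") * 9.81 * (l_ua + l_fa + 0.108 * H / 2)
  expect_equal(abs(tau[q_index(m, "upperarm_r", "abd")]), mom,
               tolerance = 1e-6 / mom)
})

test_that("torques are linear in external wrenches via the link Jacobian", {
  m <- build_skeleton(1.75, 70)
  set.seed(12)
  for (k in 1:10) {
    q <- random_postures(1, 100 + k)[1, ]
    po <- posture(q)
    st <- dyn_state(po, rnorm(72, 0, 0.5), rnorm(72, 0, 0.5))
    link <- sample(2:23, 1)
    w <- wrench(link, force = rnorm(3, 0, 20), moment = rnorm(3, 0, 5))
    t0 <- inverse_dynamics(m, st, include_foot_wrench = FALSE)
    t1 <- inverse_dynamics(m, st, list(w), include_foot_wrench = FALSE)
    J <- link_jacobian(m, po, link)
    pred <- -as.numeric(t(J[, 7:72]) %*% c(w$force, w$moment))
    expect_lt(max(abs((t1 - t0) - pred)), 1e-9)
  }
})

test_that("foot wrench approximation carries the body weight", {
  m <- build_skeleton(1.75, 70)
  fw <- foot_wrench_approximation(m, neutral_posture(m))
  total <- fw[[1]]$force[3] + fw[[2]]$force[3]
  expect_equal(total, 70 * 9.81, tolerance = 1e-9)
  # symmetric stance: equal split
  expect_equal(fw[[1]]$force[3], 70 * 9.81 / 2)
  expect_equal(fw[[1]]$moment, c(0, 0, 0))
  # single support: raise the left knee so the left foot is higher
  p1 <- set_deg(set_deg(neutral_posture(m), m, "thigh_l", "flex", 80),
                m, "shank_l", "flex", 90)
  fw1 <- foot_wrench_approximation(m, p1)
  expect_equal(fw1[[1]]$force[3], 70 * 9.81)  # right foot takes all
  expect_equal(fw1[[2]]$force[3], 0)
})

test_that("manipulability matches the two-link closed form and is invariant to base pose", {
  ch <- planar_chain(c(0.3, 0.3), c(1, 1))
  w <- manipulability(ch, posture(c(0.4, pi / 2)), "link2")
  expect_equal(w, 0.3 * 0.3, tolerance = 1e-9)
  for (q2 in c(0.3, 1.1, 2.0)) {
    w <- manipulability(ch, posture(c(-0.2, q2)), "link2")
    expect_equal(w, 0.3 * 0.3 * abs(sin(q2)), tolerance = 1e-9)
  }
  # fully extended chain is singular
  expect_equal(manipulability(ch, posture(c(0.5, 0)), "link2"), 0,
               tolerance = 1e-12)
  # human arm: non-negative, invariant to base translation and rotation
  m <- build_skeleton(1.75, 70)
  q <- random_postures(1, 77)[1, ]
  w0 <- manipulability(m, posture(q), "hand_r", from = "t8")
  expect_gte(w0, 0)
  w1 <- manipulability(m, posture(q, base_pos = c(2, -1, 0.4),
                                  base_rpy = c(0.3, 0.2, -0.5)),
                       "hand_r", from = "t8")
  expect_equal(w1, w0, tolerance = 1e-9)
  expect_error(manipulability(m, posture(q), "no_such_link"), "endpoint")
})

test_that("dynamics inputs are validated", {
  m <- build_skeleton(1.75, 70)
  p <- neutral_posture(m)
  expect_error(dyn_state(p, velocity = rep(0, 10)), "6 \\+ n_dof")
  expect_error(dyn_state(p, velocity = rep(NA_real_, 72)), "non-finite")
  expect_error(inverse_dynamics(m, dyn_state(p), list(wrench(99))),
               "invalid link")
})
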