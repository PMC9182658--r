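test_that("anthropometric scaling conserves mass and stature", {
  m <- build_skeleton(1.75, 70)
  expect_equal(m$n_dof, 66L)
  expect_length(m$segments, 23)
  expect_equal(sum(vapply(m$segments, `[[`, 0, "mass")), 70,
               tolerance = 1e-6 / 70)
  # standing vertical extent: head top to toe level ~ stature
  fk <- forward_kinematics(m, neutral_posture(m))
  head_top <- fk$p[match("head", m$names), 3] +
    m$segments[[match("head", m$names)]]$length
  toe <- fk$p[match("toe_r", m$names), 3]
  expect_equal(head_top - toe, 1.75, tolerance = 0.05 * 1.75)
  # another subject scales linearly
  m2 <- build_skeleton(1.60, 55)
  expect_equal(sum(vapply(m2$segments, `[[`, 0, "mass")), 55,
               tolerance = 1e-6 / 55)
  expect_error(build_skeleton(0.9, 70), "height")
  expect_error(build_skeleton(1.75, 300), "mass")
})

test_that("segment coefficient table is normalized and topologically ordered", {
  tab <- human_segment_table()
  expect_equal(sum(tab$mass_coeff / sum(tab$mass_coeff)), 1,
               tolerance = 1e-9)
  expect_true(all(tab$length_coeff > 0))
  idx <- match(tab$parent, tab$name)
  expect_true(all(is.na(idx) | idx < seq_len(nrow(tab))))
})

test_that("forward kinematics composes rest offsets and joint rotations", {
  m <- build_skeleton(1.75, 70)
  p0 <- neutral_posture(m)
  fk <- forward_kinematics(m, p0)
  # zero posture: link positions are cumulative rest offsets
  for (i in seq_along(m$segments)) {
    j <- m$parent[i]
    expected <- if (j == 0) m$segments[[i]]$offset
                else fk$p[j, ] + m$segments[[i]]$offset
    expect_equal(fk$p[i, ], expected, tolerance = 1e-12)
    expect_equal(fk$R[[i]], diag(3), tolerance = 1e-12)
  }
  # pelvis pose equals the base pose
  pb <- posture(rep(0, 66), base_pos = c(1, 2, 3), base_rpy = c(.2, .3, .4))
  fkb <- forward_kinematics(m, pb)
  expect_equal(fkb$p[1, ], c(1, 2, 3))
  # elbow flexion pi/2: wrist position from manual transform composition
  pe <- set_deg(p0, m, "forearm_r", "flex", 90)
  fke <- forward_kinematics(m, pe)
  ie <- match("forearm_r", m$names); ih <- match("hand_r", m$names)
  # elbow flexion axis is (0,-1,0); rotating the hand offset (0,0,-l) by
  # +90 deg about -y sends it to (+l, 0, 0)
  l <- abs(m$segments[[ih]]$offset[3])
  expect_equal(fke$p[ih, ], fke$p[ie, ] + c(l, 0, 0), tolerance = 1e-12)
  # base translation shifts every link by exactly t
  t3 <- c(0.7, -0.4, 0.2)
  q <- random_postures(1, 42)[1, ]
  f1 <- forward_kinematics(m, posture(q))
  f2 <- forward_kinematics(m, posture(q, base_pos = t3))
  expect_equal(f2$p, f1$p + rep(t3, each = 23), tolerance = 1e-12)
  expect_error(forward_kinematics(m, posture(rep(0, 10))), "66")
})

test_that("rotations stay orthonormal over random postures", {
  m <- build_skeleton(1.8, 80)
  Q <- random_postures(20, 7)
  for (k in seq_len(nrow(Q))) {
    fk <- forward_kinematics(m, posture(Q[k, ], base_rpy = c(.1, -.2, .3)))
    for (R in fk$R) {
      expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
      expect_equal(det(R), 1, tolerance = 1e-9)
    }
  }
})

test_that("link Jacobian matches finite differences of the kinematics", {
  m <- build_skeleton(1.75, 70)
  Q <- random_postures(100, 31)
  set.seed(32)
  links <- sample(2:23, 100, replace = TRUE)
  h <- 1e-6
  for (k in seq_len(nrow(Q))) {
    q <- Q[k, ]
    po <- posture(q, base_pos = c(.1, .2, .9), base_rpy = c(.05, .1, -.1))
    link <- links[k]
    J <- link_jacobian(m, po, link)
    # FD over the joint columns on the kinematic path
    path <- lemr:::path_to_root(m, link)
    cols <- unlist(lapply(path, function(i)
      m$q_start[i] + seq_len(m$ndof_seg[i])))
    for (cc in cols) {
      qp <- q; qm <- q
      qp[cc] <- qp[cc] + h; qm[cc] <- qm[cc] - h
      pp <- forward_kinematics(m, posture(qp, po$base_pos, po$base_rpy))
      pm <- forward_kinematics(m, posture(qm, po$base_pos, po$base_rpy))
      fd <- (pp$p[link, ] - pm$p[link, ]) / (2 * h)
      expect_lt(max(abs(J[1:3, 6 + cc] - fd)), 1e-6)
    }
    # columns of joints off the path are exactly zero
    off <- setdiff(seq_len(66), cols)
    expect_true(all(J[, 6 + off] == 0))
    # free-floating translation block
    expect_equal(J[1:3, 1:3], diag(3))
    expect_equal(J[4:6, 4:6], diag(3))
  }
})

test_that("kinematics and dynamics are deterministic", {
  m <- build_skeleton(1.75, 70)
  q <- random_postures(1, 3)[1, ]
  po <- posture(q)
  expect_identical(forward_kinematics(m, po), forward_kinematics(m, po))
  expect_identical(inverse_dynamics(m, dyn_state(po)),
                   inverse_dynamics(m, dyn_state(po)))
})

test_that("skeleton YAML round trip preserves the model", {
  m <- build_skeleton(1.68, 62)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_skeleton_yaml(m, path)
  m2 <- read_skeleton_yaml(path)
  expect_equal(m2$n_dof, m$n_dof)
  expect_equal(m2$names, m$names)
  for (i in seq_along(m$segments)) {
    expect_equal(m2$segments[[i]]$offset, m$segments[[i]]$offset)
    expect_equal(m2$segments[[i]]$mass, m$segments[[i]]$mass)
    expect_equal(m2$segments[[i]]$inertia, m$segments[[i]]$inertia)
  }
  q <- random_postures(1, 9)[1, ]
  expect_equal(forward_kinematics(m2, posture(q))$p,
               forward_kinematics(m, posture(q))$p, tolerance = 1e-12)
})

test_that("posture constructors validate their input", {
  m <- lemr_model()
  expect_error(posture(c(1, NA, 3)), "finite")
  expect_error(posture(rep(0, 66), base_pos = c(1, 2)), "3 position")
  expect_error(q_index(m, "femur", "flex"), "unknown segment")
  expect_error(q_index(m, "pelvis", "flex"), "invalid joint component")
})
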