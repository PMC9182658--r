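# The discrete scorer is checked against an independently hand-entered
# copy of the published worksheet (helper-lemr.R) on postures constructed
# at band corners, and on its structural guarantees.

test_that("embedded tables agree with the independently entered worksheet", {
  tb <- rula_tables()
  ref <- rula_tables_reference()
  expect_identical(tb$A, ref$A)
  expect_identical(tb$B, ref$B)
  expect_identical(unname(tb$C), unname(ref$C))
  expect_true(all(tb$A %in% 1:9) && all(tb$B %in% 1:9))
  expect_true(all(tb$C %in% 1:7))
})

test_that("band-corner postures score as the worksheet lookup", {
  m <- lemr_model()
  tb <- rula_tables()
  ref <- rula_tables_reference()
  # representative angles inside each band of each scored joint (degrees)
  cases <- list(
    upper_arm = list(col = "upperarm_r", comp = "flex",
                     ang = c(0, -30, 30, 70, 120), score = c(1, 2, 2, 3, 4)),
    lower_arm = list(col = "forearm_r", comp = "flex",
                     ang = c(80, 30, 120), score = c(1, 2, 2)),
    wrist = list(col = "hand_r", comp = "flex",
                 ang = c(0, 10, -10, 30, -30), score = c(1, 2, 2, 3, 3)),
    neck = list(col = "neck", comp = "flex",
                ang = c(5, 15, 30, -20), score = c(1, 2, 3, 4)),
    trunk = list(col = "l5", comp = "flex",
                 ang = c(0, 10, 40, 70), score = c(1, 2, 3, 4))
  )
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    for (i in seq_along(cs$ang)) {
      p <- set_deg(best_band_posture(m), m, cs$col, cs$comp, cs$ang[i])
      a <- rula(p, model = m, tables = tb)
      sub <- switch(nm, upper_arm = a$sub_scores$ua_r,
                    lower_arm = a$sub_scores$la_r,
                    wrist = a$sub_scores$wr_r,
                    neck = a$sub_scores$neck, trunk = a$sub_scores$trunk)
      expect_equal(sub, cs$score[i],
                   label = sprintf("%s at %g deg", nm, cs$ang[i]))
      # grand score agrees with the reference tables looked up by hand
      sc <- a$sub_scores
      a_ref <- max(ref$A[sc$ua_r, sc$la_r, sc$wr_r, sc$wt_r],
                   ref$A[sc$ua_l, sc$la_l, sc$wr_l, sc$wt_l])
      b_ref <- ref$B[sc$neck, sc$trunk, sc$legs]
      expect_equal(a$grand_score,
                   ref$C[min(a_ref, 8), min(b_ref, 7)])
    }
  }
})

test_that("neutral and worst-case postures hit the grand-score extremes", {
  m <- lemr_model()
  # all bands at their best (elbows inside 60-100): A=1, B=1, C(1,1)=1
  expect_equal(rula(best_band_posture(m), model = m)$grand_score, 1L)
  # a fully straightened elbow scores lower-arm 2 on the worksheet,
  # so the all-zero posture lands at grand score 2
  expect_equal(rula(neutral_posture(m), model = m)$grand_score, 2L)
  # every joint in its worst band with a heavy load saturates at 7
  p <- neutral_posture(m)
  for (s in c("l5", "l3", "t12")) p <- set_deg(p, m, s, "flex", 25)
  p <- set_deg(p, m, "l5", "rot", 25)
  p <- set_deg(p, m, "neck", "flex", -30)
  p <- set_deg(p, m, "neck", "rot", 40)
  for (s in c("upperarm_r", "upperarm_l")) p <- set_deg(p, m, s, "flex", 120)
  p <- set_deg(p, m, "upperarm_r", "abd", -40)
  p <- set_deg(p, m, "upperarm_l", "abd", 40)
  p <- set_deg(p, m, "clavicle_r", "abd", -15)
  p <- set_deg(p, m, "clavicle_l", "abd", 15)
  for (s in c("hand_r", "hand_l")) {
    p <- set_deg(p, m, s, "flex", 40)
    p <- set_deg(p, m, s, "abd", 20)
    p <- set_deg(p, m, s, "rot", 35)
  }
  p <- set_deg(p, m, "shank_r", "flex", 80)
  a <- rula(p, load = 12, model = m)
  expect_equal(a$grand_score, 7L)
})

test_that("grand scores stay within 1..7 over random postures", {
  m <- lemr_model()
  g <- rula(random_postures(500, 21), model = m)
  expect_true(all(g %in% 1:7))
})

test_that("posture adjustments raise the arm sub-scores", {
  m <- lemr_model()
  base <- best_band_posture(m)
  a0 <- rula(base, model = m)
  # shoulder raised (right clavicle elevation is negative abduction)
  a1 <- rula(set_deg(base, m, "clavicle_r", "abd", -15), model = m)
  expect_equal(a1$sub_scores$ua_r, a0$sub_scores$ua_r + 1L)
  # upper arm abducted outward
  a2 <- rula(set_deg(base, m, "upperarm_r", "abd", -45), model = m)
  expect_equal(a2$sub_scores$ua_r, a0$sub_scores$ua_r + 1L)
  # wrist deviation
  a3 <- rula(set_deg(base, m, "hand_l", "abd", 15), model = m)
  expect_equal(a3$sub_scores$wr_l, a0$sub_scores$wr_l + 1L)
  # trunk twist
  a4 <- rula(set_deg(base, m, "l5", "rot", 25), model = m)
  expect_equal(a4$sub_scores$trunk, a0$sub_scores$trunk + 1L)
})

test_that("force/load score follows the worksheet bands", {
  expect_equal(rula_load_score(c(0, 1.9, 2, 9, 11)),
               c(0L, 0L, 1L, 1L, 3L))
  expect_equal(rula_load_score(5, static = TRUE), 2L)
  m <- lemr_model()
  g0 <- rula(best_band_posture(m), load = 0, model = m)$grand_score
  g3 <- rula(best_band_posture(m), load = 12, model = m)$grand_score
  expect_gt(g3, g0)
})
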