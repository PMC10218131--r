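test_that("expected gains collapse correctly at pure GRS states", {
  set.seed(7)
  p <- random_params()
  g1 <- expected_gains(0.3, 1, p)
  expect_equal(g1$He1, p$pi_e - p$c_e + p$gamma)
  g0 <- expected_gains(0.3, 0, p)
  expect_equal(g0$He2, p$pi_e)
})

test_that("expected gains at (0.5, 0.5) match hand substitution", {
  g <- expected_gains(0.5, 0.5, baseline_params())
  expect_equal(g$He1, 6)
  expect_equal(g$He2, 8)
  expect_equal(g$Hg1, -2)
  # 0.5*(-c_v) + 0.5*(-c_v - c_s) = -2; consistent with dr/dt = 0 here
  expect_equal(g$Hg2, -2)
})

test_that("mixture identities He = m He1 + (1-m) He2 hold exactly", {
  set.seed(8)
  for (k in 1:50) {
    p <- random_params()
    m <- runif(1); r <- runif(1)
    g <- expected_gains(m, r, p)
    expect_identical(g$He, m * g$He1 + (1 - m) * g$He2)
    expect_identical(g$Hg, r * g$Hg1 + (1 - r) * g$Hg2)
  }
})

test_that("closed-form replicator rhs equals the expected-gain differences", {
  set.seed(9)
  for (k in 1:1000) {
    p <- random_params()
    m <- runif(1); r <- runif(1)
    rhs <- replicator_rhs(m, r, p)
    g <- expected_gains(m, r, p)
    expect_equal(unname(rhs[1]), m * (g$He1 - g$He), tolerance = 1e-12)
    expect_equal(unname(rhs[2]), r * (g$Hg1 - g$Hg), tolerance = 1e-12)
  }
})

test_that("replicator boundaries and bracket roots are fixed", {
  p <- baseline_params(gamma = 1.5, delta = 1)
  expect_equal(unname(replicator_rhs(0, 0.7, p)[1]), 0)
  expect_equal(unname(replicator_rhs(0.5, 0.5, baseline_params())),
               c(-0.5, 0))
  r_root <- p$c_e / (p$gamma + p$delta)   # 0.8, inside the unit interval
  for (m in c(0.2, 0.5, 0.9))
    expect_equal(unname(replicator_rhs(m, r_root, p)[1]), 0)
  expect_error(replicator_rhs(1.2, 0.5, p), "\\[0, 1\\]")
})

test_that("five candidates are always enumerated; interior existence rules", {
  set.seed(10)
  for (k in 1:30) {
    fps <- find_fixed_points(random_params())
    expect_equal(nrow(fps), 5)
    expect_true(all(fps$exists[1:4]))
  }
  # no intervention: r* = c_e / (gamma + delta) undefined
  fps0 <- find_fixed_points(baseline_params())
  expect_false(fps0$exists[fps0$point == "interior"])
  expect_equal(sum(fps0$exists), 4)
  # delta = 2.4: interior candidate at (1.72/2.72, 2/2.4)
  fps1 <- find_fixed_points(baseline_params(delta = 2.4))
  int <- fps1[fps1$point == "interior", ]
  expect_true(int$exists)
  expect_equal(int$m, 1.72 / 2.72)
  expect_equal(int$r, 2 / 2.4)
})

test_that("baseline classification: (0,1) stable sink, (1,1) unstable source", {
  fps <- find_fixed_points(baseline_params())
  p01 <- fps[fps$point == "(0,1)", ]
  expect_equal(p01$det_j, 2)
  expect_equal(p01$tr_j, -3)
  expect_equal(p01$stability, "STABLE")
  p11 <- fps[fps$point == "(1,1)", ]
  expect_equal(p11$det_j, 2)
  expect_equal(p11$tr_j, 3)
  expect_equal(p11$stability, "UNSTABLE")
})

test_that("(0,0) is a saddle whenever both brackets are positive there", {
  set.seed(11)
  found <- 0
  for (k in 1:100) {
    p <- random_params()
    if (p$c_e > 0 &&
        p$pi_g - p$c_g + p$beta * p$delta + p$c_s + p$c_v > 0) {
      fp <- find_fixed_points(p)
      expect_lt(fp$det_j[fp$point == "(0,0)"], 0)
      expect_equal(fp$stability[fp$point == "(0,0)"], "SADDLE")
      found <- found + 1
    }
  }
  expect_gt(found, 10)
})

test_that("corner Det/Tr match the printed closed forms under substitution", {
  set.seed(12)
  for (k in 1:200) {
    p <- random_params()
    fps <- find_fixed_points(p)
    for (pt in c("(0,0)", "(0,1)", "(1,0)", "(1,1)")) {
      o <- corner_detr_oracle(pt, p)
      row <- fps[fps$point == pt, ]
      expect_equal(row$det_j, unname(o["det"]), tolerance = 1e-12)
      expect_equal(row$tr_j, unname(o["tr"]), tolerance = 1e-12)
    }
  }
})

test_that("analytic Jacobian agrees with central finite differences", {
  fd_detr <- function(m, r, p, h = 1e-6) {
    # central differences of the rhs, evaluated without clipping issues
    # evaluate the closed form directly so probes may sit just outside [0,1]
    f <- function(mm, rr) {
      pp <- p
      c(mm * (1 - mm) * (rr * (pp$gamma + pp$delta) - pp$c_e),
        rr * (1 - rr) * (pp$pi_g - pp$c_g + pp$beta * pp$delta +
                           pp$c_s + pp$c_v - mm * (pp$c_s + pp$beta * pp$delta)))
    }
    j11 <- (f(m + h, r)[1] - f(m - h, r)[1]) / (2 * h)
    j12 <- (f(m, r + h)[1] - f(m, r - h)[1]) / (2 * h)
    j21 <- (f(m + h, r)[2] - f(m - h, r)[2]) / (2 * h)
    j22 <- (f(m, r + h)[2] - f(m, r - h)[2]) / (2 * h)
    c(det = j11 * j22 - j12 * j21, tr = j11 + j22)
  }
  set.seed(13)
  for (k in 1:20) {
    p <- random_params()
    fps <- find_fixed_points(p)
    for (i in which(fps$exists)) {
      o <- fd_detr(fps$m[i], fps$r[i], p)
      expect_equal(fps$det_j[i], unname(o["det"]), tolerance = 1e-6)
      expect_equal(fps$tr_j[i], unname(o["tr"]), tolerance = 1e-6)
    }
  }
})

test_that("(0,1) is stable iff gamma + delta < c_e on the relevant regime", {
  set.seed(14)
  found <- 0
  for (k in 1:300) {
    p <- random_params()
    A <- p$pi_g - p$c_g + p$beta * p$delta + p$c_v + p$c_s
    if (A > 0 && p$pi_g - p$c_g + p$c_v < 0) {
      fp <- classify_stability(0, 1, p)
      expect_equal(fp$stability == "STABLE", p$gamma + p$delta < p$c_e)
      found <- found + 1
    }
  }
  expect_gt(found, 20)
})

test_that("trajectories stay put at corners and converge to the stable sink", {
  p <- baseline_params()
  for (corner in list(c(0, 0), c(1, 1), c(0, 1), c(1, 0))) {
    tr <- integrate_replicator(corner[1], corner[2], p, horizon = 5)
    expect_equal(max(abs(tr$m - corner[1])), 0)
    expect_equal(max(abs(tr$r - corner[2])), 0)
  }
  tr <- integrate_replicator(0.1, 0.4, p, horizon = 60)
  end <- tail(tr, 1)
  expect_lt(end$m, 1e-6)
  expect_gt(end$r, 1 - 1e-6)
})

test_that("halving the integrator step leaves the endpoint unchanged", {
  p <- baseline_params(gamma = 0.6, delta = 1)
  e1 <- tail(integrate_replicator(0.3, 0.6, p, horizon = 20, step = 0.01), 1)
  e2 <- tail(integrate_replicator(0.3, 0.6, p, horizon = 20, step = 0.005), 1)
  expect_equal(c(e1$m, e1$r), c(e2$m, e2$r), tolerance = 1e-8)
})
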