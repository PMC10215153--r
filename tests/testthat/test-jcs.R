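frames <- anatomical_frames("right")

# independent forward map: compose poses directly from joint coordinates,
# written without reference to to_jcs/from_jcs internals
compose_poses <- function(fe, vv, ie, ap, ml, is, femur_pose = diag(4)) {
  RF <- femur_pose[1:3, 1:3]
  RT <- RF %*% rot_z(-fe) %*% rot_x(vv) %*% rot_y(-ie)
  e1 <- RF %*% c(0, 0, 1)
  e3 <- RT %*% c(0, 1, 0)
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  e2 <- e2 / sqrt(sum(e2^2))
  t <- femur_pose[1:3, 4] + ml * as.numeric(e1) + ap * e2 + is * as.numeric(e3)
  list(femur = femur_pose, tibia = rigid_transform(RT, t))
}

test_that("the reference pose maps to all-zero joint coordinates", {
  j <- to_jcs(diag(4), diag(4), frames)
  expect_equal(as.numeric(j), rep(0, 6))
})

test_that("single-axis motions map to single JCS coordinates", {
  ps <- kneelax:::state_poses(joint_state(fe = 30))
  expect_equal(as.numeric(to_jcs(ps$femur, ps$tibia, frames)),
               c(30, 0, 0, 0, 0, 0), tolerance = 1e-12)
  ps <- kneelax:::state_poses(joint_state(aa = -4))
  expect_equal(to_jcs(ps$femur, ps$tibia, frames)$vv, -4, tolerance = 1e-12)
  ps <- kneelax:::state_poses(joint_state(ie = 7))
  expect_equal(to_jcs(ps$femur, ps$tibia, frames)$ie, 7, tolerance = 1e-12)
  ps <- kneelax:::state_poses(joint_state(ap = -3))
  expect_equal(to_jcs(ps$femur, ps$tibia, frames)$ap, -3, tolerance = 1e-12)
})

test_that("to_jcs agrees with an independent pose-composition oracle", {
  set.seed(11)
  for (i in 1:50) {
    q <- c(fe = runif(1, -45, 45), vv = runif(1, -45, 45),
           ie = runif(1, -45, 45), ap = runif(1, -20, 20),
           ml = runif(1, -20, 20), is = runif(1, -20, 20))
    Ff <- rigid_transform(rot_x(runif(1, -30, 30)) %*% rot_z(runif(1, -60, 60)))
    ps <- compose_poses(q["fe"], q["vv"], q["ie"], q["ap"], q["ml"], q["is"],
                        femur_pose = Ff)
    got <- to_jcs(ps$femur, ps$tibia, frames)
    expect_equal(as.numeric(got[c("fe", "vv", "ie", "ap", "ml", "is")]),
                 as.numeric(q), tolerance = 1e-9)
  }
})

test_that("pose reconstruction round-trips 1000 random poses to 1e-9", {
  set.seed(12)
  worst <- 0
  for (i in 1:1000) {
    q <- tibble::tibble(fe = runif(1, -45, 45), vv = runif(1, -45, 45),
                        ie = runif(1, -45, 45), ap = runif(1, -20, 20),
                        ml = runif(1, -20, 20), is = runif(1, -20, 20))
    tp <- from_jcs(q, frames)
    back <- to_jcs(diag(4), tp, frames)
    worst <- max(worst, max(abs(as.numeric(back) - as.numeric(q))))
  }
  expect_lt(worst, 1e-9)
})

test_that("gimbal degeneracy at |adduction| = 90 degrees errors", {
  tp <- rigid_transform(rot_x(90))
  expect_error(to_jcs(diag(4), tp, frames), "gimbal")
})

test_that("mirroring to a left knee negates VV and IE but keeps FE and AP", {
  left <- anatomical_frames("left")
  M4 <- diag(4); M4[3, 3] <- -1
  set.seed(13)
  for (i in 1:20) {
    ps <- compose_poses(runif(1, 0, 60), runif(1, -8, 8), runif(1, -10, 10),
                        runif(1, -5, 5), runif(1, -5, 5), runif(1, -5, 5))
    right <- to_jcs(ps$femur, ps$tibia, frames)
    mirrored <- to_jcs(M4 %*% ps$femur %*% M4, M4 %*% ps$tibia %*% M4, left)
    expect_equal(mirrored$fe, right$fe, tolerance = 1e-9)
    expect_equal(mirrored$ap, right$ap, tolerance = 1e-9)
    expect_equal(mirrored$is, right$is, tolerance = 1e-9)
    expect_equal(mirrored$vv, -right$vv, tolerance = 1e-9)
    expect_equal(mirrored$ie, -right$ie, tolerance = 1e-9)
    expect_equal(mirrored$ml, -right$ml, tolerance = 1e-9)
  }
})

test_that("laxity is the absolute coordinate difference at matched flexion", {
  n <- tibble::tibble(fe = 30, vv = -0.4, ie = 1, ap = 0.2, ml = 0, is = 0)
  l <- tibble::tibble(fe = 30, vv = 5.1, ie = -2, ap = -0.6, ml = 0, is = 0)
  expect_equal(laxity(n, l, "vv"), 5.5)
  expect_equal(laxity(n, l, "ap"), 0.8)
  expect_equal(laxity(n, n, "vv"), 0)
  # invariant to a shared offset
  n2 <- n; l2 <- l
  n2$vv <- n2$vv + 3; l2$vv <- l2$vv + 3
  expect_equal(laxity(n2, l2, "vv"), laxity(n, l, "vv"))
  bad <- l; bad$fe <- 30.5
  expect_error(laxity(n, bad, "vv"), "flexion")
})

test_that("baseline-relative curves are zero for baseline and idempotent", {
  kin <- tidyr::expand_grid(condition = c("baseline", "external"),
                            test = c("neutral", "posterior"),
                            flexion_deg = c(0, 30, 60))
  kin$ap <- ifelse(kin$condition == "external", 1, 0) + kin$flexion_deg / 60
  kin$vv <- 0.5 * kin$flexion_deg / 30
  rel <- relative_to_baseline(kin)
  base_neutral <- dplyr::filter(rel, condition == "baseline", test == "neutral")
  expect_true(all(base_neutral$ap == 0 & base_neutral$vv == 0))
  # a condition with a constant +1 offset keeps that offset at every angle
  ext <- dplyr::filter(rel, condition == "external")
  expect_true(all(ext$ap == 1))
  # deltas of deltas vanish
  rel2 <- relative_to_baseline(rel)
  expect_equal(rel2$ap, rel$ap)
  expect_error(relative_to_baseline(dplyr::filter(kin, test != "neutral")),
               "baseline")
})
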