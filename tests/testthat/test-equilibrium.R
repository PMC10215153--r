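# a symmetric toy knee: no condylar twist, no component rotation, two
# mirror-image non-wrapping collateral ligaments
symmetric_model <- local({
  m <- NULL
  function() {
    if (!is.null(m)) return(m)
    tab <- tibble::tibble(
      name = c("aMED", "pMED", "aLAT", "pLAT"),
      ligament = c("MED", "MED", "LAT", "LAT"),
      stiffness = 1200, reference_strain = 3, augmented = FALSE)
    ins <- tibble::tibble(
      ligament = c("MED", "MED", "LAT", "LAT"),
      bundle = c("aMED", "pMED", "aLAT", "pLAT"),
      fx = c(4, -4, 4, -4), fy = 0, fz = c(-35, -35, 35, 35),
      tx = c(4, -4, 4, -4), ty = -60, tz = c(-35, -35, 35, 35),
      wrap = "")
    lp <- list(table = tab, insertions = ins, eps_t = 0.03)
    g <- make_knee_geometry(native_pca_twist = 0)
    m <<- knee_model(g, alignment_condition("custom", rotation = 0), lp)
    m
  }
})

test_that("slack, separated joints carry zero generalized load and error on solve", {
  m <- symmetric_model()
  slack <- m
  slack$bundles$l_0 <- slack$bundles$l_0 * 10
  st <- joint_state(is = -10)           # dropped tibia: no contact
  g <- generalized_loads(slack, st)
  expect_equal(unname(g), rep(0, 6), tolerance = 1e-9)
  expect_error(solve_equilibrium(slack, dof_spec(fe = 0), initial = st),
               "dislocation")
})

test_that("a single vertical fiber loads only the IS channel", {
  m <- symmetric_model()
  one <- m
  one$bundles <- tibble::tibble(
    ligament = "TOY", name = "toy", stiffness = 1000,
    fx = 0, fy = 0, fz = 0, tx = 0, ty = -50, tz = 0,
    wrap = "", l_r = 50, l_0 = 45)
  st <- joint_state(is = -5)            # tibia dropped, no contact
  g <- generalized_loads(one, st)
  strain <- (55 - 45) / 45
  # the taut fiber pulls the tibia towards the femur (proximally)
  expect_equal(unname(g[["is"]]), fiber_tension(strain, 1000),
               tolerance = 1e-9)
  expect_equal(unname(g[c("fe", "aa", "ie", "ap", "ml")]), rep(0, 5),
               tolerance = 1e-9)
})

test_that("generalized loads are the negative energy gradient", {
  m <- symmetric_model()
  # ligament system (contact separated): the projection is an exact
  # gradient, checked to far better than 1e-3 relative on every DOF
  st <- joint_state(fe = 10, aa = 0.5, ie = 2, ap = 0.5, ml = 0.3, is = -2)
  g <- generalized_loads(m, st)
  for (d in dof_names <- c("fe", "aa", "ie", "ap", "ml", "is")) {
    h <- 1e-4
    s1 <- st; s1[[d]] <- s1[[d]] - h
    s2 <- st; s2[[d]] <- s2[[d]] + h
    dE <- (kneelax:::total_energy(m, s2) - kneelax:::total_energy(m, s1)) /
      (2 * h)
    if (d %in% c("fe", "aa", "ie")) dE <- dE * 180 / pi   # moments per radian
    expect_lt(abs(unname(g[[d]]) + dE), 1e-3 * max(abs(dE), 1))
  }
  # with penalty contact engaged the IS translation gradient stays exact
  # (the contact force's IS component is the penalty pressure itself);
  # rotational contact gradients are smoothed by the interpolated normals
  # and are certified along equilibrium paths by the 2% energy-consistency
  # sweep below
  sol <- solve_equilibrium(m, dof_spec(fe = 10))
  st2 <- sol$state
  g2 <- generalized_loads(m, st2)
  h <- 2e-4
  s1 <- st2; s1[["is"]] <- s1[["is"]] - h
  s2 <- st2; s2[["is"]] <- s2[["is"]] + h
  dE <- (kneelax:::total_energy(m, s2) - kneelax:::total_energy(m, s1)) /
    (2 * h)
  expect_lt(abs(unname(g2[["is"]]) + dE), 1e-3 * max(abs(dE), 50))
})

test_that("neutral extension of a symmetric knee stays on the midline", {
  m <- symmetric_model()
  sol <- solve_equilibrium(m, dof_spec(fe = 0))
  expect_true(sol$converged)
  expect_lt(abs(sol$jcs$vv), 0.05)
  expect_lt(abs(sol$jcs$ie), 0.05)
  expect_lt(abs(sol$jcs$ml), 0.05)
  # converged residual contract
  expect_true(all(abs(sol$residuals[c("ap", "ml", "is")]) <= 0.5))
  expect_true(all(abs(sol$residuals[c("aa", "ie")]) <= 50))
})

test_that("a varus torque rotates the knee into varus, monotonically", {
  m <- default_model()
  neutral <- solve_equilibrium(m, dof_spec(fe = 15))
  expect_true(neutral$converged)
  # monotone load-displacement sweep
  vv_prev <- neutral$jcs$vv
  state <- neutral$state
  J <- attr(neutral, "jacobian")
  for (tq in c(2000, 4000, 6000, 8000)) {
    sol <- solve_equilibrium(m, dof_spec(fe = 15, targets = c(aa = tq)),
                             initial = state, J_init = J)
    expect_true(sol$converged)
    expect_gt(sol$jcs$vv, vv_prev)
    vv_prev <- sol$jcs$vv
    state <- sol$state
    J <- attr(sol, "jacobian")
  }
  expect_gt(vv_prev, neutral$jcs$vv + 0.5)
})

test_that("work done by a frictionless varus ramp equals the elastic energy gain", {
  m <- default_model()
  neutral <- solve_equilibrium(m, dof_spec(fe = 15))
  state <- neutral$state
  J <- attr(neutral, "jacobian")
  torques <- seq(0, 8000, length.out = 11)
  theta <- numeric(length(torques)); energy <- numeric(length(torques))
  theta[1] <- state[["aa"]]
  energy[1] <- kneelax:::total_energy(m, state)
  for (k in 2:length(torques)) {
    sol <- solve_equilibrium(m, dof_spec(fe = 15, targets = c(aa = torques[k])),
                             initial = state, J_init = J)
    expect_true(sol$converged)
    state <- sol$state; J <- attr(sol, "jacobian")
    theta[k] <- state[["aa"]]
    energy[k] <- kneelax:::total_energy(m, state)
  }
  d_th <- diff(theta) * pi / 180
  work <- sum((torques[-1] + torques[-length(torques)]) / 2 * d_th)
  gain <- energy[length(energy)] - energy[1]
  expect_equal(work, gain, tolerance = 0.02 * abs(gain))
})

test_that("neutral flexion is continuous and deterministic", {
  m <- default_model()
  traj <- neutral_flexion(m, c(0, 15, 30))
  vv <- vapply(traj, function(s) s$jcs$vv, 0)
  expect_true(all(abs(diff(vv)) < 3))
  expect_true(all(vapply(traj, function(s) s$converged, TRUE)))
  # identical inputs give identical solutions (fresh models, no randomness)
  g <- default_geometry()
  m1 <- knee_model(g, "baseline"); m2 <- knee_model(g, "baseline")
  s1 <- solve_equilibrium(m1, dof_spec(fe = 15))
  s2 <- solve_equilibrium(m2, dof_spec(fe = 15))
  expect_identical(s1$state, s2$state)
  expect_identical(s1$jcs, s2$jcs)
})

test_that("dof_spec enforces the simulator DOF structure", {
  expect_error(dof_spec(fe = 0, targets = c(fe = 1)), "unknown")
  expect_error(dof_spec(fe = 0, prescribed = c(vv = 1)), "unknown")
  sp <- dof_spec(fe = 30, targets = c(aa = 8000))
  expect_equal(sp$targets[["aa"]], 8000)
  expect_equal(sort(sp$free), sort(c("aa", "ie", "ap", "ml", "is")))
})
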