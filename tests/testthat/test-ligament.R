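test_that("reference strain and slack length invert each other", {
  expect_equal(reference_strain(40, 40), 0)
  expect_equal(reference_strain(52, 50), 4)
  expect_equal(slack_length(40, 0), 40)
  expect_equal(slack_length(52, 4), 50)
  # round trip identity to 1e-9 relative over a grid
  lr <- seq(10, 120, by = 7.3)
  er <- seq(-60, 60, by = 11.7)
  for (l in lr) for (e in er) {
    l0 <- slack_length(l, e)
    expect_equal(reference_strain(l, l0), e, tolerance = 1e-9)
    expect_equal(slack_length(l, reference_strain(l, l0)), l0, tolerance = 1e-9)
  }
  expect_error(reference_strain(50, 0), "positive")
  expect_error(slack_length(50, -100), "-100")
})

test_that("fiber force law is slack below zero, C1 at the toe junction, monotone", {
  k <- 1000; eps_t <- 0.03
  expect_equal(fiber_tension(-0.05, k, eps_t), 0)
  expect_equal(fiber_tension(0, k, eps_t), 0)
  # both branches agree at strain = 2*eps_t, value k*eps_t
  expect_equal(fiber_tension(2 * eps_t, k, eps_t), k * eps_t)
  # C1: slopes match across the junction
  h <- 1e-7
  slope_lo <- (fiber_tension(2 * eps_t, k, eps_t) -
               fiber_tension(2 * eps_t - h, k, eps_t)) / h
  slope_hi <- (fiber_tension(2 * eps_t + h, k, eps_t) -
               fiber_tension(2 * eps_t, k, eps_t)) / h
  expect_equal(slope_lo, slope_hi, tolerance = 1e-4)
  # closed-form spot value: linear branch k*(strain - eps_t)
  expect_equal(fiber_tension(0.10, 1000, 0.03), 70)
  # monotone non-decreasing over [-0.1, 0.5] by brute-force differencing
  s <- seq(-0.1, 0.5, by = 1e-3)
  f <- fiber_tension(s, k, eps_t)
  expect_true(all(diff(f) >= -1e-12))
})

test_that("fiber energy is the integral of the tension", {
  k <- 1481; l0 <- 95; eps_t <- 0.03
  for (s1 in c(0.01, 0.05, 0.2)) {
    num <- stats::integrate(function(e) fiber_tension(e, k, eps_t) * l0,
                            0, s1, rel.tol = 1e-10)$value
    expect_equal(fiber_energy(s1, k, l0, eps_t), num, tolerance = 1e-7)
  }
  expect_equal(fiber_energy(-0.1, k, l0, eps_t), 0)
})

test_that("bundle augmentation interpolates insertions and reference strains", {
  lp <- read_ligament_params()
  tab <- lp$table

  # collateral 3 -> 5: mean-of-neighbours reference strains match the
  # packaged final table to its printed precision
  lcl <- dplyr::inner_join(
    dplyr::filter(lp$insertions, ligament == "LCL"),
    dplyr::filter(tab, !augmented), by = c("ligament", "bundle" = "name")) |>
    dplyr::rename(name = "bundle")
  aug <- augment_bundles(lcl)
  expect_equal(nrow(aug), 5)
  expect_equal(aug$name, c("aLCL", "amLCL", "mLCL", "mpLCL", "pLCL"))
  printed <- tab$reference_strain[match(c("amLCL", "mpLCL"), tab$name)]
  got <- aug$reference_strain[match(c("amLCL", "mpLCL"), aug$name)]
  expect_true(all(abs(got - printed) <= 0.005 + 1e-9))
  # midpoint insertions
  expect_equal(aug$fx[2], (aug$fx[1] + aug$fx[3]) / 2)
  expect_equal(aug$tz[4], (aug$tz[3] + aug$tz[5]) / 2)

  smcl <- dplyr::inner_join(
    dplyr::filter(lp$insertions, ligament == "sMCL"),
    dplyr::filter(tab, !augmented), by = c("ligament", "bundle" = "name")) |>
    dplyr::rename(name = "bundle")
  aug2 <- augment_bundles(smcl)
  printed2 <- tab$reference_strain[match(c("am-sMCL", "mp-sMCL"), tab$name)]
  got2 <- aug2$reference_strain[match(c("am-sMCL", "mp-sMCL"), aug2$name)]
  expect_true(all(abs(got2 - printed2) <= 0.005 + 1e-9))

  # PCL 2 -> 3, middle bundle named mPCL with the averaged strain
  pcl <- dplyr::inner_join(
    dplyr::filter(lp$insertions, ligament == "PCL"),
    dplyr::filter(tab, !augmented), by = c("ligament", "bundle" = "name")) |>
    dplyr::rename(name = "bundle")
  aug3 <- augment_bundles(pcl)
  expect_equal(nrow(aug3), 3)
  expect_equal(aug3$name[2], "mPCL")
  expect_equal(aug3$reference_strain[2], mean(c(-28.6, -26.3)))

  # degenerate midpoint: identical neighbours collapse onto themselves
  twin <- toy_bundles(k = c(500, 500), er = c(3, 3))
  twin[2, c("fx", "fy", "fz", "tx", "ty", "tz")] <-
    twin[1, c("fx", "fy", "fz", "tx", "ty", "tz")]
  aug4 <- augment_bundles(twin)
  expect_equal(aug4$reference_strain[2], 3)
  expect_equal(unlist(aug4[2, c("fx", "fy", "fz")]),
               unlist(aug4[1, c("fx", "fy", "fz")]))

  expect_error(augment_bundles(twin[1, ]), "at least 2")
})

test_that("stiffness calibration conserves total tension at the distraction pose", {
  b <- toy_bundles()
  aug <- augment_bundles(b)
  cal <- calibrate_stiffness(b, aug, distraction = c(0, -5, 0))
  tension_at <- function(bb, d) {
    l <- sqrt((bb$fx - bb$tx)^2 + (bb$fy - (bb$ty + d))^2 + (bb$fz - bb$tz)^2)
    sum(fiber_tension((l - bb$l_0) / bb$l_0, bb$stiffness))
  }
  expect_equal(tension_at(cal, -5), tension_at(b, -5), tolerance = 1e-6)
  # uniform scaling: pre-existing bundles keep their relative force split
  ratio_orig <- with(b, {
    l <- sqrt((fx - tx)^2 + (fy - (ty - 5))^2 + (fz - tz)^2)
    f <- fiber_tension((l - l_0) / l_0, stiffness)
    f[1] / f[2]
  })
  keep <- match(b$name, cal$name)
  l <- sqrt((cal$fx - cal$tx)^2 + (cal$fy - (cal$ty - 5))^2 + (cal$fz - cal$tz)^2)
  f <- fiber_tension((l - cal$l_0) / cal$l_0, cal$stiffness)
  expect_equal(f[keep[1]] / f[keep[2]], ratio_orig, tolerance = 0.05)

  # identity case: calibrating a set against itself leaves stiffness alone
  same <- calibrate_stiffness(b, b, distraction = c(0, -5, 0))
  expect_equal(attr(same, "scale_factor"), 1, tolerance = 1e-12)
  expect_equal(same$stiffness, b$stiffness)

  # splitting two identical parallel fibers into three conserves tension
  par2 <- toy_bundles(k = c(600, 600), er = c(5, 5))
  par2$fx <- c(1, -1); par2$tx <- c(1, -1)   # parallel verticals
  par2$l_r <- sqrt((par2$fx - par2$tx)^2 + (par2$fy - par2$ty)^2 +
                   (par2$fz - par2$tz)^2)
  par2$l_0 <- slack_length(par2$l_r, par2$reference_strain)
  par3 <- calibrate_stiffness(par2, augment_bundles(par2),
                              distraction = c(0, -4, 0))
  expect_equal(tension_at(par3, -4), tension_at(par2, -4), tolerance = 1e-6)
  # closed form: scale factor must be 2/3 for identical parallel fibers
  expect_equal(attr(par3, "scale_factor"), 2 / 3, tolerance = 1e-9)

  # nominal augmented total 250 vs original 200 -> factor 0.8
  fake_orig <- b; fake_aug <- augment_bundles(b)
  t_orig <- tension_at(fake_orig, -5); t_aug <- tension_at(fake_aug, -5)
  cal2 <- calibrate_stiffness(fake_orig, fake_aug, distraction = c(0, -5, 0))
  expect_equal(attr(cal2, "scale_factor"), t_orig / t_aug, tolerance = 1e-12)

  # slack bundle at the distraction pose is an error
  slack <- b; slack$l_0[1] <- slack$l_r[1] + 50
  expect_error(calibrate_stiffness(slack, augment_bundles(b),
                                   distraction = c(0, -1, 0)),
               "slack")
})
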