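test_that("implant parameter validation enforces conforming dish radii", {
  expect_s3_class(implant_params(), "implant_params")
  expect_error(implant_params(dish_radius_sagittal = 20), "conforming")
  expect_error(implant_params(condyle_radius = -1), "positive")
  expect_error(alignment_condition("internal", rotation = 3), "implies")
  expect_equal(alignment_condition("baseline")$rotation, 3.0)
  expect_equal(alignment_condition("internal")$rotation, 1.5)
  expect_equal(alignment_condition("external")$rotation, 4.5)
})

test_that("generated geometry has two condyles with the prescribed spacing", {
  g <- default_geometry()
  expect_s3_class(g$femoral_component, "klx_mesh")
  pca <- compute_pca(g$femoral_component)
  # exactly two condylar contact regions: posterior-most points on either
  # side of the sagittal midplane, separated by the condyle spacing
  expect_equal(abs(pca$lateral[3] - pca$medial[3]),
               g$params$condyle_spacing, tolerance = 0.5)
  # symmetric component: PCA perpendicular to the sagittal midplane
  expect_equal(pca$direction, c(0, 0, 1), tolerance = 1e-6,
               ignore_attr = TRUE)
  # mirror symmetry of the component about z = 0
  v <- g$femoral_component$vertices
  vm <- v; vm[, 3] <- -vm[, 3]
  ord <- function(m) m[order(round(m[, 1], 6), round(m[, 2], 6),
                             round(m[, 3], 6)), ]
  expect_equal(ord(v), ord(vm), tolerance = 1e-8)
})

test_that("PCA is invariant to vertex order and rotates with the mesh", {
  g <- default_geometry()
  comp <- g$femoral_component
  # vertex-order invariance
  set.seed(42)
  perm <- sample(nrow(comp$vertices))
  shuffled <- klx_mesh(comp$vertices[perm, ],
                       matrix(match(comp$faces, perm), ncol = 3),
                       comp$label)
  p1 <- compute_pca(comp); p2 <- compute_pca(shuffled)
  expect_equal(p1$medial, p2$medial, tolerance = 1e-9, ignore_attr = TRUE)
  # refinement invariance (finer theta/psi grid): within 0.1 mm
  fine <- kneelax:::condyle_mesh(g$params, -g$params$condyle_spacing / 2,
                                 "m", n_theta = 121, n_psi = 25)
  coarse <- kneelax:::condyle_mesh(g$params, -g$params$condyle_spacing / 2,
                                   "m", n_theta = 41, n_psi = 9)
  post <- function(m) m$vertices[which.max(-m$vertices[, 1]), ]
  expect_equal(post(fine), post(coarse), tolerance = 0.1, ignore_attr = TRUE)
  # a component pre-rotated about the proximal axis carries its PCA with it
  rot <- transform_mesh(comp, rotation_about(c(0, 1, 0), c(0, 0, 0), -3))
  p3 <- compute_pca(rot)
  ang <- kneelax:::external_angle_axial(p1$direction, p3$direction)
  expect_equal(ang, 3, tolerance = 0.15)
  # single-condyle mesh (no intercondylar gap) errors
  expect_error(compute_pca(sphere_mesh(radius = 20)), "gap")
})

test_that("oblique posterior condyles give the brute-force PCA angle", {
  g <- default_geometry()
  p <- g$params
  z0 <- p$condyle_spacing / 2
  med <- kneelax:::condyle_mesh(p, -z0, "m")
  lat <- kneelax:::condyle_mesh(p, +z0, "l")
  med$vertices[, 1] <- med$vertices[, 1] - 2    # 2 mm extra posterior offset
  two <- kneelax:::merge_meshes(list(med, lat), "oblique")
  # independent oracle: brute-force posterior-most vertex per half
  v <- two$vertices
  zmid <- mean(range(v[, 3]))
  pm <- v[v[, 3] < zmid, ][which.min(v[v[, 3] < zmid, 1]), ]
  pl <- v[v[, 3] >= zmid, ][which.min(v[v[, 3] >= zmid, 1]), ]
  expected <- atan2(pm[1] - pl[1], pl[3] - pm[3]) * 180 / pi
  pca <- compute_pca(two)
  got <- atan2(pca$medial[1] - pca$lateral[1],
               pca$lateral[3] - pca$medial[3]) * 180 / pi
  expect_equal(got, expected, tolerance = 1e-9)
  expect_equal(abs(got), atan2(2, p$condyle_spacing) * 180 / pi,
               tolerance = 0.5)
})

test_that("component alignment is a pure axial rotation to the target angle", {
  g <- default_geometry()
  fp <- compute_pca(g$femur)
  cp <- compute_pca(g$femoral_component)

  # coincident axes and a matching target give the identity
  id <- align_component(fp, fp, alignment_condition("custom", rotation = 0))
  expect_equal(id, diag(4), tolerance = 1e-12)

  # external 4.5 deg: measured axial-plane angle on the transformed mesh
  ext <- alignment_condition("external")
  Tx <- align_component(fp, cp, ext)
  moved <- transform_mesh(g$femoral_component, Tx)
  ang <- kneelax:::external_angle_axial(fp$lateral - fp$medial,
                                        compute_pca(moved)$lateral -
                                          compute_pca(moved)$medial)
  expect_equal(ang, 4.5, tolerance = 0.01)

  # baseline then internal: the relative rotation between the two placements
  # is 1.5 deg about the proximal axis
  Tb <- align_component(fp, cp, alignment_condition("baseline"))
  Ti <- align_component(fp, cp, alignment_condition("internal"))
  rel <- Ti %*% solve(Tb)
  tr <- sum(diag(rel[1:3, 1:3]))
  expect_equal(acos((tr - 1) / 2) * 180 / pi, 1.5, tolerance = 1e-6)
  R <- rel[1:3, 1:3]
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  axis <- axis / sqrt(sum(axis^2))
  expect_equal(abs(axis[2]), 1, tolerance = 1e-9)

  # the distal-most point height is preserved (pure axial-plane rotation)
  expect_equal(min(moved$vertices[, 2]),
               min(g$femoral_component$vertices[, 2]), tolerance = 0.01)

  # degenerate axis errors
  bad <- list(medial = c(0, 0, 0), lateral = c(0, 0, 0))
  expect_error(align_component(bad, cp, ext), "degenerate")
})

test_that("alignment conditions differ only by the component transform", {
  g <- default_geometry()
  m1 <- knee_model(g, "baseline")
  m2 <- knee_model(g, "external")
  # bone and insert meshes are identical objects across conditions
  expect_identical(m1$geometry$insert, m2$geometry$insert)
  expect_identical(m1$geometry$tibia, m2$geometry$tibia)
  expect_identical(m1$geometry$femur, m2$geometry$femur)
  # the component differs purely by a rigid transform
  expect_false(isTRUE(all.equal(m1$component_medial$vertices,
                                m2$component_medial$vertices)))
  rel <- m2$component_transform %*% solve(m1$component_transform)
  back <- transform_mesh(m2$component_medial, solve(rel))
  expect_equal(back$vertices, m1$component_medial$vertices, tolerance = 1e-9)
})
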