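#' Parametric implant dimensions
#'
#' Dimensions (mm) of the synthetic single-radius cruciate-retaining TKA
#' implant surrogate. The femoral component has two toroidal condyles whose
#' sagittal profile is a single circular arc; the polyethylene insert carries
#' two conforming dished compartments separated by an intercondylar eminence.
#' Dish radii must be at least the corresponding condylar radii (conforming
#' or flat). The defaults describe a mid-size conforming CR design; they are
#' configurable, not claims about any commercial implant.
#'
#' @param condyle_radius sagittal (single) condylar radius.
#' @param condyle_coronal_radius coronal condylar cross-section radius.
#' @param condyle_spacing medial-lateral distance between condyle centres.
#' @param condyle_width coronal width of each condyle.
#' @param dish_radius_sagittal sagittal radius of each insert dish.
#' @param dish_radius_coronal coronal radius of each insert dish.
#' @param dish_half_length sagittal (AP) half-extent of each dish.
#' @param dish_half_width coronal half-extent of each dish compartment.
#' @param insert_thickness insert thickness at the dish low point.
#' @param tray_ap,tray_ml,tray_thickness tibial tray footprint and thickness.
#' @return object of class `implant_params`.
#' @export
implant_params <- function(condyle_radius = 24,
                           condyle_coronal_radius = 20,
                           condyle_spacing = 46,
                           condyle_width = 22,
                           dish_radius_sagittal = 24.4,
                           dish_radius_coronal = 21,
                           dish_half_length = 18,
                           dish_half_width = 12,
                           insert_thickness = 9,
                           tray_ap = 48, tray_ml = 74, tray_thickness = 4) {
  p <- list(condyle_radius = condyle_radius,
            condyle_coronal_radius = condyle_coronal_radius,
            condyle_spacing = condyle_spacing,
            condyle_width = condyle_width,
            dish_radius_sagittal = dish_radius_sagittal,
            dish_radius_coronal = dish_radius_coronal,
            dish_half_length = dish_half_length,
            dish_half_width = dish_half_width,
            insert_thickness = insert_thickness,
            tray_ap = tray_ap, tray_ml = tray_ml, tray_thickness = tray_thickness)
  if (any(unlist(p) <= 0)) stop("all implant dimensions must be positive")
  if (dish_radius_sagittal < condyle_radius)
    stop("sagittal dish radius must be >= condyle radius (conforming or flat)")
  if (dish_radius_coronal < condyle_coronal_radius)
    stop("coronal dish radius must be >= condyle coronal radius")
  if (condyle_width / 2 > condyle_coronal_radius)
    stop("condyle width incompatible with coronal radius")
  structure(p, class = "implant_params")
}

#' Femoral component alignment condition
#'
#' External rotation of the femoral component about the femoral
#' proximal-distal axis, referenced from the femur's posterior condyle axis
#' (PCA). The three study conditions are internal (1.5 deg), baseline
#' (3.0 deg) and external (4.5 deg) external rotation.
#'
#' @param name `"internal"`, `"baseline"` or `"external"`, or `"custom"`
#'   with an explicit `rotation`.
#' @param rotation external rotation in degrees (overrides the named value).
#' @return object of class `alignment_condition`.
#' @export
alignment_condition <- function(name = c("baseline", "internal", "external", "custom"),
                                rotation = NULL) {
  name <- match.arg(name)
  std <- c(internal = 1.5, baseline = 3.0, external = 4.5)
  if (is.null(rotation)) {
    if (name == "custom") stop("custom condition requires an explicit rotation")
    rotation <- std[[name]]
  } else if (name != "custom" && abs(rotation - std[[name]]) > 1e-12) {
    stop("named condition '", name, "' implies rotation ", std[[name]], " deg")
  }
  structure(list(name = name, rotation = rotation), class = "alignment_condition")
}

# sagittal/coronal sag of a circular arc of radius r at offset d from its apex
circ_sag <- function(d, r) r - sqrt(pmax(r^2 - d^2, 0))

# Insert articular (upper) surface height field in the tibia body frame.
# Dish low points sit at y = -condyle_radius so that at the reference pose
# (identity femur/tibia poses) the condyles rest in the dishes at zero depth.
insert_surface_height <- function(x, z, params) {
  p <- params
  d <- abs(abs(z) - p$condyle_spacing / 2)
  dmax <- 0.85 * p$dish_radius_coronal
  xs <- pmin(abs(x), 0.8 * p$dish_radius_sagittal)
  -p$condyle_radius +
    circ_sag(xs, p$dish_radius_sagittal) +
    circ_sag(pmin(d, dmax), p$dish_radius_coronal)
}

# Structured-grid triangulation of a height field y = f(x, z)
heightfield_mesh <- function(xs, zs, f, label) {
  g <- expand.grid(x = xs, z = zs)
  verts <- cbind(g$x, f(g$x, g$z), g$z)
  nx <- length(xs); nz <- length(zs)
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), nz - 1L)
  j <- rep(seq_len(nz - 1L), each = nx - 1L)
  f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  f2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  klx_mesh(verts, rbind(f1, f2), label)
}

# Toroidal condyle articular patch. theta = 0 points distal (-y), increasing
# towards posterior (-x); psi sweeps the coronal width about z0.
condyle_mesh <- function(params, z0, label,
                         theta_range = c(-56, 150), n_theta = 63, n_psi = 13) {
  p <- params
  r_maj <- p$condyle_radius - p$condyle_coronal_radius
  psi_max <- asin((p$condyle_width / 2) / p$condyle_coronal_radius)
  th <- seq(theta_range[1], theta_range[2], length.out = n_theta) * pi / 180
  ps <- seq(-psi_max, psi_max, length.out = n_psi)
  g <- expand.grid(th = th, ps = ps)
  rad <- r_maj + p$condyle_coronal_radius * cos(g$ps)
  verts <- cbind(-rad * sin(g$th), -rad * cos(g$th),
                 z0 + p$condyle_coronal_radius * sin(g$ps))
  nt <- n_theta; np <- n_psi
  idx <- function(i, j) (j - 1L) * nt + i
  i <- rep(seq_len(nt - 1L), np - 1L)
  j <- rep(seq_len(np - 1L), each = nt - 1L)
  f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  f2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  klx_mesh(verts, rbind(f1, f2), label)
}

# merge meshes into one labelled mesh
merge_meshes <- function(meshes, label) {
  offs <- cumsum(c(0, vapply(meshes, function(m) nrow(m$vertices), 0)))
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  faces <- do.call(rbind, purrr::map2(meshes, offs[-length(offs)],
                                      function(m, o) m$faces + as.integer(o)))
  klx_mesh(verts, faces, label)
}

# Tibia bone surrogate: a convex surface of revolution about the tibial long
# axis -- a plateau rim flaring linearly down to the shaft. Convexity makes
# the single-via-point wrap model exact (tangent-point contact); the sMCL
# drapes over the proximal-medial rim and flare.
tibia_profile_radius <- function(y) {
  17 + 16 * pmin(pmax((y + 92) / 62, 0), 1)
}

# closed (capped) surface of revolution of the tibial profile
revolve_closed <- function(ys, label, n_ang = 36) {
  ang <- seq(0, 2 * pi, length.out = n_ang + 1)[-(n_ang + 1)]
  g <- expand.grid(a = ang, y = ys)
  r <- tibia_profile_radius(g$y)
  verts <- cbind(r * cos(g$a), g$y, r * sin(g$a))
  ny <- length(ys)
  idx <- function(i, j) (j - 1L) * n_ang + i
  i <- rep(seq_len(n_ang), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = n_ang)
  ip1 <- ifelse(i == n_ang, 1L, i + 1L)
  f1 <- cbind(idx(i, j), idx(ip1, j), idx(ip1, j + 1L))
  f2 <- cbind(idx(i, j), idx(ip1, j + 1L), idx(i, j + 1L))
  # cap fans so the surface is closed and crossing parity is well defined
  ctop <- nrow(verts) + 1L; cbot <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, ys[1], 0), c(0, ys[ny], 0))
  i2 <- seq_len(n_ang); ip2 <- ifelse(i2 == n_ang, 1L, i2 + 1L)
  ftop <- cbind(rep(ctop, n_ang), idx(ip2, 1L), idx(i2, 1L))
  fbot <- cbind(rep(cbot, n_ang), idx(i2, ny), idx(ip2, ny))
  klx_mesh(verts, rbind(f1, f2, ftop, fbot), label)
}

tibia_bone_meshes <- function(params) {
  bone <- revolve_closed(seq(-30, -130, length.out = 28), "tibia")
  wrap <- revolve_closed(seq(-30, -80, length.out = 15), "tibia_medial_wrap")
  list(bone = bone, wrap = wrap)
}

femur_bone_mesh <- function(params, native_pca_twist = 4) {
  p <- params
  # posterior condylar prongs of the native femur (PCA reference) + shaft box;
  # condyle_mesh only reads the radii and width fields. The native posterior
  # condyles are internally twisted relative to the cylindrical flexion axis
  # (the asymmetry that motivates external component rotation): the medial
  # posterior condyle is the more posterior of the two.
  pp <- list(condyle_radius = p$condyle_radius + 2,
             condyle_coronal_radius = p$condyle_coronal_radius,
             condyle_width = p$condyle_width)
  med <- condyle_mesh(pp, -p$condyle_spacing / 2, "femur_med", c(20, 120), 21, 7)
  lat <- condyle_mesh(pp, +p$condyle_spacing / 2, "femur_lat", c(20, 120), 21, 7)
  condyles <- merge_meshes(list(med, lat), "femur_condyles")
  # internal rotation = +y for a right knee (external is -y)
  tw <- rotation_about(c(0, 1, 0), c(-(p$condyle_radius + 2), 0, 0),
                       native_pca_twist)
  condyles <- transform_mesh(condyles, tw)
  shaft <- box_mesh(c(-14, 10, -16), c(14, 120, 16), "femur_shaft")
  merge_meshes(list(condyles, shaft), "femur")
}

box_mesh <- function(lo, hi, label) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  fc <- rbind(c(1, 3, 7), c(1, 7, 5), c(2, 6, 8), c(2, 8, 4),
              c(1, 5, 6), c(1, 6, 2), c(3, 4, 8), c(3, 8, 7),
              c(1, 2, 4), c(1, 4, 3), c(5, 7, 8), c(5, 8, 6))
  klx_mesh(v, fc, label)
}

#' Generate the synthetic TKA knee geometry
#'
#' Builds all labelled parts of a right-knee TKA surrogate in a documented
#' world frame (x = anterior, y = proximal, z = lateral; mm): the two-condyle
#' femoral component (symmetric design pose, PCA parallel to z), the dished
#' UHMWPE insert, the tibial tray, a femur surrogate with native posterior
#' condyles, and a tibia surrogate whose proximal-medial band is extracted as
#' the sMCL wrapping surface. The femoral flexion axis passes through the
#' origin along z; the insert dish low points sit at `y = -condyle_radius` so
#' the reference pose has the condyles seated at zero penetration.
#'
#' @param params an [implant_params()] object.
#' @param sampling_density multiplier on the default contact sample grid
#'   density (1 gives 21 x 11 points per compartment).
#' @param native_pca_twist internal twist (degrees) of the native femoral
#'   posterior condyles relative to the flexion axis. This is the condylar
#'   asymmetry that external component rotation corrects for; with the
#'   default 4 the mechanically aligned (baseline, 3 degrees external)
#'   component leaves a slightly medial-tight flexion gap, as in a native
#'   varus-tendency knee.
#' @return A list of class `knee_geometry`: meshes `femoral_component`,
#'   `insert`, `tray`, `femur`, `tibia`, `tibia_medial_wrap`, the condyle
#'   sub-meshes `component_medial`/`component_lateral`, a `contact_samples`
#'   tibble (x, y, z, area, compartment; tibia frame) and `params`.
#' @export
make_knee_geometry <- function(params = implant_params(), sampling_density = 1,
                               native_pca_twist = 4) {
  p <- params
  z0 <- p$condyle_spacing / 2
  med <- condyle_mesh(p, -z0, "component_medial")
  lat <- condyle_mesh(p, +z0, "component_lateral")
  component <- merge_meshes(list(med, lat), "femoral_component")
  xs <- seq(-0.8 * p$dish_radius_sagittal, 0.8 * p$dish_radius_sagittal, length.out = 25)
  zs <- seq(-(z0 + p$dish_half_width + 2), z0 + p$dish_half_width + 2, length.out = 31)
  insert <- heightfield_mesh(xs, zs, function(x, z) insert_surface_height(x, z, p),
                             "insert")
  tray_top <- -p$condyle_radius - p$insert_thickness
  tray <- box_mesh(c(-p$tray_ap / 2, tray_top - p$tray_thickness, -p$tray_ml / 2),
                   c(p$tray_ap / 2, tray_top, p$tray_ml / 2), "tray")
  tib <- tibia_bone_meshes(p)
  geom <- list(femoral_component = component,
               component_medial = med, component_lateral = lat,
               insert = insert, tray = tray,
               femur = femur_bone_mesh(p, native_pca_twist),
               tibia = tib$bone, tibia_medial_wrap = tib$wrap,
               contact_samples = contact_sample_grid(p, sampling_density),
               params = p)
  class(geom) <- "knee_geometry"
  geom
}

# Contact sample points on the insert articular surface (tibia frame), one
# grid per compartment, with tributary areas (projected onto the axial plane).
contact_sample_grid <- function(params, sampling_density = 1) {
  p <- params
  nx <- max(5L, as.integer(round(21 * sampling_density)))
  nz <- max(5L, as.integer(round(11 * sampling_density)))
  xs <- seq(-19.5, 19.5, length.out = nx)
  dz <- seq(-p$dish_half_width + 1, p$dish_half_width - 1, length.out = nz)
  area <- diff(xs[1:2]) * diff(dz[1:2])
  purrr::map_dfr(c(medial = -1, lateral = +1), function(s) {
    g <- expand.grid(x = xs, dzc = dz)
    z <- s * p$condyle_spacing / 2 + g$dzc
    tibble::tibble(x = g$x, y = insert_surface_height(g$x, z, p), z = z,
                   area = area,
                   compartment = if (s < 0) "medial" else "lateral")
  })
}

#' @export
print.knee_geometry <- function(x, ...) {
  cat("<knee_geometry>\n")
  for (nm in names(x))
    if (inherits(x[[nm]], "klx_mesh")) print(x[[nm]])
  cat(sprintf("  contact samples: %d\n", nrow(x$contact_samples)))
  invisible(x)
}

#' Posterior condyle axis of a two-condyle mesh
#'
#' Splits the mesh at the sagittal midplane of its bounding box, finds the
#' posterior-most vertex of each condylar half, and returns the segment
#' joining them. Errors when the two halves are not separated by an
#' intercondylar gap (single-condyle mesh).
#'
#' @param mesh a `klx_mesh` with two condyles.
#' @param posterior_direction unit vector pointing posteriorly (default -x).
#' @return list with `medial`, `lateral` (3-vectors, ordered by z),
#'   `direction` (unit, medial to lateral) and `midpoint`.
#' @export
compute_pca <- function(mesh, posterior_direction = c(-1, 0, 0)) {
  V <- mesh$vertices
  pd <- posterior_direction / sqrt(sum(posterior_direction^2))
  zmid <- mean(range(V[, 3]))
  lo <- V[V[, 3] < zmid, , drop = FALSE]
  hi <- V[V[, 3] >= zmid, , drop = FALSE]
  if (nrow(lo) == 0 || nrow(hi) == 0)
    stop("mesh does not have two condyles about its sagittal midplane")
  post <- function(M) M[which.max(M %*% pd), ]
  p_lo <- post(lo); p_hi <- post(hi)
  # intercondylar gap check: the central band must recede from the condylar
  # posterior extremes, otherwise this is a single continuous condyle
  span <- diff(range(V[, 3]))
  band <- V[abs(V[, 3] - zmid) < 0.1 * span, , drop = FALSE]
  cond_post <- min(sum(p_lo * pd), sum(p_hi * pd))
  if (nrow(band) > 0 && max(band %*% pd) > cond_post - 2)
    stop("no intercondylar gap found: single-condyle mesh?")
  dir <- p_hi - p_lo
  dir <- dir / sqrt(sum(dir^2))
  list(medial = p_lo, lateral = p_hi, direction = dir,
       midpoint = (p_lo + p_hi) / 2)
}

# signed external rotation (deg) of axis `b` relative to axis `a`, measured
# in the axial plane about +y; external positive for a right knee (the
# lateral end of the axis moves posteriorly, the medial end anteriorly)
external_angle_axial <- function(a, b) {
  pa <- c(a[1], a[3]); pa <- pa / sqrt(sum(pa^2))
  pb <- c(b[1], b[3]); pb <- pb / sqrt(sum(pb^2))
  # y-component of a x b, then external = -theta_y
  cy <- a[3] * b[1] - a[1] * b[3]
  # use normalized axial projections for the dot
  unname(atan2(-cy / (sqrt(sum(c(a[1], a[3])^2)) * sqrt(sum(c(b[1], b[3])^2))),
               sum(pa * pb)) * 180 / pi)
}

#' Alignment transform for the femoral component
#'
#' Computes the rigid transform that places the femoral component so its PCA
#' is externally rotated by `condition$rotation` degrees from the femur's
#' PCA. The rotation is a pure axial-plane rotation about the femoral
#' proximal-distal (+y) axis through the femoral PCA midpoint; external
#' rotation is defined for a right knee (the lateral condyle moves
#' posteriorly, the medial condyle anteriorly).
#'
#' @param femur_pca,component_pca axes from [compute_pca()] (or lists with
#'   `medial`, `lateral` points).
#' @param condition an [alignment_condition()].
#' @return 4x4 rigid transform to apply to the component.
#' @export
align_component <- function(femur_pca, component_pca, condition) {
  fd <- femur_pca$lateral - femur_pca$medial
  cd <- component_pca$lateral - component_pca$medial
  if (sqrt(sum(fd^2)) < 1e-9 || sqrt(sum(cd^2)) < 1e-9)
    stop("degenerate (zero-length) PCA axis")
  cur <- external_angle_axial(fd, cd)
  delta <- condition$rotation - cur
  if (abs(delta) < 1e-15) return(diag(4))
  # external rotation is a negative right-handed rotation about +y
  rotation_about(c(0, 1, 0), femur_pca$midpoint, -delta)
}
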