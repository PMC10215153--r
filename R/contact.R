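#' Inferior-superior penetration field
#'
#' Samples penetration between the femoral component and the insert
#' articular surface along the inferior-superior (IS) direction. The IS test
#' direction follows the tibial long axis: the component mesh is expressed in
#' the tibia body frame and, for every sample point on the insert articular
#' surface, a vertical ray (+y, tibia frame) is cast against the component's
#' lower surface. The penetration depth is the overlap distance along that
#' ray (zero where the bodies are separated).
#'
#' @param geometry a `knee_geometry` (or a model's geometry) providing the
#'   condyle sub-meshes and the insert sample grid.
#' @param femur_pose,tibia_pose 4x4 world poses. The component sub-meshes are
#'   taken in femur body coordinates.
#' @param component_meshes optional named list
#'   `list(medial = , lateral = )` overriding the geometry's condyle
#'   sub-meshes (femur body frame).
#' @param samples optional sample tibble overriding the geometry's
#'   `contact_samples` (columns x, y, z, area, compartment; tibia frame).
#' @param sampling_density grid density multiplier used when `samples` is
#'   not given.
#' @return tibble (class `contact_field`): sample coordinates (tibia frame),
#'   `depth` (mm, >= 0), `area` (mm^2), `compartment`, and the component
#'   lower-surface normal components `nx, ny, nz` (tibia frame, `ny <= 0`)
#'   where depth > 0.
#' @export
penetration_field <- function(geometry, femur_pose, tibia_pose,
                              component_meshes = NULL, samples = NULL,
                              sampling_density = 1) {
  if (is.null(component_meshes))
    component_meshes <- list(medial = geometry$component_medial,
                             lateral = geometry$component_lateral)
  if (is.null(samples)) {
    samples <- if (sampling_density == 1) geometry$contact_samples
               else contact_sample_grid(geometry$params, sampling_density)
  }
  if (nrow(samples) == 0) stop("empty articular sample region")
  # component posed in the tibia frame: T = inv(tibia_pose) %*% femur_pose
  Tt <- solve(tibia_pose) %*% femur_pose
  out <- samples
  out$depth <- 0; out$nx <- 0; out$ny <- -1; out$nz <- 0
  for (side in c("medial", "lateral")) {
    cm <- transform_mesh(component_meshes[[side]], Tt)
    sel <- samples$compartment == side
    q <- mesh_lower_surface(cm$vertices, cm$faces, samples$x[sel], samples$z[sel])
    d <- samples$y[sel] - q[, 1]
    d[is.na(d) | d < 0] <- 0
    out$depth[sel] <- d
    hit <- which(sel)[d > 0]
    dh <- d > 0 & !is.na(q[, 1])
    out$nx[which(sel)[dh]] <- q[dh, 2]
    out$ny[which(sel)[dh]] <- q[dh, 3]
    out$nz[which(sel)[dh]] <- q[dh, 4]
  }
  class(out) <- c("contact_field", class(out))
  attr(out, "tibia_pose") <- tibia_pose
  out
}

#' Contact loads from a penetration field
#'
#' Penalty contact: per-point normal pressure `penalty_stiffness * depth`,
#' with the per-point force oriented along the component's local lower-
#' surface normal and scaled so its IS component equals
#' `pressure * tributary_area` (this makes the force system the exact
#' gradient of the IS penalty energy with respect to the tibial
#' translations). An optional regularised Coulomb term
#' `mu * |normal force|` opposes a supplied sliding direction; at a true
#' static equilibrium with no prescribed sliding it is zero.
#'
#' The compartment split is by the sign of the sample point's medial-lateral
#' coordinate relative to the insert midline; the medial and lateral
#' compressive components sum to the net IS compressive force exactly.
#'
#' @param field a `contact_field` from [penetration_field()].
#' @param penalty_stiffness penalty pressure modulus, N/mm per mm of depth
#'   per mm^2 of area (default 100).
#' @param friction_coefficient Coulomb coefficient mu (>= 0, default 0.04).
#' @param sliding_direction optional unit vector (tibia frame) of tibial
#'   sliding; when `NULL` no friction force is generated.
#' @param moment_center point (world) for the net moment.
#' @return list of class `contact_summary`: `net_force`, `net_moment`
#'   (world, on the tibia), `medial_N`, `lateral_N` (compressive IS force per
#'   compartment), `max_penetration_mm`, `points`/`forces` (world per-point
#'   arrays) and the input `field`.
#' @export
contact_loads <- function(field, penalty_stiffness = 100,
                          friction_coefficient = 0.04,
                          sliding_direction = NULL,
                          moment_center = c(0, 0, 0)) {
  if (penalty_stiffness < 0) stop("penalty stiffness must be >= 0")
  if (friction_coefficient < 0) stop("friction coefficient must be >= 0")
  tp <- attr(field, "tibia_pose") %||% diag(4)
  act <- field$depth > 0
  fn <- penalty_stiffness * field$depth * field$area      # IS magnitude
  # force along the local surface normal, IS component = fn (tibia frame)
  ny <- pmin(field$ny, -0.2)
  fx <- fn * field$nx / abs(ny)
  fy <- -fn
  fz <- fn * field$nz / abs(ny)
  if (!is.null(sliding_direction)) {
    s <- unitv(sliding_direction)
    fx <- fx - friction_coefficient * fn * s[1]
    fy <- fy - friction_coefficient * fn * s[2]
    fz <- fz - friction_coefficient * fn * s[3]
  }
  Ft <- cbind(fx, fy, fz)
  P <- cbind(field$x, field$y, field$z)
  R <- tp[1:3, 1:3]
  Pw <- transform_points(P, tp)
  Fw <- Ft %*% t(R)
  net <- colSums(Fw)
  r <- sweep(Pw, 2, moment_center)
  M <- c(sum(r[, 2] * Fw[, 3] - r[, 3] * Fw[, 2]),
         sum(r[, 3] * Fw[, 1] - r[, 1] * Fw[, 3]),
         sum(r[, 1] * Fw[, 2] - r[, 2] * Fw[, 1]))
  med <- sum(fn[field$compartment == "medial"])
  lat <- sum(fn[field$compartment == "lateral"])
  structure(list(net_force = unname(net), net_moment = unname(M),
                 medial_N = med, lateral_N = lat,
                 net_compression_N = med + lat,
                 max_penetration_mm = max(field$depth),
                 points = Pw[act, , drop = FALSE],
                 forces = Fw[act, , drop = FALSE],
                 field = field),
            class = "contact_summary")
}

#' @export
print.contact_summary <- function(x, ...) {
  cat(sprintf(paste0("<contact_summary: net compression %.1f N ",
                     "(medial %.1f, lateral %.1f), max penetration %.3f mm>\n"),
              x$net_compression_N, x$medial_N, x$lateral_N, x$max_penetration_mm))
  invisible(x)
}

# contact penalty energy (N mm) of a field
contact_energy <- function(field, penalty_stiffness = 100) {
  sum(0.5 * penalty_stiffness * field$depth^2 * field$area)
}
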