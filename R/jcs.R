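#' Anatomical joint coordinate frames
#'
#' Body-fixed anatomical frames used for the Grood-Suntay joint coordinate
#' system, defined at the reference pose (knee fully extended). For the
#' synthetic right-knee geometry the femoral flexion axis is the condylar
#' (PCA-parallel) z axis through the femoral origin, the femoral and tibial
#' long axes are +y, and the tibial AP axis is +x. For a left knee the
#' geometry is assumed mirrored in z; varus/valgus, internal/external and ML
#' coordinates are sign-flipped accordingly.
#'
#' @param side `"right"` or `"left"`.
#' @param femur_origin,tibia_origin body-frame origins (mm).
#' @return object of class `anatomical_frames`.
#' @export
anatomical_frames <- function(side = c("right", "left"),
                              femur_origin = c(0, 0, 0),
                              tibia_origin = c(0, 0, 0)) {
  side <- match.arg(side)
  structure(list(side = side,
                 femur_origin = femur_origin, tibia_origin = tibia_origin,
                 femur_flexion_axis = c(0, 0, 1),
                 femur_long_axis = c(0, 1, 0),
                 tibia_long_axis = c(0, 1, 0),
                 tibia_ap_axis = c(1, 0, 0)),
            class = "anatomical_frames")
}

mirror_z <- diag(c(1, 1, -1))

mirror_pose <- function(T) {
  M4 <- diag(4); M4[3, 3] <- -1
  M4 %*% T %*% M4
}

#' Convert body poses to Grood-Suntay joint coordinates
#'
#' Decomposes the relative femur-to-tibia motion into the knee joint
#' coordinate system: flexion about the femur-fixed flexion axis, axial
#' rotation about the tibia-fixed long axis, adduction-abduction about the
#' mutually perpendicular floating axis, and translations along those three
#' axes. Signs follow the right-knee convention: flexion positive, varus
#' positive, tibial external rotation positive, anterior translation
#' positive (posterior negative), lateral ML positive, proximal IS positive.
#' All six coordinates are zero at the reference pose (identity poses).
#'
#' @param femur_pose,tibia_pose 4x4 world poses of the bodies (identity =
#'   reference pose).
#' @param frames an [anatomical_frames()] object.
#' @return one-row tibble with columns `fe`, `vv`, `ie` (degrees) and `ap`,
#'   `ml`, `is` (mm).
#' @export
to_jcs <- function(femur_pose, tibia_pose, frames = anatomical_frames()) {
  if (frames$side == "left") {
    fr <- frames; fr$side <- "right"
    out <- to_jcs(mirror_pose(femur_pose), mirror_pose(tibia_pose), fr)
    out$vv <- -out$vv; out$ie <- -out$ie; out$ml <- -out$ml
    return(out)
  }
  RF <- femur_pose[1:3, 1:3]; RT <- tibia_pose[1:3, 1:3]
  R <- t(RF) %*% RT
  # R = Rz(a) Rx(b) Ry(c)
  sb <- R[3, 2]
  if (abs(sb) > 1 - 1e-9) stop("gimbal degeneracy: |adduction| = 90 degrees")
  b <- asin(sb)
  a <- atan2(-R[1, 2], R[2, 2])
  c <- atan2(-R[3, 1], R[3, 3])
  r2d <- 180 / pi
  # translations along e1 (femoral flexion axis), e2 (floating, anterior)
  # and e3 (tibial long axis)
  e1 <- RF %*% frames$femur_flexion_axis
  e3 <- RT %*% frames$tibia_long_axis
  e2 <- pracma_cross(as.numeric(e3), as.numeric(e1))
  e2 <- e2 / sqrt(sum(e2^2))
  pf <- transform_points(frames$femur_origin, femur_pose)
  pt <- transform_points(frames$tibia_origin, tibia_pose)
  d0 <- frames$tibia_origin - frames$femur_origin
  q <- as.numeric(solve(cbind(as.numeric(e1), e2, as.numeric(e3)),
                        (pt - pf) - d0))
  tibble::tibble(fe = -a * r2d, vv = b * r2d, ie = -c * r2d,
                 ap = q[2], ml = q[1], is = q[3])
}

#' Reconstruct body poses from joint coordinates
#'
#' Inverse of [to_jcs()]: given joint coordinates and the femur pose,
#' reconstructs the tibia pose (right-knee frames). Round-trips with
#' [to_jcs()] to machine precision.
#'
#' @param coords one-row tibble or named list with `fe`, `vv`, `ie`, `ap`,
#'   `ml`, `is`.
#' @param frames an [anatomical_frames()] object (right side).
#' @param femur_pose 4x4 femur pose (default identity).
#' @return 4x4 tibia pose.
#' @export
from_jcs <- function(coords, frames = anatomical_frames(), femur_pose = diag(4)) {
  if (frames$side != "right")
    stop("pose reconstruction is defined for right-knee frames")
  RF <- femur_pose[1:3, 1:3]
  R <- rot_z(-coords$fe) %*% rot_x(coords$vv) %*% rot_y(-coords$ie)
  RT <- RF %*% R
  e1 <- RF %*% frames$femur_flexion_axis
  e3 <- RT %*% frames$tibia_long_axis
  e2 <- pracma_cross(as.numeric(e3), as.numeric(e1))
  e2 <- e2 / sqrt(sum(e2^2))
  d0 <- frames$tibia_origin - frames$femur_origin
  pf <- transform_points(frames$femur_origin, femur_pose)
  pt <- pf + d0 + as.numeric(cbind(as.numeric(e1), e2, as.numeric(e3)) %*%
                               c(coords$ml, coords$ap, coords$is))
  t <- pt - RT %*% frames$tibia_origin
  rigid_transform(RT, as.numeric(t))
}

#' Laxity for one degree of freedom
#'
#' Laxity is the absolute kinematic difference between the loaded
#' equilibrium and the neutral-flexion equilibrium at the same prescribed
#' flexion angle.
#'
#' @param neutral,loaded one-row joint coordinate tibbles from [to_jcs()]
#'   at the same flexion angle (within 0.01 degrees).
#' @param dof coordinate name: one of `"ap"`, `"vv"`, `"ie"`, `"ml"`, `"is"`.
#' @return absolute difference, mm or degrees.
#' @export
laxity <- function(neutral, loaded, dof) {
  if (abs(neutral$fe - loaded$fe) > 0.01)
    stop("neutral and loaded poses are at different flexion angles")
  abs(loaded[[dof]] - neutral[[dof]])
}

#' Express condition curves relative to the baseline neutral trajectory
#'
#' Subtracts, per flexion angle, the baseline condition's neutral-flexion
#' coordinates from every condition/test curve, so the baseline neutral
#' trajectory maps to zero.
#'
#' @param kinematics tibble with columns `condition`, `test`, `flexion_deg`
#'   and coordinate columns `fe`, `vv`, `ie`, `ap`, `ml`, `is`.
#' @param baseline name of the baseline condition.
#' @return tibble of the same shape with coordinates replaced by deltas.
#' @export
relative_to_baseline <- function(kinematics, baseline = "baseline") {
  dofs <- c("fe", "vv", "ie", "ap", "ml", "is")
  dofs <- intersect(dofs, names(kinematics))
  ref <- kinematics |>
    dplyr::filter(.data$condition == baseline, .data$test == "neutral") |>
    dplyr::select("flexion_deg", dplyr::all_of(dofs)) |>
    dplyr::rename_with(~ paste0(".ref_", .x), dplyr::all_of(dofs))
  if (nrow(ref) == 0) stop("baseline neutral-flexion trajectory not present")
  missing <- setdiff(unique(kinematics$flexion_deg), ref$flexion_deg)
  if (length(missing))
    stop("baseline missing flexion angle(s): ", paste(missing, collapse = ", "))
  out <- dplyr::left_join(kinematics, ref, by = "flexion_deg")
  for (d in dofs) {
    out[[d]] <- out[[d]] - out[[paste0(".ref_", d)]]
    out[[paste0(".ref_", d)]] <- NULL
  }
  out
}
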