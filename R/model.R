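#' Assemble a TKA knee model
#'
#' Builds the full rigid-body + ligament model for one malrotation
#' condition: places the femoral component on the femur by external rotation
#' of its posterior condyle axis (PCA) relative to the femur's PCA, builds
#' the multifiber ligament set from the parameter file (original bundles,
#' bundle augmentation, stiffness calibration), measures reference-pose
#' fiber lengths on the synthetic geometry (wrapped for the sMCL) and
#' back-computes slack lengths from the tabulated reference strains.
#'
#' @param geometry a [make_knee_geometry()] result; shared across conditions.
#' @param condition an [alignment_condition()] (or a condition name).
#' @param ligament_params result of [read_ligament_params()] (or a file
#'   path). The final-table stiffnesses are carried as data for the original
#'   bundles; augmented-bundle stiffnesses come from the calibration.
#' @param penalty_stiffness contact penalty modulus (N/mm per mm^2), see
#'   [contact_loads()].
#' @param stiffness `"table"` (default) takes every bundle's stiffness from
#'   the parameter table, which already holds the final calibrated values
#'   (a bundle absent from the table, the middle PCL, gets the mean of its
#'   neighbours); `"recalibrated"` instead re-derives augmented-set
#'   stiffnesses by the distraction conservation rule of
#'   [calibrate_stiffness()] starting from the original bundles.
#' @return object of class `knee_model`.
#' @export
knee_model <- function(geometry = make_knee_geometry(),
                       condition = "baseline",
                       ligament_params = read_ligament_params(),
                       penalty_stiffness = 100,
                       stiffness = c("table", "recalibrated")) {
  stiffness <- match.arg(stiffness)
  if (is.character(condition)) condition <- alignment_condition(condition)
  if (is.character(ligament_params))
    ligament_params <- read_ligament_params(ligament_params)
  femur_pca <- compute_pca(geometry$femur)
  comp_pca <- compute_pca(geometry$femoral_component)
  T_align <- align_component(femur_pca, comp_pca, condition)
  comp_med <- transform_mesh(geometry$component_medial, T_align)
  comp_lat <- transform_mesh(geometry$component_lateral, T_align)
  wraps <- list(tibia_medial_wrap = geometry$tibia_medial_wrap)
  eps_t <- ligament_params$eps_t
  bundles <- build_ligament_set(ligament_params, wraps, stiffness)
  structure(list(geometry = geometry, condition = condition,
                 component_medial = comp_med, component_lateral = comp_lat,
                 component_transform = T_align,
                 bundles = bundles, eps_t = eps_t,
                 wrap_meshes = wraps,
                 via_cache = new.env(parent = emptyenv()),
                 penalty_stiffness = penalty_stiffness,
                 moment_center = femur_pca$midpoint,
                 frames = anatomical_frames("right")),
            class = "knee_model")
}

# Original bundles -> augmented five/five/three-bundle set with measured
# reference lengths (wrapped where the ligament wraps) and calibrated
# stiffnesses.
build_ligament_set <- function(params, wraps = list(), stiffness = "table") {
  tab <- params$table
  orig <- dplyr::inner_join(params$insertions,
                            dplyr::filter(tab, !.data$augmented),
                            by = c("ligament", "bundle" = "name")) |>
    dplyr::rename(name = "bundle")
  sets <- lapply(split(orig, orig$ligament), function(b) {
    b <- b[order(match(b$name, params$insertions$bundle)), ]
    wl <- b$wrap[1]
    measure_length <- if (!is.na(wl) && nzchar(wl)) {
      wm <- wraps[strsplit(wl, ",")[[1]]]
      function(f, t) wrap_path(t, f, wm)$length
    } else {
      function(f, t) sqrt(sum((f - t)^2))
    }
    b$l_r <- purrr::map_dbl(seq_len(nrow(b)), function(i)
      measure_length(c(b$fx[i], b$fy[i], b$fz[i]), c(b$tx[i], b$ty[i], b$tz[i])))
    b$l_0 <- slack_length(b$l_r, b$reference_strain)
    aug <- augment_bundles(b, measure_length)
    if (stiffness == "table") {
      hit <- match(aug$name, params$table$name)
      aug$stiffness <- ifelse(is.na(hit), aug$stiffness,
                              params$table$stiffness[hit])
    } else {
      d <- engaging_distraction(aug)
      aug <- calibrate_stiffness(b, aug, distraction = c(0, -d, 0))
    }
    aug
  })
  dplyr::bind_rows(sets)
}

#' @export
print.knee_model <- function(x, ...) {
  cat(sprintf("<knee_model: condition '%s' (%.1f deg external), %d bundles>\n",
              x$condition$name, x$condition$rotation, nrow(x$bundles)))
  invisible(x)
}

#' Joint state in simulator convention
#'
#' The six simulator degrees of freedom: the femur carries flexion-extension
#' (`fe`, deg, prescribed in every test) and adduction-abduction (`aa`, deg,
#' varus positive); the tibia carries the three translations `ap`, `ml`,
#' `is` (mm, anterior/lateral/proximal positive) and internal-external
#' rotation `ie` (deg, external positive). The femur has no translations or
#' axial rotation; the tibia has no flexion or adduction.
#'
#' @param fe,aa,ie,ap,ml,is DOF values (degrees / mm).
#' @return named numeric vector of class `joint_state`.
#' @export
joint_state <- function(fe = 0, aa = 0, ie = 0, ap = 0, ml = 0, is = 0) {
  structure(c(fe = fe, aa = aa, ie = ie, ap = ap, ml = ml, is = is),
            class = "joint_state")
}

# body poses from a simulator state
state_poses <- function(state) {
  femur <- rigid_transform(rot_x(-state[["aa"]]) %*% rot_z(state[["fe"]]))
  tibia <- rigid_transform(rot_y(-state[["ie"]]),
                           c(state[["ap"]], state[["is"]], state[["ml"]]))
  list(femur = femur, tibia = tibia)
}

#' Per-DOF control specification
#'
#' Mixed force/displacement control over the six simulator DOFs. Each DOF is
#' either prescribed (displacement control) or load-controlled towards a
#' target generalized load (0 for an unconstrained DOF). Flexion is always
#' prescribed; the varus-valgus torque channel is the femoral
#' adduction-abduction DOF, the axial torque channel the tibial rotation.
#'
#' @param fe prescribed flexion angle (degrees).
#' @param prescribed named numeric vector of additional prescribed DOFs
#'   (values in deg/mm), e.g. `c(is = -5)`.
#' @param targets named numeric vector of target loads for the
#'   load-controlled DOFs: N for `ap`, `ml`, `is`; N mm for `aa` (varus
#'   positive) and `ie` (external positive). Unlisted DOFs default to 0.
#' @return object of class `dof_spec`.
#' @export
dof_spec <- function(fe = 0, prescribed = c(), targets = c()) {
  dofs <- c("aa", "ie", "ap", "ml", "is")
  bad <- setdiff(names(targets), dofs)
  if (length(bad)) stop("unknown load-controlled DOF(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(prescribed), dofs)
  if (length(bad)) stop("unknown prescribed DOF(s): ", paste(bad, collapse = ", "))
  tgt <- stats::setNames(numeric(length(dofs)), dofs)
  tgt[names(targets)] <- targets
  free <- setdiff(dofs, names(prescribed))
  if (length(free) == 0 && length(prescribed) == 0) stop("no DOFs specified")
  structure(list(fe = fe, prescribed = prescribed,
                 free = free, targets = tgt[free]),
            class = "dof_spec")
}
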