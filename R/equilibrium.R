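dof_names <- c("fe", "aa", "ie", "ap", "ml", "is")

# evaluate ligament + contact loads at a state; returns the pieces needed by
# both the generalized-load projection and the reporting layer
evaluate_loads <- function(model, state) {
  poses <- state_poses(state)
  lig <- ligament_loads(model$bundles, poses$femur, poses$tibia,
                        model$wrap_meshes, model$eps_t, model$moment_center,
                        via_cache = model$via_cache)
  field <- penetration_field(model$geometry, poses$femur, poses$tibia,
                             component_meshes = list(
                               medial = model$component_medial,
                               lateral = model$component_lateral))
  con <- contact_loads(field, model$penalty_stiffness,
                       moment_center = model$moment_center)
  list(poses = poses, ligaments = lig, contact = con)
}

#' Generalized loads on the six simulator DOFs
#'
#' Projects the total internal loads (ligament fiber forces and contact
#' forces) onto the simulator's DOF directions at the current pose: net
#' world-frame forces on the tibia for the three translations, the moment on
#' the tibia about its long axis for internal-external rotation (external
#' positive), the moment on the femur about its adduction axis for
#' varus-valgus (varus positive), and the flexion moment on the femur. For
#' the frictionless system these are exact negative gradients of the total
#' elastic energy.
#'
#' @param model a [knee_model()].
#' @param state a [joint_state()].
#' @param loads optional precomputed [evaluate_loads()] result.
#' @return named numeric vector of generalized loads: N for translations,
#'   N mm for rotations.
#' @export
generalized_loads <- function(model, state, loads = NULL) {
  if (is.null(loads)) loads <- evaluate_loads(model, state)
  lig <- loads$ligaments
  con <- loads$contact
  # forces on the tibia, world frame, with application points
  Pt <- rbind(as.matrix(lig[, c("ptx", "pty", "ptz")]), con$points)
  Ft <- rbind(as.matrix(lig[, c("ftx", "fty", "ftz")]), con$forces)
  # forces on the femur: ligament reactions at femoral insertions, contact
  # reactions at the contact points
  Pf <- rbind(as.matrix(lig[, c("pfx", "pfy", "pfz")]), con$points)
  Ff <- rbind(as.matrix(lig[, c("ffx", "ffy", "ffz")]), -con$forces)
  net_t <- colSums(Ft)
  # moment on tibia about its long axis (+y world) through the tibia origin
  p_t <- loads$poses$tibia[1:3, 4]
  rt <- sweep(Pt, 2, p_t)
  M_t_y <- sum(rt[, 3] * Ft[, 1] - rt[, 1] * Ft[, 3])
  # moments on femur about the world axes through the femoral origin (0,0,0)
  M_f_x <- sum(Pf[, 2] * Ff[, 3] - Pf[, 3] * Ff[, 2])
  # flexion axis after the adduction rotation
  fe_axis <- rot_x(-state[["aa"]]) %*% c(0, 0, 1)
  Mf <- c(M_f_x,
          sum(Pf[, 3] * Ff[, 1] - Pf[, 1] * Ff[, 3]),
          sum(Pf[, 1] * Ff[, 2] - Pf[, 2] * Ff[, 1]))
  c(fe = sum(Mf * fe_axis),
    aa = -M_f_x,
    ie = -M_t_y,
    ap = unname(net_t[1]), ml = unname(net_t[3]), is = unname(net_t[2]))
}

# total elastic energy (ligaments + contact penalty), N mm
total_energy <- function(model, state) {
  poses <- state_poses(state)
  e_l <- ligament_energy(model$bundles, poses$femur, poses$tibia,
                         model$wrap_meshes, model$eps_t)
  field <- penetration_field(model$geometry, poses$femur, poses$tibia,
                             component_meshes = list(
                               medial = model$component_medial,
                               lateral = model$component_lateral))
  e_l + contact_energy(field, model$penalty_stiffness)
}

#' Solve one quasi-static equilibrium
#'
#' Adjusts the load-controlled DOFs by a damped quasi-Newton iteration
#' (finite-difference Jacobian, step limiting of 2 mm / 2 deg per iteration,
#' backtracking) until every free DOF's internal generalized load balances
#' its target applied load within tolerance (0.5 N for forces, 50 N mm for
#' moments).
#'
#' @param model a [knee_model()].
#' @param spec a [dof_spec()].
#' @param initial optional [joint_state()] initial guess (continuation
#'   recommended).
#' @param max_iter iteration cap; non-convergence returns a flagged partial
#'   solution.
#' @param force_tol,moment_tol convergence tolerances (N, N mm).
#' @param J_init optional initial Jacobian (from a nearby solve) to avoid a
#'   finite-difference rebuild; refreshed automatically when it stalls.
#' @return object of class `knee_equilibrium`: `state`, `jcs` (Grood-Suntay
#'   coordinates), `residuals`, per-bundle `tensions`, `contact` summary,
#'   `converged`, `iterations`, and the final Jacobian as attribute
#'   `jacobian`.
#' @export
solve_equilibrium <- function(model, spec, initial = NULL,
                              max_iter = 500, force_tol = 0.5,
                              moment_tol = 50, J_init = NULL) {
  state <- if (is.null(initial)) joint_state() else initial
  state[["fe"]] <- spec$fe
  for (nm in names(spec$prescribed)) state[[nm]] <- spec$prescribed[[nm]]
  free <- spec$free
  tol <- ifelse(free %in% c("aa", "ie"), moment_tol, force_tol)
  # per-iteration step caps; the IS channel is capped hardest because the
  # conforming penalty contact traverses its full force range in < 0.1 mm
  cap <- c(aa = 2, ie = 2, ap = 2, ml = 2, is = 0.25)[free]
  h <- c(aa = 0.05, ie = 0.05, ap = 0.02, ml = 0.02, is = 0.01)[free]
  resid <- function(st, loads = NULL) {
    g <- generalized_loads(model, st, loads)
    g[free] + spec$targets[free]
  }
  fd_jacobian <- function(st, r0) {
    J <- matrix(0, length(free), length(free), dimnames = list(free, free))
    for (j in seq_along(free)) {
      st2 <- st
      st2[[free[j]]] <- st2[[free[j]]] + h[j]
      J[, j] <- (resid(st2) - r0) / h[j]
    }
    J
  }
  loads <- evaluate_loads(model, state)
  check_dislocation(loads)
  r <- resid(state, loads)
  it <- 0
  J <- if (!is.null(J_init) && identical(dimnames(J_init)[[1]], free))
    J_init else NULL
  fresh_J <- FALSE
  stale <- 0
  while (max(abs(r) / tol) > 1 && it < max_iter) {
    it <- it + 1
    if (is.null(J) || stale > 10) {
      J <- fd_jacobian(state, r)
      fresh_J <- TRUE
      stale <- 0
    }
    dq <- tryCatch(-solve(J, r), error = function(e) {
      -solve(J + diag(1e-4 * pmax(abs(diag(J)), 1)), r)
    })
    sc <- max(abs(dq) / cap)
    if (sc > 1) dq <- dq / sc
    cur <- sqrt(sum((r / tol)^2))
    accepted <- FALSE
    for (alpha in c(1, 0.5, 0.25, 0.1)) {
      st2 <- state
      for (j in seq_along(free)) st2[[free[j]]] <- st2[[free[j]]] + alpha * dq[j]
      r2 <- resid(st2)
      if (sqrt(sum((r2 / tol)^2)) < cur) {
        # Broyden rank-1 update keeps the Jacobian current between
        # finite-difference refreshes
        dqa <- alpha * dq
        J <- J + ((r2 - r - J %*% dqa) %*% t(dqa)) / sum(dqa^2)
        state <- st2; r <- r2; accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      if (!fresh_J) { J <- NULL; next }   # refresh the Jacobian and retry
      # forced damped step to escape flat/kinked regions
      for (j in seq_along(free)) state[[free[j]]] <- state[[free[j]]] + 0.1 * dq[j]
      r <- resid(state)
      J <- NULL
    } else {
      fresh_J <- FALSE
      stale <- stale + 1
    }
  }
  converged <- max(abs(r) / tol) <= 1
  loads <- evaluate_loads(model, state)
  poses <- loads$poses
  res <- stats::setNames(numeric(6), dof_names)
  res[free] <- r
  out <- structure(list(state = state,
                 jcs = to_jcs(poses$femur, poses$tibia, model$frames),
                 residuals = res, free = free, targets = spec$targets,
                 tensions = loads$ligaments, contact = loads$contact,
                 converged = converged, iterations = it,
                 tolerances = c(force = force_tol, moment = moment_tol)),
            class = "knee_equilibrium")
  attr(out, "jacobian") <- J
  out
}

check_dislocation <- function(loads) {
  if (loads$contact$net_compression_N == 0 &&
      all(loads$ligaments$tension_N == 0))
    stop("joint dislocation: no contact and all ligaments slack")
  invisible(TRUE)
}

#' @export
print.knee_equilibrium <- function(x, ...) {
  cat(sprintf("<knee_equilibrium: fe %.1f deg, %s in %d iterations>\n",
              x$state[["fe"]],
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(x$jcs)
  invisible(x)
}

#' Neutral flexion trajectory
#'
#' Guides the knee through neutral flexion: flexion prescribed at each angle
#' in turn, all remaining DOFs load-controlled at zero. Solutions continue
#' sequentially (each seeds the next angle), with intermediate continuation
#' substeps no larger than `max_step` degrees.
#'
#' @param model a [knee_model()].
#' @param flexion_angles ascending flexion angles (degrees), starting at 0.
#' @param max_step largest continuation increment (degrees).
#' @param ... passed to [solve_equilibrium()].
#' @return list of `knee_equilibrium` solutions, one per requested angle.
#' @export
neutral_flexion <- function(model, flexion_angles = c(0, 15, 30, 60, 90),
                            max_step = 15, ...) {
  if (is.unsorted(flexion_angles))
    stop("flexion angles must be ascending")
  grid <- sort(unique(c(flexion_angles,
                        seq(0, max(flexion_angles), by = max_step))))
  state <- joint_state()
  out <- list()
  J <- NULL
  for (a in grid) {
    sol <- solve_equilibrium(model, dof_spec(fe = a), initial = state,
                             J_init = J, ...)
    if (!sol$converged)
      warning(sprintf("neutral flexion did not converge at %.1f deg", a))
    state <- sol$state
    J <- attr(sol, "jacobian")
    if (a %in% flexion_angles) out[[sprintf("%g", a)]] <- sol
  }
  out
}

# applied-load targets for the four laxity tests
laxity_targets <- function(test, posterior_force = 100, vv_torque = 8,
                           ie_torque = 4) {
  switch(test,
         posterior = c(ap = -posterior_force),
         varus     = c(aa = vv_torque * 1000),
         valgus    = c(aa = -vv_torque * 1000),
         internal  = c(ie = -ie_torque * 1000),
         external  = c(ie = ie_torque * 1000),
         stop("unknown laxity test: ", test))
}

#' Run one laxity test at one flexion angle
#'
#' Starting from the neutral-flexion equilibrium at the same angle, the
#' applied load (posterior force or varus/valgus/internal/external torque)
#' is ramped to its target in equal increments, solving an equilibrium at
#' each, and the loaded kinematics are returned.
#'
#' @param model a [knee_model()].
#' @param neutral the neutral `knee_equilibrium` at the same flexion angle.
#' @param test one of `"posterior"`, `"varus"`, `"valgus"`, `"internal"`,
#'   `"external"`.
#' @param posterior_force posterior drawer force (N), default 100.
#' @param vv_torque varus-valgus torque magnitude (N m), default 8.
#' @param ie_torque axial torque magnitude (N m), default 4.
#' @param n_ramp number of load increments.
#' @param ... passed to [solve_equilibrium()].
#' @return the loaded `knee_equilibrium`.
#' @export
laxity_test <- function(model, neutral, test,
                        posterior_force = 100, vv_torque = 8, ie_torque = 4,
                        n_ramp = 4, ...) {
  target <- laxity_targets(test, posterior_force, vv_torque, ie_torque)
  state <- neutral$state
  J <- attr(neutral, "jacobian")
  for (k in seq_len(n_ramp)) {
    sp <- dof_spec(fe = neutral$state[["fe"]], targets = target * k / n_ramp)
    sol <- solve_equilibrium(model, sp, initial = state, J_init = J, ...)
    state <- sol$state
    J <- attr(sol, "jacobian")
  }
  if (!sol$converged)
    warning(sprintf("%s laxity test did not converge at %.1f deg",
                    test, neutral$state[["fe"]]))
  sol
}
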