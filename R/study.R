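#' Study configuration
#'
#' Defines the full malrotation laxity study: the flexion angles, the
#' laxity-test load magnitudes (100 N posterior drawer, +/- 8 N m
#' varus-valgus torque, +/- 4 N m axial torque) and the malrotation
#' conditions (internal 1.5, baseline 3.0, external 4.5 degrees of external
#' femoral component rotation).
#'
#' @param flexion_angles ascending flexion angles in degrees.
#' @param posterior_force posterior drawer force (N).
#' @param vv_torque varus-valgus torque magnitude (N m).
#' @param ie_torque internal-external torque magnitude (N m).
#' @param conditions condition names, must include `"baseline"` for the
#'   relative outputs.
#' @param tests laxity tests to run besides neutral flexion.
#' @param params an [implant_params()].
#' @param ligament_file ligament parameter file path.
#' @param penalty_stiffness contact penalty modulus.
#' @return object of class `study_config`.
#' @export
study_config <- function(flexion_angles = c(0, 15, 30, 60, 90),
                         posterior_force = 100, vv_torque = 8, ie_torque = 4,
                         conditions = c("internal", "baseline", "external"),
                         tests = c("posterior", "varus", "valgus",
                                   "internal", "external"),
                         params = implant_params(),
                         ligament_file = default_ligament_file(),
                         penalty_stiffness = 100) {
  if (length(flexion_angles) == 0 || is.unsorted(flexion_angles))
    stop("flexion angles must be a non-empty ascending list")
  structure(list(flexion_angles = flexion_angles,
                 posterior_force = posterior_force,
                 vv_torque = vv_torque, ie_torque = ie_torque,
                 conditions = conditions, tests = tests,
                 params = params, ligament_file = ligament_file,
                 penalty_stiffness = penalty_stiffness),
            class = "study_config")
}

equilibrium_row <- function(sol, condition, test) {
  dplyr::bind_cols(
    tibble::tibble(condition = condition, test = test,
                   flexion_deg = sol$state[["fe"]]),
    sol$jcs,
    tibble::tibble(net_compression_N = sol$contact$net_compression_N,
                   medial_N = sol$contact$medial_N,
                   lateral_N = sol$contact$lateral_N,
                   max_penetration_mm = sol$contact$max_penetration_mm,
                   max_force_residual_N =
                     max(abs(sol$residuals[c("ap", "ml", "is")])),
                   max_moment_residual_Nmm =
                     max(abs(sol$residuals[c("aa", "ie")])),
                   converged = sol$converged))
}

#' Run the full malrotation laxity study
#'
#' Builds one aligned model per malrotation condition on shared synthetic
#' geometry (the ligament calibration is performed once and shared, since
#' only the femoral component placement differs), guides each through
#' neutral flexion, runs every laxity test at every flexion angle, and
#' collects kinematics (Grood-Suntay, reference-pose relative), laxities,
#' per-bundle tensions and compartmental contact forces.
#'
#' @param config a [study_config()].
#' @param quiet suppress progress messages.
#' @return object of class `knee_study`: tibbles `kinematics`, `laxity`,
#'   `tensions`, `compartments`, plus `config`.
#' @export
run_study <- function(config = study_config(), quiet = TRUE) {
  geom <- make_knee_geometry(config$params)
  lp <- read_ligament_params(config$ligament_file)
  base_model <- knee_model(geom, "baseline", lp,
                           penalty_stiffness = config$penalty_stiffness)
  kin <- list(); lax <- list(); ten <- list()
  for (cond in config$conditions) {
    model <- if (cond == "baseline") base_model else {
      m <- knee_model(geom, cond, lp,
                      penalty_stiffness = config$penalty_stiffness)
      m$bundles <- base_model$bundles    # one shared calibration
      m
    }
    if (!quiet) message("condition: ", cond)
    neutral <- withCallingHandlers(
      neutral_flexion(model, config$flexion_angles),
      warning = function(w) {
        warning(cond, ": ", conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      })
    for (a in names(neutral)) {
      sol <- neutral[[a]]
      kin[[length(kin) + 1]] <- equilibrium_row(sol, cond, "neutral")
      ten[[length(ten) + 1]] <- tension_rows(sol, cond, "neutral")
    }
    for (test in config$tests) {
      for (a in names(neutral)) {
        if (!quiet) message("  ", test, " @ ", a, " deg")
        sol <- laxity_test(model, neutral[[a]], test,
                           posterior_force = config$posterior_force,
                           vv_torque = config$vv_torque,
                           ie_torque = config$ie_torque)
        kin[[length(kin) + 1]] <- equilibrium_row(sol, cond, test)
        ten[[length(ten) + 1]] <- tension_rows(sol, cond, test)
        dof <- laxity_dof(test)
        lax[[length(lax) + 1]] <- tibble::tibble(
          condition = cond, test = test,
          flexion_deg = sol$state[["fe"]], dof = dof,
          laxity = laxity(neutral[[a]]$jcs, sol$jcs, dof),
          converged = sol$converged && neutral[[a]]$converged)
      }
    }
  }
  structure(list(kinematics = dplyr::bind_rows(kin),
                 laxity = dplyr::bind_rows(lax),
                 tensions = dplyr::bind_rows(ten),
                 compartments = dplyr::bind_rows(kin) |>
                   dplyr::select("condition", "test", "flexion_deg",
                                 "net_compression_N", "medial_N", "lateral_N",
                                 "max_penetration_mm", "converged"),
                 config = config),
            class = "knee_study")
}

laxity_dof <- function(test) {
  switch(test, posterior = "ap", varus = "vv", valgus = "vv",
         internal = "ie", external = "ie", stop("unknown test: ", test))
}

tension_rows <- function(sol, condition, test) {
  tibble::tibble(condition = condition, test = test,
                 flexion_deg = sol$state[["fe"]],
                 ligament = sol$tensions$ligament,
                 bundle = sol$tensions$name,
                 tension_N = sol$tensions$tension_N)
}

#' @export
print.knee_study <- function(x, ...) {
  cat(sprintf("<knee_study: %d conditions x %d angles, %d equilibria>\n",
              length(unique(x$kinematics$condition)),
              length(unique(x$kinematics$flexion_deg)),
              nrow(x$kinematics)))
  invisible(x)
}

#' Compartmental contact force changes relative to baseline
#'
#' Per condition and flexion angle, the difference between the condition's
#' medial (and lateral) ligament-driven compressive contact force and the
#' baseline condition's, during neutral flexion.
#'
#' @param study a `knee_study`.
#' @return tibble: condition, flexion_deg, medial_delta_N, lateral_delta_N,
#'   net_delta_N.
#' @export
compartment_deltas <- function(study) {
  comp <- dplyr::filter(study$compartments, .data$test == "neutral")
  base <- dplyr::filter(comp, .data$condition == "baseline")
  if (nrow(base) == 0) stop("baseline condition not present")
  base <- dplyr::select(base, "flexion_deg",
                        base_med = "medial_N", base_lat = "lateral_N")
  comp |>
    dplyr::left_join(base, by = "flexion_deg") |>
    dplyr::transmute(condition = .data$condition,
                     flexion_deg = .data$flexion_deg,
                     medial_delta_N = .data$medial_N - .data$base_med,
                     lateral_delta_N = .data$lateral_N - .data$base_lat,
                     net_delta_N = .data$medial_delta_N + .data$lateral_delta_N)
}

#' Across-condition laxity spread
#'
#' Per flexion angle (and per test), the max - min of the laxity value
#' across malrotation conditions; non-converged cells are excluded with a
#' warning.
#'
#' @param study a `knee_study`.
#' @param dof restrict to tests of this laxity DOF (`"ap"`, `"vv"`, `"ie"`);
#'   `NULL` for all.
#' @return tibble: test, flexion_deg, spread; attribute `overall_max`.
#' @export
laxity_spread <- function(study, dof = NULL) {
  lx <- study$laxity
  if (!is.null(dof)) lx <- dplyr::filter(lx, .data$dof == !!dof)
  if (any(!lx$converged)) {
    warning("excluding non-converged laxity cells from spreads")
    lx <- dplyr::filter(lx, .data$converged)
  }
  out <- lx |>
    dplyr::group_by(.data$test, .data$flexion_deg) |>
    dplyr::summarise(spread = max(.data$laxity) - min(.data$laxity),
                     .groups = "drop")
  attr(out, "overall_max") <- if (nrow(out)) max(out$spread) else NA_real_
  out
}

#' Neutral-flexion AP position spread across conditions
#'
#' Per flexion angle, the maximum absolute difference between each
#' condition's neutral-flexion AP position and the baseline's.
#'
#' @param study a `knee_study`.
#' @return tibble: flexion_deg, ap_spread_mm; attribute `overall_max`.
#' @export
neutral_ap_spread <- function(study) {
  rel <- relative_to_baseline(study$kinematics) |>
    dplyr::filter(.data$test == "neutral") |>
    dplyr::group_by(.data$flexion_deg) |>
    dplyr::summarise(ap_spread_mm = max(abs(.data$ap)), .groups = "drop")
  attr(rel, "overall_max") <- max(rel$ap_spread_mm)
  rel
}

#' Write the study result tables as CSV
#'
#' Writes kinematics.csv, laxity.csv, tensions.csv, compartments.csv and
#' deltas.csv into a directory.
#'
#' @param study a `knee_study`.
#' @param dir output directory (created if needed).
#' @return tibble of written paths, invisibly.
#' @export
write_study_csvs <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- list(kinematics = study$kinematics, laxity = study$laxity,
               tensions = study$tensions, compartments = study$compartments,
               deltas = compartment_deltas(study))
  paths <- purrr::imap_chr(tabs, function(tb, nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tb, p, row.names = FALSE)
    p
  })
  invisible(tibble::tibble(table = names(paths), path = unname(paths)))
}
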