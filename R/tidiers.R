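#' Tidy an equilibrium solution
#'
#' One row per simulator DOF: value, Grood-Suntay coordinate, control mode,
#' target load and residual.
#'
#' @param x a `knee_equilibrium`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.knee_equilibrium <- function(x, ...) {
  jcs_map <- c(fe = "fe", aa = "vv", ie = "ie", ap = "ap", ml = "ml", is = "is")
  tibble::tibble(
    dof = dof_names,
    value = as.numeric(x$state[dof_names]),
    jcs = as.numeric(x$jcs[jcs_map]),
    mode = ifelse(dof_names %in% x$free, "load", "prescribed"),
    target = ifelse(dof_names %in% names(x$targets),
                    x$targets[dof_names], NA_real_),
    residual = as.numeric(x$residuals[dof_names]))
}

#' @rdname tidy.knee_equilibrium
#' @export
glance.knee_equilibrium <- function(x, ...) {
  tibble::tibble(converged = x$converged, iterations = x$iterations,
                 max_force_residual_N =
                   max(abs(x$residuals[c("ap", "ml", "is")])),
                 max_moment_residual_Nmm =
                   max(abs(x$residuals[c("aa", "ie")])),
                 net_compression_N = x$contact$net_compression_N,
                 medial_N = x$contact$medial_N,
                 lateral_N = x$contact$lateral_N,
                 max_penetration_mm = x$contact$max_penetration_mm,
                 total_ligament_tension_N = sum(x$tensions$tension_N))
}

#' Tidy a study
#'
#' Returns the laxity table (`what = "laxity"`), the kinematics table
#' relative to the baseline neutral trajectory (`"kinematics"`), per-bundle
#' tensions (`"tensions"`) or compartment forces (`"compartments"`).
#'
#' @param x a `knee_study`.
#' @param what which table to return.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.knee_study <- function(x, what = c("laxity", "kinematics", "tensions",
                                        "compartments"), ...) {
  what <- match.arg(what)
  switch(what,
         laxity = x$laxity,
         kinematics = relative_to_baseline(x$kinematics),
         tensions = x$tensions,
         compartments = x$compartments)
}

#' @rdname tidy.knee_study
#' @export
glance.knee_study <- function(x, ...) {
  sp_vv <- laxity_spread(x, "vv")
  sp_ap <- dplyr::filter(x$laxity, .data$dof == "ap")
  tibble::tibble(
    n_equilibria = nrow(x$kinematics),
    n_converged = sum(x$kinematics$converged),
    max_posterior_laxity_mm = if (nrow(sp_ap)) max(sp_ap$laxity) else NA_real_,
    neutral_ap_spread_mm = attr(neutral_ap_spread(x), "overall_max"),
    vv_laxity_spread_deg = attr(sp_vv, "overall_max"),
    max_penetration_mm = max(x$compartments$max_penetration_mm))
}

#' Plot study results
#'
#' `autoplot()` methods in the style of the laxity-envelope figures:
#' kinematic trajectories relative to the baseline neutral curve, laxity
#' envelopes per test, or compartmental force deltas.
#'
#' @param object a `knee_study`.
#' @param type `"laxity"`, `"kinematics"` or `"compartments"`.
#' @param dof which JCS coordinate to show for `type = "kinematics"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.knee_study <- function(object, type = c("laxity", "kinematics",
                                                 "compartments"),
                                dof = "ap", ...) {
  type <- match.arg(type)
  if (type == "laxity") {
    ggplot2::ggplot(object$laxity,
                    ggplot2::aes(x = .data$flexion_deg, y = .data$laxity,
                                 colour = .data$condition)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::facet_wrap(~test, scales = "free_y") +
      ggplot2::labs(x = "Flexion (deg)", y = "Laxity (mm or deg)",
                    colour = "Condition")
  } else if (type == "kinematics") {
    rel <- relative_to_baseline(object$kinematics)
    ggplot2::ggplot(rel,
                    ggplot2::aes(x = .data$flexion_deg, y = .data[[dof]],
                                 colour = .data$condition,
                                 linetype = .data$test)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Flexion (deg)",
                    y = paste(toupper(dof), "relative to baseline neutral"),
                    colour = "Condition", linetype = "Test")
  } else {
    d <- compartment_deltas(object) |>
      tidyr::pivot_longer(c("medial_delta_N", "lateral_delta_N"),
                          names_to = "compartment", values_to = "delta_N")
    ggplot2::ggplot(d, ggplot2::aes(x = .data$flexion_deg, y = .data$delta_N,
                                    colour = .data$condition)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::facet_wrap(~compartment) +
      ggplot2::labs(x = "Flexion (deg)",
                    y = "Compressive force minus baseline (N)",
                    colour = "Condition")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
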