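#' Reference strain from reference and slack lengths
#'
#' The reference strain is the strain a fiber carries at the reference pose
#' (knee in full extension): `(l_r - l_0) / l_0 * 100` percent, where `l_0`
#' is the zero-force (slack) length and `l_r` the fiber length at the
#' reference pose.
#'
#' @param l_r reference-pose fiber length (mm).
#' @param l_0 zero-force (slack) length (mm), > 0.
#' @return reference strain in percent.
#' @seealso [slack_length()] for the inverse.
#' @export
reference_strain <- function(l_r, l_0) {
  if (any(l_0 <= 0)) stop("slack length l_0 must be positive")
  (l_r - l_0) / l_0 * 100
}

#' Slack length from reference length and reference strain
#'
#' Inverts the reference-strain relation: `l_0 = l_r / (1 + eps_r / 100)`.
#'
#' @param l_r reference-pose fiber length (mm).
#' @param eps_r reference strain in percent, > -100.
#' @return zero-force (slack) length (mm).
#' @export
slack_length <- function(l_r, eps_r) {
  if (any(eps_r <= -100)) stop("reference strain must exceed -100%")
  l_r / (1 + eps_r / 100)
}

#' Nonlinear fiber force law
#'
#' Quadratic-toe / linear tension-strain law for a ligament fiber: zero for
#' slack fibers, `k * strain^2 / (4 * eps_t)` in the toe region
#' `0 < strain <= 2 * eps_t`, and `k * (strain - eps_t)` beyond. The law is
#' continuous and C1 at the toe/linear junction and non-decreasing in strain;
#' `k` has units of N per unit strain.
#'
#' @param strain dimensionless fiber strain (may be a vector).
#' @param k fiber stiffness, N per unit strain.
#' @param eps_t toe transition strain (default 0.03).
#' @return tension in N.
#' @export
fiber_tension <- function(strain, k, eps_t = 0.03) {
  ifelse(strain <= 0, 0,
         ifelse(strain <= 2 * eps_t,
                k * strain^2 / (4 * eps_t),
                k * (strain - eps_t)))
}

#' Fiber strain energy
#'
#' Elastic energy stored in a fiber, the integral of tension over length
#' change (`dl = l_0 d strain`). Used for the energy-consistency checks of
#' the equilibrium solver.
#'
#' @inheritParams fiber_tension
#' @param l_0 slack length (mm); energy returned in N mm.
#' @return energy in N mm.
#' @export
fiber_energy <- function(strain, k, l_0, eps_t = 0.03) {
  ifelse(strain <= 0, 0,
         ifelse(strain <= 2 * eps_t,
                l_0 * k * strain^3 / (12 * eps_t),
                l_0 * k * ((strain - eps_t)^2 / 2 + eps_t^2 / 6)))
}

#' Path to the packaged ligament parameter file
#' @return file path of the packaged parameter YAML.
#' @export
default_ligament_file <- function() {
  system.file("extdata", "ligament_table.yaml", package = "kneelax", mustWork = TRUE)
}

#' Read a ligament parameter file
#'
#' Reads the structured parameter file: the final bundle table (name,
#' ligament, stiffness N per unit strain, reference strain percent), the
#' original-bundle insertion sites (femur/tibia body frames, mm), wrap
#' surface labels per ligament, and the force-law toe transition strain.
#'
#' @param path parameter file; defaults to the packaged file.
#' @return list with elements `table` (tibble), `insertions` (tibble with
#'   columns ligament, bundle, fx, fy, fz, tx, ty, tz, wrap), `eps_t`.
#' @export
read_ligament_params <- function(path = default_ligament_file()) {
  y <- yaml::read_yaml(path)
  tab <- purrr::map_dfr(y$table, tibble::as_tibble)
  ins <- purrr::imap_dfr(y$insertions, function(lig, nm) {
    wrap <- paste(unlist(lig$wrap), collapse = ",")
    purrr::imap_dfr(lig$bundles, function(b, bn) {
      tibble::tibble(ligament = nm, bundle = bn,
                     fx = b$femur[1], fy = b$femur[2], fz = b$femur[3],
                     tx = b$tibia[1], ty = b$tibia[2], tz = b$tibia[3],
                     wrap = wrap)
    })
  })
  list(table = tab, insertions = ins,
       eps_t = y$force_law$toe_transition_strain %||% 0.03)
}

# anterior->posterior prefix order used for bundle naming
bundle_prefix <- function(name, ligament) {
  sub(paste0("-?", ligament, "$"), "", name)
}

combined_prefix <- function(p1, p2) {
  if (p1 == "a" && p2 == "m") return("am")
  if (p1 == "m" && p2 == "p") return("mp")
  if (p1 == "a" && p2 == "p") return("m")
  paste0(p1, p2)
}

#' Augment a ligament's bundle set
#'
#' Inserts one new bundle between each adjacent pair of an anterior-to-
#' posterior ordered bundle set: the new femoral and tibial insertions are
#' the midpoints of the neighbours' insertions, and the new reference strain
#' is the arithmetic mean of the neighbours' reference strains. A 3-bundle
#' collateral becomes 5 bundles; the 2-bundle PCL becomes 3 bundles. New
#' bundles receive the mean of their neighbours' stiffnesses as a nominal
#' value (see [calibrate_stiffness()]) and their slack lengths are
#' back-computed from the measured reference length via [slack_length()].
#'
#' @param bundles tibble for one ligament, ordered anterior to posterior,
#'   with columns `name`, `ligament`, `stiffness`, `reference_strain`,
#'   `fx,fy,fz`, `tx,ty,tz` and optionally `wrap`.
#' @param measure_length function(fem_point, tib_point) returning the fiber
#'   length at the reference pose; defaults to the straight-line distance.
#'   Pass a wrapped-path length for wrapped ligaments.
#' @return tibble with the augmented, ordered bundle set, including `l_r`
#'   and `l_0` columns for every bundle and an `augmented` flag.
#' @export
augment_bundles <- function(bundles, measure_length = NULL) {
  if (nrow(bundles) < 2) stop("need at least 2 bundles to augment")
  if (is.null(measure_length))
    measure_length <- function(f, t) sqrt(sum((f - t)^2))
  lig <- bundles$ligament[1]
  hyph <- grepl("-", bundles$name[1], fixed = TRUE)
  rows <- list()
  for (i in seq_len(nrow(bundles))) {
    b <- bundles[i, ]
    b$augmented <- FALSE
    rows[[length(rows) + 1]] <- b
    if (i < nrow(bundles)) {
      b2 <- bundles[i + 1, ]
      pre <- combined_prefix(bundle_prefix(b$name, lig), bundle_prefix(b2$name, lig))
      new <- b
      new$name <- paste0(pre, if (hyph) "-" else "", lig)
      new$reference_strain <- (b$reference_strain + b2$reference_strain) / 2
      new$stiffness <- (b$stiffness + b2$stiffness) / 2
      for (cc in c("fx", "fy", "fz", "tx", "ty", "tz"))
        new[[cc]] <- (b[[cc]] + b2[[cc]]) / 2
      new$augmented <- TRUE
      rows[[length(rows) + 1]] <- new
    }
  }
  out <- dplyr::bind_rows(rows)
  out$l_r <- purrr::map_dbl(seq_len(nrow(out)), function(i)
    measure_length(c(out$fx[i], out$fy[i], out$fz[i]),
                   c(out$tx[i], out$ty[i], out$tz[i])))
  out$l_0 <- slack_length(out$l_r, out$reference_strain)
  out
}

#' Calibrate augmented-bundle stiffnesses
#'
#' Scales all stiffnesses of an augmented bundle set by one per-ligament
#' factor so that the ligament's total fiber tension at a distracted pose
#' (all bundles engaged) equals the original set's total tension at the same
#' pose. Uniform scaling preserves the relative anterior/posterior force
#' distribution of the pre-existing bundles exactly.
#'
#' @param original,augmented bundle tibbles (with `l_0` columns) for one
#'   ligament.
#' @param distraction length-3 tibial translation (mm) applied from the
#'   reference pose to reach the distracted position (e.g. `c(0, -5, 0)` for
#'   5 mm inferior distraction).
#' @param eps_t toe transition strain of the force law.
#' @return the augmented tibble with scaled `stiffness` and an attribute
#'   `scale_factor`.
#' @export
calibrate_stiffness <- function(original, augmented, distraction = c(0, -5, 0),
                                eps_t = 0.03) {
  total <- function(b) {
    l <- purrr::map_dbl(seq_len(nrow(b)), function(i)
      sqrt(sum((c(b$fx[i], b$fy[i], b$fz[i]) -
                (c(b$tx[i], b$ty[i], b$tz[i]) + distraction))^2)))
    strain <- (l - b$l_0) / b$l_0
    if (any(strain <= 0))
      stop("distraction insufficient: slack bundle(s) at the distraction pose: ",
           paste(b$name[strain <= 0], collapse = ", "))
    sum(fiber_tension(strain, b$stiffness, eps_t))
  }
  t_orig <- total(original)
  t_aug <- total(augmented)
  f <- t_orig / t_aug
  augmented$stiffness <- augmented$stiffness * f
  attr(augmented, "scale_factor") <- f
  augmented
}

# smallest inferior distraction (mm) that engages all bundles of `b` with at
# least `margin` strain; used to pick a per-ligament calibration pose
engaging_distraction <- function(b, margin = 0.01, start = 5) {
  d <- start
  repeat {
    l <- purrr::map_dbl(seq_len(nrow(b)), function(i)
      sqrt(sum((c(b$fx[i], b$fy[i], b$fz[i]) -
                (c(b$tx[i], b$ty[i], b$tz[i]) + c(0, -d, 0)))^2)))
    if (all((l - b$l_0) / b$l_0 > margin)) return(d)
    d <- d + 2.5
    if (d > 200) stop("could not engage all bundles by distraction")
  }
}
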