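unitv <- function(v) v / sqrt(sum(v^2))

#' Ligament fiber path with single-via-point wrapping
#'
#' Computes the path of a point-to-point fiber between its tibial and femoral
#' insertions (world frame). If the straight segment does not intersect any
#' wrap surface the path is the segment itself; otherwise the path is routed
#' through exactly one via point on the wrap surface, chosen to minimise the
#' total path length subject to neither sub-segment penetrating the surface.
#' The via point is found by projected-gradient descent on the surface from
#' the chord/surface intersection midpoint, with a vertex grid-search
#' fallback when the local search ends infeasible.
#'
#' @param tibial,femoral insertion points (world frame, mm).
#' @param wrap_meshes list of posed `klx_mesh` wrap surfaces (possibly empty).
#' @param n_iter projected-gradient iterations.
#' @param via_init optional warm-start via point (e.g. from a nearby pose).
#' @return list with `points` (path vertex matrix, tibial end first),
#'   `length` (mm), `wrapped` (logical), `via` (via point or NULL) and
#'   `mesh` (wrap surface label or NA).
#' @export
wrap_path <- function(tibial, femoral, wrap_meshes = list(), n_iter = 30,
                      via_init = NULL) {
  straight <- sqrt(sum((femoral - tibial)^2))
  out <- list(points = rbind(tibial, femoral), length = straight,
              wrapped = FALSE, via = NULL, mesh = NA_character_)
  for (m in wrap_meshes) {
    hits <- segment_mesh_hits(m$vertices, m$faces, tibial, femoral)
    if (length(hits) == 0) next
    if (length(hits) %% 2 == 1) {
      # odd crossing parity: either an endpoint lies inside the surface or
      # the chord grazes it tangentially; disambiguate with jittered chords
      d <- unitv(femoral - tibial)
      u <- unitv(pracma_cross(d, if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
      w <- pracma_cross(d, u)
      odd <- 0; nonzero <- 0
      for (off in list(0.01 * u, -0.01 * u, 0.01 * w, -0.01 * w)) {
        hj <- segment_mesh_hits(m$vertices, m$faces, tibial + off, femoral + off)
        odd <- odd + (length(hj) %% 2)
        nonzero <- nonzero + (length(hj) > 0)
      }
      if (odd >= 3)
        stop("insertion point inside wrap mesh '", m$label, "'")
      if (nonzero == 0) next   # tangential graze, treat as clear
    }
    via <- find_via_point(tibial, femoral, m, hits, n_iter, via_init)
    len <- sqrt(sum((via - tibial)^2)) + sqrt(sum((femoral - via)^2))
    return(list(points = rbind(tibial, via, femoral), length = len,
                wrapped = TRUE, via = via, mesh = m$label))
  }
  out
}

# A sub-segment is clear when it does not meaningfully cross the wrap
# surface. Tangent chords on a faceted surface always dip through facets by
# O(L^2/8R); successive in/out crossing pairs spanning less than `graze`
# millimetres are such grazes, not penetrations.
segment_clear <- function(V, F, a, b, graze = 1.5) {
  h <- segment_mesh_hits(V, F, a, b, tol = 1e-7)
  h <- h[h > 1e-3 & h < 1 - 1e-3]   # ignore tangency at either end
  if (length(h) == 0) return(TRUE)
  if (length(h) %% 2 == 1) {
    # unpaired crossing adjacent to an on-surface endpoint (the via): the
    # matching "crossing" is the endpoint itself
    if (1 - h[length(h)] < h[1]) h <- c(h, 1) else h <- c(0, h)
  }
  len <- sqrt(sum((b - a)^2))
  spans <- (h[seq(2, length(h), by = 2)] - h[seq(1, length(h), by = 2)]) * len
  all(spans <= graze)
}

find_via_point <- function(a, b, mesh, hits, n_iter = 30, via_init = NULL) {
  V <- mesh$vertices; F <- mesh$faces
  if (is.null(via_init)) {
    mid <- a + mean(range(hits)) * (b - a)
  } else {
    mid <- via_init
    n_iter <- min(n_iter, 10L)
  }
  p <- mesh_closest_point(V, F, mid)[1:3]
  f <- function(q) sqrt(sum((q - a)^2)) + sqrt(sum((b - q)^2))
  step <- 1.0
  fp <- f(p)
  for (i in seq_len(n_iter)) {
    g <- unitv(p - a) + unitv(p - b)
    cand <- mesh_closest_point(V, F, p - step * g)[1:3]
    fc <- f(cand)
    if (fc < fp - 1e-12) {
      p <- cand; fp <- fc
    } else {
      step <- step / 2
      if (step < 1e-4) break
    }
  }
  if (segment_clear(V, F, a, p) && segment_clear(V, F, p, b)) return(p)
  # fallback: feasible vertex with the smallest total length
  tot <- sqrt(rowSums(sweep(V, 2, a)^2)) + sqrt(rowSums(sweep(V, 2, b)^2))
  ord <- order(tot)
  for (i in ord) {
    q <- V[i, ]
    if (segment_clear(V, F, a, q) && segment_clear(V, F, q, b)) return(q)
  }
  p
}

#' Resolve ligament fiber tensions to joint loads
#'
#' Evaluates every bundle of a ligament set at the given body poses: fiber
#' path (with wrapping where enabled), strain, tension under the
#' quadratic-toe/linear force law, and the equivalent force system on the
#' two bodies. A straight fiber pulls each body at its insertion along the
#' fiber line. A wrapped fiber presses on its wrap surface at the via point;
#' because the wrap surface is rigidly part of the tibia, the insertion pull
#' and the via reaction combine into a single equivalent force on the tibia:
#' the tension along the via-to-femur segment, acting at the via point. This
#' is exactly equal and opposite (and collinear) to the femoral reaction, and
#' is the gradient of the fiber's elastic energy with respect to the tibial
#' DOFs. Moments are taken about `moment_center` (world frame).
#'
#' @param bundles bundle tibble with columns `name`, `ligament`, `stiffness`,
#'   `l_0`, insertion columns `fx..tz` (body frames) and `wrap` labels.
#' @param femur_pose,tibia_pose 4x4 world poses of the femur and tibia.
#' @param wrap_meshes named list of wrap surface meshes in *tibia body*
#'   coordinates (they are posed with `tibia_pose` internally).
#' @param eps_t toe transition strain.
#' @param moment_center point (world) about which the net moment is taken;
#'   defaults to the origin.
#' @param via_cache optional environment used to warm-start the via-point
#'   search from the previous evaluation (keyed by bundle name, tibia-frame
#'   coordinates).
#' @return tibble of per-bundle results (tension_N, strain, length_mm,
#'   wrapped, force and application point components on the tibia and femur)
#'   with attributes `net_force` and `net_moment` (on the tibia, N / N mm).
#' @export
ligament_loads <- function(bundles, femur_pose, tibia_pose, wrap_meshes = list(),
                           eps_t = 0.03, moment_center = c(0, 0, 0),
                           via_cache = NULL) {
  posed_wraps <- lapply(wrap_meshes, transform_mesh, T = tibia_pose)
  tibia_inv <- solve(tibia_pose)   # via cache lives in the tibia body frame
  n <- nrow(bundles)
  FW <- transform_points(cbind(bundles$fx, bundles$fy, bundles$fz), femur_pose)
  TW <- transform_points(cbind(bundles$tx, bundles$ty, bundles$tz), tibia_pose)
  len <- numeric(n); wrapped <- logical(n)
  DT <- TW * 0; DF <- DT
  has_wrap <- !is.na(bundles$wrap) & nzchar(bundles$wrap)
  for (i in seq_len(n)) {
    fw <- FW[i, ]; tw <- TW[i, ]
    if (has_wrap[i]) {
      wm <- posed_wraps[strsplit(bundles$wrap[i], ",")[[1]]]
      vi <- if (!is.null(via_cache)) via_cache[[bundles$name[i]]] else NULL
      if (!is.null(vi)) vi <- transform_points(vi, tibia_pose)
      path <- wrap_path(tw, fw, wm, via_init = vi)
      if (!is.null(via_cache) && path$wrapped)
        via_cache[[bundles$name[i]]] <- transform_points(path$via, tibia_inv)
      len[i] <- path$length; wrapped[i] <- path$wrapped
      if (path$wrapped) {
        # equivalent force on the tibia acts at the via point, along the
        # via -> femur segment (insertion pull + via reaction combined)
        DT[i, ] <- unitv(fw - path$via)
        TW[i, ] <- path$via
        DF[i, ] <- -DT[i, ]
      } else {
        DT[i, ] <- unitv(path$points[2, ] - tw)
        np <- nrow(path$points)
        DF[i, ] <- unitv(path$points[np - 1, ] - fw)
      }
    } else {
      d <- fw - tw
      len[i] <- sqrt(sum(d^2))
      DT[i, ] <- d / len[i]
      DF[i, ] <- -DT[i, ]
    }
  }
  strain <- (len - bundles$l_0) / bundles$l_0
  tension <- fiber_tension(strain, bundles$stiffness, eps_t)
  Ft <- DT * tension
  Ff <- DF * tension
  out <- tibble::tibble(
    ligament = bundles$ligament, name = bundles$name,
    tension_N = tension, strain = strain, length_mm = len, wrapped = wrapped,
    ftx = Ft[, 1], fty = Ft[, 2], ftz = Ft[, 3],
    ptx = TW[, 1], pty = TW[, 2], ptz = TW[, 3],
    ffx = Ff[, 1], ffy = Ff[, 2], ffz = Ff[, 3],
    pfx = FW[, 1], pfy = FW[, 2], pfz = FW[, 3])
  r <- sweep(TW, 2, moment_center)
  M <- c(sum(r[, 2] * Ft[, 3] - r[, 3] * Ft[, 2]),
         sum(r[, 3] * Ft[, 1] - r[, 1] * Ft[, 3]),
         sum(r[, 1] * Ft[, 2] - r[, 2] * Ft[, 1]))
  attr(out, "net_force") <- unname(colSums(Ft))
  attr(out, "net_moment") <- unname(M)
  out
}

# total ligament elastic energy (N mm) at the given poses
ligament_energy <- function(bundles, femur_pose, tibia_pose, wrap_meshes = list(),
                            eps_t = 0.03) {
  posed_wraps <- lapply(wrap_meshes, transform_mesh, T = tibia_pose)
  e <- 0
  for (i in seq_len(nrow(bundles))) {
    fw <- transform_points(c(bundles$fx[i], bundles$fy[i], bundles$fz[i]), femur_pose)
    tw <- transform_points(c(bundles$tx[i], bundles$ty[i], bundles$tz[i]), tibia_pose)
    wl <- bundles$wrap[i]
    wm <- if (!is.na(wl) && nzchar(wl))
      posed_wraps[strsplit(wl, ",")[[1]]] else list()
    path <- wrap_path(tw, fw, wm)
    strain <- (path$length - bundles$l_0[i]) / bundles$l_0[i]
    e <- e + fiber_energy(strain, bundles$stiffness[i], bundles$l_0[i], eps_t)
  }
  e
}
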