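# Programmatic fixtures shared across test files.

# UV-sphere mesh (closed), outward normals
sphere_mesh <- function(center = c(0, 0, 0), radius = 10, n = 24,
                        label = "sphere") {
  th <- seq(0, pi, length.out = n)           # polar
  ph <- seq(0, 2 * pi, length.out = 2 * n + 1)[-(2 * n + 1)]
  g <- expand.grid(ph = ph, th = th[-c(1, length(th))])
  verts <- cbind(radius * sin(g$th) * cos(g$ph),
                 radius * cos(g$th),
                 radius * sin(g$th) * sin(g$ph))
  np <- length(ph); nt <- length(th) - 2
  idx <- function(i, j) (j - 1L) * np + i
  i <- rep(seq_len(np), nt - 1)
  j <- rep(seq_len(nt - 1), each = np)
  ip1 <- ifelse(i == np, 1L, i + 1L)
  f1 <- cbind(idx(i, j), idx(ip1, j), idx(ip1, j + 1L))
  f2 <- cbind(idx(i, j), idx(ip1, j + 1L), idx(i, j + 1L))
  top <- nrow(verts) + 1L; bot <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, radius, 0), c(0, -radius, 0))
  i2 <- seq_len(np); ip2 <- ifelse(i2 == np, 1L, i2 + 1L)
  ftop <- cbind(rep(top, np), idx(i2, 1L), idx(ip2, 1L))
  fbot <- cbind(rep(bot, np), idx(ip2, nt), idx(i2, nt))
  m <- klx_mesh(sweep(verts, 2, -center), rbind(f1, f2, ftop, fbot), label)
  m
}

# flat rectangular plate mesh at height y0 (upward+downward facing tris)
plate_mesh <- function(y0 = 0, half = 20, n = 9, label = "plate") {
  xs <- seq(-half, half, length.out = n)
  g <- expand.grid(x = xs, z = xs)
  verts <- cbind(g$x, y0, g$z)
  idx <- function(i, j) (j - 1L) * n + i
  i <- rep(seq_len(n - 1L), n - 1L)
  j <- rep(seq_len(n - 1L), each = n - 1L)
  f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  f2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  klx_mesh(verts, rbind(f1, f2), label)
}

# a tiny 2-bundle "ligament" tibble in the layout build_ligament_set produces
toy_bundles <- function(k = c(1000, 1200), er = c(2, 4),
                        name = c("aTOY", "pTOY")) {
  b <- tibble::tibble(
    ligament = "TOY", name = name,
    stiffness = k, reference_strain = er,
    fx = c(5, -5), fy = c(0, 0), fz = c(-30, -30),
    tx = c(5, -5), ty = c(-50, -50), tz = c(-30, -30),
    wrap = "", augmented = FALSE)
  b$l_r <- sqrt((b$fx - b$tx)^2 + (b$fy - b$ty)^2 + (b$fz - b$tz)^2)
  b$l_0 <- slack_length(b$l_r, b$reference_strain)
  b
}

# shared default geometry/model (built once per test run)
default_geometry <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- make_knee_geometry()
    g
  }
})

default_model <- local({
  cache <- list()
  function(condition = "baseline") {
    if (is.null(cache[[condition]]))
      cache[[condition]] <<- knee_model(default_geometry(), condition)
    cache[[condition]]
  }
})

# memoised full study used by the acceptance tests
full_study <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- run_study(study_config())
    s
  }
})
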