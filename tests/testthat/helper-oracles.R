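# Independent oracles and small generators used across the suite. These are
# deliberately written against different formulations than the package code
# (quadratic minimization instead of Voronoi-region walks, optimisation over
# axis-angle instead of the SVD solution) so that agreement is meaningful.

random_rotation <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

random_points <- function(n, scale = 5) {
  labeled_points(matrix(stats::runif(n * 3, -scale, scale), n, 3),
                 paste0("m", seq_len(n)))
}

# point-to-triangle distance by constrained quadratic minimization
oracle_point_tri <- function(p, a, b, c) {
  E1 <- b - a; E2 <- c - a; d0 <- a - p
  A <- sum(E1 * E1); B <- sum(E1 * E2); C <- sum(E2 * E2)
  D <- sum(E1 * d0); E <- sum(E2 * d0)
  det <- A * C - B * B
  cand <- list()
  if (det > 0) cand[[1]] <- c((B * E - C * D) / det, (B * D - A * E) / det)
  cand <- c(cand,
            list(c(max(0, min(1, -D / A)), 0),
                 c(0, max(0, min(1, -E / C))),
                 { u <- max(0, min(1, (A - B + D - E) / (A - 2 * B + C)))
                   c(1 - u, u) },
                 c(0, 0), c(1, 0), c(0, 1)))
  best <- Inf
  for (st in cand) {
    s <- st[1]; t <- st[2]
    if (!is.finite(s) || !is.finite(t) || s < -1e-12 || t < -1e-12 ||
        s + t > 1 + 1e-12) next
    q <- a + s * E1 + t * E2
    best <- min(best, sqrt(sum((q - p)^2)))
  }
  best
}

# distance from one point to every triangle at once (vectorised over faces):
# the closest point is either the unconstrained barycentric solution or the
# clamped minimum along one of the three edges, so evaluating all four
# candidates per face is exhaustive
oracle_point_tris <- function(p, A, B, C) {
  E1 <- B - A; E2 <- C - A
  D0 <- sweep(A, 2, p)
  a <- rowSums(E1 * E1); b <- rowSums(E1 * E2); c <- rowSums(E2 * E2)
  d <- rowSums(E1 * D0); e <- rowSums(E2 * D0)
  det <- pmax(a * c - b * b, 1e-300)
  qdist <- function(s, t) {
    Q <- A + s * E1 + t * E2
    rowSums(sweep(Q, 2, p)^2)
  }
  s0 <- (b * e - c * d) / det
  t0 <- (b * d - a * e) / det
  d_int <- ifelse(s0 >= 0 & t0 >= 0 & s0 + t0 <= 1, qdist(s0, t0), Inf)
  d_ab <- qdist(pmax(0, pmin(1, -d / a)), 0)
  d_ac <- qdist(0, pmax(0, pmin(1, -e / c)))
  u <- pmax(0, pmin(1, (a - b + d - e) / pmax(a - 2 * b + c, 1e-300)))
  d_bc <- qdist(1 - u, u)
  sqrt(min(d_int, d_ab, d_ac, d_bc))
}

# exhaustive all-vertices-to-all-triangles symmetric scan
oracle_mesh_clearance <- function(ma, mb) {
  one_way <- function(V, mesh) {
    A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
    B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
    C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
    min(vapply(seq_len(nrow(V)), function(i)
      oracle_point_tris(V[i, ], A, B, C), numeric(1)))
  }
  min(one_way(ma$vertices, mb), one_way(mb$vertices, ma))
}

# small random closed-ish surface: a randomly rotated, offset triangulated
# sphere patch (triangle soup is fine for distance oracles)
random_small_mesh <- function(n_tri_target = 60, offset = c(0, 0, 0)) {
  n <- max(4, ceiling(sqrt(n_tri_target / 2)) + 1)
  th <- seq(0.3, pi - 0.3, length.out = n)
  ph <- seq(0, 1.6 * pi, length.out = n)
  V <- NULL
  for (i in seq_len(n))
    for (j in seq_len(n))
      V <- rbind(V, c(sin(th[i]) * cos(ph[j]), sin(th[i]) * sin(ph[j]),
                      cos(th[i])))
  F <- NULL
  id <- function(i, j) (i - 1) * n + j
  for (i in seq_len(n - 1))
    for (j in seq_len(n - 1))
      F <- rbind(F, c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                 c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  R <- random_rotation()
  V <- V %*% t(R) * stats::runif(1, 0.5, 1.5)
  V <- sweep(V, 2, offset, "+")
  tri_mesh(V, F)
}

# least-squares rigid-fit residual by direct optimisation over axis-angle
# rotation parameters (independent of the SVD route)
oracle_fit_residual <- function(A, B) {
  obj <- function(par) {
    th <- sqrt(sum(par^2))
    R <- if (th < 1e-12) diag(3) else {
      ax <- par / th
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    }
    fitted <- A %*% t(R)
    fitted <- sweep(fitted, 2, colMeans(B) - colMeans(fitted), "+")
    sum((fitted - B)^2)
  }
  starts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                  c(2, 1, -1), c(-1, 2, 1), c(3, 0, 0), c(0, 3, 0),
                  c(0, 0, 3), c(-2, -2, 2))
  best <- Inf
  for (k in seq_len(nrow(starts))) {
    r <- stats::optim(starts[k, ], obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, r$value)
  }
  sqrt(best / nrow(A))
}

# default synthetic bundle shared by several tests (noiseless, few cycles)
synth_bundle <- function(spec = motion_spec(n_cycles = 3), seed = 1,
                         resolution_mm = 0.1) {
  truth <- simulate_jaw_motion(spec)
  cap <- synth_capture(truth, noise_sigma_mm = 0, seed = seed)
  ref <- default_marker_geometry()
  ps <- estimate_pose_series(cap, ref)
  dent <- synth_dentition(resolution_mm, spec$working_side)
  model <- anatomical_model(dent$mandible, dent$maxilla, ref, dent$landmarks)
  maxpose <- register_maxilla_static(attr(cap, "static_frame"), model)
  list(truth = truth, capture = cap, reference = ref, pose_series = ps,
       dentition = dent, model = model, maxilla_pose = maxpose)
}
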