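# Fixtures and independent oracles used across the test files. Oracles are
# deliberately written as plain, slow R so they stay independent of the
# package's optimized implementations.

# closed UV-sphere triangulation (two poles + latitude rings)
make_sphere <- function(n_lat = 8L, n_lon = 12L, radius = 1, center = c(0, 0, 0)) {
  lat <- seq(0, pi, length.out = n_lat + 2L)[-c(1L, n_lat + 2L)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  v <- list(c(0, 0, radius))
  for (la in lat) {
    for (lo in lon) {
      v[[length(v) + 1L]] <- radius * c(sin(la) * cos(lo), sin(la) * sin(lo),
                                        cos(la))
    }
  }
  v[[length(v) + 1L]] <- c(0, 0, -radius)
  verts <- sweep(do.call(rbind, v), 2L, center, "+")
  idx <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  f <- list()
  for (j in seq_len(n_lon)) {
    f[[length(f) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  }
  for (i in seq_len(n_lat - 1L)) {
    for (j in seq_len(n_lon)) {
      f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
      f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    }
  }
  last <- nrow(verts)
  for (j in seq_len(n_lon)) {
    f[[length(f) + 1L]] <- c(last, idx(n_lat, j + 1L), idx(n_lat, j))
  }
  m <- tri_mesh(verts, do.call(rbind, f))
  if (signed_volume(m) < 0) m <- tri_mesh(m$vertices, m$faces[, c(1, 3, 2)])
  m
}

# random rotation matrix (QR of a Gaussian matrix, determinant fixed to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# small random closed mesh: jittered sphere (stays a valid closed surface)
random_blob <- function(n_lat = 4L, n_lon = 7L, bump = 0.25, radius = 10) {
  m <- make_sphere(n_lat, n_lon, radius = radius)
  dirs <- m$vertices / sqrt(rowSums(m$vertices^2))
  scale <- 1 + bump * stats::runif(n_vertices(m), -1, 1)
  tri_mesh(dirs * radius * scale, m$faces)
}

# brute-force neighborhood oracle: plain distance scan
neighborhood_scan <- function(mesh, j, r) {
  d <- sqrt(colSums((t(mesh$vertices) - mesh$vertices[j, ])^2))
  which(d <= r)
}

# independent rotation-only Kabsch (pinned centers), plain R
oracle_pinned_rotation <- function(u, v) {
  H <- t(u) %*% v
  sv <- svd(H)
  if (sv$d[2] <= 1e-12 * max(sv$d[1], 1e-300)) return(diag(3))
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

# independent exhaustive correspondence search: every target vertex is a
# candidate; pinned rotation refinement; hand-rolled Pearson on matched lists
oracle_exhaustive_match <- function(source, target, j, r, pre_align,
                                    max_refine = 5L) {
  sv <- source$vertices
  tv <- target$vertices
  pj <- sv[j, ]
  p0 <- as.numeric(pre_align$rotation %*% pj + pre_align$translation)
  nb_s <- which(sqrt(colSums((t(sv) - pj)^2)) <= r)
  Qs <- sv[nb_s, , drop = FALSE]
  u <- sweep(Qs, 2L, pj)
  n_t <- nrow(tv)
  scores <- rep(-Inf, n_t)
  for (c_idx in seq_len(n_t)) {
    pc <- tv[c_idx, ]
    nb_t <- which(sqrt(colSums((t(tv) - pc)^2)) <= r)
    Qt <- tv[nb_t, , drop = FALSE]
    if (nrow(Qs) < 2L || nrow(Qt) < 2L) next
    R <- pre_align$rotation
    for (it in seq_len(max_refine)) {
      X <- sweep(u %*% t(R), 2L, pc, "+")
      d2 <- outer(rowSums(X^2), rowSums(Qt^2), "+") - 2 * tcrossprod(X, Qt)
      Y <- Qt[max.col(-d2, ties.method = "first"), , drop = FALSE]
      Rn <- oracle_pinned_rotation(u, sweep(Y, 2L, pc))
      delta <- max(abs(Rn - R))
      R <- Rn
      if (delta < 1e-10) break
    }
    X <- sweep(u %*% t(R), 2L, pc, "+")
    d2 <- outer(rowSums(X^2), rowSums(Qt^2), "+") - 2 * tcrossprod(X, Qt)
    Y <- Qt[max.col(-d2, ties.method = "first"), , drop = FALSE]
    xc <- as.vector(sweep(X, 2L, colMeans(X)))
    yc <- as.vector(sweep(Y, 2L, colMeans(Y)))
    if (sum(xc^2) == 0 || sum(yc^2) == 0) next
    scores[c_idx] <- max(-1, min(1, sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))))
  }
  dist0 <- sqrt(colSums((t(tv) - p0)^2))
  order(-scores, dist0, seq_len(n_t))[1]
}

# smooth small deformation of a mesh: low-frequency sinusoidal displacement
smooth_deform <- function(mesh, amplitude) {
  v <- mesh$vertices
  scale <- max(apply(v, 2L, function(x) diff(range(x))))
  phase <- stats::runif(3, 0, 2 * pi)
  disp <- cbind(sin(2 * pi * v[, 2] / scale + phase[1]),
                sin(2 * pi * v[, 3] / scale + phase[2]),
                sin(2 * pi * v[, 1] / scale + phase[3]))
  tri_mesh(v + amplitude * disp, mesh$faces)
}

# adjacency lookup: is b the same vertex as a or an immediate mesh neighbor?
is_identity_or_neighbor <- function(mesh, a, b) {
  if (a == b) return(TRUE)
  e <- mesh_edges(mesh)
  any((e[, 1] == a & e[, 2] == b) | (e[, 1] == b & e[, 2] == a))
}

small_template <- function(n_vertices = 200L, seed = 1L) {
  make_template_mandible(n_vertices = n_vertices, n_segments = 6L, seed = seed)
}
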