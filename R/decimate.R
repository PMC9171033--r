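#' Decimate a mesh to an exact vertex count
#'
#' Quadric error edge-collapse simplification: each vertex carries the sum of
#' squared-distance quadrics of its incident face planes; the edge whose
#' contraction minimizes the quadric error is collapsed repeatedly until the
#' requested vertex count is reached. Collapses that would break the local
#' manifold structure (link condition) are skipped, which preserves
#' watertightness of closed inputs. The target count is met exactly: the
#' driver keeps collapsing edges until `n_vertices == target_n`.
#'
#' Used by the vertex-count sensitivity scan, which repeatedly reduces the
#' model by a fixed fraction of its vertices and re-runs the growth analysis.
#'
#' @param mesh a [tri_mesh()].
#' @param target_n requested vertex count, `4 <= target_n <= n_vertices(mesh)`.
#' @return A `tri_mesh` with exactly `target_n` vertices.
#' @export
decimate <- function(mesh, target_n) {
  n <- n_vertices(mesh)
  if (target_n > n) stop("target_n (", target_n, ") exceeds vertex count (", n, ")",
                         call. = FALSE)
  if (target_n < 4L) stop("target_n must be at least 4", call. = FALSE)
  if (target_n == n) return(mesh)

  v <- mesh$vertices
  f <- mesh$faces
  quad <- vertex_quadrics(v, f)
  alive <- rep(TRUE, n)

  edges <- mesh_edges(mesh)
  cost <- edge_costs(edges, quad, v)

  n_alive <- n
  while (n_alive > target_n) {
    ord <- order(cost$err)
    collapsed <- FALSE
    for (k in ord) {
      a <- edges[k, 1]; b <- edges[k, 2]
      if (!alive[a] || !alive[b]) next
      if (!link_condition_ok(f, a, b)) next
      # contract b into a at the optimal position
      v[a, ] <- cost$pos[k, ]
      quad[[a]] <- quad[[a]] + quad[[b]]
      alive[b] <- FALSE
      f[f == b] <- a
      degen <- f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]
      f <- f[!degen, , drop = FALSE]
      n_alive <- n_alive - 1L
      # rebuild the edge set touching a; drop edges touching b
      touched <- edges[, 1] == a | edges[, 2] == a | edges[, 1] == b | edges[, 2] == b
      edges <- edges[!touched, , drop = FALSE]
      cost$err <- cost$err[!touched]
      cost$pos <- cost$pos[!touched, , drop = FALSE]
      inc <- f[f[, 1] == a | f[, 2] == a | f[, 3] == a, , drop = FALSE]
      if (nrow(inc)) {
        nb <- setdiff(unique(as.vector(inc)), a)
        newe <- cbind(pmin(a, nb), pmax(a, nb))
        newc <- edge_costs(newe, quad, v)
        edges <- rbind(edges, newe)
        cost$err <- c(cost$err, newc$err)
        cost$pos <- rbind(cost$pos, newc$pos)
      }
      collapsed <- TRUE
      break
    }
    if (!collapsed) {
      stop("decimation blocked: no collapsible edge before reaching target_n",
           call. = FALSE)
    }
  }

  keep <- which(alive)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  tri_mesh(v[keep, , drop = FALSE], matrix(remap[f], ncol = 3L),
           mesh$instance_label)
}

# 4x4 plane quadrics summed per vertex (Garland-Heckbert).
vertex_quadrics <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(nrm^2)) / 2
  len <- 2 * area; len[len == 0] <- 1
  nrm <- nrm / len
  d <- -rowSums(nrm * v[f[, 1], , drop = FALSE])
  quad <- vector("list", nrow(v))
  zero <- matrix(0, 4, 4)
  for (i in seq_along(quad)) quad[[i]] <- zero
  for (k in seq_len(nrow(f))) {
    p <- c(nrm[k, ], d[k])
    Kp <- (area[k]) * tcrossprod(p)
    for (c in 1:3) quad[[f[k, c]]] <- quad[[f[k, c]]] + Kp
  }
  quad
}

edge_costs <- function(edges, quad, v) {
  m <- nrow(edges)
  err <- numeric(m)
  pos <- matrix(0, m, 3L)
  for (k in seq_len(m)) {
    Q <- quad[[edges[k, 1]]] + quad[[edges[k, 2]]]
    A <- Q[1:3, 1:3]
    b <- -Q[1:3, 4]
    p <- tryCatch(solve(A + diag(1e-12, 3), b), error = function(e) NULL)
    cands <- rbind(p, v[edges[k, 1], ], v[edges[k, 2], ],
                   (v[edges[k, 1], ] + v[edges[k, 2], ]) / 2)
    errs <- apply(cands, 1L, function(q) {
      h <- c(q, 1)
      as.numeric(h %*% Q %*% h)
    })
    best <- which.min(errs)
    err[k] <- errs[best]
    pos[k, ] <- cands[best, ]
  }
  list(err = err, pos = pos)
}

# collapse of (a,b) keeps the surface manifold iff the vertices adjacent to
# both a and b are exactly the two opposite vertices of the shared faces
link_condition_ok <- function(f, a, b) {
  inc_a <- f[f[, 1] == a | f[, 2] == a | f[, 3] == a, , drop = FALSE]
  inc_b <- f[f[, 1] == b | f[, 2] == b | f[, 3] == b, , drop = FALSE]
  na <- setdiff(unique(as.vector(inc_a)), a)
  nb <- setdiff(unique(as.vector(inc_b)), b)
  shared_faces <- inc_a[inc_a[, 1] == b | inc_a[, 2] == b | inc_a[, 3] == b, ,
                        drop = FALSE]
  common <- intersect(na, nb)
  length(common) == nrow(shared_faces) &&
    length(setdiff(common, setdiff(unique(as.vector(shared_faces)), c(a, b)))) == 0
}
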