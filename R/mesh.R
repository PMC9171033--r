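#' Triangulated surface meshes
#'
#' A `tri_mesh` stores a triangulated bone surface at one measurement
#' instance: an n x 3 matrix of vertex positions in mm and an m x 3 integer
#' matrix of faces holding 1-based vertex indices. Faces must reference valid
#' vertices and contain no repeated index; after cleanup every vertex is
#' referenced by at least one face and all coordinates are finite.
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param instance_label optional identifier of the measurement instance
#'   (e.g. `"T1"`).
#' @return An object of class `tri_mesh`.
#' @examples
#' m <- tetrahedron_mesh()
#' n_vertices(m)
#' n_faces(m)
#' @export
tri_mesh <- function(vertices, faces, instance_label = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  validate_mesh(vertices, faces)
  structure(list(vertices = vertices, faces = faces,
                 instance_label = instance_label),
            class = "tri_mesh")
}

validate_mesh <- function(vertices, faces) {
  if (nrow(vertices) == 0L) stop("mesh has no vertices", call. = FALSE)
  if (any(!is.finite(vertices))) stop("mesh has non-finite coordinates", call. = FALSE)
  if (nrow(faces) == 0L) stop("mesh has no faces", call. = FALSE)
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices outside [1, n_vertices]", call. = FALSE)
  }
  degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
    faces[, 2] == faces[, 3]
  if (any(degen)) {
    stop("degenerate faces (repeated vertex index) at rows: ",
         paste(utils::head(which(degen), 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("<tri_mesh>", n_vertices(x), "vertices,", n_faces(x), "faces")
  if (!is.null(x$instance_label)) cat(" [", x$instance_label, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @rdname tri_mesh
#' @param mesh a `tri_mesh`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname tri_mesh
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Weld duplicate vertices and drop unreferenced ones
#'
#' Vertices closer than `tol` (in every coordinate, after snapping to a grid
#' of spacing `tol`) are merged into one; faces are re-indexed; faces made
#' degenerate by welding and vertices referenced by no face are dropped.
#'
#' @param mesh a [tri_mesh()].
#' @param tol welding tolerance in mm. The default 1e-6 mm sits far below the
#'   voxel scale of CBCT reconstructions (~0.4 mm).
#' @return A cleaned `tri_mesh`.
#' @export
clean_mesh <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- match(key, key)            # representative row per duplicate group
  keep <- sort(unique(first))
  remap <- integer(nrow(v))
  remap[keep] <- seq_along(keep)
  f <- matrix(remap[first[mesh$faces]], ncol = 3L)
  degen <- f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]
  f <- f[!degen, , drop = FALSE]
  if (nrow(f) == 0L) stop("mesh has no valid faces after welding", call. = FALSE)
  v <- v[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  if (length(used) < nrow(v)) {
    remap2 <- integer(nrow(v))
    remap2[used] <- seq_along(used)
    v <- v[used, , drop = FALSE]
    f <- matrix(remap2[f], ncol = 3L)
  }
  tri_mesh(v, f, mesh$instance_label)
}

#' Unique undirected mesh edges
#'
#' Edges are derived from face adjacency: each unordered pair of vertices
#' sharing a face appears exactly once, as a row `(a, b)` with `a < b`.
#' These vertex pairs are the "adjacent vertices" whose distance changes
#' define the local morphological change of the surface.
#'
#' @param mesh a [tri_mesh()].
#' @return Integer matrix with columns `a`, `b` (1-based vertex indices),
#'   ordered lexicographically.
#' @examples
#' nrow(mesh_edges(tetrahedron_mesh())) # K4: 6 edges
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  colnames(e) <- c("a", "b")
  e
}

#' Vertices within a Euclidean ball of a given vertex
#'
#' Returns the indices of all vertices whose Euclidean distance to vertex `j`
#' is at most `r` (including `j` itself). The neighborhood metric is
#' Euclidean, not geodesic: it is well defined across disconnected parts and
#' cheap to evaluate; a geodesic variant (graph distance along mesh edges,
#' with Euclidean edge weights) is available via `metric = "geodesic"`.
#'
#' @param mesh a [tri_mesh()].
#' @param j vertex index (1-based).
#' @param r neighborhood radius in mm, > 0.
#' @param metric `"euclidean"` (default) or `"geodesic"`.
#' @return Integer vector of vertex indices, sorted, always containing `j`.
#' @export
vertex_neighborhood <- function(mesh, j, r, metric = c("euclidean", "geodesic")) {
  metric <- match.arg(metric)
  stopifnot(r > 0, j >= 1L, j <= n_vertices(mesh))
  if (metric == "euclidean") {
    d2 <- colSums((t(mesh$vertices) - mesh$vertices[j, ])^2)
    which(d2 <= r * r)
  } else {
    geodesic_ball(mesh, j, r)
  }
}

# Dijkstra over the edge graph, truncated at radius r.
geodesic_ball <- function(mesh, j, r) {
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  n <- n_vertices(mesh)
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- rbind(adj[[e[k, 1]]], c(e[k, 2], w[k]))
    adj[[e[k, 2]]] <- rbind(adj[[e[k, 2]]], c(e[k, 1], w[k]))
  }
  dist <- rep(Inf, n)
  dist[j] <- 0
  active <- j
  while (length(active)) {
    i <- active[which.min(dist[active])]
    active <- setdiff(active, i)
    nb <- adj[[i]]
    if (is.null(nb)) next
    for (k in seq_len(nrow(nb))) {
      cand <- dist[i] + nb[k, 2]
      if (cand < dist[nb[k, 1]] && cand <= r) {
        dist[nb[k, 1]] <- cand
        active <- union(active, nb[k, 1])
      }
    }
  }
  which(dist <= r)
}

#' Apply a rigid transform to a mesh
#'
#' Every vertex is mapped to `R p + v`; connectivity is unchanged. Rigidity
#' guarantees all pairwise distances are preserved.
#'
#' @param mesh a [tri_mesh()].
#' @param transform a [rigid_transform()].
#' @return The transformed `tri_mesh`.
#' @export
apply_transform <- function(mesh, transform) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (!inherits(transform, "rigid_transform")) {
    stop("transform must be a rigid_transform", call. = FALSE)
  }
  tri_mesh(transform_points(transform, mesh$vertices), mesh$faces,
           mesh$instance_label)
}

#' Mean edge length of a mesh
#'
#' Used to set scale-aware defaults for the correspondence search radii.
#'
#' @param mesh a [tri_mesh()].
#' @return Mean Euclidean edge length in mm.
#' @export
mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  mean(sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2)))
}

#' Outward vertex normals
#'
#' Area-weighted average of incident face normals, normalized. For a closed
#' mesh with consistent winding the normals are oriented outward when the
#' signed volume is positive; if the signed volume is negative the normals
#' are flipped so that "outward" is well defined.
#'
#' @param mesh a [tri_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])   # 2*area-weighted
  n <- matrix(0, nrow(v), 3L)
  for (c in 1:3) {
    n[, 1] <- n[, 1] + tabulate2(f[, c], fn[, 1], nrow(v))
    n[, 2] <- n[, 2] + tabulate2(f[, c], fn[, 2], nrow(v))
    n[, 3] <- n[, 3] + tabulate2(f[, c], fn[, 3], nrow(v))
  }
  if (signed_volume(mesh) < 0) n <- -n
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

tabulate2 <- function(index, weight, n) {
  out <- numeric(n)
  s <- rowsum(weight, index)
  out[as.integer(rownames(s))] <- s
  out
}

#' Signed volume enclosed by a mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for a
#' closed surface with outward (counter-clockwise) winding.
#'
#' @param mesh a [tri_mesh()].
#' @return Signed volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
        a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
        a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Is a mesh watertight?
#'
#' A closed (watertight) triangulation has every edge shared by exactly two
#' faces.
#'
#' @param mesh a [tri_mesh()].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Euler characteristic V - E + F
#'
#' @param mesh a [tri_mesh()].
#' @return Integer; 2 for a closed genus-0 surface.
#' @export
euler_characteristic <- function(mesh) {
  n_vertices(mesh) - nrow(mesh_edges(mesh)) + n_faces(mesh)
}

#' A unit tetrahedron test mesh
#'
#' Small closed mesh used throughout examples and tests.
#'
#' @return A `tri_mesh` with 4 vertices and 4 faces.
#' @export
tetrahedron_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  tri_mesh(v, f, "tetrahedron")
}

#' An ordered series of meshes with instance times
#'
#' Holds the longitudinal series of surface models of one growing bone. Times
#' are in months (the study convention: one "month" = a four-week interval);
#' they must be strictly increasing and at least two meshes are required.
#'
#' @param meshes list of [tri_mesh()] objects, time-ordered.
#' @param times numeric vector of instance times in months; defaults to
#'   `1:length(meshes)`.
#' @return An object of class `mesh_series`.
#' @export
mesh_series <- function(meshes, times = seq_along(meshes)) {
  if (length(meshes) < 2L) stop("a mesh series needs at least 2 meshes", call. = FALSE)
  if (!all(vapply(meshes, inherits, logical(1), "tri_mesh"))) {
    stop("all elements must be tri_mesh objects", call. = FALSE)
  }
  times <- as.numeric(times)
  if (length(times) != length(meshes) || any(diff(times) <= 0)) {
    stop("instance times must be strictly increasing, one per mesh", call. = FALSE)
  }
  structure(list(meshes = meshes, times = times), class = "mesh_series")
}

#' @export
print.mesh_series <- function(x, ...) {
  cat("<mesh_series>", length(x$meshes), "instances at times",
      paste(x$times, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.mesh_series <- function(x) length(x$meshes)
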