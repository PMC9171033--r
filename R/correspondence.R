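#' Local neighborhood of a mesh vertex
#'
#' The point set entering the correlation objective: all vertices within a
#' Euclidean ball of radius `r` around a center vertex, including the center.
#'
#' @param mesh a [tri_mesh()].
#' @param j center vertex index.
#' @param r radius in mm.
#' @return An object of class `mesh_neighborhood` with fields
#'   `center_index`, `indices`, `points` (k x 3 matrix) and `radius`.
#' @export
neighborhood <- function(mesh, j, r) {
  idx <- vertex_neighborhood(mesh, j, r)
  structure(list(center_index = j, indices = idx,
                 points = mesh$vertices[idx, , drop = FALSE], radius = r),
            class = "mesh_neighborhood")
}

# index of the nearest row of b for each row of a (brute force, vectorized)
nearest_indices <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  max.col(-d2, ties.method = "first")
}

#' Correlation between two vertex neighborhoods under a rigid transform
#'
#' The matching objective of the correspondence search. The source
#' neighborhood is mapped by the rigid transform; each transformed source
#' point is paired with its nearest target point (so unequal cardinalities
#' are handled); both matched lists are centered on their own centroids and
#' flattened to length-3m coordinate vectors whose Pearson correlation
#' (covariance over the product of standard deviations) is returned.
#'
#' @param q_src,q_tgt [neighborhood()] objects (at least 2 points each).
#' @param transform a [rigid_transform()] mapping source into target space.
#' @param pairing `"nearest"` (default) pairs each transformed source point
#'   with its nearest target point; `"index"` pairs points positionally and
#'   requires equal cardinalities (useful when the correspondence is known,
#'   e.g. in exact-copy or reflection constructions).
#' @return Correlation score in `[-1, 1]`.
#' @export
neighborhood_correlation <- function(q_src, q_tgt, transform,
                                     pairing = c("nearest", "index")) {
  pairing <- match.arg(pairing)
  if (nrow(q_src$points) < 2L || nrow(q_tgt$points) < 2L) {
    stop("neighborhood correlation needs at least 2 points on each side",
         call. = FALSE)
  }
  x <- transform_points(transform, q_src$points)
  y <- if (pairing == "nearest") {
    q_tgt$points[nearest_indices(x, q_tgt$points), , drop = FALSE]
  } else {
    if (nrow(q_tgt$points) != nrow(x)) {
      stop("index pairing requires equal neighborhood cardinalities", call. = FALSE)
    }
    q_tgt$points
  }
  xc <- as.vector(sweep(x, 2L, colMeans(x)))
  yc <- as.vector(sweep(y, 2L, colMeans(y)))
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) {
    stop("undefined correlation: zero variance (all points coincident)",
         call. = FALSE)
  }
  max(-1, min(1, sum(xc * yc) / (sx * sy)))
}

#' Global rigid pre-alignment of two meshes (iterative closest point)
#'
#' Rigidly registers the source mesh onto the target by iterating
#' nearest-neighbor pairing and Kabsch least-squares updates until the RMS
#' nearest-neighbor distance stops changing. This makes the local per-vertex
#' correspondence search well-posed by removing gross motion between
#' consecutive instances.
#'
#' @param source,target [tri_mesh()] objects.
#' @param max_iter maximum ICP iterations.
#' @param tol convergence tolerance on the RMS change (mm).
#' @return A [rigid_transform()] with attributes `rms` (final RMS
#'   nearest-neighbor distance, mm) and `iterations`.
#' @export
global_align <- function(source, target, max_iter = 50L, tol = 1e-9) {
  src <- source$vertices
  tgt <- target$vertices
  # initialize by centroid shift
  transform <- rigid_transform(diag(3), colMeans(tgt) - colMeans(src))
  rms <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    x <- transform_points(transform, src)
    nn <- nearest_indices(x, tgt)
    y <- tgt[nn, , drop = FALSE]
    new_rms <- sqrt(mean(rowSums((x - y)^2)))
    transform <- kabsch(src, y)
    if (abs(rms - new_rms) < tol || it >= max_iter) {
      rms <- new_rms
      break
    }
    rms <- new_rms
  }
  attr(transform, "rms") <- rms
  attr(transform, "iterations") <- it
  transform
}

#' Find the corresponding vertex on the next model for one source vertex
#'
#' Candidate centers are all target vertices within `rho` of the pre-aligned
#' source vertex position. For each candidate a local rigid transform is
#' solved under the rigid constraint that the source vertex maps exactly onto
#' the candidate (`t = c - R p_j`): the rotation about that pinned pair is
#' refined by Kabsch fits on nearest-neighbor pairings between the two
#' neighborhoods (up to 5 iterations, initialized at the pre-alignment
#' rotation), and the neighborhood correlation is scored under the resulting
#' transform. Pinning the center is what makes the score discriminate between
#' candidates: an unconstrained local fit would register the neighborhoods
#' equally well for several nearby candidates. The candidate with the highest
#' score wins; candidates within `score_tol` of the maximum count as tied and
#' the tie goes to the smaller Euclidean distance to the pre-aligned
#' position, then to the smaller index.
#'
#' @param source,target [tri_mesh()] objects.
#' @param j source vertex index.
#' @param r neighborhood radius (mm).
#' @param rho candidate search radius (mm); `Inf` searches all target
#'   vertices.
#' @param pre_align a [rigid_transform()] from [global_align()]; identity by
#'   default.
#' @param score_tol score resolution: candidates scoring within `score_tol`
#'   of the maximum are treated as tied, so the distance tie-break decides.
#'   Correlation differences below ~1e-4 are dominated by measurement noise
#'   on CBCT-scale data, and preferring the spatially nearest of the
#'   statistically indistinguishable candidates stabilizes the map.
#' @return A `vertex_match`: list with `source_index`, `target_index`,
#'   `transform`, `score`.
#' @export
match_vertex <- function(source, target, j, r, rho,
                         pre_align = rigid_transform(), score_tol = 2e-3) {
  stopifnot(r > 0, rho > 0, j >= 1L, j <= n_vertices(source), score_tol >= 0)
  res <- .cpp_match_vertices(source$vertices, target$vertices, as.integer(j),
                             r, rho, pre_align$rotation, pre_align$translation,
                             5L, score_tol, integer(0),
                             matrix(numeric(0), 0L, 3L))
  if (res[1, 1] < 0) {
    stop(structure(class = c("osteomap_no_candidate", "error", "condition"),
                   list(message = sprintf(
                     "no candidate target vertex within rho = %g mm of source vertex %d (enlarge rho)",
                     rho, j), call = NULL)))
  }
  structure(list(source_index = as.integer(j),
                 target_index = as.integer(res[1, 1]),
                 transform = rigid_transform(
                   matrix(res[1, 3:11], 3L, 3L, byrow = TRUE),
                   res[1, 12:14]),
                 score = res[1, 2]),
            class = "vertex_match")
}

#' Full vertex correspondence between two consecutive models
#'
#' Runs [global_align()] once, then the per-vertex candidate search for every
#' source vertex, with score ties broken by distance to a locally predicted
#' position: the pre-aligned position plus the mean nearest-neighbor
#' displacement of the vertex's mesh neighbors. The prediction acts as a
#' smoothness prior on the displacement field, which disambiguates candidates
#' that the correlation cannot separate at the noise level. Deterministic
#' given its inputs. The returned map is a tibble-backed object
#' with one row per source vertex carrying the matched index, the correlation
#' score and the local rigid transform (rotation entries `r00..r22`,
#' translation `t0..t2`).
#'
#' @param source,target [tri_mesh()] objects.
#' @param params a [correspondence_params()] list; `r` and `rho` default to
#'   5 and 3 times the mean source edge length.
#' @param verbose print a summary of the score distribution.
#' @return A `correspondence_map` tibble.
#' @export
build_correspondence <- function(source, target,
                                 params = correspondence_params(),
                                 verbose = FALSE) {
  mel <- mean_edge_length(source)
  r <- params$r %||% (5 * mel)
  rho <- params$rho %||% (3 * mel)
  pre <- global_align(source, target, max_iter = params$icp_max_iter,
                      tol = params$icp_tol)
  n <- n_vertices(source)
  score_tol <- params$score_tol %||% 2e-3
  pred <- predicted_positions(source, target, pre)
  res <- .cpp_match_vertices(source$vertices, target$vertices, seq_len(n),
                             r, rho, pre$rotation, pre$translation, 5L,
                             score_tol, integer(0), pred)
  missing <- which(res[, 1] < 0)
  if (length(missing)) {
    stop("no candidate target vertex within rho = ", signif(rho, 4),
         " mm for source vertices: ",
         paste(utils::head(missing, 5), collapse = ", "),
         " (enlarge rho)", call. = FALSE)
  }
  if (isTRUE(params$unique %||% TRUE) && n <= n_vertices(target)) {
    res <- resolve_duplicate_targets(res, source, target, r, rho, pre,
                                     score_tol, pred)
  }
  out <- res[, c(1, 1:14), drop = FALSE]
  out[, 1] <- seq_len(n)
  colnames(out) <- c("source_index", "target_index", "score",
                     "r00", "r01", "r02", "r10", "r11", "r12",
                     "r20", "r21", "r22", "t0", "t1", "t2")
  map <- tibble::as_tibble(out)
  map$source_index <- as.integer(map$source_index)
  map$target_index <- as.integer(map$target_index)
  if (verbose) {
    q <- stats::quantile(map$score, c(0, .25, .5, .75, 1))
    message(sprintf("correspondence scores: min %.4f / q25 %.4f / median %.4f / q75 %.4f / max %.4f",
                    q[1], q[2], q[3], q[4], q[5]))
  }
  new_correspondence_map(map,
                         source_label = source$instance_label,
                         target_label = target$instance_label,
                         pre_align = pre, r = r, rho = rho)
}

# Similarity (rotation + translation + isotropic scale) ICP, Umeyama
# updates. Used only to build the tie-break prediction: growth between
# instances has a large near-uniform scale component that a rigid fit leaves
# as a radial residual, which would bias nearest-neighbor displacement
# estimates. The matching itself remains rigid.
similarity_align <- function(src, tgt, pre, max_iter = 30L, tol = 1e-10) {
  R <- pre$rotation
  s <- 1
  t <- pre$translation
  for (it in seq_len(max_iter)) {
    x <- sweep(s * (src %*% t(R)), 2L, t, "+")
    y <- tgt[nearest_indices(x, tgt), , drop = FALSE]
    cx <- colMeans(src)
    cy <- colMeans(y)
    xc <- sweep(src, 2L, cx)
    yc <- sweep(y, 2L, cy)
    sv <- svd(crossprod(xc, yc))
    d <- sign(det(sv$v %*% t(sv$u)))
    if (d == 0) d <- 1
    Rn <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    sn <- sum(sv$d * c(1, 1, d)) / sum(xc^2)
    tn <- cy - sn * as.numeric(Rn %*% cx)
    delta <- max(abs(Rn - R), abs(sn - s), abs(tn - t))
    R <- Rn
    s <- sn
    t <- tn
    if (delta < tol) break
  }
  sweep(s * (src %*% t(R)), 2L, t, "+")
}

# Predicted target-space position per source vertex: the similarity-aligned
# position corrected by the mean nearest-neighbor displacement of the
# vertex's mesh neighbors (a smoothness prior used only for tie-breaking).
predicted_positions <- function(source, target, pre) {
  p0 <- similarity_align(source$vertices, target$vertices, pre)
  nn <- nearest_indices(p0, target$vertices)
  disp <- target$vertices[nn, , drop = FALSE] - p0
  e <- mesh_edges(source)
  n <- nrow(p0)
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = n)
  acc <- rowsum(rbind(disp[e[, 2], , drop = FALSE],
                      disp[e[, 1], , drop = FALSE]),
                c(e[, 1], e[, 2]))
  sm <- matrix(0, n, 3L)
  sm[as.integer(rownames(acc)), ] <- acc
  deg[deg == 0] <- 1
  p0 + sm / deg
}

# Make the map injective: when several source vertices claim one target, the
# claimant with the higher score (then smaller distance to its pre-aligned
# position, then smaller index) keeps it; the others are re-matched with all
# claimed targets excluded. Displaced vertices whose remaining candidates are
# exhausted keep their duplicate claim (a non-injective map is preferable to
# a failure). Deterministic.
resolve_duplicate_targets <- function(res, source, target, r, rho, pre,
                                      score_tol, pred) {
  n <- nrow(res)
  p0 <- pred
  dist0 <- sqrt(rowSums((p0 - target$vertices[res[, 1], , drop = FALSE])^2))
  for (sweep in 1:20) {
    dup_targets <- unique(res[duplicated(res[, 1]), 1])
    if (length(dup_targets) == 0L) break
    taken <- res[, 1]
    displaced <- integer(0)
    for (tgt_idx in dup_targets) {
      claimants <- which(res[, 1] == tgt_idx)
      ord <- order(-res[claimants, 2], dist0[claimants], claimants)
      displaced <- c(displaced, claimants[ord][-1])
    }
    for (j in sort(displaced)) {
      newres <- .cpp_match_vertices(source$vertices, target$vertices,
                                    as.integer(j), r, rho, pre$rotation,
                                    pre$translation, 5L, score_tol,
                                    as.integer(unique(taken)), pred)
      if (newres[1, 1] < 0) {
        # all candidates in the search ball are claimed: enlarge the ball
        newres <- .cpp_match_vertices(source$vertices, target$vertices,
                                      as.integer(j), r, 2 * rho, pre$rotation,
                                      pre$translation, 5L, score_tol,
                                      as.integer(unique(taken)), pred)
      }
      if (newres[1, 1] < 0) next        # exhausted: keep the duplicate claim
      res[j, ] <- newres[1, ]
      dist0[j] <- sqrt(sum((p0[j, ] - target$vertices[res[j, 1], ])^2))
      taken <- c(taken, res[j, 1])
    }
    if (length(displaced) == 0L) break
  }
  if (anyDuplicated(res[, 1])) {
    warning("correspondence map is not one-to-one: ",
            sum(duplicated(res[, 1])), " duplicated target vertices remain",
            call. = FALSE)
  }
  res
}

new_correspondence_map <- function(tbl, source_label = NULL, target_label = NULL,
                                   pre_align = NULL, r = NA_real_, rho = NA_real_) {
  structure(tbl,
            class = c("correspondence_map", class(tbl)),
            source_label = source_label, target_label = target_label,
            pre_align = pre_align, r = r, rho = rho)
}

#' @export
print.correspondence_map <- function(x, ...) {
  cat("<correspondence_map>",
      attr(x, "source_label") %||% "?", "->", attr(x, "target_label") %||% "?",
      sprintf("(%d vertices, median score %.4f)\n",
              nrow(x), stats::median(x$score)))
  NextMethod()
}

#' Default parameters of the correspondence search
#'
#' @param r neighborhood radius (mm); `NULL` means 5 x mean source edge
#'   length. The radius must span several vertex rings for the correlation to
#'   be discriminative.
#' @param rho candidate search radius after pre-alignment (mm); `NULL` means
#'   3 x mean source edge length.
#' @param icp_max_iter,icp_tol iterative-closest-point settings for the
#'   global pre-alignment.
#' @param score_tol tie tolerance on the correlation score, see
#'   [match_vertex()].
#' @param unique enforce a one-to-one map: when several source vertices claim
#'   the same target vertex, the best-scoring claimant keeps it and the
#'   others are re-matched among the remaining candidates. Keeps tracked
#'   edges from collapsing to zero length when consecutive models are
#'   chained.
#' @return A named list.
#' @export
correspondence_params <- function(r = NULL, rho = NULL, icp_max_iter = 50L,
                                  icp_tol = 1e-9, score_tol = 2e-3,
                                  unique = TRUE) {
  list(r = r, rho = rho, icp_max_iter = icp_max_iter, icp_tol = icp_tol,
       score_tol = score_tol, unique = unique)
}

#' Chain correspondence maps across a series
#'
#' Composes consecutive maps (T1 -> T2, T2 -> T3, ...) into a single map
#' T1 -> Tk by following matched indices. Local transforms compose; the
#' reported score of a chained match is the minimum score along its path
#' (the weakest link).
#'
#' @param maps list of `correspondence_map` objects in chain order.
#' @return A `correspondence_map` from the first source to the last target.
#' @export
compose_correspondence <- function(maps) {
  if (length(maps) < 1L) stop("no maps to compose", call. = FALSE)
  for (k in seq_along(maps)[-1]) {
    tl <- attr(maps[[k - 1]], "target_label")
    sl <- attr(maps[[k]], "source_label")
    if (!is.null(tl) && !is.null(sl) && !identical(tl, sl)) {
      stop("chain mismatch: map ", k - 1, " targets '", tl,
           "' but map ", k, " sources '", sl, "'", call. = FALSE)
    }
    if (max(maps[[k - 1]]$target_index) > nrow(maps[[k]])) {
      stop("chain mismatch: map ", k - 1, " targets ",
           max(maps[[k - 1]]$target_index), " vertices but map ", k,
           " has only ", nrow(maps[[k]]), " source vertices", call. = FALSE)
    }
  }
  idx <- maps[[1]]$target_index
  score <- maps[[1]]$score
  rot <- map_rotations(maps[[1]])
  trans <- as.matrix(maps[[1]][, c("t0", "t1", "t2")])
  for (k in seq_along(maps)[-1]) {
    mk <- maps[[k]]
    rk <- map_rotations(mk)
    tk <- as.matrix(mk[, c("t0", "t1", "t2")])
    for (j in seq_along(idx)) {
      i2 <- idx[j]
      R2 <- matrix(rk[i2, ], 3, 3, byrow = TRUE)
      R1 <- matrix(rot[j, ], 3, 3, byrow = TRUE)
      rot[j, ] <- as.vector(t(R2 %*% R1))
      trans[j, ] <- as.numeric(R2 %*% trans[j, ]) + tk[i2, ]
    }
    score <- pmin(score, mk$score[idx])
    idx <- mk$target_index[idx]
  }
  out <- tibble::tibble(source_index = maps[[1]]$source_index,
                        target_index = as.integer(idx), score = score)
  out <- cbind(out, as.data.frame(rot), as.data.frame(trans))
  colnames(out) <- c("source_index", "target_index", "score",
                     "r00", "r01", "r02", "r10", "r11", "r12",
                     "r20", "r21", "r22", "t0", "t1", "t2")
  new_correspondence_map(tibble::as_tibble(out),
                         source_label = attr(maps[[1]], "source_label"),
                         target_label = attr(maps[[length(maps)]], "target_label"))
}

map_rotations <- function(map) {
  as.matrix(map[, c("r00", "r01", "r02", "r10", "r11", "r12",
                    "r20", "r21", "r22")])
}

#' Read/write a correspondence map as CSV
#'
#' Columns: `source_index`, `target_index`, `score`, rotation entries
#' `r00..r22` (row-major), translation `t0..t2`.
#'
#' @param map a `correspondence_map`.
#' @param path CSV path.
#' @return `write_correspondence`: `path` invisibly; `read_correspondence`:
#'   a `correspondence_map`.
#' @export
write_correspondence <- function(map, path) {
  readr::write_csv(tibble::as_tibble(map), path)
  invisible(path)
}

#' @rdname write_correspondence
#' @export
read_correspondence <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  tbl$source_index <- as.integer(tbl$source_index)
  tbl$target_index <- as.integer(tbl$target_index)
  new_correspondence_map(tbl)
}
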