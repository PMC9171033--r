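#' Named anatomical landmark sets
#'
#' A landmark set is a tibble with columns `name`, `x`, `y`, `z` (mm). The
#' mandibular convention uses 17 landmarks: the bilateral lateral/medial
#' condylar poles (`Cd-lat`, `Cd-med`), coronoid process (`Cr`), gonion
#' (`Go`), three mental foramina (`MF1`-`MF3`) and genial fovea (`GF`), each
#' carried with a side prefix (`L_`/`R_`), plus the midline genial tubercle
#' (`GT`). Names must be unique and coordinates finite.
#'
#' @param names character vector of unique landmark names.
#' @param coords n x 3 numeric matrix (mm).
#' @return A `landmark_set` tibble.
#' @export
landmark_set <- function(names, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  if (anyDuplicated(names)) {
    stop("duplicate landmark names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "), call. = FALSE)
  }
  if (length(names) != nrow(coords)) stop("one coordinate row per name", call. = FALSE)
  if (any(!is.finite(coords))) stop("non-finite landmark coordinates", call. = FALSE)
  out <- tibble::tibble(name = as.character(names),
                        x = coords[, 1], y = coords[, 2], z = coords[, 3])
  structure(out, class = c("landmark_set", class(out)))
}

#' The 17 canonical mandibular landmark names
#'
#' @return Character vector of length 17.
#' @export
mandible_landmark_names <- function() {
  bilateral <- c("Cd-lat", "Cd-med", "Cr", "Go", "MF1", "MF2", "MF3", "GF")
  c(paste0("L_", bilateral), paste0("R_", bilateral), "GT")
}

#' Read or write landmarks as CSV
#'
#' CSV columns `name,x,y,z`; the round trip is exact to 1e-9 mm.
#'
#' @param path CSV path.
#' @return A `landmark_set`.
#' @export
read_landmarks <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("name", "x", "y", "z") %in% names(tbl))) {
    stop("landmark CSV must have columns name,x,y,z", call. = FALSE)
  }
  landmark_set(tbl$name, as.matrix(tbl[, c("x", "y", "z")]))
}

#' @rdname read_landmarks
#' @param landmarks a `landmark_set`.
#' @return `write_landmarks`: `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  readr::write_csv(tibble::as_tibble(landmarks), path)
  invisible(path)
}

landmark_coords <- function(landmarks, name) {
  i <- match(name, landmarks$name)
  if (is.na(i)) stop("missing required landmark: ", name, call. = FALSE)
  c(landmarks$x[i], landmarks$y[i], landmarks$z[i])
}

#' Anatomical coordinate frame
#'
#' Orthonormal right-handed axes for the anterior/posterior (AP),
#' superior/inferior (SI) and medial/lateral (ML) directions, plus an origin.
#' Direction components of growth rates are expressed in this frame.
#'
#' @param origin length-3 origin (mm).
#' @param ap,si,ml unit axis vectors; must be pairwise orthogonal within
#'   1e-9 and right-handed.
#' @return An `anatomical_frame` object.
#' @export
anatomical_frame <- function(origin = c(0, 0, 0), ap = c(1, 0, 0),
                             si = c(0, 1, 0), ml = c(0, 0, 1)) {
  A <- cbind(as.numeric(ap), as.numeric(si), as.numeric(ml))
  if (max(abs(crossprod(A) - diag(3))) > 1e-9) {
    stop("frame axes must be orthonormal", call. = FALSE)
  }
  if (det(A) < 0) stop("frame axes must be right-handed", call. = FALSE)
  structure(list(origin = as.numeric(origin), ap = A[, 1], si = A[, 2],
                 ml = A[, 3]), class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("<anatomical_frame> origin", paste(signif(x$origin, 6), collapse = " "), "\n")
  cat("  AP:", paste(signif(x$ap, 6), collapse = " "), "\n")
  cat("  SI:", paste(signif(x$si, 6), collapse = " "), "\n")
  cat("  ML:", paste(signif(x$ml, 6), collapse = " "), "\n")
  invisible(x)
}

#' Build the anatomical frame from mandibular landmarks
#'
#' ML is the unit vector from the right to the left lateral condylar pole;
#' AP is the direction from the gonion midpoint to the genial tubercle,
#' orthogonalized against ML; SI completes the right-handed triad
#' (`SI = ML x AP`). The origin is the gonion midpoint. Requires `L_Cd-lat`,
#' `R_Cd-lat`, `L_Go`, `R_Go` and `GT`.
#'
#' @param landmarks a [landmark_set()].
#' @return An [anatomical_frame()].
#' @export
build_frame <- function(landmarks) {
  cdl_l <- landmark_coords(landmarks, "L_Cd-lat")
  cdl_r <- landmark_coords(landmarks, "R_Cd-lat")
  go_l <- landmark_coords(landmarks, "L_Go")
  go_r <- landmark_coords(landmarks, "R_Go")
  gt <- landmark_coords(landmarks, "GT")
  ml <- cdl_l - cdl_r
  if (sqrt(sum(ml^2)) < 1e-9) stop("degenerate frame: condylar poles coincide",
                                   call. = FALSE)
  ml <- ml / sqrt(sum(ml^2))
  origin <- (go_l + go_r) / 2
  ap <- gt - origin
  ap <- ap - sum(ap * ml) * ml
  nap <- sqrt(sum(ap^2))
  if (nap < 1e-9) {
    stop("degenerate frame: GT, gonion midpoint and ML axis are collinear",
         call. = FALSE)
  }
  ap <- ap / nap
  si <- c(ml[2] * ap[3] - ml[3] * ap[2],
          ml[3] * ap[1] - ml[1] * ap[3],
          ml[1] * ap[2] - ml[2] * ap[1])
  anatomical_frame(origin, ap, si, ml)
}

#' Region labels over mesh vertices
#'
#' A partition of the vertex set into the six mandibular regions: condyle,
#' posterior ramus, anterior ramus, posterior corpus, middle corpus, anterior
#' corpus. Labels are an input (regions are drawn manually or emitted by the
#' synthetic generator), never computed from geometry here.
#'
#' @param labels character vector, one region label per vertex.
#' @return A `region_labels` tibble with columns `vertex_index`, `label`.
#' @export
region_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), mandible_region_names())
  if (length(bad)) {
    stop("unknown region labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(vertex_index = seq_along(labels), label = labels)
  structure(out, class = c("region_labels", class(out)))
}

#' @rdname region_labels
#' @export
mandible_region_names <- function() {
  c("condyle", "posterior_ramus", "anterior_ramus",
    "posterior_corpus", "middle_corpus", "anterior_corpus")
}

#' @rdname region_labels
#' @param path CSV path with columns `vertex_index,label`.
#' @export
read_region_labels <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("vertex_index", "label") %in% names(tbl))) {
    stop("region label CSV must have columns vertex_index,label", call. = FALSE)
  }
  tbl <- tbl[order(tbl$vertex_index), ]
  if (!identical(as.integer(tbl$vertex_index), seq_len(nrow(tbl)))) {
    stop("vertex_index must enumerate 1..n exactly once (a partition)",
         call. = FALSE)
  }
  region_labels(tbl$label)
}

#' @rdname region_labels
#' @param x a `region_labels` object.
#' @export
write_region_labels <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Regional means and SDs of growth rates
#'
#' Per region, instance and direction (total and the A/P, S/I, M/L
#' components), the mean and standard deviation of the per-vertex rates over
#' the region's member vertices. The labels must partition the vertex set of
#' the field.
#'
#' @param field a `growth_field` from [growth_field()].
#' @param labels a [region_labels()] object with one label per field vertex.
#' @return A `region_summary` tibble: `region`, `instance`, `time`,
#'   `direction`, `mean`, `sd`, `n_vertices`.
#' @export
region_summary <- function(field, labels) {
  n <- attr(field, "n_vertices") %||% max(field$vertex_index)
  if (nrow(labels) != n) {
    stop("labels cover ", nrow(labels), " vertices but the field has ", n,
         call. = FALSE)
  }
  long <- tidyr::pivot_longer(tibble::as_tibble(field),
                              cols = c("rate", "ap", "si", "ml"),
                              names_to = "direction", values_to = "value")
  long$direction <- ifelse(long$direction == "rate", "total", long$direction)
  long$region <- labels$label[long$vertex_index]
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$region, .data$instance, .data$time,
                    .data$direction),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    n_vertices = dplyr::n_distinct(.data$vertex_index),
    .groups = "drop"
  )
  structure(out, class = c("region_summary", class(out)))
}

#' Mean regional bone thickness by normal ray casting
#'
#' For each vertex of the region a ray is cast along the inward vertex normal
#' and the distance to its first intersection with the opposing surface is
#' taken as the local thickness. Vertices whose ray finds no intersection
#' within `cutoff` are skipped; the hit fraction is reported and a warning is
#' raised when fewer than half the rays hit.
#'
#' @param mesh a [tri_mesh()].
#' @param labels a [region_labels()] object (or `NULL` to use all vertices).
#' @param region region name; ignored when `labels` is `NULL`.
#' @param cutoff maximum ray length in mm.
#' @return A one-row tibble: `region`, `mean_thickness`, `sd_thickness`,
#'   `n_vertices`, `hit_fraction`.
#' @export
region_thickness <- function(mesh, labels = NULL, region = NULL, cutoff = 30) {
  if (is.null(labels)) {
    idx <- seq_len(n_vertices(mesh))
    region <- region %||% "all"
  } else {
    stopifnot(!is.null(region))
    idx <- labels$vertex_index[labels$label == region]
    if (length(idx) == 0L) stop("empty region: ", region, call. = FALSE)
  }
  normals <- vertex_normals(mesh)
  hits <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    v <- idx[k]
    hits[k] <- ray_mesh_distance(mesh, mesh$vertices[v, ], -normals[v, ],
                                 t_min = 1e-6, t_max = cutoff)
  }
  hit_fraction <- mean(!is.na(hits))
  if (hit_fraction < 0.5) {
    warning(sprintf("thickness rays for region '%s': only %.0f%% hit within %g mm",
                    region, 100 * hit_fraction, cutoff), call. = FALSE)
  }
  tibble::tibble(region = region,
                 mean_thickness = mean(hits, na.rm = TRUE),
                 sd_thickness = stats::sd(hits, na.rm = TRUE),
                 n_vertices = length(idx),
                 hit_fraction = hit_fraction)
}

# distance along ray (origin o, unit direction d) to the first triangle
# intersection with t in (t_min, t_max]; NA if none (Moller-Trumbore)
ray_mesh_distance <- function(mesh, o, d, t_min = 1e-6, t_max = Inf) {
  v <- mesh$vertices
  f <- mesh$faces
  p0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - p0
  e2 <- v[f[, 3], , drop = FALSE] - p0
  # h = d x e2
  h <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
             d[3] * e2[, 1] - d[1] * e2[, 3],
             d[1] * e2[, 2] - d[2] * e2[, 1])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  s <- sweep(-p0, 2L, o, "+")              # o - p0
  u <- rowSums(s * h) / a
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  vv <- (q[, 1] * d[1] + q[, 2] * d[2] + q[, 3] * d[3]) / a
  t <- rowSums(e2 * q) / a
  hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 &
    t > t_min & t <= t_max
  if (!any(hit)) return(NA_real_)
  min(t[hit])
}

#' Mediolateral width of the condylar head
#'
#' Euclidean distance between the lateral and medial condylar poles of the
#' requested side; rigid-motion invariant.
#'
#' @param landmarks a [landmark_set()].
#' @param side `"L"` or `"R"`.
#' @return Width in mm.
#' @export
condylar_width <- function(landmarks, side = c("L", "R")) {
  side <- match.arg(side)
  a <- landmark_coords(landmarks, paste0(side, "_Cd-lat"))
  b <- landmark_coords(landmarks, paste0(side, "_Cd-med"))
  sqrt(sum((a - b)^2))
}
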