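#' Rigid transforms in 3D
#'
#' A rigid (proper orthogonal) transform maps a point `p` to `R %*% p + v`,
#' where `R` is a 3x3 rotation matrix (orthonormal, det = +1) and `v` a
#' translation vector in mm. These are the building blocks of both the global
#' pre-alignment between consecutive bone models and the local per-vertex
#' refinements of the correspondence search.
#'
#' @param rotation 3x3 rotation matrix, orthonormal with determinant +1.
#' @param translation numeric length-3 translation vector (mm).
#' @return An object of class `rigid_transform`.
#' @examples
#' T0 <- rigid_transform(diag(3), c(0, 0, 0))
#' is_identity_transform(T0)
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L) {
    stop("rigid_transform needs a 3x3 rotation and a length-3 translation",
         call. = FALSE)
  }
  check_rotation(rotation)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

check_rotation <- function(R, tol = 1e-9) {
  if (any(!is.finite(R))) stop("rotation matrix has non-finite entries", call. = FALSE)
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    stop("rotation matrix is not orthonormal (R'R != I within ", tol, ")",
         call. = FALSE)
  }
  if (abs(det(R) - 1) > tol) {
    stop("rotation matrix determinant is ", format(det(R)),
         ", not +1: reflections are not rigid motions", call. = FALSE)
  }
  invisible(R)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(signif(x$rotation, 6))
  cat("translation:", paste(signif(x$translation, 6), collapse = " "), "mm\n")
  invisible(x)
}

#' Apply a rigid transform to a matrix of points
#'
#' @param transform a [rigid_transform()].
#' @param points n x 3 numeric matrix of positions (mm).
#' @return n x 3 matrix of transformed positions.
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  points <- matrix(as.numeric(points), ncol = 3L)
  sweep(points %*% t(transform$rotation), 2L, transform$translation, "+")
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` first and then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% transform$translation))
}

#' Is a transform (numerically) the identity?
#'
#' @param transform a [rigid_transform()].
#' @param tol absolute tolerance.
#' @return Logical scalar.
#' @export
is_identity_transform <- function(transform, tol = 1e-9) {
  max(abs(transform$rotation - diag(3))) <= tol &&
    max(abs(transform$translation)) <= tol
}

#' Least-squares rigid fit between paired point sets (Kabsch)
#'
#' Finds the rotation and translation minimizing the sum of squared distances
#' `sum(|R x_i + v - y_i|^2)` over paired points. The rotation is obtained
#' from the SVD of the cross-covariance with the usual determinant correction
#' so that a proper rotation (no reflection) is always returned.
#'
#' @param x,y n x 3 matrices of paired points (same n, row i of `x`
#'   corresponds to row i of `y`).
#' @param weights optional non-negative weights of length n.
#' @return A [rigid_transform()] mapping `x` onto `y` in the least-squares
#'   sense.
#' @export
kabsch <- function(x, y, weights = NULL) {
  x <- matrix(as.numeric(x), ncol = 3L)
  y <- matrix(as.numeric(y), ncol = 3L)
  if (nrow(x) != nrow(y)) stop("paired point sets must have equal size", call. = FALSE)
  if (nrow(x) < 3L) stop("rigid fit needs at least 3 paired points", call. = FALSE)
  w <- if (is.null(weights)) rep(1, nrow(x)) else as.numeric(weights)
  w <- w / sum(w)
  cx <- colSums(x * w)
  cy <- colSums(y * w)
  xc <- sweep(x, 2L, cx)
  yc <- sweep(y, 2L, cy)
  H <- crossprod(xc * w, yc)
  if (!all(is.finite(H))) stop("non-finite values in rigid fit", call. = FALSE)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  # degenerate (collinear/coincident) configurations leave the rotation
  # underdetermined; detect via the singular value spectrum
  if (sv$d[2] <= 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate point configuration: rigid fit is underdetermined",
         call. = FALSE)
  }
  rigid_transform(R, cy - as.numeric(R %*% cx))
}
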