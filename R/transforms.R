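#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation (stored as a unit quaternion)
#' followed by a translation, `x -> R x + t`. These are the only degrees of
#' freedom explored during shape superposition: conformers stay internally
#' rigid throughout.
#'
#' @param quaternion Numeric length-4 `(w, x, y, z)`; normalised on
#'   construction.
#' @param translation Numeric length-3 translation in Angstroms.
#' @return An object of class `rigid_transform`.
#' @examples
#' rigid_transform(c(1, 0, 0, 0), c(1, 2, 3))
#' @export
rigid_transform <- function(quaternion = c(1, 0, 0, 0),
                            translation = c(0, 0, 0)) {
  q <- as.numeric(quaternion)
  t <- as.numeric(translation)
  stopifnot(length(q) == 4, length(t) == 3, all(is.finite(q)), all(is.finite(t)))
  nrm <- sqrt(sum(q^2))
  if (nrm < 1e-12) stop("quaternion has (near-)zero norm")
  q <- q / nrm
  structure(list(q = q, t = t), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rigid_identity <- function() rigid_transform()

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("  quaternion:", format(x$q, digits = 6), "\n")
  cat("  translation (A):", format(x$t, digits = 6), "\n")
  invisible(x)
}

#' Rotation matrix of a rigid transform
#'
#' @param transform A `rigid_transform`.
#' @return 3x3 proper rotation matrix (det = +1).
#' @export
rotation_matrix <- function(transform) {
  q <- transform$q
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Apply a rigid transform to 3D points
#'
#' @param transform A `rigid_transform`.
#' @param points An n x 3 numeric matrix of coordinates (Angstroms).
#' @return The transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 3)
  R <- rotation_matrix(transform)
  sweep(pts %*% t(R), 2, transform$t, `+`)
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` first and `a` second; `invert_transform(a)` returns the inverse.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  q <- quat_multiply(a$q, b$q)
  Ra <- rotation_matrix(a)
  rigid_transform(q, as.numeric(Ra %*% b$t) + a$t)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(a) {
  qi <- c(a$q[1], -a$q[2:4])
  Ri <- t(rotation_matrix(a))
  rigid_transform(qi, as.numeric(-Ri %*% a$t))
}

quat_multiply <- function(p, q) {
  c(p[1] * q[1] - sum(p[2:4] * q[2:4]),
    p[1] * q[2:4] + q[1] * p[2:4] + c(
      p[3] * q[4] - p[4] * q[3],
      p[4] * q[2] - p[2] * q[4],
      p[2] * q[3] - p[3] * q[2]
    ))
}

# exponential map: rotation vector (axis * angle, radians) -> unit quaternion
quat_from_rotvec <- function(w) {
  theta <- sqrt(sum(w^2))
  if (theta < 1e-12) return(c(1, 0, 0, 0))
  c(cos(theta / 2), sin(theta / 2) * w / theta)
}

quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

# Shoemake's method: uniform random unit quaternion from three U(0,1) draws
random_unit_quaternion <- function() {
  u <- stats::runif(3)
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3]))
}
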