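#' Construct a rigid transform
#'
#' A rotation `R` (3x3, orthonormal, det +1) and translation `t` (mm) mapping
#' points as `p -> R p + t`.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (mm).
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  if (!all(dim(R) == c(3L, 3L)) || length(t) != 3L) {
    stop("rigid transform needs a 3x3 R and length-3 t")
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
    stop("R must be a proper rotation (orthonormal, det +1)")
  }
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' Apply a rigid transform to points or a mesh
#'
#' @param x an `n x 3` point matrix or a `triangle_mesh`.
#' @param transform a `rigid_transform`.
#' @return object of the same kind as `x`, transformed.
#' @export
apply_rigid <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is_triangle_mesh(x)) {
    x$vertices <- apply_rigid(x$vertices, transform)
    return(x)
  }
  x <- as.matrix(x)
  sweep(x %*% t(transform$R), 2, transform$t, "+")
}

#' Compose two rigid transforms (`second` after `first`)
#' @param second,first `rigid_transform` objects.
#' @export
compose_rigid <- function(second, first) {
  rigid_transform(second$R %*% first$R,
                  as.numeric(second$R %*% first$t) + second$t)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @export
invert_rigid <- function(transform) {
  rigid_transform(t(transform$R), -as.numeric(t(transform$R) %*% transform$t))
}

#' Rotation matrix about an axis
#' @param axis length-3 axis (normalised internally).
#' @param angle_deg rotation angle in degrees.
#' @export
rotation_about <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Geodesic angle between two rotations (degrees)
#' @param R1,R2 3x3 rotation matrices.
#' @export
rotation_angle_between <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}
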