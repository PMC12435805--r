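# Small vector/rotation helpers shared across the geometry modules.
# All coordinates are in Angstroms; all public angles are in degrees.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("zero-length vector has no direction", call. = FALSE)
  v / n
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

#' Angle between two vectors, in degrees
#'
#' The cosine is clamped to \[-1, 1\] before `acos()` so that numerically
#' parallel vectors return exactly 0 or 180 degrees.
#' @param u,v numeric 3-vectors.
#' @return angle in degrees in \[0, 180\].
#' @keywords internal
angle_between <- function(u, v) {
  nu <- vec_norm(u); nv <- vec_norm(v)
  if (nu == 0 || nv == 0) stop("angle undefined for zero-length vector", call. = FALSE)
  cosv <- sum(u * v) / (nu * nv)
  deg(acos(max(-1, min(1, cosv))))
}

# Rodrigues rotation matrix about a (unit) axis by theta degrees.
rotation_about_axis <- function(axis, theta_deg) {
  a <- unit_vec(axis)
  th <- rad(theta_deg)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# A deterministic unit vector perpendicular to v: cross v with the basis
# vector least aligned with it.
perpendicular_unit <- function(v) {
  d <- unit_vec(v)
  e <- diag(3)[, which.min(abs(d))]
  unit_vec(c(d[2] * e[3] - d[3] * e[2],
             d[3] * e[1] - d[1] * e[3],
             d[1] * e[2] - d[2] * e[1]))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Root-mean-square deviation between two n x 3 coordinate matrices.
rmsd_xyz <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}
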