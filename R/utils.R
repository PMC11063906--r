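# Small geometry helpers shared across modules. Coordinates are in
# angstroms, angles in degrees, throughout the package.

vec_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vec_norm <- function(a) sqrt(sum(a * a))

unit_vec <- function(a) {
  n <- vec_norm(a)
  if (n < 1e-12) abort("cannot normalise a zero-length vector")
  a / n
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg <- function(x) x * 180 / pi
rad <- function(x) x * pi / 180

# Wrap an angle in degrees into (-180, 180].
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

#' Signed dihedral angle of four points
#'
#' Computes the torsion angle about the p2--p3 axis with the IUPAC sign
#' convention (clockwise positive when viewed from p2 towards p3).
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (angstroms).
#' @return Angle in degrees in (-180, 180].
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(-1, 0, 1))
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vec_cross(b1, b2)
  n2 <- vec_cross(b2, b3)
  m1 <- vec_cross(n1, b2 / vec_norm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(deg(atan2(y, x)))
}

# Angle a-b-c at vertex b, degrees in [0, 180].
vertex_angle <- function(a, b, c) {
  u <- unit_vec(a - b)
  v <- unit_vec(c - b)
  deg(acos(clamp(sum(u * v), -1, 1)))
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation matrix for `angle` degrees about `axis` (normalised
#' internally). Handy for building test transforms with known ground truth.
#'
#' @param angle Rotation angle in degrees.
#' @param axis Numeric 3-vector; need not be unit length.
#' @return A 3 x 3 proper rotation matrix.
#' @examples
#' rotation_angle(rotation_about_axis(25, c(0, 0, 1)))
#' @export
rotation_about_axis <- function(angle, axis) {
  k <- unit_vec(axis)
  th <- rad(angle)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# N x 3 coordinate matrix from an atom table (or pass a matrix through).
coord_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) abort("coordinate matrix must have 3 columns")
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    need <- c("x", "y", "z")
    if (!all(need %in% names(x))) {
      abort("atom table must have columns x, y, z")
    }
    return(cbind(x = x$x, y = x$y, z = x$z))
  }
  abort("expected an atom table or an N x 3 matrix")
}

# Minimum pairwise distance between two coordinate sets, chunked so that
# full asymmetric-unit chains never allocate an n_a x n_b matrix at once.
min_pair_distance <- function(xa, xb, chunk = 2000L) {
  best <- Inf
  nb2 <- rowSums(xb^2)
  for (i in seq(1L, nrow(xa), by = chunk)) {
    idx <- i:min(i + chunk - 1L, nrow(xa))
    a <- xa[idx, , drop = FALSE]
    d2 <- outer(rowSums(a^2), nb2, "+") - 2 * (a %*% t(xb))
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

# All index pairs with distance <= cutoff, again chunked.
pairs_within <- function(xa, xb, cutoff, chunk = 2000L) {
  out <- vector("list", 0L)
  nb2 <- rowSums(xb^2)
  cut2 <- cutoff^2
  for (i in seq(1L, nrow(xa), by = chunk)) {
    idx <- i:min(i + chunk - 1L, nrow(xa))
    a <- xa[idx, , drop = FALSE]
    d2 <- outer(rowSums(a^2), nb2, "+") - 2 * (a %*% t(xb))
    hit <- which(d2 <= cut2, arr.ind = TRUE)
    if (nrow(hit)) {
      out[[length(out) + 1L]] <- cbind(i = idx[hit[, 1L]], j = hit[, 2L],
                                       d = sqrt(pmax(d2[hit], 0)))
    }
  }
  if (!length(out)) {
    return(matrix(numeric(0), ncol = 3L, dimnames = list(NULL, c("i", "j", "d"))))
  }
  do.call(rbind, out)
}
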