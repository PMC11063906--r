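# Independent oracles used to cross-check the package's own numerics.
# These deliberately use different algorithms from the implementation.

# Horn's closed-form quaternion method for least-squares superposition:
# largest eigenvalue of the 4x4 key matrix gives the optimal rotation and
# the residual directly, with no SVD involved.
quaternion_fit_oracle <- function(moving, fixed) {
  P <- sweep(moving, 2, colMeans(moving))
  Q <- sweep(fixed, 2, colMeans(fixed))
  S <- crossprod(P, Q)
  sxx <- S[1, 1]; sxy <- S[1, 2]; sxz <- S[1, 3]
  syx <- S[2, 1]; syy <- S[2, 2]; syz <- S[2, 3]
  szx <- S[3, 1]; szy <- S[3, 2]; szz <- S[3, 3]
  N <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz),
    4, 4, byrow = TRUE)
  e <- eigen(N, symmetric = TRUE)
  lam <- e$values[1]
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  n <- nrow(P)
  rmsd <- sqrt(max(sum(P^2) + sum(Q^2) - 2 * lam, 0) / n)
  list(rotation = R, rmsd = rmsd)
}

# Closed-form exposed area of each of two equal spheres of radius R whose
# centres are d apart (d < 2R): full sphere minus the buried cap.
two_sphere_exposed_area <- function(R, d) {
  h <- R - d / 2
  4 * pi * R^2 - 2 * pi * R * h
}

# Plain double-loop minimum distance (oracle for the chunked version).
min_distance_loop <- function(xa, xb) {
  best <- Inf
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      best <- min(best, sqrt(sum((xa[i, ] - xb[j, ])^2)))
    }
  }
  best
}

# Per-row RMSD by explicit loop (oracle for rmsd_noalign).
rmsd_loop <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) s <- s + sum((a[i, ] - b[i, ])^2)
  sqrt(s / nrow(a))
}

# Random proper rotation from a normalised quaternion.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
}
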