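#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between `R %*% x + t` over the moving set and the fixed set, by SVD of
#' the cross-covariance with the standard determinant correction (the sign
#' of the smallest singular direction is flipped when the raw solution is a
#' reflection), so the result is always a genuine rotation.
#'
#' @param moving,fixed N x 3 coordinate matrices (or atom tables), rows in
#'   one-to-one correspondence (see [match_residues()]).
#' @return An object of class `kabsch_fit`: list with `rotation` (3 x 3),
#'   `translation` (length 3, angstrom), `rmsd` (angstrom) and `n_matched`.
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' R <- rotation_about_axis(30, c(0, 0, 1))
#' fit <- kabsch_fit(x, x %*% t(R))
#' rotation_angle(fit)
#' @seealso [rotation_angle()], [apply_transform()], [rmsd_noalign()]
#' @export
kabsch_fit <- function(moving, fixed) {
  P <- coord_matrix(moving)
  Q <- coord_matrix(fixed)
  if (nrow(P) != nrow(Q)) abort("coordinate sets differ in size")
  if (nrow(P) < 3L) {
    abort("at least 3 paired atoms are required",
          class = "structcomp_insufficient_atoms")
  }
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp)
  Q0 <- sweep(Q, 2L, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12)) {
    warn("input is nearly collinear; rotation is poorly conditioned")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cq - R %*% cp)
  moved <- P %*% t(R)
  moved <- sweep(moved, 2L, tr, "+")
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd,
                 n_matched = nrow(P)),
            class = "kabsch_fit")
}

#' Apply a rigid transform to coordinates
#'
#' @param x An N x 3 matrix or an atom table with `x`, `y`, `z` columns.
#' @param fit A `kabsch_fit` (or a list with `rotation` and `translation`).
#' @return Same shape as `x`, transformed.
#' @export
apply_transform <- function(x, fit) {
  R <- fit$rotation
  tr <- fit$translation
  if (is.data.frame(x)) {
    m <- coord_matrix(x) %*% t(R)
    m <- sweep(m, 2L, tr, "+")
    x$x <- m[, 1L]; x$y <- m[, 2L]; x$z <- m[, 3L]
    return(x)
  }
  sweep(coord_matrix(x) %*% t(R), 2L, tr, "+")
}

#' Total rotation angle of a rigid transform
#'
#' The magnitude of the rotation, from the trace identity
#' `theta = acos((tr(R) - 1) / 2)`; the argument is clamped to `[-1, 1]`
#' before `acos` to absorb numerical round-off.
#'
#' @param x A `kabsch_fit` or a 3 x 3 rotation matrix.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(x) {
  R <- if (inherits(x, "kabsch_fit")) x$rotation else x
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  deg(acos(clamp((sum(diag(R)) - 1) / 2, -1, 1)))
}

#' Pair two selections residue-by-residue
#'
#' Pairs atoms present in both selections by `(resno, insert, elety)`,
#' ordered by residue number, and returns matched coordinate matrices.
#' Residues resolved in only one model fall out of the intersection, which
#' is how superpositions tolerate disordered loops.
#'
#' @param sel_a,sel_b Atom tables (typically C-alpha selections from
#'   [select_atoms()]).
#' @return List with `xyz_a`, `xyz_b` (N x 3), `n_matched` and `resno`.
#' @export
match_residues <- function(sel_a, sel_b) {
  key <- function(s) paste(s$resno, s$insert, s$elety, sep = "|")
  a <- mutate(sel_a, .key = key(sel_a))
  b <- mutate(sel_b, .key = key(sel_b))
  a <- distinct(a, .data$.key, .keep_all = TRUE)
  b <- distinct(b, .data$.key, .keep_all = TRUE)
  common <- inner_join(
    select(a, ".key", "resno", "insert", "elety", ax = "x", ay = "y", az = "z"),
    select(b, ".key", bx = "x", by = "y", bz = "z"),
    by = ".key")
  if (!nrow(common)) {
    abort("selections share no residues", class = "structcomp_no_overlap")
  }
  common <- arrange(common, .data$resno, .data$insert, .data$elety)
  list(xyz_a = cbind(common$ax, common$ay, common$az),
       xyz_b = cbind(common$bx, common$by, common$bz),
       n_matched = nrow(common), resno = common$resno)
}

#' RMSD between corresponding rows without fitting
#'
#' Root-mean-square of per-row Euclidean distances; used to express how far
#' a domain has moved after the structures were aligned on a different
#' (reference) domain.
#'
#' @param a,b N x 3 coordinate matrices or atom tables, rows corresponding.
#' @return RMSD in angstrom.
#' @export
rmsd_noalign <- function(a, b) {
  A <- coord_matrix(a)
  B <- coord_matrix(b)
  if (!all(dim(A) == dim(B))) abort("coordinate sets differ in shape")
  sqrt(mean(rowSums((A - B)^2)))
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("<kabsch_fit> n = %d, rmsd = %.4f A, rotation = %.2f deg\n",
              x$n_matched, x$rmsd, rotation_angle(x)))
  invisible(x)
}

#' @rdname kabsch_fit
#' @param x A `kabsch_fit`.
#' @param ... Unused.
#' @method tidy kabsch_fit
#' @export
tidy.kabsch_fit <- function(x, ...) {
  tibble(term = c("rotation_deg", paste0("t", c("x", "y", "z"))),
         estimate = c(rotation_angle(x), x$translation))
}

#' @rdname kabsch_fit
#' @method glance kabsch_fit
#' @export
glance.kabsch_fit <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_matched = x$n_matched,
         rotation_deg = rotation_angle(x))
}
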