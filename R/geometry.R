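#' Dihedral angle between four points
#'
#' Computes the torsion angle defined by four positions using the IUPAC sign
#' convention: looking from `p2` towards `p3`, a clockwise rotation of the
#' far bond relative to the near bond is positive.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Cartesian coordinates, Angstrom).
#' @return Angle in degrees in the interval (-180, 180].
#' @examples
#' dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, 1, 1))  # cis, 0 deg
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b1^2) < 1e-12 || sum(b2^2) < 1e-12 || sum(b3^2) < 1e-12)
    stop("dihedral: consecutive points coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16)
    stop("dihedral: three consecutive points are collinear; torsion undefined")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

## wrap an angle (deg) into (-180, 180]
wrap_angle <- function(x) {
  x <- (x + 180) %% 360 - 180
  ifelse(x == -180, 180, x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three reference positions `a-b-c`, returns the position `d` such
#' that |c-d| = `bond`, the angle b-c-d equals `angle` and the torsion
#' a-b-c-d equals `torsion`.
#'
#' @param a,b,c Reference positions (numeric 3-vectors).
#' @param bond Bond length c-d in Angstrom.
#' @param angle Bond angle b-c-d in degrees.
#' @param torsion Dihedral a-b-c-d in degrees.
#' @return Numeric 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("place_atom: reference frame is collinear")
  n <- n / nn
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Rigid-body superposition of two models (Kabsch fit)
#'
#' Least-squares fits `model_b` onto `model_a` over a common atom selection
#' and reports the post-fit RMSD. The rotation is a proper rotation
#' (det = +1) obtained from the SVD of the cross-covariance matrix.
#'
#' @param model_a,model_b Models (see [read_ensemble()]), or plain n x 3
#'   coordinate matrices with matching rows.
#' @param selection Optional atom selection (see [select_atoms()]); ignored
#'   when coordinate matrices are supplied.
#' @return An object of class `"superposition"`: list with `rotation`
#'   (3 x 3), `translation` (length 3; maps b onto a as `x R + t`), `rmsd`
#'   (Angstrom) and `selection`.
#' @export
superpose <- function(model_a, model_b, selection = NULL) {
  if (is.matrix(model_a)) {
    xa <- model_a
    xb <- model_b
    ids <- NULL
  } else {
    sa <- select_atoms(model_a, selection)
    sb <- select_atoms(model_b, selection)
    key_a <- atom_key(sa)
    key_b <- atom_key(sb)
    common <- intersect(key_a, key_b)
    if (length(common) < 3)
      stop("superpose: fewer than 3 common atoms in selection")
    xa <- coords(sa)[match(common, key_a), , drop = FALSE]
    xb <- coords(sb)[match(common, key_b), , drop = FALSE]
    ids <- common
  }
  if (nrow(xa) < 3) stop("superpose: fewer than 3 atoms in selection")
  ca <- colMeans(xa)
  cb <- colMeans(xb)
  ya <- sweep(xa, 2, ca)
  yb <- sweep(xb, 2, cb)
  h <- crossprod(yb, ya)               # 3x3 covariance
  if (qr(h)$rank < 2 || sum(rowSums(ya^2) > 1e-12) < 2)
    stop("superpose: selection is degenerate (collinear atoms)")
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)   # xb %*% rot ~ xa
  fitted <- yb %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - ya)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(ca - cb %*% rot),
                 rmsd = rmsd,
                 selection = ids),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Rigid-body superposition: %d atoms, rmsd = %.4f A\n",
              if (is.null(x$selection)) NA_integer_ else length(x$selection),
              x$rmsd))
  invisible(x)
}

## apply a superposition to a coordinate matrix
transform_coords <- function(x, sup) {
  sweep(x %*% sup$rotation, 2, sup$translation, `+`)
}
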