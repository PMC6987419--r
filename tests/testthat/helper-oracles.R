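## Independent oracles used across the suite. Each deliberately takes a
## different computational route than the package implementation.

## dihedral via projection onto the plane perpendicular to the central
## bond, signed by the triple product
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  b2 <- b2 / sqrt(sum(b2^2))
  u <- (p1 - p2) - sum((p1 - p2) * b2) * b2
  w <- (p4 - p3) - sum((p4 - p3) * b2) * b2
  cr <- c(u[2] * w[3] - u[3] * w[2],
          u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  ang <- atan2(sqrt(sum(cr^2)), sum(u * w))
  s <- sum(b2 * cr)
  deg <- ang * 180 / pi * ifelse(s > 0, -1, 1)
  if (deg == -180) 180 else deg
}

## quaternion (Horn) absolute-orientation solution: fits xb onto xa and
## returns the post-fit rmsd
oracle_superpose_rmsd <- function(xa, xb) {
  ya <- sweep(xa, 2, colMeans(xa))
  yb <- sweep(xb, 2, colMeans(xb))
  m <- crossprod(yb, ya)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,      -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,      -sxx - syy + szz),
    4, 4, byrow = TRUE)
  q <- eigen(k, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  sqrt(mean(rowSums((yb %*% t(rot) - ya)^2)))
}

## direct Saupe contraction: coupling for a bond vector v and interaction
## tensor t3 (Hz, N-HN scale) with a per-type scale factor
oracle_coupling <- function(v, t3, factor = 1) {
  v <- v / sqrt(sum(v^2))
  factor * as.numeric(t(v) %*% t3 %*% v)
}

## normal-equations least-squares tensor fit (vs the package's SVD route)
oracle_fit_s <- function(a, d) {
  as.numeric(solve(crossprod(a), crossprod(a, d)))
}

## minimum-weight perfect matching by bitmask dynamic programming,
## with backtracking; returns list(score = mean pair distance, matching)
oracle_min_matching <- function(d) {
  n <- nrow(d)
  full <- bitwShiftL(1L, n) - 1L
  memo <- rep(NA_real_, full + 1L)
  choice <- rep(NA_integer_, full + 1L)
  solve_mask <- function(mask) {
    if (mask == 0L) return(0)
    if (!is.na(memo[mask + 1L])) return(memo[mask + 1L])
    i <- 0L
    while (!bitwAnd(mask, bitwShiftL(1L, i))) i <- i + 1L
    best <- Inf; bestj <- NA_integer_
    for (j in seq(i + 1L, n - 1L)) {
      if (!bitwAnd(mask, bitwShiftL(1L, j))) next
      rest <- bitwAnd(mask, bitwNot(bitwOr(bitwShiftL(1L, i),
                                           bitwShiftL(1L, j))))
      v <- d[i + 1L, j + 1L] + solve_mask(rest)
      if (v < best) { best <- v; bestj <- j }
    }
    memo[mask + 1L] <<- best
    choice[mask + 1L] <<- bestj
    best
  }
  total <- solve_mask(full)
  matching <- list()
  mask <- full
  while (mask != 0L) {
    i <- 0L
    while (!bitwAnd(mask, bitwShiftL(1L, i))) i <- i + 1L
    j <- choice[mask + 1L]
    matching[[length(matching) + 1L]] <- c(i + 1L, j + 1L)
    mask <- bitwAnd(mask, bitwNot(bitwOr(bitwShiftL(1L, i),
                                         bitwShiftL(1L, j))))
  }
  list(score = total / (n / 2), matching = matching)
}

## helix axis of an ideal helix from three consecutive Calpha positions
## (bisector construction; exact for ideal geometry)
oracle_helix_axis <- function(ca) {
  v <- diff(ca)
  h1 <- v[2, ] - v[1, ]
  h2 <- v[3, ] - v[2, ]
  ax <- c(h1[2] * h2[3] - h1[3] * h2[2],
          h1[3] * h2[1] - h1[1] * h2[3],
          h1[1] * h2[2] - h1[2] * h2[1])
  ax <- ax / sqrt(sum(ax^2))
  if (sum(ax * (ca[nrow(ca), ] - ca[1, ])) < 0) ax <- -ax
  ax
}

angle_deg <- function(u, v) {
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

rigid_transform_model <- function(model, rot = random_rotation(),
                                  shift = stats::rnorm(3, 0, 20)) {
  xyz <- cbind(model$x, model$y, model$z) %*% t(rot)
  model$x <- xyz[, 1] + shift[1]
  model$y <- xyz[, 2] + shift[2]
  model$z <- xyz[, 3] + shift[3]
  model
}

## construct a disulfide_geometry object from five angles
disulfide_geometry_from <- function(chi, pair = c(1L, 2L)) {
  getFromNamespace("disulfide_geometry", "peprdc")(
    chi[1], chi[2], chi[3], chi[4], chi[5], pair = pair)
}

## a minimal model holding CYS CB atoms at given positions
cb_model <- function(positions, resnos = seq_along(positions)) {
  do.call(rbind, lapply(seq_along(positions), function(i)
    data.frame(atom = "CB", element = "C", resno = resnos[i],
               resname = "CYS", chain = "A",
               x = positions[[i]][1], y = positions[[i]][2],
               z = positions[[i]][3], stringsAsFactors = FALSE)))
}

## six-cysteine layout with a known pairing: bonded pairs at 3.8 A,
## cross distances >= 6 A
six_cys_positions <- function() {
  list(c(0, 0, 0), c(3.8, 0, 0),
       c(0, 8, 0), c(3.8, 8, 0),
       c(0, 16, 0), c(3.8, 16, 0))
}

## small helical Ala/Cys peptide used by several tests
make_test_peptide <- function(n = 16, chi1 = -60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phi <- rep(-57, n) + if (is.null(seed)) 0 else stats::rnorm(n, 0, 20)
  psi <- rep(-47, n) + if (is.null(seed)) 0 else stats::rnorm(n, 0, 20)
  seq1 <- paste(rep(c("A", "C"), length.out = n), collapse = "")
  build_peptide(seq1, phi, psi,
                chi1 = ifelse(seq_len(n) %% 2 == 0, chi1, NA))
}
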