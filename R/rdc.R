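## RDC observations are kept in a data.frame of class "rdc_set" with
## columns: chain, res_i, atom_i, res_j, atom_j, type, medium, d_obs, sigma.
## Types follow the backbone experiments plus the summed beta-methylene
## coupling: "N-HN", "CA-HA", "C-CA", "N-C", "SUM-CBHB".

#' Construct an RDC set
#'
#' @param df Data frame with columns `res_i`, `atom_i`, `res_j`, `atom_j`,
#'   `type`, `medium`, `d_obs` and optionally `chain` and `sigma`.
#' @return The validated data frame with class `"rdc_set"`.
#' @export
rdc_set <- function(df) {
  if (is.null(df$chain)) df$chain <- "A"
  if (is.null(df$sigma)) df$sigma <- NA_real_
  need <- c("chain", "res_i", "atom_i", "res_j", "atom_j", "type",
            "medium", "d_obs", "sigma")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("rdc_set: missing columns: ",
                             paste(miss, collapse = ", "))
  df <- df[, need]
  known <- dipolar_constants()$type
  bad <- setdiff(unique(df$type), known)
  if (length(bad) > 0) stop("rdc_set: unknown rdc type(s): ",
                            paste(bad, collapse = ", "))
  if (any(!is.finite(df$d_obs))) stop("rdc_set: non-finite d_obs")
  class(df) <- c("rdc_set", "data.frame")
  df
}

#' Read an RDC table (TSV)
#'
#' Expects the header
#' `chain res_i atom_i res_j atom_j type medium d_obs sigma`.
#' @param path File path.
#' @return An `"rdc_set"`.
#' @export
read_rdc_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  rdc_set(df)
}

#' Write an RDC table (TSV)
#' @param x An `"rdc_set"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rdc_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an XPLOR-style dipolar restraint table
#'
#' Parses `assign` statements of the SANI/DIPO dialect used in deposited
#' restraint files: four pseudo-atom selections for the alignment frame
#' followed by the two physical atom selections, the coupling and its
#' error. Only `resid` and `name` qualifiers are honoured.
#'
#' @param path File path.
#' @param medium Medium label attached to every record.
#' @return An `"rdc_set"`.
#' @export
read_rdc_xplor <- function(path, medium = "pf1") {
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  txt <- gsub("!.*?(\\n|$)", " ", txt)
  stmts <- regmatches(txt, gregexpr(
    "assign(\\s*\\([^)]*\\)){6}\\s*[-0-9.]+\\s+[-0-9.]+", txt,
    ignore.case = TRUE))[[1]]
  if (length(stmts) == 0) stop("read_rdc_xplor: no assign statements found")
  rows <- lapply(stmts, function(s) {
    sels <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
    phys <- utils::tail(sels, 2)
    parse_sel <- function(p) {
      res <- regmatches(p, regexpr("resid\\s+[0-9]+", p, ignore.case = TRUE))
      nm <- regmatches(p, regexpr("name\\s+[A-Za-z0-9']+", p,
                                  ignore.case = TRUE))
      c(res = as.integer(sub("resid\\s+", "", res, ignore.case = TRUE)),
        name = toupper(sub("name\\s+", "", nm, ignore.case = TRUE)))
    }
    a <- parse_sel(phys[1])
    b <- parse_sel(phys[2])
    nums <- as.numeric(utils::tail(
      strsplit(trimws(s), "\\s+")[[1]], 2))
    data.frame(res_i = as.integer(a["res"]), atom_i = a["name"],
               res_j = as.integer(b["res"]), atom_j = b["name"],
               d_obs = nums[1], sigma = nums[2], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$atom_i[df$atom_i == "HN"] <- "H"
  df$atom_j[df$atom_j == "HN"] <- "H"
  df$type <- mapply(function(ai, aj) {
    key <- paste(sort(c(ai, aj)), collapse = "-")
    switch(key, "H-N" = "N-HN", "CA-HA" = "CA-HA", "C-CA" = "C-CA",
           "C-N" = "N-C", stop("read_rdc_xplor: unrecognised pair ", key))
  }, df$atom_i, df$atom_j)
  df$medium <- medium
  rdc_set(df)
}

#' Normalize observed couplings to the N-HN scale
#'
#' Divides each coupling by its type's dipolar normalization factor
#' (see [dipolar_constants()]). The summed beta-methylene coupling is a sum
#' of two C-H couplings and is normalized by the single-pair C-H factor.
#'
#' @param x An `"rdc_set"`.
#' @param constants Dipolar constants table.
#' @return The set with an added column `d_norm`.
#' @export
normalize_rdc <- function(x, constants = dipolar_constants()) {
  f <- constants$factor[match(x$type, constants$type)]
  if (anyNA(f)) stop("normalize_rdc: unknown rdc type")
  x$d_norm <- x$d_obs / f
  x
}

## ---- design matrix ---------------------------------------------------

## For a unit internuclear vector v and the symmetric traceless interaction
## tensor T (Hz on the N-HN scale) the coupling is d = f * v' T v, with f
## the type's normalization factor. Using the traceless parameterization
## s = (T_yy, T_zz, T_xy, T_xz, T_yz), the row is
##   f * (y^2 - x^2, z^2 - x^2, 2xy, 2xz, 2yz).

unit_row <- function(v) {
  v <- v / sqrt(sum(v^2))
  c(v[2]^2 - v[1]^2, v[3]^2 - v[1]^2,
    2 * v[1] * v[2], 2 * v[1] * v[3], 2 * v[2] * v[3])
}

record_vectors <- function(model, rec) {
  if (rec$type == "SUM-CBHB") {
    cb <- atom_xyz(model, rec$res_i, "CB")
    list(atom_xyz(model, rec$res_i, "HB2") - cb,
         atom_xyz(model, rec$res_i, "HB3") - cb)
  } else {
    list(atom_xyz(model, rec$res_j, rec$atom_j) -
         atom_xyz(model, rec$res_i, rec$atom_i))
  }
}

#' Design-matrix row for one RDC record
#'
#' Builds the 5-vector a such that the back-calculated coupling is
#' `a %*% s` with `s = (T_yy, T_zz, T_xy, T_xz, T_yz)` the independent
#' elements of the traceless interaction tensor on the N-HN scale. For the
#' summed beta-methylene type the row is the sum of the two single-proton
#' rows.
#'
#' @param model Model holding both atoms.
#' @param record One-row data frame (an `"rdc_set"` row).
#' @param constants Dipolar constants table.
#' @return Numeric 5-vector.
#' @export
design_row <- function(model, record, constants = dipolar_constants()) {
  f <- constants$factor[match(record$type, constants$type)]
  if (is.na(f)) stop("design_row: unknown rdc type ", record$type)
  vs <- record_vectors(model, record)
  f * Reduce(`+`, lapply(vs, unit_row))
}

design_matrix <- function(model, records, constants = dipolar_constants()) {
  t(vapply(seq_len(nrow(records)),
           function(i) design_row(model, records[i, ], constants),
           numeric(5)))
}

## expand the 5-parameter vector into the symmetric traceless 3x3 tensor
tensor_from_s <- function(s) {
  tyy <- s[1]; tzz <- s[2]
  txx <- -tyy - tzz
  matrix(c(txx, s[3], s[4],
           s[3], tyy, s[5],
           s[4], s[5], tzz), 3, 3)
}

s_from_tensor <- function(t3) {
  c(t3[2, 2], t3[3, 3], t3[1, 2], t3[1, 3], t3[2, 3])
}

## ---- alignment tensor ------------------------------------------------

#' Construct an alignment tensor from magnitude, rhombicity and orientation
#'
#' Builds the interaction tensor with principal values
#' (2Da, -Da(1+1.5R), -Da(1-1.5R)) rotated by ZYZ Euler angles, so that a
#' coupling on the N-HN scale is \eqn{d = v^T T v}.
#'
#' @param Da Axial magnitude in Hz (N-HN scale).
#' @param R Rhombicity, in \[0, 2/3\].
#' @param euler ZYZ Euler angles (alpha, beta, gamma) in degrees.
#' @return An object of class `"alignment_tensor"`.
#' @export
make_tensor <- function(Da, R = 0, euler = c(0, 0, 0)) {
  if (R < 0 || R > 2 / 3) stop("make_tensor: R must lie in [0, 2/3]")
  pv <- diag(c(-Da * (1 - 1.5 * R), -Da * (1 + 1.5 * R), 2 * Da))
  rot <- euler_zyz(euler)
  describe_tensor(rot %*% pv %*% t(rot))
}

euler_zyz <- function(euler) {
  e <- euler * pi / 180
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1),
                           3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)),
                           3, 3)
  rz(e[1]) %*% ry(e[2]) %*% rz(e[3])
}

## derive Da, R, Euler angles and the dimensionless Saupe matrix from the
## interaction tensor T (Hz, N-HN scale)
describe_tensor <- function(t3) {
  t3 <- (t3 + t(t3)) / 2
  t3 <- t3 - diag(rep(sum(diag(t3)) / 3, 3))
  e <- eigen(t3, symmetric = TRUE)
  ord <- order(abs(e$values))          # |xx| <= |yy| <= |zz|
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  if (det(vecs) < 0) vecs[, 1] <- -vecs[, 1]
  Da <- vals[3] / 2
  R <- if (abs(Da) < 1e-300) 0 else (vals[1] - vals[2]) / (3 * Da)
  beta <- acos(max(-1, min(1, vecs[3, 3])))
  if (sin(beta) > 1e-8) {
    alpha <- atan2(vecs[2, 3], vecs[1, 3])
    gamma <- atan2(vecs[3, 2], -vecs[3, 1])
  } else {
    alpha <- atan2(vecs[2, 1], vecs[1, 1])
    gamma <- 0
  }
  structure(list(tensor = t3,
                 saupe = t3 / (2 * dmax_nh()),
                 Da = Da, R = R,
                 euler = c(alpha, beta, gamma) * 180 / pi),
            class = "alignment_tensor")
}

#' @export
print.alignment_tensor <- function(x, ...) {
  cat(sprintf("Alignment tensor: Da = %.3f Hz (N-HN scale), R = %.3f\n",
              x$Da, x$R))
  cat(sprintf("  Euler (ZYZ): %.1f, %.1f, %.1f deg\n",
              x$euler[1], x$euler[2], x$euler[3]))
  invisible(x)
}

## back-calculate couplings for records against a model and tensor
back_calculate <- function(model, records, tensor,
                           constants = dipolar_constants()) {
  s <- s_from_tensor(if (inherits(tensor, "alignment_tensor"))
    tensor$tensor else tensor)
  as.numeric(design_matrix(model, records, constants) %*% s)
}

## ---- Q factor --------------------------------------------------------

#' RDC quality factor Q
#'
#' Q = rms(Dcalc - Dobs) / rms(Dobs) with rms(x) = sqrt(mean(x^2)); lower
#' is better (0 = perfect agreement, 1 = no information).
#'
#' @param d_obs,d_calc Equal-length numeric vectors (Hz).
#' @param type Optional type labels for a per-type breakdown.
#' @return An object of class `"q_report"`: list with `q`, `n_rdc`,
#'   `rms_obs`, `rms_resid`, `per_type`.
#' @export
q_factor <- function(d_obs, d_calc, type = NULL) {
  if (length(d_obs) != length(d_calc) || length(d_obs) < 1)
    stop("q_factor: d_obs and d_calc must have equal positive length")
  rms <- function(x) sqrt(mean(x^2))
  ro <- rms(d_obs)
  if (ro == 0) stop("q_factor: rms(d_obs) is zero")
  rr <- rms(d_calc - d_obs)
  per_type <- NULL
  if (!is.null(type)) {
    per_type <- do.call(rbind, lapply(split(seq_along(d_obs), type),
      function(i) data.frame(n = length(i),
                             q = rms(d_calc[i] - d_obs[i]) / rms(d_obs[i]))))
  }
  structure(list(q = rr / ro, n_rdc = length(d_obs), rms_obs = ro,
                 rms_resid = rr, per_type = per_type), class = "q_report")
}

#' @export
print.q_report <- function(x, ...) {
  cat(sprintf("Q = %.4f over %d RDCs (rms obs %.3f Hz, rms resid %.3f Hz)\n",
              x$q, x$n_rdc, x$rms_obs, x$rms_resid))
  if (!is.null(x$per_type)) {
    for (i in seq_len(nrow(x$per_type)))
      cat(sprintf("  %-9s n = %3d  Q = %.4f\n", rownames(x$per_type)[i],
                  x$per_type$n[i], x$per_type$q[i]))
  }
  invisible(x)
}

## ---- SVD fit ---------------------------------------------------------

#' Fit the alignment tensor to a structure by SVD
#'
#' Solves the linear system D = A s in the least-squares sense through the
#' singular value decomposition of the design matrix (minimum-norm solution
#' when degenerate) for a single alignment medium, then back-calculates all
#' couplings and reports Q.
#'
#' @param model A model data frame.
#' @param rdcs An `"rdc_set"`; must contain a single medium.
#' @param weights `NULL` for unweighted least squares (default) or
#'   `"sigma"` for 1/sigma^2 weighting where sigma is present.
#' @param constants Dipolar constants table.
#' @return Object of class `"tensor_fit"`: list with `tensor`
#'   (`"alignment_tensor"`), `d_calc`, `q` (a `"q_report"`), `condition`
#'   and `n`.
#' @export
fit_tensor <- function(model, rdcs, weights = NULL,
                       constants = dipolar_constants()) {
  if (length(unique(rdcs$medium)) > 1)
    stop("fit_tensor: records span several media; fit each medium separately")
  if (nrow(rdcs) < 5)
    stop("fit_tensor: underdetermined; need at least 5 RDCs, got ",
         nrow(rdcs))
  a <- design_matrix(model, rdcs, constants)
  d <- rdcs$d_obs
  w <- NULL
  if (identical(weights, "sigma") && !all(is.na(rdcs$sigma))) {
    w <- 1 / rdcs$sigma^2
    w[!is.finite(w)] <- max(w[is.finite(w)])
    a <- a * sqrt(w)
    d <- d * sqrt(w)
  }
  sv <- svd(a)
  cond <- sv$d[1] / sv$d[5]
  if (!is.finite(cond) || cond > 1e8)
    warning(sprintf("fit_tensor: degenerate bond-vector geometry (condition number %.3g)",
                    cond))
  pos <- sv$d > max(sv$d) * 1e-12
  s <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% d) / sv$d[pos])
  s <- as.numeric(s)
  d_calc <- as.numeric(design_matrix(model, rdcs, constants) %*% s)
  structure(list(tensor = describe_tensor(tensor_from_s(s)),
                 d_calc = d_calc,
                 q = q_factor(rdcs$d_obs, d_calc, rdcs$type),
                 condition = cond, n = nrow(rdcs)),
            class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  print(x$tensor)
  print(x$q)
  invisible(x)
}

#' Fit the alignment tensor to every model of an ensemble
#'
#' Each model is fitted independently; the mean Q and its spread over the
#' ensemble are reported alongside the per-model fits.
#'
#' @inheritParams fit_tensor
#' @param ensemble An ensemble.
#' @return List with `fits` (per model), `q_mean`, `q_sd`, `q_per_model`.
#' @export
fit_tensor_ensemble <- function(ensemble, rdcs, weights = NULL,
                                constants = dipolar_constants()) {
  fits <- lapply(ensemble$models, fit_tensor, rdcs = rdcs,
                 weights = weights, constants = constants)
  qs <- vapply(fits, function(f) f$q$q, numeric(1))
  list(fits = fits, q_mean = mean(qs), q_sd = stats::sd(qs),
       q_per_model = qs)
}
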