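## Synthetic-data generators: idealized peptides and cystines built from
## internal coordinates, RDCs simulated from a known alignment tensor, and
## J-couplings from Karplus curves. All generators take an explicit seed
## and are deterministic given it.

.aa1to3 <- c(A = "ALA", G = "GLY", C = "CYS", S = "SER", T = "THR",
             V = "VAL", I = "ILE", L = "LEU", F = "PHE", Y = "TYR",
             N = "ASN", D = "ASP", E = "GLU", Q = "GLN", K = "LYS",
             R = "ARG", H = "HIS", M = "MET", W = "TRP", P = "PRO")

#' Build an idealized peptide from internal coordinates
#'
#' Constructs a polypeptide chain atom by atom (NeRF-style) with ideal bond
#' lengths and angles, at the requested backbone and chi1 torsions, with
#' hydrogens at ideal positions. Side chains are built to the gamma heavy
#' atom (SG for Cys, OG/OG1 for Ser/Thr, CG1 for Val/Ile, CG otherwise)
#' plus the beta protons; this is sufficient for all RDC and chi1 analyses
#' in the package.
#'
#' @param sequence One-letter string (e.g. `"ACSG"`) or vector of 3-letter
#'   codes.
#' @param phi,psi Numeric vectors of backbone torsions in degrees (length
#'   of the sequence; `phi[1]` and `psi[n]` are not used).
#' @param chi1 Numeric vector of chi1 torsions (degrees); `NA` allowed for
#'   Gly/Ala.
#' @param chain Chain identifier.
#' @param mirror If `TRUE`, build the mirror image (negates all torsions
#'   and impropers; for chirality tests).
#' @return A model data frame.
#' @export
build_peptide <- function(sequence, phi, psi, chi1 = NULL, chain = "A",
                          mirror = FALSE) {
  res3 <- if (length(sequence) == 1 && !toupper(sequence) %in% .aa1to3) {
    codes <- strsplit(toupper(sequence), "")[[1]]
    bad <- setdiff(codes, names(.aa1to3))
    if (length(bad) > 0) stop("build_peptide: invalid residue code(s): ",
                              paste(bad, collapse = ", "))
    unname(.aa1to3[codes])
  } else toupper(sequence)
  if (!all(res3 %in% .aa1to3))
    stop("build_peptide: invalid residue code(s): ",
         paste(setdiff(res3, .aa1to3), collapse = ", "))
  n <- length(res3)
  if (length(phi) != n || length(psi) != n)
    stop("build_peptide: phi/psi must match sequence length")
  if (is.null(chi1)) chi1 <- rep(NA_real_, n)
  if (length(chi1) != n)
    stop("build_peptide: chi1 must match sequence length")
  g <- geometry_defaults()
  sgn <- if (mirror) -1 else 1
  tor <- function(x) sgn * x
  rows <- list()
  add <- function(atom, element, resno, resname, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      atom = atom, element = element, resno = resno, resname = resname,
      chain = chain, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
    xyz
  }
  ## backbone of residue 1 laid flat in the xy-plane
  prevN <- prevCA <- prevC <- NULL
  for (i in seq_len(n)) {
    rn <- res3[i]
    if (i == 1) {
      N <- add("N", "N", i, rn, c(0, 0, 0))
      CA <- add("CA", "C", i, rn, c(g$b_n_ca, 0, 0))
      a <- g$a_n_ca_c * pi / 180
      C <- add("C", "C", i, rn,
               CA + g$b_ca_c * c(-cos(a), sgn * sin(a), 0))
    } else {
      N <- add("N", "N", i, rn,
               place_atom(prevN, prevCA, prevC, g$b_c_n, g$a_ca_c_n,
                          tor(psi[i - 1])))
      CA <- add("CA", "C", i, rn,
                place_atom(prevCA, prevC, N, g$b_n_ca, g$a_c_n_ca,
                           tor(180)))
      C <- add("C", "C", i, rn,
               place_atom(prevC, N, CA, g$b_ca_c, g$a_n_ca_c,
                          tor(phi[i])))
      add("H", "H", i, rn,
          place_atom(prevCA, prevC, N, g$b_n_h, g$a_c_n_h, tor(0)))
    }
    add("O", "O", i, rn,
        place_atom(N, CA, C, g$b_c_o, g$a_ca_c_o,
                   tor(if (i < n) psi[i] + 180 else 180)))
    if (rn == "GLY") {
      add("HA2", "H", i, rn, place_atom(C, N, CA, g$b_ca_ha, g$a_n_ca_cb,
                                        tor(g$imp_c_n_ca_cb)))
      add("HA3", "H", i, rn, place_atom(C, N, CA, g$b_ca_ha, g$a_n_ca_ha,
                                        tor(g$imp_c_n_ca_ha)))
    } else {
      CB <- add("CB", "C", i, rn,
                place_atom(C, N, CA, g$b_ca_cb, g$a_n_ca_cb,
                           tor(g$imp_c_n_ca_cb)))
      add("HA", "H", i, rn, place_atom(C, N, CA, g$b_ca_ha, g$a_n_ca_ha,
                                       tor(g$imp_c_n_ca_ha)))
      side <- build_side_chain(rn, N, CA, CB, chi1[i], g, tor)
      for (s in side) add(s$atom, s$element, i, rn, s$xyz)
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }
  new_model(do.call(rbind, rows))
}

## gamma-level side-chain atoms for one residue; returns a list of
## list(atom, element, xyz)
build_side_chain <- function(rn, N, CA, CB, chi1, g, tor) {
  out <- list()
  emit <- function(atom, element, xyz)
    out[[length(out) + 1]] <<- list(atom = atom, element = element,
                                    xyz = xyz)
  hb <- function(torsion)
    place_atom(N, CA, CB, g$b_cb_hb, g$a_ca_cb_h, tor(torsion))
  if (rn == "ALA") {
    emit("HB1", "H", hb(180))
    emit("HB2", "H", hb(-60))
    emit("HB3", "H", hb(60))
    return(out)
  }
  if (is.na(chi1))
    stop("build_peptide: chi1 required for residue type ", rn)
  gatom <- if (rn %in% names(.gamma_atom)) .gamma_atom[[rn]] else "CG"
  gel <- substring(gatom, 1, 1)
  gbond <- if (gel == "S") g$b_cb_sg else if (gel == "O") g$b_cb_og else
    g$b_cb_cg
  emit(gatom, gel, place_atom(N, CA, CB, gbond, g$a_ca_cb_x, tor(chi1)))
  if (rn %in% c("VAL", "ILE", "THR")) {
    ## beta-methine: one HB plus a second gamma substituent; offsets fixed
    ## against the ideal L-residue templates
    hb_off <- c(VAL = 120, ILE = -120, THR = -120)[[rn]]
    g2 <- c(VAL = "CG2", ILE = "CG2", THR = "CG2")[[rn]]
    emit("HB", "H", hb(chi1 + hb_off))
    emit(g2, "C", place_atom(N, CA, CB, g$b_cb_cg, g$a_ca_cb_x,
                             tor(chi1 - hb_off)))
  } else {
    emit("HB2", "H", hb(chi1 + g$off_hb2))
    emit("HB3", "H", hb(chi1 + g$off_hb3))
  }
  out
}

#' Build an idealized cystine fragment with chosen dihedrals
#'
#' Constructs a two-cysteine fragment whose five bridge dihedrals
#' (chi1, chi2, chi3, chi2', chi1') are exactly the requested values, with
#' ideal bond lengths and angles and an SG-SG bond of 2.05 Angstrom.
#'
#' @param chi Numeric length-5 vector: chi1, chi2, chi3, chi2p, chi1p in
#'   degrees.
#' @param pair Residue numbers of the two cysteines (default 1 and 2).
#' @param chain Chain identifier.
#' @return A model data frame with both cysteines (N, CA, C, O, CB, SG,
#'   HA, HB2, HB3 each).
#' @export
build_cystine <- function(chi, pair = c(1L, 2L), chain = "A") {
  stopifnot(length(chi) == 5)
  g <- geometry_defaults()
  rows <- list()
  add <- function(atom, element, resno, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      atom = atom, element = element, resno = resno, resname = "CYS",
      chain = chain, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
    xyz
  }
  r1 <- pair[1]; r2 <- pair[2]
  N1 <- add("N", "N", r1, c(0, 0, 0))
  CA1 <- add("CA", "C", r1, c(g$b_n_ca, 0, 0))
  a <- g$a_n_ca_cb * pi / 180
  CB1 <- add("CB", "C", r1, CA1 + g$b_ca_cb * c(-cos(a), sin(a), 0))
  SG1 <- add("SG", "S", r1,
             place_atom(N1, CA1, CB1, g$b_cb_sg, g$a_s_cb_ca, chi[1]))
  add("HB2", "H", r1, place_atom(N1, CA1, CB1, g$b_cb_hb, g$a_ca_cb_h,
                                 chi[1] + g$off_hb2))
  add("HB3", "H", r1, place_atom(N1, CA1, CB1, g$b_cb_hb, g$a_ca_cb_h,
                                 chi[1] + g$off_hb3))
  C1 <- add("C", "C", r1, place_atom(SG1, CB1, CA1, g$b_ca_c, g$a_cb_ca_c,
                                     chi[1] + 120))
  add("HA", "H", r1, place_atom(SG1, CB1, CA1, g$b_ca_ha, g$a_n_ca_ha,
                                chi[1] - 120))
  add("O", "O", r1, place_atom(N1, CA1, C1, g$b_c_o, g$a_ca_c_o, 180))
  SG2 <- add("SG", "S", r2,
             place_atom(CA1, CB1, SG1, g$b_s_s, g$a_cb_s_s, chi[2]))
  CB2 <- add("CB", "C", r2,
             place_atom(CB1, SG1, SG2, g$b_cb_sg, g$a_s_s_cb, chi[3]))
  CA2 <- add("CA", "C", r2,
             place_atom(SG1, SG2, CB2, g$b_ca_cb, g$a_s_cb_ca, chi[4]))
  N2 <- add("N", "N", r2,
            place_atom(SG2, CB2, CA2, g$b_n_ca, g$a_n_ca_cb, chi[5]))
  add("HB2", "H", r2, place_atom(N2, CA2, CB2, g$b_cb_hb, g$a_ca_cb_h,
                                 chi[5] + g$off_hb2))
  add("HB3", "H", r2, place_atom(N2, CA2, CB2, g$b_cb_hb, g$a_ca_cb_h,
                                 chi[5] + g$off_hb3))
  C2 <- add("C", "C", r2, place_atom(SG2, CB2, CA2, g$b_ca_c, g$a_cb_ca_c,
                                     chi[5] + 120))
  add("HA", "H", r2, place_atom(SG2, CB2, CA2, g$b_ca_ha, g$a_n_ca_ha,
                                chi[5] - 120))
  add("O", "O", r2, place_atom(N2, CA2, C2, g$b_c_o, g$a_ca_c_o, 180))
  new_model(do.call(rbind, rows))
}

#' Template of RDC records for a model
#'
#' Lays out the experiment design of a realistic backbone RDC study: the
#' four one-bond/two-bond backbone couplings (N-HN, CA-HA, C-CA, N-C) in
#' each alignment medium, plus the summed beta-methylene coupling in one
#' medium, for every residue where the required atoms exist.
#'
#' @param model A model data frame.
#' @param media Character vector of medium labels.
#' @param sum_cbhb_medium Medium carrying the SUM-CBHB experiment (`NULL`
#'   to omit).
#' @return An `"rdc_set"` without observed values (`d_obs` = 0).
#' @export
rdc_template <- function(model, media = c("pf1", "peg"),
                         sum_cbhb_medium = media[1]) {
  has <- function(res, atom) any(model$resno == res & model$atom == atom)
  residues <- sort(unique(model$resno))
  recs <- list()
  push <- function(res_i, atom_i, res_j, atom_j, type, medium)
    recs[[length(recs) + 1]] <<- data.frame(
      chain = model$chain[1], res_i = res_i, atom_i = atom_i,
      res_j = res_j, atom_j = atom_j, type = type, medium = medium,
      d_obs = 0, sigma = NA_real_, stringsAsFactors = FALSE)
  for (m in media) {
    for (r in residues) {
      if (has(r, "N") && has(r, "H")) push(r, "N", r, "H", "N-HN", m)
      if (has(r, "CA") && has(r, "HA")) push(r, "CA", r, "HA", "CA-HA", m)
      if (has(r, "C") && has(r, "CA")) push(r, "C", r, "CA", "C-CA", m)
      if (has(r, "N") && (r - 1) %in% residues && has(r - 1, "C"))
        push(r, "N", r - 1, "C", "N-C", m)
    }
  }
  if (!is.null(sum_cbhb_medium)) {
    for (r in residues)
      if (has(r, "CB") && has(r, "HB2") && has(r, "HB3"))
        push(r, "CB", r, "HB", "SUM-CBHB", sum_cbhb_medium)
  }
  rdc_set(do.call(rbind, recs))
}

#' Simulate RDC observations from a known alignment tensor
#'
#' Back-calculates every record of the template exactly from the tensor
#' and the model geometry, then adds independent Gaussian noise. The
#' summed beta-methylene coupling is simulated as the sum of the two
#' individual Cb-Hb couplings.
#'
#' @param model A model data frame.
#' @param tensor An `"alignment_tensor"` (see [make_tensor()]); the same
#'   tensor is used for all media unless a named list of tensors (one per
#'   medium) is given.
#' @param records An `"rdc_set"` template; default [rdc_template()].
#' @param noise_sd Gaussian noise standard deviation in Hz.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param constants Dipolar constants table.
#' @return An `"rdc_set"` with simulated `d_obs`; the noiseless values are
#'   attached as attribute `"d_true"`.
#' @export
simulate_rdcs <- function(model, tensor, records = NULL, noise_sd = 0,
                          seed = NULL, constants = dipolar_constants()) {
  if (is.null(records)) records <- rdc_template(model)
  d_true <- numeric(nrow(records))
  if (inherits(tensor, "alignment_tensor")) tensor <-
    stats::setNames(rep(list(tensor), length(unique(records$medium))),
                    unique(records$medium))
  for (m in unique(records$medium)) {
    i <- which(records$medium == m)
    tt <- tensor[[m]]
    if (is.null(tt)) stop("simulate_rdcs: no tensor for medium ", m)
    d_true[i] <- back_calculate(model, records[i, , drop = FALSE], tt,
                                constants)
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("simulate_rdcs: seed required for noisy data")
    set.seed(seed)
    records$d_obs <- d_true + stats::rnorm(length(d_true), 0, noise_sd)
  } else {
    records$d_obs <- d_true
  }
  records$sigma <- if (noise_sd > 0) noise_sd else NA_real_
  attr(records, "d_true") <- d_true
  records
}

#' Simulate J-couplings for chosen chi1 states or mixtures
#'
#' Produces population-weighted Karplus couplings (3J(HaHb2), 3J(HaHb3))
#' and qualitative 3J(NHb) classes for each requested residue; a residue
#' state may be a single chi1 angle or a mixture given as
#' `list(states = c(...), weights = c(...))` with weights summing to 1.
#'
#' @param states List (or numeric vector) of chi1 states per residue.
#' @param noise_sd Gaussian noise sd on the couplings (Hz).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param karplus_params Karplus coefficients, see
#'   [karplus_coefficients()].
#' @param thresholds Class cutoffs, see [chi1_thresholds()].
#' @return Data frame with columns `res`, `j_hahb2`, `j_hahb3`,
#'   `nhb2_class`, `nhb3_class`, `overlap`; the generating states are kept
#'   as attribute `"truth"`.
#' @export
simulate_jcouplings <- function(states, noise_sd = 0, seed = NULL,
                                karplus_params = karplus_coefficients(),
                                thresholds = chi1_thresholds()) {
  if (is.numeric(states)) states <- as.list(states)
  n <- length(states)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("simulate_jcouplings: seed required for noise")
    set.seed(seed)
  }
  pop_j <- function(st, kind, coef) {
    if (is.list(st)) {
      w <- st$weights
      if (abs(sum(w) - 1) > 1e-8)
        stop("simulate_jcouplings: mixture weights must sum to 1")
      sum(w * vapply(st$states, karplus, numeric(1),
                     coefficients = coef, kind = kind))
    } else karplus(st, coef, kind)
  }
  noise <- function() if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
  rows <- lapply(seq_len(n), function(i) {
    st <- states[[i]]
    j2 <- pop_j(st, "hahb2", karplus_params$hahb) + noise()
    j3 <- pop_j(st, "hahb3", karplus_params$hahb) + noise()
    nb2 <- pop_j(st, "nhb2", karplus_params$nhb) + noise()
    nb3 <- pop_j(st, "nhb3", karplus_params$nhb) + noise()
    ncl <- function(j)
      if (j >= thresholds$nhb_large) "large"
      else if (j <= thresholds$nhb_small) "small" else "medium"
    data.frame(res = i, j_hahb2 = j2, j_hahb3 = j3,
               nhb2_class = ncl(nb2), nhb3_class = ncl(nb3),
               overlap = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- states
  out
}

#' Perturbed copies of a model as a synthetic ensemble
#'
#' Generates `n_models` copies with isotropic Gaussian coordinate jitter
#' and, optionally, a rigid rotation of a designated helix segment about
#' its Calpha midpoint by an angle drawn from N(0, sd). The tilt is applied
#' about the axis perpendicular to the plane spanned by the helix axis and
#' a reference direction, so the angle to that reference changes by
#' exactly the drawn angle.
#'
#' @param model A model data frame.
#' @param n_models Number of models (>= 2).
#' @param coord_jitter_sd Per-coordinate Gaussian sd in Angstrom.
#' @param helix_jitter `NULL`, or a list with `residues` (segment to
#'   rotate), `sd` (degrees) and `reference` (unit 3-vector the tilt is
#'   measured against).
#' @param seed Integer seed (required).
#' @return An `"ensemble"`.
#' @export
perturb_ensemble <- function(model, n_models, coord_jitter_sd = 0,
                             helix_jitter = NULL, seed) {
  if (missing(seed)) stop("perturb_ensemble: seed is required")
  if (n_models < 2) stop("perturb_ensemble: need n_models >= 2")
  set.seed(seed)
  models <- lapply(seq_len(n_models), function(k) {
    m <- model
    if (!is.null(helix_jitter)) {
      hj <- helix_jitter
      idx <- m$resno %in% hj$residues
      axis <- fit_helix_axis(m, hj$residues)
      tilt_axis <- cross3(axis, hj$reference)
      nn <- sqrt(sum(tilt_axis^2))
      if (nn < 1e-8) {           # reference parallel to axis: any normal
        tilt_axis <- cross3(axis, if (abs(axis[1]) < 0.9) c(1, 0, 0)
                            else c(0, 1, 0))
        nn <- sqrt(sum(tilt_axis^2))
      }
      tilt_axis <- tilt_axis / nn
      ang <- stats::rnorm(1, 0, hj$sd) * pi / 180
      ca <- m[idx & m$atom == "CA", , drop = FALSE]
      center <- colMeans(coords(ca))
      rot <- rotation_about_axis(tilt_axis, ang)
      xyz <- coords(m[idx, , drop = FALSE])
      xyz <- sweep(sweep(xyz, 2, center) %*% t(rot), 2, center, `+`)
      m[idx, c("x", "y", "z")] <- xyz
    }
    if (coord_jitter_sd > 0) {
      m$x <- m$x + stats::rnorm(nrow(m), 0, coord_jitter_sd)
      m$y <- m$y + stats::rnorm(nrow(m), 0, coord_jitter_sd)
      m$z <- m$z + stats::rnorm(nrow(m), 0, coord_jitter_sd)
    }
    new_model(m)
  })
  new_ensemble(models, source_id = sprintf("synthetic(seed=%d)", seed))
}

rotation_about_axis <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}
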