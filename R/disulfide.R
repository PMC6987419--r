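## Cystine dihedral geometry and the spiral/hook/staple taxonomy.

#' Five dihedral angles of a cystine bridge
#'
#' chi1 = N-Ca-Cb-Sg of the lower-numbered cysteine, chi2 = Ca-Cb-Sg-Sg',
#' chi3 = Cb-Sg-Sg'-Cb', and the primed angles mirror chi2/chi1 on the
#' higher-numbered cysteine. Residue order is normalized to ascending
#' residue number regardless of the order given.
#'
#' @param model A model data frame containing both cysteines with N, CA,
#'   CB, SG atoms.
#' @param pair Integer pair of residue numbers.
#' @param model_index Optional index stored in the result.
#' @return Object of class `"disulfide_geometry"`: list with `pair`,
#'   `chi1`, `chi2`, `chi3`, `chi2p`, `chi1p` (degrees), `model_index`.
#' @export
cystine_dihedrals <- function(model, pair, model_index = NA_integer_) {
  pair <- sort(as.integer(pair))
  i <- pair[1]; j <- pair[2]
  p <- function(res, atom) atom_xyz(model, res, atom)
  structure(list(
    pair = pair,
    chi1 = dihedral(p(i, "N"), p(i, "CA"), p(i, "CB"), p(i, "SG")),
    chi2 = dihedral(p(i, "CA"), p(i, "CB"), p(i, "SG"), p(j, "SG")),
    chi3 = dihedral(p(i, "CB"), p(i, "SG"), p(j, "SG"), p(j, "CB")),
    chi2p = dihedral(p(j, "CA"), p(j, "CB"), p(j, "SG"), p(i, "SG")),
    chi1p = dihedral(p(j, "N"), p(j, "CA"), p(j, "CB"), p(j, "SG")),
    model_index = model_index), class = "disulfide_geometry")
}

disulfide_geometry <- function(chi1, chi2, chi3, chi2p, chi1p,
                               pair = c(1L, 2L),
                               model_index = NA_integer_) {
  pair <- as.integer(pair)
  if (pair[1] > pair[2]) {            # normalize residue order
    pair <- rev(pair)
    tmp <- chi1; chi1 <- chi1p; chi1p <- tmp
    tmp <- chi2; chi2 <- chi2p; chi2p <- tmp
  }
  structure(list(pair = pair, chi1 = wrap_angle(chi1),
                 chi2 = wrap_angle(chi2), chi3 = wrap_angle(chi3),
                 chi2p = wrap_angle(chi2p), chi1p = wrap_angle(chi1p),
                 model_index = model_index), class = "disulfide_geometry")
}

#' @export
print.disulfide_geometry <- function(x, ...) {
  cat(sprintf(
    "Cystine %d-%d: chi1 %7.1f  chi2 %7.1f  chi3 %7.1f  chi2' %7.1f  chi1' %7.1f\n",
    x$pair[1], x$pair[2], x$chi1, x$chi2, x$chi3, x$chi2p, x$chi1p))
  invisible(x)
}

## Sign-based shape rule, shipped as an editable table: the shape is set by
## how many of (chi2, chi2') share the sign of chi3 (2 = spiral, 1 = hook,
## 0 = staple).
disulfide_shape_table <- function() {
  c(`2` = "spiral", `1` = "hook", `0` = "staple")
}

#' Classify a disulfide into the spiral/hook/staple taxonomy
#'
#' The basic shape follows from the signs of (chi2, chi3, chi2'): when both
#' chi2 and chi2' share the sign of chi3 the bridge is a spiral, when
#' exactly one does it is a hook, when neither does it is a staple.
#' Handedness is right (RH) for chi3 > 0 and left (LH) for chi3 < 0. The
#' chi1/chi1' signs form the prefix, rendered "+" or "-" when equal; when
#' they differ the prefix is "+/-" for the swap-symmetric spiral and staple
#' shapes, while for the asymmetric hook the sign of the lower-numbered
#' (unprimed) cysteine is rendered first ("+/-" or "-/+"), giving the full
#' set of 20 types.
#'
#' @param geometry A `"disulfide_geometry"`.
#' @param borderline Angles within this many degrees of zero make the
#'   classification unreliable (default 1); such geometries return shape
#'   `"borderline"` rather than an error.
#' @return Object of class `"disulfide_class"`: list with `shape`,
#'   `handedness`, `chi1_signs`, `label`.
#' @export
classify_disulfide <- function(geometry, borderline = 1) {
  g <- geometry
  angs <- c(g$chi1, g$chi2, g$chi3, g$chi2p, g$chi1p)
  if (any(abs(angs) < borderline)) {
    return(structure(list(shape = "borderline", handedness = NA,
                          chi1_signs = NA, label = "borderline"),
                     class = "disulfide_class"))
  }
  sg <- function(x) if (x > 0) "+" else "-"
  s3 <- sg(g$chi3)
  n_agree <- sum(c(sg(g$chi2) == s3, sg(g$chi2p) == s3))
  shape <- disulfide_shape_table()[[as.character(n_agree)]]
  hand <- if (g$chi3 > 0) "RH" else "LH"
  s1 <- sg(g$chi1); s1p <- sg(g$chi1p)
  prefix <- if (s1 == s1p) s1
  else if (shape == "hook") paste0(s1, "/", s1p)
  else "+/-"
  structure(list(shape = shape, handedness = hand,
                 chi1_signs = c(s1, s1p),
                 label = paste0(prefix, hand, "-", shape)),
            class = "disulfide_class")
}

#' @export
print.disulfide_class <- function(x, ...) {
  cat(x$label, "\n")
  invisible(x)
}

#' Ideality of cystine dihedral angles
#'
#' Bins each angle into its energetically preferred window: chi1, chi2,
#' chi2', chi1' into gauche- (-90 to -30), gauche+ (30 to 90) or trans
#' (beyond +/-150, wrapping through 180), and chi3 into left (-120 to -60)
#' or right (60 to 120); anything else is "outside".
#'
#' @param geometry A `"disulfide_geometry"`.
#' @return Named character vector over chi1, chi2, chi3, chi2p, chi1p with
#'   attribute `"all_ideal"`.
#' @export
disulfide_ideality <- function(geometry) {
  side <- function(x) {
    if (x >= -90 && x <= -30) "gauche-"
    else if (x >= 30 && x <= 90) "gauche+"
    else if (abs(x) >= 150) "trans"
    else "outside"
  }
  bridge <- function(x) {
    if (x >= -120 && x <= -60) "left"
    else if (x >= 60 && x <= 120) "right"
    else "outside"
  }
  g <- geometry
  out <- c(chi1 = side(g$chi1), chi2 = side(g$chi2), chi3 = bridge(g$chi3),
           chi2p = side(g$chi2p), chi1p = side(g$chi1p))
  attr(out, "all_ideal") <- !any(out == "outside")
  out
}

#' Conformer census of disulfides across an ensemble
#'
#' Classifies every disulfide pair in every model and tabulates the labels,
#' flagging pairs whose classification is heterogeneous across the
#' ensemble.
#'
#' @param ensemble An ensemble.
#' @param pairs List of residue-number pairs; if `NULL`, located with
#'   [find_cystines()] on the first model.
#' @param borderline Passed to [classify_disulfide()].
#' @return Data frame with one row per (pair, label): columns `pair`,
#'   `label`, `count`, `heterogeneous`; the per-model detail is attached as
#'   attribute `"detail"`.
#' @export
disulfide_census <- function(ensemble, pairs = NULL, borderline = 1) {
  if (is.null(pairs)) pairs <- find_cystines(ensemble$models[[1]])
  if (length(pairs) == 0) stop("disulfide_census: no disulfides found")
  detail <- do.call(rbind, lapply(seq_along(ensemble$models), function(k) {
    do.call(rbind, lapply(pairs, function(p) {
      geo <- cystine_dihedrals(ensemble$models[[k]], p, model_index = k)
      cl <- classify_disulfide(geo, borderline)
      data.frame(model = k, pair = paste(geo$pair, collapse = "-"),
                 chi1 = geo$chi1, chi2 = geo$chi2, chi3 = geo$chi3,
                 chi2p = geo$chi2p, chi1p = geo$chi1p,
                 label = cl$label, stringsAsFactors = FALSE)
    }))
  }))
  census <- do.call(rbind, lapply(split(detail, detail$pair), function(d) {
    tab <- sort(table(d$label), decreasing = TRUE)
    data.frame(pair = d$pair[1], label = names(tab),
               count = as.integer(tab),
               heterogeneous = length(tab) > 1, stringsAsFactors = FALSE)
  }))
  rownames(census) <- NULL
  attr(census, "detail") <- detail
  census
}
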