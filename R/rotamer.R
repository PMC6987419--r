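## chi1 rotamer analysis from 3J couplings, NOE patterns and RDC sums.
##
## A chi1 call is a list of class "chi1_call" with fields: residue, rotamer
## (one of "-60", "+60", "180", "average", "undetermined",
## "ambiguous(-60|180)", "ambiguous(-60|+60)"), stereo (named character
## mapping the observed branches to HB2/HB3, or NULL), method, notes.

chi1_call <- function(residue, rotamer, stereo = NULL, method, notes = "") {
  structure(list(residue = residue, rotamer = rotamer, stereo = stereo,
                 method = method, notes = notes), class = "chi1_call")
}

#' @export
print.chi1_call <- function(x, ...) {
  st <- if (is.null(x$stereo)) "" else
    paste0(" [", paste(names(x$stereo), x$stereo, sep = "->",
                       collapse = ", "), "]")
  cat(sprintf("residue %s: chi1 = %s (%s)%s%s\n", x$residue, x$rotamer,
              x$method, st,
              if (nzchar(x$notes)) paste0(" - ", x$notes) else ""))
  invisible(x)
}

## Expected qualitative class 4-tuple (HaHb2, HaHb3, NHb2, NHb3) per
## staggered rotamer, derived from the staggered-geometry Karplus limits
## with the dihedral offsets of karplus_offsets(). Shipped as data so the
## table can be edited without code changes.
methylene_truth_table <- function() {
  tab <- rbind(
    `-60` = c("small", "small", "large", "small"),
    `180` = c("small", "large", "small", "small"),
    `+60` = c("large", "small", "small", "large"))
  colnames(tab) <- c("hahb2", "hahb3", "nhb2", "nhb3")
  tab
}

j_class <- function(j, thr) {
  ifelse(j >= thr$j_large, "large", ifelse(j <= thr$j_small, "small",
                                           "medium"))
}

#' Classify the chi1 rotamer of a beta-methylene residue
#'
#' Applies the characteristic-pattern analysis of 3J(HaHb) and qualitative
#' 3J(NHb) couplings. Couplings inside the 5.0-9.0 Hz averaging band, or a
#' "medium-medium" pair of NHb classes, indicate rotamer averaging;
#' otherwise the observed classes are matched against the staggered-rotamer
#' truth table under both possible stereo assignments of the two observed
#' branches. A "medium" observation is compatible with either expected
#' class; an observed small where large is expected (or vice versa) rejects
#' a candidate. A unique best match yields the rotamer and the
#' stereospecific HB2/HB3 assignment.
#'
#' @param jset One-row data frame with fields `res`, `j_hahb2`, `j_hahb3`
#'   (quantitative couplings of the two observed beta branches, Hz),
#'   `nhb2_class`, `nhb3_class` (each `"small"`, `"medium"`, `"large"` or
#'   `NA`) and optional logical `overlap`.
#' @param thresholds Threshold list, see [chi1_thresholds()].
#' @return A `"chi1_call"`.
#' @export
classify_methylene <- function(jset, thresholds = chi1_thresholds()) {
  thr <- thresholds
  res <- jset$res
  if (isTRUE(jset$overlap))
    return(chi1_call(res, "undetermined", method = "jcoupling",
                     notes = "overlapped Hbeta resonances"))
  j2 <- jset$j_hahb2
  j3 <- jset$j_hahb3
  n2 <- as.character(jset$nhb2_class)
  n3 <- as.character(jset$nhb3_class)
  have_j <- !is.null(j2) && !is.null(j3) && !is.na(j2) && !is.na(j3)
  have_n <- !is.na(n2) && !is.na(n3)
  if (!have_j && !have_n)
    stop("classify_methylene: need both HaHb couplings or both NHb classes")
  if (have_j &&
      ((j2 >= thr$avg_band[1] && j2 <= thr$avg_band[2]) ||
       (j3 >= thr$avg_band[1] && j3 <= thr$avg_band[2])))
    return(chi1_call(res, "average", method = "jcoupling",
                     notes = "3J(HaHb) inside 5.0-9.0 Hz averaging band"))
  if (have_n && n2 == "medium" && n3 == "medium")
    return(chi1_call(res, "average", method = "jcoupling",
                     notes = "medium-medium NHb pair"))
  obs <- c(hahb = NA, hahb_b2 = NA)
  cls_j <- if (have_j) c(j_class(j2, thr), j_class(j3, thr)) else
    c(NA, NA)
  cls_n <- if (have_n) c(n2, n3) else c(NA, NA)
  tab <- methylene_truth_table()
  compatible <- function(obs_cls, exp_cls) {
    is.na(obs_cls) | obs_cls == "medium" | obs_cls == exp_cls
  }
  cands <- list()
  for (swap in c(FALSE, TRUE)) {
    ## map observed branch (1, 2) onto (HB2, HB3) slots
    oj <- if (swap) rev(cls_j) else cls_j
    on <- if (swap) rev(cls_n) else cls_n
    o <- c(oj, on)
    for (rot in rownames(tab)) {
      e <- tab[rot, ]
      if (!all(compatible(o, e))) next
      ## exact matches score 1; an observed "medium" is a weak match, and
      ## weaker still where "large" was expected: trans couplings lie well
      ## above the medium band while gauche ones sit near the small/medium
      ## boundary, so a degraded large is stronger counter-evidence
      score <- sum((o == e) + 0.5 * (o == "medium" & e == "small") +
                     0.1 * (o == "medium" & e == "large"), na.rm = TRUE)
      cands[[length(cands) + 1]] <- list(rot = rot, swap = swap,
                                         score = score)
    }
  }
  if (length(cands) == 0)
    return(chi1_call(res, "undetermined", method = "jcoupling",
                     notes = "no staggered pattern matches"))
  scores <- vapply(cands, `[[`, numeric(1), "score")
  best <- cands[scores == max(scores)]
  rots <- unique(vapply(best, `[[`, character(1), "rot"))
  if (length(rots) > 1)
    return(chi1_call(res, "undetermined", method = "jcoupling",
                     notes = "pattern consistent with several rotamers"))
  swaps <- unique(vapply(best, `[[`, logical(1), "swap"))
  stereo <- NULL
  if (length(swaps) == 1) {
    stereo <- if (swaps) c(b1 = "HB3", b2 = "HB2") else
      c(b1 = "HB2", b2 = "HB3")
  }
  chi1_call(res, rots, stereo = stereo, method = "jcoupling")
}

#' Classify the chi1 rotamer of a beta-methine residue (Val, Ile, Thr)
#'
#' A single 3J(HaHb) coupling above the trans threshold (10 Hz; 9 Hz for
#' Thr because of the electronegative oxygen substituent) fixes the unique
#' rotamer with Ha trans to Hb; below 5 Hz the coupling is gauche,
#' consistent with the two remaining staggered rotamers; between, the
#' residue is classified as rotamer-averaged.
#'
#' @param j_hahb Observed 3J(HaHb) in Hz.
#' @param residue_type `"VAL"`, `"ILE"` or `"THR"`.
#' @param residue Residue identifier carried into the call.
#' @param thresholds Threshold list, see [chi1_thresholds()].
#' @return A `"chi1_call"`.
#' @export
classify_methine <- function(j_hahb, residue_type, residue = NA,
                             thresholds = chi1_thresholds()) {
  if (!residue_type %in% c("VAL", "ILE", "THR"))
    stop("classify_methine: residue type ", residue_type,
         " has no beta-methine proton")
  thr <- thresholds
  high <- if (residue_type == "THR") thr$methine_high_thr else
    thr$methine_high
  off <- karplus_offsets()$methine[[residue_type]]
  trans_rot <- wrap_angle(180 - off)           # chi1 with theta = 180
  gauche <- sort(wrap_angle(c(60, -60) - off))
  fmt <- function(x) ifelse(x > 0, paste0("+", x), as.character(x))
  if (j_hahb > high) {
    chi1_call(residue, fmt(trans_rot), method = "jcoupling",
              notes = sprintf("trans 3J(HaHb) = %.1f Hz", j_hahb))
  } else if (j_hahb < thr$methine_low) {
    chi1_call(residue,
              sprintf("ambiguous(%s|%s)", fmt(gauche[1]), fmt(gauche[2])),
              method = "jcoupling",
              notes = sprintf("gauche 3J(HaHb) = %.1f Hz", j_hahb))
  } else {
    chi1_call(residue, "average", method = "jcoupling",
              notes = sprintf("3J(HaHb) = %.1f Hz inside averaging band",
                              j_hahb))
  }
}

#' chi1 determination from scaled RDC sums
#'
#' Compares the observed summed beta-methylene RDC with three candidate
#' sums of backbone couplings, all placed on the common C-H scale: rule
#' \[1\] D(CaHa)_i + D(CaC')_i, rule \[2\] D(CaHa)_i + D(CaC')_{i-1}, rule
#' \[3\] D(CaC')_i + D(CaC')_{i-1}. Close agreement with rule \[1\], \[2\]
#' or \[3\] indicates chi1 = 180, +60 or -60 degrees respectively; because
#' the intra-residue Ca-N vector is only approximately parallel to the
#' preceding Ca-C' bond, a rule-\[3\] winner is reported as
#' `"ambiguous(-60|180)"`.
#'
#' @param residue Residue identifier.
#' @param d_sum_cbhb Observed summed Cb-Hb coupling (Hz, raw scale).
#' @param d_caha_i,d_cac_i,d_cac_prev Backbone couplings of the residue and
#'   its predecessor (Hz, raw scale).
#' @param constants Dipolar constants table used to compute the scale
#'   factors (nothing is hard-coded).
#' @param margin_floor Resolvability floor in Hz (default 2); if the best
#'   and second-best candidate differ by less, the call is undetermined.
#' @return A `"chi1_call"` with an `evidence` attribute (candidate sums,
#'   best rule and margin).
#' @export
chi1_from_rdc_sums <- function(residue, d_sum_cbhb, d_caha_i, d_cac_i,
                               d_cac_prev, constants = dipolar_constants(),
                               margin_floor = chi1_thresholds()$rdc_margin) {
  f <- constants$factor
  names(f) <- constants$type
  to_ch <- function(d, type) d * f[["SUM-CBHB"]] / f[[type]]
  ca_ha <- to_ch(d_caha_i, "CA-HA")
  ca_c_i <- to_ch(d_cac_i, "C-CA")
  ca_c_p <- to_ch(d_cac_prev, "C-CA")
  cand <- c(`1` = ca_ha + ca_c_i, `2` = ca_ha + ca_c_p,
            `3` = ca_c_i + ca_c_p)
  dev <- abs(d_sum_cbhb - cand)
  ord <- order(dev)
  best <- names(cand)[ord[1]]
  margin <- dev[ord[2]] - dev[ord[1]]
  evidence <- list(d_sum = d_sum_cbhb, candidates = cand,
                   best_rule = best, margin = as.numeric(margin))
  rot <- switch(best, `1` = "180", `2` = "+60", `3` = "ambiguous(-60|180)")
  call <- if (margin < margin_floor) {
    chi1_call(residue, "undetermined", method = "rdc_sum",
              notes = sprintf("margin %.2f Hz below %.2f Hz floor",
                              margin, margin_floor))
  } else {
    chi1_call(residue, rot, method = "rdc_sum",
              notes = sprintf("rule [%s], margin %.2f Hz", best, margin))
  }
  attr(call, "evidence") <- evidence
  call
}

#' Check a chi1 call against NOE intensity patterns
#'
#' Intra-residue Ha-Hb and HN-Hb NOE intensities reflect the corresponding
#' proton-proton distances: for a staggered rotamer a gauche-related pair
#' is close (strong NOE) and a trans-related pair distant (weak NOE). The
#' observed strong/medium/weak classes are compared with the pattern
#' expected for the called rotamer; equal-medium HN-Hb intensities are an
#' averaging signature and are inconsistent with a single-rotamer call.
#'
#' @param intensities Named list/vector with elements `hahb2`, `hahb3`,
#'   `hnhb2`, `hnhb3`, each `"strong"`, `"medium"`, `"weak"` or `NA`.
#' @param call A `"chi1_call"`.
#' @return `"consistent"`, `"inconsistent"` or `"unknown"`.
#' @export
noe_consistency <- function(intensities, call) {
  ii <- lapply(c("hahb2", "hahb3", "hnhb2", "hnhb3"), function(k)
    if (is.null(intensities[[k]])) NA_character_ else
      as.character(intensities[[k]]))
  names(ii) <- c("hahb2", "hahb3", "hnhb2", "hnhb3")
  if (all(is.na(unlist(ii)))) return("unknown")
  single <- call$rotamer %in% c("-60", "+60", "180")
  if (!single) return("unknown")
  if (!is.na(ii$hnhb2) && !is.na(ii$hnhb3) &&
      ii$hnhb2 == "medium" && ii$hnhb3 == "medium")
    return("inconsistent")
  off <- karplus_offsets()
  chi1 <- as.numeric(sub("\\+", "", call$rotamer))
  expected <- function(theta) {
    if (abs(wrap_angle(theta)) >= 150) "weak" else "strong"
  }
  exp_cls <- c(hahb2 = expected(chi1 + off$hahb2),
               hahb3 = expected(chi1 + off$hahb3),
               hnhb2 = expected(chi1 + off$nhb2),
               hnhb3 = expected(chi1 + off$nhb3))
  for (k in names(exp_cls)) {
    o <- ii[[k]]
    if (is.na(o) || o == "medium") next
    if (o != exp_cls[[k]]) return("inconsistent")
  }
  "consistent"
}

#' Karplus relation
#'
#' Evaluates \eqn{J(\theta) = A\cos^2(\theta) + B\cos(\theta) + C} at the
#' coupling dihedral implied by chi1 and the coupling kind: the
#' kind-specific stereochemical offset (see details in the package
#' vignette) is added to chi1 before evaluation.
#'
#' @param chi1 chi1 angle in degrees (or, for `kind = "raw"`, the coupling
#'   dihedral itself).
#' @param coefficients Numeric c(A, B, C).
#' @param kind One of `"hahb2"`, `"hahb3"`, `"nhb2"`, `"nhb3"`, `"raw"`.
#' @return Coupling in Hz.
#' @export
karplus <- function(chi1, coefficients, kind = "raw") {
  off <- switch(kind,
                raw = 0,
                hahb2 = karplus_offsets()$hahb2,
                hahb3 = karplus_offsets()$hahb3,
                nhb2 = karplus_offsets()$nhb2,
                nhb3 = karplus_offsets()$nhb3,
                stop("karplus: unknown kind ", kind))
  th <- (chi1 + off) * pi / 180
  coefficients[1] * cos(th)^2 + coefficients[2] * cos(th) + coefficients[3]
}

#' Read a J-coupling table (TSV)
#'
#' Expects columns
#' `res type j_hahb2 j_hahb3 j_hahb nhb2_class nhb3_class overlap`.
#' @param path File path.
#' @return Data frame.
#' @export
read_jcoupling_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
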