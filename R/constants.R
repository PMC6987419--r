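## Physical constants for dipolar couplings.
## Gyromagnetic ratios in 1e7 rad s^-1 T^-1; effective bond lengths in
## Angstrom are the vibrationally corrected values conventional in RDC work.
.gamma <- c(H = 26.7522128, C = 6.728284, N = -2.71261804)

#' Dipolar constants and normalization factors
#'
#' Returns the table of dipolar interaction constants used to place all RDC
#' types on a common scale. The maximal static dipolar coupling for a spin
#' pair is proportional to \eqn{\gamma_i \gamma_j / r^3}; every coupling
#' type is normalized to the one-bond N-HN coupling, i.e. the factor is
#' \eqn{|\gamma_i\gamma_j|/r^3} divided by the same quantity for N-HN. By
#' construction the N-HN factor is exactly 1. The summed beta-methylene
#' coupling (type `"SUM-CBHB"`) uses the per-proton C-H constant; the sum
#' over the two protons is handled where design rows are built.
#'
#' @param r_nh,r_ch,r_cc,r_nc Effective internuclear distances in Angstrom
#'   (defaults: 1.041, 1.117, 1.526, 1.329).
#' @return Data frame with columns `type`, `gamma_i`, `gamma_j`, `r`,
#'   `factor`.
#' @examples
#' dipolar_constants()
#' @export
dipolar_constants <- function(r_nh = 1.041, r_ch = 1.117, r_cc = 1.526,
                              r_nc = 1.329) {
  tab <- data.frame(
    type = c("N-HN", "CA-HA", "C-CA", "N-C", "SUM-CBHB"),
    gamma_i = c("N", "C", "C", "N", "C"),
    gamma_j = c("H", "H", "C", "C", "H"),
    r = c(r_nh, r_ch, r_cc, r_nc, r_ch),
    stringsAsFactors = FALSE)
  ref <- abs(.gamma["N"] * .gamma["H"]) / r_nh^3
  tab$factor <- abs(.gamma[tab$gamma_i] * .gamma[tab$gamma_j]) / tab$r^3 / ref
  rownames(tab) <- tab$type
  tab
}

#' Maximal N-H dipolar interaction constant
#'
#' The prefactor \eqn{-\mu_0 h \gamma_N \gamma_H / (16 \pi^3 r^3)} in Hz for
#' the reference N-HN pair; used to express the fitted alignment tensor as a
#' dimensionless Saupe order matrix. For r = 1.041 Angstrom this is about
#' 10.8 kHz (so the full static splitting at perfect alignment is ~21.7 kHz).
#'
#' @param r_nh Effective N-H distance in Angstrom.
#' @return Magnitude of the constant in Hz.
#' @export
dmax_nh <- function(r_nh = 1.041) {
  mu0 <- 4 * pi * 1e-7
  h <- 6.62607015e-34
  gh <- .gamma[["H"]] * 1e7
  gn <- abs(.gamma[["N"]]) * 1e7
  mu0 * h * gh * gn / (16 * pi^3 * (r_nh * 1e-10)^3)
}

## Ideal covalent geometry for the internal-coordinate builders
## (Engh-Huber-like values; shipped as a config table).
geometry_defaults <- function() {
  list(
    b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
    b_ca_cb = 1.530, b_ca_ha = 1.090, b_n_h = 1.020, b_cb_hb = 1.090,
    b_cb_sg = 1.808, b_s_s = 2.050, b_cb_cg = 1.530, b_cb_og = 1.417,
    a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
    a_ca_c_o = 120.8, a_c_n_h = 119.0,
    a_n_ca_cb = 110.4, a_n_ca_ha = 108.0, a_cb_ca_c = 110.1,
    a_ca_cb_x = 114.0, a_ca_cb_h = 109.5,
    a_cb_s_s = 104.0, a_s_s_cb = 104.0, a_s_cb_ca = 114.0,
    ## impropers fixed against ideal L-residue templates: looking down
    ## Calpha->Cbeta, Halpha sits at N+120 and C' at N-120; on Cbeta,
    ## Hbeta2 sits at (chi1-defining atom)-120 and Hbeta3 at +120.
    imp_c_n_ca_cb = 120.0, imp_c_n_ca_ha = -120.0,
    off_hb2 = -120.0, off_hb3 = 120.0)
}

## chi1-defining gamma heavy atom per residue type (3-letter code)
.gamma_atom <- c(ALA = NA, GLY = NA, CYS = "SG", SER = "OG", THR = "OG1",
                 VAL = "CG1", ILE = "CG1")

## Karplus dihedral offsets: theta = chi1 + offset, from ideal L-residue
## stereochemistry. Methylene offsets are residue-independent; methine
## offsets depend on the Cbeta configuration.
karplus_offsets <- function() {
  list(hahb2 = 120, hahb3 = 0, nhb2 = -120, nhb3 = 120,
       methine = c(VAL = 0, ILE = 120, THR = 120))
}

#' Default Karplus coefficients
#'
#' Coefficients (A, B, C) of \eqn{J(\theta) = A\cos^2\theta + B\cos\theta +
#' C} for the 3J(HaHb) and 3J(NHb) couplings. These are configuration
#' defaults for the synthetic generator and the qualitative class cutoffs,
#' chosen so that the trans/gauche limits (about 12.9 / 3.4 Hz for HaHb and
#' 4.1 / 0.9 Hz for NHb) reproduce the usual pattern analysis.
#'
#' @return Named list with elements `hahb` and `nhb`, each c(A, B, C).
#' @export
karplus_coefficients <- function() {
  list(hahb = c(A = 9.5, B = -1.6, C = 1.8),
       nhb = c(A = 3.1, B = -0.6, C = 0.4))
}

#' Thresholds for chi1 classification
#'
#' Quantitative-to-qualitative cutoffs used by the rotamer classifiers.
#' `j_large`/`j_small` bound the large/small classes of 3J(HaHb) (>= 10 Hz /
#' <= 5 Hz); `avg_band` is the 5.0-9.0 Hz motional-averaging band;
#' `methine_high` is the trans threshold for beta-methine residues (10 Hz,
#' lowered to `methine_high_thr` = 9 Hz for Thr because of the
#' electronegative oxygen substituent); `nhb_large`/`nhb_small` classify the
#' qualitative 3J(NHb) couplings; `rdc_margin` is the resolvability floor
#' (Hz) for the RDC-sum rule comparison.
#'
#' @return Named list of thresholds.
#' @export
chi1_thresholds <- function() {
  list(j_large = 10, j_small = 5, avg_band = c(5, 9),
       methine_high = 10, methine_high_thr = 9, methine_low = 5,
       nhb_large = 3, nhb_small = 1.5, rdc_margin = 2)
}
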