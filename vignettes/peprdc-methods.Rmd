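---
title: "Assessing peptide NMR structures with RDCs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing peptide NMR structures with RDCs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peprdc)
set.seed(1)
```

## The problem

Disulfide-rich peptides are mostly solved by solution NMR, and their
ensembles are often reported with sub-Angstrom precision. Precision is not
accuracy: short-range NOE restraints define local geometry very well but
say little about how helices are oriented relative to one another, and the
NMR-silent sulfur atoms hide three of the five dihedral angles of every
cystine bridge. Residual dipolar couplings (RDCs) measure bond-vector
orientations against a global molecular alignment frame and therefore
report exactly the long-range information that NOEs miss. `peprdc`
implements the analysis layer of this programme: fitting alignment tensors
to coordinate ensembles, scoring structures with Q and cross-validated
Q(free), determining side-chain chi1 rotamers from scalar couplings and
RDC sums, classifying disulfide geometry, quantifying inter-helix angular
spread, and inferring disulfide connectivity from Cbeta-Cbeta distances.

## Alignment tensor and Q

For a unit internuclear vector $v$ the residual dipolar coupling is a
quadratic form in the Saupe order matrix $S$ (symmetric, traceless, five
independent elements):

$$ D = D_{max}\, v^{T} S\, v . $$

The package works with the interaction tensor $T$ expressed in Hz on the
N-H^N scale; every other coupling type is related to it by the ratio of
dipolar constants $\gamma_i\gamma_j/r^3$ (see `dipolar_constants()`;
defaults $r_{NH} = 1.041$, $r_{CH} = 1.117$, $r_{CC} = 1.526$,
$r_{NC'} = 1.329$ angstrom — conventional vibrationally corrected values,
overridable because different labs use slightly different sets). Given at
least five couplings in one medium, the five tensor elements are solved by
singular value decomposition of the design matrix (`fit_tensor()`),
returning the minimum-norm least-squares solution; a condition number
above 1e8 triggers a degenerate-geometry warning. Axial magnitude and
rhombicity come from the eigenvalues ordered by magnitude
($D_a = t_{zz}/2$, $R = 2(t_{xx}-t_{yy})/(3 t_{zz})$, so $0 \le R \le
2/3$). Fits are always per medium: different alignment media produce
different tensors. Agreement is scored with the quality factor

$$ Q = \frac{\mathrm{rms}(D_{calc}-D_{obs})}{\mathrm{rms}(D_{obs})}, $$

with $\mathrm{rms}(x)=\sqrt{\mathrm{mean}(x^2)}$. Lower is better; $Q=0$
is perfect agreement and back-calculating zeros gives exactly $Q=1$. For
ensembles each model is fitted independently and the mean and spread of Q
are reported — whether published Q values refer to the best model or the
ensemble mean is often unstated, so both are available.

The summed beta-methylene coupling $D_{C\beta H\beta2}+D_{C\beta H\beta3}$
is handled as a first-class coupling type whose design row is the sum of
the two single-proton rows; it is normalized by the single C-H dipolar
constant.

Least squares is unweighted by default (`weights = "sigma"` enables
$1/\sigma^2$ weighting) because published RDC fits rarely state a
weighting and the couplings within one experiment have similar errors.

## Cross-validation: Q(free)

Q computed on the data used in fitting is biased by overfitting.
`make_cv_plan()` builds a stratified partition: within every experiment
(a coupling type in one medium) the records are randomly split into ten
disjoint held-out sets, so each RDC is left out exactly once and every
round omits about 10% of each experiment. `q_free()` then, per round,
optionally refines the structure against the working set (the refiner is
an injected function; the default identity refiner uses the structure
as-is), fits the tensor on the working records, back-calculates the
held-out ones and computes Q on those only.

With the identity refiner the expected noise floor can be written in
closed form: if the couplings carry independent Gaussian noise of sd
$\sigma$ and the structure is exact, the held-out residual variance is
$\sigma^2 (1 + p/n_{work})$ with $p = 5$ fitted parameters per medium, so

$$ \mathbb{E}[Q_{free}] \approx \frac{\sigma \sqrt{1 + 5/n_{work}}}
   {\mathrm{rms}(D_{obs})} \xrightarrow{n \to \infty}
   \frac{\sigma}{\mathrm{rms}(D_{obs})} . $$

A $\sqrt{2}$-inflated floor would arise only if the refiner absorbed the
working-set noise into the coordinates (an exactly interpolating refiner,
which adds an independent $\sigma$ of structure noise to the held-out
back-calculation); with the identity refiner the Monte-Carlo tests
reproduce the $\sigma$ floor within a few percent. This distinction is
asserted in the unit tests and is worth keeping in mind when comparing
published Q(free) values obtained with full restrained-refinement
pipelines, which sit between the two regimes.

## chi1 rotamers and stereospecific assignments

Three staggered chi1 rotamers (-60, +60, 180 degrees) dominate side-chain
conformation. The three-bond couplings across the Calpha-Cbeta bond have
characteristic patterns for each rotamer. The dihedral offsets used
throughout the package were fixed against ideal L-residue templates:

| coupling | dihedral |
|---|---|
| 3J(Ha-Hb2) | chi1 + 120 |
| 3J(Ha-Hb3) | chi1 |
| 3J(N-Hb2)  | chi1 - 120 |
| 3J(N-Hb3)  | chi1 + 120 |

so the expected qualitative classes (large = trans >= 10 Hz, small =
gauche <= 5 Hz for HaHb) are: chi1 = -60: (small, small) with one large
N-Hb; chi1 = 180: one large HaHb, both N-Hb small; chi1 = +60: the other
HaHb large plus one large N-Hb. `classify_methylene()` matches the
observed classes under both possible stereo assignments of the two
observed beta branches; a unique best match yields the rotamer *and* the
Hb2/Hb3 assignment. Couplings inside 5.0-9.0 Hz, or a "medium-medium"
N-Hb pair, indicate motional averaging and return `"average"` with no
stereo claim; overlapped beta resonances return `"undetermined"`. A
"medium" observation is a wildcard, but an expected *large* degraded to
medium is penalized more than an expected small, because the trans N-Hb
coupling (about 4 Hz with the default Karplus coefficients) lies well
above the class boundary while the gauche one (about 0.9 Hz) sits near
it; this asymmetry resolves most class-level ties without extra data.

Beta-methine residues (Val, Ile, Thr) have one coupling: above the trans
threshold (10 Hz, 9 Hz for Thr — the electronegative oxygen substituent
lowers the Karplus curve) it fixes the single rotamer with Ha trans to
Hb; below 5 Hz it is gauche, which is consistent with two staggered
rotamers, so the call is reported as an explicit two-state ambiguity
(e.g. `"ambiguous(-60|+60)"`) rather than a fabricated unique angle;
between the thresholds the residue is classified as averaged.

RDC sums give an independent route: assuming staggered geometry, the two
Cbeta-Hbeta bonds are parallel to pairs of backbone bonds, so the summed
methylene RDC should match one of three candidate sums (all scaled to the
C-H dipolar constant): [1] D(CaHa)_i + D(CaC')_i for chi1 = 180,
[2] D(CaHa)_i + D(CaC')_{i-1} for +60, [3] D(CaC')_i + D(CaC')_{i-1} for
-60. Rule [3] winners are reported as `"ambiguous(-60|180)"` because the
intra-residue Ca-N bond is only approximately parallel to the preceding
Ca-C' bond (about 6 degrees off in ideal geometry). Two caveats are
deliberate design features: a resolvability floor (default 2 Hz) below
which the call is `"undetermined"`, and the documented fact that a single
scalar comparison can coincidentally favour a wrong rule under some
tensor orientations (a few percent of random orientations even for exact
geometry). The method is a complement to the J-coupling analysis, not a
replacement — which is how it is used in practice.

NOE intensity patterns provide a consistency check
(`noe_consistency()`): gauche-related proton pairs are close (strong
NOE), trans pairs distant (weak), and equal-medium HN-Hb intensities are
an averaging signature that vetoes a single-rotamer call. Missing data
yields `"unknown"`, which is distinct from `"inconsistent"`.

## Disulfide geometry

A cystine bridge has five torsions chi1, chi2, chi3, chi2', chi1'. The
shape taxonomy follows the sign pattern of (chi2, chi3, chi2'): both
outer angles sharing the sign of chi3 is a *spiral*, exactly one a
*hook*, neither a *staple*; chi3 > 0 is right-handed (RH), chi3 < 0
left-handed (LH). The chi1/chi1' signs form a prefix. Spiral and staple
are symmetric under exchanging the two cysteines, so a mixed prefix is
rendered "+/-"; the hook is not symmetric (one specific cysteine carries
the chi3-like chi2), so "+/-" and "-/+" hooks are distinct, and the sign
of the lower-numbered cysteine is rendered first. This yields exactly 20
types (6 spirals + 6 staples + 8 hooks), and the partition test in the
suite confirms every non-degenerate sign pattern maps to exactly one
label. The sign table is shipped as data (`disulfide_shape_table()`) so
the reconstruction can be corrected without touching code. Angles within
1 degree of zero (configurable) make the classification unreliable and
return a `"borderline"` result instead of guessing.

Ideality windows follow the energetic minima: chi1/chi2/chi2'/chi1' in
gauche- (-90 to -30), gauche+ (30 to 90) or trans (beyond 150, wrapping
through 180); chi3 in left (-120 to -60) or right (60 to 120). Everything
else is "outside". `disulfide_census()` classifies every bridge in every
model of an ensemble and flags conformational heterogeneity.

## Helix vectors

Each helix is represented by an axis vector fitted to its Calpha atoms.
The default estimator is the bisector construction: at each interior
residue the bisector of the two flanking virtual bonds points at the
helix axis, and cross products of consecutive bisectors lie along the
axis; averaging them is exact for an ideal helix of any length. A raw
principal-component fit (`method = "pca"`) is also available but is
biased by up to about 10 degrees for 4-6 residue helices that cover a
partial turn, which is why it is not the default: short helices are
exactly the interesting case in peptides. Inter-helix angles are computed
per model against a reference helix and summarized as mean and sd across
the ensemble. The practical significance of an angular spread is made
tangible by the chord relation `tip_displacement(length, angle)` =
$2 L \sin(\theta/2)$: a 6 degree reorientation of a 10 angstrom helix
moves its tip by about 1 angstrom — invisible to local RMSD statistics.

## Disulfide connectivity

Across high-resolution structures, bonded cystine pairs show a tight
Cbeta-Cbeta distance distribution (mean near 3.8 angstrom, sd below 0.2,
essentially all below 5), while non-bonded cysteine pairs only
occasionally fall under 5 angstrom. `infer_connectivity()` therefore
scores every perfect matching of the cysteines by its mean Cbeta-Cbeta
distance on the ensemble-averaged distance matrix and returns the
minimum, with the margin to the second-best matching and any pairs at or
beyond 5 angstrom flagged as violations. Enumeration is exhaustive —
with 2n cysteines there are (2n-1)!! matchings, at most 10395 for 12
cysteines, so no heuristic is needed; ties are broken lexicographically
and flagged. `survey_cb_distances()` reproduces the database-survey
statistics behind the rule (resolution < 1.5 angstrom, molecular weight
< 50 kDa); exact sequence-duplicate removal stands in for
identity-clustering (this shifts counts, not the distance mean), and the
published single-outlier removal is generalized to an optional |z| > 10
filter, logged when applied.

## The synthetic world

Every input has a generator, so the whole pipeline is testable without
downloads; the generators are seed-deterministic and their defaults state
the world the tests live in:

* **Geometry**: `build_peptide()`/`build_cystine()` build chains atom by
  atom from internal coordinates with ideal bond lengths and angles
  (Engh-Huber-like table in `geometry_defaults()`), hydrogens included,
  and reproduce requested torsions to below 1e-6 degrees. Chirality and
  beta-proton naming were fixed against ideal L-residue templates, so
  simulated J-patterns carry the correct Hb2/Hb3 labels.
* **RDCs**: `simulate_rdcs()` back-calculates exactly from a known tensor
  and adds Gaussian noise. The default experiment layout mirrors a
  realistic backbone RDC study: four backbone coupling types in each of
  two media plus the summed methylene coupling in one medium — the same
  stratification the Q(free) machinery expects. Default tensor magnitudes
  (Da around 10 Hz, R around 0.3) and noise (1 Hz) match routine
  peptide-alignment conditions.
* **J-couplings**: `simulate_jcouplings()` uses the Karplus coefficients
  in `karplus_coefficients()` (trans/gauche limits 12.9/3.4 Hz for HaHb,
  4.1/0.9 Hz for NHb) with 0.5 Hz noise, and supports rotamer mixtures
  through population-weighted averages.
* **Ensembles**: `perturb_ensemble()` adds isotropic coordinate jitter
  and/or rigid helix tilts drawn from N(0, sd), with the tilt axis chosen
  in the plane of the helix and reference axes so the generated angular
  sd is exactly the parameter being recovered.

What the generators do *not* emulate: anisotropic coordinate
uncertainty, correlated noise between coupling types, conformational
exchange beyond two-state chi1 mixtures, and real refinement dynamics. A
green test therefore establishes the correctness of the analysis
machinery, not the accuracy of any particular experimental structure.

## Numerical choices

* Dihedrals live in (-180, 180]; collinear reference frames raise an
  error rather than returning a silent value.
* The SVD solve discards singular values below 1e-12 of the largest
  (minimum-norm solution); the normal-equations route is used only as a
  test oracle.
* Superposition uses the Kabsch SVD construction with the determinant
  sign correction, so reflections are never returned.
* Ensemble precision defaults to the mean pairwise RMSD over all model
  pairs (superposing each pair on the selection first); the RMSD to the
  iteratively superposed mean is available as `method = "to_mean"` and is
  systematically smaller by roughly $\sqrt{2}$.
* Models missing atoms relative to the rest of an ensemble are reduced to
  the common atom set with a warning; hydrogens required by an analysis
  but absent raise an explicit error instead of being rebuilt silently.
* Random choices (cross-validation plans, generators) take an explicit
  integer seed; there is no hidden global state.

## Limitations

The package deliberately stops at analysis: no RDC-restrained refinement
(the Q(free) harness accepts any refiner as a function), no prediction of
alignment tensors from molecular shape or charge, no
secondary-structure assignment (helix ranges are inputs), and no
strain-energy model for disulfides. Free cysteines are out of scope for
connectivity inference (the cysteine count must be even).
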