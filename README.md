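# peprdc

Residual dipolar coupling (RDC) quality analysis and disulfide geometry
for peptide NMR ensembles.

## What this is for

Solution NMR routinely delivers disulfide-rich peptide ensembles with
sub-Angstrom precision, but precision is driven by short-range NOE
restraints and says little about two things that matter most in these
molecules: how the helices are oriented relative to one another, and what
the cystine bridges actually look like (the NMR-silent sulfur atoms hide
three of the five bridge dihedrals). RDCs measure bond-vector orientation
against a global alignment frame and expose exactly these blind spots.

`peprdc` is aimed at structural NMR spectroscopists who want to:

* fit the Saupe alignment tensor to a structure or ensemble by SVD and
  score the agreement with the quality factor
  `Q = rms(Dcalc - Dobs) / rms(Dobs)`;
* cross-validate with **Q(free)** — each RDC held out exactly once over
  stratified rounds, with a pluggable refiner;
* determine **chi1 rotamers** and stereospecific Hb2/Hb3 assignments from
  3J(HaHb)/3J(NHb) patterns, NOE consistency, and scaled RDC sums;
* classify disulfides into the 20-type **spiral / hook / staple**
  taxonomy with handedness (sign of chi3) and chi1-sign prefixes, plus
  ideality windows and per-ensemble conformer censuses;
* quantify **inter-helix angles** and their spread across an ensemble
  (a 6 degree tilt of a 10 A helix moves its tip by ~1 A);
* infer **disulfide connectivity** by exhaustive minimisation of
  Cbeta-Cbeta distances over all perfect matchings of the cysteines.

A synthetic-data module (idealised peptide/cystine builders, RDC and
J-coupling simulators, perturbed ensembles) generates every input the
pipeline consumes, so the full analysis is testable offline.

## Worked example

Simulate a study on an idealised helical Ala/Cys peptide, fit the tensor,
cross-validate, and classify a cystine bridge:

```r
library(peprdc)
set.seed(7)
n <- 30
pep <- build_peptide(paste(rep(c("A", "C"), n / 2), collapse = ""),
                     rep(-57, n), rep(-47, n),
                     chi1 = ifelse(seq_len(n) %% 2 == 0, -60, NA))
tensor <- make_tensor(Da = 10, R = 0.3, euler = c(20, 50, 80))
rdc <- simulate_rdcs(pep, tensor, records = rdc_template(pep, media = "pf1"),
                     noise_sd = 1, seed = 7)
fit_tensor(pep, rdc)
#> Alignment tensor: Da = 9.912 Hz (N-HN scale), R = 0.304
#>   Euler (ZYZ): -160.8, 129.6, -79.4 deg
#> Q = 0.0833 over 148 RDCs (rms obs 10.897 Hz, rms resid 0.908 Hz)
#>   C-CA      n =  30  Q = 0.5974
#>   CA-HA     n =  30  Q = 0.0640
#>   N-C       n =  29  Q = 0.5606
#>   N-HN      n =  29  Q = 0.0739
#>   SUM-CBHB  n =  30  Q = 0.0579

q_free(make_cv_plan(rdc, fraction = 0.10, n_rounds = 10, seed = 8),
       rdc, pep)
#> Q(free) = 0.0925 +/- 0.0284 over 10 rounds

geo <- cystine_dihedrals(build_cystine(c(-60, -60, -85, -60, -60),
                                       pair = c(23, 33)), c(23, 33))
classify_disulfide(geo)
#> -LH-spiral
```

Reading the numbers: the fitted tensor recovers the generating Da = 10 Hz
and R = 0.3 within the 1 Hz noise; the overall Q of 0.083 is dominated by
the well-measured one-bond C-H and N-H couplings, while the small-constant
C-CA and N-C types are individually noisier (per-type Q near 0.6 at this
noise level — their couplings are ~5-10x smaller in Hz). Q(free) of 0.093
sits at the expected noise floor `sigma / rms(Dobs) = 1/10.9`, i.e. the
structure explains the held-out data down to measurement noise. The
cystine with all five torsions near gauche-/left minima is a left-handed
spiral with negative chi1 on both cysteines: `-LH-spiral`.

Other entry points: `read_ensemble()` (multi-model PDB/mmCIF),
`ensemble_precision()`, `classify_methylene()` / `classify_methine()` /
`chi1_from_rdc_sums()`, `interhelix_angles()`, `infer_connectivity()`,
`survey_cb_distances()`, `disulfide_census()`. A thin command-line
wrapper over these functions ships at `inst/cli/peprdc.R`. The methods
vignette (`vignettes/peprdc-methods.Rmd`) documents the models,
thresholds, design decisions and limitations.

## Acceptance script

`scripts/acceptance.R` exercises the whole pipeline end-to-end against
the installed package: it builds a synthetic helical disulfide-rich
peptide, simulates two-medium RDC data, fits per-medium tensors and
reports Q, runs the Q(free) cross-validation, classifies simulated
J-couplings into chi1 rotamers, classifies a three-bridge disulfide set,
infers connectivity from jittered Cbeta positions, and measures
inter-helix angular spread. Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Progress and results are printed to stderr; the JSON report is written to
`--out`.
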