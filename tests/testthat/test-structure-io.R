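test_that("dihedral matches planar limits, the atan2 oracle, and mirror symmetry", {
  ## planar cis / trans
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, 1, 1)), 0)
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(-1, -1, 1)),
               180)
  set.seed(101)
  for (k in 1:1000) {
    p <- matrix(stats::rnorm(12), 4, 3)
    if (inherits(try(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                     silent = TRUE), "try-error")) next
    d <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(d, oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
    ## mirroring (negating one axis) negates the torsion
    m <- p %*% diag(c(1, 1, -1))
    expect_equal(dihedral(m[1, ], m[2, ], m[3, ], m[4, ]),
                 -d, tolerance = 1e-9)
  }
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "coincide")
})

test_that("superpose is exact on trivial cases and agrees with the quaternion oracle", {
  m <- make_test_peptide(10)
  s_self <- superpose(m, m)
  expect_equal(s_self$rmsd, 0, tolerance = 1e-9)
  expect_equal(s_self$rotation, diag(3), tolerance = 1e-8)
  ## translation invariance
  mt <- m
  mt$x <- mt$x + 11.5; mt$y <- mt$y - 3; mt$z <- mt$z + 0.25
  expect_equal(superpose(m, mt)$rmsd, 0, tolerance = 1e-9)
  ## symmetry of the rmsd
  set.seed(7)
  m2 <- rigid_transform_model(m)
  m2$x <- m2$x + stats::rnorm(nrow(m2), 0, 0.3)
  expect_equal(superpose(m, m2)$rmsd, superpose(m2, m)$rmsd,
               tolerance = 1e-9)
  ## one displaced atom: rmsd ~ sqrt(1/n), checked against the quaternion
  ## oracle exactly and the closed form approximately
  sel <- list(atoms = "backbone")
  for (k in 1:20) {
    mb <- rigid_transform_model(m)
    i <- sample(which(mb$atom == "CA"), 1)
    mb$x[i] <- mb$x[i] + 1
    s <- superpose(m, mb, sel)
    n <- length(s$selection)
    xa <- coords(select_atoms(m, sel))
    xb <- coords(select_atoms(mb, sel))
    expect_equal(s$rmsd, oracle_superpose_rmsd(xa, xb), tolerance = 1e-9)
    ## the refit absorbs a little of the displacement, so the closed form
    ## sqrt(1/n) is an upper bound reached within ~10%
    expect_equal(s$rmsd, sqrt(1 / n), tolerance = 0.10)
    expect_lte(s$rmsd, sqrt(1 / n) + 1e-12)
  }
  expect_error(superpose(m[1:2, ], m[1:2, ]), "fewer than 3")
})

test_that("PDB write/read round-trips ensembles and honours SSBOND fallback", {
  m1 <- build_cystine(c(-60, -60, -85, -60, -60), pair = c(7, 37))
  m2 <- build_cystine(c(60, 60, 85, 60, 60), pair = c(7, 37))
  ens <- structure(list(models = list(m1, m2), source_id = "syn"),
                   class = "ensemble")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, path, ssbonds = list(c(7, 37)))
  rd <- read_ensemble(path)
  expect_length(rd$models, 2)
  expect_identical(rd$models[[1]]$atom, m1$atom)
  expect_equal(coords(rd$models[[1]]), coords(m1), tolerance = 2e-3)
  expect_equal(attr(rd, "ssbonds")[[1]], c(7, 37))
  ## SG-based cystine location
  expect_equal(find_cystines(rd$models[[1]]), list(c(7, 37)))
  ## SSBOND fallback when SG atoms are stripped
  nosg <- rd$models[[1]][rd$models[[1]]$atom != "SG", ]
  expect_equal(find_cystines(nosg, ssbonds = attr(rd, "ssbonds")),
               list(c(7, 37)))
})

test_that("models with mismatched atom sets are intersected with a warning", {
  m1 <- make_test_peptide(6)
  m2 <- m1[-5, ]
  ens <- structure(list(models = list(m1, m2), source_id = "syn"),
                   class = "ensemble")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, path)
  expect_warning(rd <- read_ensemble(path), "common atoms")
  expect_length(rd$models, 2)
  expect_equal(nrow(rd$models[[1]]), nrow(m1) - 1)
  expect_identical(rd$models[[1]]$atom, rd$models[[2]]$atom)
})

test_that("the mmCIF reader agrees with the PDB reader", {
  m <- build_cystine(c(-60, -60, -85, -60, -60))
  path <- withr::local_tempfile(fileext = ".cif")
  hdr <- c("data_synthetic", "#", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                   "auth_atom_id", "auth_comp_id",
                                   "auth_asym_id", "auth_seq_id",
                                   "Cartn_x", "Cartn_y", "Cartn_z",
                                   "pdbx_PDB_model_num")))
  body <- sprintf("ATOM %d %s %s %s %s %d %.3f %.3f %.3f 1",
                  seq_len(nrow(m)), m$element, m$atom, m$resname, m$chain,
                  m$resno, m$x, m$y, m$z)
  writeLines(c(hdr, body, "#"), path)
  rd <- read_ensemble(path)
  expect_length(rd$models, 1)
  expect_equal(coords(rd$models[[1]]), coords(m), tolerance = 2e-3)
  expect_identical(rd$models[[1]]$atom, m$atom)
})

test_that("legacy HB1/HB2 methylene names are remapped to HB2/HB3", {
  m <- build_cystine(c(-60, -60, -85, -60, -60))
  old_hb2 <- atom_xyz(m, 1, "HB2")
  old_hb3 <- atom_xyz(m, 1, "HB3")
  legacy <- m
  legacy$atom[legacy$resno == 1 & legacy$atom == "HB3"] <- "HB1"
  ## legacy convention: HB1 ~ new HB2, HB2 ~ new HB3
  legacy$atom[legacy$resno == 1 & legacy$atom == "HB2"] <- "HBX"
  legacy$atom[legacy$resno == 1 & legacy$atom == "HB1"] <- "HB2"
  legacy$atom[legacy$resno == 1 & legacy$atom == "HBX"] <- "HB1"
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(legacy, path)
  expect_message(rd <- read_ensemble(path), "HB1/HB2")
  ## remap restores the IUPAC labels: file HB1 was IUPAC HB2, file HB2
  ## was IUPAC HB3
  m1 <- rd$models[[1]]
  expect_equal(atom_xyz(m1, 1, "HB2"), old_hb2, tolerance = 2e-3)
  expect_equal(atom_xyz(m1, 1, "HB3"), old_hb3, tolerance = 2e-3)
})

test_that("ensemble_precision matches the brute-force pairwise oracle and closed form", {
  base <- make_test_peptide(12)
  ## identical models
  ens0 <- structure(list(models = list(base, base, base), source_id = ""),
                    class = "ensemble")
  expect_equal(as.numeric(ensemble_precision(ens0)), 0, tolerance = 1e-9)
  ## jittered ensemble vs direct pairwise computation
  sigma <- 0.2
  ens <- perturb_ensemble(base, 10, coord_jitter_sd = sigma, seed = 21)
  prec <- ensemble_precision(ens, list(atoms = "heavy"))
  sels <- lapply(ens$models, function(m)
    coords(select_atoms(m, list(atoms = "heavy"))))
  pairs <- utils::combn(10, 2)
  brute <- mean(apply(pairs, 2, function(p)
    oracle_superpose_rmsd(sels[[p[1]]], sels[[p[2]]])))
  expect_equal(as.numeric(prec), brute, tolerance = 1e-9)
  n_at <- nrow(sels[[1]])
  expect_equal(as.numeric(prec), sigma * sqrt(6 * (1 - 2 / n_at)),
               tolerance = 0.15)
  ## invariance under a rigid transform of one model
  set.seed(5)
  ens2 <- ens
  ens2$models[[3]] <- rigid_transform_model(ens2$models[[3]])
  expect_equal(as.numeric(ensemble_precision(ens2, list(atoms = "heavy"))),
               as.numeric(prec), tolerance = 1e-9)
  ## to-mean variant is also available and smaller than pairwise
  tm <- ensemble_precision(ens, list(atoms = "heavy"), method = "to_mean")
  expect_lt(as.numeric(tm), as.numeric(prec))
})

test_that("residue-range parsing and free-cysteine handling behave", {
  expect_equal(parse_residue_ranges("3-5,7-10"), c(3:5, 7:10))
  ## two free cysteines far apart give no cystine
  pep <- build_peptide("CAAC", rep(-120, 4), rep(130, 4),
                       chi1 = c(-60, NA, NA, -60))
  expect_equal(find_cystines(pep), list())
})
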