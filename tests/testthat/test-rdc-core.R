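test_that("dipolar normalization factors follow the constant-ratio oracle", {
  tab <- dipolar_constants()
  expect_equal(tab["N-HN", "factor"], 1)
  ## independent hand computation of the ratios from the gyromagnetic
  ## ratios (1e7 rad/s/T) and reference bond lengths
  g_h <- 26.7522128; g_c <- 6.728284; g_n <- 2.71261804
  f_ch <- (g_c * g_h / 1.117^3) / (g_n * g_h / 1.041^3)
  f_cc <- (g_c * g_c / 1.526^3) / (g_n * g_h / 1.041^3)
  f_nc <- (g_n * g_c / 1.329^3) / (g_n * g_h / 1.041^3)
  expect_equal(tab["CA-HA", "factor"], f_ch, tolerance = 1e-12)
  expect_equal(tab["C-CA", "factor"], f_cc, tolerance = 1e-12)
  expect_equal(tab["N-C", "factor"], f_nc, tolerance = 1e-12)
  expect_equal(f_ch, 2.008, tolerance = 1e-3)   # frozen oracle value
  ## normalize divides by the factor; N-HN is the identity
  rs <- rdc_set(data.frame(res_i = c(2, 2), atom_i = c("N", "CA"),
                           res_j = c(2, 2), atom_j = c("H", "HA"),
                           type = c("N-HN", "CA-HA"), medium = "pf1",
                           d_obs = c(12, 12)))
  nn <- normalize_rdc(rs)
  expect_equal(nn$d_norm, c(12, 12 / f_ch))
  expect_error(rdc_set(data.frame(res_i = 1, atom_i = "N", res_j = 1,
                                  atom_j = "H", type = "H-H",
                                  medium = "x", d_obs = 1)),
               "unknown rdc type")
})

test_that("design rows reproduce the direct Saupe contraction", {
  pep <- make_test_peptide(8)
  tab <- dipolar_constants()
  set.seed(31)
  for (k in 1:50) {
    tt <- make_tensor(Da = stats::runif(1, 2, 15),
                      R = stats::runif(1, 0, 2 / 3),
                      euler = stats::runif(3, 0, 360))
    rec <- data.frame(res_i = 4, atom_i = "N", res_j = 4, atom_j = "H",
                      type = "N-HN", medium = "pf1", stringsAsFactors = FALSE)
    row <- design_row(pep, rec)
    s <- c(tt$tensor[2, 2], tt$tensor[3, 3], tt$tensor[1, 2],
           tt$tensor[1, 3], tt$tensor[2, 3])
    v <- atom_xyz(pep, 4, "H") - atom_xyz(pep, 4, "N")
    expect_equal(sum(row * s), oracle_coupling(v, tt$tensor),
                 tolerance = 1e-9)
    ## a scaled type picks up its normalization factor
    rec2 <- rec; rec2$atom_i <- "CA"; rec2$atom_j <- "HA"
    rec2$type <- "CA-HA"
    v2 <- atom_xyz(pep, 4, "HA") - atom_xyz(pep, 4, "CA")
    expect_equal(sum(design_row(pep, rec2) * s),
                 oracle_coupling(v2, tt$tensor, tab["CA-HA", "factor"]),
                 tolerance = 1e-9)
  }
  ## RDCs are even in the bond-vector sign
  rec <- data.frame(res_i = 4, atom_i = "N", res_j = 4, atom_j = "H",
                    type = "N-HN", medium = "pf1", stringsAsFactors = FALSE)
  flip <- rec; flip$atom_i <- "H"; flip$atom_j <- "N"
  expect_equal(design_row(pep, rec), design_row(pep, flip),
               tolerance = 1e-12)
  ## the summed methylene row is the sum of the single-proton rows
  sum_rec <- data.frame(res_i = 2, atom_i = "CB", res_j = 2, atom_j = "HB",
                        type = "SUM-CBHB", medium = "pf1",
                        stringsAsFactors = FALSE)
  cb <- atom_xyz(pep, 2, "CB")
  single <- function(h) {
    v <- atom_xyz(pep, 2, h) - cb
    v <- v / sqrt(sum(v^2))
    tab["SUM-CBHB", "factor"] *
      c(v[2]^2 - v[1]^2, v[3]^2 - v[1]^2, 2 * v[1] * v[2],
        2 * v[1] * v[3], 2 * v[2] * v[3])
  }
  expect_equal(design_row(pep, sum_rec), single("HB2") + single("HB3"),
               tolerance = 1e-12)
  expect_error(design_row(pep, transform(rec, res_i = 99)), "missing atom")
})

test_that("the SVD tensor fit recovers ground truth and matches normal equations", {
  pep <- make_test_peptide(16, seed = 2)
  truth <- make_tensor(Da = 9, R = 0.25, euler = c(15, 55, 110))
  rdc0 <- simulate_rdcs(pep, truth,
                        records = rdc_template(pep, media = "pf1"))
  fit0 <- fit_tensor(pep, rdc0)
  expect_lt(max(abs(fit0$tensor$tensor - truth$tensor)), 1e-8)
  expect_lt(fit0$q$q, 1e-8)
  expect_equal(fit0$tensor$Da, 9, tolerance = 1e-8)
  expect_equal(fit0$tensor$R, 0.25, tolerance = 1e-8)
  ## noisy instances: SVD solution equals the normal-equations oracle
  set.seed(12)
  for (k in 1:100) {
    rdc <- rdc0
    rdc$d_obs <- rdc$d_obs + stats::rnorm(nrow(rdc), 0, 1)
    fit <- fit_tensor(pep, rdc)
    a <- t(vapply(seq_len(nrow(rdc)),
                  function(i) design_row(pep, rdc[i, ]), numeric(5)))
    s_or <- oracle_fit_s(a, rdc$d_obs)
    s_fit <- c(fit$tensor$tensor[2, 2], fit$tensor$tensor[3, 3],
               fit$tensor$tensor[1, 2], fit$tensor$tensor[1, 3],
               fit$tensor$tensor[2, 3])
    expect_equal(s_fit, s_or, tolerance = 1e-9)
    expect_equal(fit$q$q,
                 sqrt(mean((as.numeric(a %*% s_or) - rdc$d_obs)^2)) /
                   sqrt(mean(rdc$d_obs^2)), tolerance = 1e-9)
  }
  expect_error(fit_tensor(pep, rdc0[1:4, ]), "underdetermined")
  expect_error(fit_tensor(pep, simulate_rdcs(pep, truth)),
               "several media")
})

test_that("fitted tensors are symmetric traceless with R in [0, 2/3]", {
  set.seed(77)
  for (k in 1:1000) {
    s <- stats::rnorm(5, 0, 5)
    tt <- peprdc:::describe_tensor(peprdc:::tensor_from_s(s))
    expect_lt(abs(sum(diag(tt$tensor))), 1e-12)
    expect_equal(tt$tensor, t(tt$tensor), tolerance = 1e-14)
    expect_gte(tt$R, 0)
    expect_lte(tt$R, 2 / 3 + 1e-12)
    ## Da/R/orientation reconstruct the tensor
    back <- make_tensor(tt$Da, tt$R, tt$euler)
    expect_equal(back$tensor, tt$tensor, tolerance = 1e-8)
  }
})

test_that("Q is invariant under structure rotation, data scaling, and consistent augmentation", {
  pep <- make_test_peptide(12, seed = 3)
  truth <- make_tensor(Da = 11, R = 0.4, euler = c(70, 30, 10))
  rdc <- simulate_rdcs(pep, truth,
                       records = rdc_template(pep, media = "pf1"),
                       noise_sd = 1.5, seed = 9)
  q0 <- fit_tensor(pep, rdc)$q$q
  set.seed(41)
  for (k in 1:100) {
    q_rot <- fit_tensor(rigid_transform_model(pep), rdc)$q$q
    expect_equal(q_rot, q0, tolerance = 1e-9)
  }
  for (c_scale in c(-3, 0.5, 7)) {
    rs <- rdc; rs$d_obs <- rs$d_obs * c_scale
    expect_equal(fit_tensor(pep, rs)$q$q, q0, tolerance = 1e-9)
  }
  ## adding a record with its exact back-calculated value changes nothing
  fit <- fit_tensor(pep, rdc)
  extra <- rdc[3, ]
  extra$d_obs <- fit$d_calc[3]
  fit2 <- fit_tensor(pep, rbind(rdc, extra))
  expect_equal(fit2$tensor$tensor, fit$tensor$tensor, tolerance = 1e-9)
})

test_that("q_factor matches hand arithmetic and its exact limits", {
  expect_equal(q_factor(c(10, -5, 3), c(8, -4, 2))$q,
               sqrt(2) / sqrt(134 / 3))
  expect_equal(q_factor(c(4, -2, 7), c(4, -2, 7))$q, 0)
  expect_equal(q_factor(c(4, -2, 7), c(0, 0, 0))$q, 1)
  expect_error(q_factor(c(0, 0), c(1, 1)), "zero")
  expect_error(q_factor(1:3, 1:2), "equal")
  rep <- q_factor(c(10, -5, 3), c(8, -4, 2), type = c("a", "a", "b"))
  expect_equal(rep$q, rep$rms_resid / rep$rms_obs)
  expect_equal(sum(rep$per_type$n), 3)
})

test_that("cross-validation plans are stratified, exhaustive and deterministic", {
  pep <- make_test_peptide(50, seed = 4)
  tens <- list(pf1 = make_tensor(10, 0.3, c(10, 40, 70)),
               peg = make_tensor(7, 0.55, c(100, 20, 140)))
  rdc <- simulate_rdcs(pep, tens, noise_sd = 1, seed = 5)
  rdc_bb <- rdc[rdc$type != "SUM-CBHB", ]
  plan <- make_cv_plan(rdc_bb, seed = 17)
  held <- sort(unlist(plan$rounds))
  expect_equal(held, seq_len(nrow(rdc_bb)))      # each record exactly once
  expect_length(plan$rounds, 10)
  ## each round holds out ~10% of every experiment
  exper <- paste(rdc_bb$type, rdc_bb$medium)
  for (r in plan$rounds) {
    frac <- table(exper[r]) / table(exper)
    expect_true(all(frac > 0.02 & frac < 0.25))
  }
  expect_identical(make_cv_plan(rdc_bb, seed = 17)$rounds, plan$rounds)
  expect_false(identical(make_cv_plan(rdc_bb, seed = 18)$rounds,
                         plan$rounds))
  expect_error(make_cv_plan(rdc_bb, fraction = 0, seed = 1), "positive")
  expect_error(make_cv_plan(rdc_bb[1:12, ], seed = 1), "fewer records")
})

test_that("q_free is zero without noise and sits at the analytic noise floor", {
  pep <- make_test_peptide(50, seed = 6)
  tens <- list(pf1 = make_tensor(10, 0.3, c(10, 40, 70)),
               peg = make_tensor(7, 0.55, c(100, 20, 140)))
  rdc0 <- simulate_rdcs(pep, tens)
  rdc0 <- rdc0[rdc0$type != "SUM-CBHB", ]
  plan <- make_cv_plan(rdc0, seed = 23)
  qf0 <- q_free(plan, rdc0, pep)
  expect_true(all(qf0$rounds < 1e-8))
  ## Monte-Carlo vs closed form: with the identity refiner the held-out
  ## residual sd is sigma * sqrt(1 + p/n_work) (p = 5 tensor parameters
  ## per medium), so Q_free ~ that over rms(d_obs)
  sigma <- 1
  qfs <- vapply(1:5, function(k) {
    rdc <- rdc0
    set.seed(100 + k)
    rdc$d_obs <- rdc$d_obs + stats::rnorm(nrow(rdc), 0, sigma)
    q_free(make_cv_plan(rdc, seed = k), rdc, pep)$mean
  }, numeric(1))
  n_work <- round(0.9 * sum(rdc0$medium == "pf1"))
  floor_expected <- sigma * sqrt(1 + 5 / n_work) /
    sqrt(mean(rdc0$d_obs^2) + sigma^2)
  expect_lt(abs(mean(qfs) - floor_expected) / floor_expected, 0.10)
  ## refiner contract: failures are propagated with the round index
  expect_error(q_free(plan, rdc0, pep,
                      refiner = function(s, w) stop("boom")),
               "round 1")
  ## an injected refiner is actually applied
  ref_calls <- 0
  qf_ref <- q_free(plan, rdc0, pep, refiner = function(s, w) {
    ref_calls <<- ref_calls + 1
    s
  })
  expect_equal(ref_calls, 10)
  expect_true(all(qf_ref$rounds < 1e-8))
})

test_that("ensemble fits report per-model spread and the XPLOR reader parses", {
  pep <- make_test_peptide(20, seed = 8)
  ens <- perturb_ensemble(pep, 4, coord_jitter_sd = 0.1, seed = 11)
  truth <- make_tensor(8, 0.2, c(40, 60, 80))
  rdc <- simulate_rdcs(pep, truth,
                       records = rdc_template(pep, media = "pf1"),
                       noise_sd = 0.5, seed = 13)
  ef <- fit_tensor_ensemble(ens, rdc)
  expect_length(ef$q_per_model, 4)
  expect_equal(ef$q_mean, mean(ef$q_per_model))
  expect_gt(ef$q_sd, 0)
  ## XPLOR dipolar restraint dialect
  path <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c(
    "assign ( resid 500 and name OO )( resid 500 and name Z )",
    "       ( resid 500 and name X )( resid 500 and name Y )",
    "       ( resid 4 and name N )( resid 4 and name HN )  -2.10 0.20",
    "assign ( resid 500 and name OO )( resid 500 and name Z )",
    "       ( resid 500 and name X )( resid 500 and name Y )",
    "       ( resid 5 and name CA )( resid 5 and name HA )   7.35 0.40"),
    path)
  xp <- read_rdc_xplor(path, medium = "pf1")
  expect_equal(nrow(xp), 2)
  expect_equal(xp$type, c("N-HN", "CA-HA"))
  expect_equal(xp$d_obs, c(-2.10, 7.35))
  expect_equal(xp$sigma, c(0.20, 0.40))
  ## TSV round trip
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_rdc_tsv(rdc, p2)
  back <- read_rdc_tsv(p2)
  expect_equal(back$d_obs, rdc$d_obs)
})
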