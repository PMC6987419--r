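#' Build a stratified cross-validation plan for Q(free)
#'
#' Partitions the RDC records of every experiment (a `(type, medium)`
#' combination) into `n_rounds` disjoint held-out sets of nearly equal
#' size, so that each record is left out exactly once across the rounds and
#' each round holds out approximately `fraction` of every experiment.
#'
#' @param rdcs An `"rdc_set"`.
#' @param fraction Nominal held-out fraction per round (default 0.10; must
#'   be positive and consistent with `n_rounds`).
#' @param n_rounds Number of rounds (default 10).
#' @param seed Integer seed; required, no hidden global state.
#' @return Object of class `"cv_plan"`: list with `rounds` (list of integer
#'   index vectors into `rdcs`), `fraction`, `n_rounds`, `seed`.
#' @export
make_cv_plan <- function(rdcs, fraction = 0.10, n_rounds = 10, seed) {
  if (missing(seed)) stop("make_cv_plan: seed is required")
  if (fraction <= 0) stop("make_cv_plan: fraction must be positive")
  if (n_rounds < 2) stop("make_cv_plan: need at least 2 rounds")
  if (abs(fraction * n_rounds - 1) > 0.5)
    warning("make_cv_plan: fraction and n_rounds are inconsistent; ",
            "the partition is driven by n_rounds")
  exper <- paste(rdcs$type, rdcs$medium, sep = "/")
  groups <- split(seq_len(nrow(rdcs)), exper)
  small <- names(groups)[vapply(groups, length, integer(1)) < n_rounds]
  if (length(small) > 0)
    stop("make_cv_plan: experiment(s) with fewer records than rounds: ",
         paste(small, collapse = ", "))
  rng <- local({
    set.seed(seed)
    lapply(groups, sample)
  })
  rounds <- vector("list", n_rounds)
  for (g in rng) {
    cut_id <- rep(seq_len(n_rounds), length.out = length(g))
    cut_id <- sort(cut_id)               # contiguous near-equal chunks
    for (r in seq_len(n_rounds))
      rounds[[r]] <- c(rounds[[r]], g[cut_id == r])
  }
  rounds <- lapply(rounds, sort)
  structure(list(rounds = rounds, fraction = fraction,
                 n_rounds = n_rounds, seed = seed), class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  sizes <- vapply(x$rounds, length, integer(1))
  cat(sprintf("Cross-validation plan: %d rounds, held-out sizes %s (seed %d)\n",
              x$n_rounds, paste(sizes, collapse = "/"), x$seed))
  invisible(x)
}

#' Cross-validated quality factor Q(free)
#'
#' For each round of the plan the held-out records are removed, the
#' structure is (optionally) refined against the remaining working set, an
#' alignment tensor is fitted per medium to the working records on the
#' refined structure, the held-out couplings are back-calculated, and Q is
#' computed on the held-out records only. The default refiner is the
#' identity (the structure is used as-is); a real refiner can be injected
#' as a function `(structure, working_rdcs) -> structure`.
#'
#' @param plan A `"cv_plan"` over `rdcs`.
#' @param rdcs An `"rdc_set"` (may span several media).
#' @param structure A model data frame.
#' @param refiner `NULL` (identity) or a function of
#'   `(structure, working_rdcs)` returning a refined model.
#' @param constants Dipolar constants table.
#' @return Object of class `"q_free"`: list with `mean`, `sd`, `rounds`
#'   (per-round pooled Q), `per_medium` (matrix rounds x media).
#' @export
q_free <- function(plan, rdcs, structure, refiner = NULL,
                   constants = dipolar_constants()) {
  stopifnot(inherits(plan, "cv_plan"))
  media <- unique(rdcs$medium)
  qs <- numeric(plan$n_rounds)
  qm <- matrix(NA_real_, plan$n_rounds, length(media),
               dimnames = list(NULL, media))
  for (r in seq_len(plan$n_rounds)) {
    held <- plan$rounds[[r]]
    work <- setdiff(seq_len(nrow(rdcs)), held)
    work_set <- rdcs[work, , drop = FALSE]
    mod <- if (is.null(refiner)) structure else {
      out <- tryCatch(refiner(structure, work_set), error = function(e)
        stop(sprintf("q_free: refiner failed in round %d: %s", r,
                     conditionMessage(e))))
      out
    }
    resid <- numeric(0)
    obs <- numeric(0)
    for (m in media) {
      wi <- work_set[work_set$medium == m, , drop = FALSE]
      hi <- rdcs[held, , drop = FALSE]
      hi <- hi[hi$medium == m, , drop = FALSE]
      fit <- fit_tensor(mod, wi, constants = constants)
      if (nrow(hi) > 0) {
        dc <- back_calculate(mod, hi, fit$tensor, constants)
        qm[r, m] <- q_factor(hi$d_obs, dc)$q
        resid <- c(resid, dc - hi$d_obs)
        obs <- c(obs, hi$d_obs)
      }
    }
    qs[r] <- sqrt(mean(resid^2)) / sqrt(mean(obs^2))
  }
  structure(list(mean = mean(qs), sd = stats::sd(qs), rounds = qs,
                 per_medium = qm), class = "q_free")
}

#' @export
print.q_free <- function(x, ...) {
  cat(sprintf("Q(free) = %.4f +/- %.4f over %d rounds\n",
              x$mean, x$sd, length(x$rounds)))
  med <- colnames(x$per_medium)
  if (length(med) > 1) {
    for (m in med)
      cat(sprintf("  %-6s Q(free) = %.4f +/- %.4f\n", m,
                  mean(x$per_medium[, m]), stats::sd(x$per_medium[, m])))
  }
  invisible(x)
}
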