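## Disulfide connectivity inference by Cbeta-Cbeta distance minimization,
## and the PDB-survey statistics behind the 5 Angstrom bonded-distance rule.

#' Cbeta-Cbeta distance matrices of the cysteines of an ensemble
#'
#' @param ensemble An ensemble (a single model is accepted too).
#' @param residues Optional cysteine residue numbers; default: all CYS with
#'   a CB atom.
#' @return Object of class `"cb_distances"`: list with `residues`,
#'   `per_model` (list of symmetric matrices, Angstrom) and `average`.
#' @export
cb_distances <- function(ensemble, residues = NULL) {
  models <- if (inherits(ensemble, "ensemble")) ensemble$models
            else list(ensemble)
  m1 <- models[[1]]
  if (is.null(residues))
    residues <- sort(unique(m1$resno[m1$resname == "CYS" & m1$atom == "CB"]))
  if (length(residues) < 2)
    stop("cb_distances: need at least 2 cysteines with CB atoms")
  per <- lapply(models, function(m) {
    xyz <- t(vapply(residues, function(r) atom_xyz(m, r, "CB"), numeric(3)))
    d <- as.matrix(stats::dist(xyz))
    dimnames(d) <- list(residues, residues)
    d
  })
  avg <- Reduce(`+`, per) / length(per)
  structure(list(residues = residues, per_model = per, average = avg),
            class = "cb_distances")
}

#' Enumerate all perfect matchings of a cysteine set
#'
#' For 2n cysteines there are (2n-1)!! = (2n-1)(2n-3)...1 ways to pair them
#' all; the enumeration is exhaustive and duplicate-free.
#'
#' @param cysteines Vector of identifiers (even length >= 2).
#' @return List of matchings; each matching is a list of sorted pairs.
#' @export
enumerate_matchings <- function(cysteines) {
  n <- length(cysteines)
  if (n < 2 || n %% 2 == 1)
    stop("enumerate_matchings: need an even number (>= 2) of cysteines")
  rec <- function(xs) {
    if (length(xs) == 0) return(list(list()))
    first <- xs[1]
    out <- list()
    for (k in 2:length(xs)) {
      rest <- xs[-c(1, k)]
      for (sub in rec(rest))
        out[[length(out) + 1]] <- c(list(sort(c(first, xs[k]))), sub)
    }
    out
  }
  rec(cysteines)
}

#' Infer disulfide connectivity by Cbeta-Cbeta minimization
#'
#' Scores every perfect matching of the cysteines by the mean
#' Cbeta-Cbeta distance of its pairs on the ensemble-averaged distance
#' matrix and returns the minimum. Correctly paired cysteines yield the
#' shortest average Cbeta-Cbeta distances overall; pairs at or beyond the
#' bonded-distance threshold are flagged as violations.
#'
#' @param distance_set A `"cb_distances"` object (or a plain symmetric
#'   matrix with residue-number dimnames).
#' @param threshold Violation threshold in Angstrom (default 5: bonded
#'   pairs lie below it).
#' @return Object of class `"pairing_solution"`: list with `matching`
#'   (list of residue pairs), `score` (mean distance, Angstrom), `margin`
#'   (gap to the second-best matching), `violations`, `tie` (logical).
#' @export
infer_connectivity <- function(distance_set, threshold = 5.0) {
  d <- if (inherits(distance_set, "cb_distances")) distance_set$average
       else distance_set
  res <- as.integer(rownames(d))
  res <- sort(res)
  d <- d[as.character(res), as.character(res), drop = FALSE]
  matchings <- enumerate_matchings(res)
  score_of <- function(m) mean(vapply(m, function(p)
    d[as.character(p[1]), as.character(p[2])], numeric(1)))
  scores <- vapply(matchings, score_of, numeric(1))
  ## lexicographic tie-break on the flattened residue pairs
  keys <- vapply(matchings, function(m)
    paste(sprintf("%06d", unlist(m)), collapse = ""), character(1))
  ord <- order(scores, keys)
  best <- matchings[[ord[1]]]
  tie <- length(scores) > 1 &&
    abs(scores[ord[2]] - scores[ord[1]]) < 1e-12
  if (tie) message("infer_connectivity: tied optimal matchings; ",
                   "lexicographic tie-break applied")
  margin <- if (length(scores) > 1) scores[ord[2]] - scores[ord[1]] else Inf
  viol <- Filter(function(p)
    d[as.character(p[1]), as.character(p[2])] >= threshold, best)
  structure(list(matching = best, score = scores[ord[1]], margin = margin,
                 violations = viol, tie = tie),
            class = "pairing_solution")
}

#' @export
print.pairing_solution <- function(x, ...) {
  cat("Disulfide connectivity:",
      paste(vapply(x$matching, function(p) paste(p, collapse = "-"),
                   character(1)), collapse = ", "), "\n")
  cat(sprintf("  mean Cb-Cb = %.2f A, margin to next = %.2f A, %d violation(s)\n",
              x$score, x$margin, length(x$violations)))
  invisible(x)
}

#' Survey statistics of Cbeta-Cbeta distances
#'
#' Reproduces the database-survey statistics behind the connectivity rule:
#' after filtering structures by crystallographic resolution and molecular
#' weight (and removing duplicates), bonded (intra-disulfide) Cbeta-Cbeta
#' distances are summarized (mean, sd, count below the threshold) and the
#' number of non-bonded cysteine pairs below the threshold is counted, both
#' per unique residue pair and per record.
#'
#' @param records Data frame with columns `pdb_id`, `resolution`, `mw_kda`,
#'   `res_i`, `res_j`, `cb_dist`, `bonded` (logical) and optionally
#'   `sequence` (used by the duplicate filter).
#' @param max_resolution Maximal resolution in Angstrom (default 1.5).
#' @param max_mw Maximal molecular weight in kDa (default 50).
#' @param duplicate_policy `"sequence"` (drop exact sequence duplicates,
#'   keeping the first), `"pdb_id"` or `"none"`.
#' @param threshold Bonded-distance threshold in Angstrom (default 5).
#' @param z_outlier Drop bonded records with |z| above this (default 10;
#'   `Inf` disables). Removal is logged.
#' @return List with `n_structures`, `intra` (mean, sd, n, n_below),
#'   `inter` (n_below_pairs, n_below_records), `threshold`.
#' @export
survey_cb_distances <- function(records, max_resolution = 1.5, max_mw = 50,
                                duplicate_policy = c("sequence", "pdb_id",
                                                     "none"),
                                threshold = 5.0, z_outlier = 10) {
  duplicate_policy <- match.arg(duplicate_policy)
  keep <- records$resolution < max_resolution & records$mw_kda < max_mw
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0) stop("survey_cb_distances: empty filtered set")
  if (duplicate_policy != "none") {
    key_col <- if (duplicate_policy == "sequence" &&
                   "sequence" %in% names(records)) "sequence" else "pdb_id"
    first_ids <- !duplicated(records[[key_col]])
    keep_ids <- unique(records$pdb_id[first_ids])
    by_id <- records$pdb_id %in% keep_ids
    records <- records[by_id, , drop = FALSE]
  }
  intra <- records[records$bonded, , drop = FALSE]
  inter <- records[!records$bonded, , drop = FALSE]
  if (nrow(intra) > 1 && is.finite(z_outlier)) {
    z <- (intra$cb_dist - mean(intra$cb_dist)) / stats::sd(intra$cb_dist)
    drop <- abs(z) > z_outlier
    if (any(drop)) {
      message("survey_cb_distances: removed ", sum(drop),
              " bonded outlier record(s): ",
              paste(unique(intra$pdb_id[drop]), collapse = ", "))
      intra <- intra[!drop, , drop = FALSE]
    }
  }
  pair_key <- function(df) paste(df$pdb_id, pmin(df$res_i, df$res_j),
                                 pmax(df$res_i, df$res_j))
  inter_below <- inter[inter$cb_dist < threshold, , drop = FALSE]
  list(n_structures = length(unique(records$pdb_id)),
       intra = list(mean = mean(intra$cb_dist),
                    sd = stats::sd(intra$cb_dist),
                    n = nrow(intra),
                    n_below = sum(intra$cb_dist < threshold)),
       inter = list(n_below_pairs = length(unique(pair_key(inter_below))),
                    n_below_records = nrow(inter_below)),
       threshold = threshold)
}
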