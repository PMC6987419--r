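## Containers: a model is a data.frame with columns
##   atom, element, resno, resname, chain, x, y, z
## (author residue numbering kept verbatim). An ensemble is a list with
## elements `models` (list of models) and `source_id`, class "ensemble".

new_model <- function(df) {
  need <- c("atom", "element", "resno", "resname", "chain", "x", "y", "z")
  stopifnot(all(need %in% names(df)))
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z) ||
      any(!is.finite(df$x + df$y + df$z)))
    stop("model: non-finite coordinates")
  key <- atom_key(df)
  if (anyDuplicated(key))
    stop("model: duplicated atom identifier: ", key[duplicated(key)][1])
  class(df) <- c("pep_model", "data.frame")
  df
}

new_ensemble <- function(models, source_id = "") {
  stopifnot(length(models) >= 1)
  structure(list(models = models, source_id = source_id), class = "ensemble")
}

atom_key <- function(model) {
  paste(model$chain, model$resno, model$atom, sep = "|")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("NMR ensemble '%s': %d models, %d atoms each\n",
              x$source_id, length(x$models), nrow(x$models[[1]])))
  invisible(x)
}

#' Extract the coordinate matrix of a model
#' @param model A model data frame.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(model) {
  m <- cbind(model$x, model$y, model$z)
  colnames(m) <- c("x", "y", "z")
  m
}

## position of one atom as a 3-vector
atom_xyz <- function(model, resno, atom, chain = NULL) {
  i <- which(model$resno == resno & model$atom == atom &
             (if (is.null(chain)) TRUE else model$chain == chain))
  if (length(i) == 0)
    stop(sprintf("missing atom: residue %s atom %s", resno, atom))
  as.numeric(c(model$x[i[1]], model$y[i[1]], model$z[i[1]]))
}

#' Select atoms of a model
#'
#' @param model A model data frame.
#' @param selection `NULL` (all atoms) or a list with elements `residues`
#'   (integer vector of author residue numbers, or `NULL` for all) and
#'   `atoms` (one of `"backbone"` (N/CA/C), `"heavy"`, `"all"`, or a
#'   character vector of atom names).
#' @return The subset model.
#' @export
select_atoms <- function(model, selection = NULL) {
  if (is.null(selection)) return(model)
  res <- selection$residues
  atoms <- selection$atoms
  keep <- rep(TRUE, nrow(model))
  if (!is.null(res)) keep <- keep & model$resno %in% res
  if (!is.null(atoms)) {
    if (identical(atoms, "backbone")) {
      keep <- keep & model$atom %in% c("N", "CA", "C")
    } else if (identical(atoms, "heavy")) {
      keep <- keep & model$element != "H"
    } else if (!identical(atoms, "all")) {
      keep <- keep & model$atom %in% atoms
    }
  }
  out <- model[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("select_atoms: empty selection")
  out
}

#' Parse a residue-range string
#'
#' Turns `"3-5,7-50"` into the integer vector `c(3:5, 7:50)`.
#' @param txt Range specification.
#' @return Integer vector.
#' @export
parse_residue_ranges <- function(txt) {
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  unlist(lapply(parts, function(p) {
    p <- trimws(p)
    if (grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      seq(ab[1], ab[2])
    } else as.integer(p)
  }))
}

## ---- readers ---------------------------------------------------------

#' Read a multi-model coordinate file
#'
#' Reads all MODEL records of a PDB or mmCIF file into an ensemble.
#' Hydrogens are kept. Legacy beta-methylene proton names (HB1/HB2) are
#' remapped to the IUPAC HB2/HB3 convention with a message. Models with
#' differing atom sets are reduced to the common intersection with a
#' warning. SSBOND records (PDB) are retained as the `ssbonds` attribute.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return An object of class `"ensemble"`.
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_ensemble: file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  ens <- if (format == "pdb") read_pdb_file(path) else read_mmcif_file(path)
  if (length(ens$models) == 0) stop("read_ensemble: no models in ", path)
  ens$models <- lapply(ens$models, remap_legacy_hb)
  ens$models <- harmonize_atom_sets(ens$models)
  ens$models <- lapply(ens$models, new_model)
  ens
}

read_pdb_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1, 6)
  ssbonds <- list()
  for (l in lines[rec == "SSBOND"]) {
    ssbonds[[length(ssbonds) + 1]] <-
      c(as.integer(substring(l, 18, 21)), as.integer(substring(l, 32, 35)))
  }
  models <- list()
  cur <- NULL
  idx <- 0
  flush <- function() {
    if (!is.null(cur) && nrow(cur) > 0) models[[length(models) + 1]] <<- cur
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      flush()
      cur <- NULL
      idx <- idx + 1
    } else if (r == "ENDMDL") {
      flush()
    } else if (r %in% c("ATOM  ", "HETATM")) {
      l <- lines[i]
      if (nchar(l) < 54)
        stop("read_ensemble: truncated ATOM record at line ", i)
      xyz <- suppressWarnings(as.numeric(c(substring(l, 31, 38),
                                           substring(l, 39, 46),
                                           substring(l, 47, 54))))
      if (anyNA(xyz))
        stop("read_ensemble: unparseable coordinates at line ", i)
      altloc <- substring(l, 17, 17)
      if (!altloc %in% c(" ", "A", "1")) next
      row <- data.frame(
        atom = trimws(substring(l, 13, 16)),
        element = parse_element(l),
        resno = as.integer(substring(l, 23, 26)),
        resname = trimws(substring(l, 18, 20)),
        chain = substring(l, 22, 22),
        x = xyz[1], y = xyz[2], z = xyz[3],
        stringsAsFactors = FALSE)
      cur <- if (is.null(cur)) row else rbind(cur, row)
    }
  }
  flush()
  ens <- new_ensemble_raw(models, source_id = basename(path))
  attr(ens, "ssbonds") <- ssbonds
  ens
}

new_ensemble_raw <- function(models, source_id) {
  structure(list(models = models, source_id = source_id), class = "ensemble")
}

parse_element <- function(line) {
  el <- if (nchar(line) >= 78) trimws(substring(line, 77, 78)) else ""
  if (el == "") {
    nm <- trimws(substring(line, 13, 16))
    el <- substring(gsub("[0-9]", "", nm), 1, 1)
  }
  toupper(el)
}

read_mmcif_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ## locate the _atom_site loop
  starts <- grep("^\\s*loop_\\s*$", lines)
  atom_loop <- NULL
  for (s in starts) {
    j <- s + 1
    fields <- character()
    while (j <= length(lines) && grepl("^\\s*_", lines[j])) {
      fields <- c(fields, trimws(lines[j]))
      j <- j + 1
    }
    if (any(grepl("^_atom_site\\.", fields))) {
      atom_loop <- list(fields = sub("^_atom_site\\.", "", fields), body = j)
      break
    }
  }
  if (is.null(atom_loop))
    stop("read_ensemble: no _atom_site loop found in mmCIF file")
  fields <- atom_loop$fields
  j <- atom_loop$body
  rows <- list()
  while (j <= length(lines)) {
    l <- trimws(lines[j])
    if (l == "" || grepl("^(#|loop_|_|data_)", l)) break
    tok <- scan(text = l, what = character(), quiet = TRUE)
    if (length(tok) != length(fields))
      stop("read_ensemble: malformed _atom_site row at line ", j)
    rows[[length(rows) + 1]] <- tok
    j <- j + 1
  }
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  get <- function(nm, alt = NULL) {
    if (nm %in% fields) m[, nm]
    else if (!is.null(alt) && alt %in% fields) m[, alt]
    else stop("read_ensemble: mmCIF missing _atom_site.", nm)
  }
  df <- data.frame(
    atom = gsub('"', "", get("auth_atom_id", "label_atom_id")),
    element = toupper(get("type_symbol")),
    resno = as.integer(get("auth_seq_id", "label_seq_id")),
    resname = get("auth_comp_id", "label_comp_id"),
    chain = get("auth_asym_id", "label_asym_id"),
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    stringsAsFactors = FALSE)
  mdl <- if ("pdbx_PDB_model_num" %in% fields)
    as.integer(m[, "pdbx_PDB_model_num"]) else rep(1L, nrow(df))
  models <- lapply(split(seq_len(nrow(df)), mdl),
                   function(i) df[i, , drop = FALSE])
  new_ensemble_raw(unname(models), source_id = basename(path))
}

remap_legacy_hb <- function(model) {
  remapped <- character()
  for (res in unique(model$resno)) {
    i <- which(model$resno == res)
    nm <- model$atom[i]
    if ("HB1" %in% nm && "HB2" %in% nm && !("HB3" %in% nm)) {
      model$atom[i][nm == "HB2"] <- "HB3"
      model$atom[i][nm == "HB1"] <- "HB2"
      remapped <- c(remapped, as.character(res))
    }
  }
  if (length(remapped) > 0)
    message("remapped legacy HB1/HB2 names to HB2/HB3 for residues: ",
            paste(remapped, collapse = ", "))
  model
}

harmonize_atom_sets <- function(models) {
  keys <- lapply(models, atom_key)
  common <- Reduce(intersect, keys)
  sizes <- vapply(keys, length, integer(1))
  if (any(sizes != length(common))) {
    warning(sprintf(
      "models differ in atom content; restricting to the %d common atoms",
      length(common)))
    models <- lapply(models, function(m) {
      m[match(common, atom_key(m)), , drop = FALSE]
    })
  }
  models
}

## ---- writer ----------------------------------------------------------

#' Write an ensemble (or single model) as a PDB file
#'
#' @param x An ensemble or a single model data frame.
#' @param path Output path.
#' @param ssbonds Optional list of residue-number pairs written as SSBOND
#'   records.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, ssbonds = NULL) {
  models <- if (inherits(x, "ensemble")) x$models else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(ssbonds)) {
    for (k in seq_along(ssbonds)) {
      p <- ssbonds[[k]]
      writeLines(sprintf(
        "SSBOND  %2d CYS A %4d    CYS A %4d", k, p[1], p[2]), con)
    }
  }
  for (im in seq_along(models)) {
    m <- models[[im]]
    if (length(models) > 1) writeLines(sprintf("MODEL     %4d", im), con)
    for (i in seq_len(nrow(m))) {
      nm <- m$atom[i]
      nmfmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      writeLines(sprintf(
        "ATOM  %5d %4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, nmfmt, m$resname[i], m$chain[i], m$resno[i],
        m$x[i], m$y[i], m$z[i], m$element[i]), con)
    }
    if (length(models) > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- ensemble statistics --------------------------------------------

#' Coordinate precision of an ensemble
#'
#' Measures the spread of an NMR ensemble over an atom selection, either as
#' the mean pairwise RMSD over all model pairs (each pair superposed on the
#' selection before measuring; the default) or as the mean RMSD to the
#' iteratively superposed mean structure.
#'
#' @param ensemble An ensemble.
#' @param selection Atom selection (see [select_atoms()]).
#' @param method `"pairwise"` or `"to_mean"`.
#' @return Mean RMSD in Angstrom with attribute `"per_pair"` (pairwise) or
#'   `"per_model"` (to-mean).
#' @export
ensemble_precision <- function(ensemble, selection = NULL,
                               method = c("pairwise", "to_mean")) {
  method <- match.arg(method)
  models <- ensemble$models
  n <- length(models)
  if (n < 2) stop("ensemble_precision: need at least 2 models")
  sel <- lapply(models, function(m) select_atoms(m, selection))
  if (method == "pairwise") {
    pairs <- utils::combn(n, 2)
    r <- apply(pairs, 2, function(p) superpose(sel[[p[1]]], sel[[p[2]]])$rmsd)
    structure(mean(r), per_pair = r)
  } else {
    xs <- lapply(sel, coords)
    ref <- xs[[1]]
    for (iter in 1:5) {
      fitted <- lapply(xs, function(x) {
        s <- superpose(ref, x)
        transform_coords(x, s)
      })
      newref <- Reduce(`+`, fitted) / n
      if (max(abs(newref - ref)) < 1e-8) break
      ref <- newref
    }
    r <- vapply(fitted, function(x) sqrt(mean(rowSums((x - ref)^2))),
                numeric(1))
    structure(mean(r), per_model = r)
  }
}

#' Locate cystines in a model
#'
#' Finds disulfide-bonded cysteine pairs by the SG-SG distance; falls back
#' to SSBOND annotations carried by the source file when no SG atoms are
#' present.
#'
#' @param model A model data frame.
#' @param sg_cutoff Maximal SG-SG distance in Angstrom (default 2.3).
#' @param ssbonds Optional list of annotated pairs used as fallback.
#' @return List of integer pairs (ascending residue numbers), possibly
#'   empty.
#' @export
find_cystines <- function(model, sg_cutoff = 2.3, ssbonds = NULL) {
  sg <- model[model$atom == "SG" & model$resname == "CYS", , drop = FALSE]
  if (nrow(sg) < 2) {
    if (!is.null(ssbonds) && length(ssbonds) > 0)
      return(lapply(ssbonds, function(p) sort(as.integer(p))))
    return(list())
  }
  xyz <- coords(sg)
  d <- as.matrix(stats::dist(xyz))
  pairs <- list()
  used <- rep(FALSE, nrow(sg))
  ord <- order(sg$resno)
  for (i in ord) {
    if (used[i]) next
    j <- which(!used & seq_len(nrow(sg)) != i & d[i, ] <= sg_cutoff)
    if (length(j) == 0) next
    j <- j[which.min(d[i, j])]
    used[c(i, j)] <- TRUE
    pairs[[length(pairs) + 1]] <- sort(c(sg$resno[i], sg$resno[j]))
  }
  pairs
}
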