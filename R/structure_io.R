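#' Residue range selector
#'
#' A contiguous span of residues on one chain, in author (file) numbering,
#' inclusive at both ends. All analysis functions take ranges in this form;
#' no renumbering is ever applied, so ranges can be read straight off the
#' deposition records (e.g. a finger spanning residues 324-353 of chain A).
#'
#' @param chain_id single chain identifier character.
#' @param start,end first and last residue numbers (inclusive).
#' @return an object of class `ResidueRange`.
#' @examples
#' residue_range("A", 324, 353)
#' @export
residue_range <- function(chain_id = "A", start, end) {
  stopifnot(is.character(chain_id), nchar(chain_id) == 1L)
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end)) stop("range bounds must be integers")
  if (start > end) stop("invalid residue range: start > end")
  structure(list(chain_id = chain_id, start = start, end = end),
            class = "ResidueRange")
}

#' @export
print.ResidueRange <- function(x, ...) {
  cat(sprintf("<ResidueRange %s:%d-%d>\n", x$chain_id, x$start, x$end))
  invisible(x)
}

range_resnos <- function(range) seq.int(range$start, range$end)

new_ensemble <- function(models, source_id = "") {
  if (length(models) == 0L) stop("ensemble must contain at least one model")
  structure(list(models = models, source_id = source_id),
            class = "StructureEnsemble")
}

#' Number of models in an ensemble
#' @param ens a `StructureEnsemble`.
#' @return integer model count.
#' @export
n_models <- function(ens) {
  stopifnot(inherits(ens, "StructureEnsemble"))
  length(ens$models)
}

#' @export
print.StructureEnsemble <- function(x, ...) {
  m1 <- x$models[[1L]]
  cat(sprintf("<StructureEnsemble '%s': %d model(s), %d atoms in model 1, chains %s>\n",
              x$source_id, length(x$models), nrow(m1),
              paste(unique(m1$chain), collapse = ",")))
  invisible(x)
}

# fixed-column PDB coordinate-record fields
parse_atom_lines <- function(lines, line_numbers) {
  num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v) & nzchar(trimws(s))
    bad[!nzchar(trimws(s))] <- TRUE
    if (any(bad)) {
      stop(sprintf("malformed %s field in PDB coordinate record at line %d",
                   what, ln[which(bad)[1L]]), call. = FALSE)
    }
    v
  }
  f <- function(a, b) trimws(substring(lines, a, b))
  too_short <- nchar(lines) < 54
  if (any(too_short)) {
    stop(sprintf("truncated PDB coordinate record at line %d",
                 line_numbers[which(too_short)[1L]]), call. = FALSE)
  }
  resno <- suppressWarnings(as.integer(f(23, 26)))
  if (any(is.na(resno))) {
    stop(sprintf("malformed residue number in PDB coordinate record at line %d",
                 line_numbers[which(is.na(resno))[1L]]), call. = FALSE)
  }
  occ_raw <- substring(lines, 55, 60)
  occ <- suppressWarnings(as.numeric(occ_raw))
  occ[is.na(occ)] <- 1
  bfac <- suppressWarnings(as.numeric(substring(lines, 61, 66)))
  bfac[is.na(bfac)] <- 0
  element <- trimws(substring(lines, 77, 78))
  atom <- f(13, 16)
  # infer missing element symbols from the atom name
  blank <- !nzchar(element)
  if (any(blank)) {
    guess <- sub("^[0-9]+", "", atom[blank])
    two_letter <- c("ZN", "FE", "MG", "MN", "CU", "NA", "CL", "CA")
    is_ion <- guess %in% two_letter & f(1, 6)[blank] == "HETATM"
    element[blank] <- ifelse(is_ion, guess, substring(guess, 1L, 1L))
  }
  data.frame(
    record = f(1, 6),
    serial = suppressWarnings(as.integer(f(7, 11))),
    atom = atom,
    alt = substring(lines, 17, 17),
    resname = f(18, 20),
    chain = substring(lines, 22, 22),
    resno = resno,
    ins = trimws(substring(lines, 27, 27)),
    x = num(substring(lines, 31, 38), "x coordinate", line_numbers),
    y = num(substring(lines, 39, 46), "y coordinate", line_numbers),
    z = num(substring(lines, 47, 54), "z coordinate", line_numbers),
    occ = occ,
    bfac = bfac,
    element = element,
    stringsAsFactors = FALSE
  )
}

# keep the highest-occupancy alternate location per atom; ties -> first seen
resolve_altlocs <- function(df) {
  df$alt <- ifelse(df$alt == " ", "", df$alt)
  if (!any(nzchar(df$alt))) return(df)
  key <- paste(df$record, df$chain, df$resno, df$ins, df$atom, sep = "\r")
  ord <- order(key, -df$occ, seq_len(nrow(df)))
  keep_rows <- ord[!duplicated(key[ord])]
  out <- df[sort(keep_rows), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a (multi-model) PDB file into a structure ensemble
#'
#' Parses ATOM and HETATM records of a PDB-format text file. Each
#' MODEL/ENDMDL block becomes one model; a file without MODEL records yields
#' a single implicit model. HETATM records (e.g. zinc ions) and hydrogens
#' are retained. Alternate locations are resolved to the highest-occupancy
#' copy (ties broken by file order). Coordinates are finite by construction
#' of the format check; malformed records raise an error naming the line.
#'
#' @param path path to a PDB-format file.
#' @return a `StructureEnsemble`: a list of per-model atom tables
#'   (data.frames with columns `record`, `atom`, `resname`, `chain`,
#'   `resno`, `ins`, `x`, `y`, `z`, `occ`, `element`, ...) plus the source
#'   file name.
#' @seealso [write_ensemble()], [select_atoms()]
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop(sprintf("PDB file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM" | substring(rec, 1, 4) == "ATOM" & nchar(trimws(rec)) == 4
  is_atom <- trimws(rec) %in% c("ATOM", "HETATM")
  is_model <- trimws(rec) == "MODEL"
  is_endmdl <- trimws(rec) == "ENDMDL"

  model_id <- integer(length(lines))
  cur <- 0L
  open <- FALSE
  has_model_records <- any(is_model)
  for (i in seq_along(lines)) {
    if (is_model[i]) {
      cur <- cur + 1L
      open <- TRUE
    } else if (is_endmdl[i]) {
      open <- FALSE
    } else if (is_atom[i]) {
      model_id[i] <- if (has_model_records) {
        if (open) cur else NA_integer_
      } else 1L
    }
  }
  keep <- is_atom & !is.na(model_id) & model_id > 0L
  if (!any(keep)) stop(sprintf("no coordinate records found in %s", path))
  df <- parse_atom_lines(lines[keep], which(keep))
  ids <- model_id[keep]
  models <- lapply(split(seq_len(nrow(df)), ids), function(rows) {
    resolve_altlocs(df[rows, , drop = FALSE])
  })
  names(models) <- NULL
  new_ensemble(models, source_id = basename(path))
}

#' Write a structure ensemble as PDB text
#'
#' Emits one MODEL/ENDMDL block per model (coordinates at 3 decimals);
#' HETATM record classes are preserved. The output is round-trippable by
#' [read_ensemble()].
#'
#' @param ens a `StructureEnsemble`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "StructureEnsemble"))
  fmt_line <- function(i, m) {
    name <- m$atom[i]
    el <- m$element[i]
    name4 <- if (nchar(name) >= 4L || nchar(el) >= 2L) {
      formatC(name, width = -4)
    } else {
      formatC(paste0(" ", name), width = -4)
    }
    sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            m$record[i], i, name4,
            ifelse(nzchar(m$alt[i]), m$alt[i], " "),
            m$resname[i],
            m$chain[i], m$resno[i],
            ifelse(nzchar(m$ins[i]), m$ins[i], " "),
            m$x[i], m$y[i], m$z[i], m$occ[i], m$bfac[i], el)
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop(sprintf("cannot write to '%s': %s",
                                                   path, conditionMessage(e))))
  on.exit(close(con))
  nm <- length(ens$models)
  for (k in seq_len(nm)) {
    m <- ens$models[[k]]
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(vapply(seq_len(nrow(m)), fmt_line, character(1), m = m), con)
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

# coordinates of one atom of one residue in a model table; NULL if absent
model_atom_xyz <- function(model, chain, resno, atom) {
  hit <- which(model$chain == chain & model$resno == resno & model$atom == atom)
  if (length(hit) == 0L) return(NULL)
  as.numeric(model[hit[1L], c("x", "y", "z")])
}

#' Extract an ordered coordinate array from every model
#'
#' Selects the named atoms of every residue in `range` from every model and
#' returns them as an M x K x 3 array (models x atoms x xyz). Rows are
#' ordered by residue number and then by a fixed atom-name order (backbone
#' N, CA, C, O first), identically in every model, so the result can be fed
#' directly to superposition and RMSD routines. Completeness across models
#' is enforced here: a missing atom raises an error naming the model,
#' residue and atom.
#'
#' @param ens a `StructureEnsemble`.
#' @param range a [residue_range()].
#' @param atom_names character vector of atom names, e.g. `"CA"` or
#'   `c("N","CA","C","O")`.
#' @return numeric array of dimension `c(n_models, n_atoms, 3)` with
#'   dimnames `"resno:atom"` on the second margin.
#' @export
select_atoms <- function(ens, range, atom_names = "CA") {
  stopifnot(inherits(ens, "StructureEnsemble"), inherits(range, "ResidueRange"))
  atom_names <- unique(as.character(atom_names))
  if (length(atom_names) == 0L) stop("atom_names must contain at least one atom name")
  atoms <- atom_name_order(atom_names)
  resnos <- range_resnos(range)
  keys <- expand.grid(atom = atoms, resno = resnos,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keys <- keys[order(match(keys$resno, resnos)), c("resno", "atom")]
  nmod <- length(ens$models)
  k <- nrow(keys)
  out <- array(NA_real_, dim = c(nmod, k, 3L),
               dimnames = list(NULL, paste(keys$resno, keys$atom, sep = ":"),
                               c("x", "y", "z")))
  for (mi in seq_len(nmod)) {
    m <- ens$models[[mi]]
    sel <- m$chain == range$chain_id
    ms <- m[sel, , drop = FALSE]
    idx <- match(paste(keys$resno, keys$atom), paste(ms$resno, ms$atom))
    if (anyNA(idx)) {
      miss <- which(is.na(idx))[1L]
      stop(sprintf("model %d is missing atom %s of residue %s:%d",
                   mi, keys$atom[miss], range$chain_id, keys$resno[miss]))
    }
    out[mi, , ] <- as.matrix(ms[idx, c("x", "y", "z")])
  }
  out
}

# convenience: coordinates of one model as an N x 3 matrix
model_coords <- function(ens, model = 1L, range, atom_names = "CA") {
  sel <- select_atoms(ens, range, atom_names)
  mat <- sel[model, , , drop = FALSE]
  dim(mat) <- dim(sel)[2:3]
  dimnames(mat) <- dimnames(sel)[2:3]
  mat
}
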