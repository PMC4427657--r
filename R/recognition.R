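# Recognition-code DNA subsite prediction. A C2H2 finger docks its helix
# in the major groove and reads a 3-4 base subsite through the residues at
# helix positions -1, +3 and +6 (primary strand: +6 -> 5' base, +3 ->
# middle, -1 -> 3' base), position +2 touching the complementary strand
# just 3' of the triplet, and +10 extending the contact in bulged-out
# helices. The concrete residue -> base calls live in an editable table;
# this module is the lookup and assembly machinery.

IUPAC_FROM_SET <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y", W = "W",
  S = "S", Y = "R", K = "M", V = "B", H = "D", D = "H", B = "V", N = "N"
)

bases_to_iupac <- function(bases) {
  if (length(bases) == 0L) return("N")
  key <- paste(sort(unique(bases)), collapse = "")
  IUPAC_FROM_SET[[key]]
}

#' Complement of an IUPAC nucleotide string
#' @param x IUPAC string (no reversal is applied).
#' @return complemented string.
#' @export
iupac_complement <- function(x) {
  chartr(paste(names(IUPAC_COMPLEMENT), collapse = ""),
         paste(IUPAC_COMPLEMENT, collapse = ""), toupper(x))
}

normalize_position_label <- function(p) {
  p <- gsub("−", "-", trimws(as.character(p)))  # unicode minus
  p <- sub("^\\+", "", p)
  v <- suppressWarnings(as.integer(p))
  if (anyNA(v) || !all(v %in% c(-1L, 2L, 3L, 6L, 10L)))
    stop(sprintf("unknown helix position label: %s",
                 paste(unique(p[is.na(v) | !v %in% c(-1L, 2L, 3L, 6L, 10L)]),
                       collapse = ", ")))
  v
}

#' Load a recognition-code table
#'
#' Reads a delimited text table with columns `position` (helix position
#' label: -1, +2, +3, +6 or +10), `amino_acid` (one-letter code) and
#' `bases` (string over A/C/G/T listing the preferred bases, e.g. "GT").
#' Lines starting with `#` are comments. Duplicate (position, amino acid)
#' rows are resolved last-wins with a warning. The packaged default
#' (`system.file("extdata", "recognition_code.tsv", package = "zfarray")`)
#' holds classical canonical-code entries and is meant to be replaced or
#' extended by the user.
#'
#' @param path table file; default the packaged table.
#' @return a `RecognitionCodeTable` data.frame with integer `position`,
#'   `amino_acid`, `bases`.
#' @export
load_code_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "recognition_code.tsv",
                                package = "zfarray")
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf("recognition-code table not found: %s", path))
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("position", "amino_acid", "bases")
  if (!all(need %in% names(tab)))
    stop(sprintf("code table must have columns %s", paste(need, collapse = ", ")))
  tab$position <- normalize_position_label(tab$position)
  tab$amino_acid <- toupper(trimws(tab$amino_acid))
  if (!all(tab$amino_acid %in% AA1))
    stop("code table contains an unknown amino-acid code")
  tab$bases <- toupper(trimws(tab$bases))
  ok <- grepl("^[ACGT]+$", tab$bases)
  if (!all(ok))
    stop(sprintf("code table contains a base outside A/C/G/T: '%s'",
                 tab$bases[!ok][1L]))
  key <- paste(tab$position, tab$amino_acid)
  if (anyDuplicated(key)) {
    warning(sprintf("duplicate code entries for %s; keeping the last",
                    paste(unique(key[duplicated(key)]), collapse = "; ")))
    tab <- tab[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  rownames(tab) <- NULL
  class(tab) <- c("RecognitionCodeTable", "data.frame")
  tab
}

code_lookup <- function(code, position, aa) {
  if (is.na(aa) || !nzchar(aa)) return(character(0))
  hit <- code$bases[code$position == position & code$amino_acid == aa]
  if (length(hit) == 0L) return(character(0))
  strsplit(hit[1L], "")[[1L]]
}

#' Predict the DNA subsite of one finger
#'
#' Looks up the finger's key residues in the recognition-code table and
#' assembles the preferred subsite 5' to 3' on the finger's reading
#' strand: +6 gives the 5' base, +3 the middle, -1 the 3' base. When the
#' +2 residue has a code entry, its cross-strand contact is reported as
#' the complement base appended 3' (fourth character). In bulged-out
#' fingers without a +2 entry, a +10 entry instead prepends a 5' base.
#' Positions without an entry yield N; several preferred bases collapse to
#' the IUPAC ambiguity code.
#'
#' @param finger one row of a [scan_fingers()] table (key residues filled).
#' @param code a `RecognitionCodeTable` (default: packaged table).
#' @return a `SubsitePrediction`: list with `finger_id`, `subsite`
#'   (IUPAC, 3-4 characters), and `per_position_basis` (label ->
#'   list(residue, bases)).
#' @export
predict_subsite <- function(finger, code = load_code_table()) {
  stopifnot(nrow(finger) == 1L)
  aa_at <- function(lab) {
    col <- paste0("aa_", key_col(lab))
    if (!col %in% names(finger))
      stop("finger annotation lacks key-residue columns")
    finger[[col]]
  }
  basis <- list()
  core_labs <- c("+6", "+3", "-1")
  core <- vapply(core_labs, function(lab) {
    aa <- aa_at(lab)
    bases <- code_lookup(code, normalize_position_label(lab), aa)
    basis[[lab]] <<- list(residue = aa, bases = bases)
    bases_to_iupac(bases)
  }, character(1))
  subsite <- paste(core, collapse = "")
  aa2 <- aa_at("+2")
  b2 <- code_lookup(code, 2L, aa2)
  if (length(b2) > 0L) {
    basis[["+2"]] <- list(residue = aa2, bases = b2)
    subsite <- paste0(subsite, iupac_complement(bases_to_iupac(b2)))
  } else if (identical(finger$helix_class, "bulged_out")) {
    aa10 <- aa_at("+10")
    b10 <- code_lookup(code, 10L, aa10)
    if (length(b10) > 0L) {
      basis[["+10"]] <- list(residue = aa10, bases = b10)
      subsite <- paste0(bases_to_iupac(b10), subsite)
    }
  }
  structure(list(finger_id = paste0("ZF", finger$index),
                 finger_index = finger$index,
                 subsite = subsite,
                 per_position_basis = basis),
            class = "SubsitePrediction")
}

#' Predict subsites for a whole finger table
#'
#' @param fingers [scan_fingers()] table.
#' @param code a `RecognitionCodeTable`.
#' @return data.frame `finger_index`, `finger_id`, `subsite`, with the
#'   list of full `SubsitePrediction` objects as attribute `predictions`.
#' @export
predict_subsites <- function(fingers, code = load_code_table()) {
  preds <- lapply(seq_len(nrow(fingers)), function(i)
    predict_subsite(fingers[i, ], code))
  out <- data.frame(
    finger_index = vapply(preds, `[[`, integer(1), "finger_index"),
    finger_id = vapply(preds, `[[`, character(1), "finger_id"),
    subsite = vapply(preds, `[[`, character(1), "subsite"),
    stringsAsFactors = FALSE
  )
  attr(out, "predictions") <- preds
  out
}

#' Assemble the composite site of a tandem unit
#'
#' Consecutive fingers bind antiparallel to the DNA: each C-terminal
#' neighbour reads the next subsite toward the 5' end. The composite
#' predicted site is therefore the member subsites concatenated in reverse
#' finger order, 5' to 3'.
#'
#' @param unit integer vector of finger indices (one tandem unit, N- to
#'   C-terminal order).
#' @param subsites data.frame from [predict_subsites()] (or any frame with
#'   `finger_index` and `subsite`).
#' @return a `CompositePrediction`: list with `unit` and `sequence`.
#' @export
assemble_composite <- function(unit, subsites) {
  idx <- match(unit, subsites$finger_index)
  if (anyNA(idx))
    stop(sprintf("no subsite prediction for finger(s) %s",
                 paste(unit[is.na(idx)], collapse = ", ")))
  structure(list(unit = unit,
                 sequence = paste(rev(subsites$subsite[idx]), collapse = "")),
            class = "CompositePrediction")
}

iupac_at_gc <- function(chars) {
  at <- c("A", "T", "W")
  gc <- c("G", "C", "S")
  c(at = sum(chars %in% at), gc = sum(chars %in% gc))
}

#' AT/GC composition of predicted subsites by protein half
#'
#' Splits the fingers into an N-terminal half (indices up to
#' `ceiling(n/2)`) and a C-terminal half and reports, for each half, the
#' fraction of predicted bases that are A/T versus G/C. Only bases whose
#' IUPAC code resolves unambiguously to one class count (A, T, W versus
#' G, C, S); N and mixed codes are ignored. Halves with no informative
#' base report NA fractions.
#'
#' @param subsites data.frame from [predict_subsites()].
#' @param n_fingers total finger count (defaults to the largest index).
#' @return data.frame: `half`, `fingers`, `n_informative`, `at_fraction`,
#'   `gc_fraction`.
#' @export
gc_at_summary <- function(subsites, n_fingers = NULL) {
  n_fingers <- n_fingers %||% max(subsites$finger_index)
  cut <- ceiling(n_fingers / 2)
  half_of <- ifelse(subsites$finger_index <= cut, "N-terminal", "C-terminal")
  summarise <- function(half) {
    chars <- unlist(strsplit(subsites$subsite[half_of == half], ""))
    counts <- iupac_at_gc(chars)
    tot <- sum(counts)
    data.frame(
      half = half,
      fingers = paste(range(subsites$finger_index[half_of == half]),
                      collapse = "-"),
      n_informative = tot,
      at_fraction = if (tot > 0) counts[["at"]] / tot else NA_real_,
      gc_fraction = if (tot > 0) counts[["gc"]] / tot else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  halves <- intersect(c("N-terminal", "C-terminal"), unique(half_of))
  out <- do.call(rbind, lapply(halves, summarise))
  rownames(out) <- NULL
  out
}
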