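# C2H2 zinc-finger detection and classification from protein sequence.
#
# A finger is the pattern  C -x(cys_spacer)- C -x(core)- H -x(his_spacer)- H
# with cys_spacer in 2..4, core in 10..14 and his_spacer in 3..5 by default.
# The his spacer sets the recognition-helix class: 3 -> canonical H-X3-H,
# 4 -> bulged-out H-X4-H (one residue inserted into the helix, which bulges
# into a looser turn closed by a pi i->i-5 backbone hydrogen bond between
# the two histidines), anything else -> "other". The cys spacer sets the
# beta-loop class: 2 -> C-X2-C (Kruppel-like), 4 -> C-X4-C (extended loop).

KEY_LABELS <- c("-1", "+2", "+3", "+6", "+10")
# helix position +7 is the first coordinating His; offsets relative to his1
KEY_OFFSETS <- c(`-1` = -8L, `+2` = -5L, `+3` = -4L, `+6` = -1L, `+10` = 3L)

classify_helix <- function(his_spacer) {
  ifelse(his_spacer == 3L, "canonical",
         ifelse(his_spacer == 4L, "bulged_out", "other"))
}

classify_loop <- function(cys_spacer) {
  ifelse(cys_spacer == 2L, "CX2C",
         ifelse(cys_spacer == 4L, "CX4C", "other"))
}

# one annotated finger as a data.frame row; shared by the scanner and the
# synthetic ground-truth generator so both honour the same invariants
finger_row <- function(index, cys1, cys2, his1, his2, seq) {
  stopifnot(cys1 < cys2, cys2 < his1, his1 < his2)
  cys_spacer <- cys2 - cys1 - 1L
  his_spacer <- his2 - his1 - 1L
  helix_class <- classify_helix(his_spacer)
  row <- data.frame(
    index = as.integer(index),
    start = max(1L, cys1 - 2L),
    end = his2,
    cys1 = cys1, cys2 = cys2, his1 = his1, his2 = his2,
    cys_spacer = cys_spacer, his_spacer = his_spacer,
    helix_class = helix_class,
    loop_class = classify_loop(cys_spacer),
    stringsAsFactors = FALSE
  )
  keys <- key_positions_at(his1, helix_class, seq)
  for (lab in KEY_LABELS) {
    safe <- key_col(lab)
    row[[paste0("pos_", safe)]] <- keys$pos[[lab]] %||% NA_integer_
    row[[paste0("aa_", safe)]] <- keys$aa[[lab]] %||% NA_character_
  }
  row
}

key_col <- function(label) {
  chartr("-+", "mp", label)  # "-1" -> "m1", "+10" -> "p10"
}

key_positions_at <- function(his1, helix_class, seq) {
  labs <- KEY_LABELS
  if (helix_class != "bulged_out") labs <- setdiff(labs, "+10")
  pos <- list(); aa <- list()
  for (lab in labs) {
    p <- his1 + KEY_OFFSETS[[lab]]
    if (p < 1L || p > nchar(seq))
      stop(sprintf("key position %s of finger with His at %d falls outside the sequence",
                   lab, his1))
    pos[[lab]] <- as.integer(p)
    aa[[lab]] <- substring(seq, p, p)
  }
  list(pos = pos, aa = aa)
}

check_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  bad <- setdiff(unique(strsplit(seq, "")[[1L]]), AA1)
  if (length(bad) > 0L)
    stop(sprintf("sequence contains non-amino-acid characters: %s",
                 paste(bad, collapse = ", ")))
  seq
}

#' Scan a protein sequence for C2H2 zinc-finger motifs
#'
#' Greedy left-to-right scan for the pattern Cys, `cys_spacer` residues,
#' Cys, `core_spacer` residues, His, `his_spacer` residues, His. Matches do
#' not overlap; at each anchor the shortest spacers win ties, which keeps
#' the scan deterministic on tandem arrays. The reported finger spans
#' `cys1 - 2` (clamped to 1) through the second His. Each finger carries
#' its spacer classes, helix class (canonical / bulged_out / other),
#' beta-loop class (CX2C / CX4C / other) and the key DNA-contacting helix
#' positions -1, +2, +3, +6 (and +10 for bulged-out fingers), located
#' relative to the first coordinating His (helix position +7).
#'
#' @param seq uppercase one-letter amino-acid string (length >= 20).
#' @param cys_spacer,core_spacer,his_spacer integer windows
#'   `c(min, max)` for the three spacers.
#' @return data.frame with one row per finger: `index`, `start`, `end`,
#'   `cys1`, `cys2`, `his1`, `his2`, `cys_spacer`, `his_spacer`,
#'   `helix_class`, `loop_class`, and key-position columns
#'   `pos_m1`/`aa_m1`, `pos_p2`/`aa_p2`, `pos_p3`/`aa_p3`,
#'   `pos_p6`/`aa_p6`, `pos_p10`/`aa_p10` (NA where not applicable).
#'   Zero rows when nothing matches.
#' @examples
#' scan_fingers("AAACAACAAAAKAAAAAAFAAHAAAHAAA")
#' @export
scan_fingers <- function(seq, cys_spacer = c(2L, 4L), core_spacer = c(10L, 14L),
                         his_spacer = c(3L, 5L)) {
  seq <- check_sequence(seq)
  n <- nchar(seq)
  if (n < 20L) stop("sequence too short to contain a C2H2 finger (length < 20)")
  ch <- strsplit(seq, "")[[1L]]
  rows <- list()
  idx <- 0L
  i <- 1L
  while (i <= n - 19L) {
    if (ch[i] != "C") { i <- i + 1L; next }
    hit <- NULL
    for (cs in seq.int(cys_spacer[1L], cys_spacer[2L])) {
      c2 <- i + cs + 1L
      if (c2 > n || ch[c2] != "C") next
      for (core in seq.int(core_spacer[1L], core_spacer[2L])) {
        h1 <- c2 + core + 1L
        if (h1 > n || ch[h1] != "H") next
        for (hs in seq.int(his_spacer[1L], his_spacer[2L])) {
          h2 <- h1 + hs + 1L
          if (h2 > n || ch[h2] != "H") next
          hit <- c(i, c2, h1, h2)
          break
        }
        if (!is.null(hit)) break
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) { i <- i + 1L; next }
    idx <- idx + 1L
    rows[[idx]] <- finger_row(idx, hit[1L], hit[2L], hit[3L], hit[4L], seq)
    i <- hit[4L] + 1L
  }
  if (idx == 0L) return(empty_finger_table())
  do.call(rbind, rows)
}

empty_finger_table <- function() {
  out <- finger_row(1L, 3L, 6L, 17L, 21L, strrep("A", 30L))
  out[0L, , drop = FALSE]
}

#' Census of bulged-out recognition helices
#'
#' @param fingers finger table from [scan_fingers()].
#' @return list with `n_total`, `n_bulged`, `fraction` and `percent`
#'   (fraction as a percentage rounded to the nearest integer).
#' @export
classify_bulged_out <- function(fingers) {
  if (is.null(fingers) || nrow(fingers) == 0L)
    stop("cannot take a census of an empty finger list")
  n <- nrow(fingers)
  nb <- sum(fingers$helix_class == "bulged_out")
  list(n_total = n, n_bulged = nb, fraction = nb / n,
       percent = round(100 * nb / n))
}

#' Key DNA-contacting helix positions of one finger
#'
#' Maps the helix position labels -1, +2, +3, +6 (and +10 for bulged-out
#' fingers) to sequence positions and residues. The first coordinating His
#' sits at helix position +7, so label -1 is his1 - 8, +2 is his1 - 5,
#' +3 is his1 - 4, +6 is his1 - 1, and +10 is his1 + 3 (the extended
#' contact inside the wider bulged-out turn).
#'
#' @param finger a single-row finger table (one row of [scan_fingers()]).
#' @param seq the sequence the finger was annotated on.
#' @return named list: label -> list(position, residue).
#' @export
key_positions <- function(finger, seq) {
  seq <- check_sequence(seq)
  stopifnot(nrow(finger) == 1L)
  keys <- key_positions_at(finger$his1, finger$helix_class, seq)
  out <- lapply(names(keys$pos), function(lab)
    list(position = keys$pos[[lab]], residue = keys$aa[[lab]]))
  names(out) <- names(keys$pos)
  out
}

#' Annotate the linkers between consecutive fingers
#'
#' The linker is the stretch strictly between one finger's last His and the
#' next finger's start. Type `canonical_TGEKP` matches the conserved
#' T-G-\[E/Q\]-\[K/R\]-\[P/S\] five-residue linker that snap-locks the
#' preceding helix on DNA binding; linkers longer than `long_threshold`
#' residues are `long_spacer`; everything else (e.g. KKIK, KRNVKV, GAAP)
#' is `atypical`.
#'
#' @param fingers finger table with >= 2 rows.
#' @param seq the annotated sequence.
#' @param long_threshold length above which a linker is a long spacer.
#' @return data.frame: `upstream_finger`, `downstream_finger`, `sequence`,
#'   `length`, `linker_type`.
#' @export
annotate_linkers <- function(fingers, seq, long_threshold = 8L) {
  seq <- check_sequence(seq)
  if (is.null(fingers) || nrow(fingers) < 2L)
    stop("linker annotation needs at least two fingers")
  out <- lapply(seq_len(nrow(fingers) - 1L), function(i) {
    up <- fingers[i, ]
    down <- fingers[i + 1L, ]
    len <- down$start - up$end - 1L
    if (len < 0L)
      stop(sprintf("fingers %d and %d overlap; cannot annotate a linker",
                   up$index, down$index))
    lseq <- if (len == 0L) "" else substring(seq, up$end + 1L, down$start - 1L)
    type <- if (grepl("^TG[EQ][KR][PS]$", lseq)) "canonical_TGEKP"
    else if (len > long_threshold) "long_spacer"
    else "atypical"
    data.frame(upstream_finger = up$index, downstream_finger = down$index,
               sequence = lseq, length = len, linker_type = type,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Group fingers into tandem DNA-recognition units
#'
#' Maximal runs of consecutive fingers whose connecting linkers are at most
#' `threshold` residues long. The output partitions the finger list in
#' order.
#'
#' @param fingers finger table.
#' @param linkers linker table from [annotate_linkers()] (computed if NULL).
#' @param seq sequence, needed only when `linkers` is NULL.
#' @param threshold maximum linker length inside one unit (residues).
#' @return list of integer vectors of finger indices, one per unit.
#' @export
group_tandem_units <- function(fingers, linkers = NULL, seq = NULL,
                               threshold = 8L) {
  if (is.null(fingers) || nrow(fingers) == 0L) return(list())
  if (nrow(fingers) == 1L) return(list(fingers$index))
  if (is.null(linkers)) {
    if (is.null(seq)) stop("either linkers or seq must be supplied")
    linkers <- annotate_linkers(fingers, seq, long_threshold = threshold)
  }
  breaks <- which(linkers$length > threshold)
  bounds <- c(0L, breaks, nrow(fingers))
  lapply(seq_len(length(bounds) - 1L), function(k)
    fingers$index[(bounds[k] + 1L):bounds[k + 1L]])
}

#' Locate AT-hook motifs (G-R-P core)
#'
#' Minimal architecture landmark: positions where the Gly-Arg-Pro core of
#' an AT-hook occurs. No flanking-context scoring is attempted.
#'
#' @param seq amino-acid string.
#' @return integer vector of core start positions (possibly empty).
#' @export
find_at_hooks <- function(seq) {
  seq <- check_sequence(seq)
  out <- gregexpr("GRP", seq, fixed = TRUE)[[1L]]
  if (out[1L] == -1L) integer(0) else as.integer(out)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file (single or multi-record).
#' @return named character vector of uppercase sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop(sprintf("no sequences in FASTA file %s", path))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) stop(sprintf("empty sequence record in %s", path))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs
}
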