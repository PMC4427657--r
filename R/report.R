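# Workflow runners tying the stages together (scan -> helices ->
# flexibility -> subsite prediction) with TSV output and a JSON mirror.
# These functions, together with the thin dispatcher shipped at
# inst/scripts/zfa.R, form the command-line surface of the package.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_json_mirror <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the sequence-scan stage
#'
#' Reads a FASTA file (or takes a raw sequence), scans for C2H2 fingers,
#' annotates linkers and tandem units, and writes `fingers.tsv`,
#' `linkers.tsv`, `units.tsv` and `scan.json` into `out_dir`. Finding no
#' fingers is not an error: empty tables are written and a notice logged.
#'
#' @param fasta path to a FASTA file (first record is scanned) -- or NULL
#'   when `sequence` is given directly.
#' @param sequence amino-acid string, alternative to `fasta`.
#' @param out_dir output directory (created if needed); NULL writes nothing.
#' @param tandem_threshold maximum linker length within a tandem unit.
#' @return invisibly, list with `sequence_name`, `fingers`, `linkers`,
#'   `units`, `at_hooks`.
#' @export
run_scan <- function(fasta = NULL, sequence = NULL, out_dir = NULL,
                     tandem_threshold = 8L) {
  if (is.null(fasta) == is.null(sequence))
    stop("supply exactly one of fasta or sequence")
  if (!is.null(fasta)) {
    seqs <- read_protein_fasta(fasta)
    sequence <- seqs[[1L]]
    seq_name <- names(seqs)[1L]
  } else {
    sequence <- check_sequence(sequence)
    seq_name <- "sequence"
  }
  fingers <- scan_fingers(sequence)
  if (nrow(fingers) == 0L)
    message("scan: no C2H2 fingers found in ", seq_name)
  linkers <- if (nrow(fingers) >= 2L)
    annotate_linkers(fingers, sequence, long_threshold = tandem_threshold)
  else
    data.frame(upstream_finger = integer(0), downstream_finger = integer(0),
               sequence = character(0), length = integer(0),
               linker_type = character(0))
  units <- if (nrow(fingers) > 0L)
    group_tandem_units(fingers, linkers, threshold = tandem_threshold)
  else list()
  unit_tab <- if (length(units) > 0L)
    data.frame(unit = rep(seq_along(units), lengths(units)),
               finger_index = unlist(units))
  else data.frame(unit = integer(0), finger_index = integer(0))
  res <- list(sequence_name = seq_name, fingers = fingers, linkers = linkers,
              units = units, at_hooks = find_at_hooks(sequence))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(fingers, file.path(out_dir, "fingers.tsv"))
    write_tsv(linkers, file.path(out_dir, "linkers.tsv"))
    write_tsv(unit_tab, file.path(out_dir, "units.tsv"))
    write_json_mirror(list(sequence_name = seq_name, fingers = fingers,
                           linkers = linkers, units = units,
                           at_hooks = res$at_hooks),
                      file.path(out_dir, "scan.json"))
  }
  invisible(res)
}

#' Run the structure-analysis stage
#'
#' Computes helix reports for the given fingers on an ensemble and, when
#' two or more residue ranges are supplied, the interfinger flexibility of
#' every other range after fitting on the central one (mirroring the
#' central-finger-fitted presentation customary for tandem arrays).
#' Writes `helices.tsv`, `bulged_helices.tsv`, `flexibility.tsv` and
#' `structure.json` into `out_dir`.
#'
#' @param pdb path to a (multi-model) PDB file.
#' @param fingers finger table ([scan_fingers()]); NULL skips helix reports.
#' @param ranges named list of [residue_range()] (e.g. finger domain
#'   ranges); NULL skips flexibility.
#' @param fit_name name (in `ranges`) of the finger to fit on; default the
#'   central element.
#' @param numbering_offset sequence-to-structure numbering shift (or
#'   `"auto"` to detect it from the coordinating residues of the first
#'   mappable finger).
#' @param chain chain identifier.
#' @param atom_names atoms for the flexibility statistic.
#' @param out_dir output directory; NULL writes nothing.
#' @return invisibly, list with `helices`, `bulged_table`, `flexibility`
#'   (list of `FlexibilityResult`), `ranking`.
#' @export
run_structure_analysis <- function(pdb, fingers = NULL, ranges = NULL,
                                   fit_name = NULL, numbering_offset = 0L,
                                   chain = "A", atom_names = "CA",
                                   out_dir = NULL) {
  ens <- read_ensemble(pdb)
  helices <- NULL
  bulged <- NULL
  if (!is.null(fingers) && nrow(fingers) > 0L) {
    if (identical(numbering_offset, "auto")) {
      numbering_offset <- detect_numbering_offset(ens, fingers[1L, ], chain)
      message("structure: detected numbering offset ", numbering_offset)
    }
    helices <- analyze_helices(ens, fingers, numbering_offset, chain,
                               skip_outside = TRUE)
    bulged <- tabulate_bulged_helices(helices)
  }
  flex <- NULL
  ranking <- NULL
  if (!is.null(ranges) && length(ranges) >= 2L) {
    if (is.null(names(ranges)))
      names(ranges) <- paste0("range", seq_along(ranges))
    fit_name <- fit_name %||% names(ranges)[ceiling(length(ranges) / 2)]
    if (!fit_name %in% names(ranges))
      stop(sprintf("fit_name '%s' is not among the supplied ranges", fit_name))
    fit <- ranges[[fit_name]]
    others <- setdiff(names(ranges), fit_name)
    flex <- lapply(others, function(nm)
      interfinger_flexibility(ens, fit, ranges[[nm]], atom_names))
    names(flex) <- others
    labels <- sprintf("%s-fitted %s", fit_name, others)
    ranking <- if (length(flex) >= 2L) compare_flexibility(flex, labels)
    else flexibility_table(flex, labels)
  }
  res <- list(helices = helices, bulged_table = bulged,
              flexibility = flex, ranking = ranking)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(helices)) {
      write_tsv(helices, file.path(out_dir, "helices.tsv"))
      write_tsv(bulged, file.path(out_dir, "bulged_helices.tsv"))
    }
    if (!is.null(ranking))
      write_tsv(ranking, file.path(out_dir, "flexibility.tsv"))
    write_json_mirror(list(
      helices = helices, bulged_table = bulged,
      flexibility = lapply(flex, function(x)
        list(fit = unclass(x$fit_range), measure = unclass(x$measure_range),
             mean = x$mean, sd = x$sd, n = x$n,
             per_model_rmsd = x$per_model_rmsd)),
      ranking = ranking), file.path(out_dir, "structure.json"))
  }
  invisible(res)
}

#' Run the subsite-prediction stage
#'
#' Predicts the DNA subsite of every finger from the recognition-code
#' table, groups fingers into tandem units and assembles the composite
#' antiparallel site per unit. Writes `subsites.tsv`, `composites.tsv`,
#' `composition.tsv` and `predict.json` into `out_dir`. Fingers whose key
#' residues have no code entries yield all-N subsites (with a warning),
#' never an error.
#'
#' @param fingers finger table from [scan_fingers()].
#' @param code_table path to a recognition-code table, or a loaded
#'   `RecognitionCodeTable`; default the packaged table.
#' @param units list of tandem units (from [group_tandem_units()]);
#'   computed from the finger gaps when NULL.
#' @param tandem_threshold maximum linker length within a unit.
#' @param out_dir output directory; NULL writes nothing.
#' @return invisibly, list with `subsites`, `composites`, `composition`.
#' @export
run_predict <- function(fingers, code_table = NULL, units = NULL,
                        tandem_threshold = 8L, out_dir = NULL) {
  if (is.null(fingers) || nrow(fingers) == 0L)
    stop("no fingers to predict subsites for")
  code <- if (inherits(code_table, "RecognitionCodeTable")) code_table
  else load_code_table(code_table)
  subsites <- predict_subsites(fingers, code)
  if (any(grepl("^N+$", subsites$subsite)))
    warning(sprintf("finger(s) %s have no recognition-code entries (all-N subsite)",
                    paste(subsites$finger_id[grepl("^N+$", subsites$subsite)],
                          collapse = ", ")))
  if (is.null(units)) {
    gaps <- fingers$start[-1L] - fingers$end[-nrow(fingers)] - 1L
    breaks <- which(gaps > tandem_threshold)
    bounds <- c(0L, breaks, nrow(fingers))
    units <- lapply(seq_len(length(bounds) - 1L), function(k)
      fingers$index[(bounds[k] + 1L):bounds[k + 1L]])
  }
  composites <- data.frame(
    unit = seq_along(units),
    fingers = vapply(units, function(u) paste0("ZF", u[1L], "-ZF", u[length(u)]),
                     character(1)),
    sequence = vapply(units, function(u) assemble_composite(u, subsites)$sequence,
                      character(1)),
    stringsAsFactors = FALSE
  )
  composition <- gc_at_summary(subsites, n_fingers = max(fingers$index))
  res <- list(subsites = subsites, composites = composites,
              composition = composition)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(subsites, file.path(out_dir, "subsites.tsv"))
    write_tsv(composites, file.path(out_dir, "composites.tsv"))
    write_tsv(composition, file.path(out_dir, "composition.tsv"))
    write_json_mirror(res, file.path(out_dir, "predict.json"))
  }
  invisible(res)
}

#' Re-run the full analysis on locally available reference depositions
#'
#' Convenience driver for validating the pipeline against the deposited
#' reference data it was designed around: a directory containing
#' `Q9P243.fasta` (human ZFAT) and multi-model PDB files named by
#' accession (`2RV6.pdb`, `2RV7.pdb`, and the single-finger entries).
#' Runs the sequence scan (finger count, bulged-out census, C-X4-C
#' fingers), per-domain helix dihedral statistics, and the four
#' central-finger-fitted interfinger RMSDs on the two tandem ensembles.
#' None of these files ship with the package (they are external database
#' depositions); point `data_dir` at local copies.
#'
#' @param data_dir directory holding the FASTA/PDB files named above.
#' @param chain chain identifier in the depositions.
#' @return list with `scan` (census etc.), `helices` (per available
#'   domain), `flexibility` (the four fitted RMSDs).
#' @export
reproduce_reference_analysis <- function(data_dir, chain = "A") {
  fasta <- file.path(data_dir, "Q9P243.fasta")
  if (!file.exists(fasta))
    stop(sprintf("reference data not found: %s (download the deposition first)",
                 fasta))
  scan <- run_scan(fasta = fasta)
  census <- classify_bulged_out(scan$fingers)
  cx4c <- scan$fingers$index[scan$fingers$loop_class == "CX4C"]

  helix_entries <- list(
    hZF4 = "2RUV", hZF5 = "2RUW", hZF10 = "2RUY", hZF12 = "2RV0",
    mZF5 = "2RV4", mZF8 = "2RV5")
  helices <- list()
  for (nm in names(helix_entries)) {
    pdb <- file.path(data_dir, paste0(helix_entries[[nm]], ".pdb"))
    if (!file.exists(pdb)) next
    ens <- read_ensemble(pdb)
    # annotate fingers directly on the deposited construct sequence via
    # the structure's own residue names
    m <- ens$models[[1L]]
    m <- m[m$chain == chain & m$atom == "CA", ]
    seq3 <- stats::setNames(names(one_to_three), one_to_three)
    seq <- paste(seq3[m$resname], collapse = "")
    f <- scan_fingers(seq)
    if (nrow(f) == 0L) next
    off <- min(m$resno) - 1L
    helices[[nm]] <- analyze_helix(ens, f[1L, ], numbering_offset = off,
                                   chain = chain, finger_id = nm)
  }

  flex <- list()
  tandem <- list(
    `2RV7` = list(fit = c(324L, 353L), measure = list(ZF3 = c(297L, 325L),
                                                      ZF5 = c(352L, 381L))),
    `2RV6` = list(fit = c(297L, 325L), measure = list(ZF2 = c(269L, 297L),
                                                      ZF4 = c(324L, 353L))))
  for (acc in names(tandem)) {
    pdb <- file.path(data_dir, paste0(acc, ".pdb"))
    if (!file.exists(pdb)) next
    ens <- read_ensemble(pdb)
    spec <- tandem[[acc]]
    fit <- residue_range(chain, spec$fit[1L], spec$fit[2L])
    for (nm in names(spec$measure)) {
      mr <- spec$measure[[nm]]
      # truncate the one-residue bookkeeping overlap between neighbouring
      # domain ranges out of the measured range
      if (mr[1L] <= spec$fit[2L] && mr[2L] >= spec$fit[1L]) {
        if (mr[1L] < spec$fit[1L]) mr[2L] <- spec$fit[1L] - 1L else mr[1L] <- spec$fit[2L] + 1L
      }
      flex[[paste0(acc, "_fitted_", nm)]] <-
        interfinger_flexibility(ens, fit, residue_range(chain, mr[1L], mr[2L]))
    }
  }
  list(scan = list(n_fingers = nrow(scan$fingers), census = census,
                   cx4c_fingers = cx4c),
       helices = helices, flexibility = flex)
}
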