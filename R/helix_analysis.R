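# Structural characterisation of the recognition helix of each finger:
# ensemble phi/psi statistics at the second coordinating His, presence of
# the pi i->i-5 backbone hydrogen bond, and distance of the observed
# geometry from ideal alpha- and pi-helical dihedrals.

#' Ideal helix dihedral reference values
#'
#' Literature reference backbone dihedrals: ideal alpha helix
#' (phi = -65.0, psi = -40.0) and ideal pi helix (phi = -57.1,
#' psi = -69.7), degrees. Bulged-out C2H2 helices form the pi-type
#' i->i-5 hydrogen bond yet sit far from both references, which is why
#' they are classed as "bulged-out" rather than pi-helical.
#'
#' @return list with elements `alpha` and `pi`, each `list(phi, psi)`.
#' @export
ideal_helix_constants <- function() {
  list(alpha = list(phi = -65.0, psi = -40.0),
       pi = list(phi = -57.1, psi = -69.7))
}

#' Helix geometry report for one finger over an NMR ensemble
#'
#' Computes the ensemble circular mean +/- SD of phi at the second
#' coordinating His and of psi at the residue just before it, the fraction
#' of models forming the pi i->i-5 backbone hydrogen bond donated by the
#' second His (for a bulged-out H-X4-H finger the acceptor i-5 is exactly
#' the first His), and the shortest angular distance of the phi mean from
#' the ideal alpha and pi helix values.
#'
#' @param ens a `StructureEnsemble` covering the finger's residues.
#' @param finger one row of a [scan_fingers()] table (sequence numbering).
#' @param numbering_offset shift added to sequence positions to obtain
#'   structure (author) numbering; see [detect_numbering_offset()].
#' @param chain chain identifier in the structure.
#' @param finger_id label for the report row (default "ZF<index>").
#' @param hbond_fraction_min fraction of models above which the summary
#'   flag `pi_hbond` is TRUE.
#' @return one-row data.frame (`HelixReport`): `finger_id`, `helix_class`,
#'   `phi_mean`, `phi_sd`, `psi_mean`, `psi_sd`, `pi_hbond_fraction`,
#'   `pi_hbond`, `delta_from_ideal_alpha`, `delta_from_ideal_pi`, `n_models`.
#' @export
analyze_helix <- function(ens, finger, numbering_offset = 0L, chain = "A",
                          finger_id = NULL, hbond_fraction_min = 0.5) {
  stopifnot(inherits(ens, "StructureEnsemble"), nrow(finger) == 1L)
  his2 <- finger$his2 + numbering_offset
  first_res <- min(ens$models[[1L]]$resno[ens$models[[1L]]$chain == chain])
  last_res <- max(ens$models[[1L]]$resno[ens$models[[1L]]$chain == chain])
  if (his2 - 5L < first_res || his2 > last_res)
    stop(sprintf(
      "numbering offset %d maps the helix of finger %d outside the structure (%d-%d)",
      numbering_offset, finger$index, first_res, last_res))
  phi <- ensemble_dihedral_stats(ens, his2, "phi", chain)
  psi <- ensemble_dihedral_stats(ens, his2 - 1L, "psi", chain)
  hb <- vapply(ens$models, function(m)
    !is.null(detect_hbond(m, his2, his2 - 5L, chain)), logical(1))
  ideals <- ideal_helix_constants()
  data.frame(
    finger_id = finger_id %||% paste0("ZF", finger$index),
    helix_class = finger$helix_class,
    phi_mean = phi$mean, phi_sd = phi$sd,
    psi_mean = psi$mean, psi_sd = psi$sd,
    pi_hbond_fraction = mean(hb),
    pi_hbond = mean(hb) >= hbond_fraction_min,
    delta_from_ideal_alpha = abs(ang_diff(phi$mean, ideals$alpha$phi)),
    delta_from_ideal_pi = abs(ang_diff(phi$mean, ideals$pi$phi)),
    n_models = phi$n,
    stringsAsFactors = FALSE
  )
}

#' Helix reports for a whole finger table
#'
#' @inheritParams analyze_helix
#' @param fingers finger table from [scan_fingers()]; only fingers whose
#'   helix residues fall inside the structure are analysed when
#'   `skip_outside` is TRUE.
#' @param skip_outside silently drop fingers outside the structure range
#'   instead of raising a mapping error.
#' @return data.frame of stacked [analyze_helix()] rows.
#' @export
analyze_helices <- function(ens, fingers, numbering_offset = 0L, chain = "A",
                            skip_outside = FALSE) {
  rows <- list()
  for (i in seq_len(nrow(fingers))) {
    r <- tryCatch(
      analyze_helix(ens, fingers[i, ], numbering_offset, chain),
      error = function(e) if (skip_outside) NULL else stop(e))
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  }
  if (length(rows) == 0L)
    stop("no finger maps inside the structure under the given offset")
  do.call(rbind, rows)
}

#' Dihedral table of the bulged-out helices
#'
#' Restricts a set of helix reports to the bulged-out class and appends the
#' two ideal reference rows (pi then alpha), mirroring the customary
#' phi/psi summary table for these domains.
#'
#' @param reports data.frame of [analyze_helix()] rows.
#' @return data.frame with columns `finger_id`, `phi_mean`, `phi_sd`,
#'   `psi_mean`, `psi_sd`; ideal rows carry NA SDs.
#' @export
tabulate_bulged_helices <- function(reports) {
  if (is.null(reports) || nrow(reports) == 0L)
    stop("no helix reports to tabulate")
  keep <- reports[reports$helix_class == "bulged_out",
                  c("finger_id", "phi_mean", "phi_sd", "psi_mean", "psi_sd"),
                  drop = FALSE]
  ideals <- ideal_helix_constants()
  ref <- data.frame(
    finger_id = c("ideal_pi_helix", "ideal_alpha_helix"),
    phi_mean = c(ideals$pi$phi, ideals$alpha$phi),
    phi_sd = NA_real_,
    psi_mean = c(ideals$pi$psi, ideals$alpha$psi),
    psi_sd = NA_real_,
    stringsAsFactors = FALSE
  )
  out <- rbind(keep, ref)
  rownames(out) <- NULL
  out
}

#' Detect the sequence-to-structure numbering offset
#'
#' Deposited constructs often carry expression tags (e.g. a GSSGSSG
#' N-terminal tag) and author numbering that differs from the full-length
#' sequence numbering. This helper finds the offset under which the
#' finger's four coordinating positions land on CYS/CYS/HIS/HIS residue
#' names in the structure.
#'
#' @param ens a `StructureEnsemble`.
#' @param finger one finger row (sequence numbering).
#' @param chain chain identifier.
#' @return integer offset (structure = sequence + offset); error if no or
#'   several offsets match.
#' @export
detect_numbering_offset <- function(ens, finger, chain = "A") {
  stopifnot(nrow(finger) == 1L)
  m <- ens$models[[1L]]
  m <- m[m$chain == chain & m$atom == "CA", ]
  if (nrow(m) == 0L) stop(sprintf("chain %s has no residues", chain))
  offsets <- seq.int(min(m$resno) - finger$cys1, max(m$resno) - finger$his2)
  ok <- vapply(offsets, function(off) {
    nm <- m$resname[match(c(finger$cys1, finger$cys2, finger$his1, finger$his2) + off,
                          m$resno)]
    !anyNA(nm) && all(nm == c("CYS", "CYS", "HIS", "HIS"))
  }, logical(1))
  if (sum(ok) == 0L)
    stop("no numbering offset aligns the coordinating residues to the structure")
  if (sum(ok) > 1L)
    stop(sprintf("ambiguous numbering offset: %s all align the coordinating residues",
                 paste(offsets[ok], collapse = ", ")))
  offsets[ok]
}
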