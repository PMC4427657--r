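#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' matched point sets, via the SVD of the covariance matrix with the usual
#' determinant correction so that reflections are never returned.
#'
#' @param mobile,reference N x 3 coordinate matrices with matched rows
#'   (N >= 3).
#' @return an object of class `Superposition`: list with `rotation` (3x3,
#'   det +1), `translation` (length-3), and `rmsd` (Angstrom). The fitted
#'   mobile set is `mobile %*% t(rotation) + translation` (rows as points).
#' @examples
#' p <- matrix(rnorm(18), 6, 3)
#' kabsch_superpose(p, p)$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be N x 3 matrices of equal size")
  n <- nrow(mobile)
  if (n < 3L) stop("superposition is underdetermined with fewer than 3 points")
  if (!all(is.finite(mobile)) || !all(is.finite(reference)))
    stop("coordinates must be finite")
  mc <- colMeans(mobile)
  rc <- colMeans(reference)
  p <- sweep(mobile, 2L, mc)
  q <- sweep(reference, 2L, rc)
  cov <- crossprod(p, q)            # t(p) %*% q
  sv <- svd(cov)
  # near-degenerate (collinear) configurations are still resolved, with a
  # warning, and the reflection remains forbidden
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12))
    warning("point set is nearly collinear; rotation is poorly conditioned")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- p %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - q)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(rc - rot %*% mc),
                 rmsd = rmsd),
            class = "Superposition")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("<Superposition rmsd = %.4f A>\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sup a `Superposition`.
#' @param coords N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(sup, coords) {
  stopifnot(inherits(sup, "Superposition"))
  sweep(as.matrix(coords) %*% t(sup$rotation), 2L, sup$translation, "+")
}

#' Root-mean-square deviation between matched coordinate sets
#' @param a,b N x 3 matrices with matched rows.
#' @return RMSD in the coordinate units.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

backbone_atom <- function(model, chain, resno, atom, what) {
  xyz <- model_atom_xyz(model, chain, resno, atom)
  if (is.null(xyz))
    stop(sprintf("%s: atom %s of residue %s:%d not present",
                 what, atom, chain, resno))
  xyz
}

#' Backbone phi/psi dihedrals of one residue
#'
#' phi is the C(i-1)-N(i)-CA(i)-C(i) torsion and psi the
#' N(i)-CA(i)-C(i)-N(i+1) torsion, IUPAC sign convention, degrees in
#' (-180, 180]. Terminal residues have an undefined phi (no preceding C) or
#' psi (no following N) and raise a boundary error.
#'
#' @param model one model table of a `StructureEnsemble`
#'   (i.e. `ens$models[[i]]`).
#' @param resno residue number (author numbering).
#' @param chain chain identifier.
#' @return list with elements `phi` and `psi` (degrees).
#' @export
backbone_dihedrals <- function(model, resno, chain = "A") {
  list(phi = one_dihedral(model, resno, "phi", chain),
       psi = one_dihedral(model, resno, "psi", chain))
}

# one backbone torsion only (phi or psi), with its own boundary error, so
# that a chain-terminal residue can still deliver its defined angle
one_dihedral <- function(model, resno, angle, chain = "A") {
  n <- backbone_atom(model, chain, resno, "N", "dihedral")
  ca <- backbone_atom(model, chain, resno, "CA", "dihedral")
  cc <- backbone_atom(model, chain, resno, "C", "dihedral")
  if (angle == "phi") {
    prev_c <- model_atom_xyz(model, chain, resno - 1L, "C")
    if (is.null(prev_c))
      stop(sprintf("phi undefined for residue %s:%d: no preceding residue C atom",
                   chain, resno))
    torsion_points(prev_c, n, ca, cc)
  } else {
    next_n <- model_atom_xyz(model, chain, resno + 1L, "N")
    if (is.null(next_n))
      stop(sprintf("psi undefined for residue %s:%d: no following residue N atom",
                   chain, resno))
    torsion_points(n, ca, cc, next_n)
  }
}

#' Backbone hydrogen-bond test between two residues
#'
#' Tests the donor amide nitrogen of `donor_resno` against the carbonyl
#' oxygen of `acceptor_resno` with the common geometric criterion: N...O
#' distance below `no_cutoff`; when an amide hydrogen is present, also
#' H...O below `ho_cutoff` and an N-H...O angle above `angle_min`.
#' Used in particular for the pi (i to i-5) backbone bond that closes the
#' wider helical turn between the two zinc-coordinating histidines of a
#' bulged-out recognition helix.
#'
#' @param model one model table.
#' @param donor_resno,acceptor_resno residue numbers.
#' @param chain chain identifier.
#' @param no_cutoff N...O distance cutoff, Angstrom.
#' @param ho_cutoff H...O distance cutoff, Angstrom (applied only if an
#'   amide H is present).
#' @param angle_min minimum N-H...O angle, degrees.
#' @return an `HBond` list (`donor_residue`, `acceptor_residue`,
#'   `donor_acceptor_distance`, `angle` or NA) or `NULL` when the criterion
#'   is not met.
#' @export
detect_hbond <- function(model, donor_resno, acceptor_resno, chain = "A",
                         no_cutoff = 3.5, ho_cutoff = 2.6, angle_min = 120) {
  n <- backbone_atom(model, chain, donor_resno, "N", "hbond donor")
  o <- model_atom_xyz(model, chain, acceptor_resno, "O")
  if (is.null(o))
    stop(sprintf("hbond acceptor: atom O of residue %s:%d not present",
                 chain, acceptor_resno))
  d_no <- vnorm(n - o)
  if (d_no >= no_cutoff) return(NULL)
  h <- model_atom_xyz(model, chain, donor_resno, "H") %||%
    model_atom_xyz(model, chain, donor_resno, "HN")
  ang <- NA_real_
  if (!is.null(h)) {
    if (vnorm(h - o) >= ho_cutoff) return(NULL)
    ang <- angle_points(n, h, o)
    if (ang <= angle_min) return(NULL)
  }
  structure(list(donor_residue = donor_resno,
                 acceptor_residue = acceptor_resno,
                 donor_acceptor_distance = d_no,
                 angle = ang),
            class = "HBond")
}

#' Tetrahedral zinc-site geometry check
#'
#' Measures the four ligand-zinc distances (Cys Sgamma x2, His Nepsilon2 x2)
#' and the six ligand-zinc-ligand angles. When no zinc atom is present the
#' centroid of the four ligand atoms serves as a pseudo-zinc and the report
#' is flagged `"inferred"`. The site is flagged tetrahedral when all
#' distances fall within `dist_range` and all angles within `angle_range`
#' (defaults bracket restrained NMR coordination geometry).
#'
#' @param model one model table.
#' @param cys_resnos length-2 vector of the two Cys residue numbers.
#' @param his_resnos length-2 vector of the two His residue numbers.
#' @param chain chain identifier.
#' @param dist_range,angle_range acceptance windows (Angstrom / degrees).
#' @return list with `distances` (named, Angstrom), `angles` (named,
#'   degrees), `zinc_source` ("observed" or "inferred"), `tetrahedral`
#'   (logical) and `violations` (character).
#' @export
check_zinc_site <- function(model, cys_resnos, his_resnos, chain = "A",
                            dist_range = c(1.8, 2.6),
                            angle_range = c(90, 130)) {
  stopifnot(length(cys_resnos) == 2L, length(his_resnos) == 2L)
  lig_res <- c(cys_resnos, his_resnos)
  lig_atom <- c("SG", "SG", "NE2", "NE2")
  lig <- vector("list", 4L)
  for (i in 1:4) {
    xyz <- model_atom_xyz(model, chain, lig_res[i], lig_atom[i])
    if (is.null(xyz))
      stop(sprintf("zinc site incomplete: atom %s of residue %s:%d not present",
                   lig_atom[i], chain, lig_res[i]))
    lig[[i]] <- xyz
  }
  zn_rows <- which(model$atom == "ZN" & model$chain == chain)
  if (length(zn_rows) > 0L) {
    zn <- as.numeric(model[zn_rows[1L], c("x", "y", "z")])
    zinc_source <- "observed"
  } else {
    zn <- Reduce(`+`, lig) / 4
    zinc_source <- "inferred"
  }
  lab <- paste0(c("Cys", "Cys", "His", "His"), lig_res, ":", lig_atom)
  dists <- vapply(lig, function(p) vnorm(p - zn), numeric(1))
  names(dists) <- lab
  pairs <- utils::combn(4L, 2L)
  angs <- apply(pairs, 2L, function(ij) angle_points(lig[[ij[1]]], zn, lig[[ij[2]]]))
  names(angs) <- apply(pairs, 2L, function(ij) paste(lab[ij], collapse = "-"))
  bad_d <- dists < dist_range[1L] | dists > dist_range[2L]
  bad_a <- angs < angle_range[1L] | angs > angle_range[2L]
  violations <- c(
    if (any(bad_d)) sprintf("distance %s = %.2f A outside [%.1f, %.1f]",
                            names(dists)[bad_d], dists[bad_d],
                            dist_range[1L], dist_range[2L]),
    if (any(bad_a)) sprintf("angle %s = %.1f deg outside [%.0f, %.0f]",
                            names(angs)[bad_a], angs[bad_a],
                            angle_range[1L], angle_range[2L])
  )
  list(distances = dists, angles = angs, zinc_source = zinc_source,
       tetrahedral = length(violations) == 0L, violations = violations)
}

#' Circular mean and spread of a backbone dihedral over an ensemble
#'
#' Computes the chosen dihedral (phi or psi) of one residue in every model,
#' wraps the values into (-180, 180], takes the circular mean, and reports
#' the sample standard deviation of the shortest angular deviations from
#' that mean. Far from the wrap point this coincides with the arithmetic
#' mean +/- SD customarily printed for NMR ensembles; at the wrap it remains
#' well defined.
#'
#' @param ens a `StructureEnsemble`.
#' @param resno residue number.
#' @param angle `"phi"` or `"psi"`.
#' @param chain chain identifier.
#' @return list with `mean`, `sd` (degrees) and `n` (model count).
#' @export
ensemble_dihedral_stats <- function(ens, resno, angle = c("phi", "psi"),
                                    chain = "A") {
  stopifnot(inherits(ens, "StructureEnsemble"))
  angle <- match.arg(angle)
  vals <- vapply(seq_along(ens$models), function(i) {
    tryCatch(one_dihedral(ens$models[[i]], resno, angle, chain),
             error = function(e)
               stop(sprintf("model %d: %s", i, conditionMessage(e)),
                    call. = FALSE))
  }, numeric(1))
  m <- circular_mean(vals)
  dev <- ang_diff(vals, m)
  s <- if (length(vals) > 1L) stats::sd(dev) else 0
  list(mean = m, sd = s, n = length(vals))
}
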