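# Synthetic structures and sequences with known ground truth. These are the
# test-bed for every analysis stage: peptides built at prescribed backbone
# dihedrals, ensembles with controlled coordinate or hinge noise, and
# sequences with planted C2H2 motifs.

# Engh-Huber-like ideal backbone geometry (Angstrom / degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8

#' Specification for an ideal-geometry peptide build
#'
#' Bundles a sequence with per-residue backbone dihedrals. Bond lengths and
#' angles are fixed at ideal values (N-CA 1.458, CA-C 1.525, C-N 1.329 A);
#' only the torsions vary. `phi[1]` and `psi[n]` are not geometrically
#' constrained by neighbours but `psi[n]` still orients the final carbonyl.
#'
#' @param sequence uppercase one-letter amino-acid string.
#' @param phi,psi numeric vectors of backbone dihedrals in degrees, one per
#'   residue (scalars are recycled).
#' @param omega peptide-bond torsions in degrees (default 180, trans).
#' @return an object of class `BuildSpec`.
#' @examples
#' build_spec("AAAAAAAAAA", phi = -65, psi = -40)  # ideal alpha helix
#' @export
build_spec <- function(sequence, phi, psi, omega = 180) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 2L) stop("build spec needs at least 2 residues")
  aa <- strsplit(sequence, "")[[1L]]
  if (!all(aa %in% AA1)) stop("sequence contains non-amino-acid characters")
  rec <- function(v, what) {
    if (length(v) == 1L) v <- rep(v, n)
    if (length(v) != n)
      stop(sprintf("%s must have length 1 or %d (one per residue)", what, n))
    if (any(!is.finite(v)) || any(abs(v) > 180))
      stop(sprintf("%s values must be finite angles within [-180, 180]", what))
    as.numeric(v)
  }
  structure(list(sequence = sequence,
                 phi = rec(phi, "phi"), psi = rec(psi, "psi"),
                 omega = rec(omega, "omega")),
            class = "BuildSpec")
}

#' Build a peptide backbone at prescribed dihedrals
#'
#' Places backbone atoms (N, CA, C, O) by internal-coordinate chaining from
#' ideal bond lengths and angles, so that the measured phi/psi of the built
#' model reproduce the spec to well under 0.1 degree. The result is a
#' single-model [StructureEnsemble][read_ensemble] on chain `chain` with
#' residues numbered from `start_resno`.
#'
#' @param spec a [build_spec()].
#' @param chain chain identifier for the built model.
#' @param start_resno first residue number.
#' @return single-model `StructureEnsemble` carrying the spec as attribute
#'   `build_spec`.
#' @export
build_peptide <- function(spec, chain = "A", start_resno = 1L) {
  stopifnot(inherits(spec, "BuildSpec"))
  n <- nchar(spec$sequence)
  aa <- strsplit(spec$sequence, "")[[1L]]
  N <- CA <- CC <- O <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(BOND_N_CA, 0, 0)
  a1 <- deg2rad(180 - ANGLE_N_CA_C)
  CC[1L, ] <- CA[1L, ] + BOND_CA_C * c(cos(a1), sin(a1), 0)
  for (i in seq_len(n)) {
    O[i, ] <- nerf_place(N[i, ], CA[i, ], CC[i, ], BOND_C_O, ANGLE_CA_C_O,
                         wrap_angle(spec$psi[i] + 180))
    if (i == n) break
    N[i + 1L, ] <- nerf_place(N[i, ], CA[i, ], CC[i, ], BOND_C_N,
                              ANGLE_CA_C_N, spec$psi[i])
    CA[i + 1L, ] <- nerf_place(CA[i, ], CC[i, ], N[i + 1L, ], BOND_N_CA,
                               ANGLE_C_N_CA, spec$omega[i])
    CC[i + 1L, ] <- nerf_place(CC[i, ], N[i + 1L, ], CA[i + 1L, ], BOND_CA_C,
                               ANGLE_N_CA_C, spec$phi[i + 1L])
  }
  resno <- rep(seq.int(start_resno, length.out = n), each = 4L)
  atoms <- rep(c("N", "CA", "C", "O"), n)
  xyz <- matrix(NA_real_, 4L * n, 3L)
  xyz[seq(1L, by = 4L, length.out = n), ] <- N
  xyz[seq(2L, by = 4L, length.out = n), ] <- CA
  xyz[seq(3L, by = 4L, length.out = n), ] <- CC
  xyz[seq(4L, by = 4L, length.out = n), ] <- O
  model <- data.frame(
    record = "ATOM", serial = seq_len(4L * n), atom = atoms, alt = "",
    resname = rep(unname(one_to_three[aa]), each = 4L),
    chain = chain, resno = resno, ins = "",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    occ = 1, bfac = 0,
    element = substring(atoms, 1L, 1L),
    stringsAsFactors = FALSE
  )
  ens <- new_ensemble(list(model), source_id = "build_peptide")
  attr(ens, "build_spec") <- spec
  ens
}

#' Combine single models into one ensemble
#'
#' @param ensembles list of `StructureEnsemble` objects (their models are
#'   concatenated in order).
#' @param source_id label for the combined ensemble.
#' @return a `StructureEnsemble`.
#' @export
ensemble_from_models <- function(ensembles, source_id = "combined") {
  models <- unlist(lapply(ensembles, function(e) {
    stopifnot(inherits(e, "StructureEnsemble"))
    e$models
  }), recursive = FALSE)
  new_ensemble(models, source_id = source_id)
}

#' Multi-model ensemble with isotropic Gaussian coordinate noise
#'
#' Replicates a built peptide `n_models` times, perturbing every coordinate
#' by N(0, `noise_sigma`) independently. With `noise_sigma = 0` all models
#' are identical. Deterministic under a fixed `seed`.
#'
#' @param spec a [build_spec()].
#' @param noise_sigma per-coordinate noise SD in Angstrom (>= 0).
#' @param n_models number of models (>= 1).
#' @param seed integer RNG seed.
#' @inheritParams build_peptide
#' @return a `StructureEnsemble` of `n_models` models.
#' @export
make_finger_ensemble <- function(spec, noise_sigma = 0, n_models = 20L,
                                 seed = 1L, chain = "A", start_resno = 1L) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  n_models <- as.integer(n_models)
  if (is.na(n_models) || n_models < 1L) stop("n_models must be >= 1")
  base <- build_peptide(spec, chain = chain, start_resno = start_resno)$models[[1L]]
  set.seed(seed)
  models <- lapply(seq_len(n_models), function(i) {
    m <- base
    if (noise_sigma > 0) {
      pert <- matrix(stats::rnorm(3L * nrow(m), 0, noise_sigma), ncol = 3L)
      m$x <- m$x + pert[, 1L]
      m$y <- m$y + pert[, 2L]
      m$z <- m$z + pert[, 3L]
    }
    m
  })
  ens <- new_ensemble(models, source_id = "make_finger_ensemble")
  attr(ens, "build_spec") <- spec
  ens
}

#' Per-model dihedral variation ensemble
#'
#' Builds one model per draw, varying the phi (or psi) dihedral of one
#' residue by N(0, `angular_sigma`) about its spec value while keeping the
#' rest of the table fixed. Used for recovery tests of the circular
#' ensemble statistics.
#'
#' @inheritParams make_finger_ensemble
#' @param resno residue (in build numbering) whose dihedral varies.
#' @param angle `"phi"` or `"psi"`.
#' @param angular_sigma SD of the angular perturbation, degrees.
#' @return a `StructureEnsemble` of `n_models` models.
#' @export
make_dihedral_ensemble <- function(spec, resno, angle = c("phi", "psi"),
                                   angular_sigma = 10, n_models = 20L,
                                   seed = 1L, chain = "A", start_resno = 1L) {
  stopifnot(inherits(spec, "BuildSpec"))
  angle <- match.arg(angle)
  idx <- resno - start_resno + 1L
  if (idx < 1L || idx > nchar(spec$sequence))
    stop("resno outside the built peptide")
  set.seed(seed)
  delta <- stats::rnorm(n_models, 0, angular_sigma)
  models <- lapply(seq_len(n_models), function(i) {
    s <- spec
    s[[angle]][idx] <- wrap_angle(s[[angle]][idx] + delta[i])
    build_peptide(s, chain = chain, start_resno = start_resno)$models[[1L]]
  })
  ens <- new_ensemble(models, source_id = "make_dihedral_ensemble")
  attr(ens, "angles_true") <- wrap_angle(spec[[angle]][idx] + delta)
  ens
}

#' Specification for a hinged two-domain ensemble
#'
#' @param domain_a_spec,domain_b_spec [build_spec()] objects for the two
#'   domains (helical by default in [make_hinged_ensemble()] callers).
#' @param linker_length number of glycine linker residues between them.
#' @param hinge_sigma SD (degrees) of the per-model rotation angle of
#'   domain B about a random axis through the hinge point.
#' @param n_models number of models (>= 2).
#' @param seed integer RNG seed (axis and angles).
#' @return an object of class `HingeEnsembleSpec`.
#' @export
hinge_spec <- function(domain_a_spec, domain_b_spec, linker_length = 4L,
                       hinge_sigma = 10, n_models = 20L, seed = 1L) {
  stopifnot(inherits(domain_a_spec, "BuildSpec"),
            inherits(domain_b_spec, "BuildSpec"))
  if (hinge_sigma < 0) stop("hinge_sigma must be >= 0")
  n_models <- as.integer(n_models)
  if (is.na(n_models) || n_models < 2L) stop("n_models must be >= 2")
  linker_length <- as.integer(linker_length)
  if (linker_length < 1L) stop("linker_length must be >= 1")
  structure(list(domain_a_spec = domain_a_spec, domain_b_spec = domain_b_spec,
                 linker_length = linker_length, hinge_sigma = hinge_sigma,
                 n_models = n_models, seed = as.integer(seed)),
            class = "HingeEnsembleSpec")
}

rotation_about_axis <- function(axis, angle_deg) {
  u <- vunit(axis)
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3L, byrow = TRUE)
}

#' Two-domain ensemble with a controlled interdomain angular spread
#'
#' Builds domain A, a glycine linker and domain B as one chain, then creates
#' each model by rigidly rotating domain B (and the linker residues past the
#' hinge) by an angle drawn from N(0, `hinge_sigma`) about a fixed random
#' axis through the hinge point (the CA of the central linker residue).
#' Domain A is identical across models, so fitting on A exposes exactly the
#' injected spread of B. The ground truth (axis, hinge point, per-model
#' angles, residue ranges) is attached as attribute `hinge_truth`, and
#' [expected_hinge_rmsd()] gives the closed-form mean RMSD it implies.
#' Models whose rotated domain clashes into domain A (any CA-CA contact
#' under 2 A) are redrawn up to 100 times before a generation error.
#'
#' @param spec a [hinge_spec()].
#' @param chain chain identifier.
#' @return a `StructureEnsemble` of `spec$n_models` models.
#' @export
make_hinged_ensemble <- function(spec, chain = "A") {
  stopifnot(inherits(spec, "HingeEnsembleSpec"))
  na <- nchar(spec$domain_a_spec$sequence)
  nb <- nchar(spec$domain_b_spec$sequence)
  nl <- spec$linker_length
  full <- build_spec(
    paste0(spec$domain_a_spec$sequence, strrep("G", nl), spec$domain_b_spec$sequence),
    phi = c(spec$domain_a_spec$phi, rep(-120, nl), spec$domain_b_spec$phi),
    psi = c(spec$domain_a_spec$psi, rep(140, nl), spec$domain_b_spec$psi),
    omega = 180
  )
  base <- build_peptide(full, chain = chain)$models[[1L]]
  hinge_resno <- na + ceiling(nl / 2)
  hinge_xyz <- as.numeric(base[base$resno == hinge_resno & base$atom == "CA",
                               c("x", "y", "z")])
  moving <- base$resno > hinge_resno
  a_rows <- which(base$resno <= na & base$atom == "CA")
  b_rows <- which(base$resno > na + nl & base$atom == "CA")
  set.seed(spec$seed)
  axis <- vunit(stats::rnorm(3L))
  angles <- numeric(spec$n_models)
  models <- vector("list", spec$n_models)
  for (m in seq_len(spec$n_models)) {
    ok <- FALSE
    for (try in seq_len(100L)) {
      theta <- stats::rnorm(1L, 0, spec$hinge_sigma)
      rot <- rotation_about_axis(axis, theta)
      mm <- base
      xyz <- as.matrix(base[moving, c("x", "y", "z")])
      xyz <- sweep(sweep(xyz, 2L, hinge_xyz) %*% t(rot), 2L, hinge_xyz, "+")
      mm[moving, c("x", "y", "z")] <- xyz
      d <- as.matrix(stats::dist(as.matrix(mm[c(a_rows, b_rows), c("x", "y", "z")])))
      cross <- d[seq_along(a_rows), length(a_rows) + seq_along(b_rows)]
      if (all(cross > 2.0)) {
        angles[m] <- theta
        models[[m]] <- mm
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("clash-free placement of domain B impossible after 100 retries")
  }
  ens <- new_ensemble(models, source_id = "make_hinged_ensemble")
  attr(ens, "hinge_truth") <- list(
    axis = axis, point = hinge_xyz, angles = angles,
    hinge_sigma = spec$hinge_sigma,
    a_range = residue_range(chain, 1L, na),
    linker_range = residue_range(chain, na + 1L, na + nl),
    b_range = residue_range(chain, na + nl + 1L, na + nl + nb)
  )
  ens
}

#' Closed-form expected flexibility RMSD of a hinged ensemble
#'
#' For atoms at root-mean-square perpendicular distance R from the hinge
#' axis and rotation angles theta ~ N(0, sigma), the deviation of a model
#' from the population mean structure is
#' `R * sqrt(1 - 2 rho cos(theta) + rho^2)` with `rho = exp(-sigma^2/2)`
#' (the circular resultant). The expectation over theta is evaluated by
#' quadrature. This is the reference value that
#' [interfinger_flexibility()] on domain B (fitted on domain A) should
#' approach for large ensembles.
#'
#' @param ens an ensemble from [make_hinged_ensemble()].
#' @param atom_names atoms entering the RMSD (default CA, matching the
#'   flexibility default).
#' @return expected mean RMSD in Angstrom.
#' @export
expected_hinge_rmsd <- function(ens, atom_names = "CA") {
  truth <- attr(ens, "hinge_truth")
  if (is.null(truth)) stop("ensemble carries no hinge ground truth")
  sel <- select_atoms(ens, truth$b_range, atom_names)
  # perpendicular distances from the hinge axis, in the unrotated frame:
  # use model with the smallest |angle| as the closest stand-in is not
  # needed -- distances to the axis are rotation-invariant, any model works
  p <- sel[1L, , , drop = TRUE]
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  rel <- sweep(p, 2L, truth$point)
  along <- as.numeric(rel %*% truth$axis)
  perp2 <- rowSums(rel^2) - along^2
  r_rms <- sqrt(mean(perp2))
  sigma <- deg2rad(truth$hinge_sigma)
  if (sigma == 0) return(0)
  rho <- exp(-sigma^2 / 2)
  f <- function(th) sqrt(pmax(0, 1 - 2 * rho * cos(th) + rho^2)) *
    stats::dnorm(th, 0, sigma)
  r_rms * stats::integrate(f, -8 * sigma, 8 * sigma, rel.tol = 1e-9)$value
}

#' Synthetic zinc-coordination site
#'
#' Builds a minimal model holding the four coordinating side-chain atoms
#' (two Cys Sgamma, two His Nepsilon2) at the vertices of a regular
#' tetrahedron of radius `dist` around the origin, optionally with the zinc
#' atom at the exact centre, plus optional isotropic jitter.
#'
#' @param dist ligand-to-zinc distance, Angstrom.
#' @param zinc include the ZN HETATM at the centre?
#' @param jitter per-coordinate Gaussian noise SD, Angstrom.
#' @param seed RNG seed used when `jitter > 0`.
#' @return a single-model `StructureEnsemble`.
#' @export
make_zinc_site <- function(dist = 2.3, zinc = TRUE, jitter = 0, seed = 1L) {
  verts <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  xyz <- verts * dist
  if (jitter > 0) {
    set.seed(seed)
    xyz <- xyz + matrix(stats::rnorm(12L, 0, jitter), ncol = 3L)
  }
  model <- data.frame(
    record = c(rep("ATOM", 4L), if (zinc) "HETATM"),
    serial = seq_len(4L + as.integer(zinc)),
    atom = c("SG", "SG", "NE2", "NE2", if (zinc) "ZN"),
    alt = "",
    resname = c("CYS", "CYS", "HIS", "HIS", if (zinc) "ZN"),
    chain = "A",
    resno = c(1L, 2L, 3L, 4L, if (zinc) 99L),
    ins = "",
    x = c(xyz[, 1L], if (zinc) 0),
    y = c(xyz[, 2L], if (zinc) 0),
    z = c(xyz[, 3L], if (zinc) 0),
    occ = 1, bfac = 0,
    element = c("S", "S", "N", "N", if (zinc) "ZN"),
    stringsAsFactors = FALSE
  )
  new_ensemble(list(model), source_id = "make_zinc_site")
}

#' Synthetic protein sequence with planted C2H2 motifs
#'
#' Concatenates `n_fingers` C2H2 motifs of the requested Cys/His spacer
#' classes, joined by the given linker sequences, over a background alphabet
#' that excludes Cys and His (so no spurious motifs can arise). Returns the
#' sequence together with the ground-truth finger table in the same form
#' [scan_fingers()] produces.
#'
#' @param n_fingers number of motifs.
#' @param spacer_classes 2-column matrix (or list of length-2 vectors) of
#'   (cys_spacer, his_spacer) per finger, cys in \{2,4\}, his in \{3,4\};
#'   a single pair is recycled. Default: canonical (2, 3).
#' @param linkers character vector of linker sequences between consecutive
#'   fingers (recycled); default the canonical "TGEKP".
#' @param core_length residues between the second Cys and first His
#'   (default 12; must lie in the scanner's core window).
#' @param seed RNG seed for the background residues.
#' @return list with `sequence` (string) and `fingers` (data.frame ground
#'   truth, same columns as [scan_fingers()]).
#' @export
make_motif_sequence <- function(n_fingers, spacer_classes = c(2L, 3L),
                                linkers = "TGEKP", core_length = 12L,
                                seed = 1L) {
  n_fingers <- as.integer(n_fingers)
  stopifnot(n_fingers >= 1L)
  if (is.list(spacer_classes)) spacer_classes <- do.call(rbind, spacer_classes)
  if (is.null(dim(spacer_classes))) spacer_classes <- matrix(spacer_classes, ncol = 2L)
  if (nrow(spacer_classes) == 1L)
    spacer_classes <- spacer_classes[rep(1L, n_fingers), , drop = FALSE]
  stopifnot(nrow(spacer_classes) == n_fingers)
  if (!all(spacer_classes[, 1L] %in% c(2L, 4L)) ||
      !all(spacer_classes[, 2L] %in% c(3L, 4L)))
    stop("spacer classes must be (cys, his) pairs from {2,4} x {3,4}")
  if (n_fingers > 1L)
    linkers <- rep_len(linkers, n_fingers - 1L)
  background <- setdiff(AA1, c("C", "H"))
  set.seed(seed)
  bg <- function(k) paste(sample(background, k, replace = TRUE), collapse = "")
  pieces <- character(0)
  pos <- 0L
  truth <- vector("list", n_fingers)
  for (i in seq_len(n_fingers)) {
    cs <- spacer_classes[i, 1L]
    hs <- spacer_classes[i, 2L]
    motif <- paste0(bg(2L), "C", bg(cs), "C", bg(core_length), "H", bg(hs), "H")
    cys1 <- pos + 3L
    cys2 <- cys1 + cs + 1L
    his1 <- cys2 + core_length + 1L
    his2 <- his1 + hs + 1L
    truth[[i]] <- list(cys1 = cys1, cys2 = cys2, his1 = his1, his2 = his2)
    pieces <- c(pieces, motif)
    pos <- pos + nchar(motif)
    if (i < n_fingers) {
      pieces <- c(pieces, linkers[i])
      pos <- pos + nchar(linkers[i])
    }
  }
  sequence <- paste(pieces, collapse = "")
  fingers <- do.call(rbind, lapply(seq_along(truth), function(i) {
    t <- truth[[i]]
    finger_row(i, t$cys1, t$cys2, t$his1, t$his2, sequence)
  }))
  list(sequence = sequence, fingers = fingers)
}
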