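test_that("build specs validate their inputs", {
  expect_error(build_spec("AAA", phi = c(-60, -60), psi = -40), "length")
  expect_error(build_spec("AAA", phi = -200, psi = -40), "within")
  expect_error(build_spec("AB", phi = -60, psi = -40), "non-amino-acid")
  expect_error(make_finger_ensemble(alpha_spec(5), n_models = 0), "n_models")
  expect_error(make_finger_ensemble(alpha_spec(5), noise_sigma = -1), "noise_sigma")
})

test_that("an ideal alpha helix closes its i->i-4 hydrogen bonds", {
  m <- build_peptide(alpha_spec(20))$models[[1]]
  for (i in 5:20) {
    n <- zfarray:::model_atom_xyz(m, "A", i, "N")
    o <- zfarray:::model_atom_xyz(m, "A", i - 4, "O")
    expect_lt(sqrt(sum((n - o)^2)), 3.5)
  }
})

test_that("the builder reproduces random dihedral tables", {
  set.seed(99)
  for (k in 1:25) {
    n <- sample(4:9, 1)
    phi <- runif(n, -179, 179)
    psi <- runif(n, -179, 179)
    m <- build_peptide(build_spec(strrep("G", n), phi, psi))$models[[1]]
    for (i in 2:(n - 1)) {
      d <- backbone_dihedrals(m, i)
      expect_lt(abs(zfarray:::ang_diff(d$phi, phi[i])), 0.1)
      expect_lt(abs(zfarray:::ang_diff(d$psi, psi[i])), 0.1)
    }
  }
})

test_that("generators are deterministic under a fixed seed", {
  e1 <- make_finger_ensemble(alpha_spec(10), 0.3, 5, seed = 7)
  e2 <- make_finger_ensemble(alpha_spec(10), 0.3, 5, seed = 7)
  expect_identical(e1$models, e2$models)
  h1 <- make_hinged_ensemble(hinge_spec(alpha_spec(10), alpha_spec(10),
                                        hinge_sigma = 12, n_models = 6, seed = 4))
  h2 <- make_hinged_ensemble(hinge_spec(alpha_spec(10), alpha_spec(10),
                                        hinge_sigma = 12, n_models = 6, seed = 4))
  expect_identical(h1$models, h2$models)
  s1 <- make_motif_sequence(5, seed = 3)
  s2 <- make_motif_sequence(5, seed = 3)
  expect_identical(s1, s2)
})

test_that("zero coordinate noise yields identical models, zero dihedral spread", {
  ens <- make_finger_ensemble(alpha_spec(10), 0, 20, seed = 1)
  expect_identical(ens$models[[1]], ens$models[[20]])
  expect_equal(ensemble_dihedral_stats(ens, 5, "phi")$sd, 0)
})

test_that("coordinate noise matches the closed-form displacement expectation", {
  sigma <- 0.3
  nm <- 50
  ens <- make_finger_ensemble(alpha_spec(20), sigma, nm, seed = 7)
  sel <- select_atoms(ens, residue_range("A", 1, 20), "CA")
  mean_str <- apply(sel, c(2, 3), mean)
  per_model <- vapply(seq_len(nm), function(m)
    sqrt(mean(rowSums((sel[m, , ] - mean_str)^2))), numeric(1))
  # E[RMSD] for isotropic 3-D Gaussian noise about the sample mean
  expected <- sigma * sqrt(3 * (nm - 1) / nm)
  expect_equal(mean(per_model), expected, tolerance = 0.2)
})

test_that("hinged ensembles expose exact ground truth", {
  ens <- make_hinged_ensemble(hinge_spec(alpha_spec(15), alpha_spec(15),
                                         hinge_sigma = 0, n_models = 5, seed = 2))
  tr <- attr(ens, "hinge_truth")
  expect_equal(tr$angles, rep(0, 5))
  fr <- interfinger_flexibility(ens, tr$a_range, tr$b_range)
  expect_equal(fr$mean, 0, tolerance = 1e-9)
  # monotone in the injected spread, same seed
  m5 <- make_hinged_ensemble(hinge_spec(alpha_spec(15), alpha_spec(15),
                                        hinge_sigma = 5, n_models = 25, seed = 2))
  m30 <- make_hinged_ensemble(hinge_spec(alpha_spec(15), alpha_spec(15),
                                         hinge_sigma = 30, n_models = 25, seed = 2))
  t5 <- attr(m5, "hinge_truth"); t30 <- attr(m30, "hinge_truth")
  expect_lt(interfinger_flexibility(m5, t5$a_range, t5$b_range)$mean,
            interfinger_flexibility(m30, t30$a_range, t30$b_range)$mean)
})

test_that("hinged ensembles survive a file round trip unchanged for analysis", {
  ens <- make_hinged_ensemble(hinge_spec(alpha_spec(12), alpha_spec(12),
                                         hinge_sigma = 15, n_models = 8, seed = 6))
  tr <- attr(ens, "hinge_truth")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, tf)
  back <- read_ensemble(tf)
  f1 <- interfinger_flexibility(ens, tr$a_range, tr$b_range)
  f2 <- interfinger_flexibility(back, tr$a_range, tr$b_range)
  expect_equal(f1$mean, f2$mean, tolerance = 1e-3)
})

test_that("planted-motif sequences honour the annotation invariants", {
  set.seed(55)
  for (k in 1:10) {
    n <- sample(1:6, 1)
    ms <- make_motif_sequence(n, spacer_classes = random_classes(n), seed = k)
    f <- ms$fingers
    expect_true(all(f$cys1 < f$cys2 & f$cys2 < f$his1 & f$his1 < f$his2))
    expect_true(all(f$cys_spacer %in% 2:4))
    expect_true(all(f$his_spacer %in% 3:5))
    # background never fakes a motif: the scan finds exactly the planted set
    expect_equal(nrow(scan_fingers(ms$sequence)), n)
  }
  # background residues exclude the coordinating letters
  ms <- make_motif_sequence(2, seed = 1)
  aa <- strsplit(ms$sequence, "")[[1]]
  coord <- c(ms$fingers$cys1, ms$fingers$cys2, ms$fingers$his1, ms$fingers$his2)
  expect_false(any(aa[-coord] %in% c("C", "H")))
})
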