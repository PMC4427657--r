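test_that("superposition of a set onto itself is the identity", {
  set.seed(101)
  for (k in 1:5) {
    x <- matrix(rnorm(3 * (3 + k)), ncol = 3)
    s <- kabsch_superpose(x, x)
    expect_lt(s$rmsd, 1e-12)
    expect_equal(s$rotation, diag(3), tolerance = 1e-10)
  }
})

test_that("pure translations are recovered exactly", {
  set.seed(7)
  x <- matrix(rnorm(18), 6, 3)
  s <- kabsch_superpose(x, sweep(x, 2, c(5, 0, 0), "+"))
  expect_lt(s$rmsd, 1e-12)
  expect_equal(s$translation, c(5, 0, 0), tolerance = 1e-10)
})

test_that("Kabsch attains the brute-force quaternion-grid minimum", {
  set.seed(42)
  for (k in 1:3) {
    p <- matrix(rnorm(18), 6, 3)
    rot <- zfarray:::rotation_about_axis(rnorm(3), runif(1, -170, 170))
    q <- p %*% t(rot) + matrix(rnorm(18, 0, 0.15), 6, 3)
    ours <- kabsch_superpose(q, p)$rmsd
    expect_equal(ours, oracle_min_rmsd(q, p), tolerance = 1e-9)
  }
})

test_that("superposition RMSD is symmetric and rotations are proper", {
  set.seed(11)
  a <- matrix(rnorm(24), 8, 3)
  b <- a %*% t(zfarray:::rotation_about_axis(c(0, 1, 1), 55)) +
    matrix(rnorm(24, 0, 0.2), 8, 3)
  sab <- kabsch_superpose(a, b)
  sba <- kabsch_superpose(b, a)
  expect_equal(sab$rmsd, sba$rmsd, tolerance = 1e-9)
  expect_equal(det(sab$rotation), 1, tolerance = 1e-10)
  # a mirrored target must not elicit a reflection
  sm <- kabsch_superpose(a, a %*% diag(c(-1, 1, 1)))
  expect_equal(det(sm$rotation), 1, tolerance = 1e-10)
  expect_error(kabsch_superpose(a[1:2, ], b[1:2, ]), "underdetermined")
  expect_warning(
    kabsch_superpose(cbind(1:5, 0, 0), cbind(1:5, 0, 0)), "collinear")
})

test_that("ideal helix presets are recovered from built peptides", {
  am <- build_peptide(alpha_spec(12))$models[[1]]
  d <- backbone_dihedrals(am, 6)
  expect_equal(d$phi, -65.0, tolerance = 0.1)
  expect_equal(d$psi, -40.0, tolerance = 0.1)
  pm <- build_peptide(pi_spec(12))$models[[1]]
  dp <- backbone_dihedrals(pm, 6)
  expect_equal(dp$phi, -57.1, tolerance = 0.1)
  expect_equal(dp$psi, -69.7, tolerance = 0.1)
  expect_error(backbone_dihedrals(am, 1), "phi undefined")
  expect_error(backbone_dihedrals(am, 12), "psi undefined")
})

test_that("dihedrals agree with an independent torsion implementation", {
  skip_if_not_installed("bio3d")
  set.seed(23)
  spec <- build_spec(strrep("A", 8), phi = runif(8, -150, -40),
                     psi = runif(8, -60, 150))
  ens <- build_peptide(spec)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, tf)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(tf))
  m <- ens$models[[1]]
  for (i in 2:7) {
    d <- backbone_dihedrals(m, i)
    expect_equal(d$phi, tor$phi[i], tolerance = 0.05)
    expect_equal(d$psi, tor$psi[i], tolerance = 0.05)
  }
})

test_that("helical hydrogen-bond geometry follows the criterion", {
  am <- build_peptide(alpha_spec(14))$models[[1]]
  hb <- detect_hbond(am, 9, 5)             # alpha: i -> i-4
  expect_s3_class(hb, "HBond")
  expect_lt(hb$donor_acceptor_distance, 3.5)
  expect_null(detect_hbond(am, 9, 4))      # alpha: i -> i-5 too far
  pm <- build_peptide(pi_spec(14))$models[[1]]
  expect_s3_class(detect_hbond(pm, 9, 4), "HBond")  # pi: i -> i-5
  far <- am
  expect_null(detect_hbond(am, 14, 2))
  noO <- am[!(am$resno == 5 & am$atom == "O"), ]
  expect_error(detect_hbond(noO, 9, 5), "O of residue")
})

test_that("zinc-site geometry is classified against the tetrahedral windows", {
  site <- make_zinc_site(dist = 2.3)$models[[1]]
  rep <- check_zinc_site(site, c(1, 2), c(3, 4))
  expect_identical(rep$zinc_source, "observed")
  expect_true(rep$tetrahedral)
  expect_equal(unname(rep$distances), rep(2.3, 4), tolerance = 1e-9)
  expect_equal(unname(rep$angles), rep(109.4712, 6), tolerance = 0.01)

  pulled <- site
  pulled[pulled$atom == "SG" & pulled$resno == 1, c("x", "y", "z")] <-
    4 / sqrt(3) * c(1, 1, 1)
  rep2 <- check_zinc_site(pulled, c(1, 2), c(3, 4))
  expect_false(rep2$tetrahedral)
  expect_true(any(grepl("Cys1:SG", rep2$violations)))

  free <- make_zinc_site(zinc = FALSE)$models[[1]]
  expect_identical(check_zinc_site(free, c(1, 2), c(3, 4))$zinc_source,
                   "inferred")
  expect_error(check_zinc_site(free[-1, ], c(1, 2), c(3, 4)), "SG")
})

test_that("ensemble dihedral statistics use circular means", {
  ens <- make_finger_ensemble(alpha_spec(9), noise_sigma = 0, n_models = 20,
                              seed = 1)
  st <- ensemble_dihedral_stats(ens, 5, "phi")
  expect_equal(st$sd, 0)
  expect_equal(st$mean, -65, tolerance = 0.01)
  expect_equal(st$n, 20)
  # wrap-around set: circular mean sits near 180, far from the arithmetic mean
  wrap <- c(-170, 175, -175, 180)
  expect_equal(zfarray:::circular_mean(wrap), -177.5, tolerance = 0.01)
  expect_gt(abs(zfarray:::circular_mean(wrap) - mean(wrap)), 90)
  # away from the wrap point the two means agree
  plain <- c(-130, -120, -110, -140)
  expect_equal(zfarray:::circular_mean(plain), mean(plain), tolerance = 1e-6)
})
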