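test_that("a planted canonical motif is found and annotated", {
  seq <- "AAACAACAAAAKAAAAAAFAAHAAAHAAA"  # C at 4,7; H at 22,26
  f <- scan_fingers(seq)
  expect_equal(nrow(f), 1)
  expect_equal(f$cys1, 4)
  expect_equal(f$cys2, 7)
  expect_equal(f$his1, 22)
  expect_equal(f$his2, 26)
  expect_equal(f$cys_spacer, 2)
  expect_equal(f$his_spacer, 3)
  expect_identical(f$helix_class, "canonical")
  expect_identical(f$loop_class, "CX2C")
  expect_equal(f$start, 2)
  expect_equal(f$end, 26)

  kp <- key_positions(f, seq)
  expect_equal(kp[["-1"]]$position, 14)
  expect_equal(kp[["+2"]]$position, 17)
  expect_equal(kp[["+3"]]$position, 18)
  expect_equal(kp[["+6"]]$position, 21)
  expect_null(kp[["+10"]])

  expect_error(scan_fingers("AAACAACAAAAKAAAA1AFAAHAAAHAAA"),
               "non-amino-acid")
  expect_error(scan_fingers("ACDEFG"), "too short")
})

test_that("bulged-out fingers expose the +10 extended position", {
  ms <- make_motif_sequence(1, spacer_classes = c(2L, 4L), seed = 2)
  f <- scan_fingers(ms$sequence)
  expect_identical(f$helix_class, "bulged_out")
  expect_equal(f$pos_p10, f$his1 + 3)
  expect_false(is.na(f$aa_p10))
})

test_that("scanner recall is exact on seeded planted-motif sequences", {
  set.seed(77)
  for (k in 1:50) {
    n <- sample(2:8, 1)
    ms <- make_motif_sequence(n, spacer_classes = random_classes(n),
                              linkers = sample(c("TGEKP", "KKIK", "GAAP"), 1),
                              seed = k)
    f <- scan_fingers(ms$sequence)
    expect_equal(nrow(f), n)
    expect_equal(f$cys1, ms$fingers$cys1)
    expect_equal(f$cys2, ms$fingers$cys2)
    expect_equal(f$his1, ms$fingers$his1)
    expect_equal(f$his2, ms$fingers$his2)
  }
})

test_that("helix and loop classes are pure functions of the spacers", {
  set.seed(5)
  ms <- make_motif_sequence(12, spacer_classes = random_classes(12), seed = 8)
  f <- scan_fingers(ms$sequence)
  expect_identical(f$helix_class == "bulged_out", f$his_spacer == 4L)
  expect_identical(f$helix_class == "canonical", f$his_spacer == 3L)
  expect_identical(f$loop_class == "CX4C", f$cys_spacer == 4L)
})

test_that("the bulged-out census reports rounded percentages", {
  classes <- rbind(matrix(rep(c(2L, 4L), 8), ncol = 2, byrow = TRUE),
                   matrix(rep(c(2L, 3L), 10), ncol = 2, byrow = TRUE))
  ms <- make_motif_sequence(18, spacer_classes = classes, seed = 4)
  cen <- classify_bulged_out(scan_fingers(ms$sequence))
  expect_equal(cen$n_total, 18)
  expect_equal(cen$n_bulged, 8)
  expect_equal(cen$percent, 44)

  one <- make_motif_sequence(1, spacer_classes = c(2L, 3L), seed = 1)
  expect_equal(classify_bulged_out(scan_fingers(one$sequence))$percent, 0)

  ten <- make_motif_sequence(10, spacer_classes = rbind(
    matrix(rep(c(2L, 4L), 3), ncol = 2, byrow = TRUE),
    matrix(rep(c(2L, 3L), 7), ncol = 2, byrow = TRUE)), seed = 2)
  expect_equal(classify_bulged_out(scan_fingers(ten$sequence))$percent, 30)

  expect_error(classify_bulged_out(scan_fingers("AAAAAAAAAAAAAAAAAAAAA")),
               "empty")
})

test_that("linkers are typed by the canonical pattern and length", {
  ms <- make_motif_sequence(4, linkers = c("KKIK", "TGEKP",
                                           strrep("A", 20)), seed = 6)
  f <- scan_fingers(ms$sequence)
  lk <- annotate_linkers(f, ms$sequence)
  expect_equal(lk$sequence[1], "KKIK")
  expect_identical(lk$linker_type[1], "atypical")
  expect_identical(lk$linker_type[2], "canonical_TGEKP")
  expect_identical(lk$linker_type[3], "long_spacer")
  # TGQRS is within the conserved pattern family
  ms2 <- make_motif_sequence(2, linkers = "TGQRS", seed = 7)
  lk2 <- annotate_linkers(scan_fingers(ms2$sequence), ms2$sequence)
  expect_identical(lk2$linker_type, "canonical_TGEKP")

  over <- f[1:2, ]
  over$start[2] <- over$end[1] - 2L
  expect_error(annotate_linkers(over, ms$sequence), "overlap")
  expect_error(annotate_linkers(f[1, ], ms$sequence), "at least two")
})

test_that("tandem units partition the finger list at long linkers", {
  ms <- make_motif_sequence(6, linkers = c("TGEKP", strrep("A", 15), "KKIK",
                                           "TGEKP", strrep("A", 30)), seed = 9)
  f <- scan_fingers(ms$sequence)
  lk <- annotate_linkers(f, ms$sequence)
  units <- group_tandem_units(f, lk)
  expect_equal(units, list(1:2, 3:5, 6L))
  expect_equal(sort(unlist(units)), f$index)  # partition, order preserved

  all_long <- make_motif_sequence(3, linkers = strrep("A", 12), seed = 3)
  fl <- scan_fingers(all_long$sequence)
  expect_equal(group_tandem_units(fl, seq = all_long$sequence),
               list(1L, 2L, 3L))

  two <- make_motif_sequence(2, linkers = "GAAPS", seed = 2)
  expect_equal(group_tandem_units(scan_fingers(two$sequence),
                                  seq = two$sequence), list(1:2))
})

test_that("AT-hook cores are flagged as landmarks", {
  expect_equal(find_at_hooks("AAAGRPKAAA"), 4L)
  expect_length(find_at_hooks("AAAAAA"), 0)
})

test_that("FASTA records read back as uppercase named sequences", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">prot1 some description", "acdefghik", ">prot2", "MKLV"), tf)
  s <- read_protein_fasta(tf)
  expect_identical(names(s), c("prot1", "prot2"))
  expect_identical(unname(s[1]), "ACDEFGHIK")
})
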