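# craft a finger whose key residues are chosen letters, by editing a
# planted-motif sequence at the key positions and rescanning
finger_with_keys <- function(keys, spacer = c(2L, 3L), seed = 13) {
  ms <- make_motif_sequence(1, spacer_classes = spacer, seed = seed)
  seq <- ms$sequence
  his1 <- ms$fingers$his1
  off <- c(`-1` = -8L, `+2` = -5L, `+3` = -4L, `+6` = -1L, `+10` = 3L)
  for (lab in names(keys)) {
    p <- his1 + off[[lab]]
    substring(seq, p, p) <- keys[[lab]]
  }
  f <- scan_fingers(seq)
  stopifnot(nrow(f) == 1)
  f
}

test_that("the packaged code table loads and holds canonical entries", {
  code <- load_code_table()
  expect_s3_class(code, "RecognitionCodeTable")
  expect_true(all(c("position", "amino_acid", "bases") %in% names(code)))
  expect_identical(code$bases[code$position == -1 & code$amino_acid == "R"], "G")
})

test_that("malformed tables are rejected and duplicates resolve last-wins", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tamino_acid\tbases", "-1\tR\tX"), tf)
  expect_error(load_code_table(tf), "outside A/C/G/T")
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tamino_acid\tbases", "-7\tR\tG"), tf2)
  expect_error(load_code_table(tf2), "position")
  tf3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tamino_acid\tbases", "-1\tR\tG", "-1\tR\tT"), tf3)
  expect_warning(code <- load_code_table(tf3), "duplicate")
  expect_identical(code$bases, "T")
})

test_that("subsites assemble 5' to 3' from the +6/+3/-1 triplet", {
  code <- load_code_table()
  f <- finger_with_keys(list(`+6` = "R", `+3` = "D", `-1` = "R", `+2` = "G"))
  p <- predict_subsite(f, code)
  expect_identical(p$subsite, "GCG")
  expect_identical(p$per_position_basis[["+6"]]$bases, "G")
  # unknown residues fall back to N, never an error
  f2 <- finger_with_keys(list(`+6` = "F", `+3` = "W", `-1` = "M", `+2` = "G"))
  expect_identical(predict_subsite(f2, code)$subsite, "NNN")
})

test_that("the +2 cross-strand contact appends a complemented fourth base", {
  code <- load_code_table()
  f <- finger_with_keys(list(`+6` = "R", `+3` = "N", `-1` = "Q", `+2` = "D"))
  p <- predict_subsite(f, code)
  # +2 Asp prefers A/C on the complementary strand -> complement M is K
  expect_identical(p$subsite, "GAAK")
  expect_equal(nchar(p$subsite), 4)
})

test_that("bulged-out fingers may gain a 5' base from +10", {
  code <- load_code_table()
  f <- finger_with_keys(list(`+6` = "R", `+3` = "N", `-1` = "Q", `+2` = "G",
                             `+10` = "T"),
                        spacer = c(2L, 4L))
  p <- predict_subsite(f, code)
  expect_identical(p$subsite, "TGAA")
  # every non-N base is traceable to a recorded basis entry
  expect_setequal(names(p$per_position_basis)[
    vapply(p$per_position_basis, function(b) length(b$bases) > 0, logical(1))],
    c("+10", "+6", "+3", "-1"))
})

test_that("composites concatenate subsites in reverse finger order", {
  subs <- data.frame(finger_index = 1:3, finger_id = paste0("ZF", 1:3),
                     subsite = c("AAT", "GCG", "TTG"))
  expect_identical(assemble_composite(1:2, subs)$sequence, "GCGAAT")
  expect_identical(assemble_composite(1L, subs)$sequence, "AAT")
  expect_identical(assemble_composite(1:3, subs)$sequence, "TTGGCGAAT")
  expect_error(assemble_composite(c(1, 9), subs), "no subsite")
  # reversing the unit inverts the block order exactly
  expect_identical(assemble_composite(3:1, subs)$sequence, "AATGCGTTG")
})

test_that("predictions are a pure function of annotation and table", {
  code <- load_code_table()
  f <- finger_with_keys(list(`+6` = "K", `+3` = "H", `-1` = "E", `+2` = "G"))
  p1 <- predict_subsite(f, code)
  p2 <- predict_subsite(f, code)
  expect_identical(p1, p2)
})

test_that("AT/GC composition splits the array into halves", {
  subs <- data.frame(finger_index = 1:18,
                     finger_id = paste0("ZF", 1:18),
                     subsite = c(rep("AAT", 9), rep("GCG", 9)))
  gs <- gc_at_summary(subs, 18)
  expect_equal(gs$at_fraction[gs$half == "N-terminal"], 1.0)
  expect_equal(gs$gc_fraction[gs$half == "C-terminal"], 1.0)

  none <- data.frame(finger_index = 1:4, finger_id = paste0("ZF", 1:4),
                     subsite = rep("NNN", 4))
  gn <- gc_at_summary(none, 4)
  expect_true(all(is.na(gn$at_fraction)))

  mixed <- data.frame(finger_index = 1:4, finger_id = paste0("ZF", 1:4),
                      subsite = c("ANT", "GCW", "TTS", "NNN"))
  gm <- gc_at_summary(mixed, 4)
  # hand count: N-half (fingers 1-2): A,T,G,C,W -> 3 AT of 5; C-half: T,T,S -> 2 of 3
  expect_equal(gm$at_fraction[gm$half == "N-terminal"], 3 / 5)
  expect_equal(gm$at_fraction[gm$half == "C-terminal"], 2 / 3)
})

test_that("IUPAC complements respect ambiguity codes", {
  expect_identical(iupac_complement("ACGTMKWSN"), "TGCAKMWSN")
})
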