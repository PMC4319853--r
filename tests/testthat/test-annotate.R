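# Transcriptome mapping, ncRNA classification, temporary-database
# construction and conserved-miRNA quantification.

test_that("perfect-match mapping finds exact substrings on both strands", {
  tx <- paste0(strrep("AC", 5), FIX_MATURE, strrep("CA", 14))
  refs <- ReferenceSet(c(tx1 = tx, tx2 = tx), class = "transcript")
  lib <- TagLibrary(FIX_MATURE, 1L, "CK")
  hits <- mapPerfect(lib, refs)
  # tag at 0-based positions 10..31 of both transcripts
  expect_identical(nrow(hits), 2L)
  expect_identical(hits$start, c(10L, 10L))
  expect_identical(hits$end, c(31L, 31L))
  expect_identical(unique(hits$strand), "+")
  # one mismatch anywhere means unmapped
  mut <- paste0(substr(FIX_MATURE, 1, 10), "A", substr(FIX_MATURE, 12, 21))
  expect_identical(nrow(mapPerfect(TagLibrary(mut, 1L), refs)), 0L)
  # reverse-complement occurrence is reported on the minus strand
  rcHits <- mapPerfect(TagLibrary(rnaReverseComplement(FIX_MATURE), 1L),
                       refs)
  expect_true(all(rcHits$strand == "-"))
  expect_identical(rcHits$start, c(10L, 10L))
})

test_that("ncRNA classification follows the fixed priority order", {
  frag <- "GGAUUCGGACCUUAGGCAUU"
  refs <- ReferenceSet(
    c(rr = paste0("ACCA", frag, "UUGGAAGGAUCCA"),
      tr = paste0("GGUU", frag, "ACCAAGGCC"),
      sn = "CCGGAAUUCCGGAAUUCCGGAAUACG"),
    class = c("rRNA", "tRNA", "snRNA"))
  lib <- TagLibrary(c(frag, "UAGCUUAUCAGACUGAUGUUG"), c(4L, 1L), "CK")
  cls <- classifyNcrna(lib, refs)
  # matches both an rRNA and a tRNA record: rRNA wins
  expect_identical(cls$category[cls$sequence == frag], "rRNA")
  # unmatched tag left unclassified
  expect_false("UAGCUUAUCAGACUGAUGUUG" %in% cls$sequence)
})

test_that("temporary database keeps the highest-count tag per family", {
  m <- FIX_MATURE
  oneMm <- paste0(substr(m, 1, 7), "A", substr(m, 9, 21))
  threeMm <- paste0("AAA", substr(m, 4, 21))
  catalog <- ReferenceSet(c(`ath-miR156` = m), class = "miRNA_mature",
                          family = "miR156", species = "ath")
  lib <- TagLibrary(c(m, oneMm, threeMm), c(100L, 7L, 500L), "CK")
  db <- buildTempMirnaDb(lib, catalog)
  expect_identical(nrow(db), 1L)
  expect_identical(db$sequence, m)   # count 100 beats count 7
  expect_identical(db$count, 100L)
  # a tag with three mismatches to every member founds no family
  far <- TagLibrary(threeMm, 500L, "CK")
  expect_identical(nrow(buildTempMirnaDb(far, catalog)), 0L)
  # count tie: lexicographically smaller sequence wins
  tie <- TagLibrary(c(m, oneMm), c(5L, 5L), "CK")
  dbTie <- buildTempMirnaDb(tie, catalog)
  expect_identical(dbTie$sequence, min(m, oneMm))
})

test_that("conserved quantification sums members within two mismatches", {
  m <- FIX_MATURE
  sub1 <- paste0(substr(m, 1, 4), "A", substr(m, 6, 21))   # 1 mm
  sub2 <- paste0(substr(m, 1, 4), "A", substr(m, 6, 8), "G",
                 substr(m, 10, 21))                        # 2 mm
  sub3 <- paste0(substr(m, 1, 4), "A", substr(m, 6, 8), "G",
                 substr(m, 10, 12), "C", substr(m, 14, 21)) # 3 mm
  tempDb <- data.frame(family = "miR156", sequence = m, count = 50L,
                       stringsAsFactors = FALSE)
  lib <- TagLibrary(c(m, sub1, sub2, sub3), c(50L, 10L, 3L, 99L), "CK")
  prof <- quantifyConserved(lib, tempDb)
  expect_identical(prof$count, 63L)  # 50 + 10 + 3, the 3-mm tag excluded
  expect_identical(prof$n_members, 3L)
  # no tags near any representative -> empty result
  none <- TagLibrary("AAAACCCCAAAACCCCAAAA", 9L, "CK")
  expect_identical(nrow(quantifyConserved(none, tempDb)), 0L)
})

test_that("each tag contributes to at most one conserved profile", {
  m1 <- FIX_MATURE
  m2 <- paste0(substr(m1, 1, 10), "G", substr(m1, 12, 21)) # 1 mm from m1
  tempDb <- data.frame(family = c("famA", "famB"), sequence = c(m1, m2),
                       count = c(10L, 10L), stringsAsFactors = FALSE)
  lib <- TagLibrary(m1, 8L, "CK")
  prof <- quantifyConserved(lib, tempDb)
  # the tag matches both representatives; best hit (0 mm) is famA only
  expect_identical(prof$family[prof$count > 0], "famA")
  expect_identical(sum(prof$count), 8L)
})

test_that("tag annotation is a partition with the documented priority", {
  fx <- fixtureReferences()
  ncrna <- ReferenceSet(c(rr = paste0("GGAAUUGGCCAAGGUUCCAAGGAAUCGG")),
                        class = "rRNA")
  catalog <- ReferenceSet(c(`ath-miR156` = fx$mature),
                          class = "miRNA_mature", family = "miR156",
                          species = "ath")
  lib <- TagLibrary(c(fx$mature,                      # known miRNA
                      "GGAAUUGGCCAAGGUUCCAA",         # rRNA fragment
                      "UUUUGGGGCCCCAAAAUUUUG"),       # unmapped
                    c(30L, 5L, 2L), "CK")
  tempDb <- buildTempMirnaDb(lib, catalog)
  ann <- annotateTags(lib, fx$transcriptome, ncrna, tempDb)
  expect_identical(nrow(ann), 3L)
  expect_identical(ann$category[ann$sequence == fx$mature], "known_miRNA")
  expect_identical(ann$category[startsWith(ann$sequence, "GGAAUU")], "rRNA")
  expect_identical(ann$category[startsWith(ann$sequence, "UUUU")], "unmapped")
  expect_identical(sum(ann$count), totalCleanReads(lib))
})

test_that("annotation output is deterministic across repeated runs", {
  fx <- fixtureReferences()
  catalog <- ReferenceSet(c(`ath-miR156` = fx$mature),
                          class = "miRNA_mature", family = "miR156",
                          species = "ath")
  ncrna <- ReferenceSet(c(rr = "GGAAUUGGCCAAGGUUCCAAGGAAUCGG"),
                        class = "rRNA")
  lib <- TagLibrary(c(fx$mature, "GGAAUUGGCCAAGGUUCCAA"), c(3L, 2L), "CK")
  db <- buildTempMirnaDb(lib, catalog)
  a1 <- annotateTags(lib, fx$transcriptome, ncrna, db)
  a2 <- annotateTags(lib, fx$transcriptome, ncrna, db)
  expect_identical(a1, a2)
})
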