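# Read cleaning, tag collapsing, I/O round trips and Fig-1-style summaries.

test_that("empty read stream yields an empty library and a zero report", {
  empty <- data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE)
  res <- cleanReads(empty, FIX_ADAPTOR3, FIX_ADAPTOR5, label = "CK")
  expect_s4_class(res$library, "TagLibrary")
  expect_identical(length(tagSequences(res$library)), 0L)
  expect_identical(totalCleanReads(res$library), 0L)
  expect_true(all(cleaningCounts(res$report) == 0L))
})

test_that("the hand-built ten-read fixture cleans to the derived tag set", {
  res <- cleanReads(fixtureCleaningReads(), FIX_ADAPTOR3, FIX_ADAPTOR5,
                    label = "CK")
  exp <- fixtureCleaningExpected()
  expect_identical(sort(tagSequences(res$library)), exp$tags)
  expect_identical(totalCleanReads(res$library), exp$total)
  expect_identical(cleaningCounts(res$report), exp$report)
  # conservation: removed + retained == reads in
  expect_identical(sum(cleaningCounts(res$report)), 10L)
  # the duplicated insert collapsed to count 2
  expect_identical(unname(tagCounts(res$library)[
    rnaNormalize("TAGCTTATCAGACTGATGTTG")]), 2L)
})

test_that("length bounds are inclusive: 15 and 30 retained, 14 and 31 removed", {
  mk <- function(len) paste0(paste(rep(c("A", "C", "G", "T"),
                                       length.out = len), collapse = ""),
                             FIX_ADAPTOR3)
  reads <- data.frame(id = c("len14", "len15", "len30", "len31"),
                      sequence = vapply(c(14L, 15L, 30L, 31L), mk,
                                        character(1)),
                      quality = NA_character_, stringsAsFactors = FALSE)
  res <- cleanReads(reads, FIX_ADAPTOR3, FIX_ADAPTOR5)
  rep <- cleaningCounts(res$report)
  expect_identical(rep[["too_short"]], 1L)
  expect_identical(rep[["too_long"]], 1L)
  expect_identical(rep[["retained"]], 2L)
  expect_setequal(nchar(tagSequences(res$library)), c(15L, 30L))
})

test_that("reads without the 3' adaptor or with Ns get their own reasons", {
  reads <- data.frame(
    id = c("noad", "hasN"),
    sequence = c(strrep("ACGT", 10),
                 paste0("ACGTACGTACNTACGTACGTA", FIX_ADAPTOR3)),
    quality = NA_character_, stringsAsFactors = FALSE)
  rep <- cleaningCounts(cleanReads(reads, FIX_ADAPTOR3, FIX_ADAPTOR5)$report)
  expect_identical(rep[["no_insert"]], 1L)
  expect_identical(rep[["low_quality"]], 1L)
})

test_that("FASTQ parsing keeps qualities and normalizes T to U", {
  path <- tempfile(fileext = ".fastq")
  writeFixtureFastq(path)
  reads <- readFastqReads(path)
  expect_identical(nrow(reads), 10L)
  expect_identical(nchar(reads$quality), nchar(reads$sequence))
  res <- cleanReads(reads, FIX_ADAPTOR3, FIX_ADAPTOR5)
  expect_false(any(grepl("T", tagSequences(res$library))))
  expect_true(any(grepl("U", tagSequences(res$library))))
})

test_that("malformed FASTQ raises a parse error", {
  path <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), path) # truncated record
  expect_error(readFastqReads(path), "malformed FASTQ")
})

test_that("collapsed-tag FASTA round-trips losslessly", {
  lib <- TagLibrary(c("UAGCUUAUCAGACUGAUGUUG", "ACGGUUCGGAUCAACGUUACG",
                      "GGCAUUCAGGAUCGUACCAGU"), c(12L, 5L, 1L), "CK")
  path <- tempfile(fileext = ".fa")
  writeTagFasta(lib, path)
  back <- readTagFasta(path, "CK")
  expect_identical(tagCounts(back), tagCounts(lib))
  expect_identical(totalCleanReads(back), totalCleanReads(lib))
  # dialect: header >t1_x12 carries the count
  one <- tempfile(fileext = ".fa")
  writeLines(c(">t1_x12", "UAGCUUAUCAGACUGAUGUUG"), one)
  expect_identical(unname(tagCounts(readTagFasta(one))), 12L)
})

test_that("reference FASTA round-trips class/family/species labels", {
  ref <- ReferenceSet(c(r1 = "ACGUACGUACGUACGUACGU", m1 = "UAGCUUAUCAGACUGAUGUUG"),
                      class = c("rRNA", "miRNA_mature"),
                      family = c(NA, "miR156"), species = c(NA, "ath"))
  path <- tempfile(fileext = ".fa")
  writeReferenceFasta(ref, path)
  back <- readReferenceFasta(path)
  expect_identical(unname(refClass(back)), unname(refClass(ref)))
  expect_identical(unname(refFamily(back)), unname(refFamily(ref)))
  expect_identical(as.character(refSequences(back)),
                   as.character(refSequences(ref)))
})

test_that("collapsing is invariant under read order", {
  set.seed(41)
  base <- c(rep("UAGCUUAUCAGACUGAUGUUG", 5), rep("ACGGUUCGGAUCAACGUUACG", 3),
            "GGCAUUCAGGAUCGUACCAGU")
  ref <- TagLibrary(base, rep(1L, length(base)), "CK")
  for (i in 1:5) {
    perm <- sample(base)
    lib <- TagLibrary(perm, rep(1L, length(perm)), "CK")
    expect_identical(tagCounts(lib), tagCounts(ref))
    expect_identical(totalCleanReads(lib), totalCleanReads(ref))
  }
})

test_that("length distribution behaves by reads and by unique tags", {
  lib <- TagLibrary("UAGCUUAUCAGACUGAUGUUG", 7L, "CK")
  byReads <- lengthDistribution(lib, by = "reads")
  expect_identical(byReads, data.frame(length = 21L, count = 7L))
  byUnique <- lengthDistribution(lib, by = "unique")
  expect_identical(byUnique$count, 1L)
  # read-weighted counts sum to total clean reads
  big <- TagLibrary(c("UAGCUUAUCAGACUGAUGUUG", "ACGGUUCGGAUCAACGUUACGAAA",
                      "GGCAUUCAGGAUCGUA"), c(3L, 2L, 9L), "CK")
  expect_identical(sum(lengthDistribution(big, "reads")$count),
                   totalCleanReads(big))
})

test_that("first-nucleotide bias counts the 5' base per length", {
  lib <- TagLibrary("UAGCUUAUCAGACUGAUGUUG", 3L, "CK")
  fb <- firstNucleotideBias(lib)
  expect_identical(fb, data.frame(length = 21L, base = "U", count = 3L))
  expect_identical(nrow(firstNucleotideBias(TagLibrary())), 0L)
  # per-length rows sum to that length's read count
  big <- TagLibrary(c("UAGCUUAUCAGACUGAUGUUG", "AAGCUUAUCAGACUGAUGUUG",
                      "GGCAUUCAGGAUCGUA"), c(3L, 4L, 9L), "CK")
  fb <- firstNucleotideBias(big)
  expect_identical(sum(fb$count[fb$length == 21L]), 7L)
})
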