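# The seeded generator: determinism, construction guarantees, degenerate
# configurations, and the Poisson count model.

smallRefs <- function(seed = 7L)
  makeReferences(seed, nTranscripts = 4L, nPlantedPrecursors = 4L,
                 nConservedFamilies = 3L, nNcrna = 4L, nTargetSites = 2L)

test_that("the same seed reproduces references and reads byte for byte", {
  r1 <- smallRefs(); r2 <- smallRefs()
  expect_identical(as.character(refSequences(r1$transcriptome)),
                   as.character(refSequences(r2$transcriptome)))
  expect_identical(r1$truth$precursors, r2$truth$precursors)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  f1 <- simulateLibraries(r1, depthCk = 2000, depthTr = 2000, seed = 9L,
                          outDir = d1)
  f2 <- simulateLibraries(r2, depthCk = 2000, depthTr = 2000, seed = 9L,
                          outDir = d2)
  expect_identical(readLines(f1$ck), readLines(f2$ck))
  expect_identical(readLines(f1$tr), readLines(f2$tr))
  # FASTA writer determinism
  p1 <- tempfile(); p2 <- tempfile()
  writeReferenceFasta(r1$transcriptome, p1)
  writeReferenceFasta(r2$transcriptome, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("every planted precursor passes the discovery criteria in isolation", {
  refs <- smallRefs()
  pre <- refs$truth$precursors
  expect_gt(nrow(pre), 0L)
  for (i in seq_len(nrow(pre))) {
    ev <- evaluateCandidate(pre$precursor[i], pre$mature[i])
    expect_true(ev$verdict, info = pre$id[i])
    expect_identical(ev$arm, pre$arm[i])
    # the planted interval on the transcript really holds the precursor
    tx <- as.character(refSequences(refs$transcriptome))[[pre$transcript[i]]]
    expect_identical(substr(tx, pre$start[i] + 1L, pre$end[i]),
                     pre$precursor[i])
  }
})

test_that("with nothing planted, no window passes the hairpin criteria", {
  refs <- makeReferences(3L, nTranscripts = 2L, nPlantedPrecursors = 0L,
                         nConservedFamilies = 0L, nNcrna = 0L,
                         nTargetSites = 0L)
  txs <- as.character(refSequences(refs$transcriptome))
  accepted <- 0L
  for (tx in txs) {
    for (s in seq(1L, min(nchar(tx), 560L) - 110L, by = 55L)) {
      win <- substr(tx, s, s + 110L)
      mat <- substr(win, 46L, 66L)
      ev <- evaluateCandidate(win, mat)
      accepted <- accepted + as.integer(ev$verdict)
    }
  }
  expect_identical(accepted, 0L)
})

test_that("truth manifests round-trip through JSON", {
  refs <- smallRefs()
  path <- tempfile(fileext = ".json")
  writeTruth(refs$truth, path)
  back <- readTruth(path)
  expect_identical(back$seed, refs$truth$seed)
  expect_equal(back$precursors$start, refs$truth$precursors$start)
  expect_identical(back$precursors$mature, refs$truth$precursors$mature)
  expect_identical(back$decoys, refs$truth$decoys)
})

test_that("zero depth gives empty libraries", {
  refs <- smallRefs()
  fq <- simulateLibraries(refs, depthCk = 0, depthTr = 0, seed = 1L,
                          outDir = tempfile())
  expect_identical(length(readLines(fq$ck)), 0L)
})

test_that("without junk or isomiRs every cleaned tag traces to the truth", {
  refs <- smallRefs()
  fq <- simulateLibraries(refs, depthCk = 4000, depthTr = 0, seed = 2L,
                          outDir = tempfile(), isomirRate = 0,
                          junk = c(adaptor5 = 0, polyA = 0, no_adaptor = 0,
                                   low_quality = 0))
  lib <- cleanReads(readFastqReads(fq$ck), refs$truth$adaptor3,
                    refs$truth$adaptor5, label = "CK")$library
  truth <- refs$truth
  frag <- function(hs, seqs)
    vapply(seq_len(nrow(hs)), function(i)
      substr(seqs[[hs$ref[i]]], hs$start[i] + 1L, hs$start[i] + hs$len[i]),
      character(1))
  allowed <- c(truth$precursors$mature,
               frag(truth$ncrna_hotspots,
                    as.character(refSequences(refs$ncrna))),
               frag(truth$tx_hotspots,
                    as.character(refSequences(refs$transcriptome))))
  expect_true(all(tagSequences(lib) %in% allowed))
})

test_that("simulated counts are Poisson around the planted mean", {
  # 200 null miRNAs at TPM 100, library size 1e6: mean count 100
  cp <- simulateCountPairs(nNull = 200L, nDE = 0L,
                           baseTpmNull = c(100, 100), N1 = 1e6, N2 = 1e6,
                           seed = 17L)
  expect_lt(abs(mean(cp$x) - 100), 3 * 10 / sqrt(200))
  expect_lt(abs(stats::var(cp$x) - 100), 40)
  expect_identical(sum(cp$is_de), 0L)
})

test_that("dinucleotide shuffling preserves composition, destroys stems", {
  refs <- smallRefs()
  pre <- refs$truth$precursors$precursor[1]
  set.seed(19)
  shuf <- shuffleDinucleotides(pre)
  expect_identical(nchar(shuf), nchar(pre))
  expect_identical(sort(strsplit(shuf, "")[[1]]), sort(strsplit(pre, "")[[1]]))
  expect_gt(foldEnergy(foldHairpin(shuf)), foldEnergy(foldHairpin(pre)) + 5)
})
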