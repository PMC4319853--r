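# Precursor excision, stem-loop criteria, read support, novel calls.

test_that("window excision clips at transcript bounds and merges duplicates", {
  tx <- strrep("ACGU", 150) # 600 nt
  refs <- ReferenceSet(c(tx1 = tx), class = "transcript")
  hits <- data.frame(tag = "AAAA", transcript = "tx1", start = 5L, end = 26L,
                     strand = "+", stringsAsFactors = FALSE)
  w <- exciseCandidates(hits, refs, flank = 150L)
  expect_true(all(w$start >= 0L))
  expect_identical(min(w$start), 0L) # left window clipped at 0
  # mid-transcript 21-nt hit: flank window spans 150 + 21 + 20 = 191 nt
  hits2 <- data.frame(tag = "AAAA", transcript = "tx1", start = 300L,
                      end = 321L, strand = "+", stringsAsFactors = FALSE)
  w2 <- exciseCandidates(hits2, refs, flank = 150L)
  expect_setequal(w2$end - w2$start, 191L)
  # two hits five nt apart share merged duplicate windows
  both <- rbind(hits2, transform(hits2, start = 305L, end = 326L))
  w3 <- exciseCandidates(both, refs, flank = 150L)
  expect_identical(anyDuplicated(w3[, c("transcript", "start", "end",
                                        "strand", "tag")]), 0L)
})

test_that("a designed hairpin passes all structural criteria on either arm", {
  for (arm in c("5p", "3p")) {
    hp <- makeTestHairpin(FIX_MATURE, arm)
    ev <- evaluateCandidate(hp$precursor, hp$mature)
    expect_true(ev$c2, info = arm)
    expect_true(ev$c3, info = arm)
    expect_true(ev$c4, info = arm)
    expect_true(ev$c5, info = arm)
    expect_true(ev$verdict, info = arm)
    expect_identical(ev$arm, arm)
    expect_lte(ev$mfe, -23) # comfortable margin below the -18 threshold
    # MFEI is reported: (MFE / length x 100) / GC%
    gc <- ev$gc_frac * 100
    expect_equal(ev$mfei, (ev$mfe / nchar(hp$precursor) * 100) / gc,
                 tolerance = 1e-9)
  }
})

test_that("a 6-nt bulge inside the duplex fails the loop/bulge criterion", {
  m <- FIX_MATURE
  stem <- rnaReverseComplement(substr(m, 1, 19))
  bulged <- paste0(substr(stem, 1, 9), "AACCAA", substr(stem, 10, 19))
  pre <- paste0("ACAACCAACCAA", m, "AACCACAA", bulged, "CA", "CCAACAACACCA")
  ev <- evaluateCandidate(pre, m)
  expect_true(ev$c2)   # mature still pairs the star arm
  expect_false(ev$c4)  # but across a > 3 nt bulge
  expect_false(ev$verdict)
})

test_that("weak stems fail the energy threshold only", {
  # an A/U-only mature gives a real but shallow stem: above -18
  weak <- "UAUAAUAUUAUAAUAUUAUCA"
  hp <- makeTestHairpin(weak)
  ev <- evaluateCandidate(hp$precursor, weak)
  expect_false(ev$c3)
  expect_gt(ev$mfe, -18)
  expect_false(ev$verdict)
  # relaxing the threshold below the observed MFE flips the verdict
  # (verdict monotonicity in the threshold)
  evRelax <- evaluateCandidate(hp$precursor, weak, mfeMax = ev$mfe + 1)
  expect_true(evRelax$c3)
  strict <- makeTestHairpin(FIX_MATURE)
  evStrict <- evaluateCandidate(strict$precursor, FIX_MATURE, mfeMax = -60)
  expect_false(evStrict$c3)
})

test_that("a blunt-ended duplex fails the 3'-overhang criterion", {
  m <- FIX_MATURE
  # star pairs the full mature: no 2-nt overhangs anywhere
  pre <- paste0("ACAACCAACCAA", m, "AACCACAA", rnaReverseComplement(m),
                "CCAACAACACCA")
  ev <- evaluateCandidate(pre, m)
  expect_true(ev$c2)
  expect_false(ev$c5)
  expect_false(ev$verdict)
})

test_that("windows shorter than mature + 15 are rejected with a reason", {
  ev <- evaluateCandidate(substr(FIX_MATURE, 1, 21), FIX_MATURE)
  expect_false(ev$verdict)
  expect_identical(ev$reason, "window_too_short")
  ev2 <- evaluateCandidate(makeTestHairpin(FIX_MATURE)$precursor,
                           "UUUUGGGGCCCCAAAAUUUUG")
  expect_identical(ev2$reason, "mature_not_in_window")
})

test_that("mature read support applies the terminal-divergence rule", {
  m <- FIX_MATURE
  lib <- TagLibrary(
    c(m,                                        # exact          x10
      substr(m, 1, 20),                         # 3' -1          x4
      paste0(m, "AG"),                          # 3' +2          x3
      paste0(substr(m, 1, 9), "G", substr(m, 11, 21)), # internal mm x8
      substr(m, 5, 21)),                        # 5' shift 4     x100
    c(10L, 4L, 3L, 8L, 100L), "CK")
  expect_identical(countNovelReads(m, lib), 17L)
  expect_identical(countNovelReads(m, TagLibrary()), 0L)
})

test_that("the read-support bound is strict: five rejected, six accepted", {
  hp <- makeTestHairpin(FIX_MATURE)
  ev <- evaluateCandidate(hp$precursor, hp$mature)
  cand <- cbind(data.frame(tag = hp$mature, transcript = "tx1", start = 0L,
                           end = nchar(hp$precursor), strand = "+",
                           stringsAsFactors = FALSE), ev)
  five <- list(CK = TagLibrary(hp$mature, 5L, "CK"),
               TR = TagLibrary(hp$mature, 5L, "TR"))
  six <- list(CK = TagLibrary(hp$mature, 6L, "CK"),
              TR = TagLibrary(hp$mature, 2L, "TR"))
  expect_identical(nrow(callNovelMirnas(cand, five)), 0L)
  called <- callNovelMirnas(cand, six)
  expect_identical(nrow(called), 1L)
  expect_identical(called$id, "novel_mir_1")
  expect_identical(called$count_CK, 6L)
})

test_that("accepted novel miRNAs re-pass evaluation on their own record", {
  hp <- makeTestHairpin(FIX_MATURE, "3p")
  ev <- evaluateCandidate(hp$precursor, hp$mature)
  cand <- cbind(data.frame(tag = hp$mature, transcript = "tx1", start = 0L,
                           end = nchar(hp$precursor), strand = "+",
                           stringsAsFactors = FALSE), ev)
  libs <- list(CK = TagLibrary(hp$mature, 50L, "CK"),
               TR = TagLibrary(hp$mature, 40L, "TR"))
  called <- callNovelMirnas(cand, libs)
  expect_identical(nrow(called), 1L)
  again <- evaluateCandidate(called$precursor, called$mature)
  expect_true(again$verdict)
})
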