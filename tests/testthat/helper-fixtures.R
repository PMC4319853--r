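# Fixtures built in code: the hand-derived cleaning read set, designed
# hairpins, and duplex constructors for the target rule matrix.

FIX_ADAPTOR3 <- "TCGTATGCCGTCTTCTGCTTG"
FIX_ADAPTOR5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

# Ten raw reads with hand-derived cleaning outcomes:
#   2 with the 5' adaptor embedded in the insert   -> adaptor_5prime
#   1 pure-A insert                                -> polyA
#   1 insert of 12 nt                              -> too_short
#   1 insert of 31 nt                              -> too_long
#   5 valid 21-nt inserts, two identical           -> retained (4 unique tags)
fixtureCleaningReads <- function() {
  v1 <- "TAGCTTATCAGACTGATGTTG"                 # x2
  inserts <- c(paste0(substr(FIX_ADAPTOR5, 1, 8), "TACGATCGATCGA"),
               paste0(substr(FIX_ADAPTOR5, 1, 8), "GGCCATTAGGCCA"),
               strrep("A", 20),
               "ACGTACGTACGT",
               "ACGTACGTACGTACGTACGTACGTACGTACG",
               v1, v1,
               "ACGGTTCGGATCAACGTTACG",
               "GGCATTCAGGATCGTACCAGT",
               "CCGATTGAGACCGTTAAGCTG")
  seqs <- paste0(inserts, FIX_ADAPTOR3)
  data.frame(id = sprintf("r%02d", seq_along(seqs)), sequence = seqs,
             quality = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
}

fixtureCleaningExpected <- function() {
  list(tags = sort(rnaNormalize(c("TAGCTTATCAGACTGATGTTG",
                                  "ACGGTTCGGATCAACGTTACG",
                                  "GGCATTCAGGATCGTACCAGT",
                                  "CCGATTGAGACCGTTAAGCTG"))),
       total = 5L,
       report = c(adaptor_5prime = 2L, no_insert = 0L, polyA = 1L,
                  too_short = 1L, too_long = 1L, low_quality = 0L,
                  retained = 5L))
}

writeFixtureFastq <- function(path, reads = fixtureCleaningReads()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads)))
    writeLines(c(paste0("@", reads$id[i]), reads$sequence[i], "+",
                 reads$quality[i]), con)
  path
}

# Deterministic designed stem-loop (same geometry as the simulator's
# hairpins but with fixed filler, no RNG): mature[1..19] pairs the star
# arm, mature[20..21] and the star's trailing dinucleotide are the 2-nt
# 3' overhangs, loop and flanks are non-pairing {A,C} text.
makeTestHairpin <- function(mature, arm = "5p", loop = "AACCACAA",
                            t2 = "CA", f5 = "ACAACCAACCAA",
                            f3 = "CCAACAACACCA") {
  mature <- rnaNormalize(mature)
  stopifnot(nchar(mature) == 21L)
  stem <- rnaReverseComplement(substr(mature, 1, 19))
  if (arm == "5p") {
    pre <- paste0(f5, mature, loop, stem, t2, f3)
    mStart <- nchar(f5)
  } else {
    pre <- paste0(f5, stem, t2, loop, mature, f3)
    mStart <- nchar(f5) + 19L + 2L + nchar(loop)
  }
  list(precursor = pre, mature = mature, matureStart = mStart)
}

# a 21-nt mature over a mixed alphabet whose last two nt are {A,C}
FIX_MATURE <- "UGGAGCUGCACGGGUUCAUCA"

# per-rule miRNA designs for the target rule matrix: mismatches land over
# weak (A/U) stacks so breaking them keeps the energy ratio above 0.75,
# except in the r6 fixture which deliberately destroys strong stacks
M_GC_HEAD <- paste0("GCGGCGGCGGCG", "AAAAAAAAU")  # strong 5' half
M_AU_HEAD <- paste0("AUAAUAAUAGUA", "GCGGCGGCG")  # strong 3' half

# Duplex constructor for the target rule matrix: start from the perfect
# complement and force MM or G:U wobble at chosen miRNA positions.
makeTargetSite <- function(mirna, mm = integer(), gu = integer()) {
  site <- rnaReverseComplement(mirna)
  L <- nchar(mirna)
  mc <- strsplit(mirna, "")[[1]]
  mmBase <- c(A = "C", C = "A", G = "A", U = "C")
  for (p in mm) substr(site, L - p + 1, L - p + 1) <- mmBase[[mc[p]]]
  for (p in gu) {
    stopifnot(mc[p] %in% c("G", "U"))
    substr(site, L - p + 1, L - p + 1) <- if (mc[p] == "G") "U" else "G"
  }
  site
}

evalTargetPair <- function(mirna, site) {
  st <- alignSite(mirna, site)
  de <- duplexEnergy(mirna, site, paired = st != "MM")$energy
  applyTargetCriteria(st, de, perfectComplementEnergy(mirna))
}

# small shared reference trio for annotate tests
fixtureReferences <- function() {
  tx <- paste0("ACAACCAACC", FIX_MATURE, "CCAACAACACCAACCAAACCAACAACCA")
  list(
    transcriptome = ReferenceSet(c(tx1 = tx), class = "transcript"),
    mature = FIX_MATURE)
}
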