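# Seeded synthetic references and libraries with a ground-truth manifest.
# The generator emulates the study design: two libraries (control CK,
# copper-treated TR) of 18-30 nt tags with 21- and 24-nt modes and 5'-U
# bias, conserved miRNAs with isomiR clouds, novel hairpin precursors
# planted on transcripts, ncRNA degradation fragments drawn from a
# limited set of processing hotspots, adaptor/polyA junk, and planted
# per-miRNA fold-changes. Same seed => byte-identical outputs.

.SIM_ADAPTOR3 <- "UCGUAUGCCGUCUUCUGCUUG"
.SIM_ADAPTOR5 <- "GUUCAGAGUUCUACAGUCCGACGAUC"
.SIM_READLEN <- 42L

.FAMILY_POOL <- c("miR156", "miR157", "miR159", "miR160", "miR166", "miR167",
                  "miR169", "miR171", "miR319", "miR390", "miR396", "miR398",
                  "miR408", "miR482", "miR828", "miR845", "miR902", "miR1113")

.setSimSeed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

# non-pairing filler from {A, C} (A-A, A-C, C-C are not canonical pairs)
.acFill <- function(len) paste(sample(c("A", "C"), len, replace = TRUE),
                               collapse = "")

# a 21-nt mature: 5'-U biased, last two nt from {A,C} so the designed
# duplex overhangs cannot pair with the {A,C} loop and flanks
.randomMature <- function(p5U = 0.9) {
  first <- if (stats::runif(1) < p5U) "U" else sample(c("A", "C", "G"), 1L)
  mid <- paste(sample(c("A", "C", "G", "U"), 18L, replace = TRUE),
               collapse = "")
  paste0(first, mid, .acFill(2L))
}

# Designed stem-loop: mature positions 1..19 pair the star arm
# (reverse complement of mature[1..19]); mature[20..21] and the star's
# trailing dinucleotide are the 2-nt 3' overhangs. Loop and flanks come
# from the non-pairing {A,C} alphabet.
.buildHairpin <- function(mature, arm) {
  stem <- rnaReverseComplement(substr(mature, 1L, 19L))
  loop <- .acFill(8L)
  t2 <- .acFill(2L)
  f5 <- .acFill(12L); f3 <- .acFill(12L)
  if (arm == "5p") {
    pre <- paste0(f5, mature, loop, stem, t2, f3)
    mStart <- nchar(f5)                      # 0-based
  } else {
    pre <- paste0(f5, stem, t2, loop, mature, f3)
    mStart <- nchar(f5) + 19L + 2L + 8L
  }
  list(precursor = pre, matureStart = mStart,
       matureEnd = mStart + nchar(mature),
       star = if (arm == "5p") paste0(stem, t2) else paste0(stem, t2))
}

# build a hairpin that passes the structural criteria with an energy
# margin; bounded retries, error names the seed
.plantableHairpin <- function(mature, arm, mfeMargin = -23, seed = NA,
                              tries = 30L) {
  for (i in seq_len(tries)) {
    hp <- .buildHairpin(mature, arm)
    ev <- evaluateCandidate(hp$precursor, mature, mfeMax = mfeMargin)
    if (ev$verdict) {
      hp$mfe <- ev$mfe
      return(hp)
    }
    mature <- .randomMature() # resample the mature and retry
  }
  stop("hairpin construction infeasible after ", tries,
       " retries (seed ", seed, ")")
}

#' Generate synthetic references with ground truth
#'
#' Builds a transcriptome with planted hairpin precursors (each verified
#' to pass the discovery criteria with an energy margin) and planted
#' perfect-complement target sites, a miRBase-style conserved-miRNA
#' catalog, an ncRNA reference set with degradation hotspots, and
#' dinucleotide-shuffled decoy transcripts, plus the truth manifest that
#' every recovery test reads.
#'
#' @param seed integer seed; same seed gives byte-identical references
#' @param nTranscripts number of host transcripts (default 24)
#' @param nPlantedPrecursors novel hairpins planted (default 30)
#' @param nConservedFamilies catalog families, each planted with its own
#'   hairpin (default 12)
#' @param nNcrna ncRNA reference records (default 8)
#' @param nTargetSites planted perfect target sites (default 8)
#' @return list(transcriptome, catalog, ncrna, truth) where the first
#'   three are \code{ReferenceSet}s and truth is the manifest list
#' @export
makeReferences <- function(seed, nTranscripts = 24L, nPlantedPrecursors = 30L,
                           nConservedFamilies = 12L, nNcrna = 8L,
                           nTargetSites = 8L) {
  .setSimSeed(seed)
  stopifnot(nTranscripts >= 1L)
  families <- .FAMILY_POOL[seq_len(min(nConservedFamilies,
                                       length(.FAMILY_POOL)))]
  # matures: conserved then novel
  conMat <- vapply(families, function(f) .randomMature(p5U = 0.95),
                   character(1))
  novMat <- vapply(seq_len(nPlantedPrecursors), function(i)
    .randomMature(p5U = 0.7), character(1))
  mirIds <- c(if (length(families)) paste0("con_", families),
              if (nPlantedPrecursors > 0)
                paste0("pl_novel_", seq_len(nPlantedPrecursors)))
  if (is.null(mirIds)) mirIds <- character(0)
  mirMat <- c(conMat, novMat)
  mirType <- c(rep("conserved", length(families)),
               rep("novel", length(novMat)))
  arms <- rep(c("5p", "3p"), length.out = length(mirMat))
  hairpins <- vector("list", length(mirMat))
  for (i in seq_along(mirMat)) {
    hairpins[[i]] <- .plantableHairpin(mirMat[i], arms[i], seed = seed)
    mirMat[i] <- substr(hairpins[[i]]$precursor,
                        hairpins[[i]]$matureStart + 1L,
                        hairpins[[i]]$matureEnd) # may have been resampled
  }
  # catalog: two members per family (exact + 1 internal substitution)
  catSeqs <- character(0); catCls <- character(0)
  catFam <- character(0); catSpc <- character(0); catIds <- character(0)
  for (i in seq_along(families)) {
    m <- mirMat[i]
    pos <- sample(5:15, 1L)
    base <- substr(m, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "U"), base), 1L)
    m2 <- paste0(substr(m, 1L, pos - 1L), alt, substr(m, pos + 1L, nchar(m)))
    catIds <- c(catIds, paste0("ath-", families[i]),
                paste0("osa-", families[i]))
    catSeqs <- c(catSeqs, m, m2)
    catCls <- c(catCls, "miRNA_mature", "miRNA_mature")
    catFam <- c(catFam, families[i], families[i])
    catSpc <- c(catSpc, "ath", "osa")
  }
  catalog <- ReferenceSet(stats::setNames(catSeqs, catIds), class = catCls,
                          family = catFam, species = catSpc)
  # target sites: perfect complements of a subset of matures
  siteOf <- if (nTargetSites)
    seq_along(mirMat)[rep_len(seq_along(mirMat), nTargetSites)][
      seq_len(nTargetSites)] else integer()
  # assemble transcripts: spacers + planted elements, coordinates recorded
  txIds <- sprintf("tx_%02d", seq_len(nTranscripts))
  elements <- data.frame(kind = character(), mir = integer(),
                         tx = integer(), stringsAsFactors = FALSE)
  if (length(mirMat))
    elements <- rbind(elements,
                      data.frame(kind = "pre", mir = seq_along(mirMat),
                                 tx = rep_len(seq_len(nTranscripts),
                                              length(mirMat))))
  if (length(siteOf))
    elements <- rbind(elements,
                      data.frame(kind = "site", mir = siteOf,
                                 tx = rep_len(rev(seq_len(nTranscripts)),
                                              length(siteOf))))
  txSeq <- character(nTranscripts)
  preRows <- list(); siteRows <- list()
  for (t in seq_len(nTranscripts)) {
    el <- elements[elements$tx == t, , drop = FALSE]
    parts <- .randomRna(1L, sample(320:480, 1L))
    for (j in seq_len(nrow(el))) {
      at <- sum(nchar(parts))
      if (el$kind[j] == "pre") {
        hp <- hairpins[[el$mir[j]]]
        parts <- c(parts, hp$precursor)
        preRows[[length(preRows) + 1L]] <- data.frame(
          id = mirIds[el$mir[j]], type = mirType[el$mir[j]],
          family = if (mirType[el$mir[j]] == "conserved")
            families[el$mir[j]] else NA_character_,
          mature = mirMat[el$mir[j]], arm = arms[el$mir[j]],
          star = hp$star, precursor = hp$precursor,
          transcript = txIds[t], start = at, end = at + nchar(hp$precursor),
          mature_start = at + hp$matureStart, mature_end = at + hp$matureEnd,
          pre_mature_start = hp$matureStart, pre_mature_end = hp$matureEnd,
          mfe = hp$mfe, stringsAsFactors = FALSE)
      } else {
        site <- rnaReverseComplement(mirMat[el$mir[j]])
        parts <- c(parts, site)
        siteRows[[length(siteRows) + 1L]] <- data.frame(
          mir = mirIds[el$mir[j]], mature = mirMat[el$mir[j]],
          transcript = txIds[t], start = at, end = at + nchar(site),
          stringsAsFactors = FALSE)
      }
      parts <- c(parts, .randomRna(1L, sample(320:480, 1L)))
    }
    txSeq[t] <- paste(parts, collapse = "")
  }
  precursors <- if (length(preRows)) do.call(rbind, preRows) else
    data.frame(id = character(), type = character(), family = character(),
               mature = character(), arm = character(), star = character(),
               precursor = character(), transcript = character(),
               start = integer(), end = integer(), mature_start = integer(),
               mature_end = integer(), pre_mature_start = integer(),
               pre_mature_end = integer(), mfe = numeric(),
               stringsAsFactors = FALSE)
  targetSites <- if (length(siteRows)) do.call(rbind, siteRows) else
    data.frame(mir = character(), mature = character(),
               transcript = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  # decoys: dinucleotide-shuffled copies of the planted precursors
  decoySeq <- shuffleDinucleotides(precursors$precursor[
    precursors$type == "novel"])
  decoyIds <- if (length(decoySeq)) sprintf("decoy_%02d", seq_along(decoySeq))
    else character()
  allTx <- stats::setNames(c(txSeq, decoySeq), c(txIds, decoyIds))
  transcriptome <- ReferenceSet(allTx, class = "transcript")
  # ncRNA references with degradation hotspots
  ncClasses <- rep_len(c("rRNA", "tRNA", "snoRNA", "snRNA"), nNcrna)
  ncLen <- c(rRNA = 1200L, tRNA = 75L, snoRNA = 110L, snRNA = 150L)
  ncIds <- if (nNcrna) sprintf("%s_%02d", ncClasses, seq_len(nNcrna)) else
    character()
  ncSeq <- vapply(seq_len(nNcrna), function(i)
    .randomRna(1L, ncLen[[ncClasses[i]]]), character(1))
  ncrna <- ReferenceSet(stats::setNames(ncSeq, ncIds), class = ncClasses)
  ncHot <- list()
  for (i in seq_len(nNcrna)) {
    len <- sample(18:28, 6L, replace = TRUE,
                  prob = c(1, 1, 2, 3, 2, 2, 3, 2, 1, 1, 1))
    start <- vapply(len, function(l)
      sample.int(ncLen[[ncClasses[i]]] - l, 1L), integer(1))
    ncHot[[i]] <- data.frame(ref = ncIds[i], start = start, len = len,
                             weight = stats::rexp(6L) + 0.2,
                             stringsAsFactors = FALSE)
  }
  ncHotspots <- if (length(ncHot)) do.call(rbind, ncHot) else
    data.frame(ref = character(), start = integer(), len = integer(),
               weight = numeric(), stringsAsFactors = FALSE)
  # unannotated transcript fragments: hotspots away from precursors
  txHot <- list()
  for (t in seq_len(nTranscripts)) {
    pre <- precursors[precursors$transcript == txIds[t], , drop = FALSE]
    L <- nchar(txSeq[t])
    got <- 0L; guard <- 0L
    while (got < 3L && guard < 200L) {
      guard <- guard + 1L
      l <- sample(19:26, 1L)
      s <- sample.int(L - l, 1L)
      if (nrow(pre) && any(s < pre$end + 170L & pre$start - 170L < s + l))
        next
      got <- got + 1L
      txHot[[length(txHot) + 1L]] <- data.frame(
        ref = txIds[t], start = s, len = l, weight = stats::rexp(1L) + 0.2,
        stringsAsFactors = FALSE)
    }
  }
  txHotspots <- if (length(txHot)) do.call(rbind, txHot) else
    data.frame(ref = character(), start = integer(), len = integer(),
               weight = numeric(), stringsAsFactors = FALSE)
  # expression truth: base TPM and planted fold-changes
  nMir <- length(mirMat)
  baseTpm <- ifelse(mirType == "conserved",
                    10^stats::runif(nMir, 2.3, 4.3),
                    10^stats::runif(nMir, 2.2, 3.3))
  lfc <- numeric(nMir)
  deIdx <- c(which(mirType == "conserved")[seq_len(min(3L, sum(mirType == "conserved")))],
             which(mirType == "novel")[seq_len(min(8L, sum(mirType == "novel")))])
  lfc[deIdx] <- sample(c(-2, 2), length(deIdx), replace = TRUE)
  expression <- data.frame(id = mirIds, mature = mirMat, type = mirType,
                           base_tpm = baseTpm, lfc = lfc,
                           is_de = seq_len(nMir) %in% deIdx,
                           stringsAsFactors = FALSE)
  truth <- list(seed = as.integer(seed),
                params = list(nTranscripts = nTranscripts,
                              nPlantedPrecursors = nPlantedPrecursors,
                              nConservedFamilies = length(families),
                              nNcrna = nNcrna, nTargetSites = nTargetSites),
                adaptor3 = .SIM_ADAPTOR3, adaptor5 = .SIM_ADAPTOR5,
                read_len = .SIM_READLEN,
                families = families,
                precursors = precursors, target_sites = targetSites,
                decoys = decoyIds,
                ncrna_ids = ncIds, ncrna_classes = ncClasses,
                ncrna_hotspots = ncHotspots, tx_hotspots = txHotspots,
                expression = expression)
  list(transcriptome = transcriptome, catalog = catalog, ncrna = ncrna,
       truth = truth)
}

# isomiR cloud profile: class, offset5, offset3, tail, probability.
# 3'-end heterogeneity is roughly twice the 5' rate.
.ISOMIR_PROFILE <- data.frame(
  off5 = c(0L, 1L, -1L, 0L, 0L, 0L, 0L, 0L, 1L),
  off3 = c(0L, 0L, 0L, -1L, 1L, -2L, 0L, 0L, -1L),
  tail = c("", "", "", "", "", "", "A", "U", ""),
  prob = c(0.67, 0.04, 0.04, 0.07, 0.05, 0.04, 0.04, 0.03, 0.02),
  stringsAsFactors = FALSE)

# expand one miRNA's count into its isomiR cloud (needs precursor context
# for templated extensions); infeasible variants fold into the canonical
.isomirCloud <- function(n, pre, mStart, mEnd, isomirRate = 1) {
  prof <- .ISOMIR_PROFILE
  if (isomirRate <= 0) {
    prof <- prof[1L, ]; prof$prob <- 1
  } else if (isomirRate != 1) {
    prof$prob[-1L] <- prof$prob[-1L] * isomirRate
    prof$prob[1L] <- 1 - sum(prof$prob[-1L])
  }
  preLen <- nchar(pre)
  feasible <- (mStart + prof$off5) >= 0L & (mEnd + prof$off3) <= preLen &
    (mEnd + prof$off3) - (mStart + prof$off5) >= 15L
  prof$prob[!feasible] <- 0
  prof$prob[1L] <- prof$prob[1L] + (1 - sum(prof$prob))
  cnt <- as.integer(stats::rmultinom(1L, n, prof$prob))
  keep <- cnt > 0L
  if (!any(keep)) return(data.frame(seq = character(), count = integer()))
  sq <- vapply(which(keep), function(i) {
    paste0(substr(pre, mStart + prof$off5[i] + 1L, mEnd + prof$off3[i]),
           prof$tail[i])
  }, character(1))
  data.frame(seq = sq, count = cnt[keep], stringsAsFactors = FALSE)
}

#' Simulate the two sequencing libraries
#'
#' Draws per-miRNA read counts (Poisson; treated means scaled by
#' 2^planted-lfc), expands them into isomiR clouds, adds ncRNA
#' degradation fragments and unannotated transcript fragments from the
#' hotspot tables, mixes in adaptor-contaminated, poly(A), adaptorless
#' and N-containing junk at the configured fractions, appends the 3'
#' adaptor and writes Phred+33 FASTQ. Same (truth, depths, seed) gives
#' byte-identical files.
#'
#' @param refs list from \code{makeReferences}
#' @param depthCk,depthTr raw read depths (default 1e5 each)
#' @param seed integer seed for the read draws
#' @param outDir directory for ck.fastq / tr.fastq
#' @param isomirRate scale factor on the non-canonical isomiR
#'   probabilities (0 disables the cloud)
#' @param junk named fractions: adaptor5, polyA, no_adaptor, low_quality
#' @param ncrnaFrac,unannotFrac read fractions for ncRNA fragments and
#'   unannotated transcript fragments
#' @return list(ck, tr) FASTQ paths; attribute "expected" holds the
#'   per-miRNA expected clean counts used for the draws
#' @export
simulateLibraries <- function(refs, depthCk = 1e5, depthTr = 1e5, seed,
                              outDir = tempdir(), isomirRate = 1,
                              junk = c(adaptor5 = 0.03, polyA = 0.03,
                                       no_adaptor = 0.02, low_quality = 0.01),
                              ncrnaFrac = 0.22, unannotFrac = 0.06) {
  .setSimSeed(seed + 1L)
  truth <- refs$truth
  pre <- truth$precursors
  expr <- truth$expression
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  expected <- list()
  for (lib in c("ck", "tr")) {
    depth <- if (lib == "ck") depthCk else depthTr
    depth <- as.integer(depth)
    inserts <- character(0)
    if (depth > 0L) {
      nJunk <- vapply(junk, function(f) as.integer(round(f * depth)),
                      integer(1))
      nNc <- as.integer(round(ncrnaFrac * depth))
      nUn <- as.integer(round(unannotFrac * depth))
      nMirTotal <- max(0L, depth - sum(nJunk) - nNc - nUn)
      # per-miRNA Poisson counts
      w <- expr$base_tpm
      wLib <- if (lib == "tr") w * 2^expr$lfc else w
      mu <- nMirTotal * wLib / sum(w)
      cnt <- stats::rpois(length(mu), mu)
      expected[[lib]] <- stats::setNames(mu, expr$id)
      mirReads <- character(0)
      for (i in seq_along(cnt)) {
        if (cnt[i] == 0L) next
        j <- match(expr$id[i], pre$id)
        cloud <- .isomirCloud(cnt[i], pre$precursor[j],
                              pre$pre_mature_start[j], pre$pre_mature_end[j],
                              isomirRate = isomirRate)
        mirReads <- c(mirReads, rep(cloud$seq, cloud$count))
      }
      # ncRNA + unannotated hotspot fragments
      fragReads <- function(hs, seqs, n) {
        if (!nrow(hs) || n <= 0L) return(character(0))
        pick <- stats::rmultinom(1L, n, hs$weight)[, 1L]
        unlist(lapply(which(pick > 0L), function(i) {
          frag <- substr(seqs[[hs$ref[i]]], hs$start[i] + 1L,
                         hs$start[i] + hs$len[i])
          rep(frag, pick[i])
        }), use.names = FALSE)
      }
      ncSeqs <- stats::setNames(as.character(refSequences(refs$ncrna)),
                                names(refSequences(refs$ncrna)))
      txSeqs <- stats::setNames(as.character(refSequences(refs$transcriptome)),
                                names(refSequences(refs$transcriptome)))
      ncReads <- fragReads(truth$ncrna_hotspots, ncSeqs, nNc)
      unReads <- fragReads(truth$tx_hotspots, txSeqs, nUn)
      # junk inserts
      jAd5 <- vapply(seq_len(nJunk[["adaptor5"]]), function(i)
        paste0(substr(.SIM_ADAPTOR5, 1L, 8L), .randomRna(1L, 13L)),
        character(1))
      jPolyA <- vapply(seq_len(nJunk[["polyA"]]), function(i)
        strrep("A", sample(18:28, 1L)), character(1))
      jNoAd <- character(0) # handled at read assembly (no 3' adaptor)
      nNoAd <- nJunk[["no_adaptor"]]
      jLowQ <- vapply(seq_len(nJunk[["low_quality"]]), function(i) {
        s <- .randomRna(1L, 21L)
        paste0(substr(s, 1L, 10L), "N", substr(s, 12L, 21L))
      }, character(1))
      inserts <- c(mirReads, ncReads, unReads, jAd5, jPolyA, jLowQ)
      inserts <- inserts[sample.int(length(inserts))]
      reads <- paste0(inserts, .SIM_ADAPTOR3)
      if (nNoAd > 0L) reads <- c(reads, .randomRna(nNoAd, .SIM_READLEN))
      pad <- strrep("A", .SIM_READLEN)
      reads <- substr(paste0(reads, pad), 1L, .SIM_READLEN)
    } else reads <- character(0)
    dna <- Biostrings::DNAStringSet(chartr("UN", "TN", reads))
    names(dna) <- sprintf("%s_%06d", toupper(lib), seq_along(dna))
    qual <- Biostrings::BStringSet(rep(strrep("I", .SIM_READLEN),
                                       length(dna)))
    path <- file.path(outDir, paste0(lib, ".fastq"))
    if (length(dna) > 0L) {
      q <- Biostrings::QualityScaledDNAStringSet(
        dna, Biostrings::PhredQuality(qual))
      Biostrings::writeQualityScaledXStringSet(q, path)
    } else writeLines(character(0), path)
    paths[[lib]] <- path
  }
  attr(paths, "expected") <- expected
  paths
}

#' Simulate count pairs for differential-expression calibration
#'
#' Null miRNAs have equal means in both libraries; planted DE miRNAs get
#' means scaled by 2^lfc in library 2. Counts are Poisson with mean
#' base TPM x N / 10^6 per library.
#'
#' @param nNull,nDE numbers of null and planted-DE miRNAs
#' @param lfc planted |log2 fold-change| (sign randomized)
#' @param baseTpmNull,baseTpmDE TPM ranges (log-uniform draw)
#' @param N1,N2 library sizes
#' @param seed integer seed
#' @return data.frame(id, x, y, true_lfc, is_de)
#' @export
simulateCountPairs <- function(nNull = 180L, nDE = 20L, lfc = 2,
                               baseTpmNull = c(10, 1000),
                               baseTpmDE = c(100, 2000),
                               N1 = 1e6, N2 = 1e6, seed = 1L) {
  .setSimSeed(seed)
  n <- nNull + nDE
  isDe <- c(rep(FALSE, nNull), rep(TRUE, nDE))
  tpm0 <- c(10^stats::runif(nNull, log10(baseTpmNull[1]), log10(baseTpmNull[2])),
            10^stats::runif(nDE, log10(baseTpmDE[1]), log10(baseTpmDE[2])))
  trueLfc <- ifelse(isDe, sample(c(-lfc, lfc), n, replace = TRUE), 0)
  muX <- tpm0 * N1 / 1e6
  muY <- tpm0 * 2^trueLfc * N2 / 1e6
  data.frame(id = sprintf("mir_%03d", seq_len(n)),
             x = stats::rpois(n, muX), y = stats::rpois(n, muY),
             true_lfc = trueLfc, is_de = isDe, stringsAsFactors = FALSE)
}

#' Write / read the truth manifest as JSON
#'
#' @param truth manifest list from \code{makeReferences}
#' @param path JSON path
#' @return the path (write) or the manifest list (read)
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("precursors", "target_sites", "ncrna_hotspots", "tx_hotspots",
               "expression"))
    if (!is.null(tr[[nm]])) tr[[nm]] <- as.data.frame(tr[[nm]],
                                                      stringsAsFactors = FALSE)
  tr
}
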