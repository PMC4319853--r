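# Novel miRNA discovery: excise candidate precursor windows around
# unannotated transcriptome-mapped tags, fold them, and apply the
# stem-loop criteria:
#   c1 tag unannotated (enforced upstream by the caller)
#   c2 mature sits in one arm: >= 75% of mature positions paired, all
#      partners on the opposite arm (mature does not span the loop)
#   c3 MFE <= mfeMax (default -18, configurable)
#   c4 no internal loop or bulge > maxBulge nt inside the mature:star duplex
#   c5 the mature/star duplex shows 2-nt 3' overhangs (1 nt slack)
#   c6 mature read support > minReads-1 (applied in callNovelMirnas)

#' Excise candidate precursor windows around mapped tags
#'
#' For each perfect-match hit, two asymmetric windows are taken:
#' [start-flank, end+20) and [start-20, end+flank), clipped to the
#' transcript; the mature may sit on either arm, so one long flank per
#' side covers the observed plant precursor range (67-370 nt). Duplicate
#' windows are merged.
#'
#' @param hits data.frame from \code{mapPerfect} (tag, transcript, start,
#'   end, strand)
#' @param transcriptome a \code{ReferenceSet}
#' @param flank window extension in nt (default 150)
#' @return data.frame(tag, transcript, start, end, strand, window) with
#'   0-based half-open window coordinates and the window sequence oriented
#'   so the tag reads sense
#' @export
exciseCandidates <- function(hits, transcriptome, flank = 150L) {
  empty <- data.frame(tag = character(), transcript = character(),
                      start = integer(), end = integer(),
                      strand = character(), window = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  txSeqs <- as.character(refSequences(transcriptome))
  txLen <- nchar(txSeqs)
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    L <- txLen[[h$transcript]]
    w <- rbind(c(max(0L, h$start - flank), min(L, h$end + 20L)),
               c(max(0L, h$start - 20L), min(L, h$end + flank)))
    data.frame(tag = h$tag, transcript = h$transcript,
               start = as.integer(w[, 1L]), end = as.integer(w[, 2L]),
               strand = h$strand, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[!duplicated(res[, c("tag", "transcript", "start", "end", "strand")]), ,
             drop = FALSE]
  win <- substr(txSeqs[res$transcript], res$start + 1L, res$end)
  flip <- res$strand == "-"
  win[flip] <- rnaReverseComplement(win[flip])
  res$window <- unname(win)
  res <- res[order(res$transcript, res$start, res$end, res$tag, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# duplex geometry between the mature positions and their partners:
# returns list(ok2, ok4, ok5, arm, star) or NULL when the mature is absent
.matureDuplexFlags <- function(fold, mStart, mEnd, maxBulge = 3L) {
  pt <- pairTable(fold)
  n <- length(pt)
  mPos <- mStart:mEnd
  partners <- pt[mPos]
  pairedIdx <- which(!is.na(partners))
  fracPaired <- length(pairedIdx) / length(mPos)
  prt <- partners[pairedIdx]
  # c2: all partners strictly on one side, nested (monotone decreasing)
  oneArm <- length(pairedIdx) > 0L &&
    (all(prt > mEnd) || all(prt < mStart)) &&
    !is.unsorted(rev(prt), strictly = TRUE)
  ok2 <- fracPaired >= 0.75 && oneArm
  arm <- if (!length(pairedIdx)) NA_character_
         else if (all(prt > mEnd)) "5p" else if (all(prt < mStart)) "3p"
         else NA_character_
  ok4 <- FALSE; ok5 <- FALSE
  starLo <- NA_integer_; starHi <- NA_integer_
  if (oneArm && length(pairedIdx) >= 2L) {
    # c4: loop/bulge sizes between consecutive paired mature positions
    gapM <- diff(mPos[pairedIdx]) - 1L
    gapS <- abs(diff(prt)) - 1L
    ok4 <- all(pmax(gapM, gapS) <= maxBulge)
    # c5: 2-nt 3' overhangs on both strands (1 nt slack).
    # Mature 3' overhang: unpaired tail at the mature 3' end;
    # star 3' overhang: the two positions 3' of the star span (the span's
    # high end pairs the mature 5' side) must be free of the duplex.
    tailM <- length(mPos) - max(pairedIdx)
    headM <- min(pairedIdx) - 1L
    starLo <- min(prt); starHi <- max(prt)
    over <- c(starHi + 1L, starHi + 2L)
    over <- over[over <= n]
    starFree <- sum(is.na(pt[over]) | pt[over] < mStart | pt[over] > mEnd)
    ok5 <- tailM >= 1L && tailM <= 3L && headM <= 1L &&
      length(over) >= 1L && starFree >= 1L
  } else if (oneArm && length(pairedIdx) == 1L) {
    starLo <- prt[1L]; starHi <- prt[1L]
  }
  list(ok2 = ok2, ok4 = ok4, ok5 = ok5, arm = arm,
       starLo = starLo, starHi = starHi)
}

#' Evaluate a precursor candidate window
#'
#' Folds the window with the embedded engine and applies structural
#' criteria c2-c5 (c3 is the MFE threshold). Also reports MFEI
#' ((MFE / length x 100) / GC%) and GC fraction; MFEI is reported but not
#' filtered on.
#'
#' @param window precursor window sequence (RNA)
#' @param mature mature tag sequence; must occur exactly in the window
#' @param mfeMax MFE acceptance threshold (default -18)
#' @param maxBulge largest tolerated loop/bulge inside the duplex (default 3)
#' @return one-row data.frame: window, mature, arm, star, mfe, mfei,
#'   gc_frac, structure, c2..c5, verdict, reason
#' @export
evaluateCandidate <- function(window, mature, mfeMax = -18, maxBulge = 3L) {
  window <- rnaNormalize(window); mature <- rnaNormalize(mature)
  fail <- function(reason) {
    data.frame(window = window, mature = mature, arm = NA_character_,
               star = NA_character_, mfe = NA_real_, mfei = NA_real_,
               gc_frac = NA_real_, structure = NA_character_,
               c2 = FALSE, c3 = FALSE, c4 = FALSE, c5 = FALSE,
               verdict = FALSE, reason = reason, stringsAsFactors = FALSE)
  }
  if (nchar(window) < nchar(mature) + 15L) return(fail("window_too_short"))
  mStart <- as.integer(regexpr(mature, window, fixed = TRUE))
  if (mStart < 1L) return(fail("mature_not_in_window"))
  mEnd <- mStart + nchar(mature) - 1L
  fold <- foldHairpin(window)
  gc <- nchar(gsub("[^GC]", "", window)) / nchar(window)
  mfe <- foldEnergy(fold)
  mfei <- if (gc > 0) (mfe / nchar(window) * 100) / (gc * 100) else NA_real_
  fl <- .matureDuplexFlags(fold, mStart, mEnd, maxBulge = maxBulge)
  c3 <- mfe <= mfeMax
  star <- if (!is.na(fl$starLo))
    substr(window, fl$starLo, min(nchar(window), fl$starHi + 2L))
  else NA_character_
  verdict <- fl$ok2 && c3 && fl$ok4 && fl$ok5
  data.frame(window = window, mature = mature, arm = fl$arm, star = star,
             mfe = mfe, mfei = mfei, gc_frac = gc,
             structure = foldStructure(fold),
             c2 = fl$ok2, c3 = c3, c4 = fl$ok4, c5 = fl$ok5,
             verdict = verdict,
             reason = if (verdict) "accepted" else
               paste0("fail_", paste(c("c2", "c3", "c4", "c5")[
                 !c(fl$ok2, c3, fl$ok4, fl$ok5)], collapse = "+")),
             stringsAsFactors = FALSE)
}

#' Read support of a predicted mature miRNA
#'
#' Sums counts of library tags that match the mature exactly over their
#' mutual overlap with total terminal divergence (5' offset + 3' offset,
#' including non-template 3' additions) at most \code{maxTerminal} nt.
#' Internal mismatches disqualify a tag.
#'
#' @param mature mature sequence (18-26 nt typical)
#' @param lib a \code{TagLibrary}
#' @param maxTerminal total terminal divergence tolerance (default 3)
#' @return integer read count
#' @export
countNovelReads <- function(mature, lib, maxTerminal = 3L) {
  mature <- rnaNormalize(mature)
  tags <- tagSequences(lib)
  if (!length(tags)) return(0L)
  counts <- unname(tagCounts(lib))
  ml <- nchar(mature)
  mc <- .chars(mature)
  ok <- vapply(seq_along(tags), function(i) {
    tag <- tags[i]; tl <- nchar(tag)
    if (abs(tl - ml) > maxTerminal) return(FALSE)
    tc <- .chars(tag)
    for (s in -maxTerminal:maxTerminal) {     # tag start minus mature start
      endOff <- (s + tl) - ml                 # tag 3' end relative to mature
      div <- abs(s) + abs(endOff)
      if (div > maxTerminal) next
      lo <- max(1L, 1L + s); hi <- min(tl, ml + s)
      if (hi < lo) next
      if (all(tc[lo:hi] == mc[(lo - s):(hi - s)])) return(TRUE)
    }
    FALSE
  }, logical(1))
  as.integer(sum(counts[ok]))
}

#' Call novel miRNAs from evaluated candidates
#'
#' Keeps accepted candidates whose mature read support exceeds
#' \code{minReads - 1} in at least one library (the rule is strictly
#' "more than 5" reads, hence the default of 6). Overlapping accepted
#' candidates on the same transcript locus are deduplicated keeping the
#' lowest-MFE precursor. Ids novel_mir_N are assigned in deterministic
#' order (transcript id, then position).
#'
#' @param candidates data.frame: the \code{exciseCandidates} columns
#'   cbound with the \code{evaluateCandidate} columns
#' @param libs named list of \code{TagLibrary} (e.g. list(CK=, TR=))
#' @param minReads minimum read support, exclusive bound is minReads-1
#'   (default 6, i.e. count > 5)
#' @param maxTerminal terminal divergence for read counting (default 3)
#' @return data.frame(id, transcript, start, end, strand, mature, arm,
#'   precursor, structure, mfe, mfei, count_<lib>...)
#' @export
callNovelMirnas <- function(candidates, libs, minReads = 6L, maxTerminal = 3L) {
  libNames <- names(libs)
  countCols <- paste0("count_", libNames)
  empty <- data.frame(id = character(), transcript = character(),
                      start = integer(), end = integer(), strand = character(),
                      mature = character(), mature_start = integer(),
                      mature_end = integer(), arm = character(),
                      precursor = character(), structure = character(),
                      mfe = numeric(), mfei = numeric(),
                      stringsAsFactors = FALSE)
  for (cc in countCols) empty[[cc]] <- integer()
  acc <- candidates[which(candidates$verdict), , drop = FALSE]
  if (!nrow(acc)) return(empty)
  # read support per distinct mature (c6)
  matures <- unique(acc$mature)
  support <- sapply(libNames, function(nm) {
    vapply(matures, countNovelReads, integer(1), lib = libs[[nm]],
           maxTerminal = maxTerminal)
  })
  support <- matrix(support, nrow = length(matures),
                    dimnames = list(matures, libNames))
  keepMat <- rownames(support)[apply(support, 1L, function(x)
    any(x >= minReads))]
  acc <- acc[acc$mature %in% keepMat, , drop = FALSE]
  if (!nrow(acc)) return(empty)
  # mature interval in transcript coordinates (window was excised sense)
  off <- vapply(seq_len(nrow(acc)), function(i)
    as.integer(regexpr(acc$mature[i], acc$window[i], fixed = TRUE)) - 1L,
    integer(1))
  mlen <- nchar(acc$mature)
  plus <- acc$strand == "+"
  acc$mature_start <- ifelse(plus, acc$start + off, acc$end - off - mlen)
  acc$mature_end <- acc$mature_start + mlen
  # deduplicate calls on the same stem-loop locus: two calls on one
  # transcript whose mature intervals lie within a precursor span of each
  # other (gap <= 50 nt, either strand: a tag matching the star arm maps
  # antisense into the same hairpin) are one locus. Keep the
  # best-supported mature, then the lowest MFE.
  acc$support <- rowSums(support)[acc$mature]
  acc <- acc[order(acc$transcript, -acc$support, acc$mfe, acc$start, acc$end), ,
             drop = FALSE]
  kept <- acc[0, ]
  for (i in seq_len(nrow(acc))) {
    cand <- acc[i, ]
    gap <- pmax(kept$mature_start, cand$mature_start) -
      pmin(kept$mature_end, cand$mature_end)
    sameLocus <- kept$transcript == cand$transcript & gap <= 50L
    if (!any(sameLocus)) kept <- rbind(kept, cand)
  }
  kept <- kept[order(kept$transcript, kept$mature_start, kept$start), ,
               drop = FALSE]
  res <- data.frame(id = sprintf("novel_mir_%d", seq_len(nrow(kept))),
                    transcript = kept$transcript, start = kept$start,
                    end = kept$end, strand = kept$strand,
                    mature = kept$mature,
                    mature_start = kept$mature_start,
                    mature_end = kept$mature_end, arm = kept$arm,
                    precursor = kept$window, structure = kept$structure,
                    mfe = kept$mfe, mfei = kept$mfei,
                    stringsAsFactors = FALSE)
  for (nm in libNames)
    res[[paste0("count_", nm)]] <- unname(support[res$mature, nm])
  rownames(res) <- NULL
  res
}

#' Discover novel miRNAs end to end
#'
#' Convenience wrapper: maps the unannotated tags, excises windows,
#' evaluates each, and calls novel miRNAs across the supplied libraries.
#'
#' @param unannotatedTags character vector of unannotated mapped tag
#'   sequences (candidate matures)
#' @param libs named list of \code{TagLibrary}
#' @param transcriptome a \code{ReferenceSet}
#' @param flank window flank (default 150)
#' @param mfeMax MFE threshold (default -18)
#' @param maxBulge duplex loop/bulge tolerance (default 3)
#' @param minReads read-support bound (default 6: count > 5)
#' @return list(novel = calls, candidates = evaluated table)
#' @export
discoverNovel <- function(unannotatedTags, libs, transcriptome, flank = 150L,
                          mfeMax = -18, maxBulge = 3L, minReads = 6L) {
  pool <- TagLibrary(unannotatedTags, rep(1L, length(unannotatedTags)), "pool")
  hits <- mapPerfect(pool, transcriptome)
  wins <- exciseCandidates(hits, transcriptome, flank = flank)
  if (!nrow(wins)) {
    ev <- evaluateCandidate("A", "AAAA")[0, ] # typed empty frame
    cand <- cbind(wins, ev[0, ])
    return(list(novel = callNovelMirnas(cand, libs, minReads), candidates = cand))
  }
  ev <- do.call(rbind, lapply(seq_len(nrow(wins)), function(i) {
    evaluateCandidate(wins$window[i], wins$tag[i], mfeMax = mfeMax,
                      maxBulge = maxBulge)
  }))
  cand <- cbind(wins[, c("tag", "transcript", "start", "end", "strand")], ev)
  # per mature locus keep the best (lowest-MFE) passing window before calling
  list(novel = callNovelMirnas(cand, libs, minReads = minReads),
       candidates = cand)
}
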