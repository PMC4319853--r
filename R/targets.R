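# Rule-based miRNA target prediction on the transcriptome. Duplexes are
# ungapped; positions are 1-based from the miRNA 5' end. G:U wobble
# counts 0.5 towards the mismatch scores (rules 1 and 5) but is treated
# as paired, not mismatched, for the boolean adjacency/position rules
# (2)-(4).
#
# Acceptance rules for a candidate site:
#   r1 total mismatch score <= 4          (GU = 0.5, MM = 1)
#   r2 no run of > 2 consecutive MM anywhere
#   r3 no 2 consecutive MM within positions 2-12
#   r4 no MM at positions 10 or 11
#   r5 mismatch score over positions 1-12 <= 2.5
#   r6 duplex MFE / perfect-complement MFE >= 0.75

#' Align a miRNA against a candidate site
#'
#' The site is the transcript subsequence read 5' to 3'; the duplex is
#' antiparallel, so miRNA position i faces site position L-i+1. Each
#' miRNA position gets a state: WC (Watson-Crick), GU (wobble), or MM.
#'
#' @param mirna miRNA sequence (RNA)
#' @param site site sequence, same length
#' @return character vector of states over miRNA positions 1..L
#' @export
alignSite <- function(mirna, site) {
  mirna <- rnaNormalize(mirna); site <- rnaNormalize(site)
  L <- nchar(mirna)
  if (nchar(site) != L) stop("site and miRNA lengths differ")
  a <- .chars(mirna)
  b <- rev(.chars(site))
  key <- paste0(a, b)
  state <- rep("MM", L)
  state[key %in% c("AU", "UA", "GC", "CG")] <- "WC"
  state[key %in% c("GU", "UG")] <- "GU"
  state
}

#' Score a duplex alignment
#'
#' @param states state vector from \code{alignSite}
#' @return list(mismatch_score, score_1_12, max_mm_run, mm_adjacent_2_12,
#'   mm_10_11)
#' @export
scoreDuplex <- function(states) {
  w <- c(WC = 0, GU = 0.5, MM = 1)[states]
  L <- length(states)
  mm <- states == "MM"
  runs <- rle(mm)
  maxRun <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  idx <- 2:min(12L, L)
  adj212 <- any(mm[idx[-length(idx)]] & mm[idx[-1L]])
  list(mismatch_score = sum(w),
       score_1_12 = sum(w[seq_len(min(12L, L))]),
       max_mm_run = as.integer(maxRun),
       mm_adjacent_2_12 = adj212,
       mm_10_11 = any(mm[intersect(c(10L, 11L), seq_len(L))]))
}

#' Apply the six target-acceptance rules
#'
#' @param states state vector from \code{alignSite}
#' @param duplexMfe duplex energy of the aligned pair
#' @param perfectMfe energy of the miRNA bound to its perfect complement
#' @param maxMismatch rule 1 bound (default 4)
#' @param maxScore112 rule 5 bound (default 2.5)
#' @param minMfeRatio rule 6 bound (default 0.75)
#' @return one-row data.frame(mismatch_score, score_1_12, mfe, perfect_mfe,
#'   mfe_ratio, r1..r6, verdict)
#' @export
applyTargetCriteria <- function(states, duplexMfe, perfectMfe,
                                maxMismatch = 4, maxScore112 = 2.5,
                                minMfeRatio = 0.75) {
  sc <- scoreDuplex(states)
  ratio <- duplexMfe / perfectMfe
  r1 <- sc$mismatch_score <= maxMismatch
  r2 <- sc$max_mm_run <= 2L
  r3 <- !sc$mm_adjacent_2_12
  r4 <- !sc$mm_10_11
  r5 <- sc$score_1_12 <= maxScore112
  r6 <- is.finite(ratio) && ratio >= minMfeRatio
  data.frame(mismatch_score = sc$mismatch_score, score_1_12 = sc$score_1_12,
             mfe = duplexMfe, perfect_mfe = perfectMfe, mfe_ratio = ratio,
             r1 = r1, r2 = r2, r3 = r3, r4 = r4, r5 = r5, r6 = r6,
             verdict = r1 && r2 && r3 && r4 && r5 && r6,
             stringsAsFactors = FALSE)
}

# vectorized pre-screen of all windows of one transcript against one
# miRNA: returns data.frame(start0, mismatch_score, score112, ok_bool)
# for windows passing rules 1-5 (energies are computed only for these)
.screenTranscript <- function(mirna, tx, maxMismatch = 4, maxScore112 = 2.5) {
  L <- nchar(mirna); Tn <- nchar(tx)
  nW <- Tn - L + 1L
  if (nW < 1L) return(integer())
  a <- .chars(mirna)
  txc <- .chars(tx)
  # miRNA position i faces transcript position (start + L - i) (1-based)
  wsc <- numeric(nW); w112 <- numeric(nW)
  mmPrev <- rep(FALSE, nW); run <- integer(nW); maxRun <- integer(nW)
  adj212 <- rep(FALSE, nW); mm1011 <- rep(FALSE, nW)
  for (i in seq_len(L)) {
    tpos <- (L - i + 1L):(L - i + nW)
    key <- paste0(a[i], txc[tpos])
    wc <- key %in% c("AU", "UA", "GC", "CG")
    gu <- key %in% c("GU", "UG")
    mm <- !(wc | gu)
    wsc <- wsc + ifelse(mm, 1, ifelse(gu, 0.5, 0))
    if (i <= 12L) w112 <- w112 + ifelse(mm, 1, ifelse(gu, 0.5, 0))
    run <- ifelse(mm, run + 1L, 0L)
    maxRun <- pmax(maxRun, run)
    if (i >= 3L && i <= 12L) adj212 <- adj212 | (mm & mmPrev)
    if (i %in% c(10L, 11L)) mm1011 <- mm1011 | mm
    mmPrev <- mm
  }
  ok <- wsc <= maxMismatch & maxRun <= 2L & !adj212 & !mm1011 &
    w112 <= maxScore112
  which(ok)
}

#' Predict miRNA targets across a transcriptome
#'
#' Slides a window of miRNA length along the sense strand of every
#' transcript, evaluates the six rules on each window, and reports
#' accepted hits. Overlapping accepted windows for the same miRNA and
#' transcript are merged keeping the best hit (lowest mismatch score,
#' then lowest duplex energy, then leftmost).
#'
#' @param mirnas named character vector of miRNA sequences (18-26 nt)
#' @param transcriptome a \code{ReferenceSet} (or named character vector)
#' @param maxMismatch,maxScore112,minMfeRatio rule bounds
#' @return data.frame(mirna, transcript, start, end, site,
#'   mismatch_score, score_1_12, mfe, perfect_mfe, mfe_ratio, r1..r6,
#'   verdict); start/end 0-based half-open; accepted hits only
#' @export
predictTargets <- function(mirnas, transcriptome, maxMismatch = 4,
                           maxScore112 = 2.5, minMfeRatio = 0.75) {
  txSeqs <- if (is(transcriptome, "ReferenceSet"))
    as.character(refSequences(transcriptome)) else rnaNormalize(transcriptome)
  empty <- data.frame(mirna = character(), transcript = character(),
                      start = integer(), end = integer(), site = character(),
                      mismatch_score = numeric(), score_1_12 = numeric(),
                      mfe = numeric(), perfect_mfe = numeric(),
                      mfe_ratio = numeric(), r1 = logical(), r2 = logical(),
                      r3 = logical(), r4 = logical(), r5 = logical(),
                      r6 = logical(), verdict = logical(),
                      stringsAsFactors = FALSE)
  if (!length(mirnas) || !length(txSeqs)) return(empty)
  mirnas <- stats::setNames(rnaNormalize(mirnas),
                            if (is.null(names(mirnas)))
                              sprintf("mir_%d", seq_along(mirnas))
                            else names(mirnas))
  out <- list(); k <- 0L
  for (mn in names(mirnas)) {
    mir <- mirnas[[mn]]
    pe <- perfectComplementEnergy(mir)
    L <- nchar(mir)
    for (tn in names(txSeqs)) {
      tx <- txSeqs[[tn]]
      cand <- .screenTranscript(mir, tx, maxMismatch, maxScore112)
      if (!length(cand)) next
      rows <- lapply(cand, function(s0) {
        site <- substr(tx, s0, s0 + L - 1L)
        states <- alignSite(mir, site)
        de <- duplexEnergy(mir, site, paired = states != "MM")$energy
        res <- applyTargetCriteria(states, de, pe,
                                   maxMismatch = maxMismatch,
                                   maxScore112 = maxScore112,
                                   minMfeRatio = minMfeRatio)
        if (!res$verdict) return(NULL)
        cbind(data.frame(mirna = mn, transcript = tn, start = s0 - 1L,
                         end = s0 - 1L + L, site = site,
                         stringsAsFactors = FALSE), res)
      })
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (!length(rows)) next
      hits <- do.call(rbind, rows)
      # merge overlapping hits for this (miRNA, transcript)
      hits <- hits[order(hits$mismatch_score, hits$mfe, hits$start), ,
                   drop = FALSE]
      kept <- hits[0, ]
      for (i in seq_len(nrow(hits))) {
        h <- hits[i, ]
        if (!any(kept$start < h$end & h$start < kept$end))
          kept <- rbind(kept, h)
      }
      k <- k + 1L
      out[[k]] <- kept
    }
  }
  if (!k) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$mirna, res$transcript, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
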