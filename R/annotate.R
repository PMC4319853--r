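# Transcriptome mapping, ncRNA classification, and conserved-miRNA
# identification via the three-step temporary-database procedure:
# (1) align tags to a plant miRNA catalog (ungapped, <= 2 substitutions,
#     end offsets within 2 nt), (2) keep the highest-count tag per family
#     as that family's representative, (3) re-align the library to the
#     representatives to quantify conserved miRNAs.

# concatenated search text over both strands of a set of sequences
.bigText <- function(seqs) {
  if (!length(seqs)) return("")
  paste(c(seqs, rnaReverseComplement(seqs)), collapse = "NNN")
}

#' Map tags to a transcriptome by perfect match
#'
#' A tag maps iff it, or its reverse complement, is an exact substring of
#' a transcript (no mismatches tolerated). All occurrences are reported.
#'
#' @param lib a \code{TagLibrary}
#' @param transcriptome a \code{ReferenceSet} (all records searched)
#' @return data.frame(tag, transcript, start, end, strand); start/end are
#'   0-based half-open transcript coordinates
#' @export
mapPerfect <- function(lib, transcriptome) {
  txSeqs <- refSequences(transcriptome)
  ids <- names(txSeqs)
  tags <- tagSequences(lib)
  empty <- data.frame(tag = character(), transcript = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (!length(tags) || !length(txSeqs)) return(empty)
  big <- .bigText(as.character(txSeqs))
  out <- vector("list", 2L * length(tags))
  k <- 0L
  for (tag in tags) {
    for (strand in c("+", "-")) {
      probe <- if (strand == "+") tag else rnaReverseComplement(tag)
      if (!grepl(probe, big, fixed = TRUE)) next
      mi <- Biostrings::vmatchPattern(probe, txSeqs)
      for (s in seq_along(mi)) {
        r <- mi[[s]]
        if (length(r)) {
          k <- k + 1L
          out[[k]] <- data.frame(tag = tag, transcript = ids[s],
                                 start = IRanges::start(r) - 1L,
                                 end = IRanges::end(r),
                                 strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!k) return(empty)
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(res$tag, res$transcript, res$start, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify tags as ncRNA degradation fragments
#'
#' A tag is assigned to the first class in the fixed priority order
#' rRNA > tRNA > snoRNA > snRNA for which it is an exact substring of a
#' reference of that class (either strand). Unmatched tags are left out.
#'
#' @param lib a \code{TagLibrary}
#' @param ncrnaRefs a \code{ReferenceSet} with rRNA/tRNA/snRNA/snoRNA records
#' @return data.frame(sequence, category) for classified tags only
#' @export
classifyNcrna <- function(lib, ncrnaRefs) {
  tags <- tagSequences(lib)
  category <- rep(NA_character_, length(tags))
  cls <- refClass(ncrnaRefs)
  for (klass in c("rRNA", "tRNA", "snoRNA", "snRNA")) {
    seqs <- as.character(refSequences(ncrnaRefs))[cls == klass]
    if (!length(seqs)) next
    big <- .bigText(seqs)
    todo <- which(is.na(category))
    hit <- vapply(tags[todo], function(t) grepl(t, big, fixed = TRUE),
                  logical(1), USE.NAMES = FALSE)
    category[todo[hit]] <- klass
  }
  keep <- !is.na(category)
  data.frame(sequence = tags[keep], category = category[keep],
             stringsAsFactors = FALSE)
}

# per-tag hits against a set of mature references; ungapped, end offsets
# within maxShift, <= maxMismatch substitutions over the overlap
.matchMatures <- function(tags, matures, maxMismatch = 2L, maxShift = 2L) {
  lapply(tags, function(tag) {
    mm <- vapply(matures, function(m) {
      .alignTagToMature(tag, m, maxShift = maxShift)$mm
    }, numeric(1))
    which(mm <= maxMismatch)
  })
}

#' Build the temporary miRNA database
#'
#' Step (1)-(2) of the conserved-miRNA procedure: tags aligning to any
#' catalog mature of a family (ungapped, at most \code{maxMismatch}
#' substitutions, terminal offsets within 2 nt) are pooled per family and
#' the highest-count tag becomes the family representative (ties broken
#' by the lexicographically smaller sequence).
#'
#' @param lib a \code{TagLibrary}
#' @param catalog a \code{ReferenceSet}; records of class miRNA_mature
#'   with family labels are used
#' @param maxMismatch substitution tolerance (default 2)
#' @return data.frame(family, sequence, count), one row per family with
#'   at least one aligning tag, sorted by family
#' @export
buildTempMirnaDb <- function(lib, catalog, maxMismatch = 2L) {
  mat <- refSubset(catalog, "miRNA_mature")
  fams <- refFamily(mat)
  matSeqs <- as.character(refSequences(mat))
  empty <- data.frame(family = character(), sequence = character(),
                      count = integer(), stringsAsFactors = FALSE)
  if (!length(matSeqs)) return(empty)
  tags <- tagSequences(lib)
  counts <- unname(tagCounts(lib))
  hits <- .matchMatures(tags, matSeqs, maxMismatch = maxMismatch)
  rows <- list()
  for (fam in sort(unique(fams))) {
    members <- which(fams == fam)
    tagIdx <- which(vapply(hits, function(h) any(h %in% members), logical(1)))
    if (!length(tagIdx)) next
    o <- tagIdx[order(-counts[tagIdx], tags[tagIdx])]
    rows[[fam]] <- data.frame(family = fam, sequence = tags[o[1L]],
                              count = counts[o[1L]], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Quantify conserved miRNAs against the temporary database
#'
#' Step (3): each library tag aligning to a representative with at most
#' \code{maxMismatch} substitutions (ungapped) contributes its count to
#' that family's expression. Each tag is assigned to at most one family:
#' best hit by fewest mismatches, ties by lexicographic family name.
#'
#' @param lib a \code{TagLibrary}
#' @param tempDb data.frame from \code{buildTempMirnaDb}
#' @param maxMismatch substitution tolerance (default 2)
#' @return data.frame(family, sequence, count, n_members, members), one
#'   row per family with nonzero count; attribute "assignment" holds the
#'   per-tag table (tag, family, mismatches)
#' @export
quantifyConserved <- function(lib, tempDb, maxMismatch = 2L) {
  empty <- data.frame(family = character(), sequence = character(),
                      count = integer(), n_members = integer(),
                      members = character(), stringsAsFactors = FALSE)
  attr(empty, "assignment") <- data.frame(tag = character(),
                                          family = character(),
                                          mismatches = integer(),
                                          stringsAsFactors = FALSE)
  if (!nrow(tempDb)) return(empty)
  tags <- tagSequences(lib)
  counts <- unname(tagCounts(lib))
  fams <- tempDb$family
  asn <- lapply(seq_along(tags), function(i) {
    mm <- vapply(tempDb$sequence, function(rep) {
      .alignTagToMature(tags[i], rep)$mm
    }, numeric(1), USE.NAMES = FALSE)
    ok <- which(mm <= maxMismatch)
    if (!length(ok)) return(NULL)
    best <- ok[order(mm[ok], fams[ok])][1L]
    data.frame(tag = tags[i], family = fams[best],
               mismatches = as.integer(mm[best]), stringsAsFactors = FALSE)
  })
  asn <- do.call(rbind, asn)
  if (is.null(asn)) return(empty)
  rows <- lapply(sort(unique(asn$family)), function(fam) {
    idx <- match(asn$tag[asn$family == fam], tags)
    data.frame(family = fam,
               sequence = tempDb$sequence[match(fam, tempDb$family)],
               count = sum(counts[idx]), n_members = length(idx),
               members = paste(sort(tags[idx]), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "assignment") <- asn
  res
}

#' Annotate every tag of a library
#'
#' Assigns each unique tag exactly one category using the fixed priority
#' rRNA > tRNA > snoRNA > snRNA > known_miRNA > unannotated_mapped >
#' unmapped (ncRNA classification precedes miRNA identification). The
#' result is a partition: category counts sum to the library's unique-tag
#' count.
#'
#' @param lib a \code{TagLibrary}
#' @param transcriptome \code{ReferenceSet} of transcripts
#' @param ncrnaRefs \code{ReferenceSet} of ncRNAs
#' @param tempDb data.frame from \code{buildTempMirnaDb}
#' @return data.frame(sequence, count, category) in library order
#' @export
annotateTags <- function(lib, transcriptome, ncrnaRefs, tempDb) {
  tags <- tagSequences(lib)
  counts <- unname(tagCounts(lib))
  category <- rep(NA_character_, length(tags))
  nc <- classifyNcrna(lib, ncrnaRefs)
  category[match(nc$sequence, tags)] <- nc$category
  prof <- quantifyConserved(lib, tempDb)
  asn <- attr(prof, "assignment")
  if (!is.null(asn) && nrow(asn)) {
    idx <- match(asn$tag, tags)
    category[idx[is.na(category[idx])]] <- "known_miRNA"
  }
  todo <- which(is.na(category))
  if (length(todo)) {
    sub <- TagLibrary(tags[todo], counts[todo], libraryLabel(lib))
    hits <- mapPerfect(sub, transcriptome)
    mapped <- tags[todo] %in% hits$tag
    category[todo[mapped]] <- "unannotated_mapped"
    category[todo[!mapped]] <- "unmapped"
  }
  data.frame(sequence = tags, count = counts, category = category,
             stringsAsFactors = FALSE)
}
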