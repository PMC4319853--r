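# isomiR cataloguing: place tags on identified pre-miRNAs and classify
# each placement relative to the canonical mature. Class priority when
# several labels apply: nontemplate > both > 5p_variant/3p_variant
# (the most specific label wins).

#' Place library tags on pre-miRNA sequences
#'
#' A tag places on a precursor if a prefix of the tag of length at least
#' tag length - \code{tailMax} matches the precursor exactly; the
#' unmatched 3' remainder (at most \code{tailMax} nt) becomes the
#' candidate non-template tail. Among admissible placements the longest
#' templated prefix (shortest tail) wins; each tag keeps one placement
#' per precursor (leftmost) and contributes to exactly one precursor
#' downstream (resolved in \code{isomirCatalog} by fewest terminal
#' differences, ties by precursor id).
#'
#' @param lib a \code{TagLibrary}
#' @param premirnas named character vector (or \code{RNAStringSet}) of
#'   precursor sequences
#' @param tailMax maximum non-template tail length (default 3)
#' @return data.frame(tag, count, precursor, start, end, tail); start/end
#'   are 0-based half-open coordinates of the templated portion
#' @export
mapToPrecursor <- function(lib, premirnas, tailMax = 3L) {
  if (!is.character(premirnas)) premirnas <- as.character(premirnas)
  premirnas <- stats::setNames(rnaNormalize(premirnas), names(premirnas))
  tags <- tagSequences(lib)
  counts <- unname(tagCounts(lib))
  empty <- data.frame(tag = character(), count = integer(),
                      precursor = character(), start = integer(),
                      end = integer(), tail = character(),
                      stringsAsFactors = FALSE)
  if (!length(tags) || !length(premirnas)) return(empty)
  rows <- list(); k <- 0L
  for (i in seq_along(tags)) {
    tag <- tags[i]; tl <- nchar(tag)
    for (p in names(premirnas)) {
      pre <- premirnas[[p]]
      for (t in 0:min(tailMax, tl - 1L)) {
        prefix <- substr(tag, 1L, tl - t)
        pos <- as.integer(regexpr(prefix, pre, fixed = TRUE))
        if (pos > 0L) {
          k <- k + 1L
          rows[[k]] <- data.frame(tag = tag, count = counts[i], precursor = p,
                                  start = pos - 1L, end = pos - 1L + tl - t,
                                  tail = substr(tag, tl - t + 1L, tl),
                                  stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  if (!k) return(empty)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Classify a placement relative to the canonical mature
#'
#' Offsets are placement start/end minus canonical start/end (signed;
#' positive 5' offset means the tag starts downstream of the canonical 5'
#' end). Class: canonical iff both offsets are zero and the tail is
#' empty; otherwise nontemplate when a tail is present, both when both
#' termini shift, else 5p_variant/3p_variant. Placements overlapping the
#' canonical by fewer than \code{minOverlap} nt are not isomiRs of that
#' mature and return NULL.
#'
#' @param placement one row of \code{mapToPrecursor} output
#' @param canonicalStart,canonicalEnd canonical mature interval on the
#'   precursor (0-based half-open)
#' @param minOverlap minimum overlap with the canonical (default 10)
#' @return one-row data.frame(tag, count, precursor, offset5, offset3,
#'   tail, class) or NULL
#' @export
classifyIsomir <- function(placement, canonicalStart, canonicalEnd,
                           minOverlap = 10L) {
  ov <- min(placement$end, canonicalEnd) - max(placement$start, canonicalStart)
  if (ov < minOverlap) return(NULL)
  off5 <- placement$start - canonicalStart
  off3 <- placement$end - canonicalEnd
  tail <- placement$tail
  cls <- if (off5 == 0L && off3 == 0L && !nzchar(tail)) "canonical"
    else if (nzchar(tail)) "nontemplate"
    else if (off5 != 0L && off3 != 0L) "both"
    else if (off5 != 0L) "5p_variant"
    else "3p_variant"
  data.frame(tag = placement$tag, count = placement$count,
             precursor = placement$precursor, offset5 = off5, offset3 = off3,
             tail = tail, class = cls, stringsAsFactors = FALSE)
}

#' Build the isomiR catalog for a set of precursors
#'
#' Maps the library on the precursors and classifies every admissible
#' placement against each precursor's canonical mature. A tag placing on
#' several precursors is assigned to the one with the fewest terminal
#' differences (|offset5| + |offset3| + tail length), ties broken by
#' precursor id, so placements partition the tags.
#'
#' @param lib a \code{TagLibrary}
#' @param premirnas named character vector of precursor sequences
#' @param canonical data.frame(precursor, start, end): canonical mature
#'   intervals (0-based half-open)
#' @param tailMax maximum non-template tail (default 3)
#' @return data.frame(tag, count, precursor, offset5, offset3, tail, class)
#' @export
isomirCatalog <- function(lib, premirnas, canonical, tailMax = 3L) {
  pl <- mapToPrecursor(lib, premirnas, tailMax = tailMax)
  empty <- data.frame(tag = character(), count = integer(),
                      precursor = character(), offset5 = integer(),
                      offset3 = integer(), tail = character(),
                      class = character(), stringsAsFactors = FALSE)
  if (!nrow(pl)) return(empty)
  rows <- lapply(seq_len(nrow(pl)), function(i) {
    j <- match(pl$precursor[i], canonical$precursor)
    if (is.na(j)) return(NULL)
    classifyIsomir(pl[i, ], canonical$start[j], canonical$end[j])
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(empty)
  res$termdiff <- abs(res$offset5) + abs(res$offset3) + nchar(res$tail)
  res <- res[order(res$tag, res$termdiff, res$precursor), , drop = FALSE]
  res <- res[!duplicated(res$tag), , drop = FALSE]
  res$termdiff <- NULL
  res <- res[order(res$precursor, res$offset5, res$offset3, res$tag), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summarize the isomiR catalog per precursor
#'
#' Per precursor: number of variants, read share by class (shares sum to
#' 1), and 5' vs 3' heterogeneity (read counts of variants whose 5'
#' terminus, respectively 3' terminus including tails, deviates from the
#' canonical).
#'
#' @param variants data.frame from \code{isomirCatalog}
#' @return data.frame(precursor, n_variants, reads, share_canonical,
#'   share_5p, share_3p, share_both, share_nontemplate, het5, het3)
#' @export
summarizeIsomirs <- function(variants) {
  empty <- data.frame(precursor = character(), n_variants = integer(),
                      reads = integer(), share_canonical = numeric(),
                      share_5p = numeric(), share_3p = numeric(),
                      share_both = numeric(), share_nontemplate = numeric(),
                      het5 = integer(), het3 = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(variants)) return(empty)
  rows <- lapply(split(variants, variants$precursor), function(v) {
    tot <- sum(v$count)
    shr <- function(cl) sum(v$count[v$class == cl]) / tot
    data.frame(precursor = v$precursor[1L], n_variants = nrow(v), reads = tot,
               share_canonical = shr("canonical"), share_5p = shr("5p_variant"),
               share_3p = shr("3p_variant"), share_both = shr("both"),
               share_nontemplate = shr("nontemplate"),
               het5 = sum(v$count[v$offset5 != 0L]),
               het3 = sum(v$count[v$offset3 != 0L | nzchar(v$tail)]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$precursor), , drop = FALSE]
  rownames(res) <- NULL
  res
}
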