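# Reading, cleaning and summarising raw small-RNA reads.

#' Read raw reads from FASTQ
#'
#' Sanger Phred+33 FASTQ via Biostrings. Returns the raw-read table the
#' cleaner consumes.
#'
#' @param path FASTQ file
#' @return data.frame with columns id, sequence (uppercase, as read),
#'   quality (character Phred+33 string)
#' @export
readFastqReads <- function(path) {
  tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
    if (length(x) && any(nchar(qual) != Biostrings::width(x)))
      stop("sequence/quality length mismatch")
    data.frame(id = if (is.null(names(x))) as.character(seq_along(x)) else
                 names(x),
               sequence = toupper(as.character(x)), quality = qual,
               stringsAsFactors = FALSE)
  }, error = function(e) stop("malformed FASTQ '", path, "': ",
                              conditionMessage(e), call. = FALSE))
}

#' Read raw reads from FASTA
#'
#' @param path FASTA file
#' @return data.frame with columns id, sequence, quality (all NA)
#' @export
readFastaReads <- function(path) {
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) stop("malformed FASTA '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  data.frame(id = if (is.null(names(x))) as.character(seq_along(x)) else names(x),
             sequence = toupper(as.character(x)),
             quality = NA_character_, stringsAsFactors = FALSE)
}

#' Clean raw reads into a collapsed tag library
#'
#' Implements the read-cleaning rules of the study design: locate and trim
#' the 3' adaptor (exact match of its first \code{seedLen} nt; absent
#' adaptor means the read carries no insert), then discard inserts that
#' contain the 5' adaptor, are empty, are poly(A) (A fraction >=
#' \code{polyAFrac}), fall outside [\code{minLen}, \code{maxLen}] nt
#' (bounds inclusive: inserts of exactly 15 and 30 nt are retained with
#' the defaults), or are low quality (any N, or mean Phred <
#' \code{minMeanQ} when qualities are present). Survivors are collapsed to
#' unique tags with counts.
#'
#' Rules are applied in a fixed order (missing 3' adaptor, empty insert,
#' low quality, 5' adaptor, polyA, length) so each read gets exactly one
#' removal reason and reasons + retained always sum to the input count.
#'
#' @param reads data.frame from \code{readFastqReads}/\code{readFastaReads}
#'   (columns id, sequence, quality)
#' @param adaptor3,adaptor5 adaptor sequences (non-empty)
#' @param minLen,maxLen inclusive insert length bounds (default 15, 30)
#' @param polyAFrac A-fraction threshold for the poly(A) rule (default 0.8)
#' @param minMeanQ mean-Phred threshold (default 20); skipped when quality
#'   is NA (FASTA input)
#' @param seedLen adaptor seed length for exact matching (default 8)
#' @param label library label for the resulting \code{TagLibrary}
#' @return list(library = TagLibrary, report = CleaningReport)
#' @export
cleanReads <- function(reads, adaptor3, adaptor5, minLen = 15L, maxLen = 30L,
                       polyAFrac = 0.8, minMeanQ = 20, seedLen = 8L,
                       label = "lib") {
  stopifnot(nzchar(adaptor3), nzchar(adaptor5))
  n <- nrow(reads)
  reasons <- stats::setNames(integer(length(.CLEAN_REASONS)), .CLEAN_REASONS)
  if (n == 0L) {
    return(list(library = TagLibrary(character(), integer(), label),
                report = new("CleaningReport", counts = reasons)))
  }
  seqs <- rnaNormalize(reads$sequence)
  qual <- if ("quality" %in% names(reads)) reads$quality else rep(NA_character_, n)
  seed3 <- substr(rnaNormalize(adaptor3), 1L, seedLen)
  seed5 <- substr(rnaNormalize(adaptor5), 1L, seedLen)

  pos3 <- as.integer(regexpr(seed3, seqs, fixed = TRUE))
  insert <- ifelse(pos3 > 0L, substr(seqs, 1L, pos3 - 1L), "")
  ilen <- nchar(insert)
  hasN <- grepl("N", insert, fixed = TRUE)
  meanQ <- .meanPhred(qual, pmax(ilen, 1L))
  lowQ <- hasN | (!is.na(meanQ) & ilen > 0L & meanQ < minMeanQ)
  has5 <- grepl(seed5, insert, fixed = TRUE)
  nA <- nchar(gsub("[^A]", "", insert))
  isPolyA <- ilen > 0L & (nA / pmax(ilen, 1L)) >= polyAFrac

  reason <- rep("retained", n)
  reason[ilen < minLen] <- "too_short"
  reason[ilen > maxLen] <- "too_long"
  reason[isPolyA] <- "polyA"
  reason[has5] <- "adaptor_5prime"
  reason[lowQ] <- "low_quality"
  reason[ilen == 0L] <- "no_insert"
  reason[pos3 <= 0L] <- "no_insert"

  tab <- table(factor(reason, levels = .CLEAN_REASONS))
  reasons[] <- as.integer(tab)
  keep <- reason == "retained"
  lib <- TagLibrary(insert[keep], rep(1L, sum(keep)), label)
  list(library = lib, report = new("CleaningReport", counts = reasons))
}

#' Read a collapsed-tag FASTA
#'
#' Parses the collapsed-tag dialect with headers \code{>tagN_xCOUNT}.
#'
#' @param path FASTA file in the collapsed dialect
#' @param label library label
#' @return a \code{TagLibrary}
#' @export
readTagFasta <- function(path, label = "lib") {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(x) == 0L) return(TagLibrary(character(), integer(), label))
  m <- regmatches(names(x), regexec("^(\\S+)_x(\\d+)$", names(x)))
  bad <- which(lengths(m) != 3L)
  if (length(bad))
    stop("not a collapsed-tag header at record ", bad[1L], ": '",
         names(x)[bad[1L]], "'", call. = FALSE)
  counts <- as.integer(vapply(m, `[`, character(1), 3L))
  TagLibrary(as.character(x), counts, label)
}

#' Write a TagLibrary as collapsed-tag FASTA
#'
#' Emits headers \code{>tag<i>_x<count>} in the library's stored order
#' (count-descending, then lexicographic), so identical libraries produce
#' byte-identical files.
#'
#' @param lib a \code{TagLibrary}
#' @param path output path
#' @return the path, invisibly
#' @export
writeTagFasta <- function(lib, path) {
  seqs <- Biostrings::RNAStringSet(tagSequences(lib))
  names(seqs) <- sprintf("tag%d_x%d", seq_along(seqs), unname(tagCounts(lib)))
  Biostrings::writeXStringSet(seqs, path, format = "fasta", width = 200L)
  invisible(path)
}

#' Read a labelled reference FASTA
#'
#' Expects description lines of the form
#' \code{>id class=rRNA family=miR156 species=ath} (family/species
#' optional). Missing class defaults to "transcript".
#'
#' @param path FASTA file
#' @return a \code{ReferenceSet}
#' @export
readReferenceFasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  field <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "=(\\S+)"), hdr))
    vapply(m, function(g) if (length(g) == 2L) g[2L] else NA_character_,
           character(1))
  }
  cls <- field("class"); cls[is.na(cls)] <- "transcript"
  seqs <- stats::setNames(rnaNormalize(as.character(x)), id)
  ReferenceSet(seqs, class = cls, family = field("family"),
               species = field("species"))
}

#' Write a ReferenceSet as labelled FASTA
#'
#' @param ref a \code{ReferenceSet}
#' @param path output path
#' @return the path, invisibly
#' @export
writeReferenceFasta <- function(ref, path) {
  s <- refSequences(ref)
  mc <- S4Vectors::mcols(s)
  desc <- paste0(names(s), " class=", mc$class,
                 ifelse(is.na(mc$family), "", paste0(" family=", mc$family)),
                 ifelse(is.na(mc$species), "", paste0(" species=", mc$species)))
  out <- Biostrings::RNAStringSet(as.character(s))
  names(out) <- desc
  Biostrings::writeXStringSet(out, path, format = "fasta", width = 200L)
  invisible(path)
}

#' Tag length distribution
#'
#' One row per observed tag length, counting reads (count-weighted) or
#' unique tags. Read-weighted counts sum to \code{totalCleanReads}.
#'
#' @param lib a \code{TagLibrary}
#' @param by "reads" (count-weighted) or "unique"
#' @return data.frame(length, count) sorted by length
#' @export
lengthDistribution <- function(lib, by = c("reads", "unique")) {
  by <- match.arg(by)
  sq <- tagSequences(lib)
  if (!length(sq)) return(data.frame(length = integer(), count = integer()))
  len <- nchar(sq)
  w <- if (by == "reads") unname(tagCounts(lib)) else rep(1L, length(sq))
  agg <- rowsum(w, len)
  data.frame(length = as.integer(rownames(agg)), count = as.integer(agg[, 1L]))
}

#' First-nucleotide bias by tag length
#'
#' Count-weighted table of the 5'-terminal base per tag length; per-length
#' rows sum to that length's read count. Plant mature miRNAs are expected
#' to show a U excess.
#'
#' @param lib a \code{TagLibrary}
#' @return data.frame(length, base, count)
#' @export
firstNucleotideBias <- function(lib) {
  sq <- tagSequences(lib)
  if (!length(sq))
    return(data.frame(length = integer(), base = character(), count = integer()))
  key <- paste(nchar(sq), substr(sq, 1L, 1L))
  agg <- rowsum(as.integer(unname(tagCounts(lib))), key)
  parts <- strsplit(rownames(agg), " ", fixed = TRUE)
  out <- data.frame(length = as.integer(vapply(parts, `[`, character(1), 1L)),
                    base = vapply(parts, `[`, character(1), 2L),
                    count = as.integer(agg[, 1L]))
  out[order(out$length, out$base), , drop = FALSE]
}
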