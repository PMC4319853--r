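# Internal sequence helpers. All pipeline-internal sequence text is
# uppercase RNA; comparisons are case-insensitive at the boundaries only.

#' Normalize sequence text to uppercase RNA
#'
#' Uppercases and converts T to U. The internal alphabet of the whole
#' pipeline is RNA.
#'
#' @param x character vector of DNA/RNA sequences
#' @return character vector over A/C/G/U (other letters untouched)
#' @export
rnaNormalize <- function(x) {
  out <- chartr("Tt", "UU", toupper(as.character(x)))
  names(out) <- names(x)
  out
}

#' Reverse complement in RNA space
#'
#' @param x character vector of RNA sequences
#' @return reverse complements (character)
#' @export
rnaReverseComplement <- function(x) {
  x <- rnaNormalize(x)
  vapply(x, function(s) {
    if (!nzchar(s)) return(s)
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split into single characters (one vector per sequence)
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Ungapped end-anchored alignment of a tag against a reference miRNA.
# Tag position i faces mature position i + s; admissible shifts keep both
# terminal offsets (5': s, 3': tl + s - ml) within maxShift, and
# substitutions are counted over the overlap only. Returns the minimum
# mismatch count (Inf if no admissible shift) and the shift achieving it.
.alignTagToMature <- function(tag, mature, maxShift = 2L) {
  tl <- nchar(tag); ml <- nchar(mature)
  best <- Inf; bestShift <- NA_integer_
  if (abs(tl - ml) > 2L * maxShift) return(list(mm = best, shift = bestShift))
  tc <- .chars(tag); mc <- .chars(mature)
  for (s in -maxShift:maxShift) {
    endOff <- (tl + s) - ml
    if (abs(endOff) > maxShift) next
    lo <- max(1L, 1L - s); hi <- min(tl, ml - s) # tag coords of overlap
    if (hi < lo) next
    mm <- sum(tc[lo:hi] != mc[(lo + s):(hi + s)])
    if (mm < best) { best <- mm; bestShift <- s }
  }
  list(mm = best, shift = bestShift)
}

# Phred+33 mean quality of a quality string (optionally restricted to a
# prefix length).
.meanPhred <- function(qual, len = NULL) {
  if (is.null(len)) len <- nchar(qual)
  vapply(seq_along(qual), function(i) {
    n <- len[i]
    if (is.na(qual[i]) || n == 0L) return(NA_real_)
    mean(as.integer(charToRaw(substr(qual[i], 1L, n))) - 33L)
  }, numeric(1))
}

#' Dinucleotide-block shuffle of a sequence
#'
#' Permutes the non-overlapping dinucleotide blocks of a sequence (a
#' trailing odd nucleotide stays at the end). Preserves the dinucleotide
#' block composition while destroying long-range base-pairing structure;
#' used to build decoy transcripts for specificity tests.
#'
#' @param x character vector of sequences
#' @return shuffled sequences (character); uses the current RNG stream
#' @export
shuffleDinucleotides <- function(x) {
  vapply(rnaNormalize(x), function(s) {
    n <- nchar(s)
    if (n < 4L) return(s)
    nb <- n %/% 2L
    blocks <- substring(s, seq(1L, by = 2L, length.out = nb),
                        seq(2L, by = 2L, length.out = nb))
    tail <- if (n %% 2L) substr(s, n, n) else ""
    paste0(paste(blocks[sample.int(nb)], collapse = ""), tail)
  }, character(1), USE.NAMES = FALSE)
}

# deterministic TSV writers/readers (UTF-8, tab, header, no quoting)
.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "", fileEncoding = "UTF-8")
}

# random RNA sequence(s) from the current RNG stream
.randomRna <- function(n, len, prob = c(A = 0.3, C = 0.2, G = 0.2, U = 0.3)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))
}
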