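#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings RNAStringSet
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom Biostrings RNAStringSet DNAStringSet reverseComplement
#' @useDynLib pomiR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' TagLibrary: a collapsed small-RNA tag library
#'
#' A labelled library of unique small-RNA tag sequences with read counts,
#' the atomic unit of the pipeline. Tags are stored uppercase in RNA
#' alphabet (T normalized to U) and are unique; \code{totalCleanReads}
#' equals the sum of tag counts, i.e. the library's total clean reads that
#' the TPM normalization divides by.
#'
#' @slot label single character, e.g. "CK" (control) or "TR" (treated)
#' @slot tags \code{DataFrame} with columns \code{sequence} (character) and
#'   \code{count} (integer >= 1)
#' @slot totalCleanReads single integer, sum of counts
#' @export
setClass("TagLibrary",
  representation(label = "character", tags = "DataFrame",
                 totalCleanReads = "integer"))

setValidity("TagLibrary", function(object) {
  msg <- character()
  if (length(object@label) != 1L) msg <- c(msg, "label must be length 1")
  tg <- object@tags
  if (!all(c("sequence", "count") %in% colnames(tg)))
    msg <- c(msg, "tags must have columns 'sequence' and 'count'")
  else {
    if (anyDuplicated(tg$sequence)) msg <- c(msg, "tag sequences must be unique")
    if (nrow(tg) && any(tg$count < 1L)) msg <- c(msg, "tag counts must be >= 1")
    if (nrow(tg) && any(grepl("[^ACGU]", tg$sequence)))
      msg <- c(msg, "tags must be uppercase RNA (A/C/G/U)")
    if (object@totalCleanReads != sum(tg$count))
      msg <- c(msg, "totalCleanReads must equal sum(tag counts)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TagLibrary
#'
#' @param sequences character vector of tag sequences (DNA or RNA case
#'   insensitive; normalized to uppercase RNA). Duplicates are collapsed by
#'   summing counts.
#' @param counts integer vector of read counts, recycled against sequences
#' @param label library label, e.g. "CK"
#' @return a \code{TagLibrary}
#' @examples
#' TagLibrary(c("UAGCUUAUCAGACUGAUGUUG", "uagcuuaucagacugauguug"), c(3, 2), "CK")
#' @export
TagLibrary <- function(sequences = character(), counts = integer(),
                       label = "lib") {
  sequences <- rnaNormalize(sequences)
  counts <- rep_len(as.integer(counts), length(sequences))
  if (length(sequences)) {
    agg <- rowsum(counts, sequences)
    sequences <- rownames(agg)
    counts <- as.integer(agg[, 1L])
    o <- order(-counts, sequences)
    sequences <- sequences[o]
    counts <- counts[o]
  }
  new("TagLibrary", label = as.character(label),
      tags = S4Vectors::DataFrame(sequence = sequences, count = counts),
      totalCleanReads = as.integer(sum(counts)))
}

#' CleaningReport: per-reason read-removal accounting
#'
#' Counts of raw reads removed by each cleaning rule plus the retained
#' count; the counts always sum to the number of input reads.
#'
#' @slot counts named integer vector over reasons
#'   (adaptor_5prime, no_insert, polyA, too_short, too_long, low_quality,
#'   retained)
#' @export
setClass("CleaningReport", representation(counts = "integer"))

.CLEAN_REASONS <- c("adaptor_5prime", "no_insert", "polyA", "too_short",
                    "too_long", "low_quality", "retained")

setValidity("CleaningReport", function(object) {
  if (!identical(names(object@counts), .CLEAN_REASONS))
    return("counts must be named by the fixed reason set")
  if (any(object@counts < 0L)) return("counts must be nonnegative")
  TRUE
})

#' ReferenceSet: labelled reference sequences
#'
#' Reference sequences (transcripts, ncRNAs or a miRBase-style miRNA
#' catalog) held as an \code{RNAStringSet} with per-record metadata columns
#' \code{class} (one of transcript, rRNA, tRNA, snRNA, snoRNA,
#' miRNA_mature, miRNA_precursor), \code{family} and \code{species}.
#'
#' @slot seqs named \code{RNAStringSet}; mcols carry class/family/species
#' @export
setClass("ReferenceSet", representation(seqs = "RNAStringSet"))

.REF_CLASSES <- c("transcript", "rRNA", "tRNA", "snRNA", "snoRNA",
                  "miRNA_mature", "miRNA_precursor")

setValidity("ReferenceSet", function(object) {
  s <- object@seqs
  msg <- character()
  if (length(s)) {
    if (is.null(names(s)) || anyDuplicated(names(s)))
      msg <- c(msg, "reference ids must be present and unique")
    if (any(Biostrings::width(s) == 0L))
      msg <- c(msg, "reference sequences must be non-empty")
    mc <- S4Vectors::mcols(s)
    if (is.null(mc) || !all(c("class", "family", "species") %in% colnames(mc)))
      msg <- c(msg, "mcols must have class, family, species")
    else if (!all(mc$class %in% .REF_CLASSES))
      msg <- c(msg, "unknown reference class label")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceSet
#'
#' @param sequences named character vector or \code{RNAStringSet}
#' @param class per-record class label (recycled)
#' @param family per-record family label (miRNA records), NA otherwise
#' @param species per-record species tag, NA otherwise
#' @return a \code{ReferenceSet}
#' @export
ReferenceSet <- function(sequences, class = "transcript", family = NA_character_,
                         species = NA_character_) {
  if (is.character(sequences)) {
    ids <- names(sequences)
    sequences <- Biostrings::RNAStringSet(rnaNormalize(sequences))
    names(sequences) <- ids
  }
  n <- length(sequences)
  S4Vectors::mcols(sequences) <- S4Vectors::DataFrame(
    class = rep_len(as.character(class), n),
    family = rep_len(as.character(family), n),
    species = rep_len(as.character(species), n))
  new("ReferenceSet", seqs = sequences)
}

#' FoldResult: an RNA secondary structure with its energy
#'
#' Minimum-free-energy structure of a single sequence in dot-bracket
#' notation, the energy in engine units (~ kcal/mol), and the 1-based pair
#' table (NA for unpaired positions).
#'
#' @slot sequence RNA character
#' @slot structure dot-bracket character, same length as sequence
#' @slot energy single numeric <= 0 (0 when no pairs form)
#' @slot pairTable integer vector of 1-based partners, NA when unpaired
#' @export
setClass("FoldResult",
  representation(sequence = "character", structure = "character",
                 energy = "numeric", pairTable = "integer"))

setValidity("FoldResult", function(object) {
  msg <- character()
  if (nchar(object@structure) != nchar(object@sequence))
    msg <- c(msg, "structure and sequence lengths differ")
  if (length(object@pairTable) != nchar(object@sequence))
    msg <- c(msg, "pair table length mismatch")
  op <- lengths(regmatches(object@structure, gregexpr("(", object@structure, fixed = TRUE)))
  cl <- lengths(regmatches(object@structure, gregexpr(")", object@structure, fixed = TRUE)))
  if (op != cl) msg <- c(msg, "unbalanced dot-bracket structure")
  if (object@energy > 1e-9) msg <- c(msg, "energy must be <= 0")
  if (length(msg)) msg else TRUE
})
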