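#' @describeIn TagLibrary-class tag sequences (uppercase RNA)
#' @export
setMethod("tagSequences", "TagLibrary", function(x) x@tags$sequence)

#' @describeIn TagLibrary-class read counts, named by tag sequence
#' @export
setMethod("tagCounts", "TagLibrary", function(x) {
  stats::setNames(x@tags$count, x@tags$sequence)
})

#' @describeIn TagLibrary-class total clean reads (sum of tag counts)
#' @export
setMethod("totalCleanReads", "TagLibrary", function(x) x@totalCleanReads)

#' @describeIn TagLibrary-class library label
#' @export
setMethod("libraryLabel", "TagLibrary", function(x) x@label)

setMethod("show", "TagLibrary", function(object) {
  cat("TagLibrary '", object@label, "': ", nrow(object@tags),
      " unique tags, ", object@totalCleanReads, " clean reads\n", sep = "")
  if (nrow(object@tags)) {
    head_n <- min(3L, nrow(object@tags))
    for (i in seq_len(head_n))
      cat("  ", object@tags$sequence[i], " x", object@tags$count[i], "\n", sep = "")
    if (nrow(object@tags) > head_n) cat("  ...\n")
  }
  invisible(NULL)
})

#' @describeIn CleaningReport-class named per-reason counts
#' @export
setMethod("cleaningCounts", "CleaningReport", function(x) x@counts)

setMethod("show", "CleaningReport", function(object) {
  cat("CleaningReport (", sum(object@counts), " reads in):\n", sep = "")
  for (r in names(object@counts))
    cat(sprintf("  %-15s %d\n", r, object@counts[[r]]))
  invisible(NULL)
})

#' @describeIn ReferenceSet-class the underlying named RNAStringSet
#' @export
setMethod("refSequences", "ReferenceSet", function(x) x@seqs)

#' @describeIn ReferenceSet-class per-record class labels, named by id
#' @export
setMethod("refClass", "ReferenceSet", function(x) {
  stats::setNames(S4Vectors::mcols(x@seqs)$class, names(x@seqs))
})

#' @describeIn ReferenceSet-class per-record family labels, named by id
#' @export
setMethod("refFamily", "ReferenceSet", function(x) {
  stats::setNames(S4Vectors::mcols(x@seqs)$family, names(x@seqs))
})

setMethod("length", "ReferenceSet", function(x) length(x@seqs))

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet:", length(object@seqs), "records\n")
  if (length(object@seqs))
    print(table(S4Vectors::mcols(object@seqs)$class))
  invisible(NULL)
})

#' Subset a ReferenceSet by class label
#'
#' @param x a \code{ReferenceSet}
#' @param classes character vector of class labels to keep
#' @return a \code{ReferenceSet} with matching records
#' @export
refSubset <- function(x, classes) {
  keep <- S4Vectors::mcols(x@seqs)$class %in% classes
  new("ReferenceSet", seqs = x@seqs[keep])
}

#' @describeIn FoldResult-class minimum free energy (engine units)
#' @export
setMethod("foldEnergy", "FoldResult", function(x) x@energy)

#' @describeIn FoldResult-class dot-bracket structure string
#' @export
setMethod("foldStructure", "FoldResult", function(x) x@structure)

#' @describeIn FoldResult-class integer partners (1-based, NA unpaired)
#' @export
setMethod("pairTable", "FoldResult", function(x) x@pairTable)

setMethod("show", "FoldResult", function(object) {
  cat("FoldResult (", nchar(object@sequence), " nt, ",
      sprintf("%.2f", object@energy), " kcal/mol)\n", sep = "")
  cat(" ", object@sequence, "\n ", object@structure, "\n", sep = "")
  invisible(NULL)
})
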