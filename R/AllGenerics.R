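#' @rdname TagLibrary-class
#' @param x a \code{TagLibrary}
#' @export
setGeneric("tagSequences", function(x) standardGeneric("tagSequences"))

#' @rdname TagLibrary-class
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))

#' @rdname TagLibrary-class
#' @export
setGeneric("totalCleanReads", function(x) standardGeneric("totalCleanReads"))

#' @rdname TagLibrary-class
#' @export
setGeneric("libraryLabel", function(x) standardGeneric("libraryLabel"))

#' @rdname CleaningReport-class
#' @param x a \code{CleaningReport}
#' @export
setGeneric("cleaningCounts", function(x) standardGeneric("cleaningCounts"))

#' @rdname ReferenceSet-class
#' @param x a \code{ReferenceSet}
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))

#' @rdname ReferenceSet-class
#' @export
setGeneric("refClass", function(x) standardGeneric("refClass"))

#' @rdname ReferenceSet-class
#' @export
setGeneric("refFamily", function(x) standardGeneric("refFamily"))

#' @rdname FoldResult-class
#' @param x a \code{FoldResult}
#' @export
setGeneric("foldEnergy", function(x) standardGeneric("foldEnergy"))

#' @rdname FoldResult-class
#' @export
setGeneric("foldStructure", function(x) standardGeneric("foldStructure"))

#' @rdname FoldResult-class
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))
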