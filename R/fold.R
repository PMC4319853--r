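# RNA folding and duplex hybridization energy. The embedded engine is a
# compact nearest-neighbor model (see src/fold_engine.cpp); energies are
# "engine units ~ kcal/mol". Absolute thresholds (e.g. the -18 kcal/mol
# precursor cut-off) are configurable because absolute energies are model
# dependent.

#' Embedded folding parameter table
#'
#' The versioned nearest-neighbor parameter set: the 6x6 stack table over
#' pair types AU/UA/GC/CG/GU/UG, loop penalty constants (logarithmic size
#' dependence), the interior-loop size cap, multiloop constants, and the
#' duplex initiation term. The brute-force enumeration oracle in the test
#' suite scores structures with this same table.
#'
#' @return named list of parameters
#' @export
foldParameters <- function() .engineParams()

#' Fold a single RNA into its minimum-free-energy structure
#'
#' Deterministic minimum-free-energy folding under the embedded
#' nearest-neighbor model: canonical pairs only (AU/UA/GC/CG/GU/UG),
#' hairpin loops >= 3 nt, no pseudoknots, no dangles, lonely pairs
#' allowed. The backend is interchangeable: any function taking a
#' sequence and returning \code{list(structure=, energy=)} honours the
#' same contract.
#'
#' @param seq RNA sequence (character, length >= 10; T accepted and
#'   normalized to U)
#' @param backend "embedded" (default) or a function(seq) -> list
#' @return a \code{FoldResult}
#' @examples
#' foldHairpin("GGGGGAAAAACCCCC")
#' @export
foldHairpin <- function(seq, backend = "embedded") {
  seq <- rnaNormalize(seq)
  if (nchar(seq) < 10L) stop("fold_hairpin requires length >= 10")
  if (grepl("[^ACGU]", seq)) stop("non-RNA characters in sequence")
  if (is.function(backend)) {
    res <- backend(seq)
    structure <- res$structure
    energy <- res$energy
    pt <- .dotBracketToPairs(structure)
  } else {
    res <- .foldEngine(seq)
    structure <- res$structure
    energy <- res$energy
    pt <- res$pairs
  }
  new("FoldResult", sequence = seq, structure = structure,
      energy = as.numeric(energy), pairTable = as.integer(pt))
}

# dot-bracket -> 1-based partner table (NA unpaired)
.dotBracketToPairs <- function(db) {
  ch <- .chars(db)
  pt <- rep(NA_integer_, length(ch))
  stack <- integer()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  pt
}

# pair type index 1..6 for (AU,UA,GC,CG,GU,UG), NA if not canonical
.pairIndex <- function(a, b) {
  key <- paste0(a, b)
  match(key, c("AU", "UA", "GC", "CG", "GU", "UG"))
}

#' Hybridization energy of an ungapped duplex
#'
#' Two strands aligned position-by-position and antiparallel: position i
#' of \code{strandA} faces position L-i+1 of \code{strandB} (both written
#' 5' to 3'). The energy is the duplex initiation constant plus stacking
#' terms summed over runs of consecutive paired positions; unpaired
#' positions break stacks and contribute nothing. Every position flagged
#' paired must form a canonical or wobble pair.
#'
#' @param strandA,strandB RNA sequences of equal length
#' @param paired logical mask over positions of \code{strandA}; default
#'   pairs every position that can form a canonical/GU pair
#' @return list(energy = numeric, paired = logical mask used)
#' @export
duplexEnergy <- function(strandA, strandB, paired = NULL) {
  strandA <- rnaNormalize(strandA); strandB <- rnaNormalize(strandB)
  L <- nchar(strandA)
  if (nchar(strandB) != L) stop("duplex strands must have equal length")
  if (L == 0L) return(list(energy = 0, paired = logical()))
  a <- .chars(strandA)
  b <- rev(.chars(strandB)) # b[i] now faces a[i]
  pidx <- .pairIndex(a, b)
  if (is.null(paired)) paired <- !is.na(pidx)
  if (any(paired & is.na(pidx)))
    stop("pairing mask marks a non-pairable position as paired")
  par <- foldParameters()
  e <- par$duplex_init
  if (L > 1L) {
    both <- paired[-L] & paired[-1L]
    if (any(both))
      e <- e + sum(par$stack[cbind(pidx[-L][both], pidx[-1L][both])])
  }
  list(energy = e, paired = paired)
}

#' Energy of a miRNA bound to its perfect complement
#'
#' Definitionally \code{duplexEnergy(mirna, reverse-complement(mirna))}
#' with every position paired; the denominator of the target-prediction
#' energy-ratio rule.
#'
#' @param mirna RNA sequence (18-26 nt typical)
#' @return numeric energy
#' @export
perfectComplementEnergy <- function(mirna) {
  mirna <- rnaNormalize(mirna)
  duplexEnergy(mirna, rnaReverseComplement(mirna),
               paired = rep(TRUE, nchar(mirna)))$energy
}
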