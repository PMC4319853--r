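# Audic-Claverie differential expression of tag counts between two
# libraries (one library per condition; the test conditions on the count
# x observed in library 1 and asks how surprising the count y in library
# 2 is, given the library size ratio):
#
#   p(y|x) = (N2/N1)^y * (x+y)! / (x! y! (1 + N2/N1)^(x+y+1))
#   C(y'<=y | x), D(y'>=y | x); two-sided p = min(1, 2 min(C, D)).
#
# All probabilities are computed in log space via lgamma.

#' Transcripts-per-million normalization
#'
#' count / total clean reads x 10^6.
#'
#' @param count nonnegative count(s)
#' @param total total clean reads of the library (> 0)
#' @return numeric TPM
#' @export
tpm <- function(count, total) {
  if (any(total <= 0)) stop("total clean reads must be > 0")
  count / total * 1e6
}

#' Log2 fold-change of normalized expression
#'
#' log2((tpmTr + pseudo) / (tpmCk + pseudo)); treatment over control, so
#' positive values mean up-regulation under treatment. The pseudo-TPM
#' keeps library-exclusive miRNAs finite.
#'
#' @param tpmTr,tpmCk normalized expression in the treated/control library
#' @param pseudo pseudo-TPM added to both arms (default 0.01)
#' @return numeric log2 fold-change
#' @export
log2FoldChange <- function(tpmTr, tpmCk, pseudo = 0.01) {
  log2((tpmTr + pseudo) / (tpmCk + pseudo))
}

# log p(y|x) for scalar x, vector y (log space, lgamma)
.acLogP <- function(x, y, logr, log1pr) {
  y * logr + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1pr
}

#' Audic-Claverie p-values for count pairs
#'
#' For each pair (x in library 1 of size N1, y in library 2 of size N2)
#' returns the point probability p(y|x), the lower and upper cumulative
#' tails C(y'<=y|x) and D(y'>=y|x) (the infinite upper tail is evaluated
#' as the complement of the finite lower sum, so no truncation bias), and
#' the doubled-tail two-sided p capped at 1. C + D - p_point == 1 up to
#' floating point.
#'
#' @param x,y counts in library 1 and 2 (vectors, recycled)
#' @param N1,N2 total clean reads of the two libraries
#' @return data.frame(p_point, C, D, p_two_sided)
#' @export
acPvalue <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be nonnegative")
  if (N1 <= 0 || N2 <= 0) stop("library sizes must be positive")
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  logr <- log(N2) - log(N1)
  log1pr <- log1p(N2 / N1)
  pp <- exp(.acLogP(x, y, logr, log1pr))
  # lower tails: iterate y' = 0..max(y) over all pairs at once
  C <- numeric(n)
  maxY <- max(y)
  lp <- .acLogP(x, 0, logr, log1pr) # y' = 0
  active <- y >= 0
  C[active] <- C[active] + exp(lp[active])
  yp <- 0
  while (yp < maxY) {
    yp <- yp + 1
    # p(y|x) = p(y-1|x) * r (x+y) / (y (1+r)), in log space
    lp <- lp + logr + log(x + yp) - log(yp) - log1pr
    active <- y >= yp
    if (!any(active)) break
    C[active] <- C[active] + exp(lp[active])
  }
  C <- pmin(C, 1)
  D <- 1 - C + pp
  # the complement form bottoms out near double-precision cancellation
  # (~1e-12); far upper tails are summed directly in log space instead
  redo <- which(D < 1e-8)
  for (i in redo) {
    cur <- .acLogP(x[i], y[i], logr, log1pr)
    top <- cur
    acc <- 1
    yp <- y[i]
    while (yp - y[i] < 1e5) {
      yp <- yp + 1
      cur <- cur + logr + log(x[i] + yp) - log(yp) - log1pr
      if (cur < top - 40) break
      acc <- acc + exp(cur - top)
    }
    D[i] <- exp(top) * acc
  }
  data.frame(p_point = pp, C = C, D = D,
             p_two_sided = pmin(1, 2 * pmin(C, D)))
}

#' Audic-Claverie confidence interval for y given x
#'
#' The interval [y_min, y_max] at level epsilon: the smallest y with
#' lower-tail mass >= epsilon and the smallest y with mass >= 1 - epsilon
#' under p(.|x). A descriptive utility; the significance path uses the
#' two-sided p-value.
#'
#' @param x count in library 1
#' @param N1,N2 library sizes
#' @param eps tail level (default 0.025 per side)
#' @return c(y_min, y_max)
#' @export
acInterval <- function(x, N1, N2, eps = 0.025) {
  logr <- log(N2) - log(N1)
  log1pr <- log1p(N2 / N1)
  lp <- .acLogP(x, 0, logr, log1pr)
  cum <- exp(lp)
  yMin <- NA_integer_; yMax <- NA_integer_
  yp <- 0
  repeat {
    if (is.na(yMin) && cum >= eps) yMin <- yp
    if (cum >= 1 - eps) { yMax <- yp; break }
    yp <- yp + 1
    lp <- lp + logr + log(x + yp) - log(yp) - log1pr
    cum <- cum + exp(lp)
    if (yp > 1e7) break
  }
  c(y_min = yMin, y_max = yMax)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of raw p-values (the significance threshold of
#' the pipeline applies to these adjusted values).
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted p-values, same order as input
#' @export
adjustPvalues <- function(p) stats::p.adjust(p, method = "BH")

#' Call differential expression
#'
#' significant iff adjusted p < \code{pThresh} and |log2 fold-change| >
#' \code{lfcThresh} (both strict); direction from the sign of the
#' fold-change.
#'
#' @param results data.frame with columns p_adjusted and log2fc
#' @param pThresh adjusted-p threshold (default 0.01)
#' @param lfcThresh |log2 fold-change| threshold (default 1)
#' @return the input with columns significant and direction appended
#' @export
callDE <- function(results, pThresh = 0.01, lfcThresh = 1) {
  results$significant <- results$p_adjusted < pThresh &
    abs(results$log2fc) > lfcThresh
  results$direction <- ifelse(results$log2fc > 0, "up",
                              ifelse(results$log2fc < 0, "down", "unchanged"))
  results
}

#' Differential expression of miRNA counts between two libraries
#'
#' The full path: TPM normalization, log2 fold-change with pseudo-TPM,
#' Audic-Claverie p-values, BH adjustment, significance calls.
#'
#' @param counts data.frame(id, x, y): counts in library 1 (CK) and 2 (TR)
#' @param N1,N2 total clean reads of the two libraries
#' @param pseudo pseudo-TPM (default 0.01)
#' @param pThresh,lfcThresh significance thresholds (default 0.01, 1)
#' @return data.frame(id, x, y, tpm_ck, tpm_tr, log2fc, p_point, C, D,
#'   p_two_sided, p_adjusted, significant, direction)
#' @export
diffExpression <- function(counts, N1, N2, pseudo = 0.01, pThresh = 0.01,
                           lfcThresh = 1) {
  stopifnot(all(c("id", "x", "y") %in% names(counts)))
  tpmCk <- tpm(counts$x, N1)
  tpmTr <- tpm(counts$y, N2)
  ac <- acPvalue(counts$x, counts$y, N1, N2)
  res <- data.frame(id = counts$id, x = counts$x, y = counts$y,
                    tpm_ck = tpmCk, tpm_tr = tpmTr,
                    log2fc = log2FoldChange(tpmTr, tpmCk, pseudo = pseudo),
                    stringsAsFactors = FALSE)
  res <- cbind(res, ac)
  res$p_adjusted <- adjustPvalues(res$p_two_sided)
  callDE(res, pThresh = pThresh, lfcThresh = lfcThresh)
}
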