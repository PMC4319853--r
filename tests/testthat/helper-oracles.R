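# Independent oracles used by the test suite. They share only the
# parameter table with the implementation, never its algorithms.

# ---- brute-force secondary-structure oracle -------------------------------
# Enumerates every valid pair set (canonical pairs, hairpin loops >= 3 nt)
# and scores each complete structure by loop decomposition.

oraclePairOk <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

oracleEnumStructures <- function(ch, i, j,
                                 memo = new.env(parent = emptyenv())) {
  if (j - i < 4) return(list(matrix(integer(), nrow = 2)))
  key <- paste(i, j)
  if (!is.null(memo[[key]])) return(memo[[key]])
  out <- list()
  for (s in oracleEnumStructures(ch, i + 1, j, memo)) out[[length(out) + 1]] <- s
  for (k in (i + 4):j) {
    if (!oraclePairOk(ch[i], ch[k])) next
    inner <- oracleEnumStructures(ch, i + 1, k - 1, memo)
    outer <- oracleEnumStructures(ch, k + 1, j, memo)
    for (s1 in inner) for (s2 in outer)
      out[[length(out) + 1]] <- cbind(c(i, k), s1, s2)
  }
  memo[[key]] <- out
  out
}

oracleScoreStructure <- function(ch, pairs, par = foldParameters()) {
  if (ncol(pairs) == 0) return(0)
  pidx <- function(i, j)
    match(paste0(ch[i], ch[j]), c("AU", "UA", "GC", "CG", "GU", "UG"))
  np <- ncol(pairs)
  parent <- rep(0L, np)
  for (a in seq_len(np)) {
    bw <- Inf
    for (b in seq_len(np)) {
      if (b == a) next
      if (pairs[1, b] < pairs[1, a] && pairs[2, a] < pairs[2, b]) {
        w <- pairs[2, b] - pairs[1, b]
        if (w < bw) { bw <- w; parent[a] <- b }
      }
    }
  }
  e <- 0
  for (a in seq_len(np)) {
    i <- pairs[1, a]; j <- pairs[2, a]
    kids <- which(parent == a)
    if (length(kids) == 0) {
      e <- e + par$hairpin_base + par$loop_slope * log((j - i - 1) / 3)
    } else if (length(kids) == 1) {
      k <- pairs[1, kids]; l <- pairs[2, kids]
      n1 <- k - i - 1; n2 <- j - l - 1
      if (n1 + n2 > par$max_interior) return(Inf)
      e <- e + if (n1 == 0 && n2 == 0) par$stack[pidx(i, j), pidx(k, l)]
        else if (n1 == 0 || n2 == 0)
          par$bulge_base + par$loop_slope * log(n1 + n2)
        else par$internal_base + par$loop_slope * log((n1 + n2) / 2)
    } else {
      e <- e + par$multi_a + par$multi_b * (length(kids) + 1)
    }
  }
  e
}

oracleBruteForceMfe <- function(seq) {
  ch <- strsplit(rnaNormalize(seq), "")[[1]]
  structs <- oracleEnumStructures(ch, 1L, length(ch))
  min(c(0, vapply(structs, function(s) oracleScoreStructure(ch, s),
                  numeric(1))))
}

# ---- Audic-Claverie recurrence oracle -------------------------------------
# Direct evaluation of the printed formula by multiplicative recurrence in
# linear space (no log-gamma): p(0|x) = (1+r)^-(x+1),
# p(y|x) = p(y-1|x) * r (x+y) / (y (1+r)).

oracleAcDist <- function(x, maxY, N1, N2) {
  r <- N2 / N1
  p <- numeric(maxY + 1)
  p[1] <- (1 + r)^(-(x + 1))
  for (y in seq_len(maxY)) p[y + 1] <- p[y] * r * (x + y) / (y * (1 + r))
  p
}
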