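## Shared fixtures and independent oracles used across test files.

## Width-1 scored sites on one chromosome/strand.
makeSites <- function(pos, score, gene_id = "geneA", chrom = "chrS",
                      strand = "+") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                         strand = strand, score = as.integer(score),
                         gene_id = gene_id)
}

## A small simulated study, computed once per test run.
tinyStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateClipStudy(clipSimConfig(nGenes = 80, nLigands = 15,
                                                seed = 101))
    cache
  }
})

## Independent chi-square oracle: sum (O - E)^2 / E on a 2x2 table.
oracleChi2 <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  list(expected = E, statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

## Independent BH step-up oracle.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

## Exact two-sided Wilcoxon rank-sum p by full enumeration (no ties).
oracleWilcoxExact <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2   # Mann-Whitney U of x
  combos <- utils::combn(n + m, n)
  allRanks <- seq_len(n + m)
  wAll <- apply(combos, 2, function(ix) sum(allRanks[ix])) -
    n * (n + 1) / 2
  pLe <- mean(wAll <= wObs)
  pGe <- mean(wAll >= wObs)
  min(1, 2 * min(pLe, pGe))
}

## Overlapping-motif oracle via regex lookahead.
oracleUguCount <- function(s) {
  s <- toupper(chartr("U", "T", s))
  length(gregexpr("(?=TGT)", s, perl = TRUE)[[1L]] |>
           (\(v) v[v > 0])())
}
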