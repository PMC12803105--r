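#' Set algebra on two ligand lists
#'
#' @param clip1,clip2 character vectors of gene ids from the two
#'   experiments.
#' @return list of class \code{ligandSets}: clip1, clip2, intersection,
#'   union, an integer counts vector (clip1, clip2, intersection, union,
#'   clip1_only, clip2_only) and \code{containment2} = |intersection| /
#'   |clip2|, the fraction of the high-stringency set contained in the
#'   other.
#' @examples
#' s <- buildSets(c("a", "b", "c"), c("b", "c", "d"))
#' s$counts
#' @export
buildSets <- function(clip1, clip2) {
  clip1 <- unique(clip1); clip2 <- unique(clip2)
  int <- sort(intersect(clip1, clip2))
  uni <- sort(union(clip1, clip2))
  structure(list(
    clip1 = sort(clip1), clip2 = sort(clip2),
    intersection = int, union = uni,
    counts = c(clip1 = length(clip1), clip2 = length(clip2),
               intersection = length(int), union = length(uni),
               clip1_only = length(setdiff(clip1, clip2)),
               clip2_only = length(setdiff(clip2, clip1))),
    containment2 = if (length(clip2)) length(int) / length(clip2)
    else NA_real_),
    class = "ligandSets")
}

#' @export
print.ligandSets <- function(x, ...) {
  cat("Ligand sets:",
      sprintf("|clip1| = %d, |clip2| = %d, shared = %d, union = %d\n",
              x$counts["clip1"], x$counts["clip2"],
              x$counts["intersection"], x$counts["union"]))
  invisible(x)
}

#' Rank genes by signed FDR
#'
#' Each gene gets the statistic sign(log2FC) * (-log10 FDR) and the table
#' is sorted descending, so the most significantly up-regulated genes (up
#' in the knockout) come first and the most significantly down-regulated
#' last. FDR values of exactly 0 are capped at half the smallest non-zero
#' FDR in the table before taking logs. Ties are broken by |log2FC|
#' descending, then gene id, so the order is total and reproducible.
#'
#' @param deTable data.frame with columns gene_id, log2FC and fdr.
#' @return data.frame (gene_id, log2FC, fdr, stat) in ranked order.
#' @export
rankGenes <- function(deTable) {
  need <- c("gene_id", "log2FC", "fdr")
  if (!all(need %in% names(deTable)))
    stop("deTable must have columns gene_id, log2FC, fdr")
  if (anyNA(deTable$fdr) || anyNA(deTable$log2FC))
    stop("missing FDR or log2FC")
  fdr <- deTable$fdr
  if (any(fdr == 0)) {
    nz <- min(fdr[fdr > 0])
    fdr[fdr == 0] <- nz / 2
  }
  stat <- sign(deTable$log2FC) * (-log10(fdr))
  o <- order(-stat, -abs(deTable$log2FC), deTable$gene_id)
  data.frame(gene_id = deTable$gene_id[o], log2FC = deTable$log2FC[o],
             fdr = deTable$fdr[o], stat = stat[o], row.names = NULL)
}

## Core running sum: +1/|S| at hits, -1/(N-|S|) at misses.
gseaRunning <- function(hits) {
  nh <- sum(hits); nm <- length(hits) - nh
  cumsum(ifelse(hits, 1 / nh, -1 / nm))
}

gseaEsFromHits <- function(hits) {
  run <- gseaRunning(hits)
  run[which.max(abs(run))]
}

#' GSEA-like enrichment score of a gene set in a ranked list
#'
#' The classic unweighted running sum: walking down the ranked list the sum
#' gains 1/|S| at every set member ("hit") and loses 1/(N - |S|) at every
#' non-member, where S is the set restricted to the ranked universe. The
#' enrichment score is the running value of maximal absolute deviation,
#' keeping its sign; the leading edge (for positive ES) is the set members
#' at or before the running-sum maximum (at or after the minimum for
#' negative ES). Set members absent from the ranked list are dropped with a
#' message.
#'
#' @param ranked a data.frame from [rankGenes()] or a character vector of
#'   ranked gene ids.
#' @param geneSet character vector of set member ids.
#' @return a [GseaResult-class] with \code{pPerm = NA} (see
#'   [gseaPermutationP()] / [runGsea()] for the permutation p-value).
#' @examples
#' gseaES(letters[1:10], c("a", "b", "j"))  # ES = 2/3
#' @export
gseaES <- function(ranked, geneSet) {
  ids <- if (is.data.frame(ranked)) ranked$gene_id else as.character(ranked)
  geneSet <- unique(geneSet)
  dropped <- sum(!geneSet %in% ids)
  if (dropped > 0L)
    message(dropped, " set member(s) absent from the ranked list dropped")
  hits <- ids %in% geneSet
  nh <- sum(hits)
  if (nh == 0L || nh == length(ids))
    stop("gene set must be a non-empty proper subset of the ranked list")
  run <- gseaRunning(hits)
  peak <- which.max(abs(run))
  es <- run[peak]
  le <- if (es >= 0) ids[seq_len(peak)][hits[seq_len(peak)]]
  else ids[peak:length(ids)][hits[peak:length(ids)]]
  new("GseaResult", es = es, pPerm = NA_real_, nPerm = 0L,
      alternative = NA_character_, leadingEdge = le,
      runningProfile = run, setSize = nh, nDropped = as.integer(dropped))
}

#' Permutation p-value for a GSEA-like enrichment score
#'
#' Draws \code{nPerm} random gene sets of the same size without replacement
#' from the ranked universe and compares their signed enrichment scores
#' with the observed one, with an add-one correction. The default
#' two-sided tail, p = (1 + #\{|ES_perm| >= |ES_obs|\}) / (nPerm + 1), is
#' exactly uniform under the null; \code{alternative = "greater"} /
#' \code{"less"} give the directional tails p = (1 + #\{ES_perm >=
#' ES_obs\}) / (nPerm + 1) and its mirror.
#'
#' @param ranked ranked gene ids (data.frame or character).
#' @param geneSet character vector of set members.
#' @param nPerm number of random sets (>= 1).
#' @param seed integer seed.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return numeric p-value in (0, 1].
#' @export
gseaPermutationP <- function(ranked, geneSet, nPerm = 1000L, seed = 1L,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  ids <- if (is.data.frame(ranked)) ranked$gene_id else as.character(ranked)
  geneSet <- intersect(unique(geneSet), ids)
  N <- length(ids)
  nh <- length(geneSet)
  if (nh == 0L || nh == N)
    stop("gene set must be a non-empty proper subset of the ranked list")
  hits <- ids %in% geneSet
  esObs <- gseaEsFromHits(hits)
  set.seed(seed)
  esPerm <- vapply(seq_len(nPerm), function(b) {
    h <- logical(N)
    h[sample.int(N, nh)] <- TRUE
    gseaEsFromHits(h)
  }, numeric(1))
  hitsCount <- switch(alternative,
    two.sided = sum(abs(esPerm) >= abs(esObs) - 1e-12),
    greater = sum(esPerm >= esObs - 1e-12),
    less = sum(esPerm <= esObs + 1e-12))
  (1 + hitsCount) / (nPerm + 1)
}

#' Run a complete GSEA-like analysis
#'
#' Convenience wrapper: [gseaES()] plus [gseaPermutationP()] into one
#' [GseaResult-class].
#'
#' @inheritParams gseaPermutationP
#' @return a [GseaResult-class].
#' @export
runGsea <- function(ranked, geneSet, nPerm = 1000L, seed = 1L,
                    alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  res <- gseaES(ranked, geneSet)
  p <- gseaPermutationP(ranked, geneSet, nPerm = nPerm, seed = seed,
                        alternative = alternative)
  new("GseaResult", es = res@es, pPerm = p, nPerm = as.integer(nPerm),
      alternative = alternative, leadingEdge = res@leadingEdge,
      runningProfile = res@runningProfile, setSize = res@setSize,
      nDropped = res@nDropped)
}

#' Overlap test between two gene sets over a universe
#'
#' Builds the 2x2 membership table of the universe against set A and set B
#' and applies a Pearson chi-square test (1 df). Expected counts under
#' independence (row x column / total) are reported the way the study
#' prints them in parentheses.
#'
#' @param setA,setB character vectors, both subsets of \code{universe}.
#' @param universe character vector of all genes considered.
#' @param correct apply Yates continuity correction.
#' @return list of class \code{clipContingency}: observed, expected,
#'   statistic, p.value.
#' @export
overlapTest <- function(setA, setB, universe, correct = FALSE) {
  universe <- unique(universe)
  setA <- unique(setA); setB <- unique(setB)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("sets must be contained in the universe")
  chiSquare2x2(table(
    factor(ifelse(universe %in% setA, "inA", "notA"),
           levels = c("inA", "notA")),
    factor(ifelse(universe %in% setB, "inB", "notB"),
           levels = c("inB", "notB"))), correct = correct)
}

#' Wilcoxon rank-sum test between two groups of values
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test. With small untied
#' samples the exact null distribution is used; otherwise the normal
#' approximation with tie correction (no continuity correction), which
#' returns p = 1 for identical samples.
#'
#' @param valuesInSet,valuesOutOfSet numeric vectors.
#' @param exact logical or NULL (auto: exact when both n < 50 and no ties).
#' @return numeric two-sided p-value.
#' @export
rankSumTest <- function(valuesInSet, valuesOutOfSet, exact = NULL) {
  ht <- suppressWarnings(
    wilcox.test(valuesInSet, valuesOutOfSet, exact = exact,
                correct = FALSE))
  ht$p.value
}
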