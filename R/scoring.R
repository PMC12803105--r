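#' Per-gene CLIP score
#'
#' The CLIP score of a gene is the sum of the scores of its binding
#' clusters located in the 3'UTR; clusters in other regions do not
#' contribute.
#'
#' @param clusters GRanges of clusters with \code{gene_id},
#'   \code{cluster_score} and \code{region} columns.
#' @return named numeric of CLIP scores, one entry per gene that has at
#'   least one 3'UTR cluster.
#' @export
clipScores <- function(clusters) {
  u <- clusters[clusters$region == "3UTR"]
  if (!length(u)) return(setNames(numeric(0), character(0)))
  vapply(split(u$cluster_score, u$gene_id), sum, numeric(1))
}

#' Build per-gene CLIP profiles
#'
#' Combines 3'UTR cluster scores, expression, 3'UTR cluster counts and the
#' per-gene maximum UGU count into one profile table. By default every
#' expressed gene gets a row (CLIP score 0 when it has no 3'UTR cluster);
#' \code{onlyWithClusters = TRUE} restricts the population to genes with at
#' least one 3'UTR cluster, the population shown in the study's
#' score-vs-expression plot.
#'
#' @param clusters GRanges of region-labelled clusters.
#' @param expression named numeric of per-gene expression (> 0), or a
#'   data.frame with columns gene_id and expression.
#' @param utr3 optional DNAStringSet of 3'UTR sequences (named by gene id)
#'   used to compute \code{max_ugu}; when missing, \code{max_ugu} is NA.
#' @param geneModels optional GRanges gene models used to locate clusters
#'   within the 3'UTR sequence.
#' @param onlyWithClusters restrict rows to genes with >= 1 3'UTR cluster.
#' @return data.frame: gene_id, clip_score, expression, n_3utr_clusters,
#'   max_ugu.
#' @export
buildGeneProfiles <- function(clusters, expression, utr3 = NULL,
                              geneModels = NULL,
                              onlyWithClusters = FALSE) {
  if (is.data.frame(expression))
    expression <- setNames(expression$expression, expression$gene_id)
  cs <- clipScores(clusters)
  u <- clusters[clusters$region == "3UTR"]
  nClust <- table(u$gene_id)
  ids <- if (onlyWithClusters) sort(names(cs)) else sort(names(expression))
  if (!all(ids %in% names(expression)))
    stop("expression missing for some profiled genes")
  maxUgu <- rep(NA_integer_, length(ids))
  if (!is.null(utr3) && !is.null(geneModels)) {
    mu <- maxUguPerGene(u, utr3, geneModels)
    maxUgu <- ifelse(ids %in% names(mu), mu[ids], 0L)
  }
  data.frame(
    gene_id = ids,
    clip_score = as.numeric(ifelse(ids %in% names(cs), cs[ids], 0)),
    expression = as.numeric(expression[ids]),
    n_3utr_clusters = as.integer(ifelse(ids %in% names(nClust),
                                        nClust[ids], 0L)),
    max_ugu = as.integer(maxUgu), row.names = NULL)
}

#' Retain ligand genes by the dual percentile rule
#'
#' Genes in the top \code{clipTopFrac} of CLIP scores are retained, except
#' those in the top \code{exprTopFrac} of expression (very abundant RNAs,
#' crystallins in the lens, attract non-specific signal). Both rank cuts
#' use k = ceiling(frac * N) on the full input populations computed
#' independently before the set difference (the study draws both
#' thresholds on the complete score-vs-expression plot);
#' \code{thresholdAfterExclusion = TRUE} instead recomputes the CLIP cut
#' after removing expression outliers. Ties are broken by gene id so the
#' call is deterministic.
#'
#' @param profiles data.frame from [buildGeneProfiles()] (columns gene_id,
#'   clip_score, expression; expression must be > 0).
#' @param clipTopFrac top fraction of CLIP scores retained.
#' @param exprTopFrac top fraction of expression excluded.
#' @param thresholdAfterExclusion recompute the CLIP threshold on the
#'   population that survives the expression exclusion.
#' @return data.frame: gene_id, retained, reason (one of retained,
#'   below_clip_threshold, expression_outlier).
#' @export
retainLigands <- function(profiles, clipTopFrac = 0.10,
                          exprTopFrac = 0.005,
                          thresholdAfterExclusion = FALSE) {
  if (!nrow(profiles)) stop("empty profile table")
  stopifnot(all(profiles$expression > 0))
  ids <- profiles$gene_id
  topBy <- function(values, tieIds, k) {
    o <- order(-values, tieIds)
    tieIds[o][seq_len(min(k, length(tieIds)))]
  }
  kExpr <- ceiling(exprTopFrac * nrow(profiles))
  exprTop <- topBy(profiles$expression, ids, kExpr)
  if (thresholdAfterExclusion) {
    keep <- !(ids %in% exprTop)
    kClip <- ceiling(clipTopFrac * sum(keep))
    clipTop <- topBy(profiles$clip_score[keep], ids[keep], kClip)
  } else {
    kClip <- ceiling(clipTopFrac * nrow(profiles))
    clipTop <- topBy(profiles$clip_score, ids, kClip)
  }
  retained <- ids %in% clipTop & !(ids %in% exprTop)
  reason <- ifelse(retained, "retained",
                   ifelse(ids %in% clipTop & ids %in% exprTop,
                          "expression_outlier", "below_clip_threshold"))
  data.frame(gene_id = ids, retained = retained, reason = reason)
}

#' Count overlapping UGU trinucleotides
#'
#' Counts occurrences of the UGU motif in a nucleotide sequence with a
#' sliding window, overlaps allowed ("UGUGUGU" contains three). T and U are
#' equivalent and case is ignored.
#'
#' @param sequence a character string, DNAString or RNAString.
#' @return integer count.
#' @examples
#' countUgu("UGUGUGU")  # 3
#' @export
countUgu <- function(sequence) {
  s <- toupper(chartr("U", "T", as.character(sequence)))
  if (grepl("[^ACGT]", s))
    stop("non-nucleotide characters in sequence")
  if (nchar(s) < 3L) return(0L)
  Biostrings::countPattern("TGT", Biostrings::DNAString(s))
}

#' Maximum per-gene UGU count over binding clusters
#'
#' For every gene, extracts the sequence under each of its 3'UTR clusters
#' (the part of the cluster interval that overlaps the annotated 3'UTR,
#' read in transcript orientation) and keeps the highest UGU count among
#' them.
#'
#' @param clusters GRanges of 3'UTR clusters with \code{gene_id}.
#' @param utr3 DNAStringSet of 3'UTR sequences named by gene id, stored in
#'   transcript (5' to 3') orientation.
#' @param geneModels GRanges gene models locating each 3'UTR.
#' @return named integer, one entry per gene with at least one
#'   sequence-resolvable cluster.
#' @export
maxUguPerGene <- function(clusters, utr3, geneModels) {
  if (!length(clusters)) return(setNames(integer(0), character(0)))
  sel <- geneModels$type == "three_prime_utr"
  utrStart <- setNames(start(geneModels)[sel], geneModels$gene_id[sel])
  utrEnd <- setNames(end(geneModels)[sel], geneModels$gene_id[sel])
  utrNeg <- setNames(as.character(strand(geneModels))[sel] == "-",
                     geneModels$gene_id[sel])
  counts <- integer(length(clusters))
  keep <- logical(length(clusters))
  cStart <- start(clusters); cEnd <- end(clusters)
  seqs <- as.character(utr3)
  for (i in seq_along(clusters)) {
    gid <- clusters$gene_id[i]
    if (!gid %in% names(utrStart) || !gid %in% names(seqs)) next
    lo <- max(cStart[i], utrStart[[gid]])
    hi <- min(cEnd[i], utrEnd[[gid]])
    if (lo > hi) next
    if (utrNeg[[gid]]) {
      from <- utrEnd[[gid]] - hi + 1L
      to <- utrEnd[[gid]] - lo + 1L
    } else {
      from <- lo - utrStart[[gid]] + 1L
      to <- hi - utrStart[[gid]] + 1L
    }
    counts[i] <- countUgu(substr(seqs[[gid]], from, to))
    keep[i] <- TRUE
  }
  if (!any(keep)) return(setNames(integer(0), character(0)))
  vapply(split(counts[keep], clusters$gene_id[keep]), max, integer(1))
}

#' UGU enrichment among retained ligands
#'
#' Tests whether retained genes are enriched for UGU-rich binding clusters:
#' a 2x2 contingency table of (retained vs not) against (max UGU count >=
#' threshold vs <= threshold - 1), compared by Pearson chi-square with 1
#' degree of freedom (no continuity correction by default).
#'
#' @param calls data.frame from [retainLigands()] (gene_id, retained).
#' @param profiles data.frame with gene_id and max_ugu.
#' @param threshold minimum UGU count defining a UGU-rich cluster.
#' @param correct apply Yates continuity correction.
#' @return list of class \code{clipContingency}: observed, expected,
#'   statistic, p.value.
#' @export
uguEnrichment <- function(calls, profiles, threshold = 3L,
                          correct = FALSE) {
  mu <- profiles$max_ugu[match(calls$gene_id, profiles$gene_id)]
  if (anyNA(mu)) stop("max_ugu missing for some genes")
  chiSquare2x2(table(
    factor(ifelse(calls$retained, "retained", "not_retained"),
           levels = c("retained", "not_retained")),
    factor(ifelse(mu >= threshold, "ugu_rich", "ugu_poor"),
           levels = c("ugu_rich", "ugu_poor"))), correct = correct)
}

## Shared 2x2 Pearson chi-square with margin checks; wraps stats::chisq.test.
chiSquare2x2 <- function(tab, correct = FALSE) {
  tab <- as.table(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate contingency table: zero margin")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  structure(list(observed = tab, expected = ct$expected,
                 statistic = unname(ct$statistic),
                 p.value = ct$p.value),
            class = "clipContingency")
}

#' @export
print.clipContingency <- function(x, ...) {
  cat("2x2 contingency (expected in parentheses):\n")
  obs <- x$observed; exp <- x$expected
  for (i in seq_len(nrow(obs))) {
    cat(" ", format(rownames(obs)[i], width = 14))
    for (j in seq_len(ncol(obs)))
      cat(sprintf(" %6d (%7.1f)", obs[i, j], exp[i, j]))
    cat("\n")
  }
  cat("  chi-square =", format(x$statistic, digits = 5),
      " p =", format(x$p.value, digits = 3), "\n")
  invisible(x)
}
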