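#' Derive scored cross-link sites from read alignments
#'
#' In iCLIP, reverse transcription usually truncates at the cross-linked
#' nucleotide, so each read marks a cross-link at its 5'-terminal aligned
#' position shifted by \code{offset} in the 5' direction of the read
#' strand. The default \code{offset = -1} is the truncation convention
#' (cross-link one nt upstream of the read 5' end); \code{offset = 0} takes
#' the read terminus itself. Reads are aggregated per (chromosome, strand,
#' position) into sites scored by read count.
#'
#' @param reads GRanges of read alignments (strand required).
#' @param offset integer shift applied along the read strand
#'   (\code{pos5 + offset * strandSign}).
#' @return GRanges of width-1 sites with \code{score} and, when the input
#'   carries a \code{gene_id} column, the gene id of the reads at that
#'   position (first contributor on the rare mixed position). The
#'   number of rejected (strandless) records is reported via a message and
#'   attached as \code{metadata(result)$rejected}.
#' @examples
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 129), "+")
#' deriveCrosslinkSites(c(r, r, r))  # one site at 99, score 3
#' @export
deriveCrosslinkSites <- function(reads, offset = -1L) {
  if (!length(reads))
    return(GRanges(score = integer(), gene_id = character()))
  str <- as.character(strand(reads))
  bad <- str == "*"
  if (any(bad)) {
    message(sum(bad), " strandless record(s) rejected")
    reads <- reads[!bad]
    str <- str[!bad]
  }
  if (!length(reads)) {
    out <- GRanges(score = integer(), gene_id = character())
    S4Vectors::metadata(out)$rejected <- sum(bad)
    return(out)
  }
  sign <- ifelse(str == "-", -1L, 1L)
  fiveP <- ifelse(str == "-", end(reads), start(reads))
  pos <- fiveP + as.integer(offset) * sign
  key <- paste(as.character(seqnames(reads)), str, pos)
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  o <- order(parts[, 1L], as.integer(parts[, 3L]), parts[, 2L])
  out <- GRanges(parts[o, 1L],
                 IRanges(as.integer(parts[o, 3L]), width = 1L),
                 strand = parts[o, 2L],
                 score = as.integer(tab)[o])
  if (!is.null(reads$gene_id)) {
    first <- !duplicated(key)
    out$gene_id <- reads$gene_id[first][match(names(tab)[o], key[first])]
  }
  S4Vectors::metadata(out)$rejected <- sum(bad)
  out
}

windowHeights <- function(counts, window) {
  ## counts: per-position event/score vector over the gene span;
  ## returns the +/- window running sum at every position
  L <- length(counts)
  cs <- cumsum(c(0, counts))
  hi <- pmin(L, seq_len(L) + window)
  lo <- pmax(0L, seq_len(L) - window - 1L)
  cs[hi + 1L] - cs[lo + 1L]
}

## Numeric core of the permutation FDR: positions are 1-based within the
## gene span of length L. Returns per-site window heights and monotonized
## FDRs without touching any S4 container, so the per-gene driver stays
## cheap at thousands of genes.
peakFdrCore <- function(pos, score, L, nPerm, window, seed) {
  counts <- numeric(L)
  counts[pos] <- score
  hObs <- windowHeights(counts, window)[pos]
  nEvents <- sum(score)
  hs <- sort(unique(hObs))                # increasing observed heights
  nObsGe <- vapply(hs, function(h) sum(hObs >= h), numeric(1))
  set.seed(seed)
  permPos <- matrix(sample.int(L, nEvents * nPerm, replace = TRUE),
                    nrow = nEvents)
  ratioSum <- numeric(length(hs))
  for (b in seq_len(nPerm)) {
    ev <- sort.int(permPos[, b], method = "radix")
    occ <- unique(ev)
    ## window height at each occupied position = events within +/- window
    hb <- sort.int(findInterval(occ + window, ev) -
                     findInterval(occ - window - 1L, ev),
                   method = "radix")
    ## random occupied positions with height >= h, for each observed h
    nRandGe <- length(hb) - findInterval(hs - 1e-9, hb)
    ratioSum <- ratioSum + nRandGe / nObsGe
  }
  fdrH <- pmin(1, pmax(0, ratioSum / nPerm))
  fdrH <- cummin(fdrH)                    # running minimum as h increases
  list(height = as.integer(hObs), fdr = fdrH[match(hObs, hs)])
}

#' Call significant cross-link peaks within one gene by permutation FDR
#'
#' For each observed site the window height is the sum of site scores
#' within +/- \code{window} nt. The gene's total events (site scores
#' treated as individual cross-link events) are redistributed uniformly
#' over the gene span \code{nPerm} times; for every observed height h,
#' FDR(h) is the mean over permutations of (number of random occupied
#' positions with height >= h) / (number of observed sites with height >=
#' h), clipped to [0, 1] and monotonized by a running minimum as h
#' increases (so a taller site never has a larger FDR). Sites with FDR <
#' \code{alpha} are returned as peaks.
#'
#' @param sites GRanges of width-1 scored sites, all belonging to one gene
#'   and strand.
#' @param geneSpan GRanges (or integer vector \code{c(start, end)}) of the
#'   gene's genomic span, the randomization domain.
#' @param nPerm number of background randomizations (>= 1).
#' @param window half-width in nt of the height window.
#' @param alpha FDR threshold for retaining peaks.
#' @param seed integer seed for the randomization stream.
#' @return The peak subset of \code{sites} with added columns
#'   \code{window_height} and \code{fdr}. The FDRs of *all* sites are
#'   attached as \code{metadata(result)$siteFdr} alongside
#'   \code{metadata(result)$siteHeight}.
#' @export
callPeaks <- function(sites, geneSpan, nPerm = 100L, window = 3L,
                      alpha = 0.05, seed = 1L) {
  if (nPerm < 1L) stop("nPerm must be >= 1")
  if (is(geneSpan, "GRanges")) {
    gs <- start(geneSpan)[1L]; ge <- end(geneSpan)[1L]
  } else {
    gs <- geneSpan[1L]; ge <- geneSpan[2L]
  }
  L <- ge - gs + 1L
  if (is.na(L) || L < 1L) stop("empty gene span")
  empty <- sites[0L]
  empty$window_height <- integer(); empty$fdr <- numeric()
  if (!length(sites)) return(empty)
  pos <- start(sites) - gs + 1L
  if (any(pos < 1L | pos > L)) stop("sites outside the gene span")
  core <- peakFdrCore(pos, sites$score, L, nPerm, window, seed)
  keep <- core$fdr < alpha
  out <- sites[keep]
  out$window_height <- core$height[keep]
  out$fdr <- core$fdr[keep]
  S4Vectors::metadata(out)$siteFdr <- core$fdr
  S4Vectors::metadata(out)$siteHeight <- core$height
  out
}

#' Call peaks for every gene of a site table
#'
#' Applies [callPeaks()] gene by gene with per-gene seeds derived
#' deterministically from the global seed and the gene id, so results do
#' not depend on gene order.
#'
#' @param sites GRanges of scored sites with a \code{gene_id} column.
#' @param geneModels GRanges gene models (rows with \code{type == "gene"}
#'   provide the spans).
#' @param nPerm,window,alpha,seed as in [callPeaks()].
#' @return GRanges of peaks across genes, with per-site FDR totals attached
#'   as \code{metadata(result)$nSites} (sites seen) and
#'   \code{metadata(result)$nCalled}.
#' @export
callPeaksByGene <- function(sites, geneModels, nPerm = 100L, window = 3L,
                            alpha = 0.05, seed = 1L) {
  genes <- geneModels[geneModels$type == "gene"]
  geneStart <- setNames(start(genes), genes$gene_id)
  geneEnd <- setNames(end(genes), genes$gene_id)
  ## work on plain vectors; assemble one GRanges at the end
  pos <- start(sites)
  score <- sites$score
  gid <- sites$gene_id
  chrom <- as.character(seqnames(sites))
  str <- as.character(strand(sites))
  idxByGene <- split(seq_along(pos), gid)
  idxByGene <- idxByGene[names(idxByGene) %in% genes$gene_id]
  keepAll <- vector("list", length(idxByGene))
  hAll <- vector("list", length(idxByGene))
  fdrAll <- vector("list", length(idxByGene))
  for (k in seq_along(idxByGene)) {
    g <- names(idxByGene)[k]
    ix <- idxByGene[[k]]
    gs <- geneStart[[g]]
    L <- geneEnd[[g]] - gs + 1L
    core <- peakFdrCore(pos[ix] - gs + 1L, score[ix], L, nPerm, window,
                        seed = stageSeed(seed, g))
    sel <- core$fdr < alpha
    keepAll[[k]] <- ix[sel]
    hAll[[k]] <- core$height[sel]
    fdrAll[[k]] <- core$fdr[sel]
  }
  ix <- unlist(keepAll, use.names = FALSE)
  o <- order(ix)
  ix <- ix[o]
  out <- GRanges(if (length(ix)) chrom[ix] else character(),
                 IRanges(pos[ix], width = 1L),
                 strand = str[ix],
                 score = score[ix], gene_id = gid[ix],
                 window_height = unlist(hAll, use.names = FALSE)[o],
                 fdr = unlist(fdrAll, use.names = FALSE)[o])
  S4Vectors::metadata(out)$nSites <- length(unlist(idxByGene,
                                                   use.names = FALSE))
  S4Vectors::metadata(out)$nCalled <- length(out)
  out
}

#' Merge peaks into scored binding clusters
#'
#' Peaks of one gene are merged transitively whenever consecutive positions
#' differ by less than \code{maxGap} nt (20 by default: peaks exactly 20 nt
#' apart start separate clusters). The cluster interval extends
#' \code{flank} nt beyond the outermost member peaks, and the cluster score
#' is the sum of member peak scores plus the scores of non-peak sites
#' falling inside the interval ("adjacent signal").
#'
#' @param peaks GRanges of peaks (one gene) as returned by [callPeaks()].
#' @param allSites GRanges of all scored sites of the same gene.
#' @param maxGap merge threshold in nt (strict inequality).
#' @param flank nt added on both sides of the member span.
#' @return GRanges of clusters with columns \code{gene_id},
#'   \code{cluster_score}, \code{n_peaks}, \code{member_positions}
#'   (CharacterList-like comma string).
#' @export
clusterPeaks <- function(peaks, allSites, maxGap = 20L, flank = 3L) {
  empty <- GRanges(gene_id = character(), cluster_score = integer(),
                   n_peaks = integer(), member_positions = character())
  if (!length(peaks)) return(empty)
  o <- order(start(peaks))
  pos <- start(peaks)[o]
  sc <- peaks$score[o]
  grp <- cumsum(c(1L, as.integer(diff(pos) >= maxGap)))
  sitePos <- start(allSites)
  siteSc <- allSites$score
  isPeakSite <- sitePos %in% pos
  res <- lapply(split(seq_along(pos), grp), function(ix) {
    lo <- pos[ix[1L]] - flank
    hi <- pos[ix[length(ix)]] + flank
    adj <- !isPeakSite & sitePos >= lo & sitePos <= hi
    data.frame(start = lo, end = hi,
               cluster_score = sum(sc[ix]) + sum(siteSc[adj]),
               n_peaks = length(ix),
               member_positions = paste(pos[ix], collapse = ","))
  })
  df <- do.call(rbind, res)
  GRanges(as.character(seqnames(peaks))[1L], IRanges(df$start, df$end),
          strand = as.character(strand(peaks))[1L],
          gene_id = peaks$gene_id[1L],
          cluster_score = as.integer(df$cluster_score),
          n_peaks = df$n_peaks, member_positions = df$member_positions)
}

#' Cluster peaks for every gene
#'
#' @param peaks GRanges of peaks across genes (with \code{gene_id}).
#' @param sites GRanges of all sites across genes.
#' @param maxGap,flank as in [clusterPeaks()].
#' @return GRanges of clusters across genes.
#' @export
clusterPeaksByGene <- function(peaks, sites, maxGap = 20L, flank = 3L) {
  if (!length(peaks))
    return(GRanges(gene_id = character(), cluster_score = integer(),
                   n_peaks = integer(), member_positions = character()))
  ids <- unique(peaks$gene_id)
  res <- lapply(ids, function(g)
    clusterPeaks(peaks[peaks$gene_id == g], sites[sites$gene_id == g],
                 maxGap = maxGap, flank = flank))
  do.call(c, res)
}

#' Assign each cluster to a gene region
#'
#' The region is that of the cluster midpoint; when the midpoint overlaps
#' several annotated features the precedence is 3'UTR > 5'UTR > CDS >
#' intron. A midpoint outside every annotated feature is labelled "other".
#'
#' @param clusters GRanges of clusters with \code{gene_id}.
#' @param geneModels GRanges gene models with \code{type} and
#'   \code{gene_id}.
#' @return \code{clusters} with an added \code{region} column taking values
#'   in 5UTR, CDS, 3UTR, intron, other.
#' @export
assignRegions <- function(clusters, geneModels) {
  if (!length(clusters)) {
    clusters$region <- character()
    return(clusters)
  }
  regOf <- c(three_prime_utr = "3UTR", five_prime_utr = "5UTR",
             CDS = "CDS", intron = "intron")
  precedence <- c("3UTR", "5UTR", "CDS", "intron")
  mid <- floor((start(clusters) + end(clusters)) / 2)
  region <- character(length(clusters))
  sel <- geneModels$type %in% names(regOf)
  feats <- data.frame(start = start(geneModels)[sel],
                      end = end(geneModels)[sel],
                      gene_id = geneModels$gene_id[sel],
                      lab = regOf[geneModels$type[sel]])
  featsByGene <- split(feats, feats$gene_id)
  cgid <- clusters$gene_id
  for (i in seq_along(clusters)) {
    f <- featsByGene[[cgid[i]]]
    if (!is.null(f))
      f <- f[f$start <= mid[i] & f$end >= mid[i], , drop = FALSE]
    if (is.null(f) || !nrow(f)) { region[i] <- "other"; next }
    region[i] <- precedence[min(match(f$lab, precedence))]
  }
  clusters$region <- region
  clusters
}

#' Distribution of clusters across gene regions
#'
#' @param clusters GRanges with a \code{region} column (see
#'   [assignRegions()]).
#' @return data.frame with region, count and fraction (fractions sum to 1;
#'   an empty input yields a zero-total frame).
#' @export
regionDistribution <- function(clusters) {
  if (!length(clusters))
    return(data.frame(region = character(), count = integer(),
                      fraction = numeric(), total = integer()))
  tab <- table(clusters$region)
  data.frame(region = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / length(clusters),
             total = length(clusters), row.names = NULL)
}
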