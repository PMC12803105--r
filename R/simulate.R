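#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
#' @importFrom Biostrings DNAStringSet DNAString readDNAStringSet
#'   writeXStringSet countPattern reverseComplement subseq
NULL

## Deterministic per-stage seed: a 31-bit polynomial hash of the stage name
## folded into the global seed, so each pipeline stage has its own stream
## independent of execution order.
stageSeed <- function(seed, stage) {
  s <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(stage)) s <- (s * 31 + code) %% 2147483647
  as.integer(s)
}

lnormPars <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  c(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

randomSeq <- function(len, comp) {
  paste(sample(names(comp), len, replace = TRUE, prob = comp), collapse = "")
}

#' Simulate a synthetic transcriptome with planted binding sites
#'
#' Lays out \code{nGenes} single-isoform genes along one synthetic
#' chromosome, each with a 5'UTR, CDS (optionally split by one intron) and a
#' log-normally sized 3'UTR. A random subset of genes ("ligands") carries
#' \code{sitesPerLigand} planted copies of the UGU-rich site motif in its
#' 3'UTR; these intervals are the ground truth against which downstream
#' recovery is measured. 3'UTR sequences are generated from the configured
#' base composition (DNA alphabet, T standing for U).
#'
#' @param cfg a [ClipSimConfig-class].
#' @return A list with elements \code{geneModels} (GRanges of gene /
#'   five_prime_utr / CDS / intron / three_prime_utr features, with
#'   \code{gene_id}, and \code{expression} on gene rows), \code{utr3}
#'   (DNAStringSet named by gene id), \code{genes} (data.frame of gene_id,
#'   strand, expression), and \code{truth} (list: \code{ligandGeneIds},
#'   \code{plantedSites} with within-UTR 0-based half-open and genomic
#'   1-based coordinates).
#' @examples
#' tx <- simulateTranscriptome(clipSimConfig(nGenes = 10, nLigands = 2))
#' table(tx$geneModels$type)
#' @export
simulateTranscriptome <- function(cfg) {
  stopifnot(is(cfg, "ClipSimConfig"))
  set.seed(stageSeed(cfg@seed, "transcriptome"))
  n <- cfg@nGenes
  if (n == 0L) {
    return(list(
      geneModels = GRanges(),
      utr3 = DNAStringSet(),
      genes = data.frame(gene_id = character(), strand = character(),
                         expression = numeric()),
      truth = list(ligandGeneIds = character(),
                   plantedSites = data.frame(
                     gene_id = character(), site = integer(),
                     start = integer(), end = integer(),
                     genomic_start = integer(), genomic_end = integer()))))
  }
  ids <- sprintf("gene%04d", seq_len(n))
  lp <- lnormPars(cfg@utr3LenMean, cfg@utr3LenSd)
  motif <- cfg@siteMotif
  m <- nchar(motif)
  minUtr <- max(50L, cfg@sitesPerLigand * (m + 4L) + 10L)
  utr3Len <- pmax(minUtr, as.integer(round(rlnorm(n, lp[1], lp[2]))))
  hasIntron <- runif(n) < cfg@intronProb
  strand <- rep("+", n)
  if (cfg@minusStrandFrac > 0)
    strand[runif(n) < cfg@minusStrandFrac] <- "-"
  expression <- rlnorm(n, cfg@expressionMu, cfg@expressionSigma)
  ligands <- sort(sample(ids, cfg@nLigands))

  gap <- 100L
  featList <- vector("list", n)
  cursor <- 1L
  utrSeqs <- character(n)
  planted <- vector("list", n)
  for (i in seq_len(n)) {
    ## transcript-order region lengths
    lens <- c(five_prime_utr = cfg@utr5Len,
              CDS = if (hasIntron[i]) cfg@cdsLen %/% 2L else cfg@cdsLen,
              intron = if (hasIntron[i]) cfg@intronLen else 0L,
              CDS2 = if (hasIntron[i]) cfg@cdsLen - cfg@cdsLen %/% 2L else 0L,
              three_prime_utr = utr3Len[i])
    lens <- lens[lens > 0L]
    types <- sub("CDS2", "CDS", names(lens))
    if (strand[i] == "-") { lens <- rev(lens); types <- rev(types) }
    starts <- cursor + c(0L, cumsum(lens))[seq_along(lens)]
    ends <- starts + lens - 1L
    geneStart <- cursor
    geneEnd <- ends[length(ends)]
    featList[[i]] <- data.frame(
      start = c(geneStart, starts), end = c(geneEnd, ends),
      type = c("gene", types), gene_id = ids[i], strand = strand[i])
    cursor <- geneEnd + gap + 1L

    ## 3'UTR sequence (transcript orientation) with planted sites
    L <- utr3Len[i]
    s <- randomSeq(L, cfg@baseComposition)
    if (ids[i] %in% ligands) {
      k <- cfg@sitesPerLigand
      block <- L %/% k
      start0 <- vapply(seq_len(k) - 1L, function(b)
        b * block + sample.int(block - m + 1L, 1L) - 1L, integer(1))
      for (st in start0)
        substr(s, st + 1L, st + m) <- motif
      utrIdx <- which(types == "three_prime_utr")
      utrGs <- starts[utrIdx]; utrGe <- ends[utrIdx]
      if (strand[i] == "+") {
        gs <- utrGs + start0; ge <- gs + m - 1L
      } else {
        ge <- utrGe - start0; gs <- ge - m + 1L
      }
      planted[[i]] <- data.frame(
        gene_id = ids[i], site = seq_len(k),
        start = start0, end = start0 + m,
        genomic_start = as.integer(gs), genomic_end = as.integer(ge))
    }
    utrSeqs[i] <- s
  }
  feats <- do.call(rbind, featList)
  gr <- GRanges("chrS", IRanges(feats$start, feats$end),
                strand = feats$strand,
                type = feats$type, gene_id = feats$gene_id)
  gr$expression <- ifelse(gr$type == "gene",
                          expression[match(gr$gene_id, ids)], NA_real_)
  utr3 <- DNAStringSet(setNames(utrSeqs, ids))
  plantedSites <- if (length(planted) && any(!vapply(planted, is.null,
                                                     logical(1))))
    do.call(rbind, planted[!vapply(planted, is.null, logical(1))])
  else data.frame(gene_id = character(), site = integer(),
                  start = integer(), end = integer(),
                  genomic_start = integer(), genomic_end = integer())
  list(geneModels = gr, utr3 = utr3,
       genes = data.frame(gene_id = ids, strand = strand,
                          expression = expression),
       truth = list(ligandGeneIds = ligands, plantedSites = plantedSites))
}

#' Simulate cross-link events for one pseudo-experiment
#'
#' Per gene the event count is Poisson with mean
#' \code{expression * readsPerGeneScale * depthFactor}. On ligand genes each
#' event falls inside a uniformly chosen planted site with probability
#' \code{signalFraction}, otherwise (and on all non-ligand genes) uniformly
#' over the full genomic gene span, introns included. Events are aggregated
#' per position into cross-link sites scored by event count, so per gene the
#' sum of site scores equals the number of simulated events.
#'
#' @param cfg a [ClipSimConfig-class].
#' @param transcriptome output of [simulateTranscriptome()].
#' @param depthFactor depth multiplier (> 0); typically
#'   \code{cfg@depthFactorExp1} or \code{cfg@depthFactorExp2}.
#' @param seed integer seed for this draw.
#' @return GRanges of width-1 cross-link sites with metadata columns
#'   \code{score} (event count) and \code{gene_id}, sorted by position.
#' @export
simulateClipEvents <- function(cfg, transcriptome,
                               depthFactor = cfg@depthFactorExp1,
                               seed = stageSeed(cfg@seed, "events")) {
  stopifnot(is(cfg, "ClipSimConfig"))
  if (depthFactor <= 0) stop("depthFactor must be > 0")
  set.seed(seed)
  gm <- transcriptome$geneModels
  genes <- gm[gm$type == "gene"]
  truth <- transcriptome$truth
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    gid <- genes$gene_id[i]
    lambda <- genes$expression[i] * cfg@readsPerGeneScale * depthFactor
    nEv <- rpois(1L, lambda)
    if (nEv == 0L) next
    gs <- start(genes)[i]; ge <- end(genes)[i]
    pos <- gs + sample.int(ge - gs + 1L, nEv, replace = TRUE) - 1L
    if (gid %in% truth$ligandGeneIds && cfg@signalFraction > 0) {
      ps <- truth$plantedSites[truth$plantedSites$gene_id == gid, ,
                               drop = FALSE]
      inSite <- runif(nEv) < cfg@signalFraction
      k <- sum(inSite)
      if (k > 0L) {
        si <- sample.int(nrow(ps), k, replace = TRUE)
        w <- ps$genomic_end[si] - ps$genomic_start[si] + 1L
        pos[inSite] <- ps$genomic_start[si] +
          floor(runif(k) * w)
      }
    }
    tab <- table(pos)
    out[[i]] <- data.frame(pos = as.integer(names(tab)),
                           score = as.integer(tab), gene_id = gid,
                           strand = as.character(strand(genes))[i])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(GRanges(score = integer(), gene_id = character()))
  df <- do.call(rbind, out)
  gr <- GRanges("chrS", IRanges(df$pos, width = 1L), strand = df$strand,
                score = df$score, gene_id = df$gene_id)
  gr[order(start(gr))]
}

#' Emit synthetic read alignments from cross-link sites
#'
#' A thin alignment emitter exercising [deriveCrosslinkSites()]: each site
#' contributes \code{score} reads whose 5' ends sit one nucleotide
#' downstream of the cross-link (the truncation convention: reverse
#' transcription halts at the cross-linked base, so the read starts just
#' 3' of it).
#'
#' @param sites GRanges of cross-link sites with a \code{score} column.
#' @param readLen read length in nt.
#' @return GRanges of read alignments (one range per read).
#' @export
emitReadAlignments <- function(sites, readLen = 30L) {
  if (!length(sites)) return(GRanges())
  idx <- rep(seq_along(sites), sites$score)
  pos <- start(sites)[idx]
  neg <- as.character(strand(sites))[idx] == "-"
  fiveP <- ifelse(neg, pos - 1L, pos + 1L)
  st <- ifelse(neg, pmax(1L, fiveP - readLen + 1L), fiveP)
  en <- ifelse(neg, fiveP, fiveP + readLen - 1L)
  GRanges(as.character(seqnames(sites))[idx], IRanges(st, en),
          strand = ifelse(neg, "-", "+"))
}

#' Simulate a knockout-vs-wild-type differential-expression table
#'
#' Non-ligand genes have true log2 fold change 0; ligand genes have true
#' log2FC drawn from Normal(\code{deLfcMean}, \code{deLfcSd}) (positive =
#' up-regulated in the knockout, i.e. de-repressed). Observed log2FC adds
#' Normal(0, \code{deNoiseSd}) noise and the p-value is the two-sided normal
#' tail of observed/\code{deNoiseSd}, so null genes have exactly uniform
#' p-values. FDR is Benjamini-Hochberg.
#'
#' @param cfg a [ClipSimConfig-class].
#' @param truth ground-truth list from [simulateTranscriptome()].
#' @param geneIds genes to tabulate (default: all with planted truth plus
#'   the ids implied by \code{cfg@nGenes}).
#' @param seed integer seed.
#' @return data.frame with columns gene_id, log2FC, pvalue, fdr.
#' @export
simulateDeTable <- function(cfg, truth,
                            geneIds = sprintf("gene%04d",
                                              seq_len(cfg@nGenes)),
                            seed = stageSeed(cfg@seed, "de")) {
  set.seed(seed)
  n <- length(geneIds)
  isLig <- geneIds %in% truth$ligandGeneIds
  lfcTrue <- numeric(n)
  lfcTrue[isLig] <- rnorm(sum(isLig), cfg@deLfcMean, cfg@deLfcSd)
  lfc <- lfcTrue + rnorm(n, 0, cfg@deNoiseSd)
  p <- 2 * pnorm(-abs(lfc) / cfg@deNoiseSd)
  data.frame(gene_id = geneIds, log2FC = lfc, pvalue = p,
             fdr = p.adjust(p, method = "BH"))
}

#' Simulate funnel annotation resources
#'
#' Emulates the literature/disease/tissue resources of the prioritization
#' funnel: per-gene citation counts from a negative binomial (ligand means
#' multiplied by \code{pubsLigandMult}), disease-catalogue membership as
#' Bernoulli flags with an elevated rate among a configurable fraction of
#' ligands, and a continuous lens-enrichment score (standard normal, ligand
#' genes shifted by \code{lensShift}).
#'
#' @param cfg a [ClipSimConfig-class].
#' @param truth ground-truth list from [simulateTranscriptome()].
#' @param geneIds genes to annotate.
#' @param diseaseLigandFrac fraction of ligands subject to the elevated
#'   disease rate (the rest use the background rate).
#' @param seed integer seed.
#' @return data.frame with columns gene_id, n_pubs, in_disease_list,
#'   lens_enrichment.
#' @export
simulateAnnotations <- function(cfg, truth,
                                geneIds = sprintf("gene%04d",
                                                  seq_len(cfg@nGenes)),
                                diseaseLigandFrac = 1,
                                seed = stageSeed(cfg@seed, "annotations")) {
  set.seed(seed)
  n <- length(geneIds)
  isLig <- geneIds %in% truth$ligandGeneIds
  mu <- ifelse(isLig, cfg@pubsMu * cfg@pubsLigandMult, cfg@pubsMu)
  nPubs <- rnbinom(n, size = cfg@pubsNbSize, mu = mu)
  rate <- rep(cfg@diseaseRate, n)
  elevated <- isLig & runif(n) < diseaseLigandFrac
  rate[elevated] <- cfg@diseaseLigandRate
  disease <- runif(n) < rate
  lens <- rnorm(n) + ifelse(isLig, cfg@lensShift, 0)
  data.frame(gene_id = geneIds, n_pubs = nPubs,
             in_disease_list = disease, lens_enrichment = lens)
}

#' Simulate a complete synthetic iCLIP study
#'
#' Runs the whole generator under per-stage seeds derived from
#' \code{cfg@seed}: transcriptome with planted sites, two cross-link
#' pseudo-experiments at the two configured depths, the
#' knockout-vs-wild-type differential-expression table, and the funnel
#' annotation table. Optionally writes all of it to disk (GTF, FASTA, two
#' BED6 files, TSVs, and the ground truth as JSON with the planted
#' intervals in 0-based half-open within-UTR coordinates). The ground truth
#' is emitted alongside the data and is never consumed by analysis
#' functions.
#'
#' @param cfg a [ClipSimConfig-class].
#' @param outDir optional directory to write all files into.
#' @return A list: \code{cfg}, \code{geneModels}, \code{utr3}, \code{genes},
#'   \code{truth}, \code{sites1}, \code{sites2}, \code{deTable},
#'   \code{annotations}.
#' @examples
#' study <- simulateClipStudy(clipSimConfig(nGenes = 15, nLigands = 3,
#'                                          seed = 7))
#' length(study$sites1)
#' @export
simulateClipStudy <- function(cfg, outDir = NULL) {
  tx <- simulateTranscriptome(cfg)
  sites1 <- simulateClipEvents(cfg, tx, cfg@depthFactorExp1,
                               seed = stageSeed(cfg@seed, "events_exp1"))
  sites2 <- simulateClipEvents(cfg, tx, cfg@depthFactorExp2,
                               seed = stageSeed(cfg@seed, "events_exp2"))
  de <- simulateDeTable(cfg, tx$truth)
  ann <- simulateAnnotations(cfg, tx$truth)
  study <- list(cfg = cfg, geneModels = tx$geneModels, utr3 = tx$utr3,
                genes = tx$genes, truth = tx$truth,
                sites1 = sites1, sites2 = sites2,
                deTable = de, annotations = ann)
  if (!is.null(outDir)) writeClipStudy(study, outDir)
  invisible(study)
}

#' Write a simulated study to disk
#'
#' @param study list from [simulateClipStudy()].
#' @param outDir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
writeClipStudy <- function(study, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeGeneModels(study$geneModels, file.path(outDir, "genes.gtf"))
  writeXStringSet(study$utr3, file.path(outDir, "utr3.fa"))
  writeCrosslinkBed(study$sites1, file.path(outDir, "sites_clip1.bed"))
  writeCrosslinkBed(study$sites2, file.path(outDir, "sites_clip2.bed"))
  writeTsv(study$deTable, file.path(outDir, "de_table.tsv"))
  writeTsv(study$annotations, file.path(outDir, "annotations.tsv"))
  writeTsv(study$genes, file.path(outDir, "expression.tsv"))
  jsonlite::write_json(
    list(ligand_gene_ids = study$truth$ligandGeneIds,
         planted_sites = study$truth$plantedSites),
    file.path(outDir, "ground_truth.json"), auto_unbox = FALSE, digits = NA)
  invisible(outDir)
}

#' Simulate dual-luciferase reporter wells
#'
#' Generates firefly/renilla luminescence for every combination of
#' construct, condition (effector vs control effector), biological and
#' technical replicate. The firefly/renilla ratio carries a per-replicate
#' batch factor, a per-construct baseline, the planted log2 effect
#' (effector condition only) and multiplicative log2-normal noise, so the
#' sequential normalization chain recovers the planted effects.
#'
#' @param effects named numeric of true log2 activities per construct
#'   (the control construct should be 0).
#' @param controlConstruct name of the control-3'UTR construct.
#' @param nBioReps,nTechReps replicate counts.
#' @param sigma per-well multiplicative noise sd (log2 units).
#' @param seed integer seed.
#' @return data.frame of wells: construct_id, condition, bio_rep, tech_rep,
#'   firefly, renilla.
#' @export
simulateLuciferaseWells <- function(effects,
                                    controlConstruct = names(effects)[1L],
                                    nBioReps = 6L, nTechReps = 4L,
                                    sigma = 0.05, seed = 1L) {
  stopifnot(!is.null(names(effects)), controlConstruct %in% names(effects))
  set.seed(seed)
  constructs <- names(effects)
  grid <- expand.grid(construct_id = constructs,
                      condition = c("effector", "control_effector"),
                      bio_rep = seq_len(nBioReps),
                      tech_rep = seq_len(nTechReps),
                      stringsAsFactors = FALSE)
  batch <- rlnorm(nBioReps, 0, 0.3)
  baseline <- setNames(rlnorm(length(constructs), 0, 0.2), constructs)
  ratio <- batch[grid$bio_rep] * baseline[grid$construct_id] *
    ifelse(grid$condition == "effector",
           2^effects[grid$construct_id], 1) *
    2^rnorm(nrow(grid), 0, sigma)
  renilla <- rlnorm(nrow(grid), log(2e4), 0.2)
  grid$firefly <- as.numeric(renilla * ratio)
  grid$renilla <- as.numeric(renilla)
  grid
}

#' Simulate paired eye/lens morphometry
#'
#' One row per larva, side and structure with minor and major diameters;
#' the injected side is shrunk by the given area reductions (diameters
#' scaled by the square root) with multiplicative noise. Cornea thickness
#' is attached to the eye rows and thickened on the injected side.
#'
#' @param nLarvae number of larvae.
#' @param lensAreaReduction,eyeAreaReduction fractional area reduction on
#'   the injected side.
#' @param corneaThickening multiplicative cornea thickening on the injected
#'   side.
#' @param noise multiplicative diameter noise sd (log scale).
#' @param seed integer seed.
#' @return data.frame: larva_id, side, structure, minor_diameter,
#'   major_diameter, cornea_thickness.
#' @export
simulateEyeMeasurements <- function(nLarvae = 8L, lensAreaReduction = 0.3,
                                    eyeAreaReduction = 0.1,
                                    corneaThickening = 1.5,
                                    noise = 0.05, seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(larva_id = sprintf("larva%02d", seq_len(nLarvae)),
                      side = c("control", "injected"),
                      structure = c("eye", "lens"),
                      stringsAsFactors = FALSE)
  base <- ifelse(grid$structure == "eye", 500, 200)  # micrometres
  shrink <- ifelse(grid$side == "injected",
                   sqrt(1 - ifelse(grid$structure == "lens",
                                   lensAreaReduction, eyeAreaReduction)), 1)
  grid$minor_diameter <- base * shrink * rlnorm(nrow(grid), 0, noise)
  grid$major_diameter <- base * 1.2 * shrink * rlnorm(nrow(grid), 0, noise)
  grid$cornea_thickness <- ifelse(
    grid$structure == "eye",
    30 * ifelse(grid$side == "injected", corneaThickening, 1) *
      rlnorm(nrow(grid), 0, noise),
    NA_real_)
  grid
}
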