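#' @import methods
#' @importFrom stats rlnorm rpois rnorm runif rbinom rnbinom pnorm p.adjust
#'   chisq.test wilcox.test t.test ks.test setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Simulation configuration for a synthetic iCLIP study
#'
#' An S4 container holding every parameter of the synthetic-data generator:
#' transcriptome geometry, planted binding sites, cross-link event sampling
#' for two pseudo-experiments of different depth (emulating two RNase
#' stringencies), the knockout-vs-wild-type differential-expression table,
#' and the annotation resources consumed by the prioritization funnel.
#' Identical configuration plus seed yields byte-identical outputs.
#'
#' @slot nGenes number of genes on the synthetic chromosome.
#' @slot utr3LenMean,utr3LenSd mean and sd (nt) of the log-normal 3'UTR
#'   length distribution.
#' @slot utr5Len,cdsLen,intronLen fixed lengths (nt) of the remaining gene
#'   regions; an intron is inserted inside the CDS with probability
#'   \code{intronProb}.
#' @slot intronProb probability a gene carries an intron.
#' @slot minusStrandFrac fraction of genes placed on the minus strand
#'   (0 by default; set > 0 to exercise strand handling).
#' @slot baseComposition named probabilities over A, C, G, T (written as DNA;
#'   T plays the role of U) summing to 1.
#' @slot nLigands number of planted target ("ligand") genes.
#' @slot sitesPerLigand planted binding sites per ligand 3'UTR.
#' @slot siteMotif sequence planted at each site (DNA alphabet; default
#'   tandem UGU repeats).
#' @slot signalFraction probability a cross-link event on a ligand gene
#'   falls inside a planted site rather than uniformly over the gene span.
#' @slot expressionMu,expressionSigma log-normal expression parameters
#'   (natural-log scale, TPM-like units).
#' @slot readsPerGeneScale expected cross-link events per expression unit at
#'   depth factor 1.
#' @slot depthFactorExp1,depthFactorExp2 depth multipliers for the two
#'   pseudo-experiments; the second is lower by default, emulating the
#'   harsher RNase digestion that yields fewer uniquely mapped reads.
#' @slot deLfcMean,deLfcSd log2 fold-change distribution of ligand genes in
#'   the knockout (positive = up-regulated when the repressor is absent).
#' @slot deNoiseSd measurement noise sd of observed log2 fold changes; the
#'   reported p-value is the two-sided normal tail of lfc/deNoiseSd, so
#'   null genes have exactly Uniform(0,1) p.
#' @slot pubsNbSize,pubsMu negative-binomial size and mean of per-gene
#'   citation counts; ligand means are multiplied by \code{pubsLigandMult}.
#' @slot pubsLigandMult citation-count mean multiplier for ligand genes.
#' @slot diseaseRate,diseaseLigandRate Bernoulli rates of disease-catalogue
#'   membership for non-ligand and ligand genes.
#' @slot lensShift additive shift of the continuous lens-enrichment score
#'   for ligand genes (units of its sd, which is 1).
#' @slot seed integer seed governing all randomness.
#' @seealso [clipSimConfig()], [simulateClipStudy()]
#' @exportClass ClipSimConfig
setClass("ClipSimConfig", representation(
  nGenes = "integer",
  utr3LenMean = "numeric", utr3LenSd = "numeric",
  utr5Len = "integer", cdsLen = "integer",
  intronLen = "integer", intronProb = "numeric",
  minusStrandFrac = "numeric",
  baseComposition = "numeric",
  nLigands = "integer", sitesPerLigand = "integer", siteMotif = "character",
  signalFraction = "numeric",
  expressionMu = "numeric", expressionSigma = "numeric",
  readsPerGeneScale = "numeric",
  depthFactorExp1 = "numeric", depthFactorExp2 = "numeric",
  deLfcMean = "numeric", deLfcSd = "numeric", deNoiseSd = "numeric",
  pubsNbSize = "numeric", pubsMu = "numeric", pubsLigandMult = "numeric",
  diseaseRate = "numeric", diseaseLigandRate = "numeric",
  lensShift = "numeric",
  seed = "integer"
))

setValidity("ClipSimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 0L) msg <- c(msg, "nGenes must be >= 0")
  if (object@nLigands < 0L || object@nLigands > object@nGenes)
    msg <- c(msg, "nLigands must lie in [0, nGenes]")
  if (object@signalFraction < 0 || object@signalFraction > 1)
    msg <- c(msg, "signalFraction must lie in [0, 1]")
  bc <- object@baseComposition
  if (length(bc) != 4L || !setequal(names(bc), c("A", "C", "G", "T")))
    msg <- c(msg, "baseComposition must be named over A, C, G, T")
  else if (any(bc < 0) || abs(sum(bc) - 1) > 1e-8)
    msg <- c(msg, "baseComposition must be non-negative and sum to 1")
  for (s in c("utr3LenMean", "utr3LenSd", "utr5Len", "cdsLen", "intronLen",
              "readsPerGeneScale", "sitesPerLigand"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be > 0"))
  if (object@depthFactorExp1 <= 0 || object@depthFactorExp2 <= 0)
    msg <- c(msg, "depth factors must be > 0")
  if (object@intronProb < 0 || object@intronProb > 1)
    msg <- c(msg, "intronProb must lie in [0, 1]")
  if (object@minusStrandFrac < 0 || object@minusStrandFrac > 1)
    msg <- c(msg, "minusStrandFrac must lie in [0, 1]")
  if (nchar(object@siteMotif) < 3L ||
      grepl("[^ACGTU]", toupper(object@siteMotif)))
    msg <- c(msg, "siteMotif must be a nucleotide string of length >= 3")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' All arguments default to the study conditions emulated by the package:
#' 500 genes on one synthetic chromosome, 50 ligand genes each carrying
#' three planted tandem-UGU sites in its 3'UTR, roughly 50 cross-link
#' events per gene in the first pseudo-experiment and a five-fold shallower
#' second pseudo-experiment, ligands up-regulated by one log2 unit in the
#' knockout, and funnel annotations in which ligands are citation-,
#' disease- and lens-enrichment-shifted.
#'
#' @param nGenes,nLigands,sitesPerLigand counts; see [ClipSimConfig-class].
#' @param utr3LenMean,utr3LenSd,utr5Len,cdsLen,intronLen,intronProb gene
#'   geometry, in nucleotides.
#' @param minusStrandFrac fraction of minus-strand genes.
#' @param baseComposition named numeric over A, C, G, T summing to 1.
#' @param siteMotif planted site sequence (DNA alphabet).
#' @param signalFraction per-event probability of landing in a planted site.
#' @param expressionMu,expressionSigma log-normal expression parameters.
#' @param readsPerGeneScale events per expression unit.
#' @param depthFactorExp1,depthFactorExp2 depth multipliers of the two
#'   pseudo-experiments.
#' @param deLfcMean,deLfcSd,deNoiseSd differential-expression parameters
#'   (log2 units).
#' @param pubsNbSize,pubsMu,pubsLigandMult,diseaseRate,diseaseLigandRate,lensShift
#'   annotation-table parameters.
#' @param seed integer seed.
#' @return A validated [ClipSimConfig-class] object.
#' @examples
#' cfg <- clipSimConfig(nGenes = 20, nLigands = 4, seed = 1)
#' cfg
#' @export
clipSimConfig <- function(nGenes = 500L,
                          utr3LenMean = 800, utr3LenSd = 300,
                          utr5Len = 150L, cdsLen = 900L,
                          intronLen = 400L, intronProb = 0.5,
                          minusStrandFrac = 0,
                          baseComposition = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                          nLigands = 50L, sitesPerLigand = 3L,
                          siteMotif = "TGTTGTTGTTGT",
                          signalFraction = 0.8,
                          expressionMu = 3, expressionSigma = 1,
                          readsPerGeneScale = 1.5,
                          depthFactorExp1 = 1, depthFactorExp2 = 0.2,
                          deLfcMean = 1, deLfcSd = 0.25, deNoiseSd = 0.5,
                          pubsNbSize = 0.5, pubsMu = 2, pubsLigandMult = 5,
                          diseaseRate = 0.05, diseaseLigandRate = 0.3,
                          lensShift = 1,
                          seed = 42L) {
  new("ClipSimConfig",
      nGenes = as.integer(nGenes),
      utr3LenMean = utr3LenMean, utr3LenSd = utr3LenSd,
      utr5Len = as.integer(utr5Len), cdsLen = as.integer(cdsLen),
      intronLen = as.integer(intronLen), intronProb = intronProb,
      minusStrandFrac = minusStrandFrac,
      baseComposition = baseComposition[c("A", "C", "G", "T")],
      nLigands = as.integer(nLigands),
      sitesPerLigand = as.integer(sitesPerLigand),
      siteMotif = toupper(chartr("U", "T", siteMotif)),
      signalFraction = signalFraction,
      expressionMu = expressionMu, expressionSigma = expressionSigma,
      readsPerGeneScale = readsPerGeneScale,
      depthFactorExp1 = depthFactorExp1, depthFactorExp2 = depthFactorExp2,
      deLfcMean = deLfcMean, deLfcSd = deLfcSd, deNoiseSd = deNoiseSd,
      pubsNbSize = pubsNbSize, pubsMu = pubsMu,
      pubsLigandMult = pubsLigandMult,
      diseaseRate = diseaseRate, diseaseLigandRate = diseaseLigandRate,
      lensShift = lensShift,
      seed = as.integer(seed))
}

setMethod("show", "ClipSimConfig", function(object) {
  cat("ClipSimConfig:", object@nGenes, "genes,",
      object@nLigands, "planted ligands,",
      object@sitesPerLigand, "sites/ligand (motif", object@siteMotif, ")\n")
  cat("  signalFraction:", object@signalFraction,
      " depth factors:", object@depthFactorExp1, "/",
      object@depthFactorExp2, "\n")
  cat("  DE shift:", object@deLfcMean, "log2  seed:", object@seed, "\n")
})

#' Result of a GSEA-like running-sum enrichment analysis
#'
#' Holds the signed enrichment score (maximal absolute deviation of the
#' classic unweighted hit/miss running sum), the per-rank running profile,
#' the permutation p-value from random same-size gene sets, and the leading
#' edge (set members at or before the running-sum extremum).
#'
#' @slot es signed enrichment score in \eqn{[-1, 1]}.
#' @slot pPerm permutation p-value in \eqn{(0, 1]} (NA when no permutations
#'   were run).
#' @slot nPerm number of permutations.
#' @slot alternative how the permutation tail was formed
#'   ("two.sided", "greater" or "less").
#' @slot leadingEdge character vector of leading-edge gene ids.
#' @slot runningProfile numeric running-sum value at every rank.
#' @slot setSize number of set members present in the ranked list.
#' @slot nDropped set members absent from the ranked universe (dropped).
#' @exportClass GseaResult
setClass("GseaResult", representation(
  es = "numeric", pPerm = "numeric", nPerm = "integer",
  alternative = "character",
  leadingEdge = "character", runningProfile = "numeric",
  setSize = "integer", nDropped = "integer"
))

setValidity("GseaResult", function(object) {
  msg <- character()
  if (length(object@es) != 1L || abs(object@es) > 1 + 1e-12)
    msg <- c(msg, "es must be a single value in [-1, 1]")
  if (length(object@runningProfile) &&
      abs(abs(object@es) - max(abs(object@runningProfile))) > 1e-9)
    msg <- c(msg, "|es| must equal max |runningProfile|")
  if (!is.na(object@pPerm) && (object@pPerm <= 0 || object@pPerm > 1))
    msg <- c(msg, "pPerm must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname GseaResult-class
#' @param object,x a \code{GseaResult}.
#' @export
setGeneric("enrichmentScore", function(x) standardGeneric("enrichmentScore"))
#' @rdname GseaResult-class
#' @export
setGeneric("leadingEdge", function(x) standardGeneric("leadingEdge"))
#' @rdname GseaResult-class
#' @export
setGeneric("runningProfile", function(x) standardGeneric("runningProfile"))
#' @rdname GseaResult-class
#' @export
setGeneric("permPValue", function(x) standardGeneric("permPValue"))

#' @rdname GseaResult-class
#' @export
setMethod("enrichmentScore", "GseaResult", function(x) x@es)
#' @rdname GseaResult-class
#' @export
setMethod("leadingEdge", "GseaResult", function(x) x@leadingEdge)
#' @rdname GseaResult-class
#' @export
setMethod("runningProfile", "GseaResult", function(x) x@runningProfile)
#' @rdname GseaResult-class
#' @export
setMethod("permPValue", "GseaResult", function(x) x@pPerm)

setMethod("show", "GseaResult", function(object) {
  cat("GseaResult: ES =", format(object@es, digits = 4))
  if (!is.na(object@pPerm))
    cat(", permutation p =", format(object@pPerm, digits = 3),
        sprintf("(%d perms, %s)", object@nPerm, object@alternative))
  cat("\n  set size:", object@setSize,
      " leading edge:", length(object@leadingEdge), "genes")
  if (object@nDropped > 0L)
    cat("  (", object@nDropped, "set members absent from ranking )")
  cat("\n")
})

#' Result of the multistep gene prioritization funnel
#'
#' @slot stages data.frame with one row per filtering stage: \code{stage},
#'   \code{predicate}, \code{nIn}, \code{nOut}.
#' @slot genes character vector of genes surviving the last stage.
#' @exportClass FunnelResult
setClass("FunnelResult", representation(
  stages = "data.frame", genes = "character"
))

setValidity("FunnelResult", function(object) {
  st <- object@stages
  msg <- character()
  if (nrow(st)) {
    if (any(st$nOut > st$nIn))
      msg <- c(msg, "stage output must not exceed input")
    if (nrow(st) > 1L && any(st$nIn[-1L] != st$nOut[-nrow(st)]))
      msg <- c(msg, "stage k+1 input must equal stage k output")
    if (length(object@genes) != st$nOut[nrow(st)])
      msg <- c(msg, "final gene count must match last stage output")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname FunnelResult-class
#' @param x a \code{FunnelResult}.
#' @export
setGeneric("stageTable", function(x) standardGeneric("stageTable"))
#' @rdname FunnelResult-class
#' @export
setGeneric("finalGenes", function(x) standardGeneric("finalGenes"))
#' @rdname FunnelResult-class
#' @export
setMethod("stageTable", "FunnelResult", function(x) x@stages)
#' @rdname FunnelResult-class
#' @export
setMethod("finalGenes", "FunnelResult", function(x) x@genes)

setMethod("show", "FunnelResult", function(object) {
  cat("FunnelResult:",
      paste(c(object@stages$nIn[1L], object@stages$nOut), collapse = " -> "),
      "\n")
  for (i in seq_len(nrow(object@stages)))
    cat(sprintf("  %d. %-22s %5d -> %d\n", i, object@stages$stage[i],
                object@stages$nIn[i], object@stages$nOut[i]))
})
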