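## Rank-based "top quarter" membership: k = ceiling(frac * n), descending
## values, ties broken by gene id so the cut is total and deterministic.
topFractionIds <- function(values, ids, frac = 0.25) {
  k <- ceiling(frac * length(ids))
  o <- order(-values, ids)
  ids[o][seq_len(min(k, length(ids)))]
}

#' Default stages of the gene prioritization funnel
#'
#' The study's order: (1) expressed in the tissue; (2) ligand in at least
#' one CLIP experiment (union); (3) ligand in both (intersection); (4)
#' upper quarter of literature co-citations with the tissue keyword; (5)
#' membership in the disease catalogue; (6) upper quarter of the
#' lens-enrichment score. Quartile cuts are computed within each stage's
#' input population (the survivors of the previous stage).
#'
#' @return list of stage definitions (name, predicate description, filter
#'   function taking the annotation subset and returning a logical).
#' @export
funnelStages <- function() {
  list(
    list(stage = "expressed", predicate = "expressed in tissue",
         filter = function(a) as.logical(a$expressed)),
    list(stage = "ligand_union", predicate = "in_clip1 OR in_clip2",
         filter = function(a) a$in_clip1 | a$in_clip2),
    list(stage = "ligand_intersection", predicate = "in_clip1 AND in_clip2",
         filter = function(a) a$in_clip1 & a$in_clip2),
    list(stage = "pubs_top_quarter",
         predicate = "n_pubs in upper quarter of stage input",
         filter = function(a)
           a$gene_id %in% topFractionIds(a$n_pubs, a$gene_id, 0.25)),
    list(stage = "disease_list", predicate = "in_disease_list",
         filter = function(a) as.logical(a$in_disease_list)),
    list(stage = "lens_top_quarter",
         predicate = "lens_enrichment in upper quarter of stage input",
         filter = function(a)
           a$gene_id %in% topFractionIds(a$lens_enrichment, a$gene_id,
                                         0.25)))
}

#' Run the multistep prioritization funnel
#'
#' Applies the stage filters sequentially; each stage sees only the
#' survivors of the previous one, so rank-based quartile stages are
#' relative to their own input (permuting stage order can change the
#' outcome).
#'
#' @param annotation data.frame with one row per gene and the columns each
#'   stage needs (gene_id, expressed, in_clip1, in_clip2, n_pubs,
#'   in_disease_list, lens_enrichment for the default stages).
#' @param stages list of stage definitions, see [funnelStages()].
#' @return a [FunnelResult-class].
#' @examples
#' ann <- data.frame(gene_id = sprintf("g%02d", 1:8), expressed = TRUE,
#'                   in_clip1 = rep(c(TRUE, FALSE), 4),
#'                   in_clip2 = c(TRUE, TRUE, FALSE, FALSE)[c(1,1,2,2,3,3,4,4)],
#'                   n_pubs = 8:1, in_disease_list = TRUE,
#'                   lens_enrichment = 1:8)
#' runFunnel(ann)
#' @export
runFunnel <- function(annotation, stages = funnelStages()) {
  if (!nrow(annotation)) stop("empty annotation table")
  if (!"gene_id" %in% names(annotation)) stop("missing column: gene_id")
  cur <- annotation
  rows <- vector("list", length(stages))
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    nIn <- nrow(cur)
    keep <- if (nIn) st$filter(cur) else logical(0)
    if (anyNA(keep) || length(keep) != nIn)
      stop("stage '", st$stage,
           "' failed to evaluate its predicate (missing column?)")
    cur <- cur[keep, , drop = FALSE]
    rows[[k]] <- data.frame(stage = st$stage, predicate = st$predicate,
                            nIn = nIn, nOut = nrow(cur))
  }
  new("FunnelResult", stages = do.call(rbind, rows),
      genes = sort(cur$gene_id))
}

#' Chi-square test of citation presence for ligands vs non-ligands
#'
#' 2x2 table of (ligand vs non-ligand) against (no citation vs at least
#' one citation with the tissue keyword), Pearson chi-square with 1 df.
#'
#' @param ligandFlags logical vector (is the gene a ligand).
#' @param nPubs integer citation counts, same length.
#' @param correct apply Yates continuity correction.
#' @return list of class \code{clipContingency}.
#' @export
citationPresenceTest <- function(ligandFlags, nPubs, correct = FALSE) {
  stopifnot(length(ligandFlags) == length(nPubs), all(nPubs >= 0))
  chiSquare2x2(table(
    factor(ifelse(ligandFlags, "ligand", "non_ligand"),
           levels = c("ligand", "non_ligand")),
    factor(ifelse(nPubs >= 1, "cited", "uncited"),
           levels = c("cited", "uncited"))), correct = correct)
}

#' Compare lens-enrichment scores of ligands vs non-ligands
#'
#' Delegates to [rankSumTest()] (two-sided Wilcoxon).
#'
#' @param ligandFlags logical vector.
#' @param lensEnrichment numeric scores, same length.
#' @return two-sided p-value.
#' @export
lensEnrichmentCompare <- function(ligandFlags, lensEnrichment) {
  stopifnot(length(ligandFlags) == length(lensEnrichment))
  rankSumTest(lensEnrichment[ligandFlags], lensEnrichment[!ligandFlags])
}
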