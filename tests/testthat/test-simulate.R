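test_that("degenerate and forced configurations behave as documented", {
  tx0 <- simulateTranscriptome(clipSimConfig(nGenes = 0, nLigands = 0))
  expect_length(tx0$geneModels, 0)
  expect_length(tx0$utr3, 0)
  expect_length(tx0$truth$ligandGeneIds, 0)

  txAll <- simulateTranscriptome(clipSimConfig(nGenes = 12, nLigands = 12,
                                               seed = 2))
  expect_setequal(txAll$truth$ligandGeneIds, txAll$genes$gene_id)

  expect_error(clipSimConfig(nGenes = 5, nLigands = 6), "nLigands")
  expect_error(clipSimConfig(signalFraction = 1.5), "signalFraction")
  expect_error(clipSimConfig(baseComposition = c(A = 1, C = 1, G = 0,
                                                 T = 0)), "sum to 1")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- clipSimConfig(nGenes = 25, nLigands = 5, seed = 1)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  simulateClipStudy(cfg, outDir = d1)
  simulateClipStudy(cfg, outDir = d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6),
                     label = paste("bytes of", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted site intervals lie within their 3'UTR and carry the motif", {
  tx <- tinyStudy()
  ps <- tx$truth$plantedSites
  expect_gt(nrow(ps), 0)
  utrLen <- Biostrings::width(tx$utr3)[match(ps$gene_id, names(tx$utr3))]
  expect_true(all(ps$start >= 0))
  expect_true(all(ps$end <= utrLen))
  motif <- "TGTTGTTGTTGT"
  seqs <- as.character(tx$utr3)
  planted <- substr(seqs[ps$gene_id], ps$start + 1, ps$end)
  expect_true(all(planted == motif))
  ## genomic intervals sit inside the annotated 3'UTR feature
  gm <- tx$geneModels
  utr <- gm[gm$type == "three_prime_utr"]
  us <- GenomicRanges::start(utr)[match(ps$gene_id, utr$gene_id)]
  ue <- GenomicRanges::end(utr)[match(ps$gene_id, utr$gene_id)]
  expect_true(all(ps$genomic_start >= us & ps$genomic_end <= ue))
})

test_that("background cross-linking is uniform over the gene span", {
  ## one gene, no planted signal, ~10000 events
  cfg <- clipSimConfig(nGenes = 1, nLigands = 0, signalFraction = 0,
                       expressionMu = log(7000), expressionSigma = 0,
                       readsPerGeneScale = 1.5, intronProb = 1, seed = 5)
  tx <- simulateTranscriptome(cfg)
  sites <- simulateClipEvents(cfg, tx)
  expect_gt(sum(sites$score), 8000)
  gene <- tx$geneModels[tx$geneModels$type == "gene"]
  span <- c(GenomicRanges::start(gene), GenomicRanges::end(gene))
  ev <- rep(GenomicRanges::start(sites), sites$score)
  bins <- cut(ev, breaks = seq(span[1] - 0.5, span[2] + 0.5,
                               length.out = 21))
  gof <- suppressWarnings(chisq.test(table(bins)))
  expect_gt(gof$p.value, 0.01)
})

test_that("the shallow experiment scales event totals by its depth factor", {
  cfg <- clipSimConfig(nGenes = 150, nLigands = 0, signalFraction = 0,
                       seed = 8)
  tx <- simulateTranscriptome(cfg)
  n1 <- sum(simulateClipEvents(cfg, tx, cfg@depthFactorExp1, seed = 21)$score)
  n2 <- sum(simulateClipEvents(cfg, tx, cfg@depthFactorExp2, seed = 22)$score)
  ## ratio of Poisson sums: 0.2 within ~4 sd
  expected <- 0.2 * n1
  tol <- 4 * sqrt(expected)
  expect_lt(abs(n2 - expected), tol)
})

test_that("a gene with zero expression yields zero events", {
  cfg <- clipSimConfig(nGenes = 10, nLigands = 0, seed = 3)
  tx <- simulateTranscriptome(cfg)
  gRows <- which(tx$geneModels$type == "gene")
  tx$geneModels$expression[gRows[1]] <- 0
  gid <- tx$geneModels$gene_id[gRows[1]]
  sites <- simulateClipEvents(cfg, tx, seed = 4)
  expect_false(gid %in% sites$gene_id)
  ## depth factor must be positive
  expect_error(simulateClipEvents(cfg, tx, depthFactor = 0), "depthFactor")
})

test_that("site tables have unique positions and integer scores", {
  st <- tinyStudy()
  key <- paste(GenomicRanges::start(st$sites1),
               GenomicRanges::strand(st$sites1))
  expect_false(any(duplicated(key)))
  expect_true(all(st$sites1$score >= 1))
})

test_that("DE table is calibrated under the null and BH-adjusted", {
  ## null ligand shift: ligand and non-ligand log2FC indistinguishable
  cfg <- clipSimConfig(nGenes = 500, nLigands = 100, deLfcMean = 0,
                       deLfcSd = 0, seed = 6)
  truth <- list(ligandGeneIds = sprintf("gene%04d", 1:100))
  de <- simulateDeTable(cfg, truth, seed = 31)
  isLig <- de$gene_id %in% truth$ligandGeneIds
  expect_gt(rankSumTest(de$log2FC[isLig], de$log2FC[!isLig]), 0.01)
  ## BH conservatism: almost nothing passes FDR < 0.05 under the full null
  cfg0 <- clipSimConfig(nGenes = 500, nLigands = 0, seed = 7)
  de0 <- simulateDeTable(cfg0, list(ligandGeneIds = character()), seed = 32)
  expect_lte(mean(de0$fdr < 0.05), 0.01)
  expect_equal(de0$fdr, oracleBH(de0$pvalue), tolerance = 1e-12)
  ## single-gene table: FDR equals p
  de1 <- simulateDeTable(cfg0, list(ligandGeneIds = character()),
                         geneIds = "gene0001", seed = 33)
  expect_equal(de1$fdr, de1$pvalue)
})

test_that("annotation tables carry the planted ligand shifts", {
  cfg <- clipSimConfig(nGenes = 400, nLigands = 50, seed = 9)
  truth <- list(ligandGeneIds = sprintf("gene%04d", 1:50))
  ann <- simulateAnnotations(cfg, truth, seed = 41)
  expect_named(ann, c("gene_id", "n_pubs", "in_disease_list",
                      "lens_enrichment"))
  expect_true(all(ann$n_pubs >= 0))
  isLig <- ann$gene_id %in% truth$ligandGeneIds
  ## planted shifts produce enrichment in the expected direction
  expect_lt(lensEnrichmentCompare(isLig, ann$lens_enrichment), 0.01)
  expect_gt(mean(ann$in_disease_list[isLig]),
            mean(ann$in_disease_list[!isLig]))

  ## with all ligand effects removed, funnel tests are calibrated
  cfg0 <- clipSimConfig(nGenes = 400, nLigands = 50, pubsLigandMult = 1,
                        diseaseLigandRate = cfg@diseaseRate, lensShift = 0,
                        seed = 9)
  ps <- vapply(1:5, function(s) {
    a <- simulateAnnotations(cfg0, truth, seed = 50 + s)
    lensEnrichmentCompare(a$gene_id %in% truth$ligandGeneIds,
                          a$lens_enrichment)
  }, numeric(1))
  expect_gt(mean(ps), 0.05)

  ## extreme association: disease rate 1 for ligands, 0 otherwise
  cfgX <- clipSimConfig(nGenes = 400, nLigands = 50, diseaseRate = 0,
                        diseaseLigandRate = 1, seed = 9)
  annX <- simulateAnnotations(cfgX, truth, seed = 61)
  ov <- overlapTest(truth$ligandGeneIds,
                    annX$gene_id[annX$in_disease_list], annX$gene_id)
  expect_lt(ov$p.value, 1e-50)

  ## empty ligand set still yields all columns for all genes
  ann0 <- simulateAnnotations(cfg, list(ligandGeneIds = character()),
                              seed = 62)
  expect_equal(nrow(ann0), 400)
})

test_that("the alignment emitter round-trips through site derivation", {
  st <- tinyStudy()
  reads <- emitReadAlignments(st$sites1[1:200])
  rec <- deriveCrosslinkSites(reads, offset = -1)
  expect_equal(GenomicRanges::start(rec), GenomicRanges::start(st$sites1[1:200]))
  expect_equal(rec$score, st$sites1$score[1:200])
})
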