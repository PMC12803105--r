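#' Read cross-link sites from a BED6 file
#'
#' Expects one width-1 interval per line (0-based half-open, so end =
#' start + 1), the name column carrying the gene id (or "."), an integer
#' read-count score >= 1 and a +/- strand. Validation failures report the
#' offending line number. Parsing is deliberately strict and line-oriented
#' so malformed records are diagnosed precisely.
#'
#' @param path BED6 file path.
#' @return GRanges of width-1 sites (1-based internally) with \code{score}
#'   and \code{gene_id} columns.
#' @export
readCrosslinkBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(GRanges(score = integer(), gene_id = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 6L)
  if (length(bad))
    stop("line ", bad[1L], ": expected 6 tab-separated fields")
  m <- do.call(rbind, parts)
  start0 <- suppressWarnings(as.integer(m[, 2L]))
  end0 <- suppressWarnings(as.integer(m[, 3L]))
  score <- suppressWarnings(as.numeric(m[, 5L]))
  for (chk in list(
    list(is.na(start0) | is.na(end0), "non-integer coordinates"),
    list(!is.na(start0) & !is.na(end0) & end0 - start0 != 1L,
         "interval width must be 1"),
    list(is.na(score) | score != floor(score) | score < 1,
         "score must be an integer read count >= 1"),
    list(!m[, 6L] %in% c("+", "-"), "strand must be + or -"))) {
    if (any(chk[[1L]])) stop("line ", which(chk[[1L]])[1L], ": ", chk[[2L]])
  }
  GRanges(m[, 1L], IRanges(start0 + 1L, width = 1L), strand = m[, 6L],
          score = as.integer(score), gene_id = m[, 4L])
}

#' Write cross-link sites (or peaks) to BED6
#'
#' @param sites GRanges with \code{score} (and optionally \code{gene_id}
#'   used as the name column; peaks may carry \code{fdr}, appended to the
#'   name as \code{id|fdr=...}).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCrosslinkBed <- function(sites, path) {
  name <- if (!is.null(sites$gene_id)) sites$gene_id
  else rep(".", length(sites))
  if (!is.null(sites$fdr))
    name <- sprintf("%s|fdr=%.6g", name, sites$fdr)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   as.character(seqnames(sites)), start(sites) - 1L,
                   end(sites), name, as.integer(sites$score),
                   as.character(strand(sites)))
  writeLines(lines, path)
  invisible(path)
}

#' Write clusters to BED (score = cluster score)
#'
#' @param clusters GRanges with \code{gene_id}, \code{cluster_score} and
#'   optionally \code{region} (appended to the name).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeClusterBed <- function(clusters, path) {
  name <- clusters$gene_id
  if (!is.null(clusters$region))
    name <- paste(name, clusters$region, sep = "|")
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   as.character(seqnames(clusters)), start(clusters) - 1L,
                   end(clusters), name,
                   as.integer(clusters$cluster_score),
                   as.character(strand(clusters)))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Imports via rtracklayer (GTF's 1-based inclusive coordinates map
#' directly onto GRanges) and validates: every feature must carry a
#' gene_id, and UTR/CDS/intron features of one gene must not overlap one
#' another.
#'
#' @param path GTF file with gene / five_prime_utr / CDS / intron /
#'   three_prime_utr features.
#' @return GRanges with \code{type}, \code{gene_id} and, when present in
#'   the file, numeric \code{expression} on gene rows.
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("missing gene_id attribute")
  gr$type <- as.character(gr$type)
  if (!is.null(gr$expression))
    gr$expression <- as.numeric(gr$expression)
  sub <- gr[gr$type %in% c("five_prime_utr", "CDS", "intron",
                           "three_prime_utr")]
  for (g in unique(sub$gene_id)) {
    f <- sub[sub$gene_id == g]
    if (length(f) > 1L) {
      o <- order(start(f))
      if (any(start(f)[o][-1L] <= end(f)[o][-length(f)]))
        stop("overlapping features within gene ", g)
    }
  }
  gr
}

#' Write gene models to GTF
#'
#' Deterministic writer: one line per feature, gene rows carry the
#' expression attribute when available.
#'
#' @param geneModels GRanges with \code{type} and \code{gene_id}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGeneModels <- function(geneModels, path) {
  attr <- sprintf('gene_id "%s";', geneModels$gene_id)
  if (!is.null(geneModels$expression)) {
    has <- !is.na(geneModels$expression)
    attr[has] <- sprintf('%s expression "%.6g";', attr[has],
                         geneModels$expression[has])
  }
  lines <- sprintf("%s\tclipfunnel\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   as.character(seqnames(geneModels)), geneModels$type,
                   start(geneModels), end(geneModels),
                   as.character(strand(geneModels)), attr)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a TSV table with header
#'
#' TSV with a header row is the interchange format for all non-genomic
#' tables; writing is deterministic (no quoting, no row names, fixed NA
#' string).
#'
#' @param path file path.
#' @return \code{readTsv}: a data.frame.
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname readTsv
#' @param x data.frame to write.
#' @export
writeTsv <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a simulated (or equivalently formatted) study from disk
#'
#' Counterpart of [writeClipStudy()]; reads the analysis inputs only (the
#' ground-truth JSON, if present, is deliberately not loaded -- analysis
#' never consumes it).
#'
#' @param dir directory with genes.gtf, utr3.fa, sites_clip1.bed,
#'   sites_clip2.bed, de_table.tsv, annotations.tsv, expression.tsv.
#' @return list with geneModels, utr3, genes, sites1, sites2, deTable,
#'   annotations.
#' @export
readClipStudy <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input: ", p)
    p
  }
  list(geneModels = readGeneModels(need("genes.gtf")),
       utr3 = readDNAStringSet(need("utr3.fa")),
       genes = readTsv(need("expression.tsv")),
       sites1 = readCrosslinkBed(need("sites_clip1.bed")),
       sites2 = readCrosslinkBed(need("sites_clip2.bed")),
       deTable = readTsv(need("de_table.tsv")),
       annotations = readTsv(need("annotations.tsv")))
}
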