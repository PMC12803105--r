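---
title: "Methods: from cross-link events to prioritized RBP targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from cross-link events to prioritized RBP targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipfunnel)
```

# The problem

iCLIP experiments map where an RNA-binding protein (RBP) touches the
transcriptome at single-nucleotide resolution: reverse transcription
truncates at the cross-linked base, so the 5' end of each read marks a
protein–RNA contact. `clipfunnel` implements the downstream analysis for
such an experiment — modelled on CELF1 iCLIP in mouse lens, where the
protein acts as a post-transcriptional repressor and its de-repressed
targets are candidate cataract genes. The pipeline turns per-position read
counts into statistically significant peaks, merges them into scored
binding clusters, ranks genes by how strongly the protein binds their
3'UTR, and pushes the resulting ligand sets through enrichment statistics
and a literature/disease prioritization funnel.

Everything runs offline: a synthetic-data generator with planted ground
truth stands in for the sequencing data, so each stage is testable
end-to-end.

# Cross-link sites, peaks and clusters

**Sites.** A cross-link site is a (chromosome, strand, position) with a
score equal to its supporting read count. `deriveCrosslinkSites()` places
the site at the read's 5'-terminal position shifted by `offset` along the
read strand. The truncation convention puts the cross-link one nucleotide
upstream of the read start, so the default is `offset = -1`; `offset = 0`
uses the read terminus itself. Both conventions appear in the literature
and the choice only translates all coordinates by one, so no downstream
statistic changes.

**Peaks.** Significance of a site is judged by its *window height*: the
sum of site scores within ±3 nt (`window = 3`). The null model
redistributes the gene's events — each unit of score is one cross-link
event — uniformly over the gene's genomic span, `nPerm` times. For an
observed height $h$,

$$\widehat{FDR}(h) = \frac{1}{B}\sum_{b=1}^{B}
  \frac{\#\{\text{random occupied positions with height} \ge h\}_b}
       {\#\{\text{observed sites with height} \ge h\}},$$

clipped to $[0,1]$. Raw ratios need not be monotone in $h$, so they are
monotonized by a running minimum as $h$ increases, which makes the
"FDR < 0.05" cut well defined: a taller site can never have a larger FDR.
Sites passing `alpha = 0.05` are peaks.

Two modelling choices deserve note. First, the randomization domain is
the full genomic gene span, introns included — the simplest null that
preserves the gene's total signal; restricting the domain to the mature
transcript would make intronic background look more surprising than it
is. Second, events (not sites) are redistributed, so a gene whose signal
is concentrated in few positions is penalized against a null with the
same sequencing depth.

**Clusters.** Peaks closer than 20 nt (strictly) merge transitively into
clusters. The cluster interval extends `flank = 3` nt beyond the outer
member peaks — tying "adjacent signal" to the same ±3 nt window used for
significance, the least arbitrary reading of an otherwise undefined
adjacency — and the cluster score is the sum of member peak scores plus
all non-peak site scores inside the interval. Each cluster is assigned
the region of its midpoint (3'UTR > 5'UTR > CDS > intron on overlap;
"other" outside all features).

# CLIP scores and ligand retention

A gene's **CLIP score** is the sum of its 3'UTR cluster scores — binding
elsewhere does not count, because the repressive mechanism under study
acts through 3'UTRs. `retainLigands()` keeps genes in the top 10% of CLIP
scores and removes genes in the top 0.5% of expression, because very
abundant transcripts (crystallins, in the lens) accumulate nonspecific
signal in proportion to their abundance. Both cuts are rank counts,
$k = \lceil \mathrm{frac} \times N\rceil$, with ties broken by gene id —
deterministic and free of any quantile-definition dependency. The two
thresholds are computed independently on the full population and then
combined as a set difference; whether the original analysis recomputed
the CLIP threshold after the expression exclusion is not documented, so
that variant is available as `thresholdAfterExclusion = TRUE` (it changes
at most a handful of borderline genes).

The profile population defaults to *all expressed genes* (CLIP score 0
without clusters). `onlyWithClusters = TRUE` restricts to genes with at
least one 3'UTR cluster, which is the population shown in the study's
score-versus-expression figure; on deeply sequenced real data the two
populations nearly coincide, because most expressed genes carry at least
one cluster. On sparse simulations they do not, and the all-expressed
default keeps the "top 10%" meaningful.

**UGU enrichment.** CELF-family binding sites are UGU-rich. For each gene
the cluster with the highest overlapping-UGU count is kept
(`maxUguPerGene()`, T≡U, case-insensitive), and a 2×2 Pearson chi-square
(no continuity correction, matching the study's tests) compares retained
vs non-retained genes above/below a UGU threshold of 3.

# Ranked-list enrichment (GSEA-like)

Genes are ranked by $\mathrm{sign}(\log_2 FC)\times(-\log_{10} FDR)$ from
a knockout-vs-wild-type differential-expression table, most significantly
up-regulated first. Zero FDRs are capped at half the smallest non-zero
FDR — rank-preserving and finite. The enrichment statistic is the classic
unweighted Kolmogorov–Smirnov-like running sum (+1/|S| at hits,
−1/(N−|S|) at misses), whose extremum is the signed enrichment score;
the weighted GSEA variant needs a trustworthy per-gene weight, which a
signed-FDR rank does not reliably provide. The permutation null resamples
same-size gene sets from the ranked universe (the package holds no
sample-level expression, so phenotype permutation is unavailable).

The permutation p-value defaults to the **two-sided** tail
$p = (1 + \#\{|ES_b| \ge |ES_{obs}|\})/(B+1)$. The familiar one-sided-
on-observed-sign convention is available as `alternative = "greater"` /
`"less"`, but it is *not* uniform under the null: the signed ES is
symmetric, so conditioning the tail on the observed sign doubles the
density of small p-values. The two-sided form is exactly uniform up to
ties in $|ES|$; at small list sizes those ties make it slightly
conservative, which is visible in calibration checks below a few hundred
genes and negligible at study scale.

# The prioritization funnel

`runFunnel()` applies six filters in the study's order: expressed →
ligand in at least one experiment → ligand in both → upper quarter of
per-gene literature citations with the tissue keyword → disease-catalogue
membership → upper quarter of the lens-enrichment score. Quartile cuts
use the same $\lceil 0.25 N\rceil$ rank rule and are computed **within
each stage's input population** — the funnel arrows imply sequential
filtration — so permuting stages can legitimately change the result. The
published counts (10,640 → 689 → 293 → 39 → 17 → 11) cannot be reproduced
without the deposited tables and the original PubMed/Cat-Map/iSyTE
snapshots; notably 293 × 0.25 ≈ 73 ≠ 39, suggesting the original
citation quartile was taken over a larger population or with an
additional unstated criterion. The package documents its own rule and
exposes the stage list for replacement.

# Reporter statistics

**Dual luciferase.** Wells are normalized sequentially: firefly/renilla
per well; median over ≥4 technical replicates per (construct, condition,
biological replicate) — the median per the study's design, with
biological replicates as test units; division by the control-construct
median of the *same condition and biological replicate* (the legend's
sequential wording does not pin this pairing; within-replicate pairing
maximizes batch-effect cancellation); and optional division by the
control-effector value of the same construct and replicate. Reported as
log2, the chain is exactly multiplicative: any per-replicate rescaling of
firefly readings cancels. Per-construct one-sample t tests against 0 are
BH-adjusted across the batch; zero-variance constructs report p = 1 with
a flag rather than failing a whole batch.

**Morphometry.** Eye and lens areas are diameter products
(minor × major) — the study's planimetric proxy — with lens/eye ratios
per side and two-sided paired t tests across larvae. Unpaired larvae are
dropped per endpoint with a warning.

# The synthetic-data generator

`simulateClipStudy()` emulates the study's structure, not its scale:

* one synthetic chromosome of single-isoform genes (5'UTR 150 nt, CDS
  900 nt, one 400 nt intron in half the genes, log-normal 3'UTR of mean
  800 ± 300 nt), plus-strand by default with a `minusStrandFrac` switch
  for strand handling;
* 500 genes with log-normal expression (meanlog 3, sdlog 1, TPM-like)
  and, at `readsPerGeneScale = 1.5`, about 50 cross-link events per gene
  in the first pseudo-experiment — enough signal for stable peak calls at
  desk scale;
* two pseudo-experiments at depth factors 1 and 0.2, mirroring the
  lower unique-read yield of the harsher RNase digestion;
* 50 ligand genes (10%) carrying three planted tandem-UGU sites
  (`TGTTGTTGTTGT`) in the 3'UTR; each ligand event falls inside a planted
  site with probability `signalFraction = 0.8`, otherwise uniformly over
  the gene span — a deliberately strong but not saturating contact
  density;
* a DE table in which ligands are up-regulated by 1 log2 unit (sd 0.25)
  against measurement noise of sd 0.5, giving null genes exactly uniform
  p-values by construction;
* annotation resources with negative-binomial citation counts (ligand
  mean ×5), Bernoulli disease membership (5% background, 30% ligands)
  and a +1 sd ligand shift in the continuous lens-enrichment score.

Ground truth (ligand ids, planted intervals in 0-based half-open
within-UTR coordinates) is written alongside the data and never consumed
by analysis code. Per-stage seeds derive from the global seed by a fixed
hash of the stage name, so any stage can be re-run in isolation and a
fixed configuration + seed reproduces every output byte for byte.

What the generator does *not* model: PCR duplicates and UMIs, sequencing
error, multi-isoform genes, cross-link sequence bias, or correlated
background. Passing tests therefore demonstrate the correctness and
calibration of the algorithms under a clean generative model, not
robustness to those real-data artefacts.

# Numerical and engineering choices

* Coordinates are 1-based closed intervals internally (the
  GenomicRanges idiom); BED is converted at the boundary and the
  ground-truth JSON keeps 0-based half-open intervals.
* The permutation FDR core works on plain integer vectors (sorted-
  position counting, $O(n\log n)$ per permutation) so a thousand genes
  at 100 permutations complete in seconds; results are identical to the
  naive tabulation, which the tests verify against a brute-force oracle
  sharing the same randomization stream.
* Standard statistics are delegated: chi-square to
  `stats::chisq.test(correct = FALSE)`, Wilcoxon to
  `stats::wilcox.test` (exact for small untied samples, otherwise the
  tie-corrected normal approximation), BH to `stats::p.adjust`, and
  FASTA/pattern work to Biostrings. The test suite checks each against
  an independent brute-force implementation (hand chi-square, full
  enumeration of rank-sum assignments, manual step-up, regex-lookahead
  motif counting).
* Degenerate inputs fail loudly and specifically: zero-margin
  contingency tables, empty gene spans, missing normalization pairings,
  sets not contained in their universe, missing funnel columns.

# Problem sizes used in the automated checks

The bundled checks run at: 200 genes for null FDR calibration
(about 10,000 sites), 1000 genes / 100 planted ligands for recovery and
UGU enrichment, 500 repetitions of the full permutation procedure (199
permutations each over 200-gene rankings) for null calibration of the
GSEA p-value, 800 genes / 1000 permutations for the powered GSEA run, and
two complete pipeline executions at the 500-gene defaults for the
byte-identity check. These sizes keep every property estimate well away
from its acceptance boundary while completing in a few minutes on one
core.

# Known limitations

* The permutation FDR estimates a global error rate per gene; genes with
  very few events have coarse, conservative FDRs (a single event can
  never be significant — any random placement produces one occupied
  position of height ≥ 1).
* The signed-FDR ranking collapses effect size and significance into one
  axis; two genes with equal FDR but different fold changes tie up to
  the |log2FC| tie-break.
* Funnel quartiles are rank-based and therefore jumpy on very small
  stage inputs (a one-gene stage keeps its single gene).
* The unweighted ES treats all ranks equally; depletion at the bottom of
  the list contributes to a negative score with the same weight as
  enrichment at the top contributes to a positive one.
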