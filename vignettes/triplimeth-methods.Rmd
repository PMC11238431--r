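---
title: "Methods: comparative epigenomics of a triplicated plant genome"
author: "triplimeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative epigenomics of a triplicated plant genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`triplimeth` implements the downstream comparative-epigenomics analyses used
to characterise a plant genome carrying an ancient whole-genome triplication
(WGT): calling differentially methylated regions (DMRs) from bisulfite
cytosine reports, profiling DNA methylation around genes, transposable
elements (TEs) and structural-variant (SV) breakpoints, quantifying
presence/absence-variant (PAV) enrichment at feature boundaries, classifying
duplicate genes from syntenic collinearity, and summarising consensus
N6-methyladenosine (m6A) sites on transcripts. Upstream tool chains (read
alignment, methylation extraction, SV calling, basecalling) are out of
scope: the package starts from their standard outputs (GFF3, VCF with
cuteSV-style INFO keys, Bismark-style CX reports, site and expression
tables).

All interval arithmetic uses the Bioconductor convention: 1-based, closed
intervals in `GRanges`/`IRanges` containers, with `rtracklayer` and
`VariantAnnotation` converting at the file boundary. This keeps every
coordinate operation on the containers the rest of the installed stack
expects; positions printed by the package (TSS, breakpoints, DMR bounds) are
therefore 1-based genomic positions.

# The DMR caller

Methylation levels are always *weighted* levels: the pooled ratio
sum(methylated reads) / sum(all reads) over covered cytosines, so deeply
covered sites carry proportionally more weight and a region with no covered
site is *undefined* (`NA`), never 0.

DMRs are called per context (CG, CHG, CHH) on 200-bp sliding windows with a
100-bp step. Per window and replicate, the weighted level is computed over
context cytosines with coverage >= `min_cov` (default 4 reads); a window is
*tested* only if every replicate has at least `min_sites` (default 4) such
cytosines. Across the two groups, a one-way ANOVA on the per-replicate
window levels gives a p-value; Benjamini–Hochberg over all tested windows of
the context gives q. Windows with q < 0.05 *and* an absolute group-mean
difference of at least the context cutoff — 0.5 for CG and CHG, 0.1 for
CHH — are candidates; same-direction candidates separated by at most one
step are merged, levels recomputed over the merged span, and merged regions
failing the cutoff after recomputation are dropped, so every reported DMR
satisfies its cutoff and FDR exactly as stored. Direction (`hyper`/`hypo`)
is relative to the first (treatment) group.

Two choices here were genuinely open and are the package's own:

* **The ANOVA observation unit.** The procedure's ANOVA needs replicate
  observations; we use the per-replicate window-weighted level. This makes
  the test sensitive to consistent between-group differences and robust to
  depth differences between replicates.
* **The step and the merge.** "Sliding" windows are given a 100-bp
  (half-window) step, the common convention, and overlapping or adjacent
  (gap <= step) significant windows of the same direction are merged. Both
  the tested windows and the merged regions are returned, since either may
  be the quantity a study reports.

`min_cov = 4` and `min_sites = 4` are standard bisulfite filtering values;
both are arguments.

# Metaprofiles

`metaprofile()` aligns features 5'-to-3' (minus-strand features are
flipped), splits 2-kb flanks into fixed 100-bp bins and the feature body
into 20 equal fractions (`scaled_body`) or fixed 100-bp bins (`absolute`),
and pools one weighted level per bin across all features. Body binning uses
the site's midpoint offset, which makes plus- and minus-strand orientations
exactly symmetric. Features shorter than the number of body bins are
skipped and counted. Breakpoint profiles (`breakpoint_methylation_profile`)
use the same pooling over fixed 200-bp bins spanning +-8 kb of each
breakpoint, compare with the genome-wide weighted level of the context, and
test, per breakpoint, the central window (+-400 bp) against the same
breakpoint's distal flank (outermost 400 bp) with the Wilcoxon signed-rank
test; both zone widths are arguments. Breakpoints within one flank of a
contig end are dropped (partial windows would bias bin means) and counted.
Boundary densities (`boundary_density`) count breakpoints per feature per
100-bp bin around each feature edge, with the right edge flipped so
positive offsets always point into the feature.

# The statistical kernel

The Wilcoxon tests are exact by complete enumeration in the small-sample
regimes where enumeration is fast: all label assignments for the rank-sum
test when the smaller group has at most 8 observations (and no tied value
spans the groups, and the binomial count stays below 2 x 10^6 — one sample
of size 8 against a very large one is combinatorially unbounded), and all
2^n sign patterns for the signed-rank test when n <= 12. Outside those
regimes a normal approximation with mid-rank tie correction and continuity
correction is used; the `method` field of every result records which route
produced the p-value. Zero paired differences are discarded before ranking
(Wilcoxon's convention); an all-zero input returns p = 1 with
`n_effective = 0` and a warning rather than an error. Ties take mid-ranks
everywhere. The two-group ANOVA and the pooled t-test are linked by
t^2 = F, which the test suite asserts numerically, and the two-sided pooled
t p-value is reported as the equivalent F-tail probability.

One caveat is documented rather than resolved: class-wise expression
comparisons between *unpaired* gene sets use the rank-sum (Mann–Whitney)
test, even where a paired test is named in comparable published figure
legends, because no pairing of, say, WGT genes with singletons exists.

# Duplicate-gene classification

Genes are ranked per chromosome by start position (ties by end, then id).
Homolog pairs become anchors on the rank dot-plot of their chromosome pair,
and `chain_collinear_blocks()` extracts maximal monotone chains (both
orientations) with rank gaps of at most `max_gap = 25` in either genome,
greedily and without anchor reuse; chains with fewer than `min_anchors = 5`
anchors are discarded. These are MCScanX-like defaults and are arguments.
Intra-chromosomal anchors within `self_gap = 10` ranks of the diagonal are
excluded before chaining — the standard removal of tandem/proximal
self-matches, without which runs of tandem pairs on one chromosome would
chain into spurious "syntenic" blocks.

Classification precedence is wgt > tandem > proximal > dispersed: an anchor
gene in any block is `wgt` (WGT retention being the analysis target); a
non-anchor with a rank-adjacent same-chromosome paralog is `tandem`; with a
paralog within `proximal_gap = 10` intervening genes, `proximal`; any
remaining paired gene is `dispersed`; unpaired genes are `singleton`. WGT
genes are grouped by transitive closure over anchors; a group's copy number
is its number of distinct syntenic loci, and groups with more than three
loci are reported as-is but excluded from the 2-/3-copy dichotomy.

# m6A summarisation

A consensus site must be present with probability >= 0.9 in *every*
replicate at the *exact* (transcript, position); both the threshold (the
conventional m6anet cutoff — the source studies rarely print one) and the
exact-position rule are explicit choices, the latter because positional
tolerance would need an arbitrary window. The DRACH matcher treats T as U
and matches D = A/G/U, R = A/G, A, C, H = A/C/U. The metagene axis
concatenates 5'UTR, CDS and 3'UTR, each normalised to unit width with
10/20/20 bins — enough to resolve a 3'UTR peak without starving bins at
realistic site counts; sites on transcripts lacking any annotated region
are excluded and counted. The High/Low m6A expression split is
operationalised as modified vs unmodified members within homoeolog groups
that contain both; groups entirely on one side carry no contrast and are
excluded.

# The synthetic-data generator

Every analysis is validated end-to-end on seeded synthetic data with
planted ground truth. The generator emulates:

* **Genome and annotation.** Random sequence (GC 0.4) over nine
  chromosomes; intronless genes (0.9–3 kb) with 10%/70%/20%
  UTR5/CDS/UTR3 splits; TEs of the four repeat classes dropped into
  gene-free space. The duplication plan places tandem pairs rank-adjacent,
  proximal pairs with one intervening gene, dispersed pairs on different
  chromosomes (on chromosome pairs hosting no syntenic segment, so stray
  anchors cannot extend a real block), and syntenic segments as
  order-preserving 10-gene runs copied to two or three chromosomes. The
  default plan — 100 singletons, 50 tandem, 50 proximal and 50 dispersed
  pairs, 150 WGT genes of which 30 sit in 3-copy groups — makes the true
  3-copy fraction exactly 20%.
* **Methylomes.** Per cytosine: coverage ~ Poisson(20); a site-level
  methylation probability ~ Beta centred on the baseline of the covering
  feature class (TE class overrides genic overrides intergenic) with
  precision 50, giving the replicate overdispersion that makes the DMR
  ANOVA non-degenerate; methylated reads ~ Binomial. Baselines follow
  plant-typical context hierarchies (e.g. CG: TE 0.6–0.8, gene 0.2,
  intergenic 0.3; CHH: everywhere low). Planted DMRs (default: 200 regions
  of 400 bp, delta 0.6 in CG) shift the group-B mean inside their
  interval; they are placed outside TEs so the shifted mean stays
  realisable below 1. Breakpoint effects add a CHH delta (0.3 within
  +-500 bp) for both groups. Two groups of three replicates each match the
  smallest replicated bisulfite design the DMR test supports.
* **SVs, expression, m6A.** SV counts per type default to 300 INS / 100
  DEL plus minor types, with breakpoints uniform or TE-boundary-biased by a
  configurable odds weight; log-normal FPKM with a +1 log-scale shift for
  WGT genes (the detectable-effect regime); m6A sites drawn per transcript
  with class-dependent modification probabilities (WGT highest at 0.12,
  singletons 0.05), a 67.41% 3'UTR region bias, DRACH 5-mers with A-heavy
  weights (reproducing AAACU/AAACA-type top k-mers), 90% per-replicate
  detection and 10% false positives. Site records carry their 5-mer
  directly; transcript sequences are not materialised because no
  downstream operation reads them.

Each sub-generator draws from its own RNG stream derived from the master
seed, so adding one generator never perturbs another, and all outputs are
byte-identical under a fixed seed.

What passing these suites does *not* show: the generator has no sequence
evolution, no correlated methylation along the genome beyond feature
baselines, no coverage biases, introns, alternative isoforms or mapping
artefacts. Recovery rates on this synthetic data are therefore upper bounds
on real-data behaviour, and the aggregation checks (SV tables, fraction
arithmetic) are the only places where published numbers are reproduced
exactly.

# Validation problem sizes and numerical choices

The validation suites run at desk scale, chosen so every check completes on
one CPU while keeping each estimate's sampling error far from its
acceptance margin: DMR recovery and null calibration on a 1-Mb genome with
2 x 3 replicates at depth 20 (about 10,000 tested CG windows); metaprofile
flatness over 500 genes (binomial SE per bin well under the +-0.02 band);
breakpoint profiles over 300 planted insertions; m6A suites at >= 2,000
sites (SE of the 3'UTR fraction about 1%). The collinearity null
calibration runs on a 9 x 600-gene ranking rather than the 550-gene plan
genome: with only ~60 genes per chromosome, a 25-rank gap window spans most
of the dot-plot and *any* anchor set chains — an artefact of the miniature,
not of the chaining, since real chromosomes carry thousands of genes. The
chaining parameters themselves are never changed for the null.

Degenerate inputs resolve deterministically: zero within- and between-group
variance gives F = 0, p = 1; an all-zero paired sample warns and returns
p = 1 with zero effective observations; empty record sets summarise to zero
counts with an undefined (NA) fraction; a zero-coverage region has an
undefined, not zero, level. Reported percentages round half away from zero
to two decimals (base R's half-to-even would change printed second
decimals). One documented claim was dropped as mathematically false: BH
adjustment is not idempotent (p = (0.4, 0.5, 0.9) adjusts to
(0.75, 0.75, 0.9), which re-adjusts to (0.9, 0.9, 0.9)); the suite asserts
the true BH properties instead.

# Interfaces and limitations

The package is used from R; the exported functions plus this vignette are
the interface, and `scripts/acceptance.R` reproduces the headline numbers
from the command line. Known limitations: no BAM/CRAM or FASTQ handling
(extraction belongs to Bismark et al.); no single-cytosine differential
tests or HMM segmentation; homolog pairs are an input, not computed (no
BLAST wrapper); no Ks dating or cross-species synteny; m6A analysis starts
from site tables, not signal data.
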