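# triplimeth

Comparative epigenomics of duplicated plant genomes: DMR calling,
SV-breakpoint methylation, duplicate-gene classification and m⁶A profiles.

## What this package is for

Plant genomes that went through an ancient whole-genome triplication (WGT)
— lettuce being the motivating case, with nine chromosomes and thousands of
retained triplication paralogs — pose a recurring set of downstream
questions once the standard tool chains (Bismark, cuteSV, m6anet, an
annotation pipeline) have produced their outputs:

* Where did DNA methylation change between two conditions (e.g. callus vs
  seedling), and which genes do those regions touch?
* How does methylation behave around genes, transposable elements and
  structural-variant breakpoints — in particular, are presence/absence
  variants (PAVs = insertions + deletions) enriched at repeat boundaries,
  and do breakpoints carry elevated CHH methylation?
* Which genes are retained WGT duplicates (2-copy or 3-copy), which are
  tandem/proximal/dispersed duplicates, and how do expression and m⁶A
  modification differ between those classes?

`triplimeth` implements these analyses as tested, reusable R functions for
researchers working from the standard files: GFF3 annotations, VCFs with
cuteSV-style INFO keys, Bismark-style per-cytosine (CX) reports, FPKM
tables, and per-replicate m⁶A site tables.

## The methods at the core

**DMR calling.** Per context *c* ∈ {CG, CHG, CHH}, 200-bp windows slide at
a 100-bp step. For window *w* and replicate *r* the weighted level is
*m(w,r)* = Σ meth / Σ (meth+unmeth) over context cytosines with coverage ≥ 4;
windows with ≥ 4 such cytosines in every replicate are tested with a
one-way ANOVA across the two replicate groups, p-values are
Benjamini–Hochberg adjusted over all tested windows, and windows with
*q* < 0.05 and |Δ| = |m̄₍A₎ − m̄₍B₎| ≥ 0.5 (CG, CHG) or ≥ 0.1 (CHH) are
merged (gap ≤ step, same direction) into DMRs.

**Breakpoint/boundary profiles.** Weighted levels pooled into fixed bins
around breakpoints (±8 kb) or feature boundaries (±2 kb), compared against
the genome-wide context mean, with per-anchor central-vs-distal Wilcoxon
signed-rank tests. The small-sample Wilcoxon tests (rank-sum and
signed-rank) are exact by complete enumeration of the permutation null.

**Duplicate classification.** Homolog pairs become anchors on the
per-chromosome gene-rank dot-plot; monotone chains with rank gaps ≤ 25 and
≥ 5 anchors are collinear blocks. Precedence wgt > tandem (rank-adjacent
paralog) > proximal (≤ 10 intervening genes) > dispersed; unpaired genes
are singletons. WGT genes group by transitive closure over anchors; group
copy number = distinct syntenic loci.

**m⁶A.** Consensus sites are (transcript, position) pairs with probability
≥ 0.9 in every replicate; 5-mers are tested against DRACH
(D = A/G/U, R = A/G, H = A/C/U, central A); metagene distributions map
sites onto a normalised 5′UTR/CDS/3′UTR axis.

A seeded synthetic-data generator (`sim_config()`, `simulate_*()`) plants
ground-truth DMRs, breakpoint effects, duplication classes, expression
shifts and m⁶A sites, so every stage is validated end-to-end. See the
methods vignette (`vignettes/triplimeth-methods.Rmd`) for models,
parameters and design choices.

## Worked example

```r
library(triplimeth)

# aggregate a published SV table: counts per type -> total and PAV fraction
sv_summary(c(INS = 52741, DEL = 64147, DUP = 4164, INV = 4302, TRANS = 2327))
#> SVs: INS=52741, DEL=64147, DUP=4164, INV=4302, TRANS=2327 | total=127681, PAV=116888 (91.55%)
summarize_fraction(787, 4612)   # percent of WGT genes with 3 retained copies
#> [1] 17.06

# end-to-end DMR calling on a simulated two-group bisulfite experiment
cfg <- sim_config(seed = 1, chrom_lengths = c(Chr1 = 300000L),
                  plan = dup_plan(singleton = 40, tandem_pairs = 0,
                                  proximal_pairs = 0, dispersed_pairs = 0,
                                  seg2 = 0, seg3 = 0),
                  te_count = 15L)
ann <- simulate_annotation(cfg)
cfg$dmrs <- plant_dmrs(ann, n = 30, width = 400, delta = 0.6,
                       context = "CG", seed = 1)     # planted ground truth
ms  <- simulate_methylome_set(ann, cfg)              # A1..A3, B1..B3
res <- call_dmrs(ms[1:3], ms[4:6], context = "CG")
res$n_tested; length(res$dmrs)
#> [1] 2992
#> [1] 30
head(res$dmrs, 3)
#> GRanges object with 3 ranges and 8 metadata columns:
#>       seqnames      ranges strand |     context   level_a   level_b     delta
#>   [1]     Chr1 11001-11300      * |          CG  0.323996  0.883008 -0.559012
#>   [2]     Chr1 17201-17600      * |          CG  0.305272  0.840548 -0.535275
#>   [3]     Chr1 20301-20700      * |          CG  0.210764  0.761472 -0.550708
#>           p_value     q_value   direction n_windows
#>   [1] 5.27293e-06 0.000447390        hypo         2
#>   [2] 7.84836e-06 0.000512947        hypo         3
#>   [3] 2.90917e-06 0.000322379        hypo         3
```

Of 2,992 tested 200-bp windows, exactly the 30 planted regions come back as
DMRs: each with its pooled group levels (`level_a`, `level_b`), the group
difference `delta` (here ≈ −0.56: group B was shifted up by 0.6, so the
regions are *hypo* relative to group A), the window ANOVA p, the BH q, and
the number of merged windows.

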