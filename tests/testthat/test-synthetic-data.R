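# Generator: determinism, plan realisation, planted-signal calibration,
# parser round-trips.

test_that("generation is deterministic under the seed and responds to it", {
  cfg <- fx_small_ann()$cfg
  ann1 <- simulate_annotation(cfg)
  ann2 <- simulate_annotation(cfg)
  expect_identical(as.character(ann1$genome), as.character(ann2$genome))
  expect_identical(ann1$truth$gene_table, ann2$truth$gene_table)
  expect_identical(simulate_methylome(ann1, cfg, "A", 1),
                   simulate_methylome(ann2, cfg, "A", 1))
  cfg3 <- cfg; cfg3$seed <- cfg$seed + 1L
  ann3 <- simulate_annotation(cfg3)
  expect_false(identical(as.character(ann1$genome), as.character(ann3$genome)))
  # replicates and groups draw from distinct streams
  expect_false(identical(simulate_methylome(ann1, cfg, "A", 1),
                         simulate_methylome(ann1, cfg, "A", 2)))
})

test_that("the duplication plan is realised in gene ranks and homolog pairs", {
  ann <- fx_plan_ann()
  ranks <- rank_genes(ann$genes)
  tab <- merge(ann$truth$gene_table, ranks, by = "gene_id")
  pairs <- ann$pairs

  # tandem members are rank-adjacent on one chromosome
  tan <- pairs[grepl("^TAN", pairs$gene_a)]
  ra <- ranks[match(tan$gene_a, ranks$gene_id)]
  rb <- ranks[match(tan$gene_b, ranks$gene_id)]
  expect_true(all(ra$chrom == rb$chrom))
  expect_true(all(abs(ra$rank - rb$rank) == 1L))

  # proximal members have exactly the configured spacing
  prx <- pairs[grepl("^PRX", pairs$gene_a)]
  ra <- ranks[match(prx$gene_a, ranks$gene_id)]
  rb <- ranks[match(prx$gene_b, ranks$gene_id)]
  expect_true(all(ra$chrom == rb$chrom))
  expect_true(all(abs(ra$rank - rb$rank) == 2L))  # one intervening gene

  # dispersed members never share a chromosome
  dsp <- pairs[grepl("^DSP", pairs$gene_a)]
  ra <- ranks[match(dsp$gene_a, ranks$gene_id)]
  rb <- ranks[match(dsp$gene_b, ranks$gene_id)]
  expect_true(all(ra$chrom != rb$chrom))

  # WGT groups: every group has as many members as its copy number, and
  # every planted object exists in the annotation
  wgt <- ann$truth$wgt_groups
  sizes <- wgt[, .N, by = .(group_id, copy_number)]
  expect_true(all(sizes$N == sizes$copy_number))
  expect_true(all(c(pairs$gene_a, pairs$gene_b) %in% ann$genes$gene_id))
  expect_true(all(table(ann$truth$classes$class)[
    c("singleton", "tandem", "proximal", "dispersed", "wgt")] ==
      c(100, 100, 100, 100, 150)))
})

test_that("an infeasible duplication plan errors before writing", {
  expect_error(simulate_annotation(
    sim_config(seed = 1, chrom_lengths = c(Chr1 = 200000L),
               plan = dup_plan(dispersed_pairs = 5, seg2 = 0, seg3 = 0,
                               tandem_pairs = 0, proximal_pairs = 0))),
    "infeasible")
  expect_error(simulate_annotation(
    sim_config(seed = 1, chrom_lengths = c(Chr1 = 50000L),
               plan = dup_plan(singleton = 200, tandem_pairs = 0,
                               proximal_pairs = 0, dispersed_pairs = 0,
                               seg2 = 0, seg3 = 0))),
    "infeasible")
})

test_that("zero baselines give a fully unmethylated methylome", {
  cfg <- sim_config(seed = 103, chrom_lengths = c(Chr1 = 60000L),
                    plan = dup_plan(singleton = 10, tandem_pairs = 0,
                                    proximal_pairs = 0, dispersed_pairs = 0,
                                    seg2 = 0, seg3 = 0),
                    te_count = 5L, baselines = uniform_baselines(0))
  ann <- simulate_annotation(cfg)
  calls <- simulate_methylome(ann, cfg, "A", 1)
  expect_true(all(calls$count_meth == 0L))
  expect_true(any(calls$count_unmeth > 0L))
})

test_that("planted DMRs shift the observed group difference by ~delta", {
  cfg <- sim_config(seed = 104, chrom_lengths = c(Chr1 = 300000L),
                    plan = dup_plan(singleton = 40, tandem_pairs = 0,
                                    proximal_pairs = 0, dispersed_pairs = 0,
                                    seg2 = 0, seg3 = 0),
                    te_count = 10L)
  ann <- simulate_annotation(cfg)
  cfg$dmrs <- plant_dmrs(ann, n = 30, width = 400, delta = 0.6,
                         context = "CG", seed = 104)
  ms <- simulate_methylome_set(ann, cfg)
  in_dmr <- function(calls) {
    dt <- data.table::as.data.table(calls)[context == "CG"]
    gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
    truth <- GenomicRanges::GRanges(cfg$dmrs$chrom,
                                    IRanges::IRanges(cfg$dmrs$start, cfg$dmrs$end))
    weighted_level(dt[IRanges::overlapsAny(gr, truth)])
  }
  lev_a <- mean(vapply(ms[1:3], in_dmr, numeric(1)))
  lev_b <- mean(vapply(ms[4:6], in_dmr, numeric(1)))
  expect_lt(abs((lev_b - lev_a) - 0.6), 0.1)
})

test_that("flagged SV breakpoints elevate nearby CHH means by ~delta", {
  small <- fx_small_ann()
  cfg <- small$cfg; ann <- small$ann
  svs <- simulate_svs(ann, cfg)
  expect_gt(sum(svs$breakpoints$flagged), 0)
  cfg$sv_chh <- svs$sv_chh
  calls <- simulate_methylome(ann, cfg, "A", 1)
  dt <- data.table::as.data.table(calls)[context == "CHH"]
  gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
  bp <- svs$breakpoints[svs$breakpoints$flagged, ]
  near <- GenomicRanges::GRanges(bp$chrom,
                                 IRanges::IRanges(pmax(1, bp$pos - 500), bp$pos + 500))
  lev_near <- weighted_level(dt[IRanges::overlapsAny(gr, near)])
  # compare against unaffected sites, not the genome mean (which includes
  # the elevated windows themselves)
  lev_far <- weighted_level(dt[!IRanges::overlapsAny(gr, near)])
  expect_lt(abs((lev_near - lev_far) - 0.3), 0.05)

  # boundary weight 0 means uniform placement: no TE-boundary pile-up
  expect_equal(cfg$sv_plan$boundary_weight, 0)
})

test_that("empty SV plan yields a header-only VCF", {
  small <- fx_small_ann()
  cfg <- small$cfg
  cfg$sv_plan$n[] <- 0L
  svs <- simulate_svs(small$ann, cfg)
  expect_equal(nrow(svs$records), 0L)
  f <- tempfile(fileext = ".vcf")
  write_sv_vcf(svs$records, f, contigs = cfg$chrom_lengths)
  expect_true(all(startsWith(readLines(f), "#")))
})

test_that("expression generator: exchangeable classes under zero shift, detectable under shift", {
  ann <- fx_plan_ann()
  base_cfg <- sim_config(seed = 1)
  base_cfg$expr$class_shifts[] <- 0
  pvals <- vapply(1:50, function(s) {
    cfg <- base_cfg; cfg$seed <- 1000L + s
    expr <- simulate_expression(ann$truth$classes, cfg)
    per_gene <- expr[, .(fpkm = mean(fpkm)), by = gene_id]
    lab <- merge(per_gene, ann$truth$classes, by = "gene_id")
    wilcoxon_rank_sum(lab$fpkm[lab$class == "wgt"],
                      lab$fpkm[lab$class == "singleton"])$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)  # null p-values consistent with U(0,1)

  shift_cfg <- sim_config(seed = 2)  # default +1 log shift for wgt
  expr <- simulate_expression(ann$truth$classes, shift_cfg)
  per_gene <- expr[, .(fpkm = mean(fpkm)), by = gene_id]
  lab <- merge(per_gene, ann$truth$classes, by = "gene_id")
  p <- wilcoxon_rank_sum(lab$fpkm[lab$class == "wgt"],
                         lab$fpkm[lab$class == "singleton"])$p_value
  expect_lt(p, 0.01)
})

test_that("generated annotation files parse cleanly through genome_io", {
  small <- fx_small_ann()
  d <- tempfile()
  paths <- export_annotation(small$ann, d)
  parsed <- parse_gff3(paths["gff3"])
  expect_setequal(parsed$genes$gene_id, small$ann$genes$gene_id)
  i <- match(small$ann$genes$gene_id, parsed$genes$gene_id)
  expect_equal(GenomicRanges::start(parsed$genes)[i],
               GenomicRanges::start(small$ann$genes))
  expect_equal(parsed$genes$tss[i], small$ann$genes$tss)
  expect_equal(length(parsed$repeats), length(small$ann$repeats))
  tx <- parsed$transcripts[order(transcript_id)]
  tx0 <- small$ann$transcripts[order(transcript_id)]
  expect_equal(tx$utr5_len, tx0$utr5_len)
  expect_equal(tx$cds_len, tx0$cds_len)
  expect_equal(tx$utr3_len, tx0$utr3_len)
  genome <- Biostrings::readDNAStringSet(paths["fasta"])
  expect_equal(Biostrings::width(genome),
               unname(small$cfg$chrom_lengths))
})
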