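# Weighted levels, the DMR caller, DMR annotation, metaprofiles.

test_that("weighted_level is the pooled count ratio with an undefined sentinel", {
  expect_equal(weighted_level(make_calls("Chr1", 1:3, 0, c(5, 8, 2))), 0)
  expect_equal(weighted_level(make_calls("Chr1", 1:2, c(3, 7), c(7, 3))), 0.5)
  expect_true(is.na(weighted_level(make_calls("Chr1", 1, 0, 0))))
})

test_that("global context mean and fold change behave on edge cases", {
  calls <- make_calls("Chr1", 1:4, c(2, 2, 9, 9), c(8, 8, 1, 1),
                      context = c("CG", "CG", "CHH", "CHH"))
  expect_equal(global_context_mean(calls, "CG"), 0.2)
  expect_equal(global_context_mean(calls, "CHH"), 0.9)
  expect_error(global_context_mean(calls[1:2], "CHH"), "no covered")
  expect_equal(fold_change(0.7, 0.2), 3.5)
  expect_error(fold_change(1, 0), "zero")
})

# six replicates over one 200-bp window with exactly controlled levels
single_window_reps <- function(levels_a, levels_b, n_sites = 5, cov = 100) {
  mk <- function(lv) make_calls("Chr1", seq(10, 190, length.out = n_sites),
                                meth = round(lv * cov), unmeth = cov - round(lv * cov))
  c(lapply(levels_a, mk), lapply(levels_b, mk))
}

test_that("call_dmrs reproduces the hand-worked single-window ANOVA", {
  la <- c(0.90, 0.95, 0.92); lb <- c(0.10, 0.12, 0.08)
  reps <- single_window_reps(la, lb)
  res <- call_dmrs(reps[1:3], reps[4:6], "CG")
  expect_equal(res$n_tested, 1L)
  expect_equal(length(res$dmrs), 1L)
  d <- res$dmrs
  expect_equal(d$direction, "hyper")
  expect_equal(d$delta, mean(la) - mean(lb), tolerance = 1e-9)
  expect_gte(abs(d$delta), 0.5)
  # one tested window: q = p, and p matches the stand-alone ANOVA kernel
  ref <- one_way_anova(list(la, lb))
  expect_equal(d$p_value, ref$p_value, tolerance = 1e-9)
  expect_equal(d$q_value, d$p_value)
  expect_lt(d$p_value, 0.001)
})

test_that("identical groups produce no DMRs and too few replicates error", {
  lv <- c(0.5, 0.6, 0.4)
  reps <- single_window_reps(lv, lv)
  res <- call_dmrs(reps[1:3], reps[4:6], "CG")
  expect_equal(length(res$dmrs), 0L)
  expect_error(call_dmrs(reps[1], reps[4:6], "CG"), ">= 2 replicates")
  expect_error(call_dmrs(reps[1:3], reps[4:6], "CG", window = 250, step = 100),
               "multiple")
})

test_that("reported DMRs store internally consistent statistics and merge cleanly", {
  stats_dmr <- dmr_recovery_stats(31)
  run <- run_dmr_scenario(31, planted = TRUE)
  d <- run$res$dmrs
  expect_gt(length(d), 0)
  # invariant: every stored DMR satisfies its cutoff and FDR exactly as stored
  expect_true(all(abs(d$delta) >= run$res$cutoff))
  expect_true(all(d$q_value < run$res$fdr))
  expect_true(all(d$direction == ifelse(d$delta > 0, "hyper", "hypo")))
  # merging is complete: no two same-direction DMRs remain within one step
  for (dir in c("hyper", "hypo")) {
    sub <- d[d$direction == dir]
    if (length(sub) >= 2) {
      gaps <- GenomicRanges::start(sub)[-1] -
        GenomicRanges::end(sub)[-length(sub)] - 1L
      expect_true(all(gaps > 100L))
    }
  }
  expect_gte(stats_dmr[["sensitivity"]], 0.9)
})

test_that("DMR genomic distribution partitions by precedence and majority overlap", {
  genes <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(10001, 12000),
                                  strand = "+")
  genes$gene_id <- "g1"
  tes <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(30001, 32000))
  dmrs <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(
    c(10500, 30500, 50000, 9500, 12500),
    c(10900, 30900, 50400, 9900, 12900)))
  out <- dmr_genomic_distribution(dmrs, genes, tes)
  expect_equal(sum(out), 1)
  cnt <- attr(out, "counts")
  expect_equal(as.integer(cnt[c("gene_body", "TE", "intergenic",
                                "upstream_2kb", "downstream_2kb")]),
               c(1L, 1L, 1L, 1L, 1L))
})

test_that("DMR-gene association respects the 2-kb flank rule", {
  genes <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(10001, 12000),
                                  strand = "+")
  genes$gene_id <- "g1"
  near <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(8401, 8500))   # 1.5 kb upstream
  far <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(7401, 7500))    # 2.5 kb upstream
  expect_equal(nrow(associate_dmrs_to_genes(near, genes)), 1L)
  expect_equal(nrow(associate_dmrs_to_genes(far, genes)), 0L)

  two <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(c(10001, 14001),
                                                         c(12000, 16000)),
                                strand = "+")
  two$gene_id <- c("g1", "g2")
  between <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(12900, 13100))
  hit <- associate_dmrs_to_genes(between, two)
  expect_setequal(hit$gene_id, c("g1", "g2"))  # overlaps both flanks
})

test_that("metaprofiles mirror when all features change strand", {
  small <- fx_small_ann()
  calls <- simulate_methylome(small$ann, small$cfg, "A", 1)
  # fixed-width features so plus/minus binning is exactly symmetric
  g <- small$ann$genes
  feats <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                  IRanges::IRanges(GenomicRanges::start(g),
                                                   width = 2000))
  fp <- feats; GenomicRanges::strand(fp) <- "+"
  fm <- feats; GenomicRanges::strand(fm) <- "-"
  p_plus <- metaprofile(calls, fp, "CG")
  p_minus <- metaprofile(calls, fm, "CG")
  expect_equal(p_minus$profile$level, rev(p_plus$profile$level),
               tolerance = 1e-12)
  expect_equal(p_plus$used + p_plus$skipped, length(feats))
})

test_that("metaprofile skips features shorter than the body bin count", {
  calls <- make_calls("Chr1", seq(1, 2000, by = 7), 3, 7)
  feats <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(c(501, 901),
                                                           c(510, 1900)),
                                  strand = "+")
  mp <- metaprofile(calls, feats, "CG", body_bins = 20)
  expect_equal(mp$skipped, 1L)
  expect_equal(mp$used, 1L)
})
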