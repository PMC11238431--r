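# Gene ranking, collinear-block chaining, duplicate classification,
# copy-number grouping, class-wise expression comparison.

mk_genes <- function(chrom, start, end, id, strand = "+") {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                              strand = strand)
  g$gene_id <- id
  g
}

empty_blocks_tbl <- function() {
  data.table::data.table(block_id = integer(), chrom_a = character(),
                         chrom_b = character(), orientation = character(),
                         gene_a = character(), gene_b = character(),
                         rank_a = integer(), rank_b = integer())
}

test_that("gene ranks are dense per chromosome with deterministic tie-breaks", {
  g <- mk_genes(c("Chr1", "Chr1", "Chr1", "Chr2", "Chr2"),
                c(100, 500, 900, 100, 100),
                c(200, 600, 1000, 300, 250),
                c("a", "b", "c", "d", "e"))
  r <- rank_genes(g)
  expect_equal(r$rank[match(c("a", "b", "c"), r$gene_id)], 0:2)
  # Chr2 ranked independently; tie on start broken by end
  expect_equal(r$rank[r$gene_id == "e"], 0L)
  expect_equal(r$rank[r$gene_id == "d"], 1L)
})

test_that("chaining finds collinear runs and respects the anchor threshold", {
  # 12 genes on each of two chromosomes; anchors collinear with small gaps
  ga <- mk_genes("Chr1", seq(1000, 12000, by = 1000),
                 seq(1400, 12400, by = 1000), sprintf("a%02d", 1:12))
  gb <- mk_genes("Chr2", seq(1000, 12000, by = 1000),
                 seq(1400, 12400, by = 1000), sprintf("b%02d", 1:12))
  genes <- suppressWarnings(c(ga, gb))
  ranks <- rank_genes(genes)
  pairs6 <- data.table::data.table(gene_a = sprintf("a%02d", c(1, 3, 5, 7, 9, 11)),
                                   gene_b = sprintf("b%02d", c(2, 4, 6, 8, 10, 12)))
  blocks <- chain_collinear_blocks(pairs6, ranks)
  expect_equal(length(unique(blocks$block_id)), 1L)
  expect_equal(nrow(blocks), 6L)

  blocks4 <- chain_collinear_blocks(pairs6[1:4], ranks)
  expect_equal(nrow(blocks4), 0L)  # below min_anchors

  # reversed orientation chains too
  pairs_rev <- data.table::data.table(gene_a = sprintf("a%02d", 1:6),
                                      gene_b = sprintf("b%02d", 12:7))
  blocks_rev <- chain_collinear_blocks(pairs_rev, ranks)
  expect_equal(nrow(blocks_rev), 6L)
  expect_equal(unique(blocks_rev$orientation), "-")
})

test_that("classification applies the documented precedence rules", {
  # Chr1: t1,t2 tandem; p1, spacer x1..x2, p2 proximal; lone singleton s1
  g <- suppressWarnings(
    c(mk_genes("Chr1", c(1000, 2000, 5000, 6000, 7000, 8000, 20000),
               c(1500, 2500, 5500, 6500, 7500, 8500, 20500),
               c("t1", "t2", "p1", "x1", "x2", "p2", "s1")),
      mk_genes("Chr2", c(1000, 9000), c(1500, 9500), c("d2", "x3"))))
  pairs <- data.table::data.table(gene_a = c("t1", "p1", "x1"),
                                  gene_b = c("t2", "p2", "d2"))
  lab <- classify_duplicates(g, pairs, empty_blocks_tbl(), proximal_gap = 10)
  lookup <- function(id) lab$label[lab$gene_id == id]
  expect_equal(lookup("t1"), "tandem")
  expect_equal(lookup("t2"), "tandem")
  expect_equal(lookup("p1"), "proximal")   # 2 intervening genes
  expect_equal(lookup("p2"), "proximal")
  expect_equal(lookup("x1"), "dispersed")  # cross-chromosome paralog
  expect_equal(lookup("d2"), "dispersed")
  expect_equal(lookup("s1"), "singleton")
  expect_equal(lookup("x3"), "singleton")
  # labels partition the gene set
  expect_equal(nrow(lab), length(g))

  expect_error(classify_duplicates(g, data.table::data.table(
    gene_a = "t1", gene_b = "ghost"), empty_blocks_tbl()), "absent")
})

test_that("copy groups close transitively and count distinct loci", {
  blocks <- data.table::data.table(
    block_id = c(1L, 2L), chrom_a = "Chr1", chrom_b = c("Chr2", "Chr3"),
    orientation = "+",
    gene_a = c("A", "B"), gene_b = c("B", "C"),
    rank_a = c(0L, 0L), rank_b = c(0L, 0L))
  grp <- wgt_copy_groups(blocks)
  expect_equal(length(unique(grp$groups$group_id)), 1L)
  expect_equal(unique(grp$groups$copy_number), 3L)
  expect_setequal(grp$groups$gene_id, c("A", "B", "C"))
})

test_that("the full synthetic plan classifies perfectly with 20% 3-copy WGT genes", {
  ann <- fx_plan_ann()
  ranks <- rank_genes(ann$genes)
  blocks <- chain_collinear_blocks(ann$pairs, ranks)
  lab <- classify_duplicates(ann$genes, ann$pairs, blocks)
  truth <- merge(lab, ann$truth$classes, by = "gene_id")
  expect_equal(mean(truth$label == truth$class), 1)
  n3 <- sum(lab$copy_number == 3, na.rm = TRUE)
  nw <- sum(lab$label == "wgt")
  expect_equal(n3, 30L)
  expect_equal(summarize_fraction(n3, nw), 20.00)
  # classification is invariant under chromosome renaming
  g2 <- ann$genes
  GenomeInfoDb::seqlevels(g2) <- paste0("X", GenomeInfoDb::seqlevels(g2))
  lab2 <- classify_duplicates(g2, ann$pairs,
                              chain_collinear_blocks(ann$pairs, rank_genes(g2)))
  expect_equal(lab2$label[match(lab$gene_id, lab2$gene_id)], lab$label)
})

test_that("percentage aggregation reproduces printed worked examples", {
  expect_equal(summarize_fraction(787, 4612), 17.06)
  expect_equal(summarize_fraction(30672, 42406), 72.33)
  expect_equal(summarize_fraction(0, 100), 0)
  expect_error(summarize_fraction(1, 0), "positive")
})

test_that("class-wise expression comparison detects the planted WGT shift", {
  ann <- fx_plan_ann()
  cfg <- sim_config(seed = 201)  # default +1 log-scale shift for wgt
  expr <- simulate_expression(ann$truth$classes, cfg)
  res <- compare_expression_by_class(expr, ann$truth$classes)
  wgt_vs_sing <- res$tests[(class_a == "singleton" & class_b == "wgt") |
                             (class_a == "wgt" & class_b == "singleton")]
  expect_lt(wgt_vs_sing$q_value, 0.01)
  expect_gt(res$medians[["wgt"]], res$medians[["singleton"]])

  # no signal between the unshifted classes at this seed
  null_pair <- res$tests[(class_a == "proximal" & class_b == "tandem") |
                           (class_a == "tandem" & class_b == "proximal")]
  expect_gt(null_pair$q_value, 0.05)
  expect_error(compare_expression_by_class(expr[1:3],
                                           ann$truth$classes[1:2]),
               ">= 2 classes")
})
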