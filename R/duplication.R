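# Collinear-block chaining on the gene-rank dot-plot and the five-way
# duplicate-gene classification (singleton / WGT / tandem / proximal /
# dispersed) with 2-/3-copy grouping of WGT genes.

#' Rank genes by position within each chromosome
#'
#' Dense 0-based ordinals per chromosome, ordered by start position; ties
#' broken by end, then gene id, so ranking is deterministic.
#'
#' @param genes GRanges with `gene_id`
#' @return `data.table` with `gene_id`, `chrom`, `rank`
#' @export
rank_genes <- function(genes) {
  dt <- data.table(gene_id = genes$gene_id,
                   chrom = as.character(seqnames(genes)),
                   start = start(genes), end = end(genes))
  setorder(dt, chrom, start, end, gene_id)
  dt[, rank := seq_len(.N) - 1L, by = chrom]
  dt[, .(gene_id, chrom, rank)]
}

#' Chain homolog anchors into collinear blocks
#'
#' Places each homolog pair on the rank dot-plot of its chromosome pair and
#' chains anchors whose ranks advance monotonically in both genomes
#' (increasing or decreasing in the second) with rank gaps of at most
#' `max_gap`. Maximal chains are extracted greedily without anchor reuse;
#' chains shorter than `min_anchors` are discarded. Intra-chromosomal
#' anchors closer than `self_gap` ranks to the diagonal (tandem/proximal
#' pairs) are excluded, as is standard for synteny chaining.
#'
#' @param pairs data.table/data.frame with `gene_a`, `gene_b`
#' @param ranks [rank_genes()] output
#' @param min_anchors minimum anchors per block
#' @param max_gap maximum rank gap in either genome
#' @param self_gap diagonal exclusion for same-chromosome anchors
#' @return `data.table` with `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `gene_a`, `gene_b`, `rank_a`, `rank_b`
#' @export
chain_collinear_blocks <- function(pairs, ranks, min_anchors = 5L,
                                   max_gap = 25L, self_gap = 10L) {
  pairs <- as.data.table(pairs)
  if (nrow(pairs) == 0)
    return(empty_blocks())
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), ranks$gene_id)
  if (length(missing))
    stop("paired gene(s) missing from the ranking: ",
         paste(head(missing, 3), collapse = ", "))
  idx <- function(g) match(g, ranks$gene_id)
  a <- idx(pairs$gene_a); b <- idx(pairs$gene_b)
  anch <- data.table(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    chrom_a = ranks$chrom[a], rank_a = ranks$rank[a],
    chrom_b = ranks$chrom[b], rank_b = ranks$rank[b])
  # orient unordered pairs so the dot-plot is unique
  flip <- anch$chrom_a > anch$chrom_b |
    (anch$chrom_a == anch$chrom_b & anch$rank_a > anch$rank_b)
  anch[flip, c("gene_a", "gene_b", "chrom_a", "rank_a", "chrom_b", "rank_b") :=
         .(gene_b, gene_a, chrom_b, rank_b, chrom_a, rank_a)]
  anch <- unique(anch)
  anch <- anch[!(chrom_a == chrom_b & abs(rank_a - rank_b) <= self_gap)]
  if (nrow(anch) == 0) return(empty_blocks())

  out <- list(); block_n <- 0L
  for (key in unique(paste(anch$chrom_a, anch$chrom_b, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- anch[chrom_a == parts[1] & chrom_b == parts[2]]
    setorder(sub, rank_a, rank_b)
    used <- rep(FALSE, nrow(sub))
    repeat {
      best <- best_chain(sub, used, max_gap)
      if (length(best$members) < min_anchors) break
      block_n <- block_n + 1L
      blk <- sub[best$members]
      blk[, `:=`(block_id = block_n, orientation = best$orientation)]
      out[[length(out) + 1L]] <- blk
      used[best$members] <- TRUE
    }
  }
  if (!length(out)) return(empty_blocks())
  res <- rbindlist(out)[, .(block_id, chrom_a, chrom_b, orientation,
                            gene_a, gene_b, rank_a, rank_b)]
  res[]
}

empty_blocks <- function() {
  data.table(block_id = integer(), chrom_a = character(), chrom_b = character(),
             orientation = character(), gene_a = character(),
             gene_b = character(), rank_a = integer(), rank_b = integer())
}

# O(n^2) longest-chain DP over unused anchors, run for both orientations;
# returns the member indices of the single best chain
best_chain <- function(sub, used, max_gap) {
  avail <- which(!used)
  best <- list(members = integer(), orientation = "+")
  if (!length(avail)) return(best)
  ra <- sub$rank_a[avail]; rb <- sub$rank_b[avail]
  n <- length(avail)
  for (orient in c("+", "-")) {
    score <- rep(1L, n); prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      da <- ra[i] - ra
      db <- if (orient == "+") rb[i] - rb else rb - rb[i]
      ok <- which(da >= 1 & da <= max_gap & db >= 1 & db <= max_gap)
      if (length(ok)) {
        j <- ok[which.max(score[ok])]
        if (score[j] + 1L > score[i]) { score[i] <- score[j] + 1L; prev[i] <- j }
      }
    }
    top <- which.max(score)
    if (score[top] > length(best$members)) {
      members <- integer(); k <- top
      while (!is.na(k)) { members <- c(k, members); k <- prev[k] }
      best <- list(members = avail[members], orientation = orient)
    }
  }
  best
}

#' Group WGT genes by syntenic copy number
#'
#' Joins block anchor genes into groups by transitive closure over anchor
#' pairs; a group's copy number is its number of distinct syntenic loci
#' (member genes). Groups with more than 3 loci are reported as-is and
#' excluded from the 2-/3-copy dichotomy.
#'
#' @param blocks [chain_collinear_blocks()] output
#' @return list: `groups` (`data.table` `gene_id`, `group_id`,
#'   `copy_number`), `counts` (genes per copy number)
#' @export
wgt_copy_groups <- function(blocks) {
  if (nrow(blocks) == 0)
    return(list(groups = data.table(gene_id = character(),
                                    group_id = integer(),
                                    copy_number = integer()),
                counts = integer()))
  g <- igraph::graph_from_data_frame(blocks[, .(gene_a, gene_b)],
                                     directed = FALSE)
  comp <- igraph::components(g)
  groups <- data.table(gene_id = names(comp$membership),
                       group_id = as.integer(comp$membership))
  groups[, copy_number := .N, by = group_id]
  counts <- groups[, .N, by = copy_number][order(copy_number)]
  list(groups = groups[], counts = stats::setNames(counts$N, counts$copy_number))
}

#' Classify genes into duplication classes
#'
#' Precedence: a gene anchored in any collinear block is `wgt`; otherwise a
#' gene with a rank-adjacent same-chromosome paralog is `tandem`; otherwise
#' with a paralog within `proximal_gap` intervening genes, `proximal`;
#' otherwise, having any paralog, `dispersed`; genes with no homolog pair
#' are `singleton`. WGT genes carry their copy group id and copy number from
#' [wgt_copy_groups()].
#'
#' @param genes GRanges with `gene_id`
#' @param pairs homolog pair table (`gene_a`, `gene_b`)
#' @param blocks [chain_collinear_blocks()] output
#' @param proximal_gap maximum intervening genes for `proximal`
#' @return `data.table` with `gene_id`, `label`, `wgt_group_id`,
#'   `copy_number`
#' @export
classify_duplicates <- function(genes, pairs, blocks, proximal_gap = 10L) {
  ranks <- rank_genes(genes)
  pairs <- as.data.table(pairs)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), ranks$gene_id)
  if (length(missing))
    stop("gene(s) in the pair table absent from the annotation: ",
         paste(head(missing, 3), collapse = ", "))

  grp <- wgt_copy_groups(blocks)
  wgt_genes <- grp$groups$gene_id

  # symmetric pair list for neighbour lookups
  sym <- rbind(pairs[, .(g = gene_a, h = gene_b)],
               pairs[, .(g = gene_b, h = gene_a)])
  sym <- merge(sym, ranks, by.x = "g", by.y = "gene_id")
  setnames(sym, c("chrom", "rank"), c("chrom_g", "rank_g"))
  sym <- merge(sym, ranks, by.x = "h", by.y = "gene_id")
  setnames(sym, c("chrom", "rank"), c("chrom_h", "rank_h"))
  sym[, gap := ifelse(chrom_g == chrom_h, abs(rank_g - rank_h) - 1, NA_real_)]
  min_gap <- sym[, .(gap = suppressWarnings(min(gap, na.rm = TRUE))), by = g]

  lab <- data.table(gene_id = ranks$gene_id)
  lab[, label := "singleton"]
  paired <- unique(c(pairs$gene_a, pairs$gene_b))
  lab[gene_id %in% paired, label := "dispersed"]
  prox <- min_gap$g[is.finite(min_gap$gap) & min_gap$gap <= proximal_gap]
  lab[gene_id %in% prox, label := "proximal"]
  tand <- min_gap$g[is.finite(min_gap$gap) & min_gap$gap == 0L]
  lab[gene_id %in% tand, label := "tandem"]
  lab[gene_id %in% wgt_genes, label := "wgt"]

  lab <- merge(lab, grp$groups, by = "gene_id", all.x = TRUE, sort = FALSE)
  setnames(lab, "group_id", "wgt_group_id")
  stopifnot(nrow(lab) == length(genes))  # labels partition the gene set
  lab[]
}

#' Fraction as a rounded percentage
#'
#' `100 * numerator / denominator`, rounded half-up to 2 decimals.
#' @param numerator,denominator counts; `denominator > 0`
#' @return percentage
#' @examples
#' summarize_fraction(787, 4612)  # 17.06
#' @export
summarize_fraction <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  round_half_up(100 * numerator / denominator, 2)
}

#' Compare expression distributions across duplication classes
#'
#' Per-gene expression (mean FPKM over samples) split by class label, with
#' optional subdivision of WGT genes into 2-copy and 3-copy; class medians
#' plus all pairwise unpaired Wilcoxon rank-sum tests, Benjamini-Hochberg
#' adjusted across the pairs.
#'
#' @param expression `data.table` with `gene_id`, `sample_id`, `fpkm`
#' @param labels [classify_duplicates()] output
#' @param split_wgt split `wgt` into `wgt_2copy` / `wgt_3copy`
#' @return list: `medians` (named), `tests` (`data.table` `class_a`,
#'   `class_b`, `statistic`, `p_value`, `q_value`), `n_excluded` (labelled
#'   genes without expression)
#' @export
compare_expression_by_class <- function(expression, labels, split_wgt = FALSE) {
  expr <- as.data.table(expression)[, .(fpkm = mean(fpkm)), by = gene_id]
  lab <- normalize_labels(labels)
  if (split_wgt) {
    if (!"copy_number" %in% names(lab))
      stop("split_wgt needs a copy_number column (classify_duplicates output)")
    lab <- copy(lab)
    lab[label == "wgt" & copy_number == 2L, label := "wgt_2copy"]
    lab[label == "wgt" & copy_number == 3L, label := "wgt_3copy"]
  }
  dt <- merge(lab, expr, by = "gene_id")
  n_excluded <- nrow(lab) - nrow(dt)
  classes <- sort(unique(dt$label))
  sizes <- dt[, .N, by = label]
  if (any(sizes$N < 2L) || length(classes) < 2L)
    stop("need >= 2 classes with >= 2 genes each")
  medians <- vapply(classes, function(cl) stats::median(dt$fpkm[dt$label == cl]),
                    numeric(1))
  cmb <- combn(classes, 2)
  tests <- rbindlist(lapply(seq_len(ncol(cmb)), function(i) {
    x <- dt$fpkm[dt$label == cmb[1, i]]
    y <- dt$fpkm[dt$label == cmb[2, i]]
    tr <- wilcoxon_rank_sum(x, y, "two_sided")
    data.table(class_a = cmb[1, i], class_b = cmb[2, i],
               statistic = tr$statistic, p_value = tr$p_value)
  }))
  tests[, q_value := benjamini_hochberg(p_value)]
  list(medians = medians, tests = tests[], n_excluded = n_excluded)
}
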