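# Seeded simulator: genome, annotation and duplication ground truth.
#
# The generator lays out genes on a small multi-chromosome genome according
# to a duplication plan (singletons, tandem pairs, proximal pairs, dispersed
# pairs, and syntenic segments retained in 2 or 3 copies), emits the homolog
# pair table for every planted paralog relation, and records the true class
# of every gene. Each sub-generator draws from its own RNG stream derived
# from the master seed.

#' Duplication plan for the synthetic annotation
#'
#' @param singleton number of single-copy genes (proximal spacer genes are
#'   drawn from this pool)
#' @param tandem_pairs number of tandem duplicate pairs (rank-adjacent)
#' @param proximal_pairs number of proximal pairs (separated by
#'   `proximal_spacing` intervening genes)
#' @param dispersed_pairs number of dispersed pairs (members on different
#'   chromosomes)
#' @param seg2,seg3 number of syntenic segments retained in 2 / 3 copies
#' @param genes_per_segment genes per syntenic segment
#' @param proximal_spacing intervening singletons inside a proximal pair
#' @return list describing the plan
#' @export
dup_plan <- function(singleton = 100L, tandem_pairs = 50L, proximal_pairs = 50L,
                     dispersed_pairs = 50L, seg2 = 6L, seg3 = 1L,
                     genes_per_segment = 10L, proximal_spacing = 1L) {
  as.list(environment())
}

default_baselines <- function() {
  list(
    CG  = c(gene = 0.20, intergenic = 0.30, Copia = 0.80, Gypsy = 0.80,
            LINE = 0.70, DNA_TE = 0.60, other = 0.50),
    CHG = c(gene = 0.05, intergenic = 0.15, Copia = 0.60, Gypsy = 0.60,
            LINE = 0.45, DNA_TE = 0.40, other = 0.30),
    CHH = c(gene = 0.03, intergenic = 0.05, Copia = 0.15, Gypsy = 0.15,
            LINE = 0.10, DNA_TE = 0.10, other = 0.08))
}

#' Uniform methylation baselines
#'
#' Convenience constructor giving every context and feature class the same
#' mean methylation level (used for flatness / null calibrations).
#' @param p mean level in \[0, 1\]
#' @return baseline list as expected by [sim_config()]
#' @export
uniform_baselines <- function(p) {
  cls <- c("gene", "intergenic", "Copia", "Gypsy", "LINE", "DNA_TE", "other")
  stats::setNames(lapply(CONTEXTS, function(ctx) stats::setNames(rep(p, 7), cls)),
                  CONTEXTS)
}

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator in one object. Defaults encode
#' the study conditions exercised by the package's validation suites: a
#' 9-chromosome plant-like genome, two groups of three bisulfite replicates
#' at 20x depth, beta-binomial methylation noise, plant-typical context
#' baselines, and an m6A plan biased to the 3' UTR.
#'
#' @param seed master seed; every sub-generator derives its own stream
#' @param chrom_lengths named vector of chromosome lengths (bp)
#' @param gc genome GC fraction
#' @param plan [dup_plan()] gene duplication plan
#' @param gene_length,intergenic_gap,te_length `c(min, max)` ranges in bp
#' @param utr5_frac,utr3_frac UTR fractions of the transcript length
#' @param te_count transposable elements to place
#' @param te_class_probs sampling weights over repeat classes
#' @param depth mean read depth (Poisson)
#' @param replicates named vector, replicates per group (e.g. `c(A=3, B=3)`)
#' @param baselines per-context, per-feature-class mean methylation levels
#' @param beta_precision beta precision (a+b) of the site-level beta-binomial
#'   noise; smaller = more replicate overdispersion
#' @param dmrs planted DMRs: data.table/data.frame with `chrom`, `start`,
#'   `end`, `context`, `delta` (added to group B inside the interval)
#' @param sv_chh breakpoint CHH elevation: `chrom`, `pos`, `delta`,
#'   `halfwidth` (added to CHH sites within `pos +- halfwidth`, both groups)
#' @param tss_dip optional `list(factor, frac)` multiplying the site mean by
#'   `factor` within the first `frac` of each gene body (strand-aware)
#' @param sv_plan list: `n` (named counts per SV type), `boundary_weight`
#'   (odds of placing a breakpoint at a TE boundary vs uniform),
#'   `chh_effect` (`delta`, `halfwidth`, `types`, `fraction` flagged)
#' @param expr list: `meanlog`, `sdlog`, `samples`, `class_shifts` (additive
#'   log-scale shifts per duplication class), `m6a_shift` (additive log-scale
#'   shift for m6A-modified genes when a modified set is supplied)
#' @param m6a list: `class_prob` (per-class transcript modification
#'   probability), `sites_lambda` (Poisson for extra sites per modified
#'   transcript), `region_bias` (named fractions utr5/cds/utr3),
#'   `detection_prob`, `fp_rate` (false positives per replicate as a fraction
#'   of true sites), `n_replicates`, `prob_range` (detected-site probability)
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed,
                       chrom_lengths = stats::setNames(rep(250000L, 9), paste0("Chr", 1:9)),
                       gc = 0.4,
                       plan = dup_plan(),
                       gene_length = c(900L, 3000L),
                       intergenic_gap = c(400L, 2000L),
                       utr5_frac = 0.1, utr3_frac = 0.2,
                       te_count = 150L,
                       te_length = c(500L, 4000L),
                       te_class_probs = c(Copia = 0.3, Gypsy = 0.4, LINE = 0.1, DNA_TE = 0.2),
                       depth = 20,
                       replicates = c(A = 3L, B = 3L),
                       baselines = default_baselines(),
                       beta_precision = 50,
                       dmrs = NULL,
                       sv_chh = NULL,
                       tss_dip = NULL,
                       sv_plan = list(
                         n = c(INS = 300L, DEL = 100L, DUP = 15L, INV = 15L, TRANS = 10L),
                         boundary_weight = 0,
                         chh_effect = list(delta = 0.3, halfwidth = 500L,
                                           types = "INS", fraction = 1)),
                       expr = list(meanlog = 1, sdlog = 1, samples = 3L,
                                   class_shifts = c(singleton = 0, tandem = 0,
                                                    proximal = 0, dispersed = 0,
                                                    wgt = 1),
                                   m6a_shift = 0.8),
                       m6a = list(class_prob = c(wgt = 0.12, tandem = 0.07,
                                                 proximal = 0.06, dispersed = 0.06,
                                                 singleton = 0.05),
                                  sites_lambda = 1.5,
                                  region_bias = c(utr5 = 0.0759, cds = 0.25,
                                                  utr3 = 0.6741),
                                  detection_prob = 0.9, fp_rate = 0.1,
                                  n_replicates = 3L,
                                  prob_range = c(0.90, 0.999))) {
  cfg <- as.list(environment())
  for (ctx in CONTEXTS)
    if (any(cfg$baselines[[ctx]] < 0 | cfg$baselines[[ctx]] > 1))
      stop("methylation baselines must lie in [0, 1]")
  stopifnot(abs(sum(cfg$m6a$region_bias) - 1) < 1e-6)
  class(cfg) <- "sim_config"
  cfg
}

# ---- gene layout -----------------------------------------------------------

# Assign duplication-plan units to chromosomes and order them. Segment copies
# go to distinct chromosomes; dispersed pair members go to chromosome pairs
# that host no syntenic segment (so stray anchors cannot extend a real
# block); tandem/proximal units cycle over chromosomes.
plan_layout <- function(plan, n_chrom) {
  units <- list()
  seg_pairs <- character()
  n_seg <- plan$seg2 + plan$seg3
  if (n_seg > 0 && n_chrom < 2) stop("infeasible plan: segments need >= 2 chromosomes")
  base <- 0L
  for (s in seq_len(n_seg)) {
    k <- if (s <= plan$seg2) 2L else 3L
    chroms <- ((base + 0:(k - 1)) %% n_chrom) + 1L
    base <- base + k
    if (anyDuplicated(chroms)) stop("infeasible plan: too few chromosomes for segment copies")
    for (cp in combn(sort(chroms), 2, simplify = FALSE))
      seg_pairs <- c(seg_pairs, paste(cp, collapse = "-"))
    for (ci in seq_len(k)) {
      g <- data.table(
        gene_id = sprintf("WGT_s%02d_c%d_g%02d", s, ci, seq_len(plan$genes_per_segment)),
        class = "wgt",
        group_id = sprintf("s%02d_g%02d", s, seq_len(plan$genes_per_segment)),
        copy_number = k)
      units[[length(units) + 1L]] <- list(chrom = chroms[ci], genes = g)
    }
  }

  rr <- function(i) ((i - 1L) %% n_chrom) + 1L
  for (t in seq_len(plan$tandem_pairs)) {
    g <- data.table(gene_id = sprintf("TAN_%03d_%s", t, c("a", "b")),
                    class = "tandem", group_id = NA_character_, copy_number = NA_integer_)
    units[[length(units) + 1L]] <- list(chrom = rr(t), genes = g)
  }

  n_spacers <- plan$proximal_pairs * plan$proximal_spacing
  if (n_spacers > plan$singleton)
    stop("infeasible plan: not enough singletons to space proximal pairs")
  spc <- 0L
  for (p in seq_len(plan$proximal_pairs)) {
    ids <- c(sprintf("PRX_%03d_a", p),
             sprintf("SNG_%03d", spc + seq_len(plan$proximal_spacing)),
             sprintf("PRX_%03d_b", p))
    spc <- spc + plan$proximal_spacing
    g <- data.table(gene_id = ids,
                    class = c("proximal", rep("singleton", plan$proximal_spacing), "proximal"),
                    group_id = NA_character_, copy_number = NA_integer_)
    units[[length(units) + 1L]] <- list(chrom = rr(p + 3L), genes = g)
  }

  if (plan$dispersed_pairs > 0) {
    if (n_chrom < 2) stop("infeasible plan: dispersed pairs need >= 2 chromosomes")
    all_pairs <- apply(combn(n_chrom, 2), 2, paste, collapse = "-")
    free_pairs <- setdiff(all_pairs, seg_pairs)
    if (!length(free_pairs)) free_pairs <- all_pairs
    for (d in seq_len(plan$dispersed_pairs)) {
      cp <- as.integer(strsplit(free_pairs[((d - 1L) %% length(free_pairs)) + 1L],
                                "-", fixed = TRUE)[[1]])
      for (side in 1:2) {
        g <- data.table(gene_id = sprintf("DSP_%03d_%s", d, c("a", "b")[side]),
                        class = "dispersed", group_id = NA_character_,
                        copy_number = NA_integer_)
        units[[length(units) + 1L]] <- list(chrom = cp[side], genes = g)
      }
    }
  }

  n_free <- plan$singleton - n_spacers
  for (i in seq_len(max(0L, n_free))) {
    g <- data.table(gene_id = sprintf("SNG_%03d", n_spacers + i),
                    class = "singleton", group_id = NA_character_,
                    copy_number = NA_integer_)
    units[[length(units) + 1L]] <- list(chrom = rr(i + 5L), genes = g)
  }
  units
}

# All planted paralog pairs: tandem, proximal, dispersed, and every pair of
# copies inside a WGT group.
planted_pairs <- function(gene_tab) {
  out <- list()
  for (pre in c("TAN", "PRX", "DSP")) {
    ids <- grep(paste0("^", pre, "_"), gene_tab$gene_id, value = TRUE)
    if (!length(ids)) next
    stem <- sub("_[ab]$", "", ids)
    for (s in unique(stem))
      out[[length(out) + 1L]] <- data.table(gene_a = paste0(s, "_a"),
                                            gene_b = paste0(s, "_b"))
  }
  wgt <- gene_tab[!is.na(group_id)]
  if (nrow(wgt)) {
    for (gid in unique(wgt$group_id)) {
      members <- sort(wgt$gene_id[wgt$group_id == gid])
      if (length(members) >= 2) {
        cmb <- combn(members, 2)
        out[[length(out) + 1L]] <- data.table(gene_a = cmb[1, ], gene_b = cmb[2, ])
      }
    }
  }
  rbindlist(out)
}

#' Simulate a genome, gene/TE annotation and duplication ground truth
#'
#' Realises the duplication plan in `config$plan`: tandem pairs are
#' rank-adjacent, proximal pairs have the configured number of intervening
#' genes, dispersed pair members sit on different chromosomes, and each
#' syntenic segment is an order-preserving run of genes copied to 2 or 3
#' chromosomes. Emits the homolog-pair table for all planted paralogs.
#'
#' @param config [sim_config()]
#' @return list of class `sim_annotation` with `genome` (`DNAStringSet`),
#'   `genes` (GRanges: `gene_id`, `tss`, `tts`), `transcripts` (data.table),
#'   `repeats` (GRanges: `repeat_class`), `pairs` (data.table `gene_a`,
#'   `gene_b`, `score`), `sites` (per-cytosine context table) and `truth`
#'   (gene classes + WGT groups)
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "annotation"))
  chrlen <- config$chrom_lengths
  n_chrom <- length(chrlen)
  units <- plan_layout(config$plan, n_chrom)

  # shuffle unit order within each chromosome, then lay genes left to right
  rows <- list()
  for (ci in seq_len(n_chrom)) {
    mine <- units[vapply(units, function(u) u$chrom == ci, logical(1))]
    if (!length(mine)) next
    mine <- mine[sample(length(mine))]
    cur <- 0L
    for (u in mine) {
      for (j in seq_len(nrow(u$genes))) {
        gap <- sample(config$intergenic_gap[1]:config$intergenic_gap[2], 1)
        len <- sample(config$gene_length[1]:config$gene_length[2], 1)
        st <- cur + gap
        en <- st + len - 1L
        if (en > chrlen[ci])
          stop("infeasible plan: genes exceed chromosome ", names(chrlen)[ci])
        rows[[length(rows) + 1L]] <- data.table(
          chrom = names(chrlen)[ci], start = st, end = en,
          strand = sample(c("+", "-"), 1),
          gene_id = u$genes$gene_id[j], class = u$genes$class[j],
          group_id = u$genes$group_id[j], copy_number = u$genes$copy_number[j])
        cur <- en
      }
    }
  }
  gene_tab <- rbindlist(rows)

  genes <- GRanges(gene_tab$chrom,
                   IRanges(gene_tab$start, gene_tab$end),
                   strand = gene_tab$strand,
                   seqlengths = chrlen)
  genes$gene_id <- gene_tab$gene_id
  plus <- gene_tab$strand == "+"
  genes$tss <- ifelse(plus, gene_tab$start, gene_tab$end)
  genes$tts <- ifelse(plus, gene_tab$end, gene_tab$start)

  # one intronless transcript per gene, partitioned into UTR5/CDS/UTR3
  len <- width(genes)
  u5 <- pmax(1L, as.integer(round(len * config$utr5_frac)))
  u3 <- pmax(1L, as.integer(round(len * config$utr3_frac)))
  transcripts <- data.table(
    transcript_id = paste0(gene_tab$gene_id, ".1"),
    gene_id = gene_tab$gene_id,
    utr5_len = u5, cds_len = len - u5 - u3, utr3_len = u3)

  # TEs dropped uniformly into gene-free space
  reps <- place_tes(genes, chrlen, config)

  # random genome sequence
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  genome <- Biostrings::DNAStringSet(vapply(chrlen, function(L)
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
    character(1)))
  names(genome) <- names(chrlen)

  pairs <- planted_pairs(gene_tab)
  pairs$score <- round(runif(nrow(pairs), 50, 100), 1)

  ann <- list(
    genome = genome, genes = genes, transcripts = transcripts, repeats = reps,
    pairs = pairs, sites = cytosine_sites(genome),
    truth = list(classes = gene_tab[, .(gene_id, class)],
                 wgt_groups = gene_tab[!is.na(group_id),
                                       .(gene_id, group_id, copy_number)],
                 gene_table = gene_tab))
  class(ann) <- c("sim_annotation", "list")
  ann
}

place_tes <- function(genes, chrlen, config) {
  n <- config$te_count
  if (n == 0)
    return(GRanges(seqlengths = chrlen))
  # draw candidates in bulk, drop those touching genes or earlier candidates
  k <- n * 25L
  ci <- sample(length(chrlen), k, replace = TRUE)
  len <- sample(config$te_length[1]:config$te_length[2], k, replace = TRUE)
  st <- pmax(1L, as.integer(floor(runif(k, 1, pmax(2L, chrlen[ci] - len)))))
  cand <- GRanges(names(chrlen)[ci], IRanges(st, st + len - 1L),
                  seqlengths = chrlen)
  cand <- cand[!overlapsAny(cand, genes)]
  self <- findOverlaps(cand, cand)
  dup <- unique(queryHits(self)[queryHits(self) > subjectHits(self)])
  cand <- cand[setdiff(seq_along(cand), dup)]
  reps <- head(cand, n)
  if (length(reps) < n)
    warning("placed only ", length(reps), " of ", n, " TEs")
  if (length(reps)) {
    reps$repeat_class <- factor(
      sample(names(config$te_class_probs), length(reps), replace = TRUE,
             prob = config$te_class_probs),
      levels = REPEAT_CLASSES)
    reps <- sort(reps)
  }
  reps
}

#' Enumerate cytosine sites and their contexts from a genome
#'
#' Both strands; a cytosine on the minus strand appears at the position of
#' the plus-strand G. Context follows the plant convention: CG, CHG
#' (H = A/T/C), CHH. Sites whose context runs off the sequence end are
#' assigned by the available bases (treated as H).
#'
#' @param genome `DNAStringSet`
#' @return `data.table` with `chrom`, `pos`, `strand`, `context`, `tri`
#' @export
cytosine_sites <- function(genome) {
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    s <- as.character(genome[[i]])
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    L <- length(v)
    at <- function(idx) { b <- rep("N", length(idx)); ok <- idx >= 1 & idx <= L
      b[ok] <- v[idx[ok]]; b }

    cpos <- which(v == "C")
    n1 <- at(cpos + 1L); n2 <- at(cpos + 2L)
    ctx_p <- ifelse(n1 == "G", "CG", ifelse(n2 == "G", "CHG", "CHH"))
    tri_p <- paste0("C", n1, n2)

    gpos <- which(v == "G")
    m1 <- at(gpos - 1L); m2 <- at(gpos - 2L)
    # downstream on the minus strand = upstream on plus, complemented
    ctx_m <- ifelse(m1 == "C", "CG", ifelse(m2 == "C", "CHG", "CHH"))
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    tri_m <- paste0("C", comp[m1], comp[m2])

    out[[i]] <- data.table(
      chrom = names(genome)[i],
      pos = c(cpos, gpos),
      strand = rep(c("+", "-"), c(length(cpos), length(gpos))),
      context = c(ctx_p, ctx_m),
      tri = c(tri_p, tri_m))
  }
  sites <- rbindlist(out)
  setorder(sites, chrom, pos, strand)
  sites[]
}

#' Write a simulated annotation to FASTA + GFF3 + pair table
#'
#' @param ann [simulate_annotation()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
export_annotation <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(ann$genome, fa)

  genes <- ann$genes
  tx <- ann$transcripts
  feats <- list()
  g <- granges(genes)
  mcols(g) <- DataFrame(type = "gene", ID = genes$gene_id,
                        Parent = NA_character_, phase = NA_integer_,
                        repeat_class = NA_character_)
  feats[[1]] <- g
  # transcript + region children (intronless: regions tile the gene body)
  idx <- match(tx$gene_id, genes$gene_id)
  for (k in seq_len(nrow(tx))) {
    gi <- idx[k]
    gs <- start(genes)[gi]; ge <- end(genes)[gi]
    str <- as.character(strand(genes))[gi]
    u5 <- tx$utr5_len[k]; u3 <- tx$utr3_len[k]
    # intronless transcript: mRNA spans the gene; UTR5 sits at the 5' end of
    # the strand, UTR3 at the 3' end, CDS between them
    if (str == "+") {
      reg <- IRanges(start = c(gs, gs, gs + u5, ge - u3 + 1L),
                     end = c(ge, gs + u5 - 1L, ge - u3, ge))
    } else {
      reg <- IRanges(start = c(gs, ge - u5 + 1L, gs + u3, gs),
                     end = c(ge, ge, ge - u5, gs + u3 - 1L))
    }
    rg <- GRanges(seqnames(genes)[gi], reg, strand = str,
                  seqlengths = seqlengths(genes))
    mcols(rg) <- DataFrame(
      type = c("mRNA", "five_prime_UTR", "CDS", "three_prime_UTR"),
      ID = c(tx$transcript_id[k], paste0(tx$transcript_id[k], c(".utr5", ".cds", ".utr3"))),
      Parent = c(tx$gene_id[k], rep(tx$transcript_id[k], 3)),
      phase = c(NA_integer_, NA_integer_, 0L, NA_integer_),
      repeat_class = NA_character_)
    feats[[length(feats) + 1L]] <- rg
  }
  if (length(ann$repeats)) {
    r <- granges(ann$repeats)
    mcols(r) <- DataFrame(type = "transposable_element",
                          ID = sprintf("TE%04d", seq_along(r)),
                          Parent = NA_character_, phase = NA_integer_,
                          repeat_class = as.character(ann$repeats$repeat_class))
    feats[[length(feats) + 1L]] <- r
  }
  all <- suppressWarnings(do.call(c, feats))
  gff <- file.path(dir, "annotation.gff3")
  rtracklayer::export(all, gff, format = "gff3")

  pairs <- file.path(dir, "pairs.tsv")
  fwrite(ann$pairs, pairs, sep = "\t")
  invisible(c(fasta = fa, gff3 = gff, pairs = pairs))
}
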