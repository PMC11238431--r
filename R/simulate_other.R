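# Seeded simulators for structural variants, expression and m6A site tables.

#' Simulate structural variants with optional breakpoint CHH elevation
#'
#' Breakpoint positions are a mixture of uniform-random and TE-boundary
#' placements controlled by `sv_plan$boundary_weight` (odds of a boundary
#' placement; 0 means fully uniform). A configurable fraction of records of
#' the types in `sv_plan$chh_effect$types` is flagged; the returned `sv_chh`
#' table can be passed to [sim_config()] so the methylome generator elevates
#' CHH means around those breakpoints.
#'
#' @param ann [simulate_annotation()] result
#' @param config [sim_config()]
#' @return list with `records` (SV table as from [parse_sv_vcf()]),
#'   `breakpoints` (`chrom`, `pos`, `sv_type`, `flagged`) and `sv_chh`
#'   (elevation table for the methylome generator; NULL when nothing flagged)
#' @export
simulate_svs <- function(ann, config) {
  set.seed(derive_seed(config$seed, "svs"))
  plan <- config$sv_plan
  chrlen <- seqlengths(ann$genes)
  w <- plan$boundary_weight %||% 0
  p_boundary <- w / (w + 1)

  boundaries <- if (length(ann$repeats)) {
    data.table(chrom = rep(as.character(seqnames(ann$repeats)), 2),
               pos = c(start(ann$repeats), end(ann$repeats)))
  } else data.table(chrom = character(), pos = integer())

  draw_pos <- function(k) {
    use_b <- nrow(boundaries) > 0 & runif(k) < p_boundary
    ci <- sample(length(chrlen), k, replace = TRUE, prob = chrlen / sum(chrlen))
    chrom <- names(chrlen)[ci]
    pos <- as.integer(floor(runif(k, 1, chrlen[ci])))
    if (any(use_b)) {
      bi <- sample(nrow(boundaries), sum(use_b), replace = TRUE)
      chrom[use_b] <- boundaries$chrom[bi]
      pos[use_b] <- pmax(1L, boundaries$pos[bi] +
                           as.integer(round(runif(sum(use_b), -100, 100))))
    }
    data.table(chrom = chrom, pos = pos)
  }

  recs <- list()
  for (ty in SV_TYPES) {
    k <- plan$n[[ty]] %||% 0L
    if (k == 0L) next
    at <- draw_pos(k)
    len <- as.integer(round(exp(rnorm(k, log(500), 0.8)))) + 50L
    endp <- chr2 <- rep(NA_integer_, k); c2 <- rep(NA_character_, k)
    if (ty %in% c("DEL", "DUP", "INV")) {
      endp <- pmin(at$pos + len, chrlen[at$chrom])
      len <- endp - at$pos
    } else if (ty == "TRANS") {
      mate <- draw_pos(k)
      c2 <- mate$chrom; endp <- mate$pos; len <- rep(NA_integer_, k)
    }
    recs[[ty]] <- data.table(
      id = sprintf("%s%04d", ty, seq_len(k)), chrom = at$chrom, pos = at$pos,
      end = as.integer(endp), chrom2 = c2,
      sv_type = factor(ty, levels = SV_TYPES), length = as.numeric(len))
  }
  records <- if (length(recs)) rbindlist(recs) else
    data.table(id = character(), chrom = character(), pos = integer(),
               end = integer(), chrom2 = character(),
               sv_type = factor(character(), levels = SV_TYPES),
               length = numeric())

  eff <- plan$chh_effect
  flagged_ids <- character()
  if (!is.null(eff) && (eff$fraction %||% 0) > 0) {
    cand <- records[sv_type %in% eff$types]
    n_fl <- round(nrow(cand) * eff$fraction)
    flagged_ids <- cand$id[sample(nrow(cand), n_fl)]
  }

  bp <- extract_breakpoints(records, which = "all", per_record = TRUE)
  bp$flagged <- bp$id %in% flagged_ids
  sv_chh <- if (any(bp$flagged))
    data.table(chrom = bp$chrom[bp$flagged], pos = bp$pos[bp$flagged],
               delta = eff$delta, halfwidth = eff$halfwidth)
  else NULL

  list(records = records, breakpoints = bp, sv_chh = sv_chh)
}

#' Simulate an FPKM expression table
#'
#' Log-normal FPKM with additive log-scale shifts per duplication class and,
#' optionally, for m6A-modified genes.
#'
#' @param labels data.table/data.frame with `gene_id` and `class` (levels
#'   singleton/tandem/proximal/dispersed/wgt)
#' @param config [sim_config()]
#' @param modified_genes optional character vector of gene ids receiving the
#'   additional `config$expr$m6a_shift` on the log scale
#' @return `data.table` with `gene_id`, `sample_id`, `fpkm`
#' @export
simulate_expression <- function(labels, config, modified_genes = NULL) {
  set.seed(derive_seed(config$seed, "expression"))
  labels <- normalize_labels(labels)
  e <- config$expr
  shift <- e$class_shifts[labels$label]
  shift[is.na(shift)] <- 0
  if (!is.null(modified_genes))
    shift <- shift + (labels$gene_id %in% modified_genes) * e$m6a_shift
  out <- rbindlist(lapply(seq_len(e$samples), function(s) data.table(
    gene_id = labels$gene_id,
    sample_id = sprintf("S%d", s),
    fpkm = exp(rnorm(nrow(labels), e$meanlog + shift, e$sdlog)))))
  out[]
}

# weighted DRACH alphabet used when writing site k-mers; the heavy A weights
# reproduce the AAACU/AAACA-type top k-mers seen in plant m6A data
draw_drach <- function(k) {
  D <- sample(c("A", "G", "U"), k, replace = TRUE, prob = c(0.6, 0.25, 0.15))
  R <- sample(c("A", "G"), k, replace = TRUE, prob = c(0.6, 0.4))
  H <- sample(c("U", "A", "C"), k, replace = TRUE, prob = c(0.45, 0.35, 0.2))
  paste0(D, R, "A", "C", H)
}

#' Simulate replicate m6A site tables
#'
#' True sites are placed on transcripts of genes drawn per-class with the
#' configured modification probability; positions fall into the 5'UTR, CDS
#' or 3'UTR with the configured region bias (uniformly within the region),
#' and carry DRACH 5-mers. Each replicate observes each true site with the
#' detection probability (probability value drawn from `prob_range`), plus
#' false-positive sites at random positions with sub-threshold-leaning
#' probabilities.
#'
#' @param ann [simulate_annotation()] result
#' @param labels gene class table (`gene_id`, `class`); defaults to the
#'   annotation's ground truth
#' @param config [sim_config()]
#' @return list with `replicates` (list of site `data.table`s:
#'   `transcript_id`, `position`, `probability`, `kmer`), `truth` (true site
#'   table incl. `gene_id`) and `modified_genes`
#' @export
simulate_m6a <- function(ann, config, labels = NULL) {
  set.seed(derive_seed(config$seed, "m6a"))
  labels <- normalize_labels(labels %||% ann$truth$classes)
  mp <- config$m6a
  tx <- as.data.table(ann$transcripts)
  tx[, length := utr5_len + cds_len + utr3_len]
  tx <- merge(tx, labels, by = "gene_id", sort = FALSE)

  pmod <- mp$class_prob[tx$label]
  pmod[is.na(pmod)] <- 0
  is_mod <- runif(nrow(tx)) < pmod
  mod_tx <- tx[is_mod]

  truth <- list()
  if (nrow(mod_tx)) {
    n_sites <- 1L + rpois(nrow(mod_tx), mp$sites_lambda)
    for (i in seq_len(nrow(mod_tx))) {
      k <- n_sites[i]
      region <- sample(c("utr5", "cds", "utr3"), k, replace = TRUE,
                       prob = mp$region_bias[c("utr5", "cds", "utr3")])
      lo <- c(utr5 = 1L,
              cds = mod_tx$utr5_len[i] + 1L,
              utr3 = mod_tx$utr5_len[i] + mod_tx$cds_len[i] + 1L)
      hi <- c(utr5 = mod_tx$utr5_len[i],
              cds = mod_tx$utr5_len[i] + mod_tx$cds_len[i],
              utr3 = mod_tx$length[i])
      pos <- unique(as.integer(floor(runif(k, lo[region], hi[region] + 1))))
      pos <- pmin(pos, mod_tx$length[i])
      truth[[length(truth) + 1L]] <- data.table(
        transcript_id = mod_tx$transcript_id[i], position = pos,
        kmer = draw_drach(length(pos)), gene_id = mod_tx$gene_id[i])
    }
  }
  truth <- if (length(truth)) rbindlist(truth) else
    data.table(transcript_id = character(), position = integer(),
               kmer = character(), gene_id = character())

  reps <- lapply(seq_len(mp$n_replicates), function(r) {
    keep <- runif(nrow(truth)) < mp$detection_prob
    obs <- truth[keep, .(transcript_id, position, kmer)]
    obs$probability <- runif(nrow(obs), mp$prob_range[1], mp$prob_range[2])
    n_fp <- round(nrow(truth) * mp$fp_rate)
    if (n_fp > 0 && nrow(tx)) {
      ti <- sample(nrow(tx), n_fp, replace = TRUE)
      fp <- data.table(transcript_id = tx$transcript_id[ti],
                       position = as.integer(ceiling(runif(n_fp) * tx$length[ti])),
                       kmer = draw_drach(n_fp),
                       probability = runif(n_fp, 0.5, 0.99))
      obs <- rbind(obs, fp)
      obs <- obs[!duplicated(obs[, .(transcript_id, position)])]
    }
    setorder(obs, transcript_id, position)
    obs[, .(transcript_id, position, probability, kmer)]
  })
  list(replicates = reps, truth = truth,
       modified_genes = unique(truth$gene_id))
}
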