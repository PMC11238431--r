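# Methylation-level computation, the sliding-window DMR caller, DMR
# annotation, and the feature metaprofile engine.
#
# DMR procedure: 200-bp sliding windows (100-bp step); per window and
# replicate a weighted methylation level over context cytosines with
# coverage >= min_cov; windows with fewer than min_sites such cytosines in
# any replicate are untested; one-way ANOVA across the two replicate groups
# gives p; Benjamini-Hochberg over all tested windows of the context gives
# q; windows with q < fdr and |group mean difference| >= the context cutoff
# (0.5 for CG/CHG, 0.1 for CHH) are merged (gap <= step, same direction)
# into DMRs with levels recomputed over the merged span.

DMR_CUTOFFS <- c(CG = 0.5, CHG = 0.5, CHH = 0.1)

#' Weighted methylation level
#'
#' Pooled ratio `sum(methylated) / sum(methylated + unmethylated)` over
#' covered cytosines. Returns `NA` (undefined, distinct from 0) when no call
#' has coverage.
#'
#' @param calls data.table with `count_meth`, `count_unmeth`
#' @return level in \[0, 1\], or `NA_real_`
#' @export
weighted_level <- function(calls) {
  tot <- sum(as.numeric(calls$count_meth)) + sum(as.numeric(calls$count_unmeth))
  if (tot == 0) return(NA_real_)
  sum(as.numeric(calls$count_meth)) / tot
}

#' Genome-wide weighted methylation level of one context
#'
#' @param calls CX-style call table
#' @param context `"CG"`, `"CHG"` or `"CHH"`
#' @return weighted level
#' @export
global_context_mean <- function(calls, context) {
  ctx <- context
  sub <- calls[calls$context == ctx & (calls$count_meth + calls$count_unmeth) > 0, ]
  if (nrow(sub) == 0) stop("no covered ", ctx, " calls")
  weighted_level(sub)
}

#' Fold change of two levels
#' @param a,b levels; `b` must be nonzero
#' @return `a / b`
#' @export
fold_change <- function(a, b) {
  if (b == 0) stop("denominator level is zero")
  a / b
}

# per-replicate window aggregation: window k covers (k*step, k*step+window]
window_levels <- function(calls, context, window, step, min_cov) {
  ctx <- context
  dt <- as.data.table(calls)[context == ctx &
                               (count_meth + count_unmeth) >= min_cov]
  if (nrow(dt) == 0)
    return(data.table(chrom = character(), win = integer(), meth = numeric(),
                      total = numeric(), n_sites = integer()))
  n_off <- window %/% step
  pieces <- lapply(seq_len(n_off) - 1L, function(off) {
    w <- (dt$pos - 1L) %/% step - off
    data.table(chrom = dt$chrom, win = w,
               meth = as.numeric(dt$count_meth),
               total = as.numeric(dt$count_meth + dt$count_unmeth))[w >= 0L]
  })
  rbindlist(pieces)[, .(meth = sum(meth), total = sum(total), n_sites = .N),
                    by = .(chrom, win)]
}

#' Call differentially methylated regions between two replicate groups
#'
#' @param calls_a,calls_b lists of CX-style call tables, one per replicate
#'   (at least 2 per group; the ANOVA needs within-group degrees of freedom)
#' @param context cytosine context analysed (contexts are analysed
#'   separately)
#' @param window,step sliding-window size and step in bp (`window` must be a
#'   multiple of `step`)
#' @param min_sites minimum context cytosines with coverage >= `min_cov`
#'   required in every replicate for a window to be tested
#' @param min_cov minimum read coverage per cytosine
#' @param cutoff minimum |group mean difference|; defaults to the context
#'   cutoff (0.5 for CG/CHG, 0.1 for CHH)
#' @param fdr Benjamini-Hochberg threshold on window q-values
#' @return list of class `dmr_result`: `dmrs` (GRanges with `context`,
#'   `level_a`, `level_b`, `delta`, `p_value`, `q_value`, `direction` --
#'   hyper/hypo relative to group A -- and `n_windows`), `windows` (all
#'   tested windows with statistics) and `n_tested`
#' @export
call_dmrs <- function(calls_a, calls_b, context,
                      window = 200L, step = 100L,
                      min_sites = 4L, min_cov = 4L,
                      cutoff = NULL, fdr = 0.05) {
  if (length(calls_a) < 2L || length(calls_b) < 2L)
    stop("need >= 2 replicates per group; single-replicate paired-cytosine ",
         "fallback is unsupported")
  if (window %% step != 0) stop("window must be a multiple of step")
  cutoff <- cutoff %||% DMR_CUTOFFS[[context]]

  reps <- c(calls_a, calls_b)
  grp <- rep(c("A", "B"), c(length(calls_a), length(calls_b)))
  agg <- rbindlist(lapply(seq_along(reps), function(i) {
    w <- window_levels(reps[[i]], context, window, step, min_cov)
    if (nrow(w)) { w$rep_id <- i; w$grp <- grp[i] }
    w
  }), fill = TRUE)
  if (nrow(agg) == 0)
    return(empty_dmr_result(context))

  # tested = window observed in every replicate with enough sites in each
  ok <- agg[, .(n_reps = .N, min_sites_seen = min(n_sites)), by = .(chrom, win)]
  ok <- ok[n_reps == length(reps) & min_sites_seen >= min_sites]
  agg <- agg[ok[, .(chrom, win)], on = c("chrom", "win")]
  if (nrow(agg) == 0)
    return(empty_dmr_result(context))
  agg[, level := meth / total]

  # vectorised two-group one-way ANOVA on replicate window levels
  st <- agg[, {
    la <- level[grp == "A"]; lb <- level[grp == "B"]
    na <- length(la); nb <- length(lb)
    ma <- mean(la); mb <- mean(lb); g <- mean(level)
    ssb <- na * (ma - g)^2 + nb * (mb - g)^2
    ssw <- sum((la - ma)^2) + sum((lb - mb)^2)
    .(mean_a = ma, mean_b = mb, ssb = ssb, ssw = ssw, n = na + nb)
  }, by = .(chrom, win)]
  dfw <- st$n - 2L
  f <- ifelse(st$ssw > 0, (st$ssb / 1) / (st$ssw / dfw),
              ifelse(st$ssb > 0, Inf, 0))
  p <- ifelse(is.infinite(f), 0,
              ifelse(st$ssw > 0, pf(f, 1, dfw, lower.tail = FALSE), 1))
  st[, `:=`(f_stat = f, p_value = p, q_value = benjamini_hochberg(p),
            start = win * step + 1L, end = win * step + window,
            delta = mean_a - mean_b)]

  cand <- st[q_value < fdr & abs(delta) >= cutoff]
  dmrs <- merge_dmr_windows(cand, reps, grp, context, step, min_cov, cutoff)
  structure(list(dmrs = dmrs, windows = st[], n_tested = nrow(st),
                 context = context, cutoff = cutoff, fdr = fdr),
            class = "dmr_result")
}

empty_dmr_result <- function(context) {
  structure(list(dmrs = GRanges(), windows = data.table(), n_tested = 0L,
                 context = context, cutoff = NA_real_, fdr = NA_real_),
            class = "dmr_result")
}

# merge overlapping/adjacent (gap <= step) same-direction candidate windows
# and recompute pooled levels over the merged span; merged regions failing
# the cutoff after recomputation are dropped so that every reported DMR
# satisfies |delta| >= cutoff as stored
merge_dmr_windows <- function(cand, reps, grp, context, step, min_cov, cutoff) {
  if (nrow(cand) == 0) return(GRanges())
  ctx <- context
  pool <- rbindlist(lapply(seq_along(reps), function(i) {
    dt <- as.data.table(reps[[i]])[context == ctx &
                                     (count_meth + count_unmeth) >= min_cov,
                                   .(chrom, pos, count_meth, count_unmeth)]
    dt$grp <- grp[i]
    dt
  }))

  out <- list()
  for (dir_sign in c(1, -1)) {
    sub <- cand[sign(delta) == dir_sign]
    if (nrow(sub) == 0) next
    gr <- reduce(GRanges(sub$chrom, IRanges(sub$start, sub$end)),
                 min.gapwidth = step + 1L)
    if (!length(gr)) next
    hit <- findOverlaps(GRanges(sub$chrom, IRanges(sub$start, sub$end)), gr)
    pmin_ <- tapply(sub$p_value[queryHits(hit)], subjectHits(hit), min)
    qmin_ <- tapply(sub$q_value[queryHits(hit)], subjectHits(hit), min)
    nwin <- tabulate(subjectHits(hit), nbins = length(gr))

    span <- data.table(chrom = as.character(seqnames(gr)),
                       start = start(gr), end = end(gr),
                       idx = seq_along(gr))
    shit <- pool[span, on = .(chrom, pos >= start, pos <= end),
                 .(idx = i.idx, grp = x.grp, count_meth = x.count_meth,
                   count_unmeth = x.count_unmeth), nomatch = NULL]
    lev <- shit[, .(level = sum(as.numeric(count_meth)) /
                      sum(as.numeric(count_meth + count_unmeth))),
                by = .(idx, grp)]
    la <- lev[grp == "A"]$level[match(seq_along(gr), lev[grp == "A"]$idx)]
    lb <- lev[grp == "B"]$level[match(seq_along(gr), lev[grp == "B"]$idx)]

    gr$context <- ctx
    gr$level_a <- la
    gr$level_b <- lb
    gr$delta <- la - lb
    gr$p_value <- as.numeric(pmin_[as.character(seq_along(gr))])
    gr$q_value <- as.numeric(qmin_[as.character(seq_along(gr))])
    gr$direction <- ifelse(gr$delta > 0, "hyper", "hypo")
    gr$n_windows <- nwin
    out[[length(out) + 1L]] <- gr[!is.na(gr$delta) & abs(gr$delta) >= cutoff &
                                    sign(gr$delta) == dir_sign]
  }
  if (!length(out)) return(GRanges())
  res <- sort(suppressWarnings(do.call(c, out)))
  res
}

#' Genomic distribution of DMRs
#'
#' Assigns each DMR to one of `gene_body`, `upstream_2kb` (2 kb upstream of
#' the TSS), `downstream_2kb` (2 kb downstream of the TTS), `TE`, or
#' `intergenic` (excluding TEs) by largest overlap, with precedence
#' gene_body > upstream > downstream > TE > intergenic breaking ties.
#'
#' @param dmrs GRanges (e.g. `call_dmrs()$dmrs`)
#' @param genes gene GRanges (strand-aware)
#' @param tes repeat GRanges
#' @param flank flank size in bp
#' @return named fractions summing to 1 (over categories, attribute
#'   `counts` keeps the raw counts)
#' @export
dmr_genomic_distribution <- function(dmrs, genes, tes, flank = 2000L) {
  cats <- c("gene_body", "upstream_2kb", "downstream_2kb", "TE", "intergenic")
  if (length(dmrs) == 0)
    return(stats::setNames(rep(NA_real_, 5), cats))
  up <- trim_soft(promoters(genes, upstream = flank, downstream = 0))
  dn <- trim_soft(flank_downstream(genes, flank))
  sets <- list(gene_body = reduce(granges(genes)),
               upstream_2kb = reduce(granges(up)),
               downstream_2kb = reduce(granges(dn)),
               TE = if (length(tes)) reduce(granges(tes)) else GRanges())
  cov <- vapply(sets, function(s) overlap_bp(dmrs, s), numeric(length(dmrs)))
  if (is.null(dim(cov))) cov <- matrix(cov, nrow = length(dmrs))
  union_all <- reduce(unlist(GRangesList(sets)))
  cov_int <- width(dmrs) - overlap_bp(dmrs, union_all)
  mat <- cbind(cov, intergenic = cov_int)
  colnames(mat) <- cats
  assigned <- cats[apply(mat, 1, which.max)]  # which.max = first max -> precedence
  counts <- table(factor(assigned, levels = cats))
  frac <- as.numeric(counts) / length(dmrs)
  structure(stats::setNames(frac, cats), counts = counts)
}

# total bp of each query covered by a (reduced) subject set
overlap_bp <- function(query, subject) {
  if (length(subject) == 0) return(numeric(length(query)))
  hit <- findOverlaps(query, subject)
  ov <- pmin(end(query)[queryHits(hit)], end(subject)[subjectHits(hit)]) -
    pmax(start(query)[queryHits(hit)], start(subject)[subjectHits(hit)]) + 1L
  out <- numeric(length(query))
  if (length(hit)) {
    s <- tapply(ov, queryHits(hit), sum)
    out[as.integer(names(s))] <- as.numeric(s)
  }
  out
}

# strand-aware downstream flank (after the TTS)
flank_downstream <- function(genes, flank) {
  flank(genes, width = flank, start = FALSE)
}

trim_soft <- function(gr) {
  start(gr) <- pmax(start(gr), 1L)
  suppressWarnings(trim(gr))
}

#' Associate DMRs with genes within a flank
#'
#' A DMR is associated with every gene whose body extended by `flank` bp on
#' both sides it overlaps by at least 1 bp (a DMR can be listed under
#' several genes).
#'
#' @param dmrs GRanges
#' @param genes gene GRanges with `gene_id`
#' @param flank flank in bp
#' @return `data.table` with `gene_id`, `dmr_index`
#' @export
associate_dmrs_to_genes <- function(dmrs, genes, flank = 2000L) {
  ext <- genes
  start(ext) <- pmax(1L, start(ext) - flank)
  end(ext) <- end(ext) + flank
  ext <- suppressWarnings(trim(ext))
  hit <- findOverlaps(dmrs, ext)
  data.table(gene_id = genes$gene_id[subjectHits(hit)],
             dmr_index = queryHits(hit))[order(gene_id, dmr_index)]
}

#' Methylation metaprofile over features
#'
#' Aligns features on their 5' ends, splits 2-kb flanks into fixed bins and
#' the body into `body_bins` equal fractions (`scaled_body` mode) or fixed
#' `flank_bin`-bp bins (`absolute` mode, truncating longer bodies), flips
#' minus-strand features so bin 0 is 5'-most, and pools a weighted level per
#' bin over all covered context cytosines of all features.
#'
#' @param calls CX-style call table
#' @param features GRanges (genes or TEs; strand used for orientation)
#' @param context cytosine context
#' @param flank flank size in bp
#' @param flank_bin flank bin width in bp
#' @param body_bins number of body bins
#' @param mode `"scaled_body"` or `"absolute"`
#' @param min_cov minimum coverage per cytosine
#' @return list of class `meta_profile`: `profile` (data.table `bin`,
#'   `zone`, `level`, `n_sites`, `n_features`), `used`, `skipped`
#' @export
metaprofile <- function(calls, features, context, flank = 2000L,
                        flank_bin = 100L, body_bins = 20L,
                        mode = c("scaled_body", "absolute"), min_cov = 1L) {
  mode <- match.arg(mode)
  if (length(features) == 0) stop("no features supplied")
  keep <- if (mode == "scaled_body") width(features) >= body_bins else
    rep(TRUE, length(features))
  skipped <- sum(!keep)
  features <- features[keep]
  if (length(features) == 0) stop("all features shorter than body_bins bp")

  ctx <- context
  dt <- as.data.table(calls)[context == ctx &
                               (count_meth + count_unmeth) >= min_cov]
  gr_sites <- GRanges(dt$chrom, IRanges(dt$pos, dt$pos))
  ext <- features
  start(ext) <- pmax(1L, start(ext) - flank)
  end(ext) <- end(ext) + flank
  ext <- suppressWarnings(trim(ext))
  hit <- findOverlaps(gr_sites, ext)
  if (length(hit) == 0) stop("no covered ", ctx, " sites near the features")

  si <- queryHits(hit); fi <- subjectHits(hit)
  fstart <- start(features)[fi]; fend <- end(features)[fi]
  fwidth <- fend - fstart + 1L
  plus <- as.character(strand(features))[fi] != "-"
  off <- ifelse(plus, dt$pos[si] - fstart, fend - dt$pos[si])

  nb_fl <- flank %/% flank_bin
  bin <- integer(length(off))
  in_up <- off < 0
  in_body <- off >= 0 & off < fwidth
  in_dn <- off >= fwidth
  bin[in_up] <- (off[in_up] + flank) %/% flank_bin
  bin[in_body] <- if (mode == "scaled_body") {
    # midpoint scaling keeps plus/minus orientation exactly symmetric
    nb_fl + pmin(body_bins - 1L,
                 as.integer(floor((off[in_body] + 0.5) / fwidth[in_body] *
                                    body_bins)))
  } else {
    nb_fl + pmin(body_bins - 1L, off[in_body] %/% flank_bin)
  }
  bin[in_dn] <- nb_fl + body_bins +
    pmin(nb_fl - 1L, (off[in_dn] - fwidth[in_dn]) %/% flank_bin)
  keep_row <- bin >= 0 & bin < (2L * nb_fl + body_bins)
  if (mode == "absolute")  # truncated bodies: drop sites beyond the window
    keep_row <- keep_row & !(in_body & off >= body_bins * flank_bin)

  pooled <- data.table(bin = bin[keep_row], feature = fi[keep_row],
                       meth = as.numeric(dt$count_meth[si][keep_row]),
                       total = as.numeric(dt$count_meth[si][keep_row] +
                                            dt$count_unmeth[si][keep_row]))
  prof <- pooled[, .(level = sum(meth) / sum(total), n_sites = .N,
                     n_features = length(unique(feature))), by = bin]
  setorder(prof, bin)
  all_bins <- data.table(bin = 0:(2L * nb_fl + body_bins - 1L))
  prof <- prof[all_bins, on = "bin"]
  prof[, zone := c(rep("upstream", nb_fl), rep("body", body_bins),
                   rep("downstream", nb_fl))]
  structure(list(profile = prof[], used = length(features), skipped = skipped,
                 mode = mode, flank = flank, flank_bin = flank_bin,
                 body_bins = body_bins),
            class = "meta_profile")
}
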