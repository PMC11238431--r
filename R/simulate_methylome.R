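# Seeded bisulfite methylome simulator with beta-binomial noise and planted
# differential regions.

# Per-site mean methylation level implied by the annotation and config:
# TE-class baseline overrides genic overrides intergenic; then the optional
# TSS dip, planted DMR shifts (group B only) and breakpoint CHH elevation
# (both groups) are applied, and the result clipped into [0, 0.995].
site_means <- function(ann, config, group) {
  sites <- ann$sites
  gr <- GRanges(sites$chrom, IRanges(sites$pos, sites$pos))
  cls <- rep("intergenic", nrow(sites))
  hit_g <- findOverlaps(gr, ann$genes)
  cls[queryHits(hit_g)] <- "gene"
  if (length(ann$repeats)) {
    hit_t <- findOverlaps(gr, ann$repeats)
    cls[queryHits(hit_t)] <- as.character(ann$repeats$repeat_class[subjectHits(hit_t)])
  }
  m <- numeric(nrow(sites))
  for (ctx in CONTEXTS) {
    sel <- sites$context == ctx
    m[sel] <- config$baselines[[ctx]][cls[sel]]
  }

  if (!is.null(config$tss_dip)) {
    dip <- config$tss_dip
    genes <- ann$genes
    w <- pmax(1L, as.integer(round(width(genes) * dip$frac)))
    plus <- as.character(strand(genes)) != "-"
    dip_gr <- GRanges(seqnames(genes),
                      IRanges(ifelse(plus, start(genes), end(genes) - w + 1L),
                              ifelse(plus, start(genes) + w - 1L, end(genes))))
    hit <- findOverlaps(gr, dip_gr)
    m[unique(queryHits(hit))] <- m[unique(queryHits(hit))] * dip$factor
  }

  if (!is.null(config$dmrs) && group == "B") {
    dmr <- as.data.table(config$dmrs)
    hit <- findOverlaps(gr, GRanges(dmr$chrom, IRanges(dmr$start, dmr$end)))
    q <- queryHits(hit); s <- subjectHits(hit)
    ok <- sites$context[q] == dmr$context[s] & !duplicated(q)
    m[q[ok]] <- m[q[ok]] + dmr$delta[s[ok]]
  }

  if (!is.null(config$sv_chh)) {
    eff <- as.data.table(config$sv_chh)
    hit <- findOverlaps(gr, GRanges(eff$chrom,
                                    IRanges(pmax(1L, eff$pos - eff$halfwidth),
                                            eff$pos + eff$halfwidth)))
    q <- queryHits(hit); s <- subjectHits(hit)
    ok <- sites$context[q] == "CHH" & !duplicated(q)
    m[q[ok]] <- m[q[ok]] + eff$delta[s[ok]]
  }

  pmin(pmax(m, 0), 0.995)
}

#' Simulate one bisulfite replicate (CX-style cytosine calls)
#'
#' Per cytosine: coverage ~ Poisson(`depth`); a site-level methylation
#' probability ~ Beta centred on the baseline of the covering feature
#' (beta-binomial noise gives replicate overdispersion); methylated count ~
#' Binomial(coverage, p). Planted DMRs shift the group-B mean by their delta
#' inside their interval; breakpoint CHH elevations apply to both groups.
#' Fully deterministic given `config$seed`, `group` and `replicate`, each on
#' its own RNG stream.
#'
#' @param ann [simulate_annotation()] result
#' @param config [sim_config()]
#' @param group group label, `"A"` or `"B"`
#' @param replicate replicate index within the group
#' @param .means precomputed [site_means()] vector (internal reuse)
#' @return `data.table` with `chrom`, `pos`, `strand`, `count_meth`,
#'   `count_unmeth`, `context`, `tri`
#' @export
simulate_methylome <- function(ann, config, group = "A", replicate = 1L,
                               .means = NULL) {
  stopifnot(inherits(ann, "sim_annotation"), group %in% names(config$replicates))
  m <- .means %||% site_means(ann, config, group)
  set.seed(derive_seed(config$seed, paste0("methylome:", group, ":", replicate)))
  n <- length(m)
  coverage <- rpois(n, config$depth)
  p <- numeric(n)
  mid <- m > 0 & m < 1
  p[mid] <- rbeta(sum(mid), m[mid] * config$beta_precision,
                  (1 - m[mid]) * config$beta_precision)
  p[m >= 1] <- 1
  meth <- rbinom(n, coverage, p)
  out <- data.table(
    chrom = ann$sites$chrom, pos = ann$sites$pos, strand = ann$sites$strand,
    count_meth = meth, count_unmeth = coverage - meth,
    context = ann$sites$context, tri = ann$sites$tri)
  out[]
}

#' Simulate all replicates of both groups
#'
#' @inheritParams simulate_methylome
#' @return named list of call tables, e.g. `A1, A2, A3, B1, B2, B3`,
#'   plus attribute `groups` mapping names to group labels
#' @export
simulate_methylome_set <- function(ann, config) {
  out <- list()
  for (g in names(config$replicates)) {
    means_g <- site_means(ann, config, g)
    for (r in seq_len(config$replicates[[g]])) {
      out[[paste0(g, r)]] <- simulate_methylome(ann, config, g, r, .means = means_g)
    }
  }
  attr(out, "groups") <- sub("[0-9]+$", "", names(out))
  out
}

#' Plant differential methylation regions
#'
#' Samples `n` non-overlapping intervals of the given width on the simulated
#' genome, avoiding TE annotations (so the shifted mean stays below 1 on top
#' of the local baseline), and returns them as the `dmrs` entry for
#' [sim_config()].
#'
#' @param ann [simulate_annotation()] result
#' @param n number of regions
#' @param width region width in bp
#' @param delta methylation shift added to group B
#' @param context cytosine context carrying the shift
#' @param seed RNG seed for placement
#' @return `data.table` with `chrom`, `start`, `end`, `context`, `delta`
#' @export
plant_dmrs <- function(ann, n = 200L, width = 400L, delta = 0.6,
                       context = "CG", seed = 1L) {
  set.seed(derive_seed(seed, "plant_dmrs"))
  chrlen <- seqlengths(ann$genes)
  got <- GRanges(seqlengths = chrlen)
  tries <- 0L
  while (length(got) < n && tries < n * 100L) {
    tries <- tries + 1L
    ci <- sample(length(chrlen), 1)
    st <- sample(chrlen[ci] - width, 1)
    cand <- GRanges(names(chrlen)[ci], IRanges(st, st + width - 1L),
                    seqlengths = chrlen)
    if (length(ann$repeats) && length(findOverlaps(cand, ann$repeats))) next
    if (length(findOverlaps(cand, got, maxgap = 1000L))) next
    got <- c(got, cand)
  }
  if (length(got) < n)
    stop("could not place ", n, " non-overlapping regions; genome too small")
  data.table(chrom = as.character(seqnames(got)), start = start(got),
             end = end(got), context = context, delta = delta)
}
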