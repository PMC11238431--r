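# Consensus m6A site filtering, k-mer/DRACH analysis, metagene distribution,
# and integration with duplication classes and expression.

validate_kmers <- function(kmer) {
  if (any(nchar(kmer) != 5L))
    stop("k-mers must be 5-mers")
  up <- chartr("tT", "uU", toupper(kmer))
  if (any(!grepl("^[ACGU]{5}$", up)))
    stop("k-mers may only contain A, C, G, U/T")
  up
}

#' Consensus m6A sites across replicates
#'
#' A site (transcript, position) is kept iff it is present with probability
#' >= `probability_threshold` in every replicate. The k-mer is taken from
#' the first replicate; every consensus k-mer must carry the modified A at
#' its centre. Also returns the per-transcript site-count histogram.
#'
#' @param replicates list of >= 2 site tables (`transcript_id`, `position`,
#'   `probability`, `kmer`)
#' @param probability_threshold minimum per-replicate modification
#'   probability
#' @return list of class `m6a_consensus`: `sites` (`transcript_id`,
#'   `position`, `kmer`, `min_probability`), `histogram` (sites per
#'   transcript), `threshold`
#' @export
consensus_sites <- function(replicates, probability_threshold = 0.9) {
  if (length(replicates) < 2L) stop("need >= 2 replicate site tables")
  reps <- lapply(replicates, as.data.table)
  for (i in seq_along(reps)) {
    if (anyDuplicated(reps[[i]][, .(transcript_id, position)]))
      stop("duplicate (transcript, position) within replicate ", i)
  }
  passing <- lapply(reps, function(r) r[probability >= probability_threshold])
  key <- function(r) paste(r$transcript_id, r$position, sep = "\r")
  common <- Reduce(intersect, lapply(passing, key))
  first <- passing[[1]][key(passing[[1]]) %in% common]
  minp <- first$probability
  for (r in passing[-1]) {
    m <- match(key(first), key(r))
    minp <- pmin(minp, r$probability[m])
  }
  sites <- first[, .(transcript_id, position, kmer)]
  sites$min_probability <- minp
  if (nrow(sites)) {
    km <- validate_kmers(sites$kmer)
    if (any(substr(km, 3, 3) != "A"))
      stop("consensus k-mer without A at the centre")
  }
  setorder(sites, transcript_id, position)
  hist <- sites[, .(n_sites = .N), by = transcript_id]
  structure(list(sites = sites[], histogram = hist[],
                 threshold = probability_threshold),
            class = "m6a_consensus")
}

#' Ranked 5-mer frequencies of m6A sites
#'
#' @param sites site table with a `kmer` column
#' @return `data.table` with `kmer`, `count`, `frequency` (summing to 1),
#'   ordered by descending frequency, ties broken lexicographically
#' @export
kmer_frequency <- function(sites) {
  km <- validate_kmers(as.data.table(sites)$kmer)
  tab <- as.data.table(table(kmer = km))
  setnames(tab, "N", "count")
  tab[, frequency := count / sum(count)]
  setorder(tab, -frequency, kmer)
  tab[]
}

#' DRACH motif match
#'
#' TRUE iff the 5-mer matches D-R-A-C-H with D = A/G/U, R = A/G, H = A/C/U
#' and the modified A at the centre (T is read as U). Vectorised.
#'
#' @param kmer character vector of 5-mers
#' @return logical vector
#' @examples
#' is_drach(c("AAACU", "GGACA", "CCACC"))  # TRUE TRUE FALSE
#' @export
is_drach <- function(kmer) {
  up <- validate_kmers(kmer)
  substr(up, 1, 1) %in% c("A", "G", "U") &
    substr(up, 2, 2) %in% c("A", "G") &
    substr(up, 3, 3) == "A" &
    substr(up, 4, 4) == "C" &
    substr(up, 5, 5) %in% c("A", "C", "U")
}

#' Metagene distribution of m6A sites
#'
#' Maps each site to its transcript region (5'UTR, CDS, 3'UTR) by position,
#' then to a normalised bin within the region. Sites on transcripts lacking
#' an annotated region (any zero length) are excluded and counted. Per-bin
#' density is scaled so it integrates to 1 over the concatenated
#' three-region axis (each region normalised to unit width).
#'
#' @param sites consensus site table (`transcript_id`, `position`, 1-based
#'   along the spliced transcript)
#' @param transcripts transcript table with `utr5_len`, `cds_len`,
#'   `utr3_len`
#' @param bins bins per region, `c(utr5, cds, utr3)`
#' @return list of class `metagene`: `region_fractions` (sums to 1),
#'   `density` (`region`, `bin`, `fraction`, `density`), `n_sites`,
#'   `n_excluded`
#' @export
metagene_distribution <- function(sites, transcripts, bins = c(10L, 20L, 20L)) {
  st <- as.data.table(sites)
  tx <- as.data.table(transcripts)
  dt <- merge(st, tx[, .(transcript_id, utr5_len, cds_len, utr3_len)],
              by = "transcript_id")
  if (nrow(dt) < nrow(st))
    stop("site(s) on transcripts missing from the transcript table")
  dt[, length := utr5_len + cds_len + utr3_len]
  if (any(dt$position > dt$length))
    stop("site position beyond transcript length")
  lacking <- dt$utr5_len == 0L | dt$cds_len == 0L | dt$utr3_len == 0L
  n_excluded <- sum(lacking)
  dt <- dt[!lacking]

  region <- ifelse(dt$position <= dt$utr5_len, "utr5",
                   ifelse(dt$position <= dt$utr5_len + dt$cds_len, "cds", "utr3"))
  rel <- numeric(nrow(dt))
  rel[region == "utr5"] <- (dt$position[region == "utr5"] - 0.5) /
    dt$utr5_len[region == "utr5"]
  rel[region == "cds"] <- (dt$position[region == "cds"] -
                             dt$utr5_len[region == "cds"] - 0.5) /
    dt$cds_len[region == "cds"]
  rel[region == "utr3"] <- (dt$position[region == "utr3"] -
                              dt$utr5_len[region == "utr3"] -
                              dt$cds_len[region == "utr3"] - 0.5) /
    dt$utr3_len[region == "utr3"]

  regions <- c("utr5", "cds", "utr3")
  nb <- stats::setNames(as.integer(bins), regions)
  bini <- pmin(nb[region] - 1L, as.integer(floor(rel * nb[region])))
  n_total <- nrow(dt)
  # metagene axis normalised to unit length, one third per region; a bin of
  # region rg has width 1 / (3 * nb[rg]) so density integrates to 1
  dens <- rbindlist(lapply(regions, function(rg) {
    cnt <- tabulate(bini[region == rg] + 1L, nbins = nb[[rg]])
    data.table(region = rg, bin = seq_len(nb[[rg]]) - 1L,
               fraction = cnt / n_total,
               bin_width = 1 / (3 * nb[[rg]]),
               density = (cnt / n_total) * 3 * nb[[rg]])
  }))
  frac <- vapply(regions, function(rg) sum(region == rg) / n_total, numeric(1))
  structure(list(region_fractions = frac, density = dens[],
                 n_sites = n_total, n_excluded = n_excluded),
            class = "metagene")
}

#' Fraction of genes per duplication class with m6A-modified transcripts
#'
#' @param sites consensus site table
#' @param transcripts transcript table with `transcript_id`, `gene_id`
#' @param labels class labels (`gene_id`, `label`)
#' @return `data.table` with `label`, `n_genes`, `n_modified`, `fraction`
#' @export
m6a_fraction_by_class <- function(sites, transcripts, labels) {
  tx <- as.data.table(transcripts)
  lab <- normalize_labels(labels)
  mod_tx <- unique(as.data.table(sites)$transcript_id)
  mod_genes <- unique(tx$gene_id[tx$transcript_id %in% mod_tx])
  out <- lab[, .(n_genes = .N, n_modified = sum(gene_id %in% mod_genes)),
             by = label]
  out[, fraction := n_modified / n_genes]
  setorder(out, -fraction)
  out[]
}

#' Expression of m6A-modified vs unmodified homoeologs
#'
#' Within each homoeolog group that has at least one modified and one
#' unmodified member, modified members go to the High-m6A pool and
#' unmodified members to the Low pool; the pooled per-gene expression
#' distributions are compared with the unpaired Wilcoxon rank-sum test.
#' Groups that are entirely modified or entirely unmodified are excluded.
#'
#' @param sites consensus site table
#' @param expression `gene_id`, `sample_id`, `fpkm`
#' @param groups homoeolog groups (`gene_id`, `group_id`)
#' @param transcripts transcript table linking transcripts to genes
#' @return list: `high`, `low` (per-gene mean FPKM vectors), `test`
#'   ([test_result()]), `n_groups_used`
#' @export
expression_by_m6a <- function(sites, expression, groups, transcripts) {
  tx <- as.data.table(transcripts)
  mod_tx <- unique(as.data.table(sites)$transcript_id)
  mod_genes <- unique(tx$gene_id[tx$transcript_id %in% mod_tx])
  grp <- as.data.table(groups)
  grp[, modified := gene_id %in% mod_genes]
  mixed <- grp[, .(use = any(modified) && any(!modified)), by = group_id]
  grp <- grp[group_id %in% mixed$group_id[mixed$use]]
  if (nrow(grp) == 0) stop("no homoeolog group with both modified and ",
                           "unmodified members")
  expr <- as.data.table(expression)[, .(fpkm = mean(fpkm)), by = gene_id]
  dt <- merge(grp, expr, by = "gene_id")
  high <- dt$fpkm[dt$modified]
  low <- dt$fpkm[!dt$modified]
  list(high = high, low = low,
       test = wilcoxon_rank_sum(high, low, "two_sided"),
       n_groups_used = length(unique(grp$group_id)))
}
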