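# SV summarisation, PAV boundary-density enrichment around features, and
# breakpoint-anchored methylation profiles.

#' Summarise a structural-variant record set
#'
#' Counts per type, total, and the presence/absence-variant (PAV = INS + DEL)
#' fraction as a percentage rounded half-up to 2 decimals. An empty record
#' set yields zero counts and an undefined (NA) fraction.
#'
#' @param records SV table as from [parse_sv_vcf()] (needs `sv_type`),
#'   or a named vector/list of per-type counts
#' @return list of class `sv_summary`: `counts`, `total`, `pav_count`,
#'   `pav_fraction`
#' @export
sv_summary <- function(records) {
  counts <- if (is.data.frame(records)) {
    tab <- table(factor(as.character(records$sv_type), levels = SV_TYPES))
    stats::setNames(as.integer(tab), SV_TYPES)
  } else {
    cnt <- stats::setNames(rep(0L, length(SV_TYPES)), SV_TYPES)
    cnt[names(records)] <- as.integer(unlist(records))
    cnt
  }
  total <- sum(counts)
  stopifnot(total == sum(counts))  # asserted on every call
  pav <- counts[["INS"]] + counts[["DEL"]]
  frac <- if (total > 0) round_half_up(100 * pav / total, 2) else NA_real_
  structure(list(counts = counts, total = total, pav_count = pav,
                 pav_fraction = frac),
            class = "sv_summary")
}

#' @export
print.sv_summary <- function(x, ...) {
  cat("SVs:", paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      sprintf("| total=%d, PAV=%d (%.2f%%)\n", x$total, x$pav_count,
              x$pav_fraction))
  invisible(x)
}

#' Extract breakpoint positions from SV records
#'
#' INS contributes its POS; DEL/DUP/INV contribute POS and END; TRANS
#' contributes both mates' positions. `pav_only` keeps INS + DEL records.
#'
#' @param records SV table as from [parse_sv_vcf()]
#' @param which `"pav_only"` or `"all"`
#' @param per_record keep the source record id on each breakpoint
#' @return `data.table` with `chrom`, `pos` (and `id`, `sv_type` if
#'   `per_record`)
#' @export
extract_breakpoints <- function(records, which = c("pav_only", "all"),
                                per_record = FALSE) {
  which <- match.arg(which)
  dt <- as.data.table(records)
  if (which == "pav_only") dt <- dt[sv_type %in% c("INS", "DEL")]
  if (nrow(dt) == 0) {
    out <- data.table(chrom = character(), pos = integer(),
                      id = character(), sv_type = character())
    if (!per_record) out <- out[, .(chrom, pos)]
    return(out[])
  }
  first <- dt[, .(chrom, pos, id, sv_type)]
  second <- dt[sv_type %in% c("DEL", "DUP", "INV") & !is.na(end),
               .(chrom, pos = as.integer(end), id, sv_type)]
  mates <- dt[sv_type == "TRANS" & !is.na(chrom2) & !is.na(end),
              .(chrom = chrom2, pos = as.integer(end), id, sv_type)]
  out <- rbindlist(list(first, second, mates))
  out$sv_type <- as.character(out$sv_type)
  if (!per_record) out <- out[, .(chrom, pos)]
  out[]
}

#' Methylation profile around breakpoints
#'
#' Pools weighted context levels into fixed bins spanning +-`flank` of every
#' breakpoint, compares them with the genome-wide baseline, and tests the
#' per-breakpoint central-window level against the same breakpoint's distal
#' flank level with the Wilcoxon signed-rank test. Breakpoints closer than
#' `flank` to a contig end are dropped (partial windows would bias bin
#' means) and counted.
#'
#' @param breakpoints `data.table` with `chrom`, `pos`
#' @param calls CX-style call table
#' @param context cytosine context
#' @param flank half-width of the profiled window (must be a multiple of
#'   `bin`)
#' @param bin bin width in bp
#' @param central half-width of the central test zone
#' @param distal width of the outermost flank zone used as the paired
#'   reference
#' @param chrom_lengths named contig lengths; inferred from `calls` if NULL
#' @param min_cov minimum coverage per cytosine
#' @return list of class `breakpoint_profile`: `profile` (`bin_start`,
#'   `level`, `n_sites`), `baseline`, `test` ([test_result()]),
#'   `n_breakpoints`, `n_dropped`
#' @export
breakpoint_methylation_profile <- function(breakpoints, calls, context,
                                           flank = 8000L, bin = 200L,
                                           central = 400L, distal = 400L,
                                           chrom_lengths = NULL,
                                           min_cov = 1L) {
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  bp <- as.data.table(breakpoints)
  if (nrow(bp) == 0) stop("no breakpoints supplied")
  ctx <- context
  dt <- as.data.table(calls)[context == ctx &
                               (count_meth + count_unmeth) >= min_cov]
  if (is.null(chrom_lengths)) {
    cl <- dt[, .(len = max(pos)), by = chrom]
    chrom_lengths <- stats::setNames(cl$len, cl$chrom)
  }
  lim <- chrom_lengths[bp$chrom]
  keep <- !is.na(lim) & bp$pos > flank & bp$pos + flank <= lim
  n_dropped <- sum(!keep)
  bp <- bp[keep]
  if (nrow(bp) == 0) stop("all breakpoints within `flank` of a contig end")
  bp$bp_id <- seq_len(nrow(bp))

  win <- GRanges(bp$chrom, IRanges(bp$pos - flank, bp$pos + flank))
  hit <- findOverlaps(GRanges(dt$chrom, IRanges(dt$pos, dt$pos)), win)
  si <- queryHits(hit); bi <- subjectHits(hit)
  off <- dt$pos[si] - bp$pos[bi]
  bidx <- pmin((off + flank) %/% bin, 2L * (flank %/% bin) - 1L)
  pooled <- data.table(bidx = bidx, bp_id = bi, off = off,
                       meth = as.numeric(dt$count_meth[si]),
                       total = as.numeric(dt$count_meth[si] + dt$count_unmeth[si]))
  prof <- pooled[, .(level = sum(meth) / sum(total), n_sites = .N), by = bidx]
  setorder(prof, bidx)
  prof[, offset_start := bidx * bin - flank]
  prof[, bidx := NULL]

  baseline <- global_context_mean(calls, ctx)

  per_bp <- pooled[, .(
    central = sum(meth[abs(off) <= central]) / sum(total[abs(off) <= central]),
    distal = sum(meth[abs(off) > flank - distal]) /
      sum(total[abs(off) > flank - distal])), by = bp_id]
  per_bp <- per_bp[is.finite(central) & is.finite(distal)]
  test <- wilcoxon_signed_rank(per_bp$central, per_bp$distal)

  structure(list(profile = prof[], baseline = baseline, test = test,
                 n_breakpoints = nrow(bp), n_dropped = n_dropped,
                 central = central, distal = distal, flank = flank),
            class = "breakpoint_profile")
}

#' Breakpoint density around feature boundaries
#'
#' Counts breakpoints in fixed bins spanning +-`flank` of each feature's
#' left and right boundary (the right boundary is flipped so positive
#' offsets always point into the feature), normalised per feature per bin.
#' Per feature, the boundary-zone count (|offset| <= 2 bins, both
#' boundaries) is paired with the distal-zone count (|offset| >
#' `flank` - 2 bins) in a Wilcoxon signed-rank test. Features shorter than
#' `2 * bin` are skipped and counted.
#'
#' @param breakpoints `data.table` with `chrom`, `pos`
#' @param features GRanges
#' @param flank profiled half-width in bp
#' @param bin bin width in bp
#' @return list of class `boundary_profile`: `profile` (`offset_start`,
#'   `density` per boundary side), `test`, `n_features`, `n_skipped`
#' @export
boundary_density <- function(breakpoints, features, flank = 2000L, bin = 100L) {
  if (length(features) == 0) stop("no features supplied")
  keep <- width(features) >= 2L * bin
  n_skipped <- sum(!keep)
  features <- features[keep]
  bp <- as.data.table(breakpoints)
  nb <- flank %/% bin

  empty_profile <- data.table(
    offset_start = rep(((-nb):(nb - 1L)) * bin, 2),
    side = rep(c("left", "right"), each = 2L * nb),
    density = 0)

  if (nrow(bp) == 0) {
    return(structure(list(profile = empty_profile,
                          test = test_result(0, 1, "exact", 0L),
                          n_features = length(features),
                          n_skipped = n_skipped),
                     class = "boundary_profile"))
  }

  bp_gr <- GRanges(bp$chrom, IRanges(bp$pos, bp$pos))
  sides <- list(left = start(features), right = end(features))
  counts <- list()
  per_feat <- matrix(0, nrow = length(features), ncol = 2,
                     dimnames = list(NULL, c("boundary", "distal")))
  for (side in names(sides)) {
    anchor <- sides[[side]]
    win <- GRanges(seqnames(features),
                   IRanges(pmax(1L, anchor - flank), anchor + flank))
    hit <- findOverlaps(bp_gr, win)
    fi <- subjectHits(hit)
    off <- bp$pos[queryHits(hit)] - anchor[fi]
    if (side == "right") off <- -off  # positive offsets point into the feature
    bidx <- pmin((off + flank) %/% bin, 2L * nb - 1L)
    tab <- tapply(rep(1L, length(bidx)), factor(bidx, levels = 0:(2L * nb - 1L)),
                  sum, default = 0L)
    counts[[side]] <- as.numeric(tab) / length(features)
    in_boundary <- abs(off) <= 2L * bin
    in_distal <- abs(off) > flank - 2L * bin
    if (length(fi)) {
      add_b <- tapply(as.integer(in_boundary), fi, sum)
      add_d <- tapply(as.integer(in_distal), fi, sum)
      per_feat[as.integer(names(add_b)), "boundary"] <-
        per_feat[as.integer(names(add_b)), "boundary"] + as.numeric(add_b)
      per_feat[as.integer(names(add_d)), "distal"] <-
        per_feat[as.integer(names(add_d)), "distal"] + as.numeric(add_d)
    }
  }
  profile <- data.table(
    offset_start = rep(((-nb):(nb - 1L)) * bin, 2),
    side = rep(c("left", "right"), each = 2L * nb),
    density = c(counts$left, counts$right))
  test <- wilcoxon_signed_rank(per_feat[, "boundary"], per_feat[, "distal"])
  structure(list(profile = profile, test = test,
                 n_features = length(features), n_skipped = n_skipped),
            class = "boundary_profile")
}
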