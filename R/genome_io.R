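# Readers/writers for the standard formats the pipeline touches and the
# interval primitives built on them. All internal coordinates follow the
# Bioconductor convention (1-based, closed intervals, GRanges/IRanges);
# rtracklayer and VariantAnnotation convert at the file boundary.

REPEAT_CLASSES <- c("Copia", "Gypsy", "LINE", "DNA_TE", "other")
CONTEXTS <- c("CG", "CHG", "CHH")
SV_TYPES <- c("INS", "DEL", "DUP", "INV", "TRANS")

# map free-text repeat annotations onto the fixed class enum
normalize_repeat_class <- function(x) {
  out <- rep("other", length(x))
  out[grepl("copia", x, ignore.case = TRUE)] <- "Copia"
  out[grepl("gypsy", x, ignore.case = TRUE)] <- "Gypsy"
  out[grepl("line", x, ignore.case = TRUE)] <- "LINE"
  out[grepl("^dna|dna[_-]?te|terminal inverted", x, ignore.case = TRUE)] <- "DNA_TE"
  out[x %in% REPEAT_CLASSES] <- x[x %in% REPEAT_CLASSES]
  factor(out, levels = REPEAT_CLASSES)
}

validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("malformed GFF3 line ", i, ": expected 9 tab-separated fields")
    st <- suppressWarnings(as.numeric(f[4])); en <- suppressWarnings(as.numeric(f[5]))
    if (is.na(st) || is.na(en))
      stop("malformed GFF3 line ", i, ": non-numeric coordinates")
    if (en < st)
      stop("malformed GFF3 line ", i, ": end < start")
    if (!f[7] %in% c("+", "-", "."))
      stop("unknown strand '", f[7], "' at GFF3 line ", i)
  }
  invisible(TRUE)
}

#' Parse a GFF3 annotation into gene, transcript and repeat models
#'
#' Genes become a `GRanges` with strand-aware `tss`/`tts` positions (the TSS
#' is the 5'-most genomic base of the gene: `start` on `+`, `end` on `-`).
#' Transcript models carry the 5'UTR/CDS/3'UTR lengths summed over their
#' child features. Features whose `type` is listed in `repeat_types` become
#' repeat annotations, classed through the attribute named by
#' `repeat_class_attr` (free text is matched onto Copia/Gypsy/LINE/DNA_TE,
#' anything else is `other`).
#'
#' @param path GFF3 file (1-based inclusive coordinates per the standard)
#' @param repeat_types GFF3 `type` values treated as repeats
#' @param repeat_class_attr attribute naming the repeat class
#' @return list with `genes` (GRanges: `gene_id`, `tss`, `tts`),
#'   `transcripts` (data.table: `transcript_id`, `gene_id`, `utr5_len`,
#'   `cds_len`, `utr3_len`) and `repeats` (GRanges: `repeat_class`)
#' @export
parse_gff3 <- function(path,
                       repeat_types = c("transposable_element", "repeat_region"),
                       repeat_class_attr = "repeat_class") {
  validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")

  genes <- gr[gr$type == "gene"]
  if (length(genes)) {
    genes$gene_id <- as.character(genes$ID)
    plus <- as.character(strand(genes)) != "-"
    genes$tss <- ifelse(plus, start(genes), end(genes))
    genes$tts <- ifelse(plus, end(genes), start(genes))
    mcols(genes) <- mcols(genes)[, c("gene_id", "tss", "tts")]
  }

  tx <- gr[gr$type %in% c("mRNA", "transcript")]
  transcripts <- data.table(transcript_id = character(), gene_id = character(),
                            utr5_len = integer(), cds_len = integer(),
                            utr3_len = integer())
  if (length(tx)) {
    parent_of <- function(g) vapply(as.list(g$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    kids <- gr[gr$type %in% c("five_prime_UTR", "CDS", "three_prime_UTR")]
    kid_dt <- data.table(parent = parent_of(kids),
                         type = as.character(kids$type),
                         width = width(kids))
    lens <- kid_dt[, .(len = sum(width)), by = .(parent, type)]
    transcripts <- data.table(transcript_id = as.character(tx$ID),
                              gene_id = parent_of(tx))
    for (ty in c("five_prime_UTR", "CDS", "three_prime_UTR")) {
      col <- c(five_prime_UTR = "utr5_len", CDS = "cds_len",
               three_prime_UTR = "utr3_len")[[ty]]
      sub <- lens[type == ty]
      transcripts[[col]] <- as.integer(sub$len[match(transcripts$transcript_id,
                                                     sub$parent)])
      transcripts[[col]][is.na(transcripts[[col]])] <- 0L
    }
  }

  reps <- gr[as.character(gr$type) %in% repeat_types]
  if (length(reps)) {
    raw <- if (repeat_class_attr %in% names(mcols(reps)))
      as.character(mcols(reps)[[repeat_class_attr]]) else rep("other", length(reps))
    raw[is.na(raw)] <- "other"
    reps$repeat_class <- normalize_repeat_class(raw)
    mcols(reps) <- mcols(reps)[, "repeat_class", drop = FALSE]
  }

  list(genes = genes, transcripts = transcripts, repeats = reps)
}

#' Read a Bismark-style cytosine (CX) report
#'
#' One row per cytosine: chromosome, 1-based position, strand, methylated and
#' unmethylated read counts, context (CG/CHG/CHH) and trinucleotide.
#' Zero-coverage rows are retained; their level is undefined and they are
#' excluded from weighted means downstream.
#'
#' @param path tab-separated CX report
#' @return `data.table` with columns `chrom`, `pos`, `strand`, `count_meth`,
#'   `count_unmeth`, `context`, `tri`
#' @export
parse_cx_report <- function(path) {
  calls <- fread(path, header = FALSE, sep = "\t",
                 col.names = c("chrom", "pos", "strand", "count_meth",
                               "count_unmeth", "context", "tri"),
                 colClasses = list(character = c(1, 3, 6, 7),
                                   integer = c(2, 4, 5)))
  bad <- setdiff(unique(calls$context), CONTEXTS)
  if (length(bad))
    stop("unknown methylation context token(s): ", paste(bad, collapse = ", "))
  if (any(calls$count_meth < 0 | calls$count_unmeth < 0))
    stop("negative read counts in CX report")
  calls[]
}

#' Write a CX report
#' @param calls data.table as returned by [parse_cx_report()]
#' @param path output path
#' @export
write_cx_report <- function(calls, path) {
  fwrite(calls[, .(chrom, pos, strand, count_meth, count_unmeth, context, tri)],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Parse structural variants from a cuteSV-style VCF
#'
#' Reads `SVTYPE`, `SVLEN`, `END` and (for translocations) `CHR2` INFO keys.
#' `BND`/`TRA` records map to type `TRANS`; `SVLEN` signs are discarded.
#' Records with an unknown `SVTYPE` are skipped with a warning and counted in
#' the `n_skipped` attribute; a missing `SVTYPE` is an error.
#'
#' @param path VCF 4.x file
#' @return `data.table` with `id`, `chrom`, `pos`, `end`, `chrom2`,
#'   `sv_type`, `length` (1-based positions as in the VCF)
#' @export
parse_sv_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  if (!"SVTYPE" %in% names(info)) stop("VCF lacks the SVTYPE INFO key")
  svtype_raw <- as.character(info$SVTYPE)
  if (anyNA(svtype_raw)) stop("record(s) missing SVTYPE")

  unlist1 <- function(x) {
    if (is.list(x) || is(x, "List"))
      vapply(as.list(x), function(v) if (length(v)) as.numeric(v[[1]]) else NA_real_,
             numeric(1))
    else as.numeric(x)
  }
  svlen <- if ("SVLEN" %in% names(info)) abs(unlist1(info$SVLEN)) else
    rep(NA_real_, length(rr))
  endpos <- if ("END" %in% names(info)) unlist1(info$END) else
    rep(NA_real_, length(rr))
  chr2 <- if ("CHR2" %in% names(info)) as.character(info$CHR2) else
    rep(NA_character_, length(rr))

  sv_type <- svtype_raw
  sv_type[sv_type %in% c("BND", "TRA")] <- "TRANS"
  keep <- sv_type %in% SV_TYPES
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    warning(n_skipped, " record(s) with unknown SVTYPE skipped: ",
            paste(unique(svtype_raw[!keep]), collapse = ", "))

  out <- data.table(
    id = names(rr), chrom = as.character(seqnames(rr)),
    pos = start(rr), end = as.integer(endpos), chrom2 = chr2,
    sv_type = factor(sv_type, levels = SV_TYPES), length = svlen)[keep]
  len_fallback <- is.na(out$length) & !is.na(out$end)
  out$length[len_fallback] <- out$end[len_fallback] - out$pos[len_fallback]
  if (any(!is.na(out$end) & is.na(out$chrom2) & out$end < out$pos))
    stop("SV record with END < POS")
  if (any(out$sv_type != "TRANS" & (is.na(out$length) | out$length <= 0)))
    stop("non-TRANS SV record without a positive length")
  attr(out, "n_skipped") <- n_skipped
  out[]
}

#' Write structural variants as a cuteSV-style VCF
#'
#' @param records data.table as returned by [parse_sv_vcf()]
#' @param path output path
#' @param contigs named integer vector of contig lengths for the header
#' @export
write_sv_vcf <- function(records, path, contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of structural variant">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of structural variant">',
    '##INFO=<ID=CHR2,Number=1,Type=String,Description="Mate chromosome for translocations">')
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("SVTYPE=%s", as.character(records$sv_type))
  has_len <- !is.na(records$length)
  info[has_len] <- paste0(info[has_len], ";SVLEN=",
                          as.integer(records$length[has_len]))
  has_end <- !is.na(records$end)
  info[has_end] <- paste0(info[has_end], ";END=",
                          as.integer(records$end[has_end]))
  has_c2 <- !is.na(records$chrom2)
  info[has_c2] <- paste0(info[has_c2], ";CHR2=", records$chrom2[has_c2])
  body <- if (nrow(records)) sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\t%s",
    records$chrom, records$pos, records$id,
    sub("TRANS", "TRA", as.character(records$sv_type)), info) else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Tile sequences into overlapping windows
#'
#' Windows of `window` bp every `step` bp starting at the sequence 5' end.
#' After the last full window, one truncated terminal window is emitted if it
#' extends coverage and is at least `step` bp long. Window names encode the
#' source coordinates as `chrom:start-end` (1-based inclusive).
#'
#' @param seqs `Biostrings::DNAStringSet` (or path to a FASTA file)
#' @param window window size in bp
#' @param step step size in bp (`window >= step >= 1`)
#' @return `DNAStringSet` of windowed sequences
#' @export
tile_genome <- function(seqs, window = 10000L, step = 100L) {
  if (is.character(seqs)) seqs <- Biostrings::readDNAStringSet(seqs)
  stopifnot(window >= step, step >= 1)
  out <- list()
  for (i in seq_along(seqs)) {
    L <- width(seqs)[i]
    starts <- tile_starts(L, window, step)
    if (!length(starts)) next
    ends <- pmin(starts + window - 1L, L)
    w <- Biostrings::DNAStringSet(seqs[[i]], start = starts, end = ends)
    names(w) <- sprintf("%s:%d-%d", names(seqs)[i], starts, ends)
    out[[length(out) + 1L]] <- w
  }
  if (!length(out)) return(Biostrings::DNAStringSet())
  do.call(c, out)
}

# 1-based start positions of the tiling; closed-form full-window count plus
# at most one truncated terminal window
tile_starts <- function(L, window, step) {
  if (L < 1L) return(integer())
  n_full <- if (L >= window) (L - window) %/% step + 1L else 0L
  starts <- if (n_full > 0) (seq_len(n_full) - 1L) * step + 1L else integer()
  part_start <- n_full * step + 1L
  covered <- if (n_full > 0) (n_full - 1L) * step + window else 0L
  if (L > covered && (L - part_start + 1L) >= step)
    starts <- c(starts, part_start)
  starts
}

#' Pairwise overlap length of genomic intervals
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled)
#' @return integer vector of overlap lengths in bp (0 for different
#'   chromosomes or disjoint ranges)
#' @export
interval_overlap <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n); b <- rep(b, length.out = n)
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  as.integer(ifelse(same, pmax(0L, ov), 0L))
}
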