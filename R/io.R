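#' Read SV calls from a VCF file
#'
#' Parses a VCF 4.x file with the usual SV conventions: `SVTYPE` in INFO,
#' interval extent from `END` and/or `SVLEN`, symbolic (`<DEL>`, `<INS>`,
#' `<DUP>`, `<INV>`) or sequence-resolved ALT alleles. Coordinates are
#' converted to the internal 0-based half-open convention (VCF `POS` is taken
#' as the 1-based first affected base, so a DEL at POS=101, END=200 becomes
#' `[100, 200)`). Negative `SVLEN` for deletions is normalized to a positive
#' length.
#'
#' The reader is loss-counting: records lacking `SVTYPE`, with irreconcilable
#' `END` vs `SVLEN` (disagreement beyond 1 bp for DEL/INV/DUP), or shorter
#' than `min_sv_len` are skipped with a warning, and
#' `attr(result, "tally")` reports `records`, `parsed` and `skipped` counts
#' (always `records == parsed + skipped`).
#'
#' @param path VCF file (plain or gzipped).
#' @param sample_id,caller_id provenance labels attached to every call.
#' @param min_sv_len minimum length retained (default 10 bp).
#' @return An [sv_calls()] table with a `"tally"` attribute.
#' @export
read_sv_vcf <- function(path, sample_id = "S1", caller_id = "caller",
                        min_sv_len = 10) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.null(fix) && is.null(dim(fix)))  # single record drops dims
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- if (is.null(fix)) 0L else nrow(fix)
  if (n == 0) {
    out <- sv_calls()
    attr(out, "tally") <- c(records = 0L, parsed = 0L, skipped = 0L)
    return(out)
  }
  pos <- as.numeric(fix[, "POS"])
  alt <- fix[, "ALT"]
  filt <- fix[, "FILTER"]
  filt[is.na(filt)] <- "."
  svtype <- vcfR::extract.info(v, "SVTYPE")
  endf <- suppressWarnings(as.numeric(vcfR::extract.info(v, "END")))
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(v, "SVLEN")))

  skip <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  mark <- function(bad, why) {
    new <- bad & !skip
    skip[new] <<- TRUE
    reason[new] <<- why
  }
  mark(is.na(svtype) | !(svtype %in% SV_TYPES), "missing or unknown SVTYPE")

  ins <- !skip & svtype == "INS"
  span <- !skip & svtype %in% c("DEL", "INV", "DUP")
  # resolve extent: prefer END, fall back to POS + |SVLEN|
  end0 <- ifelse(!is.na(endf), endf, pos + abs(svlen))
  mark(span & is.na(end0), "no END or SVLEN")
  span <- span & !skip
  # END and SVLEN must agree to 1 bp when both are present
  both <- span & !is.na(endf) & !is.na(svlen)
  mark(both & abs((endf - pos + 1) - abs(svlen)) > 1, "END/SVLEN disagree")
  span <- span & !skip

  len <- rep(NA_real_, n)
  len[span] <- end0[span] - pos[span] + 1
  ins_seq <- rep(NA_character_, n)
  seq_res <- ins & !startsWith(alt, "<") & !is.na(alt) & nchar(alt) > 1
  ins_seq[seq_res] <- substring(alt[seq_res], 2)
  len[ins] <- ifelse(!is.na(svlen[ins]), abs(svlen[ins]),
                     nchar(ins_seq[ins]))
  mark(ins & is.na(len), "INS without SVLEN or sequence ALT")
  mark(!skip & len < min_sv_len, paste0("length < ", min_sv_len))

  keep <- !skip
  out <- if (any(keep)) {
    as_sv_calls(data.frame(
      chrom = fix[keep, "CHROM"],
      start = ifelse(svtype[keep] == "INS", pos[keep] - 1, pos[keep] - 1),
      end = ifelse(svtype[keep] == "INS", pos[keep] - 1, end0[keep]),
      svtype = svtype[keep], length = len[keep],
      sample_id = sample_id, caller_id = caller_id,
      filter_status = filt[keep], inserted_seq = ins_seq[keep],
      stringsAsFactors = FALSE
    ), min_sv_len = min_sv_len)
  } else sv_calls()
  n_skip <- sum(skip)
  if (n_skip > 0)
    warning(sprintf("%s: skipped %d of %d records (%s)", basename(path),
                    n_skip, n, paste(unique(stats::na.omit(reason)),
                                     collapse = "; ")))
  attr(out, "tally") <- c(records = n, parsed = sum(keep), skipped = n_skip)
  attr(out, "skip_reasons") <- table(reason[skip])
  out
}

vcf_header <- function(sample_cols, extra_info = character(), seed = NULL) {
  c("##fileformat=VCFv4.2",
    "##source=svmosaic",
    if (!is.null(seed)) paste0("##svmosaic_seed=", seed),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    extra_info,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Presence (1) or absence (.) of the event\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(sample_cols)) c("FORMAT", sample_cols)),
          collapse = "\t"))
}

#' Write per-sample SV calls as a VCF file
#'
#' Inverse of [read_sv_vcf()] at the interval level: internal 0-based
#' half-open intervals become 1-based `POS`/`END`, deletions get a negative
#' `SVLEN` per VCF convention, insertions are written at their site with the
#' inserted sequence in ALT when available, otherwise a symbolic `<INS>`.
#'
#' @param calls an [sv_calls()] table (one sample).
#' @param path output file.
#' @param seed optional integer recorded in the header.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path, seed = NULL) {
  calls <- calls[order(calls$chrom, calls$start, calls$end), , drop = FALSE]
  ins <- calls$svtype == "INS"
  svlen <- ifelse(calls$svtype == "DEL", -calls$length, calls$length)
  alt <- paste0("<", calls$svtype, ">")
  has_seq <- ins & !is.na(calls$inserted_seq)
  alt[has_seq] <- paste0("N", calls$inserted_seq[has_seq])
  info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", calls$svtype,
                  as.integer(ifelse(ins, calls$start + 1, calls$end)),
                  as.integer(svlen))
  lines <- c(vcf_header(character(), seed = seed),
             if (nrow(calls)) sprintf(
               "%s\t%d\t%s\tN\t%s\t.\t%s\t%s",
               calls$chrom, as.integer(calls$start + 1),
               paste0("sv", seq_len(nrow(calls))), alt,
               calls$filter_status, info))
  writeLines(lines, path)
  invisible(path)
}

#' Write an SV cluster catalog as a multi-sample VCF
#'
#' One record per cluster at its representative breakpoints, with INFO fields
#' `SVTYPE`, `END`, `SVLEN`, `NSAMP` (distinct carrier samples) and
#' `TIGHTNESS`, and haploid-style presence/absence genotypes (`1` carrier,
#' `.` non-carrier) for every panel sample. Records are written
#' coordinate-sorted. The representative interval round-trips exactly through
#' [read_sv_vcf()].
#'
#' @param clusters an `sv_cluster_set` from [cluster_all()].
#' @param path output file.
#' @param seed optional integer recorded in the header.
#' @return `path`, invisibly.
#' @export
write_cluster_vcf <- function(clusters, path, seed = NULL) {
  cat_df <- clusters$clusters
  panel <- clusters$panel
  ord <- order(cat_df$chrom, cat_df$rep_start, cat_df$rep_end)
  cat_df <- cat_df[ord, , drop = FALSE]
  memb <- clusters$membership[, cat_df$cluster_id, drop = FALSE]
  ins <- cat_df$svtype == "INS"
  svlen <- ifelse(cat_df$svtype == "DEL", -cat_df$rep_length, cat_df$rep_length)
  info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;NSAMP=%d;TIGHTNESS=%.6g",
                  cat_df$svtype,
                  as.integer(ifelse(ins, cat_df$rep_start + 1, cat_df$rep_end)),
                  as.integer(svlen), cat_df$n_samples, cat_df$tightness)
  cm <- t(memb)  # clusters x samples
  gt_str <- apply(cm, 1, function(x) paste(ifelse(x, "1", "."),
                                           collapse = "\t"))
  extra <- c(
    "##INFO=<ID=NSAMP,Number=1,Type=Integer,Description=\"Number of carrier samples\">",
    "##INFO=<ID=TIGHTNESS,Number=1,Type=Float,Description=\"Mean per-side breakpoint deviation over representative length\">")
  lines <- c(vcf_header(panel, extra_info = extra, seed = seed),
             if (nrow(cat_df)) sprintf(
               "%s\t%d\t%s\tN\t<%s>\t.\tPASS\t%s\tGT\t%s",
               cat_df$chrom, as.integer(cat_df$rep_start + 1),
               cat_df$cluster_id, cat_df$svtype, info, gt_str))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Builds one transcript model per gene from `gene`/`mRNA`/`CDS`/UTR
#' features, keeping the longest mRNA per gene (longest-isoform convention).
#' Introns are the within-transcript gaps between exonic features. GFF
#' 1-based inclusive coordinates become 0-based half-open; `tss` is the
#' 0-based position of the transcription start (the larger genomic coordinate
#' for minus-strand genes). Genes whose CDS lies outside the gene span are
#' rejected with a warning; the `"tally"` attribute counts genes in, parsed
#' and skipped.
#'
#' @param path GFF3 file.
#' @return A `gene_models` object: list with `genes` (gene_id, chrom, strand,
#'   start, end, tss) and `features` (gene_id, type, start, end) data.frames.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   id = if (!is.null(gr$ID)) as.character(gr$ID) else NA,
                   stringsAsFactors = FALSE)
  par <- gr$Parent
  df$parent <- if (is.null(par)) NA_character_ else
    vapply(as.list(par), function(p) if (length(p)) p[[1]] else NA_character_, "")
  genes <- df[df$type == "gene", , drop = FALSE]
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  feats <- df[df$type %in% c("CDS", "five_prime_UTR", "three_prime_UTR",
                             "exon"), , drop = FALSE]
  out_genes <- list(); out_feats <- list(); skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gm <- mrna[mrna$parent %in% g$id, , drop = FALSE]
    if (nrow(gm) == 0) { skipped <- skipped + 1L; next }
    m <- gm[which.max(gm$end - gm$start), ]
    f <- feats[feats$parent %in% m$id, , drop = FALSE]
    cds <- f[f$type == "CDS", , drop = FALSE]
    if (nrow(cds) && (min(cds$start) < g$start || max(cds$end) > g$end)) {
      warning("gene ", g$id, ": CDS outside gene span; gene rejected")
      skipped <- skipped + 1L
      next
    }
    exonic <- f[f$type %in% c("CDS", "five_prime_UTR", "three_prime_UTR",
                              "exon"), , drop = FALSE]
    introns <- interval_gaps(exonic$start, exonic$end, m$start, m$end)
    fk <- rbind(
      if (nrow(f)) data.frame(gene_id = g$id,
                              type = sub("^exon$", "exon", f$type),
                              start = f$start, end = f$end,
                              stringsAsFactors = FALSE),
      if (nrow(introns)) data.frame(gene_id = g$id, type = "intron",
                                    start = introns$start, end = introns$end,
                                    stringsAsFactors = FALSE))
    out_feats[[length(out_feats) + 1L]] <- fk
    out_genes[[length(out_genes) + 1L]] <- data.frame(
      gene_id = g$id, chrom = g$chrom, strand = g$strand,
      start = g$start, end = g$end,
      tss = if (g$strand == "-") g$end - 1 else g$start,
      stringsAsFactors = FALSE)
  }
  res <- gene_models(
    genes = if (length(out_genes)) do.call(rbind, out_genes) else
      data.frame(gene_id = character(), chrom = character(),
                 strand = character(), start = numeric(), end = numeric(),
                 tss = numeric(), stringsAsFactors = FALSE),
    features = if (length(out_feats)) do.call(rbind, out_feats) else
      data.frame(gene_id = character(), type = character(),
                 start = numeric(), end = numeric(), stringsAsFactors = FALSE))
  attr(res, "tally") <- c(records = nrow(genes),
                          parsed = nrow(genes) - skipped, skipped = skipped)
  res
}

#' @rdname read_gff_genes
#' @param genes,features the two component data.frames (see return value).
#' @export
gene_models <- function(genes, features) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end", "tss") %in%
                  names(genes)),
            all(c("gene_id", "type", "start", "end") %in% names(features)),
            all(genes$strand %in% c("+", "-")))
  rownames(genes) <- NULL; rownames(features) <- NULL
  structure(list(genes = genes, features = features), class = "gene_models")
}

# gaps of [start,end) blocks within [lo,hi)
interval_gaps <- function(start, end, lo, hi) {
  if (!length(start))
    return(data.frame(start = numeric(), end = numeric()))
  o <- order(start)
  start <- start[o]; end <- cummax(end[o])
  gs <- c(lo, end); ge <- c(start, hi)
  keep <- gs < ge
  # collapse overlapping blocks first
  res <- data.frame(start = gs[keep], end = ge[keep])
  res[res$start < res$end & res$start >= lo & res$end <= hi, , drop = FALSE]
}

#' Write gene models as GFF3
#'
#' @param models a `gene_models` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(models, path) {
  g <- models$genes; f <- models$features
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    mid <- paste0(gi$gene_id, ".1")
    lines <- c(lines,
      sprintf("%s\tsvmosaic\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              gi$chrom, as.integer(gi$start + 1), as.integer(gi$end),
              gi$strand, gi$gene_id),
      sprintf("%s\tsvmosaic\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              gi$chrom, as.integer(gi$start + 1), as.integer(gi$end),
              gi$strand, mid, gi$gene_id))
    fi <- f[f$gene_id == gi$gene_id & f$type != "intron", , drop = FALSE]
    if (nrow(fi))
      lines <- c(lines, sprintf(
        "%s\tsvmosaic\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
        gi$chrom, fi$type, as.integer(fi$start + 1), as.integer(fi$end),
        gi$strand, mid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an annotation track from a BED-like file
#'
#' BED 4+ with optional fifth column carrying a class label (e.g. a TE
#' superfamily such as DTT, DTH, DTM, RLG). BED coordinates are already
#' 0-based half-open and are taken as-is. Malformed lines (`start >= end`)
#' are skipped and counted in the `"tally"` attribute.
#'
#' @param path BED file (tab-separated, no header; `track`/`#` lines ignored).
#' @return A data.frame of class `annotation_track` with columns `chrom`,
#'   `start`, `end`, `name`, `class`, sorted by chrom and start.
#' @export
read_bed_track <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  raw <- raw[!startsWith(as.character(raw[[1]]), "track"), , drop = FALSE]
  n <- nrow(raw)
  df <- data.frame(
    chrom = as.character(raw[[1]]),
    start = as.numeric(raw[[2]]), end = as.numeric(raw[[3]]),
    name = if (ncol(raw) >= 4) as.character(raw[[4]]) else
      paste0("feat", seq_len(n)),
    class = if (ncol(raw) >= 5) as.character(raw[[5]]) else NA_character_,
    stringsAsFactors = FALSE)
  bad <- !(df$start < df$end) | is.na(df$start) | is.na(df$end)
  if (any(bad))
    warning(basename(path), ": skipped ", sum(bad), " malformed BED lines")
  df <- df[!bad, , drop = FALSE]
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotation_track", "data.frame")
  attr(df, "tally") <- c(records = n, parsed = n - sum(bad),
                         skipped = sum(bad))
  df
}

#' @rdname read_bed_track
#' @param track an `annotation_track` data.frame.
#' @export
write_bed_track <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", track$chrom,
                   as.integer(track$start), as.integer(track$end),
                   track$name, ifelse(is.na(track$class), ".", track$class))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file into a named sequence set
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet]; duplicate sequence IDs are an error.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate sequence IDs in ", basename(path), ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(seqs) <- ids
  seqs
}
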