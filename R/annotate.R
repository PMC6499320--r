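cluster_catalog <- function(clusters) {
  if (inherits(clusters, "sv_cluster_set")) clusters$clusters else clusters
}

track_granges <- function(track) {
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(start = track$start + 1,
                                          end = track$end))
}

catalog_granges <- function(cat_df) {
  ins <- cat_df$svtype == "INS"
  GenomicRanges::GRanges(cat_df$chrom, IRanges::IRanges(
    start = cat_df$rep_start + 1,
    end = ifelse(ins, cat_df$rep_start + 1, cat_df$rep_end)))
}

#' Classify clusters by transposable-element overlap
#'
#' A cluster is `strict_te` when some single TE record reaches 80%
#' reciprocal overlap with it (at least 80% of the TE covered by the SV and
#' at least 80% of the SV covered by the TE); otherwise `repeat_associated`
#' when the union of TE/repeat records covers at least half of the cluster
#' length; otherwise `none`. Insertions have no reference extent and are
#' classified `none`. The best label is the class of the maximum-RO TE.
#'
#' @param clusters an `sv_cluster_set` or its catalog data.frame.
#' @param te_track an `annotation_track` of TE/repeat intervals.
#' @param strict_ro reciprocal-overlap threshold for `strict_te`.
#' @param cover_frac union-coverage threshold for `repeat_associated`.
#' @return A data.frame with `cluster_id`, `te_status`, `best_class`,
#'   `best_ro`, `union_cover`.
#' @export
classify_te_overlap <- function(clusters, te_track, strict_ro = 0.8,
                                cover_frac = 0.5) {
  cat_df <- cluster_catalog(clusters)
  n <- nrow(cat_df)
  res <- data.frame(cluster_id = cat_df$cluster_id,
                    te_status = rep("none", n),
                    best_class = NA_character_, best_ro = 0,
                    union_cover = 0, stringsAsFactors = FALSE)
  if (!n || !nrow(te_track)) {
    class(res) <- c("te_classification", "data.frame")
    return(res)
  }
  span <- cat_df$svtype != "INS"
  gc <- catalog_granges(cat_df)
  gt <- track_granges(te_track)
  h <- GenomicRanges::findOverlaps(gc[span], gt)
  qi <- which(span)[S4Vectors::queryHits(h)]
  ti <- S4Vectors::subjectHits(h)
  if (length(qi)) {
    ov <- pmin(cat_df$rep_end[qi], te_track$end[ti]) -
      pmax(cat_df$rep_start[qi], te_track$start[ti])
    len_c <- cat_df$rep_end[qi] - cat_df$rep_start[qi]
    len_t <- te_track$end[ti] - te_track$start[ti]
    ro <- pmin(ov / len_c, ov / len_t)
    best <- tapply(seq_along(qi), qi, function(ix) ix[which.max(ro[ix])])
    bi <- unlist(best)
    rows <- as.integer(names(best))
    res$best_ro[rows] <- ro[bi]
    res$best_class[rows] <- te_track$class[ti[bi]]
    # union coverage of each cluster by the track
    cover <- tapply(seq_along(qi), qi, function(ix) {
      iv <- IRanges::reduce(IRanges::IRanges(
        start = pmax(cat_df$rep_start[qi[ix]], te_track$start[ti[ix]]) + 1,
        end = pmin(cat_df$rep_end[qi[ix]], te_track$end[ti[ix]])))
      sum(IRanges::width(iv))
    })
    res$union_cover[rows] <- unlist(cover) /
      (cat_df$rep_end[rows] - cat_df$rep_start[rows])
    res$te_status[rows] <- ifelse(
      res$best_ro[rows] >= strict_ro, "strict_te",
      ifelse(res$union_cover[rows] >= cover_frac, "repeat_associated",
             "none"))
  }
  class(res) <- c("te_classification", "data.frame")
  res
}

promoter_interval <- function(genes, promoter_len) {
  plus <- genes$strand == "+"
  data.frame(start = ifelse(plus, genes$tss - promoter_len, genes$tss + 1),
             end = ifelse(plus, genes$tss, genes$tss + 1 + promoter_len))
}

#' Assign each cluster to a single genomic feature class
#'
#' Every cluster receives exactly one label by precedence over all
#' overlapping genes: `CDS > five_prime_UTR > three_prime_UTR > intron >
#' promoter > intergenic`. The promoter is the strand-aware
#' `[TSS - promoter_len, TSS)` window (default 500 bp upstream).
#'
#' @param clusters an `sv_cluster_set` or its catalog data.frame.
#' @param models a `gene_models` object.
#' @param promoter_len promoter length in bp.
#' @return A data.frame with `cluster_id`, `feature`, `gene_id` (NA for
#'   intergenic), `overlap_bp`.
#' @export
assign_feature <- function(clusters, models, promoter_len = 500) {
  cat_df <- cluster_catalog(clusters)
  prec <- c("CDS", "five_prime_UTR", "three_prime_UTR", "intron",
            "promoter", "intergenic")
  feats <- models$features[models$features$type %in% prec, , drop = FALSE]
  g <- models$genes
  chrom_of <- stats::setNames(g$chrom, g$gene_id)
  prom <- promoter_interval(g, promoter_len)
  all_feats <- rbind(
    data.frame(gene_id = feats$gene_id, type = feats$type,
               chrom = unname(chrom_of[feats$gene_id]),
               start = feats$start, end = feats$end,
               stringsAsFactors = FALSE),
    data.frame(gene_id = g$gene_id, type = "promoter", chrom = g$chrom,
               start = prom$start, end = prom$end, stringsAsFactors = FALSE))
  res <- data.frame(cluster_id = cat_df$cluster_id, feature = "intergenic",
                    gene_id = NA_character_, overlap_bp = 0,
                    stringsAsFactors = FALSE)
  if (!nrow(cat_df) || !nrow(all_feats)) return(res)
  gc <- catalog_granges(cat_df)
  gf <- GenomicRanges::GRanges(all_feats$chrom, IRanges::IRanges(
    start = all_feats$start + 1, end = all_feats$end))
  h <- GenomicRanges::findOverlaps(gc, gf)
  qi <- S4Vectors::queryHits(h); fi <- S4Vectors::subjectHits(h)
  if (length(qi)) {
    # for INS points, treat the 1-bp site as the overlap unit
    c_start <- cat_df$rep_start[qi]
    c_end <- ifelse(cat_df$svtype[qi] == "INS", cat_df$rep_start[qi] + 1,
                    cat_df$rep_end[qi])
    ov <- pmin(c_end, all_feats$end[fi]) - pmax(c_start, all_feats$start[fi])
    rank <- match(all_feats$type[fi], prec)
    pick <- tapply(seq_along(qi), qi,
                   function(ix) ix[order(rank[ix], -ov[ix])][1])
    pi <- unlist(pick)
    rows <- as.integer(names(pick))
    res$feature[rows] <- all_feats$type[fi[pi]]
    res$gene_id[rows] <- all_feats$gene_id[fi[pi]]
    res$overlap_bp[rows] <- ov[pi]
  }
  res
}

#' TSS-relative coverage profiles for short and long SVs
#'
#' For every position `x` in `[-half_window, +half_window]` relative to each
#' gene's TSS (strand-aware, upstream negative), counts the genes whose
#' genomic position at offset `x` is covered by at least one SV, split into
#' short (`length < short_cutoff`, default 40 bp) and long tracks, and
#' normalizes by the per-position number of genes whose window position
#' exists (genes near a contig edge contribute only where their window is
#' complete).
#'
#' @param calls an `sv_calls` table or an `sv_cluster_set` (representative
#'   intervals are used).
#' @param models a `gene_models` object.
#' @param half_window window half-width in bp.
#' @param short_cutoff length threshold separating short from long SVs.
#' @param chrom_lengths optional named vector for edge truncation.
#' @return A data.frame with columns `pos`, `n_genes`, `short_count`,
#'   `long_count`, `short_frac`, `long_frac`.
#' @export
tss_profile <- function(calls, models, half_window = 1000,
                        short_cutoff = 40, chrom_lengths = NULL) {
  stopifnot(half_window >= 1)
  if (inherits(calls, "sv_cluster_set")) {
    cat_df <- calls$clusters
    calls <- as_sv_calls(data.frame(
      chrom = cat_df$chrom, start = cat_df$rep_start,
      end = ifelse(cat_df$svtype == "INS", cat_df$rep_start,
                   cat_df$rep_end),
      svtype = cat_df$svtype, length = cat_df$rep_length,
      stringsAsFactors = FALSE))
  }
  pos <- seq(-half_window, half_window)
  npos <- length(pos)
  n_genes <- integer(npos)
  short_ct <- integer(npos); long_ct <- integer(npos)
  g <- models$genes
  span <- calls[calls$svtype != "INS", , drop = FALSE]
  plus <- g$strand == "+"
  valid_mat <- matrix(TRUE, max(1, nrow(g)), npos)
  for (i in seq_len(nrow(g))) {
    gpos <- if (plus[i]) g$tss[i] + pos else g$tss[i] - pos
    valid <- gpos >= 0
    if (!is.null(chrom_lengths) && g$chrom[i] %in% names(chrom_lengths))
      valid <- valid & gpos < chrom_lengths[[g$chrom[i]]]
    valid_mat[i, ] <- valid
    n_genes <- n_genes + valid
  }
  if (nrow(span) && nrow(g)) {
    gr_w <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(
      start = pmax(0, g$tss - half_window) + 1,
      end = g$tss + half_window + 1))
    h <- GenomicRanges::findOverlaps(gr_w, calls_granges(span))
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    short_cov <- matrix(FALSE, nrow(g), npos)
    long_cov <- matrix(FALSE, nrow(g), npos)
    for (k in seq_along(qi)) {
      i <- qi[k]
      gpos <- if (plus[i]) g$tss[i] + pos else g$tss[i] - pos
      covered <- valid_mat[i, ] & gpos >= span$start[si[k]] &
        gpos < span$end[si[k]]
      if (span$length[si[k]] < short_cutoff)
        short_cov[i, ] <- short_cov[i, ] | covered
      else long_cov[i, ] <- long_cov[i, ] | covered
    }
    short_ct <- colSums(short_cov)
    long_ct <- colSums(long_cov)
  }
  data.frame(pos = pos, n_genes = n_genes,
             short_count = short_ct, long_count = long_ct,
             short_frac = ifelse(n_genes > 0, short_ct / n_genes, NA_real_),
             long_frac = ifelse(n_genes > 0, long_ct / n_genes, NA_real_))
}

#' Genes fully deleted in at least one sample
#'
#' A gene counts as deleted in a sample when the union of the deletion
#' clusters the sample carries covers every CDS base of the gene (strict
#' full-length coverage). Genes without CDS are excluded with a warning.
#'
#' @param clusters an `sv_cluster_set` (uses DEL clusters and the
#'   per-sample membership matrix).
#' @param models a `gene_models` object.
#' @param groups optional named vector mapping sample ids to variety-group
#'   labels for the per-group summary.
#' @param min_group_freq genes deleted in at least this many samples enter
#'   the sharing table (default 5).
#' @return A list with `per_sample` (named list of deleted gene-id vectors),
#'   `per_sample_fraction`, `gene_freq` (deletion carrier count per gene),
#'   `per_group` (list, when `groups` given), and `sharing` (data.frame of
#'   genes at frequency >= `min_group_freq` with their carrier groups).
#' @export
deleted_genes <- function(clusters, models, groups = NULL,
                          min_group_freq = 5) {
  stopifnot(inherits(clusters, "sv_cluster_set"))
  cat_df <- clusters$clusters
  del <- cat_df[cat_df$svtype == "DEL", , drop = FALSE]
  memb <- clusters$membership
  panel <- clusters$panel
  g <- models$genes
  cds <- models$features[models$features$type == "CDS", , drop = FALSE]
  no_cds <- setdiff(g$gene_id, cds$gene_id)
  if (length(no_cds)) {
    warning("excluding ", length(no_cds), " gene(s) without CDS: ",
            paste(utils::head(no_cds, 5), collapse = ", "))
    g <- g[!(g$gene_id %in% no_cds), , drop = FALSE]
  }
  per_sample <- stats::setNames(vector("list", length(panel)), panel)
  for (s in panel) per_sample[[s]] <- character()
  if (nrow(del) && nrow(g)) {
    gr_del <- catalog_granges(del)
    for (i in seq_len(nrow(g))) {
      gi <- g[i, ]
      ci <- cds[cds$gene_id == gi$gene_id, , drop = FALSE]
      gr_cds <- GenomicRanges::GRanges(gi$chrom, IRanges::IRanges(
        start = ci$start + 1, end = ci$end))
      h <- GenomicRanges::findOverlaps(gr_cds, gr_del)
      cand <- unique(S4Vectors::subjectHits(h))
      if (!length(cand)) next
      for (s in panel) {
        have <- cand[memb[s, del$cluster_id[cand]]]
        if (!length(have)) next
        cov <- IRanges::reduce(IRanges::IRanges(
          start = del$rep_start[have] + 1, end = del$rep_end[have]))
        uncovered <- IRanges::setdiff(IRanges::IRanges(
          start = ci$start + 1, end = ci$end), cov)
        if (sum(IRanges::width(uncovered)) == 0)
          per_sample[[s]] <- c(per_sample[[s]], gi$gene_id)
      }
    }
  }
  gene_freq <- table(unlist(per_sample))
  out <- list(
    per_sample = per_sample,
    per_sample_fraction = vapply(per_sample, length, 0) /
      max(1, nrow(g)),
    gene_freq = gene_freq)
  if (!is.null(groups)) {
    grp_of <- groups[panel]
    per_group <- lapply(split(panel, grp_of), function(ss)
      sort(unique(unlist(per_sample[ss]))))
    shared_genes <- names(gene_freq)[gene_freq >= min_group_freq]
    sharing <- data.frame(
      gene_id = shared_genes,
      groups = vapply(shared_genes, function(gid)
        paste(sort(unique(names(per_group)[vapply(per_group, function(x)
          gid %in% x, TRUE)])), collapse = ","), ""),
      freq = as.integer(gene_freq[shared_genes]),
      stringsAsFactors = FALSE)
    out$per_group <- per_group
    out$mean_deleted_per_group <- vapply(split(panel, grp_of), function(ss)
      mean(vapply(per_sample[ss], length, 0)), 0)
    out$sharing <- sharing
  }
  out
}

#' Variant density in sliding windows, with optional track correlation
#'
#' Counts variants (by start position) in sliding windows (default 100 kb
#' with 50-kb steps) per chromosome, flags windows with counts at least
#' twice the genome-wide mean, and, when a second variant set is given,
#' reports the Pearson correlation of the two window-count tracks.
#'
#' @param a an `sv_calls` table, cluster catalog, or any data.frame with
#'   `chrom` and `start` (cluster catalogs use `rep_start`).
#' @param b optional second variant set, aligned on the same windows.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window,step window and step size in bp; `step` must divide
#'   `window`.
#' @return A list with `windows` (data.frame `chrom`, `start`, `end`,
#'   `count`, `count_b`, `flagged`), `mean_count`, and `correlation`
#'   (NA without `b`).
#' @export
density_windows <- function(a, b = NULL, chrom_lengths,
                            window = 100000, step = 50000) {
  stopifnot(window %% step == 0)
  starts_of <- function(x) {
    if (inherits(x, "sv_cluster_set")) x <- x$clusters
    s <- if (!is.null(x$rep_start)) x$rep_start else x$start
    data.frame(chrom = x$chrom, start = s, stringsAsFactors = FALSE)
  }
  av <- starts_of(a)
  bv <- if (!is.null(b)) starts_of(b)
  win <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    ws <- seq(0, max(0, L - 1), by = step)
    ws <- ws[ws == 0 | ws + window <= L + step]  # last window truncated
    data.frame(chrom = ch, start = ws, end = pmin(ws + window, L),
               stringsAsFactors = FALSE)
  }))
  count_in <- function(v) {
    vapply(seq_len(nrow(win)), function(i)
      sum(v$chrom == win$chrom[i] & v$start >= win$start[i] &
            v$start < win$end[i]), 0)
  }
  win$count <- count_in(av)
  if (!is.null(bv)) win$count_b <- count_in(bv)
  m <- mean(win$count)
  win$flagged <- win$count >= 2 * m & win$count > 0
  list(windows = win, mean_count = m,
       correlation = if (!is.null(bv) && nrow(win) > 1)
         stats::cor(win$count, win$count_b) else NA_real_)
}
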