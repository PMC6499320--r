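#' Parameters for cross-sample clustering of SV calls into allelic events
#'
#' Calls of one SV type that overlap by at least 1 bp are first grouped;
#' within each group a similarity graph connects calls with reciprocal
#' overlap of at least `ro_strong` (0.9), or at least `ro_weak` (0.7) with a
#' breakpoint error of at most `bp_error_cap` (10 bp, inclusive) — the weak
#' rule admits small events with large relative but small absolute boundary
#' differences. Each connected component is then agglomerated by complete
#' linkage under the breakpoint distance
#' `d(a,b) = (|a.start - b.start| + |a.end - b.end|) / (length(a) + length(b))`
#' and cut at `height_cutoff` (0.1, inclusive). Insertions are instead
#' chained by single linkage over sites at most `ins_gap` bp apart.
#'
#' @param ro_strong,ro_weak reciprocal-overlap thresholds (fractions).
#' @param bp_error_cap breakpoint-error cap for the weak rule (bp, `<=`).
#' @param height_cutoff complete-linkage cut height (dimensionless).
#' @param ins_gap insertion-site chaining gap (bp, `<=`).
#' @param length_norm denominator of the breakpoint distance: `"sum"`
#'   (default, the two lengths added) or `"mean"` (half that).
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(ro_strong = 0.9, ro_weak = 0.7, bp_error_cap = 10,
                           height_cutoff = 0.1, ins_gap = 10,
                           length_norm = c("sum", "mean")) {
  stopifnot(ro_weak < ro_strong, height_cutoff > 0)
  structure(list(ro_strong = ro_strong, ro_weak = ro_weak,
                 bp_error_cap = bp_error_cap, height_cutoff = height_cutoff,
                 ins_gap = ins_gap, length_norm = match.arg(length_norm)),
            class = "cluster_params")
}

#' Group same-type calls that overlap by at least 1 bp
#'
#' Transitive closure of pairwise >= 1 bp overlap, computed by reducing the
#' sorted intervals per chromosome: each maximal run of mutually touching
#' intervals is one initial group.
#'
#' @param calls an `sv_calls` table of non-INS calls of one type.
#' @return Integer vector of group ids, one per call.
#' @export
group_by_overlap <- function(calls) {
  if (!nrow(calls)) return(integer())
  if (any(calls$svtype == "INS"))
    stop("group_by_overlap applies to calls with positive extent, not INS")
  gr <- calls_granges(calls)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  S4Vectors::subjectHits(GenomicRanges::findOverlaps(gr, red))
}

#' Build the similarity graph over one initial group
#'
#' Edges connect calls `a`, `b` with `RO(a,b) >= ro_strong`, or
#' `RO(a,b) >= ro_weak` and `breakpoint_error(a,b) <= bp_error_cap`.
#'
#' @param calls an `sv_calls` table (one group, one chromosome, one type).
#' @param params a [cluster_params()].
#' @return A data.frame of edges with columns `i`, `j` (row indices, i < j).
#' @export
build_similarity_graph <- function(calls, params = cluster_params()) {
  n <- nrow(calls)
  if (n < 2) return(data.frame(i = integer(), j = integer()))
  gr <- calls_granges(calls)
  h <- GenomicRanges::findOverlaps(gr, gr)
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  sel <- qi < si
  qi <- qi[sel]; si <- si[sel]
  if (!length(qi)) return(data.frame(i = integer(), j = integer()))
  ro <- reciprocal_overlap(calls[qi, ], calls[si, ])
  e <- breakpoint_error(calls[qi, ], calls[si, ])
  keep <- ro >= params$ro_strong |
    (ro >= params$ro_weak & e <= params$bp_error_cap)
  data.frame(i = qi[keep], j = si[keep])
}

#' Split a similarity graph into connected components
#'
#' @param n number of nodes.
#' @param edges edge data.frame from [build_similarity_graph()].
#' @return Integer vector of component ids per node.
#' @export
split_components <- function(n, edges) {
  g <- igraph::make_graph(rbind(edges$i, edges$j), n = n, directed = FALSE)
  as.integer(igraph::components(g)$membership)
}

# breakpoint distance matrix used for complete linkage
breakpoint_distance <- function(calls, params) {
  n <- nrow(calls)
  ds <- abs(outer(calls$start, calls$start, "-")) +
    abs(outer(calls$end, calls$end, "-"))
  denom <- outer(calls$length, calls$length, "+")
  if (params$length_norm == "mean") denom <- denom / 2
  ds / denom
}

# Deterministic complete-linkage agglomeration cut at `height` (inclusive).
# Merge ties are broken lexicographically by each cluster's (min start,
# min end, smallest sample_id), which makes the partition independent of
# input order — stats::hclust resolves ties by input position instead.
complete_linkage_cut <- function(d, calls, height) {
  n <- nrow(calls)
  if (n == 1) return(1L)
  memb <- as.list(seq_len(n))
  key <- function(ix) {
    list(min(calls$start[ix]), min(calls$end[ix]),
         min(calls$sample_id[ix]))
  }
  repeat {
    k <- length(memb)
    if (k == 1) break
    best <- NULL; best_d <- Inf
    keys <- lapply(memb, key)
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        dd <- max(d[memb[[a]], memb[[b]]])
        if (dd < best_d - 1e-12 ||
            (abs(dd - best_d) <= 1e-12 &&
               !is.null(best) && key_less(keys[[a]], keys[[b]],
                                          keys[[best[1]]], keys[[best[2]]]))) {
          best <- c(a, b); best_d <- dd
        }
      }
    }
    if (best_d > height) break
    memb[[best[1]]] <- c(memb[[best[1]]], memb[[best[2]]])
    memb[[best[2]]] <- NULL
  }
  out <- integer(n)
  for (c_i in seq_along(memb)) out[memb[[c_i]]] <- c_i
  out
}

# TRUE if the (ka, kb) pair sorts before the (kc, kd) pair lexicographically;
# elements are compared in place so numeric keys stay numeric
key_less <- function(ka, kb, kc, kd) {
  va <- sort_pair(ka, kb); vb <- sort_pair(kc, kd)
  for (i in seq_along(va)) {
    if (va[[i]] < vb[[i]]) return(TRUE)
    if (va[[i]] > vb[[i]]) return(FALSE)
  }
  FALSE
}

sort_pair <- function(k1, k2) {
  for (i in seq_along(k1)) {
    if (k1[[i]] < k2[[i]]) return(c(k1, k2))
    if (k1[[i]] > k2[[i]]) return(c(k2, k1))
  }
  c(k1, k2)
}

#' Complete-linkage clustering of one connected component
#'
#' Agglomerates the component under the breakpoint distance and cuts the
#' dendrogram at `height_cutoff` (a cell survives while its complete-linkage
#' merge height stays <= the cutoff). Singleton components yield one
#' singleton cluster.
#'
#' @param calls an `sv_calls` table (one connected component).
#' @param params a [cluster_params()].
#' @return Integer vector of cluster ids per call.
#' @export
cluster_component <- function(calls, params = cluster_params()) {
  if (nrow(calls) == 1) return(1L)
  d <- breakpoint_distance(calls, params)
  complete_linkage_cut(d, calls, params$height_cutoff)
}

#' Cluster insertion calls across samples by site chaining
#'
#' Single-linkage chaining of insertion sites at most `ins_gap` bp apart.
#'
#' @param calls an `sv_calls` table of INS calls.
#' @param params a [cluster_params()].
#' @return Integer vector of cluster ids per call (input order).
#' @export
cluster_insertions <- function(calls, params = cluster_params()) {
  if (!nrow(calls)) return(integer())
  stopifnot(all(calls$svtype == "INS"))
  o <- order(calls$chrom, calls$start)
  chain <- chain_positions(calls$chrom[o], calls$start[o], params$ins_gap)
  out <- integer(nrow(calls))
  out[o] <- chain
  out
}

# low median: the lower of the two middle order statistics, always an
# observed value (keeps representative coordinates integral)
low_median <- function(x) sort(x)[ceiling(length(x) / 2)]

summarize_cluster <- function(members, cluster_id, panel_size) {
  ins <- members$svtype[1] == "INS"
  rep_start <- low_median(members$start)
  rep_end <- low_median(members$end)
  rep_length <- if (ins) low_median(members$length) else rep_end - rep_start
  dev <- abs(members$start - rep_start) + abs(members$end - rep_end)
  n_samples <- length(unique(members$sample_id))
  data.frame(cluster_id = cluster_id, chrom = members$chrom[1],
             svtype = members$svtype[1],
             rep_start = rep_start, rep_end = rep_end,
             rep_length = rep_length, n_members = nrow(members),
             n_samples = n_samples,
             allele_frequency = n_samples / panel_size,
             tightness = mean(dev) / (2 * rep_length),
             stringsAsFactors = FALSE)
}

#' Cluster merged per-sample calls into a cross-sample event catalog
#'
#' Runs the full pipeline per SV type and chromosome: 1-bp overlap grouping,
#' similarity graph, connected components, complete-linkage cut (insertions:
#' site chaining), then summarizes each final cluster with representative
#' breakpoints (per-side low median of member breakpoints), carrier-sample
#' count, allele frequency over the panel, and tightness (mean per-side
#' breakpoint deviation from the representative divided by the
#' representative length). Input order never affects the partition: calls
#' are canonically sorted before clustering.
#'
#' @param calls an `sv_calls` table pooling merged calls from all samples,
#'   or a list of per-sample tables.
#' @param params a [cluster_params()].
#' @param panel character vector of all panel sample ids (defaults to the
#'   samples present in `calls`); the allele-frequency denominator.
#' @return An `sv_cluster_set`: list with `clusters` (catalog data.frame
#'   sorted by coordinate), `members` (calls with a `cluster_id` column),
#'   `membership` (samples x clusters logical matrix), `panel` and `params`.
#' @export
cluster_all <- function(calls, params = cluster_params(), panel = NULL) {
  calls <- if (is.data.frame(calls)) calls else rbind_sv_calls(calls)
  if (is.null(panel)) panel <- sort(unique(calls$sample_id))
  if (!nrow(calls)) {
    empty_cat <- data.frame(cluster_id = character(), chrom = character(),
                            svtype = character(), rep_start = numeric(),
                            rep_end = numeric(), rep_length = numeric(),
                            n_members = integer(), n_samples = integer(),
                            allele_frequency = numeric(),
                            tightness = numeric(), stringsAsFactors = FALSE)
    calls$cluster_id <- character()
    return(structure(list(clusters = empty_cat, members = calls,
                          membership = matrix(FALSE, length(panel), 0,
                                              dimnames = list(panel, NULL)),
                          panel = panel, params = params),
                     class = "sv_cluster_set"))
  }
  calls <- calls[order(calls$chrom, calls$start, calls$end,
                       calls$sample_id, calls$caller_id), , drop = FALSE]
  rownames(calls) <- NULL
  part <- rep(NA_character_, nrow(calls))
  for (type in unique(calls$svtype)) {
    ti <- which(calls$svtype == type)
    sub <- calls[ti, , drop = FALSE]
    if (type == "INS") {
      cl <- cluster_insertions(sub, params)
      part[ti] <- paste(type, cl, sep = "_")
      next
    }
    grp <- group_by_overlap(sub)
    for (g in unique(grp)) {
      gi <- which(grp == g)
      gsub <- sub[gi, , drop = FALSE]
      edges <- build_similarity_graph(gsub, params)
      comp <- split_components(nrow(gsub), edges)
      for (cc in unique(comp)) {
        ci <- which(comp == cc)
        cl <- cluster_component(gsub[ci, , drop = FALSE], params)
        part[ti[gi[ci]]] <- paste(type, g, cc, cl, sep = "_")
      }
    }
  }
  # catalog, sorted by representative coordinate
  cells <- split(seq_len(nrow(calls)), part)
  cat_list <- lapply(cells, function(ix)
    summarize_cluster(calls[ix, , drop = FALSE], part[ix[1]],
                      length(panel)))
  cat_df <- do.call(rbind, cat_list)
  ord <- order(cat_df$chrom, cat_df$rep_start, cat_df$rep_end, cat_df$svtype)
  cat_df <- cat_df[ord, , drop = FALSE]
  ids <- sprintf("%s_%s_%06d", cat_df$svtype, cat_df$chrom,
                 seq_len(nrow(cat_df)))
  id_map <- stats::setNames(ids, cat_df$cluster_id)
  cat_df$cluster_id <- ids
  rownames(cat_df) <- NULL
  calls$cluster_id <- unname(id_map[part])
  membership <- matrix(FALSE, nrow = length(panel), ncol = nrow(cat_df),
                       dimnames = list(panel, ids))
  if (nrow(calls))
    membership[cbind(match(calls$sample_id, panel),
                     match(calls$cluster_id, ids))] <- TRUE
  structure(list(clusters = cat_df, members = calls,
                 membership = membership, panel = panel, params = params),
            class = "sv_cluster_set")
}

#' @export
print.sv_cluster_set <- function(x, ...) {
  cat("sv_cluster_set:", nrow(x$clusters), "clusters from",
      nrow(x$members), "calls across", length(x$panel), "samples\n")
  tab <- table(x$clusters$svtype)
  cat("  by type:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  mean tightness:",
      signif(mean(x$clusters$tightness, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Summary statistics of a cluster catalog
#'
#' @param object an `sv_cluster_set`.
#' @param ... unused.
#' @return A list with per-type cluster counts, the carrier-frequency
#'   spectrum (`table` of `n_samples`), and mean tightness per type.
#' @export
summary.sv_cluster_set <- function(object, ...) {
  cl <- object$clusters
  list(n_clusters = nrow(cl),
       n_calls = nrow(object$members),
       by_type = table(cl$svtype),
       frequency_spectrum = table(cl$n_samples),
       mean_tightness = tapply(cl$tightness, cl$svtype, mean),
       overall_mean_tightness = mean(cl$tightness))
}
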