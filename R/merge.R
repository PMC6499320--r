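#' Policy for within-sample multi-caller merging
#'
#' The merge retains, per sample: (a) every anchor-caller call with FILTER
#' `PASS`, regardless of other callers' support; (b) every inversion from
#' the designated keep-all caller; (c) every other call supported by at
#' least `support_min` callers, where two calls of the same type support
#' each other when their reciprocal overlap reaches `ro_relaxed` (default
#' 0.7) if the relaxed caller is one of the pair and `ro_default` (default
#' 0.9) otherwise. Supported groups already represented by a retained anchor
#' call are dropped; each remaining group is emitted once with breakpoints
#' from the highest-priority caller present. Insertions are merged
#' separately by single-linkage chaining of sites within
#' `ins_cluster_radius` (see [merge_sample_insertions()]).
#'
#' @param anchor_caller caller whose PASS calls are always kept.
#' @param inversion_keep_all_caller caller whose inversions are all kept.
#' @param support_min minimum number of distinct supporting callers
#'   (including the call's own) for rule (c).
#' @param ro_default,ro_relaxed reciprocal-overlap thresholds.
#' @param relaxed_caller caller granted the relaxed threshold (its breakpoint
#'   resolution for duplications motivates the 0.7).
#' @param ins_cluster_radius insertion-site chaining radius in bp.
#' @param caller_priority order used to pick representative breakpoints.
#' @return A list of class `merge_policy`.
#' @export
merge_policy <- function(anchor_caller = "pindel",
                         inversion_keep_all_caller = "lumpy",
                         support_min = 2,
                         ro_default = 0.9, ro_relaxed = 0.7,
                         relaxed_caller = "lumpy",
                         ins_cluster_radius = 10,
                         caller_priority = c("pindel", "delly", "grom",
                                             "lumpy", "metasv",
                                             "mindthegap")) {
  stopifnot(support_min >= 2, ro_default > 0, ro_default <= 1,
            ro_relaxed > 0, ro_relaxed <= 1)
  structure(list(anchor_caller = anchor_caller,
                 inversion_keep_all_caller = inversion_keep_all_caller,
                 support_min = support_min, ro_default = ro_default,
                 ro_relaxed = ro_relaxed, relaxed_caller = relaxed_caller,
                 ins_cluster_radius = ins_cluster_radius,
                 caller_priority = caller_priority),
            class = "merge_policy")
}

# RO threshold applicable to a pair of callers
pair_ro_threshold <- function(caller_a, caller_b, policy) {
  ifelse(caller_a == policy$relaxed_caller | caller_b == policy$relaxed_caller,
         policy$ro_relaxed, policy$ro_default)
}

supports_of <- function(calls) {
  if (!is.null(calls$supports)) {
    s <- calls$supports
    s[is.na(s) | s == ""] <- calls$caller_id[is.na(s) | s == ""]
    s
  } else calls$caller_id
}

caller_rank <- function(caller_id, policy) {
  r <- match(caller_id, policy$caller_priority)
  unknown <- is.na(r)
  if (any(unknown))
    warning("caller(s) not in priority list: ",
            paste(unique(caller_id[unknown]), collapse = ", "))
  r[unknown] <- length(policy$caller_priority) + 1L
  r
}

#' Merge one sample's call sets from multiple callers
#'
#' Applies the retention rules of [merge_policy()] to all calls of one
#' sample. Insertions are routed through [merge_sample_insertions()]. The
#' output records all supporting callers of each retained call in a
#' `supports` column (comma-separated), which makes the merge idempotent:
#' re-merging the merged output returns it unchanged.
#'
#' @param callsets an `sv_calls` table with calls from several callers, or a
#'   list of such tables (e.g. one per caller) to be concatenated.
#' @param policy a [merge_policy()].
#' @return An `sv_calls` table with a `supports` column.
#' @export
merge_sample_calls <- function(callsets, policy = merge_policy()) {
  calls <- if (is.data.frame(callsets)) callsets else rbind_sv_calls(callsets)
  if (!nrow(calls)) {
    out <- sv_calls(); out$supports <- character(); return(out)
  }
  if (length(unique(calls$sample_id)) > 1)
    stop("merge_sample_calls operates on a single sample")
  calls$supports <- supports_of(calls)
  calls <- calls[order(calls$chrom, calls$start, calls$end,
                       caller_rank(calls$caller_id, policy)), , drop = FALSE]
  ins <- calls[calls$svtype == "INS", , drop = FALSE]
  span <- calls[calls$svtype != "INS", , drop = FALSE]

  kept <- list()
  # (a) anchor PASS calls, any type
  anchor_keep <- span[span$caller_id == policy$anchor_caller &
                        span$filter_status == "PASS", , drop = FALSE]
  kept$anchor <- anchor_keep
  # (b) all inversions from the keep-all caller
  inv_keep <- span[span$caller_id == policy$inversion_keep_all_caller &
                     span$svtype == "INV", , drop = FALSE]
  # (c) support rule over the remaining non-anchor calls
  rest <- span[!(span$caller_id == policy$anchor_caller &
                   span$filter_status == "PASS") &
                 !(span$caller_id == policy$inversion_keep_all_caller &
                     span$svtype == "INV"), , drop = FALSE]
  supported <- list()
  for (type in unique(rest$svtype)) {
    cand <- rest[rest$svtype == type, , drop = FALSE]
    if (!nrow(cand)) next
    # pairwise same-type support edges among candidates
    gr <- calls_granges(cand)
    h <- GenomicRanges::findOverlaps(gr, gr)
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    sel <- qi < si
    qi <- qi[sel]; si <- si[sel]
    edge <- logical(length(qi))
    if (length(qi)) {
      ro <- reciprocal_overlap(cand[qi, ], cand[si, ])
      thr <- pair_ro_threshold(cand$caller_id[qi], cand$caller_id[si], policy)
      edge <- ro >= thr & cand$caller_id[qi] != cand$caller_id[si]
    }
    # distinct supporting callers per candidate (own callers + neighbours)
    own <- strsplit(cand$supports, ",", fixed = TRUE)
    supp <- own
    for (k in which(edge)) {
      supp[[qi[k]]] <- union(supp[[qi[k]]], own[[si[k]]])
      supp[[si[k]]] <- union(supp[[si[k]]], own[[qi[k]]])
    }
    n_supp <- lengths(supp)
    ok <- n_supp >= policy$support_min
    if (!any(ok)) next
    cand <- cand[ok, , drop = FALSE]
    cand$supports <- vapply(supp[ok], function(s)
      paste(sort(s), collapse = ","), "")
    # drop candidates already represented by a retained anchor call
    akeep <- anchor_keep[anchor_keep$svtype == type, , drop = FALSE]
    if (nrow(akeep)) {
      ha <- GenomicRanges::findOverlaps(calls_granges(cand),
                                        calls_granges(akeep))
      if (length(ha)) {
        ro <- reciprocal_overlap(cand[S4Vectors::queryHits(ha), ],
                                 akeep[S4Vectors::subjectHits(ha), ])
        thr <- pair_ro_threshold(
          cand$caller_id[S4Vectors::queryHits(ha)],
          akeep$caller_id[S4Vectors::subjectHits(ha)], policy)
        dup <- unique(S4Vectors::queryHits(ha)[ro >= thr])
        if (length(dup)) cand <- cand[-dup, , drop = FALSE]
      }
    }
    if (!nrow(cand)) next
    # one representative per mutually-supporting group, carrying the
    # provenance of the whole group
    grp <- support_components(cand, policy)
    rep_list <- lapply(split(seq_len(nrow(cand)), grp), function(ix) {
      r <- caller_rank(cand$caller_id[ix], policy)
      rc <- cand[ix[order(r, cand$start[ix], cand$end[ix])][1], ,
                 drop = FALSE]
      rc$supports <- paste(sort(unique(unlist(
        strsplit(cand$supports[ix], ",", fixed = TRUE)))), collapse = ",")
      rc
    })
    supported[[type]] <- rbind_sv_calls(rep_list)
  }
  # inversion keep-all calls: dedup against retained anchor inversions
  if (nrow(inv_keep)) {
    akeep <- anchor_keep[anchor_keep$svtype == "INV", , drop = FALSE]
    if (nrow(akeep)) {
      ha <- GenomicRanges::findOverlaps(calls_granges(inv_keep),
                                        calls_granges(akeep))
      if (length(ha)) {
        ro <- reciprocal_overlap(inv_keep[S4Vectors::queryHits(ha), ],
                                 akeep[S4Vectors::subjectHits(ha), ])
        thr <- pair_ro_threshold(
          inv_keep$caller_id[S4Vectors::queryHits(ha)],
          akeep$caller_id[S4Vectors::subjectHits(ha)], policy)
        dup <- unique(S4Vectors::queryHits(ha)[ro >= thr])
        if (length(dup)) inv_keep <- inv_keep[-dup, , drop = FALSE]
      }
    }
  }
  out <- rbind_sv_calls(c(list(anchor_keep, inv_keep), supported,
                          list(merge_sample_insertions(ins, policy))))
  out <- out[order(out$chrom, out$start, out$end, out$svtype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# connected components of the mutual-support graph among candidate calls
support_components <- function(cand, policy) {
  n <- nrow(cand)
  if (n == 1) return(1L)
  gr <- calls_granges(cand)
  h <- GenomicRanges::findOverlaps(gr, gr)
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  sel <- qi < si
  qi <- qi[sel]; si <- si[sel]
  keep <- logical(length(qi))
  if (length(qi)) {
    ro <- reciprocal_overlap(cand[qi, ], cand[si, ])
    thr <- pair_ro_threshold(cand$caller_id[qi], cand$caller_id[si], policy)
    keep <- ro >= thr
  }
  g <- igraph::make_graph(rbind(qi[keep], si[keep]), n = n, directed = FALSE)
  igraph::components(g)$membership
}

#' Merge one sample's insertion calls by site chaining
#'
#' Insertion sites within `ins_cluster_radius` bp of each other (default 10)
#' are chained by single linkage; each chain is emitted once, at its leftmost
#' site, carrying the longest assembled inserted sequence in the chain.
#' Unchained (unique) insertions from any caller are kept as-is.
#'
#' @param ins an `sv_calls` table of INS calls (one sample).
#' @param policy a [merge_policy()].
#' @return An `sv_calls` table with a `supports` column.
#' @export
merge_sample_insertions <- function(ins, policy = merge_policy()) {
  if (!nrow(ins)) {
    out <- sv_calls(); out$supports <- character(); return(out)
  }
  stopifnot(all(ins$svtype == "INS"))
  ins$supports <- supports_of(ins)
  ins <- ins[order(ins$chrom, ins$start), , drop = FALSE]
  chain <- chain_positions(ins$chrom, ins$start, policy$ins_cluster_radius)
  out <- lapply(split(seq_len(nrow(ins)), chain), function(ix) {
    rep_i <- ix[order(ins$start[ix], -ins$length[ix])][1]
    r <- ins[rep_i, , drop = FALSE]
    # keep the longest assembly in the chain, preferring calls that carry
    # the inserted sequence
    with_seq <- ix[!is.na(ins$inserted_seq[ix])]
    best <- if (length(with_seq)) with_seq[which.max(ins$length[with_seq])]
            else ix[which.max(ins$length[ix])]
    r$inserted_seq <- ins$inserted_seq[best]
    r$length <- ins$length[best]
    r$supports <- paste(sort(unique(unlist(
      strsplit(ins$supports[ix], ",")))), collapse = ",")
    r
  })
  out <- rbind_sv_calls(out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# single-linkage chains of positions within `gap` bp, per chromosome;
# returns an integer chain id per input element (input must be sorted)
chain_positions <- function(chrom, pos, gap) {
  n <- length(pos)
  if (!n) return(integer())
  new_chain <- c(TRUE, chrom[-1] != chrom[-n] | pos[-1] - pos[-n] > gap)
  cumsum(new_chain)
}
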