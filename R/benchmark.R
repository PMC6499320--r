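#' Matching criteria for benchmarking SV predictions against a truth set
#'
#' A prediction `p` matches a simulated truth event `S` of the same type when:
#' \itemize{
#'   \item DEL/INV: reciprocal overlap `RO(p,S) >= ro_threshold` (default
#'     0.9) and breakpoint error `e < min(bp_error_cap,
#'     bp_error_frac * (length(p) + length(S)))` — the 10% rule binds only
#'     for small events, demanding less error when the combined size is
#'     below `bp_error_cap / bp_error_frac` (100 bp at the defaults).
#'   \item DUP: `RO >= dup_ro_threshold` (default 0.7) with no breakpoint
#'     error constraint, reflecting the poor breakpoint resolution of
#'     duplication calls.
#'   \item INS: positional distance between sites `<= ins_distance_cap`
#'     (default 10 bp); reciprocal overlap is inapplicable to point events.
#' }
#' `error_rule = "or"` instead applies the plain disjunction
#' `e < bp_error_cap OR e < bp_error_frac * (length(p) + length(S))`.
#'
#' @param ro_threshold minimum reciprocal overlap for DEL/INV (fraction).
#' @param dup_ro_threshold minimum RO for DUP (fraction).
#' @param bp_error_cap absolute breakpoint-error cap in bp (strict `<`).
#' @param bp_error_frac relative breakpoint-error cap as a fraction of the
#'   combined length.
#' @param ins_distance_cap maximum insertion-site distance in bp (`<=`).
#' @param error_rule `"min"` (default) or `"or"`, see Details.
#' @return A list of class `match_criteria`.
#' @export
match_criteria <- function(ro_threshold = 0.9, dup_ro_threshold = 0.7,
                           bp_error_cap = 10, bp_error_frac = 0.1,
                           ins_distance_cap = 10,
                           error_rule = c("min", "or")) {
  stopifnot(ro_threshold > 0, ro_threshold <= 1,
            dup_ro_threshold > 0, dup_ro_threshold <= 1,
            bp_error_cap >= 0, bp_error_frac >= 0, ins_distance_cap >= 0)
  structure(list(ro_threshold = ro_threshold,
                 dup_ro_threshold = dup_ro_threshold,
                 bp_error_cap = bp_error_cap, bp_error_frac = bp_error_frac,
                 ins_distance_cap = ins_distance_cap,
                 error_rule = match.arg(error_rule)),
            class = "match_criteria")
}

#' Test whether predictions match truth events
#'
#' Row-wise application of the matching criterion (see [match_criteria()]).
#' Pairs with mismatched SV types are `FALSE`, not an error.
#'
#' @param p,s `sv_calls` tables compared row-wise (single rows recycled).
#' @param criteria a [match_criteria()] object.
#' @return Logical vector.
#' @export
#' @examples
#' p <- sv_calls("chr1", 100, 200, "DEL")
#' s <- sv_calls("chr1", 104, 204, "DEL")
#' is_match(p, s, match_criteria())  # TRUE (RO 0.96, e = 8)
is_match <- function(p, s, criteria = match_criteria()) {
  pr <- recycle_pair(p, s)
  p <- pr$a; s <- pr$b
  out <- rep(FALSE, nrow(p))
  same <- p$svtype == s$svtype & p$chrom == s$chrom
  if (!any(same)) return(out)

  idx <- which(same & p$svtype == "INS")
  if (length(idx))
    out[idx] <- abs(p$start[idx] - s$start[idx]) <= criteria$ins_distance_cap

  idx <- which(same & p$svtype == "DUP")
  if (length(idx))
    out[idx] <- reciprocal_overlap(p[idx, ], s[idx, ]) >=
      criteria$dup_ro_threshold

  idx <- which(same & p$svtype %in% c("DEL", "INV"))
  if (length(idx)) {
    ro <- reciprocal_overlap(p[idx, ], s[idx, ])
    e <- breakpoint_error(p[idx, ], s[idx, ])
    comb <- p$length[idx] + s$length[idx]
    e_ok <- if (criteria$error_rule == "min")
      e < pmin(criteria$bp_error_cap, criteria$bp_error_frac * comb)
    else
      e < criteria$bp_error_cap | e < criteria$bp_error_frac * comb
    out[idx] <- ro >= criteria$ro_threshold & e_ok
  }
  out
}

# candidate (pred, truth) index pairs that could possibly match:
# overlapping intervals for spans, sites within the INS radius for points
candidate_pairs <- function(pred, truth, criteria) {
  if (!nrow(pred) || !nrow(truth))
    return(data.frame(pi = integer(), ti = integer()))
  gp <- calls_granges(pred)
  gt <- calls_granges(truth)
  hits_span <- GenomicRanges::findOverlaps(gp[pred$svtype != "INS"],
                                           gt[truth$svtype != "INS"])
  pi_span <- which(pred$svtype != "INS")[S4Vectors::queryHits(hits_span)]
  ti_span <- which(truth$svtype != "INS")[S4Vectors::subjectHits(hits_span)]
  hits_ins <- GenomicRanges::findOverlaps(
    gp[pred$svtype == "INS"], gt[truth$svtype == "INS"],
    maxgap = criteria$ins_distance_cap)
  pi_ins <- which(pred$svtype == "INS")[S4Vectors::queryHits(hits_ins)]
  ti_ins <- which(truth$svtype == "INS")[S4Vectors::subjectHits(hits_ins)]
  data.frame(pi = c(pi_span, pi_ins), ti = c(ti_span, ti_ins))
}

#' Greedy one-to-one matching of a prediction set against a truth set
#'
#' All candidate pairs satisfying the matching criterion are ranked by
#' descending reciprocal overlap, ascending breakpoint error, then coordinate
#' order (for insertions: ascending site distance), and assigned greedily so
#' that every prediction and every truth event is used at most once. The
#' ranking makes the assignment deterministic and independent of input order.
#'
#' @param pred,truth `sv_calls` tables.
#' @param criteria a [match_criteria()] object.
#' @return A list with `pairs` (data.frame of matched `pred_idx`,
#'   `truth_idx`, `ro`, `bp_error`), `unmatched_pred` and `unmatched_truth`
#'   (integer row indices).
#' @export
match_callsets <- function(pred, truth, criteria = match_criteria()) {
  cand <- candidate_pairs(pred, truth, criteria)
  if (nrow(cand)) {
    ok <- is_match(pred[cand$pi, ], truth[cand$ti, ], criteria)
    cand <- cand[ok, , drop = FALSE]
  }
  pairs <- data.frame(pred_idx = integer(), truth_idx = integer(),
                      ro = numeric(), bp_error = numeric())
  if (nrow(cand)) {
    ins <- pred$svtype[cand$pi] == "INS"
    ro <- rep(NA_real_, nrow(cand))
    e <- abs(pred$start[cand$pi] - truth$start[cand$ti]) +
      abs(pred$end[cand$pi] - truth$end[cand$ti])
    if (any(!ins))
      ro[!ins] <- reciprocal_overlap(pred[cand$pi[!ins], ],
                                     truth[cand$ti[!ins], ])
    score_ro <- ifelse(ins, 2, ro)  # exact-site INS sorts by distance only
    ord <- order(-score_ro, e, pred$start[cand$pi], truth$start[cand$ti],
                 cand$pi, cand$ti)
    used_p <- logical(nrow(pred)); used_t <- logical(nrow(truth))
    keep <- integer()
    for (k in ord) {
      if (!used_p[cand$pi[k]] && !used_t[cand$ti[k]]) {
        used_p[cand$pi[k]] <- TRUE
        used_t[cand$ti[k]] <- TRUE
        keep <- c(keep, k)
      }
    }
    pairs <- data.frame(pred_idx = cand$pi[keep], truth_idx = cand$ti[keep],
                        ro = ro[keep], bp_error = e[keep])
  }
  list(pairs = pairs,
       unmatched_pred = setdiff(seq_len(nrow(pred)), pairs$pred_idx),
       unmatched_truth = setdiff(seq_len(nrow(truth)), pairs$truth_idx))
}

#' Benchmark a prediction set against a truth set per SV type and size bin
#'
#' Runs [match_callsets()] and tallies TP/FP/FN per `(svtype, bin)` cell.
#' True positives and false negatives are binned by the truth event length,
#' false positives by the predicted length. Sensitivity `tp/(tp+fn)` and
#' precision `tp/(tp+fp)` are `NA` (never 0 by convention) when their
#' denominator is empty.
#'
#' @inheritParams match_callsets
#' @return A data.frame of class `benchmark_result` with columns `svtype`,
#'   `bin`, `tp`, `fp`, `fn`, `sensitivity`, `precision`.
#' @export
evaluate_callset <- function(pred, truth, criteria = match_criteria()) {
  m <- match_callsets(pred, truth, criteria)
  bins <- c(size_bins$label, "unbinned")
  cell <- function(type, bin) {
    tp <- sum(truth$svtype[m$pairs$truth_idx] == type &
                size_bin(truth$length[m$pairs$truth_idx]) == bin)
    fn <- sum(truth$svtype[m$unmatched_truth] == type &
                size_bin(truth$length[m$unmatched_truth]) == bin)
    fp <- sum(pred$svtype[m$unmatched_pred] == type &
                size_bin(pred$length[m$unmatched_pred]) == bin)
    c(tp = tp, fp = fp, fn = fn)
  }
  grid <- expand.grid(svtype = intersect(SV_TYPES,
                                         c(truth$svtype, pred$svtype)),
                      bin = bins, stringsAsFactors = FALSE)
  counts <- t(mapply(cell, grid$svtype, grid$bin))
  res <- cbind(grid, as.data.frame(counts))
  res <- res[res$tp + res$fp + res$fn > 0, , drop = FALSE]
  res$sensitivity <- ifelse(res$tp + res$fn > 0,
                            res$tp / (res$tp + res$fn), NA_real_)
  res$precision <- ifelse(res$tp + res$fp > 0,
                          res$tp / (res$tp + res$fp), NA_real_)
  res <- res[order(res$svtype, match(res$bin, bins)), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("benchmark_result", "data.frame")
  res
}
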