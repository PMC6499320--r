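#' Per-gene indicator matrix over a TSS-anchored window
#'
#' Builds a genes x positions logical matrix marking, for each gene and each
#' strand-aware offset in `[-upstream, +downstream]` around its TSS, whether
#' the position is covered by any interval of `track` (an annotation track
#' or an `sv_calls` table). Upstream is always negative regardless of
#' strand.
#'
#' @param models a `gene_models` object.
#' @param track intervals with `chrom`, `start`, `end` (0-based half-open).
#' @param upstream,downstream window extent in bp.
#' @return Logical matrix with rownames from `gene_id` and colnames the
#'   relative positions.
#' @export
tss_indicator_matrix <- function(models, track, upstream = 500,
                                 downstream = 500) {
  g <- models$genes
  pos <- seq(-upstream, downstream)
  mat <- matrix(FALSE, nrow = nrow(g), ncol = length(pos),
                dimnames = list(g$gene_id, pos))
  if (!nrow(track)) return(mat)
  gr_t <- GenomicRanges::GRanges(track$chrom, IRanges::IRanges(
    start = track$start + 1, end = track$end))
  plus <- g$strand == "+"
  win_lo <- pmax(0, ifelse(plus, g$tss - upstream, g$tss - downstream))
  win_hi <- ifelse(plus, g$tss + downstream, g$tss + upstream)
  gr_w <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(
    start = win_lo + 1, end = win_hi + 1))
  h <- GenomicRanges::findOverlaps(gr_w, gr_t)
  qi <- S4Vectors::queryHits(h); ti <- S4Vectors::subjectHits(h)
  # relative-offset range covered by each hit (strand-aware)
  r1 <- ifelse(plus[qi], track$start[ti] - g$tss[qi],
               g$tss[qi] - track$end[ti] + 1)
  r2 <- ifelse(plus[qi], track$end[ti] - 1 - g$tss[qi],
               g$tss[qi] - track$start[ti])
  c1 <- pmax(r1, -upstream) + upstream + 1
  c2 <- pmin(r2, downstream) + upstream + 1
  for (k in which(c1 <= c2))
    mat[qi[k], c1[k]:c2[k]] <- TRUE
  mat
}

#' Position-wise independence test between TFBS and SV presence
#'
#' At every position around the TSS, genes are cross-classified by whether
#' a TFBS and whether an SV covers that position, and the 2x2 table is
#' tested for independence (two-sided Fisher's exact test by default; a
#' chi-squared test is available). The table also reports the per-position
#' probabilities `P_x(TFBS)`, `P_x(SV)`, the joint `P_x(TFBS & SV)`, and
#' the conditional `P_x(SV | TFBS) = P_x(TFBS & SV) / P_x(TFBS)` (missing
#' where no gene has a TFBS, in which case the test is skipped). The
#' association sign is the sign of the 2x2 cross-product difference
#' (negative = mutual avoidance).
#'
#' @param tfbs_mat,sv_mat aligned logical matrices from
#'   [tss_indicator_matrix()] (same genes, same positions).
#' @param method `"fisher"` (default) or `"chisq"`.
#' @param adjust optionally add Benjamini-Hochberg adjusted p-values.
#' @return A data.frame of class `tss_position_table`, one row per position.
#' @export
tfbs_sv_independence <- function(tfbs_mat, sv_mat,
                                 method = c("fisher", "chisq"),
                                 adjust = FALSE) {
  stopifnot(identical(dim(tfbs_mat), dim(sv_mat)), nrow(tfbs_mat) >= 2)
  method <- match.arg(method)
  npos <- ncol(tfbs_mat)
  n <- nrow(tfbs_mat)
  pos <- as.integer(colnames(tfbs_mat))
  n_tfbs <- colSums(tfbs_mat)
  n_sv <- colSums(sv_mat)
  n_both <- colSums(tfbs_mat & sv_mat)
  p_value <- rep(NA_real_, npos)
  for (j in seq_len(npos)) {
    if (n_tfbs[j] == 0) next
    a <- n_both[j]
    b <- n_tfbs[j] - a
    c_ <- n_sv[j] - a
    d <- n - n_tfbs[j] - c_
    tab <- matrix(c(a, b, c_, d), 2)
    p_value[j] <- if (method == "fisher")
      stats::fisher.test(tab)$p.value
    else
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  sign_assoc <- sign(n_both * (n - n_tfbs - n_sv + n_both) -
                       (n_tfbs - n_both) * (n_sv - n_both))
  res <- data.frame(
    pos = pos, n_genes = n, n_tfbs = n_tfbs, n_sv = n_sv, n_both = n_both,
    p_tfbs = n_tfbs / n, p_sv = n_sv / n, p_joint = n_both / n,
    p_sv_given_tfbs = ifelse(n_tfbs > 0, n_both / n_tfbs, NA_real_),
    p_value = p_value, sign = sign_assoc, row.names = NULL)
  if (adjust) res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  class(res) <- c("tss_position_table", "data.frame")
  res
}

# distinct substrings of each length 1..N in one word
count_words <- function(chars, N) {
  vapply(seq_len(N), function(i) {
    n_sub <- length(chars) - i + 1
    length(unique(vapply(seq_len(n_sub), function(s)
      paste(chars[s:(s + i - 1)], collapse = ""), "")))
  }, 0)
}

#' Linguistic complexity profile of a sequence
#'
#' For every window of `N` consecutive bases, the linguistic complexity is
#' `CL = sum_i V_i / sum_i Vmax_i` for word sizes `i = 1..N`, where `V_i`
#' is the number of distinct substrings of length `i` observed in the
#' window and `Vmax_i = min(K^i, N - i + 1)` is the maximum possible for an
#' alphabet of size `K`. `CL` lies in (0, 1]; homopolymers score lowest and
#' windows of maximal vocabulary score 1. Windows containing characters
#' outside the alphabet (e.g. N or masked bases) are reported as `NA`.
#'
#' @param sequence a single character string or [Biostrings::DNAString].
#' @param N window size in bp (default 10).
#' @param K alphabet size (default 4).
#' @param alphabet characters counted as valid (default A, C, G, T).
#' @return Numeric vector of CL values, one per window start
#'   (length `nchar(sequence) - N + 1`).
#' @export
#' @examples
#' linguistic_complexity(strrep("A", 10))  # 10/49
linguistic_complexity <- function(sequence, N = 10, K = 4,
                                  alphabet = c("A", "C", "G", "T")) {
  if (N < 1) stop("window size N must be >= 1")
  sequence <- toupper(as.character(sequence))
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L < N) stop("sequence shorter than the window size")
  vmax_total <- sum(pmin(K ^ seq_len(N), N - seq_len(N) + 1))
  ok <- chars %in% alphabet
  vapply(seq_len(L - N + 1), function(s) {
    idx <- s:(s + N - 1)
    if (!all(ok[idx])) return(NA_real_)
    sum(count_words(chars[idx], N)) / vmax_total
  }, 0)
}

#' Average linguistic-complexity profile across aligned sequences
#'
#' Computes [linguistic_complexity()] for each sequence (e.g. TSS-anchored
#' promoter regions) and averages position-wise, ignoring masked windows.
#'
#' @param sequences character vector or [Biostrings::DNAStringSet] of
#'   equal-length sequences.
#' @inheritParams linguistic_complexity
#' @return Numeric vector: mean CL per window start.
#' @export
complexity_profile <- function(sequences, N = 10, K = 4) {
  seqs <- as.character(sequences)
  stopifnot(length(unique(nchar(seqs))) == 1)
  prof <- vapply(seqs, linguistic_complexity, N = N, K = K,
                 FUN.VALUE = numeric(nchar(seqs[1]) - N + 1))
  rowMeans(matrix(prof, ncol = length(seqs)), na.rm = TRUE)
}

#' Over-representation test for a gene list against a population
#'
#' One-sided hypergeometric (Fisher's exact) upper-tail probability of
#' observing at least `list_hits` category members among `list_total` drawn
#' from a population of `pop_total` genes containing `pop_hits` members,
#' with the sample odds ratio of the 2x2 table. All arguments are
#' vectorized; with more than one category, Benjamini-Hochberg adjusted
#' p-values are included.
#'
#' @param list_hits,list_total hits in and size of the query list.
#' @param pop_hits,pop_total hits in and size of the population.
#' @param category optional category labels for the result table.
#' @return A data.frame with `category`, `list_hits`, `list_total`,
#'   `pop_hits`, `pop_total`, `odds_ratio`, `p_value` (and `p_adj` for
#'   multiple categories). Zero margins give `p_value = 1` and `NA` odds
#'   ratio.
#' @export
#' @examples
#' enrichment_test(10, 20, 100, 1000)
enrichment_test <- function(list_hits, list_total, pop_hits, pop_total,
                            category = NULL) {
  stopifnot(all(list_hits <= list_total), all(list_total <= pop_total),
            all(list_hits <= pop_hits), all(pop_hits <= pop_total))
  n <- max(lengths(list(list_hits, list_total, pop_hits, pop_total)))
  list_hits <- rep_len(list_hits, n); list_total <- rep_len(list_total, n)
  pop_hits <- rep_len(pop_hits, n); pop_total <- rep_len(pop_total, n)
  # P(X >= list_hits), X ~ Hypergeom(pop_hits, pop_total - pop_hits,
  # list_total); >= 0 successes has probability 1 by convention
  p <- stats::phyper(list_hits - 1, pop_hits, pop_total - pop_hits,
                     list_total, lower.tail = FALSE)
  a <- list_hits
  b <- list_total - list_hits
  c_ <- pop_hits - list_hits
  d <- (pop_total - list_total) - (pop_hits - list_hits)
  or <- ifelse(b * c_ > 0, (a * d) / (b * c_),
               ifelse(a * d > 0, Inf, NA_real_))
  zero_margin <- list_total == 0 | pop_hits == 0 | pop_hits == pop_total
  p[zero_margin] <- 1
  or[zero_margin] <- NA_real_
  res <- data.frame(
    category = if (is.null(category)) paste0("cat", seq_len(n)) else
      as.character(category),
    list_hits = list_hits, list_total = list_total,
    pop_hits = pop_hits, pop_total = pop_total,
    odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  if (n > 1) res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  res
}
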