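#' svmosaic: population-scale structural variant catalogs
#'
#' Build SV catalogs from multi-caller call sets: within-sample merging,
#' cross-sample clustering into allelic events, simulation-based caller
#' benchmarking, and downstream genome annotation / regulatory statistics.
#'
#' All coordinates are handled internally as 0-based half-open intervals
#' `[start, end)`; VCF and GFF readers and writers convert to and from the
#' 1-based inclusive conventions of those formats. Insertions are modeled as
#' point events (`start == end`) carrying the inserted length.
#'
#' @keywords internal
#' @aliases svmosaic-package
"_PACKAGE"

SV_TYPES <- c("DEL", "INS", "INV", "DUP")

#' Benchmark size bins
#'
#' The six SV length bins used throughout benchmarking: A (50-150 bp),
#' B (151-500 bp), C (501-5000 bp), D (5001-50000 bp), E (50001-250000 bp),
#' F (250001-1000000 bp). The published B/C boundary is ambiguous at 500 bp;
#' it is resolved here as B inclusive of 500 with C starting at 501, so the
#' bins partition [50, 1e6].
#'
#' @format A data.frame with columns `label`, `lo`, `hi` (inclusive bp bounds).
#' @export
size_bins <- data.frame(
  label = c("A", "B", "C", "D", "E", "F"),
  lo = c(50, 151, 501, 5001, 50001, 250001),
  hi = c(150, 500, 5000, 50000, 250000, 1000000),
  stringsAsFactors = FALSE
)

#' Construct a validated table of SV calls
#'
#' An `sv_calls` object is a data.frame with one row per SV call in one
#' sample from one caller. Intervals are 0-based half-open. Deletions,
#' inversions and duplications have positive extent with
#' `length == end - start`; insertions are points (`start == end`) whose
#' `length` is the inserted-sequence length.
#'
#' @param chrom character chromosome names.
#' @param start,end 0-based half-open interval bounds (bp). For INS,
#'   `start == end` marks the insertion site.
#' @param svtype one of `"DEL"`, `"INS"`, `"INV"`, `"DUP"` (recycled).
#' @param length event length in bp; defaults to `end - start` for non-INS
#'   calls and must be supplied for INS.
#' @param sample_id,caller_id provenance labels (recycled).
#' @param filter_status caller FILTER field, e.g. `"PASS"`.
#' @param inserted_seq optional inserted nucleotide sequence (INS only); when
#'   present its width must equal `length`.
#' @param min_sv_len minimum event length admitted (default 10 bp).
#' @return A data.frame of class `sv_calls`.
#' @export
#' @examples
#' sv_calls("chr1", 100, 200, "DEL")
sv_calls <- function(chrom = character(), start = numeric(), end = numeric(),
                     svtype = character(), length = NULL,
                     sample_id = "S1", caller_id = "caller",
                     filter_status = "PASS", inserted_seq = NA_character_,
                     min_sv_len = 10) {
  n <- max(base::length(chrom), base::length(start), base::length(end),
           base::length(svtype))
  if (base::length(chrom) == 0) n <- 0
  if (n == 0) {
    df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     svtype = character(), length = numeric(),
                     sample_id = character(), caller_id = character(),
                     filter_status = character(), inserted_seq = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("sv_calls", "data.frame")
    return(df)
  }
  svtype <- rep_len(svtype, n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  if (is.null(length)) {
    if (any(svtype == "INS"))
      stop("`length` must be supplied for INS calls")
    length <- end - start
  }
  df <- data.frame(
    chrom = as.character(rep_len(chrom, n)),
    start = as.numeric(start), end = as.numeric(end),
    svtype = svtype, length = as.numeric(rep_len(length, n)),
    sample_id = as.character(rep_len(sample_id, n)),
    caller_id = as.character(rep_len(caller_id, n)),
    filter_status = as.character(rep_len(filter_status, n)),
    inserted_seq = as.character(rep_len(inserted_seq, n)),
    stringsAsFactors = FALSE
  )
  validate_sv_calls(df, min_sv_len = min_sv_len)
  class(df) <- c("sv_calls", "data.frame")
  df
}

#' @rdname sv_calls
#' @param x a data.frame with at least the columns of [sv_calls()].
#' @export
as_sv_calls <- function(x, min_sv_len = 10) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end", "svtype", "length")
  miss <- setdiff(need, names(x))
  if (base::length(miss))
    stop("missing sv_calls columns: ", paste(miss, collapse = ", "))
  if (is.null(x$sample_id)) x$sample_id <- "S1"
  if (is.null(x$caller_id)) x$caller_id <- "caller"
  if (is.null(x$filter_status)) x$filter_status <- "PASS"
  if (is.null(x$inserted_seq)) x$inserted_seq <- NA_character_
  x <- x[, c(need, "sample_id", "caller_id", "filter_status", "inserted_seq")]
  validate_sv_calls(x, min_sv_len = min_sv_len)
  class(x) <- c("sv_calls", "data.frame")
  rownames(x) <- NULL
  x
}

validate_sv_calls <- function(df, min_sv_len = 10) {
  if (!all(df$svtype %in% SV_TYPES))
    stop("svtype must be one of ", paste(SV_TYPES, collapse = ", "))
  ins <- df$svtype == "INS"
  if (any(df$start[!ins] >= df$end[!ins]))
    stop("DEL/INV/DUP calls require start < end")
  if (any(df$length[!ins] != df$end[!ins] - df$start[!ins]))
    stop("length must equal end - start for DEL/INV/DUP")
  if (any(df$start[ins] != df$end[ins]))
    stop("INS calls are points: start must equal end")
  has_seq <- ins & !is.na(df$inserted_seq)
  if (any(nchar(df$inserted_seq[has_seq]) != df$length[has_seq]))
    stop("INS length must equal the inserted sequence width")
  if (any(df$length < min_sv_len))
    stop("all calls must have length >= ", min_sv_len, " bp")
  invisible(df)
}

rbind_sv_calls <- function(lst) {
  lst <- lst[vapply(lst, nrow, 0L) > 0]
  if (!base::length(lst)) return(sv_calls())
  out <- do.call(rbind, lapply(lst, function(x) {
    class(x) <- "data.frame"
    x
  }))
  rownames(out) <- NULL
  class(out) <- c("sv_calls", "data.frame")
  out
}

#' Reciprocal overlap between paired SV calls
#'
#' The reciprocal overlap (RO) of two intervals is the smaller of the two
#' fractions of each interval covered by their intersection:
#' `min(overlap/length(a), overlap/length(b))`. It is 0 for disjoint calls or
#' calls on different chromosomes, and undefined (an error) for insertions,
#' which are point events compared by positional distance instead.
#'
#' @param a,b `sv_calls` tables compared row-wise (single rows are recycled).
#' @return Numeric vector of RO fractions in `[0, 1]`.
#' @seealso [breakpoint_error()]
#' @export
#' @examples
#' a <- sv_calls("chr1", 100, 200, "DEL")
#' b <- sv_calls("chr1", 150, 250, "DEL")
#' reciprocal_overlap(a, b)  # 0.5
reciprocal_overlap <- function(a, b) {
  p <- recycle_pair(a, b)
  if (any(p$a$svtype == "INS") || any(p$b$svtype == "INS"))
    stop("reciprocal overlap is undefined for INS (point) events; ",
         "compare insertion sites by positional distance")
  ov <- pmax(0, pmin(p$a$end, p$b$end) - pmax(p$a$start, p$b$start))
  ro <- pmin(ov / p$a$length, ov / p$b$length)
  ro[p$a$chrom != p$b$chrom] <- 0
  ro
}

#' Breakpoint error between paired SV calls
#'
#' The breakpoint error `e` of two calls on the same chromosome is the sum of
#' the absolute distances between their start and their end coordinates.
#'
#' @inheritParams reciprocal_overlap
#' @return Numeric vector of non-negative bp distances.
#' @export
#' @examples
#' a <- sv_calls("chr1", 100, 200, "DEL")
#' b <- sv_calls("chr1", 105, 205, "DEL")
#' breakpoint_error(a, b)  # 10
breakpoint_error <- function(a, b) {
  p <- recycle_pair(a, b)
  if (any(p$a$chrom != p$b$chrom))
    stop("breakpoint error requires calls on the same chromosome")
  abs(p$a$start - p$b$start) + abs(p$a$end - p$b$end)
}

recycle_pair <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != n) a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  if (nrow(b) != n) b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  list(a = a, b = b)
}

#' Assign SV lengths to benchmark size bins
#'
#' @param length numeric vector of SV lengths (bp).
#' @return Character vector of bin labels `"A"`..`"F"`; lengths outside
#'   `[50, 1e6]` get the sentinel `"unbinned"` (still clusterable, just
#'   excluded from binned benchmarking).
#' @export
#' @examples
#' size_bin(c(100, 500, 501, 250001))  # "A" "B" "C" "F"
size_bin <- function(length) {
  idx <- findInterval(length, size_bins$lo)
  out <- rep("unbinned", base::length(length))
  ok <- idx >= 1 & length <= size_bins$hi[pmax(idx, 1)]
  out[ok] <- size_bins$label[idx[ok]]
  out
}

# GRanges view of non-INS calls (INS become width-1 points at the site)
calls_granges <- function(calls) {
  w0 <- calls$svtype == "INS"
  end1 <- ifelse(w0, calls$start + 1, calls$end)
  GenomicRanges::GRanges(calls$chrom,
                         IRanges::IRanges(start = calls$start + 1, end = end1))
}
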