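#' Configuration for the seeded synthetic-data generators
#'
#' Holds every knob of the synthetic-data module. The generators emulate the
#' call-level behaviour of short-read SV callers on a rice-scale genome:
#' ground-truth events drawn per size bin (defaults mirror a benchmark
#' design of 1000 events per type for bins A-D and 200/100 for E/F),
#' breakpoint jitter, false-negative dropout, bin-matched false positives,
#' and multi-sample panels with planted allelic events. Each generator
#' derives its own RNG substream deterministically from `seed`, so every
#' output is reproducible from the configuration alone.
#'
#' The read-level design constants of the emulated sequencing experiment
#' (83-bp reads, 500-bp insert size with SD 50, 2% base error) are recorded
#' in `read_design` for provenance; the generators work at the call level
#' and do not use them.
#'
#' @param seed integer master seed.
#' @param genome_lengths named vector of chromosome lengths in bp (default:
#'   twelve 31-Mb chromosomes, a rice-scale genome).
#' @param truth_counts named vector of per-bin event counts (names A-F).
#' @param jitter_sd breakpoint jitter SD for emulated callers (bp).
#' @param fn_rate,fp_rate false-negative and false-positive rates in [0,1].
#' @param panel_size number of samples in simulated panels.
#' @param af_range allele-frequency range for planted events.
#' @param jitter_rel per-sample breakpoint jitter of planted panel events,
#'   as a fraction of event length (default 0.02, matching the breakpoint
#'   scatter observed in real multi-sample SV clusters).
#' @param max_attempts placement attempts per event before failing.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       genome_lengths = stats::setNames(
                         rep(31e6, 12), paste0("chr", sprintf("%02d", 1:12))),
                       truth_counts = c(A = 1000, B = 1000, C = 1000,
                                        D = 1000, E = 200, F = 100),
                       jitter_sd = 3, fn_rate = 0.1, fp_rate = 0.05,
                       panel_size = 20, af_range = c(0.1, 1),
                       jitter_rel = 0.02, max_attempts = 1000) {
  stopifnot(fn_rate >= 0, fn_rate <= 1, fp_rate >= 0, fp_rate <= 1,
            all(truth_counts >= 0), all(genome_lengths > 0),
            jitter_sd >= 0, panel_size >= 1)
  stopifnot(all(names(truth_counts) %in% size_bins$label))
  structure(list(seed = as.integer(seed), genome_lengths = genome_lengths,
                 truth_counts = truth_counts, jitter_sd = jitter_sd,
                 fn_rate = fn_rate, fp_rate = fp_rate,
                 panel_size = panel_size, af_range = af_range,
                 jitter_rel = jitter_rel, max_attempts = max_attempts,
                 read_design = c(read_length = 83, insert_size = 500,
                                 insert_sd = 50, error_rate = 0.02)),
            class = "sim_config")
}

# substream seed for a named generator, kept under 2^31
substream_seed <- function(cfg, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((cfg$seed * 10007 + h) %% .Machine$integer.max)
}

#' Simulate a ground-truth SV event set
#'
#' Draws `truth_counts[bin]` events per requested SV type and size bin, with
#' lengths uniform within each bin and non-overlapping placement per type
#' (each type is benchmarked as its own truth layer). Placement is by
#' rejection sampling; an infeasible packing fails with an error naming the
#' bin. Insertion events are points with a minimum spacing of 100 bp.
#'
#' @param cfg a [sim_config()].
#' @param svtypes SV types to simulate.
#' @return An `sv_calls` table with a `truth_id` column, caller `"truth"`.
#' @export
simulate_truth_set <- function(cfg, svtypes = "DEL") {
  set.seed(substream_seed(cfg, "truth"))
  chroms <- names(cfg$genome_lengths)
  out <- list()
  for (type in svtypes) {
    # lengths per bin, largest placed first to ease packing
    lens <- unlist(lapply(names(cfg$truth_counts), function(b) {
      n <- cfg$truth_counts[[b]]
      if (n == 0) return(numeric())
      bb <- size_bins[size_bins$label == b, ]
      floor(stats::runif(n, bb$lo, bb$hi + 1))
    }))
    if (!length(lens)) next
    lens <- sort(lens, decreasing = TRUE)
    placed_s <- lapply(chroms, function(x) numeric())
    placed_e <- lapply(chroms, function(x) numeric())
    names(placed_s) <- names(placed_e) <- chroms
    rows <- vector("list", length(lens))
    pchr <- sample(chroms, length(lens), replace = TRUE,
                   prob = cfg$genome_lengths)
    pad <- if (type == "INS") 100 else 0
    for (i in seq_along(lens)) {
      len <- lens[i]
      ok <- FALSE
      for (att in seq_len(cfg$max_attempts)) {
        ch <- if (att == 1) pchr[i] else
          sample(chroms, 1, prob = cfg$genome_lengths)
        L <- cfg$genome_lengths[[ch]]
        ext <- if (type == "INS") pad else len
        if (L <= ext + 1) next
        s <- floor(stats::runif(1, 0, L - ext))
        e <- if (type == "INS") s else s + len
        lo <- s - pad; hi <- e + pad
        ss <- placed_s[[ch]]; ee <- placed_e[[ch]]
        j <- findInterval(lo, ss)
        clash <- (j >= 1 && ee[j] > lo) ||
          (j < length(ss) && ss[j + 1] < hi)
        if (!clash) {
          placed_s[[ch]] <- append(ss, s, after = j)
          placed_e[[ch]] <- append(ee, e, after = j)
          rows[[i]] <- data.frame(chrom = ch, start = s, end = e,
                                  svtype = type, length = len,
                                  stringsAsFactors = FALSE)
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place a ", type, " event of length ", len,
             " (bin ", size_bin(len), ") after ", cfg$max_attempts,
             " attempts; enlarge the genome or reduce counts")
    }
    out[[type]] <- do.call(rbind, rows)
  }
  if (!length(out)) {
    res <- sv_calls()
    res$truth_id <- character()
    return(res)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  res <- as_sv_calls(transform(df, sample_id = "sim", caller_id = "truth"))
  res$truth_id <- sprintf("T_%s_%05d", res$svtype, seq_len(nrow(res)))
  res
}

#' Emulate a caller's output from a truth set
#'
#' Independently drops each truth event with probability `fn_rate`, perturbs
#' surviving breakpoints with integer Gaussian noise of SD `jitter_sd`
#' (clipped so `start < end` and the length stays >= 10 bp; insertion sites
#' are shifted as a whole), and adds `round(fp_rate * n_truth)` spurious
#' calls with lengths resampled from the truth set (bin-matched) at uniform
#' positions. All provenance fields are set; FILTER is `PASS`.
#'
#' @param truth truth set from [simulate_truth_set()].
#' @param cfg a [sim_config()].
#' @param caller_id label for the emulated caller (also salts its RNG
#'   substream, so different callers err independently).
#' @param sample_id sample label.
#' @return An `sv_calls` table.
#' @export
emulate_caller <- function(truth, cfg, caller_id = "emul",
                           sample_id = "S1") {
  set.seed(substream_seed(cfg, paste0("emulate:", caller_id)))
  n <- nrow(truth)
  keep <- stats::runif(n) >= cfg$fn_rate
  surv <- truth[keep, , drop = FALSE]
  if (nrow(surv)) {
    ins <- surv$svtype == "INS"
    ds <- round(stats::rnorm(nrow(surv), 0, cfg$jitter_sd))
    de <- round(stats::rnorm(nrow(surv), 0, cfg$jitter_sd))
    surv$start <- surv$start + ds
    surv$end <- ifelse(ins, surv$start, surv$end + de)
    surv$start <- pmax(surv$start, 0)
    bad <- !ins & (surv$end - surv$start < 10)
    surv$end[bad] <- surv$start[bad] + 10
    surv$length <- ifelse(ins, surv$length, surv$end - surv$start)
  }
  n_fp <- round(cfg$fp_rate * n)
  fp <- NULL
  if (n_fp > 0 && n > 0) {
    src <- truth[sample.int(n, n_fp, replace = TRUE), , drop = FALSE]
    chroms <- names(cfg$genome_lengths)
    ch <- sample(chroms, n_fp, replace = TRUE, prob = cfg$genome_lengths)
    maxs <- cfg$genome_lengths[ch] - ifelse(src$svtype == "INS", 1,
                                            src$length)
    s <- floor(stats::runif(n_fp, 0, pmax(maxs, 1)))
    fp <- data.frame(chrom = ch, start = s,
                     end = ifelse(src$svtype == "INS", s, s + src$length),
                     svtype = src$svtype, length = src$length,
                     stringsAsFactors = FALSE)
  }
  surv_df <- if (nrow(surv)) surv[, c("chrom", "start", "end", "svtype",
                                      "length")] else NULL
  df <- rbind(surv_df, fp)
  if (is.null(df) || !nrow(df)) return(sv_calls())
  df$sample_id <- sample_id
  df$caller_id <- caller_id
  df$filter_status <- "PASS"
  truth_id <- c(if (nrow(surv)) truth$truth_id[keep],
                rep(NA_character_, if (is.null(fp)) 0 else nrow(fp)))
  o <- order(df$chrom, df$start, df$end)
  res <- as_sv_calls(df[o, , drop = FALSE])
  res$truth_id <- truth_id[o]
  res
}

#' Simulate a multi-sample panel with planted allelic SV clusters
#'
#' Plants `n_events` deletion events at well-separated positions, assigns
#' each an allele frequency drawn uniformly from `cfg$af_range`, samples
#' carriers as independent Bernoulli draws per panel sample (events drawn
#' with zero carriers are assigned one random carrier so every planted
#' cluster is observable), and jitters each carrier's breakpoints with SD
#' `cfg$jitter_rel * length`. The answer key is the `planted_id` column:
#' calls sharing it descend from one planted event.
#'
#' @param cfg a [sim_config()].
#' @param n_events number of planted clusters.
#' @param length_range min/max planted event length (bp, log-uniform).
#' @param svtype planted event type (`"DEL"` or `"INV"`).
#' @return A list with `calls` (an `sv_calls` table with `planted_id`),
#'   `events` (planted event table with `planted_id`, `freq`), and
#'   `panel` (sample ids).
#' @export
simulate_panel <- function(cfg, n_events = 50, length_range = c(200, 5000),
                           svtype = "DEL") {
  set.seed(substream_seed(cfg, "panel"))
  panel <- sprintf("S%03d", seq_len(cfg$panel_size))
  lens <- floor(exp(stats::runif(n_events, log(length_range[1]),
                                 log(length_range[2]))))
  # sequential placement with generous spacing so planted events stay
  # disjoint even after jitter
  gaps <- pmax(3 * lens, 2000)
  chroms <- names(cfg$genome_lengths)
  ev <- NULL
  pos <- 1000; ci <- 1
  starts <- numeric(n_events); chs <- character(n_events)
  for (i in seq_len(n_events)) {
    if (pos + lens[i] + gaps[i] > cfg$genome_lengths[[chroms[ci]]]) {
      ci <- ci + 1
      if (ci > length(chroms)) stop("panel events do not fit the genome")
      pos <- 1000
    }
    starts[i] <- pos; chs[i] <- chroms[ci]
    pos <- pos + lens[i] + gaps[i]
  }
  freq <- stats::runif(n_events, cfg$af_range[1], cfg$af_range[2])
  events <- data.frame(planted_id = sprintf("P%04d", seq_len(n_events)),
                       chrom = chs, start = starts, end = starts + lens,
                       svtype = svtype, length = lens, freq = freq,
                       stringsAsFactors = FALSE)
  calls <- list()
  for (i in seq_len(n_events)) {
    carriers <- panel[stats::runif(cfg$panel_size) < freq[i]]
    if (!length(carriers)) carriers <- sample(panel, 1)
    k <- length(carriers)
    sd_i <- cfg$jitter_rel * lens[i]
    ds <- round(stats::rnorm(k, 0, sd_i)); de <- round(stats::rnorm(k, 0, sd_i))
    s <- pmax(0, events$start[i] + ds)
    e <- events$end[i] + de
    e <- pmax(e, s + 10)
    df <- data.frame(chrom = events$chrom[i], start = s, end = e,
                     svtype = svtype, length = e - s, sample_id = carriers,
                     caller_id = "merged", filter_status = "PASS",
                     stringsAsFactors = FALSE)
    df$planted_id <- events$planted_id[i]
    calls[[i]] <- df
  }
  df <- do.call(rbind, calls)
  o <- order(df$chrom, df$start, df$end, df$sample_id)
  res <- as_sv_calls(df[o, c("chrom", "start", "end", "svtype", "length",
                             "sample_id", "caller_id", "filter_status")])
  res$planted_id <- df$planted_id[o]
  list(calls = res, events = events, panel = panel)
}

#' Compare a recovered clustering against the planted answer key
#'
#' Joins the clustered members back to the planted calls on
#' (sample, chrom, start, end) and returns the two partition label vectors.
#'
#' @param panel_sim result of [simulate_panel()].
#' @param cluster_set result of [cluster_all()] on `panel_sim$calls`.
#' @return A data.frame with columns `planted_id` and `cluster_id`.
#' @export
planted_vs_recovered <- function(panel_sim, cluster_set) {
  key <- paste(panel_sim$calls$sample_id, panel_sim$calls$chrom,
               panel_sim$calls$start, panel_sim$calls$end)
  mem <- cluster_set$members
  mkey <- paste(mem$sample_id, mem$chrom, mem$start, mem$end)
  idx <- match(key, mkey)
  stopifnot(!anyNA(idx))
  data.frame(planted_id = panel_sim$calls$planted_id,
             cluster_id = mem$cluster_id[idx], stringsAsFactors = FALSE)
}

#' Simulate gene models, annotation tracks and sequence
#'
#' Generates a single-chromosome locus with `n_genes` genes of fixed
#' UTR/CDS/intron architecture on random strands, a TE annotation track, a
#' TFBS track placed in the `[TSS-500, TSS+500]` regulatory window of each
#' gene, and deletion calls in the same windows. With `avoidance = 0`, TFBS
#' and SV placements are statistically independent (the null the
#' independence test is calibrated against); `avoidance > 0` rejects
#' TFBS-overlapping SV proposals with probability `1 - exp(-avoidance)`,
#' creating mutual avoidance of tunable strength.
#'
#' @param cfg a [sim_config()].
#' @param n_genes number of genes.
#' @param n_te number of TE intervals (classes drawn from common rice
#'   superfamily labels).
#' @param tfbs_per_gene,sv_per_gene Poisson means per gene.
#' @param avoidance TFBS-avoidance strength for SV placement (>= 0).
#' @param ssr_insets optional list of `list(gene, motif, times)` entries;
#'   each overwrites the start of that gene's 5' UTR sequence with
#'   `strrep(motif, times)` to create a low-complexity inset.
#' @param with_sequence generate the random genome sequence (FASTA-ready).
#' @return A list with `genes` (a `gene_models`), `te_track`, `tfbs_track`
#'   (annotation tracks), `sv_calls`, `genome` (a
#'   [Biostrings::DNAStringSet] or NULL), and `chrom_lengths`.
#' @export
simulate_annotations <- function(cfg, n_genes = 100, n_te = 50,
                                 tfbs_per_gene = 36, sv_per_gene = 4,
                                 avoidance = 0, ssr_insets = NULL,
                                 with_sequence = FALSE) {
  set.seed(substream_seed(cfg, "annot"))
  chrom <- "chrS"
  spacing <- 4000
  chrom_len <- 2000 + n_genes * spacing
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  # fixed architecture (widths in bp, 5' to 3'):
  arch_w <- c(200, 300, 150, 300, 150, 300, 200)
  arch_t <- c("five_prime_UTR", "CDS", "intron", "CDS", "intron", "CDS",
              "three_prime_UTR")
  gene_width <- sum(arch_w)
  gs <- 1000 + (seq_len(n_genes) - 1) * spacing + 700  # promoter headroom
  gid <- sprintf("g%04d", seq_len(n_genes))
  plus <- strands == "+"
  genes_df <- data.frame(gene_id = gid, chrom = chrom, strand = strands,
                         start = gs, end = gs + gene_width,
                         tss = ifelse(plus, gs, gs + gene_width - 1),
                         stringsAsFactors = FALSE)
  nf <- length(arch_w)
  off_end <- cumsum(arch_w); off_start <- off_end - arch_w
  rev_start <- gene_width - rev(off_end)
  feats_df <- data.frame(
    gene_id = rep(gid, each = nf),
    type = as.vector(vapply(plus, function(p)
      if (p) arch_t else rev(arch_t), character(nf))),
    start = rep(gs, each = nf) + as.vector(vapply(plus, function(p)
      if (p) off_start else rev_start, numeric(nf))),
    stringsAsFactors = FALSE)
  feats_df$end <- feats_df$start + rep_len(0, nrow(feats_df)) +
    as.vector(vapply(plus, function(p)
      if (p) arch_w else rev(arch_w), numeric(nf)))
  gm <- gene_models(genes_df, feats_df)

  te_classes <- c("DTT", "DTH", "DTM", "DTA", "RLG", "RLC", "RSU")
  te <- NULL
  if (n_te > 0) {
    tlen <- floor(exp(stats::runif(n_te, log(100), log(5000))))
    ts <- floor(stats::runif(n_te, 0, chrom_len - tlen))
    te <- data.frame(chrom = chrom, start = ts, end = ts + tlen,
                     name = sprintf("TE%04d", seq_len(n_te)),
                     class = sample(te_classes, n_te, replace = TRUE),
                     stringsAsFactors = FALSE)
    te <- te[order(te$start), , drop = FALSE]
    rownames(te) <- NULL
    class(te) <- c("annotation_track", "data.frame")
  } else {
    te <- data.frame(chrom = character(), start = numeric(),
                     end = numeric(), name = character(),
                     class = character(), stringsAsFactors = FALSE)
    class(te) <- c("annotation_track", "data.frame")
  }

  tf_len <- 10
  tss <- gm$genes$tss
  # TFBS: Poisson number per gene, uniform in the regulatory window
  k <- stats::rpois(n_genes, tfbs_per_gene)
  tgi <- rep(seq_len(n_genes), k)
  rel_t <- floor(stats::runif(sum(k), -500, 500 - tf_len))
  t_s <- ifelse(plus[tgi], tss[tgi] + rel_t, tss[tgi] - rel_t - tf_len + 1)
  tfbs_track <- data.frame(
    chrom = rep(chrom, sum(k)), start = t_s, end = t_s + tf_len,
    name = if (sum(k)) sprintf("%s_tf%d", gid[tgi],
                               unlist(lapply(k[k > 0], seq_len))) else
      character(),
    class = rep("TFBS", sum(k)), stringsAsFactors = FALSE)
  tfbs_track <- tfbs_track[order(tfbs_track$start), , drop = FALSE]
  rownames(tfbs_track) <- NULL
  class(tfbs_track) <- c("annotation_track", "data.frame")

  # deletions: Poisson per gene; short/long length mixture; optional
  # rejection of TFBS-overlapping proposals with strength `avoidance`
  m <- stats::rpois(n_genes, sv_per_gene)
  sgi <- rep(seq_len(n_genes), m)
  nsv <- length(sgi)
  len <- ifelse(stats::runif(nsv) < 0.5,
                sample(10:39, nsv, replace = TRUE),
                sample(40:400, nsv, replace = TRUE))
  rel_s <- floor(stats::runif(nsv, -500, 500 - pmin(len, 400)))
  if (avoidance > 0 && nsv) {
    rel_tf_by_gene <- split(rel_t, factor(tgi, levels = seq_len(n_genes)))
    for (j in seq_len(nsv)) {
      rt <- rel_tf_by_gene[[sgi[j]]]
      if (!length(rt)) next
      for (att in seq_len(50)) {
        hits_tf <- any(rel_s[j] < rt + tf_len & rel_s[j] + len[j] > rt)
        if (!hits_tf || stats::runif(1) >= 1 - exp(-avoidance)) break
        rel_s[j] <- floor(stats::runif(1, -500, 500 - min(len[j], 400)))
      }
    }
  }
  sv <- if (nsv) {
    s_s <- ifelse(plus[sgi], tss[sgi] + rel_s,
                  tss[sgi] - rel_s - len + 1)
    as_sv_calls(data.frame(
      chrom = chrom, start = s_s, end = s_s + len, svtype = "DEL",
      length = len, sample_id = "simpop", caller_id = "sim",
      filter_status = "PASS", stringsAsFactors = FALSE))
  } else sv_calls()

  genome <- NULL
  if (with_sequence) {
    seq <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    for (inset in ssr_insets) {
      g <- gm$genes[inset$gene, ]
      utr <- gm$features[gm$features$gene_id == g$gene_id &
                           gm$features$type == "five_prime_UTR", ][1, ]
      motif <- strsplit(strrep(inset$motif, inset$times), "")[[1]]
      at <- utr$start + seq_along(motif)  # 1-based into seq vector
      seq[at] <- motif
    }
    genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
    names(genome) <- chrom
  }
  list(genes = gm, te_track = te, tfbs_track = tfbs_track, sv_calls = sv,
       genome = genome,
       chrom_lengths = stats::setNames(chrom_len, chrom))
}
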