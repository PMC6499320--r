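# Independent oracles and tiny fixture builders used across the suite.
# Everything here is deliberately naive and recomputes from first
# principles, independent of the package's code paths.

mk <- function(chrom, start, end, svtype = "DEL", ...) {
  sv_calls(chrom, start, end, svtype, ...)
}

# naive reciprocal overlap straight from the definition
naive_ro <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  min(ov / (e1 - s1), ov / (e2 - s2))
}

# brute-force hypergeometric upper-tail sum (exact, no phyper)
hyper_tail <- function(list_hits, list_total, pop_hits, pop_total) {
  ks <- list_hits:min(list_total, pop_hits)
  sum(exp(lchoose(pop_hits, ks) +
            lchoose(pop_total - pop_hits, list_total - ks) -
            lchoose(pop_total, list_total)))
}

# set-based linguistic complexity of one window, by exhaustive enumeration
naive_cl <- function(word, K = 4) {
  N <- nchar(word)
  v <- vmax <- 0
  for (i in seq_len(N)) {
    subs <- unique(substring(word, 1:(N - i + 1), i:N))
    v <- v + length(subs)
    vmax <- vmax + min(K^i, N - i + 1)
  }
  v / vmax
}

# Naive reimplementation of the whole cross-sample clustering pipeline for
# one SV type on one chromosome: repeated-pass transitive closure for the
# 1-bp grouping, double-loop similarity edges, BFS components, and an
# agglomeration loop that recomputes every complete-linkage distance from
# scratch each round (same lexicographic tie-break as documented).
naive_cluster <- function(df, cutoff = 0.1) {
  n <- nrow(df)
  lab <- seq_len(n)
  # transitive closure of >=1bp overlap by repeated passes
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (lab[i] != lab[j] && df$chrom[i] == df$chrom[j] &&
          min(df$end[i], df$end[j]) - max(df$start[i], df$start[j]) > 0) {
        lab[lab == lab[j]] <- lab[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- integer(n)
  nxt <- 0L
  for (g in unique(lab)) {
    ix <- which(lab == g)
    m <- length(ix)
    adj <- matrix(FALSE, m, m)
    for (a in seq_len(m)) for (b in seq_len(m)) {
      if (a == b) next
      i <- ix[a]; j <- ix[b]
      ro <- naive_ro(df$start[i], df$end[i], df$start[j], df$end[j])
      e <- abs(df$start[i] - df$start[j]) + abs(df$end[i] - df$end[j])
      if (ro >= 0.9 || (ro >= 0.7 && e <= 10)) adj[a, b] <- TRUE
    }
    # BFS components
    comp <- rep(0L, m)
    cc <- 0L
    for (s in seq_len(m)) {
      if (comp[s] > 0) next
      cc <- cc + 1L
      queue <- s
      comp[s] <- cc
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        for (v in which(adj[u, ] & comp == 0)) {
          comp[v] <- cc; queue <- c(queue, v)
        }
      }
    }
    for (c_id in unique(comp)) {
      cix <- ix[comp == c_id]
      cells <- naive_complete_linkage(df[cix, , drop = FALSE], cutoff)
      for (cell in unique(cells)) {
        nxt <- nxt + 1L
        out[cix[cells == cell]] <- nxt
      }
    }
  }
  out
}

naive_complete_linkage <- function(df, cutoff) {
  m <- nrow(df)
  if (m == 1) return(1L)
  cl <- as.list(seq_len(m))
  dfun <- function(i, j) {
    (abs(df$start[i] - df$start[j]) + abs(df$end[i] - df$end[j])) /
      (df$length[i] + df$length[j])
  }
  ckey <- function(ix) c(min(df$start[ix]), min(df$end[ix]))
  repeat {
    k <- length(cl)
    if (k == 1) break
    bd <- Inf; bp <- NULL
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      dd <- max(vapply(cl[[a]], function(i)
        max(vapply(cl[[b]], function(j) dfun(i, j), 0)), 0))
      better <- dd < bd - 1e-12
      tie <- !better && abs(dd - bd) <= 1e-12 && !is.null(bp) &&
        pair_key_less(ckey(cl[[a]]), ckey(cl[[b]]),
                      ckey(cl[[bp[1]]]), ckey(cl[[bp[2]]]), df, cl,
                      c(a, b), bp)
      if (better || tie) { bd <- dd; bp <- c(a, b) }
    }
    if (bd > cutoff) break
    cl[[bp[1]]] <- c(cl[[bp[1]]], cl[[bp[2]]])
    cl[[bp[2]]] <- NULL
  }
  out <- integer(m)
  for (i in seq_along(cl)) out[cl[[i]]] <- i
  out
}

pair_key_less <- function(k1, k2, k3, k4, df, cl, pa, pb) {
  samp <- function(ix) min(df$sample_id[ix])
  full <- function(kx, ix) c(as.list(kx), samp(ix))
  a <- sort_key_pair(full(k1, cl[[pa[1]]]), full(k2, cl[[pa[2]]]))
  b <- sort_key_pair(full(k3, cl[[pb[1]]]), full(k4, cl[[pb[2]]]))
  for (i in seq_along(a)) {
    if (a[[i]] < b[[i]]) return(TRUE)
    if (a[[i]] > b[[i]]) return(FALSE)
  }
  FALSE
}

sort_key_pair <- function(k1, k2) {
  for (i in seq_along(k1)) {
    if (k1[[i]] < k2[[i]]) return(c(k1, k2))
    if (k1[[i]] > k2[[i]]) return(c(k2, k1))
  }
  c(k1, k2)
}

# partitions equal up to relabeling
same_partition <- function(a, b) {
  ta <- as.integer(factor(a, levels = unique(a)))
  tb <- as.integer(factor(b, levels = unique(b)))
  all(tapply(tb, ta, function(x) length(unique(x))) == 1) &&
    all(tapply(ta, tb, function(x) length(unique(x))) == 1)
}

# random clusterable instance: planted base events, jittered replicates,
# plus scattered noise calls
random_instance <- function(n_max = 30) {
  n_base <- sample(3:6, 1)
  lens <- sample(c(30:80, 200:800), n_base, replace = TRUE)
  starts <- cumsum(sample(50:2000, n_base, replace = TRUE))
  rows <- list()
  for (b in seq_len(n_base)) {
    reps <- sample(1:4, 1)
    for (r in seq_len(reps)) {
      js <- round(rnorm(1, 0, 0.02 * lens[b]))
      je <- round(rnorm(1, 0, 0.02 * lens[b]))
      s <- max(0, starts[b] + js)
      e <- max(s + 10, starts[b] + lens[b] + je)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "chr1", start = s, end = e, svtype = "DEL",
        length = e - s, sample_id = sprintf("S%02d", r),
        caller_id = "m", filter_status = "PASS",
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (nrow(df) > n_max) df <- df[seq_len(n_max), , drop = FALSE]
  as_sv_calls(df)
}

write_vcf_text <- function(lines, path) {
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
               "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO"), collapse = "\t"),
               lines), path)
  path
}

toy_gff <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t2600\t.\t+\t.\tID=gA",
    "chr1\ttest\tmRNA\t1001\t2600\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\ttest\tfive_prime_UTR\t1001\t1200\t.\t+\t.\tParent=gA.1",
    "chr1\ttest\tCDS\t1201\t1500\t.\t+\t.\tParent=gA.1",
    "chr1\ttest\tCDS\t1651\t1950\t.\t+\t.\tParent=gA.1",
    "chr1\ttest\tthree_prime_UTR\t1951\t2600\t.\t+\t.\tParent=gA.1",
    "chr1\ttest\tgene\t9001\t10600\t.\t-\t.\tID=gB",
    "chr1\ttest\tmRNA\t9001\t10600\t.\t-\t.\tID=gB.1;Parent=gB",
    "chr1\ttest\tthree_prime_UTR\t9001\t9200\t.\t-\t.\tParent=gB.1",
    "chr1\ttest\tCDS\t9201\t10400\t.\t-\t.\tParent=gB.1",
    "chr1\ttest\tfive_prime_UTR\t10401\t10600\t.\t-\t.\tParent=gB.1"),
    path)
  path
}
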