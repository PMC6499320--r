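par <- cluster_params()

test_that("1-bp overlap grouping is a transitive closure with half-open bounds", {
  calls <- as_sv_calls(data.frame(
    chrom = "chr1", start = c(0, 99, 100), end = c(100, 200, 200),
    svtype = "DEL", length = c(100, 101, 100), stringsAsFactors = FALSE))
  g <- group_by_overlap(calls)
  expect_equal(g[1], g[2])            # [0,100) and [99,200) share 1 bp
  # abutting intervals [0,100) and [100,200) do not overlap
  two <- as_sv_calls(data.frame(
    chrom = "chr1", start = c(0, 100), end = c(100, 200), svtype = "DEL",
    length = 100, stringsAsFactors = FALSE))
  expect_equal(length(unique(group_by_overlap(two))), 2)
  # chain A-B, B-C groups all three even when A and C are disjoint
  chain <- as_sv_calls(data.frame(
    chrom = "chr1", start = c(0, 80, 160), end = c(100, 180, 260),
    svtype = "DEL", length = 100, stringsAsFactors = FALSE))
  expect_equal(length(unique(group_by_overlap(chain))), 1)
  expect_error(group_by_overlap(sv_calls("c", 1, 1, "INS", length = 10)),
               "INS")
})

test_that("similarity edges follow the strong-RO or weak-RO rules", {
  e <- function(a, b) nrow(build_similarity_graph(rbind_svc(a, b), par))
  rbind_svc <- function(a, b) {
    out <- rbind(as.data.frame(a), as.data.frame(b))
    as_sv_calls(out)
  }
  a <- mk("chr1", 100, 200)
  expect_equal(e(a, mk("chr1", 105, 205)), 1)  # RO 0.95: strong edge
  expect_equal(e(a, mk("chr1", 95, 220)), 0)   # RO 0.8, e 25: no edge
  expect_equal(e(a, mk("chr1", 103, 205)), 1)  # RO ~0.924: strong edge
  # weak rule: RO in [0.7, 0.9) with e <= 10
  expect_equal(e(mk("chr1", 100, 130), mk("chr1", 104, 134)), 1)
})

test_that("connected components match an igraph-free BFS oracle", {
  set.seed(55)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    edges <- data.frame(i = integer(), j = integer())
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.2) edges <- rbind(edges, data.frame(i = i, j = j))
    got <- split_components(n, edges)
    # BFS oracle
    adj <- matrix(FALSE, n, n)
    if (nrow(edges)) {
      adj[cbind(edges$i, edges$j)] <- TRUE
      adj[cbind(edges$j, edges$i)] <- TRUE
    }
    comp <- rep(0L, n); cc <- 0L
    for (s in seq_len(n)) {
      if (comp[s] > 0) next
      cc <- cc + 1L; q <- s; comp[s] <- cc
      while (length(q)) {
        u <- q[1]; q <- q[-1]
        for (v in which(adj[u, ] & comp == 0)) { comp[v] <- cc; q <- c(q, v) }
      }
    }
    expect_true(same_partition(got, comp))
  }
})

test_that("complete linkage cuts at the documented height", {
  close_pair <- as_sv_calls(data.frame(
    chrom = "chr1", start = c(1000, 1005), end = c(2000, 2005),
    svtype = "DEL", length = 1000, sample_id = c("S1", "S2"),
    stringsAsFactors = FALSE))
  expect_equal(length(unique(cluster_component(close_pair, par))), 1)
  far_pair <- as_sv_calls(data.frame(
    chrom = "chr1", start = c(1000, 1150), end = c(2000, 2150),
    svtype = "DEL", length = 1000, sample_id = c("S1", "S2"),
    stringsAsFactors = FALSE))
  # d = 300/2000 = 0.15 > 0.1 (these also fail both edge rules upstream)
  expect_equal(length(unique(cluster_component(far_pair, par))), 2)
  # cut is inclusive at exactly 0.1: d = 200/2000 = 0.1 stays together
  edge_pair <- as_sv_calls(data.frame(
    chrom = "chr1", start = c(1000, 1100), end = c(2000, 2100),
    svtype = "DEL", length = 1000, sample_id = c("S1", "S2"),
    stringsAsFactors = FALSE))
  expect_equal(length(unique(cluster_component(edge_pair, par))), 1)
})

test_that("identical calls across samples form one tight cluster", {
  k <- 7
  calls <- as_sv_calls(data.frame(
    chrom = "chr1", start = 1000, end = 2000, svtype = "DEL",
    length = 1000, sample_id = sprintf("S%d", 1:k),
    stringsAsFactors = FALSE))
  cs <- cluster_all(calls, par)
  expect_equal(nrow(cs$clusters), 1)
  expect_equal(cs$clusters$n_samples, k)
  expect_equal(cs$clusters$tightness, 0)
  expect_equal(cs$clusters$allele_frequency, 1)
})

test_that("insertion clustering chains sites at most 10 bp apart", {
  ins <- sv_calls("chr1", c(100, 108, 117), c(100, 108, 117), "INS",
                  length = 30, sample_id = c("S1", "S2", "S3"))
  expect_equal(length(unique(cluster_insertions(ins, par))), 1)
  ins2 <- sv_calls("chr1", c(100, 111), c(100, 111), "INS", length = 30,
                   sample_id = c("S1", "S2"))
  expect_equal(length(unique(cluster_insertions(ins2, par))), 2)
  expect_equal(length(cluster_insertions(sv_calls()[0, ], par)), 0)
})

test_that("cluster_all conserves calls, nests partitions and respects the cutoff", {
  set.seed(66)
  pan <- simulate_panel(sim_config(seed = 66, panel_size = 10),
                        n_events = 15)
  cs <- cluster_all(pan$calls, par)
  # conservation: every call in exactly one cluster
  expect_equal(nrow(cs$members), nrow(pan$calls))
  expect_false(anyNA(cs$members$cluster_id))
  expect_equal(sum(cs$clusters$n_members), nrow(pan$calls))
  # nesting: clusters refine overlap groups
  grp <- group_by_overlap(cs$members)
  expect_true(all(tapply(grp, cs$members$cluster_id,
                         function(x) length(unique(x))) == 1))
  # complete-linkage guarantee: max pairwise d within a cluster <= 0.1
  for (cid in cs$clusters$cluster_id) {
    mem <- cs$members[cs$members$cluster_id == cid, ]
    if (nrow(mem) < 2) next
    for (i in 1:(nrow(mem) - 1)) for (j in (i + 1):nrow(mem)) {
      d <- (abs(mem$start[i] - mem$start[j]) +
              abs(mem$end[i] - mem$end[j])) /
        (mem$length[i] + mem$length[j])
      expect_lte(d, par$height_cutoff)
    }
  }
})

test_that("clustering is invariant to input permutation", {
  set.seed(77)
  pan <- simulate_panel(sim_config(seed = 77, panel_size = 8),
                        n_events = 12)
  cs1 <- cluster_all(pan$calls, par)
  perm <- sample(nrow(pan$calls))
  cs2 <- cluster_all(pan$calls[perm, ], par)
  expect_equal(cs1$clusters, cs2$clusters)
  key1 <- paste(cs1$members$sample_id, cs1$members$start, cs1$members$end)
  key2 <- paste(cs2$members$sample_id, cs2$members$start, cs2$members$end)
  expect_equal(cs1$members$cluster_id[order(key1)],
               cs2$members$cluster_id[order(key2)])
})

test_that("cluster_all agrees with the naive brute-force pipeline", {
  set.seed(88)
  for (rep in 1:30) {
    inst <- random_instance(30)
    cs <- cluster_all(inst, par)
    key <- paste(inst$chrom, inst$start, inst$end, inst$sample_id)
    mkey <- paste(cs$members$chrom, cs$members$start, cs$members$end,
                  cs$members$sample_id)
    got <- cs$members$cluster_id[match(key, mkey)]
    expect_true(same_partition(got, naive_cluster(inst)))
  }
})

test_that("representative breakpoints and tightness summarize members", {
  calls <- as_sv_calls(data.frame(
    chrom = "chr1", start = c(1000, 1002, 1004), end = c(2000, 2002, 2004),
    svtype = "DEL", length = 1000, sample_id = c("S1", "S2", "S3"),
    stringsAsFactors = FALSE))
  cs <- cluster_all(calls, par)
  expect_equal(cs$clusters$rep_start, 1002)  # median
  expect_equal(cs$clusters$rep_end, 2002)
  # mean per-side deviation: (2+2, 0+0, 2+2)/3 = 8/3; over 2*length
  expect_equal(cs$clusters$tightness, (8 / 3) / 2000)
})
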