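toy_clusters <- function(df) {
  calls <- as_sv_calls(df)
  cluster_all(calls, cluster_params())
}

test_that("TE classification distinguishes strict, associated and none", {
  cs <- toy_clusters(data.frame(
    chrom = "chr1", start = c(0, 5000, 20000), end = c(1000, 6000, 21000),
    svtype = "DEL", length = 1000, stringsAsFactors = FALSE))
  te <- data.frame(chrom = "chr1",
                   start = c(50, 5000, 5400), end = c(950, 5300, 5600),
                   name = c("t1", "t2", "t3"),
                   class = c("DTT", "RLG", "DTH"),
                   stringsAsFactors = FALSE)
  res <- classify_te_overlap(cs, te)
  res <- res[order(res$cluster_id), ]
  # [0,1000) vs TE [50,950): RO = min(0.9, 1.0) = 0.9 >= 0.8
  expect_equal(res$te_status[1], "strict_te")
  expect_equal(res$best_class[1], "DTT")
  # [5000,6000): union cover = 300+200 = 500 = 50% but best RO 0.3
  expect_equal(res$te_status[2], "repeat_associated")
  expect_equal(res$te_status[3], "none")
  # strict implies the associated criterion also holds (nesting)
  expect_gte(res$union_cover[1], 0.5)
  # empty track
  res0 <- classify_te_overlap(cs, te[0, ])
  expect_true(all(res0$te_status == "none"))
})

test_that("feature assignment follows the severity precedence", {
  models <- read_gff_genes(toy_gff(tempfile(fileext = ".gff3")))
  # gA (+): span [1000,2600), 5'UTR [1000,1200), CDS [1200,1500)+[1650,1950)
  cs <- toy_clusters(data.frame(
    chrom = "chr1",
    start = c(1250, 1450, 1020, 520, 50000),
    end = c(1300, 1700, 1080, 580, 50100),
    svtype = "DEL", stringsAsFactors = FALSE,
    length = c(50, 250, 60, 60, 100)))
  res <- assign_feature(cs, models)
  res <- res[order(cs$clusters$rep_start), ]
  got <- stats::setNames(res$feature, cs$clusters$rep_start)
  expect_equal(unname(got[as.character(520)]), "promoter")
  expect_equal(unname(got[as.character(1020)]), "five_prime_UTR")
  expect_equal(unname(got[as.character(1250)]), "CDS")
  expect_equal(unname(got[as.character(1450)]), "CDS")  # spans CDS+intron
  expect_equal(unname(got[as.character(50000)]), "intergenic")
  # every cluster gets exactly one label
  expect_equal(nrow(res), nrow(cs$clusters))
})

test_that("promoters are strand-aware", {
  models <- read_gff_genes(toy_gff(tempfile(fileext = ".gff3")))
  # gB is minus-strand with tss = 10599; 300 bp upstream = higher coords
  cs <- toy_clusters(data.frame(
    chrom = "chr1", start = 10850, end = 10950, svtype = "DEL",
    length = 100, stringsAsFactors = FALSE))
  res <- assign_feature(cs, models)
  expect_equal(res$feature, "promoter")
  expect_equal(res$gene_id, "gB")
})

test_that("TSS profiles cover exactly the deleted offsets", {
  gm <- gene_models(
    data.frame(gene_id = "g1", chrom = "chr1", strand = "+", start = 5000,
               end = 6600, tss = 5000, stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", type = "CDS", start = 5200, end = 5500,
               stringsAsFactors = FALSE))
  svp <- sv_calls("chr1", 5005, 5015, "DEL")
  tp <- tss_profile(svp, gm, half_window = 50)
  expect_equal(tp$short_frac[tp$pos %in% 5:14], rep(1, 10))
  expect_equal(sum(tp$short_frac), 10)
  expect_equal(sum(tp$long_frac), 0)
  # no SVs: all-zero profile
  tp0 <- tss_profile(sv_calls(), gm, half_window = 50)
  expect_equal(sum(tp0$short_count) + sum(tp0$long_count), 0)
  # minus-strand gene: upstream offsets map to higher coordinates
  gm2 <- gene_models(
    data.frame(gene_id = "g2", chrom = "chr1", strand = "-", start = 5000,
               end = 6600, tss = 6599, stringsAsFactors = FALSE),
    data.frame(gene_id = "g2", type = "CDS", start = 5200, end = 5500,
               stringsAsFactors = FALSE))
  sv2 <- sv_calls("chr1", 6620, 6630, "DEL")  # genomic downstream = upstream
  tp2 <- tss_profile(sv2, gm2, half_window = 50)
  expect_equal(which(tp2$short_frac > 0),
               which(tp2$pos %in% -30:-21))
})

test_that("uniformly placed SVs give a flat TSS profile", {
  cfg <- sim_config(seed = 51)
  ann <- simulate_annotations(cfg, n_genes = 300, n_te = 0)
  tp <- tss_profile(ann$sv_calls, ann$genes, half_window = 450)
  cover <- tp$short_frac + tp$long_frac
  # interior positions have near-constant expected coverage; allow binomial
  # noise around the mean
  interior <- cover[abs(tp$pos) <= 300]
  p_hat <- mean(interior)
  expect_lt(max(abs(interior - p_hat)), 5 * sqrt(p_hat * (1 - p_hat) / 300))
})

test_that("deleted genes require full CDS union coverage", {
  gm <- gene_models(
    data.frame(gene_id = "g1", chrom = "chr1", strand = "+", start = 50,
               end = 600, tss = 50, stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", type = "CDS", start = 100, end = 400,
               stringsAsFactors = FALSE))
  run <- function(dels, samples) {
    calls <- as_sv_calls(data.frame(
      chrom = "chr1", start = dels$start, end = dels$end, svtype = "DEL",
      length = dels$end - dels$start, sample_id = samples,
      stringsAsFactors = FALSE))
    cs <- cluster_all(calls, cluster_params(), panel = c("sA", "sB"))
    deleted_genes(cs, gm)
  }
  # single spanning deletion
  r1 <- run(data.frame(start = 50, end = 500), "sA")
  expect_equal(r1$per_sample$sA, "g1")
  expect_equal(r1$per_sample$sB, character(0))
  # two abutting deletions whose union covers the CDS
  r2 <- run(data.frame(start = c(50, 240), end = c(250, 500)),
            c("sA", "sA"))
  expect_equal(r2$per_sample$sA, "g1")
  # 99% coverage is not deletion
  r3 <- run(data.frame(start = 103, end = 500), "sA")
  expect_equal(r3$per_sample$sA, character(0))
})

test_that("deleted-gene sets are monotone in added deletions and group-aware", {
  gm <- gene_models(
    data.frame(gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
               start = c(50, 1050), end = c(600, 1600), tss = c(50, 1050),
               stringsAsFactors = FALSE),
    data.frame(gene_id = c("g1", "g2"), type = "CDS",
               start = c(100, 1100), end = c(400, 1400),
               stringsAsFactors = FALSE))
  mkcs <- function(df) cluster_all(as_sv_calls(df), cluster_params(),
                                   panel = c("sA", "sB", "sC"))
  base <- data.frame(chrom = "chr1", start = 50, end = 500,
                     svtype = "DEL", length = 450, sample_id = "sA",
                     stringsAsFactors = FALSE)
  more <- rbind(base, data.frame(chrom = "chr1", start = 1050, end = 1500,
                                 svtype = "DEL", length = 450,
                                 sample_id = "sA",
                                 stringsAsFactors = FALSE))
  d1 <- deleted_genes(mkcs(base), gm)
  d2 <- deleted_genes(mkcs(more), gm)
  expect_true(all(d1$per_sample$sA %in% d2$per_sample$sA))
  grp <- c(sA = "Indica", sB = "Japonica", sC = "Indica")
  d3 <- deleted_genes(mkcs(more), gm, groups = grp, min_group_freq = 1)
  expect_equal(sort(d3$per_group$Indica), c("g1", "g2"))
  expect_equal(d3$per_group$Japonica, character(0))
  expect_true(all(d3$sharing$groups == "Indica"))
})

test_that("genes without CDS are excluded with a warning", {
  gm <- gene_models(
    data.frame(gene_id = c("g1", "nocds"), chrom = "chr1", strand = "+",
               start = c(50, 2000), end = c(600, 2500), tss = c(50, 2000),
               stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", type = "CDS", start = 100, end = 400,
               stringsAsFactors = FALSE))
  calls <- as_sv_calls(data.frame(
    chrom = "chr1", start = 50, end = 500, svtype = "DEL", length = 450,
    sample_id = "sA", stringsAsFactors = FALSE))
  cs <- cluster_all(calls, cluster_params())
  expect_warning(deleted_genes(cs, gm), "without CDS")
})

test_that("density windows count starts, flag 2x-mean, and correlate", {
  # hand-built example: 11 variants over one 350-kb chromosome
  # windows (100 kb / 50 kb): starts 0,50k,100k,150k,200k,250k
  pos <- c(10e3, 60e3, 110e3, 160e3, 210e3, rep(260e3, 6))
  a <- data.frame(chrom = "chr1", start = pos)
  dw <- density_windows(a, a, chrom_lengths = c(chr1 = 350e3))
  expect_equal(dw$correlation, 1.0)
  counts <- dw$windows$count
  expect_equal(sum(counts), sum(vapply(pos, function(p)
    sum(p >= dw$windows$start & p < dw$windows$end), 0)))
  expect_true(any(dw$windows$flagged))
  expect_true(all(dw$windows$count[dw$windows$flagged] >=
                    2 * dw$mean_count))
  # all-equal counts: nothing flagged
  b <- data.frame(chrom = "chr1", start = c(10e3, 60e3, 110e3, 160e3,
                                            210e3, 260e3, 310e3))
  dwb <- density_windows(b, chrom_lengths = c(chr1 = 350e3))
  expect_false(any(dwb$windows$flagged))
  # chromosome shorter than the window: one truncated window
  tiny <- density_windows(data.frame(chrom = "c", start = 5),
                          chrom_lengths = c(c = 40e3))
  expect_equal(nrow(tiny$windows), 1)
  expect_equal(tiny$windows$end, 40e3)
})
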