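test_that("the matching criterion follows the documented error rule", {
  crit <- match_criteria()
  p <- mk("chr1", 100, 200)
  # RO = 0.95 but e = 10 is not < 10 (strict): reject
  expect_false(is_match(p, mk("chr1", 105, 205), crit))
  # RO = 0.96, e = 8: accept
  expect_true(is_match(p, mk("chr1", 104, 204), crit))
  # DUP: RO 0.8 >= 0.7, breakpoint error ignored
  expect_true(is_match(mk("chr1", 0, 1000, "DUP"),
                       mk("chr1", 200, 1200, "DUP"), crit))
  # same intervals as DEL would fail (RO 0.8 < 0.9)
  expect_false(is_match(mk("chr1", 0, 1000), mk("chr1", 200, 1200), crit))
  # type mismatch is FALSE, not an error
  expect_false(is_match(p, mk("chr1", 100, 200, "INV"), crit))
})

test_that("small events get the relative error cap; the or-variant relaxes it", {
  # combined length 60: min rule caps e at 6
  a <- sv_calls("chr1", 100, 130, "DEL", min_sv_len = 10)
  b <- sv_calls("chr1", 104, 134, "DEL", min_sv_len = 10)  # e = 8, RO ~0.87
  c2 <- sv_calls("chr1", 102, 132, "DEL", min_sv_len = 10) # e = 4, RO ~0.93
  expect_false(is_match(a, b, match_criteria()))
  expect_true(is_match(a, c2, match_criteria()))
  # plain OR lets large events through on the 10% leg
  big_p <- mk("chr1", 0, 10000)
  big_s <- mk("chr1", 400, 10400)  # RO 0.96, e = 800 < 0.1*20000
  expect_false(is_match(big_p, big_s, match_criteria()))
  expect_true(is_match(big_p, big_s, match_criteria(error_rule = "or")))
})

test_that("insertions match by site distance", {
  crit <- match_criteria()
  i1 <- sv_calls("chr1", 100, 100, "INS", length = 50)
  expect_true(is_match(i1, sv_calls("chr1", 110, 110, "INS", length = 48),
                       crit))
  expect_false(is_match(i1, sv_calls("chr1", 111, 111, "INS", length = 50),
                        crit))
})

test_that("greedy matching is one-to-one and picks the best candidate", {
  truth <- mk("chr1", 1000, 2000)
  # two predictions both pass; only the higher-RO one becomes the TP
  pred <- as_sv_calls(data.frame(
    chrom = "chr1", start = c(1001, 1004), end = c(2001, 2004),
    svtype = "DEL", length = 1000, stringsAsFactors = FALSE))
  m <- match_callsets(pred, truth)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$pred_idx, 1)  # RO higher for the closer call
  expect_equal(m$unmatched_pred, 2)
  # brute force over all one-to-one assignments confirms max cardinality
  expect_equal(length(m$unmatched_truth), 0)
})

test_that("greedy matching reaches maximum cardinality on small instances", {
  set.seed(33)
  for (rep in 1:40) {
    n_t <- sample(2:5, 1); n_p <- sample(2:8, 1)
    ts <- cumsum(sample(300:600, n_t))
    truth <- as_sv_calls(data.frame(
      chrom = "chr1", start = ts, end = ts + 200, svtype = "DEL",
      length = 200, stringsAsFactors = FALSE))
    pick <- sample(n_t, n_p, replace = TRUE)
    ps <- ts[pick] + sample(-2:2, n_p, replace = TRUE)
    pred <- as_sv_calls(data.frame(
      chrom = "chr1", start = ps, end = ps + 200, svtype = "DEL",
      length = 200, stringsAsFactors = FALSE))
    m <- match_callsets(pred, truth)
    # exhaustive maximum bipartite matching by recursion
    ok <- outer(seq_len(n_p), seq_len(n_t), function(i, j)
      is_match(pred[i, ], truth[j, ]))
    best <- function(av_t, i) {
      if (i > n_p) return(0L)
      res <- best(av_t, i + 1L)
      for (j in which(av_t & ok[i, ]))
        res <- max(res, 1L + best(replace(av_t, j, FALSE), i + 1L))
      res
    }
    expect_equal(nrow(m$pairs), best(rep(TRUE, n_t), 1L))
  }
})

test_that("matching is invariant to input order", {
  set.seed(44)
  ts <- cumsum(sample(300:600, 6))
  te <- ts + sample(100:300, 6)
  truth <- as_sv_calls(data.frame(
    chrom = "chr1", start = ts, end = te, svtype = "DEL",
    length = te - ts, stringsAsFactors = FALSE))
  pred <- truth
  pred$start <- pred$start + sample(-3:3, 6, replace = TRUE)
  pred$end <- pred$end + sample(-3:3, 6, replace = TRUE)
  pred$length <- pred$end - pred$start
  m1 <- match_callsets(pred, truth)
  perm <- sample(6)
  m2 <- match_callsets(pred[perm, ], truth)
  got1 <- m1$pairs[order(m1$pairs$truth_idx), c("truth_idx", "ro")]
  got2 <- m2$pairs[order(m2$pairs$truth_idx), c("truth_idx", "ro")]
  expect_equal(got1$truth_idx, got2$truth_idx)
  expect_equal(got1$ro, got2$ro)
})

test_that("evaluation tallies TP/FP/FN per type and bin", {
  truth <- as_sv_calls(data.frame(
    chrom = "chr1", start = c(1000, 5000), end = c(1100, 5800),
    svtype = "DEL", length = c(100, 800), stringsAsFactors = FALSE))
  # perfect call for the first, nothing for the second, plus one FP
  pred <- as_sv_calls(data.frame(
    chrom = "chr1", start = c(1000, 9000), end = c(1100, 9100),
    svtype = "DEL", length = 100, stringsAsFactors = FALSE))
  res <- evaluate_callset(pred, truth)
  a <- res[res$bin == "A", ]
  expect_equal(c(a$tp, a$fp, a$fn), c(1, 1, 0))
  expect_equal(a$sensitivity, 1)
  expect_equal(a$precision, 0.5)
  c_ <- res[res$bin == "C", ]
  expect_equal(c(c_$tp, c_$fn), c(0, 1))
  expect_equal(c_$sensitivity, 0)
  expect_true(is.na(c_$precision))  # no predictions in C: undefined, not 0
})

test_that("an FP-only callset yields zero sensitivity and precision", {
  truth <- mk("chr1", 1000, 1100)
  pred <- mk("chr1", 50000, 50100)
  res <- evaluate_callset(pred, truth)
  expect_equal(sum(res$tp), 0)
  expect_equal(res$sensitivity[!is.na(res$sensitivity)], 0)
  expect_equal(res$precision[!is.na(res$precision)], 0)
})

test_that("sensitivity and precision degrade with increasing jitter", {
  sens_at <- function(jit) {
    mean(vapply(1:5, function(s) {
      cfg <- sim_config(seed = s, truth_counts = c(A = 150), fn_rate = 0,
                        fp_rate = 0, jitter_sd = jit)
      tr <- simulate_truth_set(cfg)
      r <- evaluate_callset(emulate_caller(tr, cfg), tr)
      r$sensitivity[r$bin == "A"]
    }, 0))
  }
  s <- c(sens_at(0), sens_at(4), sens_at(40))
  expect_equal(s[1], 1)
  expect_true(s[1] > s[2] && s[2] > s[3])
})
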