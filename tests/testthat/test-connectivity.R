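test_that("KS tag score matches hand-derived examples", {
  # values computed with the brute-force oracle in helper-oracles.R
  r1 <- ks_tag_score(c(1, 2), 10)
  expect_equal(r1$a, 0.8)
  expect_equal(r1$b, 0.1)
  expect_equal(r1$es, 0.8)
  expect_equal(r1$es, brute_ks(c(1, 2), 10))

  r2 <- ks_tag_score(c(9, 10), 10)
  expect_equal(r2$a, 0.0)
  expect_equal(r2$b, 0.9)
  expect_equal(r2$es, -0.9)
  expect_equal(r2$es, brute_ks(c(9, 10), 10))
})

test_that("KS tag score equals brute force on random cases", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(3:50, 1)
    t <- sample(seq_len(n - 1), 1)
    v <- sort(sample.int(n, t))
    expect_identical(ks_tag_score(v, n)$es, brute_ks(v, n))
  }
})

test_that("closed forms hold for tags packed at either extreme", {
  for (n in c(10, 50, 200, 1000)) {
    for (t in c(1, 2, 5, n %/% 4)) {
      if (n <= t + 1) next
      expect_equal(ks_tag_score(seq_len(t), n)$es, 1 - t / n)
      expect_equal(ks_tag_score(seq.int(n - t + 1, n), n)$es,
                   -(1 - (t - 1) / n))
    }
  }
})

test_that("degenerate tag sets are rejected", {
  expect_error(ks_tag_score(integer(0), 10))
  expect_error(ks_tag_score(1:10, 10))       # t = n
  expect_error(ks_tag_score(c(2, 1), 10))    # not increasing
  expect_error(ks_tag_score(c(0, 5), 10))    # out of range
})

test_that("raw combination follows the sign rule", {
  expect_equal(stemscreen:::combine_raw(0.8, -0.9), 1.7)
  expect_equal(stemscreen:::combine_raw(0.5, 0.4), 0)
  expect_equal(stemscreen:::combine_raw(-0.5, -0.4), 0)

  # an exact-inverse signature scores negative on its instance
  n <- 100
  column <- setNames(seq_len(n), sprintf("p%03d", seq_len(n)))
  sig <- gene_signature("inv", up_tags = names(column)[91:100],
                        down_tags = names(column)[1:10])
  r <- instance_connectivity(sig, column)
  expect_lt(r$raw, 0)
  # and within [-2, 2]
  expect_gte(r$raw, -2)
})

test_that("swapping up and down tags negates the raw score", {
  set.seed(5)
  ids <- sprintf("p%03d", 1:80)
  for (i in 1:20) {
    column <- setNames(sample.int(80), ids)
    sig <- make_random_sig(ids, 8, 8, seed = i)
    swapped <- gene_signature("sw", sig$down_tags, sig$up_tags)
    expect_equal(instance_connectivity(swapped, column)$raw,
                 -instance_connectivity(sig, column)$raw)
  }
})

test_that("consistent probe relabeling leaves all scores unchanged", {
  rm <- make_random_rm(60, c("a", "b"), instances_each = 2, seed = 9)
  sig <- make_random_sig(rm$probe_ids, 6, 6, seed = 2)
  res1 <- compound_summary(rm, sig, n_perm = 100, seed = 4)

  relabel <- setNames(sprintf("q%04d", seq_along(rm$probe_ids)), rm$probe_ids)
  m2 <- rm$ranks
  rownames(m2) <- relabel[rownames(m2)]
  rm2 <- rank_matrix(m2, rm$meta)
  sig2 <- gene_signature(sig$name, relabel[sig$up_tags], relabel[sig$down_tags])
  res2 <- compound_summary(rm2, sig2, n_perm = 100, seed = 4)
  expect_equal(res1$mean_es, res2$mean_es)
  expect_equal(res1$p, res2$p)
})

test_that("scale_scores maps raws onto [-1, 1] with the extremes attained", {
  expect_equal(scale_scores(c(1.7, 0.85, -0.5)), c(1.0, 0.5, -1.0))
  expect_equal(scale_scores(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(scale_scores(-0.3), -1.0)
  set.seed(3)
  raw <- rnorm(50)
  s <- scale_scores(raw)
  expect_true(all(s >= -1 & s <= 1))
  expect_true(any(abs(s) == 1))
  expect_identical(s == 0, raw == 0)
})

test_that("missing signature tags are dropped with a warning, heavy loss errors", {
  rm <- make_random_rm(60, "a", instances_each = 1, seed = 2)
  sig <- gene_signature("s", c(rm$probe_ids[1:5], "absent1"),
                        rm$probe_ids[6:10])
  expect_warning(res <- compound_summary(rm, sig, n_perm = 100, seed = 1),
                 "absent from the rank matrix")
  expect_equal(nrow(res), 1L)

  mostly_missing <- gene_signature("s", c(rm$probe_ids[1], paste0("x", 1:9)),
                                   rm$probe_ids[6:10])
  expect_error(suppressWarnings(
    compound_summary(rm, mostly_missing, n_perm = 100, seed = 1)), "25%")
})

test_that("compound mean is the arithmetic mean of scaled instance scores", {
  rm <- make_random_rm(80, c("a", "b", "c"), instances_each = 3, seed = 6)
  sig <- make_random_sig(rm$probe_ids, 8, 8, seed = 1)
  q <- query_connectivity(rm, sig, n_perm = 100, seed = 2)
  by_hand <- tapply(q$instances$scaled, q$instances$compound, mean)
  expect_equal(q$compounds$mean_es, as.numeric(by_hand[q$compounds$compound]))
  expect_true(all(q$compounds$mean_es >= -1 & q$compounds$mean_es <= 1))
  expect_true(all(q$compounds$p > 0 & q$compounds$p <= 1))
})

test_that("a perfect planted inversion attains the minimum permutation p", {
  sim <- default_insilico_experiment(seed = 8, n_probes = 1000,
                                     n_compounds = 20, n_planted = 1,
                                     tag_size = 100, strength = 1)
  # on raw (unscaled) scores no random tag set can reach the attainable
  # extreme for these tag sizes, so the permutation p is its minimum
  res <- compound_summary(sim$rank_matrix, sim$lsc_signature,
                          n_perm = 200, seed = 8, scaled = FALSE)
  planted <- sim$manifest$compounds$compound[sim$manifest$compounds$planted]
  expect_equal(res$p[res$compound == planted], 1 / 201)
  expect_lt(res$mean_es[res$compound == planted], -1.79)
})

test_that("permutation p-values are reproducible under a fixed seed", {
  rm <- make_random_rm(60, c("a", "b"), instances_each = 2, seed = 12)
  sig <- make_random_sig(rm$probe_ids, 6, 6, seed = 3)
  r1 <- compound_summary(rm, sig, n_perm = 150, seed = 99)
  r2 <- compound_summary(rm, sig, n_perm = 150, seed = 99)
  expect_identical(r1, r2)
})

test_that("rank matrix construction rejects non-permutation columns", {
  ids <- sprintf("p%02d", 1:10)
  good <- matrix(c(sample(10), sample(10)), ncol = 2,
                 dimnames = list(ids, c("i1", "i2")))
  meta <- data.frame(instance_id = c("i1", "i2"), compound = c("a", "b"))
  expect_s3_class(rank_matrix(good, meta), "rank_matrix")
  bad <- good
  bad[1, 1] <- bad[2, 1]
  expect_error(rank_matrix(bad, meta), "permutation")
})

test_that("rank matrix TSV round-trip is lossless", {
  rm <- make_random_rm(25, c("a", "b"), instances_each = 2, seed = 4)
  mp <- withr::local_tempfile(fileext = ".tsv")
  me <- withr::local_tempfile(fileext = ".tsv")
  write_rank_matrix(rm, mp, me)
  back <- read_rank_matrix(mp, me)
  expect_equal(back$ranks, rm$ranks)
  expect_equal(back$meta$compound, rm$meta$compound)
})
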