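test_that("top-k signature takes the k largest and k smallest statistics", {
  de <- make_de(c(5, 4, 3, -3, -4, -5))
  sig <- build_top_k_signature(de, k = 2)
  expect_setequal(sig$up_tags, de$feature_id[de$stat %in% c(5, 4)])
  expect_setequal(sig$down_tags, de$feature_id[de$stat %in% c(-5, -4)])

  # k = |de|/2 partitions all features and stays disjoint
  sig_half <- build_top_k_signature(de, k = 3)
  expect_setequal(c(sig_half$up_tags, sig_half$down_tags), de$feature_id)
  expect_length(intersect(sig_half$up_tags, sig_half$down_tags), 0)
})

test_that("top-k boundary ties are resolved deterministically with a warning", {
  de <- make_de(c(2, 1, 1, -1, -1, -2), p = c(.01, .5, .2, .2, .5, .01))
  expect_warning(sig1 <- build_top_k_signature(de, k = 2), "ties")
  expect_warning(sig2 <- build_top_k_signature(de, k = 2), "ties")
  expect_identical(sig1$up_tags, sig2$up_tags)
  # tie broken by smaller p
  expect_true("f03" %in% sig1$up_tags && !"f02" %in% sig1$up_tags)

  # all-equal stats, k = 1: deterministic pick by feature_id order
  de_eq <- make_de(c(1, 1, 1, 1))
  expect_warning(s <- build_top_k_signature(de_eq, k = 1), "ties")
  expect_identical(s$up_tags, "f01")
  expect_identical(s$down_tags, "f02")
})

test_that("top-k signature refuses undersized tables", {
  expect_error(build_top_k_signature(make_de(c(1, -1)), k = 2), "2k")
})

test_that("p-threshold signature filters by sign and significance", {
  de <- make_de(c(1, 1, -1), p = c(0.01, 0.2, 0.04))
  sig <- build_p_threshold_signature(de, alpha = 0.05)
  expect_identical(sig$up_tags, "f01")
  expect_identical(sig$down_tags, "f03")

  # alpha -> 1 includes every non-zero-stat feature
  sig_all <- build_p_threshold_signature(de, alpha = 1 - 1e-9)
  expect_setequal(c(sig_all$up_tags, sig_all$down_tags), de$feature_id)

  # an empty side is an error naming the side
  de_up_only <- make_de(c(1, 2, -1), p = c(0.01, 0.01, 0.9))
  expect_error(build_p_threshold_signature(de_up_only, 0.05), "down")
})

test_that("p-threshold signatures are monotone in alpha", {
  set.seed(7)
  de <- make_de(stat = rnorm(200), p = runif(200))
  for (pair in list(c(0.05, 0.2), c(0.2, 0.5), c(0.5, 0.9))) {
    s1 <- build_p_threshold_signature(de, pair[1])
    s2 <- build_p_threshold_signature(de, pair[2])
    expect_true(all(s1$up_tags %in% s2$up_tags))
    expect_true(all(s1$down_tags %in% s2$down_tags))
  }
})

test_that("gene-to-probe conversion expands 1:many and reports problems", {
  sig <- gene_signature("g", "G1", "G2")
  out <- genes_to_probes(sig, list(G1 = c("p1", "p2"), G2 = "p3"))
  expect_setequal(out$up_tags, c("p1", "p2"))
  expect_identical(out$down_tags, "p3")

  # probe reached from both sides is dropped from both, with warning
  sig2 <- gene_signature("g", c("G1", "G3"), "G2")
  expect_warning(
    out2 <- genes_to_probes(sig2, list(G1 = "p1", G2 = c("p1", "p2"), G3 = "p4")),
    "both sides")
  expect_false("p1" %in% c(out2$up_tags, out2$down_tags))
  expect_identical(out2$down_tags, "p2")

  # unmapped genes are reported; >50% unmapped is a hard error
  expect_warning(
    out3 <- genes_to_probes(gene_signature("g", c("G1", "GX"), "G2"),
                            list(G1 = "p1", G2 = "p2", G3 = "p3")),
    "no probe mapping")
  expect_identical(attr(out3, "n_unmapped_up"), 1L)
  expect_error(
    suppressWarnings(genes_to_probes(gene_signature("g", c("GX", "GY"), "G2"),
                                     list(G2 = "p2"))),
    "misconfigured")
})

test_that("GRP round-trip reproduces identical tag sets", {
  sig <- make_random_sig(sprintf("p%03d", 1:50), 10, 12, seed = 3, name = "rt")
  dir <- withr::local_tempdir()
  paths <- write_signature_grp(sig, dir)
  back <- read_signature_grp(paths["up"], paths["down"])
  expect_identical(back$up_tags, sig$up_tags)
  expect_identical(back$down_tags, sig$down_tags)
  expect_identical(back$name, "rt")
})

test_that("GMT round-trip reproduces the collection", {
  sets <- list(alpha = c("a", "b", "c"), beta = c("x", "y"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_identical(read_gmt(path), sets)
})

test_that("DE table validation catches malformed input", {
  expect_error(validate_de_table(make_de(c(1, NA))), "finite")
  expect_error(validate_de_table(make_de(c(1, 2), p = c(0.5, 1.5))), "p must")
  bad <- make_de(c(1, 2)); bad$feature_id <- c("a", "a")
  expect_error(validate_de_table(bad), "unique")
})
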