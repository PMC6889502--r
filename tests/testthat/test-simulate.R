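test_that("simulated rank matrices are reproducible and valid permutations", {
  sig <- gene_signature("s", sprintf("probe_%04d", 1:10),
                        sprintf("probe_%04d", 11:20))
  sim1 <- simulate_rank_matrix(100, c(a = 2, b = 1), sig,
                               effects = list(planted_effect("a", 0.7)),
                               seed = 5)
  sim2 <- simulate_rank_matrix(100, c(a = 2, b = 1), sig,
                               effects = list(planted_effect("a", 0.7)),
                               seed = 5)
  expect_identical(sim1$rank_matrix$ranks, sim2$rank_matrix$ranks)
  n <- nrow(sim1$rank_matrix$ranks)
  expect_true(all(apply(sim1$rank_matrix$ranks, 2,
                        function(col) identical(sort(unname(col)), seq_len(n)))))
  expect_identical(sim1$manifest$compounds$planted, c(TRUE, FALSE))
})

test_that("per-compound substreams regenerate a compound independently", {
  sig <- gene_signature("s", sprintf("probe_%04d", 1:10),
                        sprintf("probe_%04d", 11:20))
  full <- simulate_rank_matrix(100, c(a = 2, b = 2), sig, seed = 9)
  # regenerating with an extra later compound leaves earlier columns intact
  wider <- simulate_rank_matrix(100, c(a = 2, b = 2, c = 1), sig, seed = 9)
  expect_identical(full$rank_matrix$ranks[, "a.1"],
                   wider$rank_matrix$ranks[, "a.1"])
  expect_identical(full$rank_matrix$ranks[, "b.2"],
                   wider$rank_matrix$ranks[, "b.2"])
})

test_that("a strength-1 inversion attains the extreme raw score", {
  n <- 1000
  t <- 100
  sim <- default_insilico_experiment(seed = 3, n_probes = n, n_compounds = 5,
                                     n_planted = 1, tag_size = t,
                                     strength = 1,
                                     instances_per_compound = 1)
  col <- setNames(sim$rank_matrix$ranks[, 1], sim$rank_matrix$probe_ids)
  raw <- instance_connectivity(sim$lsc_signature, col)$raw
  min_attainable <- -((1 - (t - 1) / n) + (1 - t / n))
  expect_lt(abs(raw - min_attainable), 0.05)
})

test_that("planted effect strength moves the mean score monotonically", {
  # averaged over seeds, stronger planting never weakens |mean_es|
  strengths <- c(0.1, 0.4, 0.8)
  mean_abs <- sapply(strengths, function(s) {
    vals <- sapply(1:20, function(seed) {
      sim <- default_insilico_experiment(seed = seed, n_probes = 200,
                                         n_compounds = 2, n_planted = 1,
                                         tag_size = 20, strength = s,
                                         instances_per_compound = 2)
      res <- suppressWarnings(
        query_connectivity(sim$rank_matrix, sim$lsc_signature,
                           n_perm = 100, seed = seed))
      abs(res$compounds$mean_es[res$compounds$compound == "cmpd_001"])
    })
    mean(vals)
  })
  expect_true(all(diff(mean_abs) >= 0))
})

test_that("strength-0 effects are indistinguishable from nulls", {
  sig <- gene_signature("s", sprintf("probe_%04d", 1:10),
                        sprintf("probe_%04d", 11:20))
  sim <- simulate_rank_matrix(100, c(a = 2), sig,
                              effects = list(planted_effect("a", 0)), seed = 4)
  null <- simulate_rank_matrix(100, c(a = 2), sig, seed = 4)
  expect_identical(sim$rank_matrix$ranks, null$rank_matrix$ranks)
})

test_that("oversized tag sets are rejected by the generator", {
  sig <- gene_signature("s", sprintf("probe_%04d", 1:40),
                        sprintf("probe_%04d", 41:80))
  expect_error(simulate_rank_matrix(75, c(a = 1), sig, seed = 1),
               "universe")
})

test_that("noiseless screen simulation reproduces the 4PL curve exactly", {
  design <- data.frame(compound = "d1", population = c("bulk", "CD15+"),
                       top = 1, bottom = 0, hill = 2, lc50 = 5,
                       stringsAsFactors = FALSE)
  sim <- simulate_screen(design, noise_sd = 0, seed = 1,
                         lsc_population = "bulk", blast_population = "CD15+")
  rel <- normalize_to_control(sim$screen_table)
  expected <- 1 / (1 + (rel$dose / 5)^2)
  expect_equal(rel$rel_viability, expected, tolerance = 1e-12)
})

test_that("forced screen outcomes are recovered from the simulated counts", {
  pops <- c("bulk", "CD34+CD38-", "CD34+CD38+", "CD15+")
  design <- rbind(
    data.frame(compound = "panToxic", population = pops, top = 1, bottom = 0,
               hill = 2, lc50 = 0.5),   # lc50 far below the lowest dose
    data.frame(compound = "lscOnly", population = pops, top = 1, bottom = 0,
               hill = 2, lc50 = ifelse(pops == "CD34+CD38-", 0.5, 500)))
  sim <- simulate_screen(design, noise_sd = 0.02, seed = 11)
  calls <- call_hits(normalize_to_control(sim$screen_table))
  cats <- categorize_compounds(calls, "CD34+CD38-", "CD15+")
  expect_identical(cats$category[cats$compound == "panToxic"], "1")
  expect_identical(cats$category[cats$compound == "lscOnly"], "2")
  expect_identical(sim$manifest$true_categories$category,
                   cats$category[match(sim$manifest$true_categories$compound,
                                       cats$compound)])
})

test_that("the default screen design encodes the intended true patterns", {
  design <- default_screen_design(seed = 2)
  expect_identical(length(unique(design$compound)), 84L)
  tab <- table(unique(design[, c("compound", "true_pattern")])$true_pattern)
  expect_identical(as.integer(tab[c("cat1", "cat2", "cat3", "inactive")]),
                   c(30L, 15L, 3L, 36L))
  sim <- simulate_screen(design, noise_sd = 0, seed = 2)
  truth <- merge(sim$manifest$true_categories,
                 unique(design[, c("compound", "true_pattern")]))
  map <- c(cat1 = "1", cat2 = "2", cat3 = "3", inactive = "none")
  expect_identical(truth$category, unname(map[truth$true_pattern]))
})
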