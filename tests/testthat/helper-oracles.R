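# independent oracles and small fixture builders used across test files

# brute-force KS tag statistic: literal evaluation of both maxima over all j
brute_ks <- function(positions, n) {
  t <- length(positions)
  a <- max(vapply(seq_len(t), function(j) j / t - positions[j] / n, numeric(1)))
  b <- max(vapply(seq_len(t), function(j) positions[j] / n - (j - 1) / t,
                  numeric(1)))
  if (a > b) a else -b
}

# a tiny DE table with controllable stats/p
make_de <- function(stat, p = NULL, ids = NULL) {
  n <- length(stat)
  data.frame(feature_id = ids %||% sprintf("f%02d", seq_len(n)),
             stat = stat,
             p = p %||% rep(0.01, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small random rank matrix with given compounds (all-null instances)
make_random_rm <- function(n_probes, compounds, instances_each = 2, seed = 1) {
  set.seed(seed)
  ids <- sprintf("p%04d", seq_len(n_probes))
  cols <- list()
  meta <- list()
  for (cp in compounds) {
    for (k in seq_len(instances_each)) {
      id <- paste0(cp, ".", k)
      cols[[id]] <- sample.int(n_probes)
      meta[[id]] <- data.frame(instance_id = id, compound = cp,
                               stringsAsFactors = FALSE)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- ids
  rank_matrix(m, do.call(rbind, meta))
}

# random disjoint signature over a probe universe
make_random_sig <- function(probe_ids, t_up, t_down, seed = 1, name = "sig") {
  set.seed(seed)
  pick <- sample(probe_ids, t_up + t_down)
  gene_signature(name, pick[seq_len(t_up)], pick[t_up + seq_len(t_down)])
}

# fabricate a compound_summary-style table directly
make_conn <- function(compound, mean_es, p) {
  data.frame(compound = compound, n_instances = 3L,
             mean_es = mean_es, p = p, stringsAsFactors = FALSE)
}
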