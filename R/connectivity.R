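#' Kolmogorov-Smirnov tag-set enrichment score
#'
#' The unweighted build-02-style tag statistic. Given the sorted ranks
#' `V(1..t)` of a tag set within a ranked list of `n` probes (rank 1 = most
#' up-regulated), it computes
#' \deqn{a = \max_j ( j/t - V_j/n ), \quad b = \max_j ( V_j/n - (j-1)/t )}
#' and returns `es = a` if `a > b`, else `es = -b`. A positive score means
#' the tags concentrate at the top of the list, a negative one at the bottom.
#'
#' @param tag_positions strictly increasing integer ranks in `1..n`.
#' @param n total number of probes in the ranked list.
#' @return list with elements `a`, `b`, `es`.
#' @export
ks_tag_score <- function(tag_positions, n) {
  t <- length(tag_positions)
  assert_that(t >= 1 && t < n, "tag set must satisfy 1 <= t < n")
  assert_that(all(tag_positions >= 1 & tag_positions <= n),
              "tag positions must lie in 1..n")
  assert_that(all(diff(tag_positions) > 0),
              "tag positions must be strictly increasing")
  j <- seq_len(t)
  a <- max(j / t - tag_positions / n)
  b <- max(tag_positions / n - (j - 1) / t)
  list(a = a, b = b, es = if (a > b) a else -b)
}

# vectorised KS tag scores for one tag set over all columns of a rank matrix.
# ranks: n x m integer matrix; tag_idx: row indices of the tags.
score_tags_matrix <- function(ranks, tag_idx) {
  t <- length(tag_idx)
  n <- nrow(ranks)
  m <- ncol(ranks)
  pos <- ranks[tag_idx, , drop = FALSE]              # t x m tag positions
  o <- order(col(pos), pos)                          # sort within each column
  ps <- matrix(pos[o], t, m)
  jt <- seq_len(t) / t
  a <- col_maxs(jt - ps / n)
  b <- col_maxs(ps / n - (jt - 1 / t))
  ifelse(a > b, a, -b)
}

# resolve a signature's tags to row indices of the matrix; drop missing tags
# with a warning, error if a side loses >75% of its tags or empties out.
match_signature <- function(sig, probe_ids, warn = TRUE) {
  side_idx <- function(tags, side) {
    idx <- match(tags, probe_ids)
    missing <- sum(is.na(idx))
    if (missing > 0 && warn) {
      warning(sprintf("%d of %d %s tags absent from the rank matrix; scoring on the intersection",
                      missing, length(tags), side), call. = FALSE)
    }
    idx <- idx[!is.na(idx)]
    assert_that(length(idx) > 0,
                sprintf("no %s tags present in the rank matrix", side))
    assert_that(length(idx) >= 0.25 * length(tags),
                sprintf("fewer than 25%% of %s tags survive matching to the rank matrix", side))
    idx
  }
  list(up = side_idx(sig$up_tags, "up"), down = side_idx(sig$down_tags, "down"))
}

# combine up/down KS scores into the build-02 raw connectivity score:
# zero when both sides agree in sign, es_up - es_down otherwise.
combine_raw <- function(es_up, es_down) {
  ifelse(sign(es_up) == sign(es_down), 0, es_up - es_down)
}

#' Raw connectivity of one signature with one instance
#'
#' Scores the up and down tag sets with [ks_tag_score()] against a single
#' instance's rank column and combines them: `raw = es_up - es_down` when
#' the two scores differ in sign, 0 otherwise (the build-02 rule). A
#' signature-inverting ("inhibiting") instance gets a negative raw score.
#'
#' @param sig a [gene_signature()].
#' @param column named integer vector: one instance's ranks, names = probe
#'   IDs, values a permutation of `1..n`.
#' @return list with `es_up`, `es_down`, `raw`, `n_up`, `n_down` (tag counts
#'   after intersection with the probe universe).
#' @export
instance_connectivity <- function(sig, column) {
  assert_that(!is.null(names(column)), "column must be named by probe ID")
  idx <- match_signature(sig, names(column))
  up <- ks_tag_score(sort(column[idx$up]), length(column))
  down <- ks_tag_score(sort(column[idx$down]), length(column))
  list(es_up = up$es, es_down = down$es,
       raw = combine_raw(up$es, down$es),
       n_up = length(idx$up), n_down = length(idx$down))
}

#' Scale raw connectivity scores within one query
#'
#' Positive raw scores are divided by the maximum positive raw score,
#' negative ones by the absolute minimum negative raw score; zeros stay
#' zero. After scaling all values lie in `[-1, 1]` and, unless all raws are
#' zero, at least one equals 1 or -1.
#'
#' @param raw numeric vector of raw connectivity scores for all instances of
#'   one query.
#' @return numeric vector of scaled scores.
#' @export
scale_scores <- function(raw) {
  assert_that(length(raw) >= 1, "need at least one instance score")
  out <- raw
  pos <- raw > 0
  neg <- raw < 0
  if (any(pos)) out[pos] <- raw[pos] / max(raw[pos])
  if (any(neg)) out[neg] <- raw[neg] / abs(min(raw[neg]))
  out
}

# score a signature against every instance: returns raw vector (length m)
raw_query <- function(rm, up_idx, down_idx) {
  es_up <- score_tags_matrix(rm$ranks, up_idx)
  es_down <- score_tags_matrix(rm$ranks, down_idx)
  combine_raw(es_up, es_down)
}

#' Per-compound connectivity summary with permutation p-values
#'
#' Scores a signature against every instance of a rank matrix, scales the
#' raw scores within the query, averages them per compound, and attaches a
#' permutation p-value: the null re-scores the same instances with random
#' tag sets of the same up/down sizes drawn without replacement from the
#' probe universe; `p = (1 + #\{|null mean| >= |observed mean|\}) /
#' (1 + n_perm)` (two-sided, add-one).
#'
#' @param rm a [rank_matrix()].
#' @param sig a [gene_signature()].
#' @param n_perm number of random tag-set permutations (>= 100).
#' @param seed integer seed for the permutation null.
#' @param scaled summarise scaled (default) or raw scores.
#' @return data.frame with columns `compound`, `n_instances`, `mean_es`,
#'   `p`; attributes `seed`, `n_perm`, `signature`, `scaled`.
#' @export
compound_summary <- function(rm, sig, n_perm = 1000, seed = 1, scaled = TRUE) {
  assert_that(n_perm >= 100, "n_perm must be at least 100")
  idx <- match_signature(sig, rm$probe_ids)
  raw <- raw_query(rm, idx$up, idx$down)
  obs <- if (scaled) scale_scores(raw) else raw

  comp <- factor(rm$meta$compound)
  n_inst <- as.integer(table(comp))
  obs_mean <- as.numeric(rowsum(obs, comp)) / n_inst

  n <- nrow(rm$ranks)
  t_up <- length(idx$up)
  t_down <- length(idx$down)
  set.seed(as.integer(seed))
  exceed <- numeric(nlevels(comp))
  for (b in seq_len(n_perm)) {
    pick <- sample.int(n, t_up + t_down)
    null_raw <- raw_query(rm, pick[seq_len(t_up)], pick[-seq_len(t_up)])
    null_s <- if (scaled) scale_scores(null_raw) else null_raw
    null_mean <- as.numeric(rowsum(null_s, comp)) / n_inst
    exceed <- exceed + (abs(null_mean) >= abs(obs_mean))
  }
  out <- data.frame(compound = levels(comp),
                    n_instances = n_inst,
                    mean_es = obs_mean,
                    p = (1 + exceed) / (1 + n_perm),
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "n_perm") <- n_perm
  attr(out, "signature") <- sig$name
  attr(out, "scaled") <- scaled
  out
}

#' Full connectivity query: per-instance scores plus per-compound summary
#'
#' @inheritParams compound_summary
#' @return list of class `connectivity_result` with `instances` (data.frame:
#'   `instance_id`, `compound`, `es_up`, `es_down`, `raw`, `scaled`) and
#'   `compounds` (the [compound_summary()] data.frame).
#' @export
query_connectivity <- function(rm, sig, n_perm = 1000, seed = 1, scaled = TRUE) {
  idx <- match_signature(sig, rm$probe_ids)
  es_up <- score_tags_matrix(rm$ranks, idx$up)
  es_down <- score_tags_matrix(rm$ranks, idx$down)
  raw <- combine_raw(es_up, es_down)
  inst <- data.frame(instance_id = colnames(rm$ranks),
                     compound = rm$meta$compound,
                     es_up = es_up, es_down = es_down,
                     raw = raw, scaled = scale_scores(raw),
                     stringsAsFactors = FALSE)
  comps <- suppressWarnings(
    compound_summary(rm, sig, n_perm = n_perm, seed = seed, scaled = scaled))
  structure(list(instances = inst, compounds = comps, signature = sig$name),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("connectivity_result for signature '%s': %d instances, %d compounds\n",
              x$signature, nrow(x$instances), nrow(x$compounds)))
  invisible(x)
}

#' Write a per-compound connectivity table as TSV
#'
#' @param compounds data.frame from [compound_summary()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_connectivity <- function(compounds, path) {
  write.table(compounds, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
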