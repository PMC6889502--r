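#' Collapse selected instances of a rank matrix to one ranked profile
#'
#' Sums each probe's ranks across the selected instances, optionally
#' collapses probes to genes by summing the per-probe rank sums within a
#' gene, and orders the result from highest to lowest rank sum (ties broken
#' by feature ID). With rank 1 = most up-regulated per instance, the head of
#' the profile holds the features most consistently down-regulated across
#' the selected instances; reverse the profile for the opposite reading.
#'
#' @param rm a [rank_matrix()].
#' @param instance_ids instances to aggregate (default: all).
#' @param map optional [probe_map()] (gene -> probes) for probe-to-gene
#'   collapse; probes not covered by the map are kept under their own ID.
#' @return data.frame with columns `feature` and `rank_sum`, ordered by
#'   decreasing `rank_sum`.
#' @export
aggregate_instances_to_profile <- function(rm, instance_ids = NULL, map = NULL) {
  if (is.null(instance_ids)) instance_ids <- colnames(rm$ranks)
  assert_that(length(instance_ids) >= 1, "need at least one instance")
  missing <- setdiff(instance_ids, colnames(rm$ranks))
  assert_that(length(missing) == 0,
              paste("unknown instance(s):", paste(head(missing, 5), collapse = ", ")))
  sums <- rowSums(rm$ranks[, instance_ids, drop = FALSE])
  feature <- rm$probe_ids
  if (!is.null(map)) {
    map <- probe_map(map)
    probe2gene <- setNames(rep(names(map), lengths(map)),
                           unlist(map, use.names = FALSE))
    feature <- ifelse(is.na(probe2gene[feature]), feature, probe2gene[feature])
    agg <- rowsum(sums, feature)
    feature <- rownames(agg)
    sums <- as.numeric(agg)
  }
  ord <- order(-sums, feature)
  data.frame(feature = feature[ord], rank_sum = sums[ord],
             stringsAsFactors = FALSE)
}

#' Preranked gene-set enrichment with the unweighted tag statistic
#'
#' Scores each gene set against an ordered feature list with the same KS tag
#' statistic used for connectivity scoring ([ks_tag_score()]), and attaches
#' a permutation p-value from random sets of matched size (two-sided on
#' |es|, add-one estimator). Sets whose intersection with the profile falls
#' outside `[min_size, max_size]` are skipped and reported.
#'
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()]).
#' @param profile character vector of feature IDs, ordered (position 1 =
#'   head of the ranking), or a data.frame from
#'   [aggregate_instances_to_profile()].
#' @param n_perm permutations per set size (default 1000).
#' @param min_size,max_size set-size bounds after intersection (defaults 8
#'   and 1000).
#' @param seed integer seed.
#' @return data.frame with columns `set`, `size`, `es`, `p`; skipped sets
#'   are listed in attribute `skipped`.
#' @export
preranked_enrichment <- function(gene_sets, profile, n_perm = 1000,
                                 min_size = 8, max_size = 1000, seed = 1) {
  if (is.data.frame(profile)) profile <- profile$feature
  profile <- as.character(profile)
  assert_that(length(profile) > 0, "profile must be non-empty")
  assert_that(!anyDuplicated(profile), "profile features must be unique")
  assert_that(!is.null(names(gene_sets)), "gene_sets must be named")
  n <- length(profile)

  positions <- lapply(gene_sets, function(s) sort(match(unique(s), profile)))
  positions <- lapply(positions, function(p) p[!is.na(p)])
  sizes <- lengths(positions)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  skipped <- names(gene_sets)[!keep]
  if (length(skipped) > 0) {
    message(sprintf("%d set(s) outside size bounds [%d, %d] skipped: %s",
                    length(skipped), min_size, max_size,
                    paste(head(skipped, 10), collapse = ", ")))
  }
  positions <- positions[keep]
  sizes <- sizes[keep]
  es <- vapply(positions, function(p) ks_tag_score(p, n)$es, numeric(1))

  # shared null per distinct set size
  set.seed(as.integer(seed))
  p <- rep(NA_real_, length(es))
  for (t in unique(sizes)) {
    null_abs <- vapply(seq_len(n_perm), function(b) {
      abs(ks_tag_score(sort(sample.int(n, t)), n)$es)
    }, numeric(1))
    for (i in which(sizes == t)) {
      p[i] <- (1 + sum(null_abs >= abs(es[i]))) / (1 + n_perm)
    }
  }
  out <- data.frame(set = names(positions), size = as.integer(sizes),
                    es = es, p = p, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  attr(out, "seed") <- seed
  attr(out, "n_perm") <- n_perm
  out
}
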