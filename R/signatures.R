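#' Construct a gene signature from up and down tag sets
#'
#' A gene signature is a pair of disjoint, non-empty identifier sets marking
#' features high (`up_tags`) versus low (`down_tags`) in a cell state, e.g.
#' an LSC-enriched versus non-LSC fraction. Signatures are the query objects
#' for connectivity scoring.
#'
#' @param name label for the signature.
#' @param up_tags character vector of feature (probe or gene) identifiers.
#' @param down_tags character vector of feature identifiers.
#' @return An object of class `gene_signature` with elements `name`,
#'   `up_tags` and `down_tags` (both sorted, unique character vectors).
#' @export
gene_signature <- function(name, up_tags, down_tags) {
  up <- sort(unique(as.character(up_tags)))
  down <- sort(unique(as.character(down_tags)))
  assert_that(length(up) > 0, "up_tags must be non-empty")
  assert_that(length(down) > 0, "down_tags must be non-empty")
  both <- intersect(up, down)
  assert_that(length(both) == 0,
              paste0("up and down tag sets must be disjoint; shared: ",
                     paste(head(both, 5), collapse = ", ")))
  structure(list(name = as.character(name), up_tags = up, down_tags = down),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d up tags, %d down tags\n",
              x$name, length(x$up_tags), length(x$down_tags)))
  invisible(x)
}

#' Read a differential-expression table
#'
#' Expects a TSV with header columns `feature_id`, `stat` (signed association
#' statistic: correlation or t-statistic; positive = associated with the
#' state of interest) and `p` (p-value).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `feature_id`, `stat`, `p`.
#' @export
read_de_table <- function(path) {
  de <- read.delim(path, stringsAsFactors = FALSE)
  validate_de_table(de)
}

#' Validate a differential-expression table
#'
#' @param de data.frame with columns `feature_id`, `stat`, `p`.
#' @return the validated data.frame (invisibly usable downstream).
#' @export
validate_de_table <- function(de) {
  need <- c("feature_id", "stat", "p")
  missing <- setdiff(need, names(de))
  assert_that(length(missing) == 0,
              paste("DE table lacks column(s):", paste(missing, collapse = ", ")))
  de$feature_id <- as.character(de$feature_id)
  assert_that(!anyDuplicated(de$feature_id),
              "feature_id must be unique within a DE table")
  assert_that(all(is.finite(de$stat)), "stat must be finite")
  assert_that(all(de$p >= 0 & de$p <= 1), "p must lie in [0, 1]")
  de
}

#' Build a signature from the top and bottom k features
#'
#' Takes the `k` features with the largest signed statistic as up tags and
#' the `k` with the smallest as down tags (e.g. the 100 probes most
#' correlated with LSCs and the 100 most correlated with non-LSCs). Ties
#' spanning the k-th boundary are resolved deterministically by
#' (|stat| descending, p ascending, feature_id ascending) and a warning is
#' emitted.
#'
#' @param de DE table (see [validate_de_table()]).
#' @param k number of features per side; `de` must have at least `2k` rows.
#' @param name signature label.
#' @return a [gene_signature()].
#' @export
build_top_k_signature <- function(de, k, name = "topk") {
  de <- validate_de_table(de)
  k <- as.integer(k)
  assert_that(k >= 1, "k must be a positive integer")
  assert_that(nrow(de) >= 2L * k,
              sprintf("DE table has %d rows; need at least 2k = %d", nrow(de), 2L * k))

  ord_up <- order(-de$stat, de$p, de$feature_id)
  up_idx <- ord_up[seq_len(k)]
  # the down side is drawn from the remaining features, so heavy ties can
  # never produce overlapping tag sets
  rest <- de[-up_idx, , drop = FALSE]
  ord_dn <- order(rest$stat, rest$p, rest$feature_id)
  dn_ids <- rest$feature_id[ord_dn[seq_len(k)]]

  # a tie spans the boundary when the k-th and (k+1)-th statistic coincide
  tie_up <- nrow(de) > k && de$stat[ord_up[k]] == de$stat[ord_up[k + 1L]]
  tie_dn <- nrow(rest) > k && rest$stat[ord_dn[k]] == rest$stat[ord_dn[k + 1L]]
  if (tie_up || tie_dn) {
    warning("ties span the top-k boundary; resolved by (stat, p asc, ",
            "feature_id asc) with the down side drawn from the remaining features",
            call. = FALSE)
  }
  gene_signature(name, de$feature_id[up_idx], dn_ids)
}

#' Build a signature from a p-value threshold
#'
#' Up tags are the features with positive statistic and `p <= alpha`; down
#' tags those with negative statistic and `p <= alpha` (the HSC-style rule,
#' default alpha 0.05).
#'
#' @param de DE table.
#' @param alpha p-value cutoff in (0, 1).
#' @param name signature label.
#' @return a [gene_signature()].
#' @export
build_p_threshold_signature <- function(de, alpha = 0.05, name = "pthresh") {
  de <- validate_de_table(de)
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  up <- de$feature_id[de$stat > 0 & de$p <= alpha]
  down <- de$feature_id[de$stat < 0 & de$p <= alpha]
  assert_that(length(up) > 0,
              sprintf("no up-side features at alpha = %g", alpha))
  assert_that(length(down) > 0,
              sprintf("no down-side features at alpha = %g", alpha))
  gene_signature(name, up, down)
}

#' Read a gene-to-probe mapping table
#'
#' Two-column TSV (`gene`, `probe`); a gene may map to several probes.
#'
#' @param path path to the TSV file.
#' @return named list: gene symbol -> character vector of probe IDs.
#' @export
read_probe_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("gene", "probe") %in% names(tab)),
              "probe map needs columns 'gene' and 'probe'")
  probe_map(split(as.character(tab$probe), as.character(tab$gene)))
}

#' Validate a gene-to-probe map
#'
#' @param map named list of character vectors (gene -> probes).
#' @return the validated map.
#' @export
probe_map <- function(map) {
  assert_that(length(map) > 0, "probe map must be non-empty")
  assert_that(!is.null(names(map)) && all(nzchar(names(map))),
              "probe map must be named by gene symbol")
  lens <- lengths(map)
  assert_that(all(lens > 0), "probe map has genes with empty probe lists")
  lapply(map, as.character)
}

#' Convert a gene-symbol signature to a probe-level signature
#'
#' Each gene expands to all of its mapped probes (1:many). Genes absent from
#' the map are counted and reported via warning; more than 50 percent
#' unmapped is treated as a misconfigured map and raises an error. A probe
#' reached from both the up and the down side is removed from both, since the
#' enrichment statistic assumes disjoint tag sets.
#'
#' @param sig_genes a [gene_signature()] whose tags are gene symbols.
#' @param map a [probe_map()].
#' @return a [gene_signature()] over probe IDs; attributes `n_unmapped_up`
#'   and `n_unmapped_down` record unmapped gene counts.
#' @export
genes_to_probes <- function(sig_genes, map) {
  map <- probe_map(map)
  expand <- function(genes) {
    hit <- genes %in% names(map)
    list(probes = unique(unlist(map[genes[hit]], use.names = FALSE)),
         unmapped = genes[!hit])
  }
  up <- expand(sig_genes$up_tags)
  down <- expand(sig_genes$down_tags)
  n_total <- length(sig_genes$up_tags) + length(sig_genes$down_tags)
  n_unmapped <- length(up$unmapped) + length(down$unmapped)
  assert_that(n_unmapped <= 0.5 * n_total,
              sprintf("%d of %d signature genes are unmapped (>50%%); map looks misconfigured",
                      n_unmapped, n_total))
  if (n_unmapped > 0) {
    warning(sprintf("%d signature gene(s) had no probe mapping: %s",
                    n_unmapped,
                    paste(head(c(up$unmapped, down$unmapped), 10), collapse = ", ")),
            call. = FALSE)
  }
  shared <- intersect(up$probes, down$probes)
  if (length(shared) > 0) {
    warning(sprintf("%d probe(s) mapped from both sides removed from both: %s",
                    length(shared), paste(head(shared, 10), collapse = ", ")),
            call. = FALSE)
  }
  out <- gene_signature(sig_genes$name,
                        setdiff(up$probes, shared),
                        setdiff(down$probes, shared))
  attr(out, "n_unmapped_up") <- length(up$unmapped)
  attr(out, "n_unmapped_down") <- length(down$unmapped)
  out
}
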