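#' Construct a perturbation rank matrix
#'
#' A rank matrix holds one column per treatment instance (compound x cell
#' line x dose); each column is a permutation of `1..n` over the probe
#' universe, with rank 1 the probe most up-regulated by the treatment and
#' rank n the most down-regulated.
#'
#' @param ranks integer matrix, probes x instances; rownames are probe IDs,
#'   colnames instance IDs. Every column must be a permutation of
#'   `1..nrow(ranks)`.
#' @param meta data.frame with columns `instance_id`, `compound` and
#'   optionally `cell_line`, `dose`; one row per column of `ranks`.
#' @return object of class `rank_matrix` with elements `probe_ids`, `ranks`,
#'   `meta`.
#' @export
rank_matrix <- function(ranks, meta) {
  ranks <- as.matrix(ranks)
  storage.mode(ranks) <- "integer"
  n <- nrow(ranks)
  assert_that(n >= 2, "rank matrix needs at least 2 probes")
  assert_that(!is.null(rownames(ranks)), "ranks must have probe IDs as rownames")
  assert_that(!is.null(colnames(ranks)), "ranks must have instance IDs as colnames")
  assert_that(!anyDuplicated(rownames(ranks)), "probe IDs must be unique")
  assert_that(!anyDuplicated(colnames(ranks)), "instance IDs must be unique")
  # each column must be a permutation of 1..n; reject rather than re-rank
  cs <- colSums(ranks)
  ok <- cs == n * (n + 1) / 2 &
    apply(ranks, 2L, function(col) all(col >= 1L & col <= n) && !anyDuplicated(col))
  assert_that(all(ok),
              paste("column(s) not a permutation of 1..n:",
                    paste(head(colnames(ranks)[!ok], 5), collapse = ", ")))

  assert_that(all(c("instance_id", "compound") %in% names(meta)),
              "meta needs columns instance_id and compound")
  meta$instance_id <- as.character(meta$instance_id)
  meta$compound <- as.character(meta$compound)
  assert_that(!anyDuplicated(meta$instance_id), "instance_id must be unique")
  assert_that(all(nzchar(meta$compound)), "every instance needs a compound label")
  assert_that(setequal(meta$instance_id, colnames(ranks)),
              "meta instance_ids must match rank matrix columns")
  meta <- meta[match(colnames(ranks), meta$instance_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(probe_ids = rownames(ranks), ranks = ranks, meta = meta),
            class = "rank_matrix")
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("rank_matrix: %d probes x %d instances (%d compounds)\n",
              nrow(x$ranks), ncol(x$ranks), length(unique(x$meta$compound))))
  invisible(x)
}

#' Read a rank matrix and its instance metadata from TSV
#'
#' The matrix TSV has probe IDs in the first column (`probe_id`) and one
#' integer-rank column per instance; the metadata TSV has columns
#' `instance_id`, `compound` and optionally `cell_line`, `dose`.
#'
#' @param matrix_path,meta_path paths to the two TSV files.
#' @return a [rank_matrix()].
#' @export
read_rank_matrix <- function(matrix_path, meta_path) {
  tab <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(names(tab)[1] == "probe_id",
              "first column of the rank matrix TSV must be 'probe_id'")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab$probe_id)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  rank_matrix(m, meta)
}

#' Write a rank matrix and its instance metadata to TSV
#'
#' @param rm a [rank_matrix()].
#' @param matrix_path,meta_path output paths.
#' @return invisibly, the two paths.
#' @export
write_rank_matrix <- function(rm, matrix_path, meta_path) {
  tab <- data.frame(probe_id = rm$probe_ids, rm$ranks,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(rm$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = matrix_path, meta = meta_path))
}
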