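#' Configuration of the dual-signature selection rule
#'
#' @param lsc_p_max permutation-p cutoff for calling a compound an LSC hit
#'   (default 0.1; the screen rule is negative mean ES with p <= 0.1).
#' @param lsc_combination `"any"` (default) or `"all"`: whether a compound
#'   must hit any or every LSC signature.
#' @param hsc_rule `"strict_nonnegative"` (default: the HSC mean ES must be
#'   >= 0) or `"not_significantly_negative"` (reject only compounds whose
#'   HSC mean ES is negative with p <= `lsc_p_max`).
#' @param hsc_enhance_p_max p cutoff for the HSC-enhancing bucket (default
#'   0.1): selected compounds with positive HSC mean ES significant at this
#'   level are labelled `hsc_enhancing`.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(lsc_p_max = 0.1,
                             lsc_combination = c("any", "all"),
                             hsc_rule = c("strict_nonnegative",
                                          "not_significantly_negative"),
                             hsc_enhance_p_max = 0.1) {
  assert_that(lsc_p_max > 0 && lsc_p_max < 1, "lsc_p_max must lie in (0,1)")
  assert_that(hsc_enhance_p_max > 0 && hsc_enhance_p_max < 1,
              "hsc_enhance_p_max must lie in (0,1)")
  structure(list(lsc_p_max = lsc_p_max,
                 lsc_combination = match.arg(lsc_combination),
                 hsc_rule = match.arg(hsc_rule),
                 hsc_enhance_p_max = hsc_enhance_p_max),
            class = "selection_config")
}

#' Partition compounds by the dual-signature selection rule
#'
#' A compound is an LSC hit iff `mean_es < 0` and `p <= lsc_p_max` for
#' any (default) or all of the LSC signatures. LSC hits then pass the HSC
#' filter iff their HSC `mean_es >= 0` (strict mode) or they are not
#' significantly negative on HSC (lenient mode). Passing hits whose HSC
#' `mean_es > 0` with `p <= hsc_enhance_p_max` go to the `hsc_enhancing`
#' bucket, the rest to `hsc_neutral`; everything else is `rejected` with a
#' reason (`not_lsc_hit`, `hsc_negative`, or `missing_scores` for compounds
#' absent from some result table). The three buckets always partition the
#' full compound universe.
#'
#' @param lsc_results one [compound_summary()] data.frame, or a (optionally
#'   named) list of them, one per LSC signature.
#' @param hsc_results a [compound_summary()] data.frame for the HSC
#'   signature.
#' @param cfg a [selection_config()].
#' @return object of class `candidate_partition`: list with `table`
#'   (data.frame: `compound`, `bucket`, `reason`, per-signature `mean_es`
#'   and `p` columns), `counts` (named vector: hsc_neutral, hsc_enhancing,
#'   rejected, universe) and `config`.
#' @export
select_candidates <- function(lsc_results, hsc_results, cfg = selection_config()) {
  if (is.data.frame(lsc_results)) lsc_results <- list(lsc_results)
  assert_that(length(lsc_results) >= 1, "need at least one LSC result table")
  nms <- names(lsc_results)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- vapply(seq_along(lsc_results), function(i) {
      attr(lsc_results[[i]], "signature") %||% paste0("lsc", i)
    }, character(1))
    names(lsc_results) <- make.unique(nms)
  }

  universe <- sort(unique(c(unlist(lapply(lsc_results, `[[`, "compound")),
                            hsc_results$compound)))
  assert_that(length(universe) > 0, "empty compound universe")

  tab <- data.frame(compound = universe, stringsAsFactors = FALSE)
  lsc_hit <- matrix(NA, nrow = length(universe), ncol = length(lsc_results))
  for (i in seq_along(lsc_results)) {
    res <- lsc_results[[i]]
    m <- match(universe, res$compound)
    tab[[paste0(names(lsc_results)[i], "_mean_es")]] <- res$mean_es[m]
    tab[[paste0(names(lsc_results)[i], "_p")]] <- res$p[m]
    lsc_hit[, i] <- res$mean_es[m] < 0 & res$p[m] <= cfg$lsc_p_max
  }
  mh <- match(universe, hsc_results$compound)
  tab$hsc_mean_es <- hsc_results$mean_es[mh]
  tab$hsc_p <- hsc_results$p[mh]

  missing <- rowSums(is.na(lsc_hit)) > 0 | is.na(mh)
  if (any(missing)) {
    warning(sprintf("%d compound(s) absent from some result table; rejected as missing_scores",
                    sum(missing)), call. = FALSE)
  }
  hit <- if (cfg$lsc_combination == "any") {
    rowSums(lsc_hit, na.rm = TRUE) > 0 & !missing
  } else {
    rowSums(lsc_hit, na.rm = TRUE) == ncol(lsc_hit) & !missing
  }
  hsc_pass <- if (cfg$hsc_rule == "strict_nonnegative") {
    tab$hsc_mean_es >= 0
  } else {
    !(tab$hsc_mean_es < 0 & tab$hsc_p <= cfg$lsc_p_max)
  }
  hsc_pass[is.na(hsc_pass)] <- FALSE
  enhancing <- tab$hsc_mean_es > 0 & tab$hsc_p <= cfg$hsc_enhance_p_max
  enhancing[is.na(enhancing)] <- FALSE

  bucket <- ifelse(missing, "rejected",
            ifelse(!hit, "rejected",
            ifelse(!hsc_pass, "rejected",
            ifelse(enhancing, "hsc_enhancing", "hsc_neutral"))))
  reason <- ifelse(missing, "missing_scores",
            ifelse(!hit, "not_lsc_hit",
            ifelse(!hsc_pass, "hsc_negative", "")))
  tab$bucket <- bucket
  tab$reason <- reason
  tab <- tab[, c("compound", "bucket", "reason",
                 setdiff(names(tab), c("compound", "bucket", "reason")))]

  counts <- c(hsc_neutral = sum(bucket == "hsc_neutral"),
              hsc_enhancing = sum(bucket == "hsc_enhancing"),
              rejected = sum(bucket == "rejected"),
              universe = length(universe))
  stopifnot(sum(counts[1:3]) == counts[["universe"]])
  structure(list(table = tab, counts = counts, config = cfg),
            class = "candidate_partition")
}

#' @export
print.candidate_partition <- function(x, ...) {
  cat(sprintf(paste0("candidate_partition: %d compounds -> %d selected ",
                     "(%d HSC-neutral + %d HSC-enhancing), %d rejected\n"),
              x$counts[["universe"]],
              x$counts[["hsc_neutral"]] + x$counts[["hsc_enhancing"]],
              x$counts[["hsc_neutral"]], x$counts[["hsc_enhancing"]],
              x$counts[["rejected"]]))
  invisible(x)
}

#' Write a candidate partition as TSV plus a JSON count summary
#'
#' @param partition a [select_candidates()] result.
#' @param tsv_path path for the per-compound table.
#' @param json_path optional path for a JSON summary of bucket counts.
#' @return invisibly, the TSV path.
#' @export
write_candidates <- function(partition, tsv_path, json_path = NULL) {
  write.table(partition$table, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(partition$counts), json_path,
                         auto_unbox = TRUE)
  }
  invisible(tsv_path)
}
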