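#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file (or an equivalent R list) with fields:
#' \preformatted{
#' rank_matrix: path to the rank-matrix TSV
#' meta: path to the instance-metadata TSV
#' lsc_signatures:          # one or more
#'   - {name: LSC_R, up: lscR_up.grp, down: lscR_down.grp}
#' hsc_signature: {name: HSC_R, up: hscR_up.grp, down: hscR_down.grp}
#' n_perm: 1000
#' seed: 7
#' selection: {lsc_p_max: 0.1, lsc_combination: any,
#'             hsc_rule: strict_nonnegative, hsc_enhance_p_max: 0.1}
#' out_dir: results/
#' }
#'
#' @param config path to a YAML file, or a list with the fields above.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    assert_that(file.exists(config), paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  assert_that(is.list(config), "config must be a list or a YAML path")
  for (f in c("rank_matrix", "meta", "hsc_signature", "out_dir")) {
    assert_that(!is.null(config[[f]]), paste("config field missing:", f))
  }
  assert_that(length(config$lsc_signatures) >= 1,
              "config needs at least one LSC signature")
  paths <- c(config$rank_matrix, config$meta,
             unlist(lapply(config$lsc_signatures, function(s) c(s$up, s$down))),
             config$hsc_signature$up, config$hsc_signature$down)
  missing <- paths[!file.exists(paths)]
  assert_that(length(missing) == 0,
              paste("config references missing file(s):",
                    paste(missing, collapse = ", ")))
  config$n_perm <- as.integer(config$n_perm %||% 1000)
  config$seed <- as.integer(config$seed %||% 1)
  sel <- config$selection %||% list()
  config$selection <- selection_config(
    lsc_p_max = sel$lsc_p_max %||% 0.1,
    lsc_combination = sel$lsc_combination %||% "any",
    hsc_rule = sel$hsc_rule %||% "strict_nonnegative",
    hsc_enhance_p_max = sel$hsc_enhance_p_max %||% 0.1)
  structure(config, class = c("run_config", "list"))
}

#' Run the full in silico screen from a configuration
#'
#' Executes connectivity scoring for every LSC signature and the HSC
#' signature against the configured rank matrix, applies the dual-signature
#' selection rule, and persists all intermediate per-compound connectivity
#' TSVs, the candidate table, and a JSON run summary (bucket counts, their
#' sum check, seed, and a config hash) under `out_dir`.
#'
#' @param config a [read_run_config()] input (path or list).
#' @return the [select_candidates()] partition, invisibly extended with
#'   `summary` (the run-summary list).
#' @export
run_in_silico <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }
  rm <- stage("load", read_rank_matrix(cfg$rank_matrix, cfg$meta))

  lsc_results <- list()
  for (s in cfg$lsc_signatures) {
    sig <- stage("signatures",
                 read_signature_grp(s$up, s$down, name = s$name))
    res <- stage(paste0("connectivity:", sig$name),
                 compound_summary(rm, sig, n_perm = cfg$n_perm,
                                  seed = cfg$seed))
    write_connectivity(res, file.path(cfg$out_dir,
                                      paste0("connectivity_", sig$name, ".tsv")))
    lsc_results[[sig$name]] <- res
  }
  hsig <- stage("signatures",
                read_signature_grp(cfg$hsc_signature$up, cfg$hsc_signature$down,
                                   name = cfg$hsc_signature$name %||% "HSC"))
  hsc_res <- stage(paste0("connectivity:", hsig$name),
                   compound_summary(rm, hsig, n_perm = cfg$n_perm,
                                    seed = cfg$seed))
  write_connectivity(hsc_res, file.path(cfg$out_dir,
                                        paste0("connectivity_", hsig$name, ".tsv")))

  part <- stage("selection",
                select_candidates(lsc_results, hsc_res, cfg$selection))
  write_candidates(part,
                   file.path(cfg$out_dir, "candidates.tsv"),
                   file.path(cfg$out_dir, "candidate_counts.json"))

  summary <- list(
    seed = cfg$seed,
    n_perm = cfg$n_perm,
    config_hash = fnv1a_hash(unclass(cfg)),
    lsc_signatures = names(lsc_results),
    hsc_signature = hsig$name,
    counts = as.list(part$counts),
    partition_identity_ok =
      sum(unlist(part$counts[c("hsc_neutral", "hsc_enhancing", "rejected")])) ==
        part$counts[["universe"]])
  jsonlite::write_json(summary, file.path(cfg$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  part$summary <- summary
  invisible(part)
}
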