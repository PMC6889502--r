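#' Read a long-format screen table
#'
#' CSV columns: `compound`, `dose`, `unit`, `population`, `replicate`,
#' `count`, `is_control`. Control (vehicle, e.g. DMSO) rows have
#' `is_control = TRUE` and may carry dose 0/NA; treated rows need dose > 0.
#'
#' @param path path to the CSV file.
#' @return validated data.frame.
#' @export
read_screen_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_screen_table(tab)
}

#' Validate a screen table
#'
#' @param tab data.frame in the long screen format (see
#'   [read_screen_table()]).
#' @return the validated data.frame.
#' @export
validate_screen_table <- function(tab) {
  need <- c("compound", "dose", "population", "replicate", "count", "is_control")
  missing <- setdiff(need, names(tab))
  assert_that(length(missing) == 0,
              paste("screen table lacks column(s):", paste(missing, collapse = ", ")))
  tab$is_control <- as.logical(tab$is_control)
  assert_that(all(tab$count >= 0), "counts must be non-negative")
  treated <- tab[!tab$is_control, , drop = FALSE]
  assert_that(all(treated$dose > 0), "treated records need dose > 0")
  pops_treated <- unique(treated$population)
  pops_ctrl <- unique(tab$population[tab$is_control])
  orphan <- setdiff(pops_treated, pops_ctrl)
  assert_that(length(orphan) == 0,
              paste("population(s) without control records:",
                    paste(orphan, collapse = ", ")))
  tab
}

#' Normalise treated counts to the vehicle control
#'
#' Relative viability of each (compound, dose, population) cell is the mean
#' treated replicate count divided by the mean vehicle count of the same
#' population stratum.
#'
#' @param tab validated screen table.
#' @return data.frame with columns `compound`, `dose`, `population`,
#'   `rel_viability`, `n_replicates`.
#' @export
normalize_to_control <- function(tab) {
  tab <- validate_screen_table(tab)
  ctrl <- tab[tab$is_control, , drop = FALSE]
  ctrl_mean <- tapply(ctrl$count, ctrl$population, mean)
  bad <- names(ctrl_mean)[!is.finite(ctrl_mean) | ctrl_mean <= 0]
  assert_that(length(bad) == 0,
              paste("zero or absent control mean in population stratum:",
                    paste(bad, collapse = ", ")))
  treated <- tab[!tab$is_control, , drop = FALSE]
  key <- interaction(treated$compound, treated$dose, treated$population,
                     drop = TRUE, sep = "\r")
  agg <- data.frame(mean_count = as.numeric(tapply(treated$count, key, mean)),
                    n_replicates = as.integer(table(key)))
  parts <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  out <- data.frame(compound = parts[, 1],
                    dose = as.numeric(parts[, 2]),
                    population = parts[, 3],
                    rel_viability = agg$mean_count /
                      as.numeric(ctrl_mean[parts[, 3]]),
                    n_replicates = agg$n_replicates,
                    stringsAsFactors = FALSE)
  out[order(out$compound, out$population, out$dose), , drop = FALSE]
}

#' Call viability hits at the +/-50 percent thresholds
#'
#' A cell is called `decreased` when relative viability is at most 0.5
#' (viability reduced by at least 50 percent), `increased` when it is at
#' least 1.5, `none` otherwise. Both boundaries are inclusive ("at least
#' 50%").
#'
#' @param rel data.frame from [normalize_to_control()], or a numeric vector
#'   of relative viabilities.
#' @return the input with a `call` column added (or a character vector for
#'   vector input).
#' @export
call_hits <- function(rel) {
  v <- if (is.data.frame(rel)) rel$rel_viability else rel
  assert_that(all(v >= 0), "relative viability must be non-negative")
  call <- ifelse(v <= 0.5, "decreased", ifelse(v >= 1.5, "increased", "none"))
  if (is.data.frame(rel)) {
    rel$call <- call
    rel
  } else {
    call
  }
}

#' Categorise one compound's hit pattern across populations
#'
#' Categories follow the screen's reading of multi-population toxicity:
#' * **1** — every tracked population shows decreased viability at >= 1 dose
#'   (pan-leukemic toxicity);
#' * **2** — the LSC-containing population is decreased at some dose at
#'   which the blast population is not (LSC-preferential);
#' * **3** — some population is decreased or increased but neither rule
#'   above holds (e.g. the differentiation pattern: blasts expand while
#'   nothing else is called);
#' * **none** — no calls at all.
#' Rules are tested in the order 1, 2, 3.
#'
#' @param calls data.frame from [call_hits()] restricted to one compound
#'   (columns `dose`, `population`, `call`).
#' @param lsc_population label of the LSC-enriched population (e.g.
#'   `"CD34+CD38-"`).
#' @param blast_population label of the differentiated blast population
#'   (e.g. `"CD15+"`), the non-LSC reference for category 2.
#' @return list with `category` (`"1"`, `"2"`, `"3"` or `"none"`) and
#'   `basis` (per-population summary of decreased doses).
#' @export
categorize_compound <- function(calls, lsc_population, blast_population) {
  pops <- unique(calls$population)
  assert_that(length(pops) >= 2, "need calls for at least 2 populations")
  assert_that(lsc_population %in% pops,
              paste("unknown LSC population label:", lsc_population))
  assert_that(blast_population %in% pops,
              paste("unknown blast population label:", blast_population))

  dec <- calls$call == "decreased"
  dec_by_pop <- tapply(dec, calls$population, any)
  lsc_dec_doses <- calls$dose[dec & calls$population == lsc_population]
  blast_dec_doses <- calls$dose[dec & calls$population == blast_population]
  any_call <- any(calls$call != "none")

  category <- if (all(dec_by_pop)) {
    "1"
  } else if (length(setdiff(lsc_dec_doses, blast_dec_doses)) > 0) {
    "2"
  } else if (any_call) {
    "3"
  } else {
    "none"
  }
  basis <- vapply(pops, function(p) {
    d <- sort(unique(calls$dose[dec & calls$population == p]))
    if (length(d) == 0) "" else paste(d, collapse = ",")
  }, character(1))
  list(category = category, basis = basis)
}

#' Categorise every compound in a hit-call table
#'
#' @param calls data.frame from [call_hits()] covering many compounds.
#' @inheritParams categorize_compound
#' @return data.frame with columns `compound`, `category`, `affected`
#'   (TRUE when any call was made).
#' @export
categorize_compounds <- function(calls, lsc_population, blast_population) {
  comps <- sort(unique(calls$compound))
  cat <- vapply(comps, function(cp) {
    categorize_compound(calls[calls$compound == cp, , drop = FALSE],
                        lsc_population, blast_population)$category
  }, character(1))
  data.frame(compound = comps, category = cat,
             affected = cat != "none", row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Screen heat-matrix in the -1/0/+1 encoding
#'
#' One row per compound, one column per dose x population cell; -1 encodes a
#' decreased call, +1 an increased call, 0 none.
#'
#' @param calls data.frame from [call_hits()].
#' @return integer matrix, rows = compounds, columns = `population@dose`.
#' @export
hit_matrix <- function(calls) {
  code <- ifelse(calls$call == "decreased", -1L,
                 ifelse(calls$call == "increased", 1L, 0L))
  cols <- paste0(calls$population, "@", calls$dose)
  comps <- sort(unique(calls$compound))
  ucols <- unique(cols[order(calls$population, calls$dose)])
  m <- matrix(0L, length(comps), length(ucols),
              dimnames = list(comps, ucols))
  m[cbind(match(calls$compound, comps), match(cols, ucols))] <- code
  m
}
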