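#' Describe a planted compound effect for rank-matrix simulation
#'
#' @param compound compound label.
#' @param strength inversion intensity in `[0, 1]`: 0 = null (uniform random
#'   instance), 1 = down tags forced to the extreme top ranks and up tags to
#'   the extreme bottom (for `direction = "invert"`).
#' @param direction `"invert"` (the compound opposes the signature; its
#'   connectivity score is negative) or `"mimic"` (reinforces it).
#' @return list of class `planted_effect`.
#' @export
planted_effect <- function(compound, strength, direction = c("invert", "mimic")) {
  assert_that(strength >= 0 && strength <= 1, "strength must lie in [0, 1]")
  structure(list(compound = as.character(compound),
                 strength = strength,
                 direction = match.arg(direction)),
            class = "planted_effect")
}

# one simulated instance column: an integer rank permutation of 1..n with
# tag probes placed by Beta-skewed positions (nearest-free de-duplication)
planted_column <- function(n, top_idx, bottom_idx, strength) {
  ranks <- integer(n)
  free <- rep(TRUE, n)
  place <- function(targets, idx) {
    for (k in seq_along(idx)) {
      d <- targets[k]
      if (!free[d]) {
        step <- 1L
        repeat {
          if (d - step >= 1L && free[d - step]) { d <- d - step; break }
          if (d + step <= n && free[d + step]) { d <- d + step; break }
          step <- step + 1L
        }
      }
      ranks[idx[k]] <<- d
      free[d] <<- FALSE
    }
  }
  t_top <- length(top_idx)
  t_bot <- length(bottom_idx)
  if (strength >= 1) {
    place(seq_len(t_top), top_idx)
    place(seq.int(n, n - t_bot + 1L), bottom_idx)
  } else {
    shape <- 1 + 9 * strength
    top_targets <- pmin(pmax(ceiling(n * rbeta(t_top, 1, shape)), 1L), n)
    bot_targets <- pmin(pmax(ceiling(n * (1 - rbeta(t_bot, 1, shape))), 1L), n)
    place(top_targets, top_idx)
    place(bot_targets, bottom_idx)
  }
  free_ranks <- which(free)
  ranks[ranks == 0L] <- free_ranks[sample.int(length(free_ranks))]
  ranks
}

#' Simulate a perturbation rank matrix with planted compounds
#'
#' Null instances are uniform random rank permutations. Instances of planted
#' compounds draw their tag positions from Beta(1, 1 + 9 strength)
#' order-statistic distributions: for `direction = "invert"` the signature's
#' down tags are skewed toward rank 1 (up-regulated by the treatment) and
#' the up tags toward rank n, i.e. the compound's profile opposes the
#' signature; `"mimic"` is the mirror image. At strength 1 the tags occupy
#' the exact extreme ranks. Every column remains a valid permutation.
#' Per-compound random substreams are derived from `seed`, so any single
#' compound can be regenerated independently.
#'
#' @param n_probes size of the probe universe (must exceed twice the larger
#'   tag-set size).
#' @param instances named integer vector: compound -> number of instances.
#' @param signature the [gene_signature()] the planted effects act on.
#' @param effects list of [planted_effect()]s (compounds not listed are
#'   null).
#' @param seed integer seed.
#' @param probe_ids optional probe universe (default
#'   `probe_0001...`); must contain all signature tags.
#' @return list with `rank_matrix` (a [rank_matrix()]) and `manifest`
#'   (list: `seed`, per-compound data.frame of planted truth).
#' @export
simulate_rank_matrix <- function(n_probes, instances, signature, effects = list(),
                                 seed = 1, probe_ids = NULL) {
  if (is.null(probe_ids)) probe_ids <- sprintf("probe_%04d", seq_len(n_probes))
  assert_that(length(probe_ids) == n_probes, "probe_ids length must equal n_probes")
  tmax <- max(length(signature$up_tags), length(signature$down_tags))
  assert_that(n_probes > 2 * tmax,
              "probe universe must exceed twice the larger tag-set size")
  assert_that(all(c(signature$up_tags, signature$down_tags) %in% probe_ids),
              "signature tags exceed the probe universe")
  assert_that(!is.null(names(instances)) && all(instances >= 1),
              "instances must be a named vector of positive counts")

  eff_comp <- vapply(effects, `[[`, character(1), "compound")
  assert_that(all(eff_comp %in% names(instances)),
              "planted effects reference unknown compounds")
  up_idx <- match(signature$up_tags, probe_ids)
  down_idx <- match(signature$down_tags, probe_ids)

  cols <- list()
  meta <- list()
  comps <- names(instances)
  for (ci in seq_along(comps)) {
    cp <- comps[ci]
    set.seed(substream_seed(seed, ci))
    e <- effects[match(cp, eff_comp)][[1]]
    for (k in seq_len(instances[[cp]])) {
      col <- if (is.null(e) || e$strength == 0) {
        sample.int(n_probes)
      } else if (e$direction == "invert") {
        planted_column(n_probes, down_idx, up_idx, e$strength)
      } else {
        planted_column(n_probes, up_idx, down_idx, e$strength)
      }
      id <- sprintf("%s.%d", cp, k)
      cols[[id]] <- col
      meta[[id]] <- data.frame(instance_id = id, compound = cp,
                               cell_line = "synthetic", dose = NA_real_,
                               stringsAsFactors = FALSE)
    }
  }
  ranks <- do.call(cbind, cols)
  rownames(ranks) <- probe_ids
  rm <- rank_matrix(ranks, do.call(rbind, meta))

  truth <- data.frame(compound = comps,
                      n_instances = as.integer(instances),
                      planted = comps %in% eff_comp,
                      strength = vapply(comps, function(cp) {
                        e <- effects[match(cp, eff_comp)][[1]]
                        if (is.null(e)) 0 else e$strength
                      }, numeric(1)),
                      direction = vapply(comps, function(cp) {
                        e <- effects[match(cp, eff_comp)][[1]]
                        if (is.null(e)) "" else e$direction
                      }, character(1)),
                      row.names = NULL, stringsAsFactors = FALSE)
  list(rank_matrix = rm,
       manifest = list(seed = seed, signature = signature$name,
                       compounds = truth))
}

#' Default in silico benchmark experiment
#'
#' The study conditions for synthetic recovery testing: a 1000-probe
#' universe, disjoint random LSC and HSC signatures of 100 up + 100 down
#' tags each, 200 compounds with 3 instances apiece, of which 20 are planted
#' LSC-inverters at strength 0.8 and 180 are null.
#'
#' @param seed integer seed.
#' @param n_probes,n_compounds,n_planted,instances_per_compound,tag_size,strength
#'   experiment dimensions (defaults as above).
#' @return list with `rank_matrix`, `manifest`, `lsc_signature`,
#'   `hsc_signature`.
#' @export
default_insilico_experiment <- function(seed = 1, n_probes = 1000,
                                        n_compounds = 200, n_planted = 20,
                                        instances_per_compound = 3,
                                        tag_size = 100, strength = 0.8) {
  probe_ids <- sprintf("probe_%04d", seq_len(n_probes))
  set.seed(substream_seed(seed, 0))
  pick <- sample(probe_ids, 4 * tag_size)
  lsc <- gene_signature("LSC_synthetic",
                        pick[seq_len(tag_size)],
                        pick[tag_size + seq_len(tag_size)])
  hsc <- gene_signature("HSC_synthetic",
                        pick[2 * tag_size + seq_len(tag_size)],
                        pick[3 * tag_size + seq_len(tag_size)])
  comps <- sprintf("cmpd_%03d", seq_len(n_compounds))
  planted <- comps[seq_len(n_planted)]
  sim <- simulate_rank_matrix(
    n_probes,
    setNames(rep(instances_per_compound, n_compounds), comps),
    signature = lsc,
    effects = lapply(planted, planted_effect, strength = strength,
                     direction = "invert"),
    seed = seed, probe_ids = probe_ids)
  c(sim, list(lsc_signature = lsc, hsc_signature = hsc))
}

fourpl <- function(d, top, bottom, hill, lc50) {
  bottom + (top - bottom) / (1 + (d / lc50)^hill)
}

#' Simulate a multi-population viability screen
#'
#' Viable-cell counts follow known four-parameter logistic curves:
#' `count = control_count * v(dose) * (1 + eps)` with
#' `eps ~ Normal(0, noise_sd)`, truncated at 0. Vehicle-control replicates
#' (same multiplicative noise around `control_count`) are included for every
#' population. The manifest records each compound's true per-population
#' curves and the true category obtained by applying the hit rules to the
#' noiseless curves at the design doses.
#'
#' @param design data.frame with columns `compound`, `population`, `top`,
#'   `bottom`, `hill`, `lc50` (one row per compound x population).
#' @param doses treatment doses (default the screen design 2.5/5/10).
#' @param replicates treated replicates per cell (default 2, duplicate
#'   wells).
#' @param noise_sd multiplicative noise s.d. (default 0.05).
#' @param control_count vehicle mean count (default 10000).
#' @param control_replicates vehicle replicates per population (default 2).
#' @param seed integer seed.
#' @param unit dose unit label (default `"uM"`).
#' @param lsc_population,blast_population labels used for the manifest's
#'   true categories.
#' @return list with `screen_table` (long-format data.frame) and `manifest`
#'   (list: `seed`, `true_categories` data.frame, `design`).
#' @export
simulate_screen <- function(design, doses = c(2.5, 5, 10), replicates = 2,
                            noise_sd = 0.05, control_count = 10000,
                            control_replicates = 2, seed = 1, unit = "uM",
                            lsc_population = "CD34+CD38-",
                            blast_population = "CD15+") {
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  assert_that(all(doses > 0), "doses must be positive")
  need <- c("compound", "population", "top", "bottom", "hill", "lc50")
  assert_that(all(need %in% names(design)), "design lacks required columns")

  comps <- unique(design$compound)
  pops <- unique(design$population)
  rows <- vector("list", length(comps) + 1L)

  set.seed(substream_seed(seed, 0))
  ctrl <- expand.grid(population = pops,
                      replicate = seq_len(control_replicates),
                      stringsAsFactors = FALSE)
  ctrl_counts <- pmax(control_count * (1 + rnorm(nrow(ctrl), 0, noise_sd)), 0)
  rows[[1]] <- data.frame(compound = "DMSO", dose = 0, unit = unit,
                          population = ctrl$population,
                          replicate = ctrl$replicate,
                          count = ctrl_counts, is_control = TRUE,
                          stringsAsFactors = FALSE)

  for (ci in seq_along(comps)) {
    set.seed(substream_seed(seed, ci))
    sub <- design[design$compound == comps[ci], , drop = FALSE]
    grid <- expand.grid(i = seq_len(nrow(sub)), dose = doses,
                        replicate = seq_len(replicates))
    v <- fourpl(grid$dose, sub$top[grid$i], sub$bottom[grid$i],
                sub$hill[grid$i], sub$lc50[grid$i])
    counts <- pmax(control_count * v * (1 + rnorm(nrow(grid), 0, noise_sd)), 0)
    rows[[ci + 1L]] <- data.frame(compound = comps[ci], dose = grid$dose,
                                  unit = unit,
                                  population = sub$population[grid$i],
                                  replicate = grid$replicate,
                                  count = counts, is_control = FALSE,
                                  stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)

  # manifest truth: hit rules applied to the noiseless curves
  grid <- expand.grid(i = seq_len(nrow(design)), dose = doses)
  true_rel <- data.frame(compound = design$compound[grid$i],
                         dose = grid$dose,
                         population = design$population[grid$i],
                         rel_viability = fourpl(grid$dose, design$top[grid$i],
                                                design$bottom[grid$i],
                                                design$hill[grid$i],
                                                design$lc50[grid$i]),
                         stringsAsFactors = FALSE)
  truth <- categorize_compounds(call_hits(true_rel),
                                lsc_population, blast_population)
  list(screen_table = validate_screen_table(tab),
       manifest = list(seed = seed, true_categories = truth, design = design))
}

#' Default synthetic screen design
#'
#' Emulates a realistic screen composition: 84 compounds at doses
#' 2.5/5/10 in duplicate across four populations (bulk, CD34+CD38-,
#' CD34+CD38+, CD15+), of which 30 are pan-toxic (category 1), 15
#' LSC-preferential (category 2: the CD34+ compartments are sensitive,
#' bulk and CD15+ blasts are not), 3 differentiation-inducing (category 3:
#' CD15+ blasts expand at least 1.5-fold, nothing else is called) and 36
#' inactive. Curve parameters are drawn per seed from category-specific
#' log-uniform LC50 windows chosen to keep the noiseless curves clear of the
#' +/-50 percent call boundaries at the design doses.
#'
#' @param seed integer seed.
#' @param n_cat1,n_cat2,n_cat3,n_inactive compound counts per true pattern.
#' @return data.frame usable as the `design` of [simulate_screen()].
#' @export
default_screen_design <- function(seed = 1, n_cat1 = 30, n_cat2 = 15,
                                  n_cat3 = 3, n_inactive = 36) {
  pops <- c("bulk", "CD34+CD38-", "CD34+CD38+", "CD15+")
  set.seed(substream_seed(seed, 997))
  n_total <- n_cat1 + n_cat2 + n_cat3 + n_inactive
  comps <- sprintf("drug_%03d", seq_len(n_total))
  kind <- rep(c("cat1", "cat2", "cat3", "inactive"),
              c(n_cat1, n_cat2, n_cat3, n_inactive))

  lu <- function(k, lo, hi) exp(runif(k, log(lo), log(hi)))
  rows <- lapply(seq_len(n_total), function(i) {
    h <- runif(4, 1.5, 3)
    lc50 <- switch(kind[i],
      cat1 = lu(4, 0.3, 1.2),
      cat2 = ifelse(pops %in% c("CD34+CD38-", "CD34+CD38+"),
                    lu(4, 0.3, 1.2), lu(4, 40, 100)),
      cat3 = lu(4, 300, 1000),
      inactive = lu(4, 300, 1000))
    top <- rep(1, 4)
    bottom <- rep(0, 4)
    if (kind[i] == "cat3") {
      # blast expansion: viability rises toward 2.2x with dose
      blast <- pops == "CD15+"
      bottom[blast] <- 2.2
      lc50[blast] <- lu(1, 0.5, 1.5)
    }
    data.frame(compound = comps[i], population = pops, top = top,
               bottom = bottom, hill = h, lc50 = lc50,
               true_pattern = kind[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
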