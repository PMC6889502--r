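#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{v(d) = bottom + (top - bottom) / (1 + (d / lc50)^{hill})}
#' to relative viabilities, parameterised in log10 dose and solved with
#' bounded Levenberg-Marquardt (minpack.lm), with multistart initialisation
#' of the LC50 across the dose range. Bounds: top in [0, 2], bottom in
#' [0, 1], hill in [0.2, 10]. With fewer than 4 distinct doses the
#' asymptotes are fixed at top = 1 and bottom = 0 (viability anchored at
#' vehicle) and only hill and LC50 are fitted.
#'
#' The LC50 is flagged `extrapolated` when it falls outside
#' `[min dose / 10, max dose * 10]` or when the fitted span
#' `|top - bottom|` is below 0.05 (no measurable effect to locate an LC50
#' on). A numerically constant response is reported directly as a flat
#' converged fit (`top = bottom = mean`, LC50 undefined and flagged).
#'
#' @param dose numeric vector of doses (> 0); replicate observations are
#'   passed as repeated doses.
#' @param rel_viability numeric vector of DMSO-relative viabilities.
#' @param n_starts number of LC50 multistarts (default 5).
#' @return object of class `dose_response_fit`: list with `top`, `bottom`,
#'   `hill`, `lc50`, `rss`, `converged`, `extrapolated`, `n_obs`,
#'   `dose_range`, `reduced` (TRUE when asymptotes were fixed).
#' @export
fit_dose_response <- function(dose, rel_viability, n_starts = 5) {
  assert_that(length(dose) == length(rel_viability),
              "dose and rel_viability lengths differ")
  assert_that(all(dose > 0), "doses must be positive")
  assert_that(all(is.finite(rel_viability)), "viabilities must be finite")
  nd <- length(unique(dose))
  assert_that(nd >= 2, "need at least 2 distinct doses")
  reduced <- nd < 4

  # a (numerically) constant response carries no dose information: report an
  # honest flat fit rather than letting the optimiser chase a singular model
  if (diff(range(rel_viability)) < 1e-6) {
    m <- mean(rel_viability)
    return(structure(list(top = m, bottom = m, hill = NA_real_,
                          lc50 = NA_real_,
                          rss = sum((rel_viability - m)^2),
                          converged = TRUE, extrapolated = TRUE,
                          n_obs = length(dose), dose_range = range(dose),
                          reduced = reduced),
                     class = "dose_response_fit"))
  }

  ld <- log10(dose)
  dat <- data.frame(ld = ld, v = rel_viability)
  lo_l <- min(ld) - 2
  hi_l <- max(ld) + 2
  start_l <- seq(min(ld), max(ld), length.out = n_starts)

  fits <- list()
  for (s in start_l) {
    fit <- tryCatch({
      if (reduced) {
        minpack.lm::nlsLM(
          v ~ 1 / (1 + 10^(hill * (ld - loglc50))),
          data = dat,
          start = list(hill = 1, loglc50 = s),
          lower = c(hill = 0.2, loglc50 = lo_l),
          upper = c(hill = 10, loglc50 = hi_l),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          v ~ bottom + (top - bottom) / (1 + 10^(hill * (ld - loglc50))),
          data = dat,
          start = list(top = min(max(max(rel_viability) + 0.1, 0.6), 2),
                       bottom = max(min(min(rel_viability) - 0.1, 0.9), 0),
                       hill = 1, loglc50 = s),
          lower = c(top = 0, bottom = 0, hill = 0.2, loglc50 = lo_l),
          upper = c(top = 2, bottom = 1, hill = 10, loglc50 = hi_l),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  assert_that(length(fits) > 0 || TRUE, "")  # fall through to honest failure
  if (length(fits) == 0) {
    out <- list(top = NA_real_, bottom = NA_real_, hill = NA_real_,
                lc50 = NA_real_, rss = NA_real_, converged = FALSE,
                extrapolated = TRUE, n_obs = length(dose),
                dose_range = range(dose), reduced = reduced)
    return(structure(out, class = "dose_response_fit"))
  }
  rss <- vapply(fits, function(f) sum(resid(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- coef(best)
  top <- if (reduced) 1 else unname(cf["top"])
  bottom <- if (reduced) 0 else unname(cf["bottom"])
  lc50 <- 10^unname(cf["loglc50"])
  extrapolated <- lc50 < min(dose) / 10 || lc50 > max(dose) * 10 ||
    abs(top - bottom) < 0.05
  structure(list(top = top, bottom = bottom, hill = unname(cf["hill"]),
                 lc50 = lc50, rss = min(rss),
                 converged = best$convInfo$isConv %||% TRUE,
                 extrapolated = extrapolated, n_obs = length(dose),
                 dose_range = range(dose), reduced = reduced),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("4PL fit: top=%.3f bottom=%.3f hill=%.2f LC50=%.4g ",
                     "(rss=%.3g, converged=%s%s)\n"),
              x$top, x$bottom, x$hill, x$lc50, x$rss, x$converged,
              if (x$extrapolated) ", extrapolated" else ""))
  invisible(x)
}

#' LC50 selectivity ratio between two dose-response fits
#'
#' `ratio = lc50_b / lc50_a`, with `a` the population of interest (e.g. AML)
#' and `b` the comparator (e.g. normal cord blood); a ratio above 1 means
#' the compound is selective for `a` (kills it at lower concentration).
#'
#' @param fit_a,fit_b converged [fit_dose_response()] objects.
#' @return numeric selectivity ratio.
#' @export
selectivity_ratio <- function(fit_a, fit_b) {
  assert_that(isTRUE(fit_a$converged), "fit_a did not converge")
  assert_that(isTRUE(fit_b$converged), "fit_b did not converge")
  fit_b$lc50 / fit_a$lc50
}

#' Fit dose-response curves for every (compound, population) stratum
#'
#' @param rel data.frame from [normalize_to_control()].
#' @param min_doses strata with fewer distinct doses are skipped.
#' @return data.frame with one row per stratum: `compound`, `population`,
#'   `top`, `bottom`, `hill`, `lc50`, `rss`, `converged`, `extrapolated`.
#' @export
fit_screen_curves <- function(rel, min_doses = 2) {
  key <- unique(rel[, c("compound", "population")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sub <- rel[rel$compound == key$compound[i] &
               rel$population == key$population[i], , drop = FALSE]
    if (length(unique(sub$dose)) < min_doses) return(NULL)
    f <- fit_dose_response(sub$dose, sub$rel_viability)
    data.frame(compound = key$compound[i], population = key$population[i],
               top = f$top, bottom = f$bottom, hill = f$hill, lc50 = f$lc50,
               rss = f$rss, converged = f$converged,
               extrapolated = f$extrapolated, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
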