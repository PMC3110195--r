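#' Conformer pool for population estimation
#'
#' Energies of conformers pooled from several models (the reference
#' analysis pools 500 conformers from each of 6 models, 3000 in total).
#'
#' @param energies tibble or data frame with columns `model` (label) and
#'   `energy` (kcal/mol), or a named list of numeric energy vectors.
#' @param temperature Kelvin.
#' @return An `ab_conformer_pool` tibble (`model`, `energy`) with a
#'   `temperature` attribute.
#' @export
conformer_pool <- function(energies, temperature = 330) {
  if (is.list(energies) && !is.data.frame(energies)) {
    energies <- tibble(model = rep(names(energies), lengths(energies)),
                       energy = unlist(energies, use.names = FALSE))
  }
  if (!all(c("model", "energy") %in% names(energies))) {
    abort("conformer pool needs columns 'model' and 'energy'")
  }
  if (nrow(energies) == 0) abort("conformer pool is empty")
  if (!all(is.finite(energies$energy))) abort("all conformer energies must be finite")
  out <- as_tibble(energies[, c("model", "energy")])
  attr(out, "temperature") <- temperature
  class(out) <- c("ab_conformer_pool", class(out))
  out
}

#' Estimate per-model ensemble populations
#'
#' Boltzmann weighting at the pool temperature (energies shifted by the
#' pool minimum for numerical stability): the population of a model is
#' the summed weight `exp(-E/kT)` of its conformers over the pooled
#' total. The `"metropolis"` method is a literal Monte Carlo reading of
#' the same quantity: a long single-chain random walk over conformer
#' indices with uniform proposals and Metropolis acceptance, reporting
#' per-model visit fractions; it converges to the Boltzmann result.
#' Populations are invariant under adding a constant to all energies and
#' sum to 100 percent.
#'
#' @param pool an [conformer_pool()] (or data frame with `model`,
#'   `energy`).
#' @param method `"boltzmann"` (default) or `"metropolis"`.
#' @param temperature Kelvin; defaults to the pool's attribute (330).
#' @param n_steps Metropolis chain length.
#' @param seed Metropolis seed.
#' @return A tibble `model`, `population_pct` (summing to 100).
#' @export
estimate_populations <- function(pool, method = c("boltzmann", "metropolis"),
                                 temperature = NULL, n_steps = 1e5, seed = 1L) {
  method <- match.arg(method)
  if (!inherits(pool, "ab_conformer_pool")) pool <- conformer_pool(pool)
  temperature <- temperature %||% attr(pool, "temperature") %||% 330
  kT <- .kB * temperature
  models <- unique(pool$model)
  if (method == "boltzmann") {
    w <- exp(-(pool$energy - min(pool$energy)) / kT)
    pct <- vapply(models, function(m) sum(w[pool$model == m]), numeric(1))
    pct <- 100 * pct / sum(pct)
  } else {
    e <- pool$energy
    nconf <- length(e)
    visits <- withr::with_seed(seed, {
      cur <- sample.int(nconf, 1)
      prop <- sample.int(nconf, n_steps, replace = TRUE)
      u <- stats::runif(n_steps)
      v <- integer(nconf)
      for (s in seq_len(n_steps)) {
        j <- prop[s]
        if (u[s] < exp(-(e[j] - e[cur]) / kT)) cur <- j
        v[cur] <- v[cur] + 1L
      }
      v
    })
    pct <- vapply(models, function(m) sum(visits[pool$model == m]), numeric(1))
    pct <- 100 * pct / sum(pct)
  }
  tibble(model = models, population_pct = unname(pct))
}

#' Format a population table
#'
#' Mirrors the layout of a per-model summary table: one row per model in
#' the declared order, with populations printed to one decimal and a
#' `"/"` entry for models excluded from the pooled estimate (as done for
#' mutant models that are not part of the wild-type ensemble).
#'
#' @param estimates output of [estimate_populations()].
#' @param models row order; defaults to the estimate's models followed
#'   by the excluded ones.
#' @param exclude model labels shown as `"/"`.
#' @return A tibble `model`, `population_pct` (numeric, `NA` when
#'   excluded), `population` (formatted text).
#' @export
population_report <- function(estimates, models = NULL, exclude = character()) {
  models <- models %||% c(estimates$model, exclude)
  pct <- estimates$population_pct[match(models, estimates$model)]
  pct[models %in% exclude] <- NA_real_
  tibble(model = models,
         population_pct = pct,
         population = ifelse(is.na(pct), "/", sprintf("%.1f", pct)))
}
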