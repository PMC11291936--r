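#' Mean population stress
#'
#' Arithmetic mean of individual stress values
#' \eqn{\sum_i \rho(x_i) / N}; 0 for a perfectly adapted population,
#' rising whenever the environment jumps away from the phenotypes.
#'
#' @param x A developed [found_cohort()] cohort, or a numeric vector of
#'   developed phenotypes.
#' @param p Environmental parameter.
#' @param gamma Stress tolerance.
#' @return Mean stress in `[0, 1)`; `NA` for an empty population.
#' @export
population_stress <- function(x, p, gamma = 2.2) {
  if (inherits(x, "plast_cohort")) x <- x$x
  if (length(x) == 0L) return(NA_real_)
  mean(stress(x, p, gamma))
}

#' Genetic load of a population
#'
#' Load is measured on fitnesses *without epigenetic alterations*: every
#' individual's phenotype is recomputed with all plastic loci active, fitness
#' is evaluated for each at the shared current population size and
#' environment, and the load is
#' \deqn{(W^o_{max} - \bar W^o) / W^o_{max},}
#' regardless of whether the best unaltered genotype is actually adequate in
#' the current environment. A large load means the population carries many
#' sub-optimal genotypes shielded from selection — here, shielded by
#' developmental plasticity.
#'
#' @param cohort A [found_cohort()] cohort.
#' @param p Environmental parameter.
#' @param N_eval Population size at which fitness is evaluated (defaults to
#'   the cohort size).
#' @param params A [selection_params()].
#' @return The load, or `NA` (flagged undefined) when the maximum unaltered
#'   fitness is not positive or the population is empty.
#' @export
genetic_load <- function(cohort, p, N_eval = cohort$n,
                         params = selection_params()) {
  stopifnot(inherits(cohort, "plast_cohort"))
  if (cohort$n == 0L) return(NA_real_)
  x_o <- cohort_phenotypes_unaltered(cohort)
  W_o <- fitness(x_o, cohort$omega, N_eval, p, params)
  w_max <- max(W_o)
  if (w_max <= 0) return(NA_real_)
  (w_max - mean(W_o)) / w_max
}

#' Developmental phenotype-variance ratio
#'
#' Ratio of end-of-development to start-of-development sums of squared
#' deviations from the respective cohort means,
#' \deqn{V_\tau/V_0 = \frac{\sum_i (x_{i,\tau} - \bar x_\tau)^2}
#'                         {\sum_i (x_{i,0} - \bar x_0)^2}.}
#' Values below 1 diagnose canalization (heterogeneous genotypes converging
#' on similar phenotypes); values above 1 indicate that epimutations are so
#' frequent that development releases rather than removes phenotypic
#' variance. Both vectors come from the same generation's cohort, so lengths
#' always match; raw sums are used, and since the same `N` appears in
#' numerator and denominator the ratio equals the ratio of sample variances.
#'
#' @param x_start Phenotypes before development.
#' @param x_end Phenotypes after development (same length, >= 2).
#' @return The ratio, or `NA` (flagged undefined) when the pre-development
#'   variance is zero.
#' @export
variance_ratio <- function(x_start, x_end) {
  if (length(x_start) != length(x_end)) {
    stop("x_start and x_end must have the same length", call. = FALSE)
  }
  if (length(x_start) < 2L) return(NA_real_)
  v0 <- sum((x_start - mean(x_start))^2)
  if (v0 == 0) return(NA_real_)
  sum((x_end - mean(x_end))^2) / v0
}

#' Per-generation summary record
#'
#' Collects the standard per-generation metrics for a developed cohort:
#' size, mean stress, genetic load, variance ratio across its development,
#' sensitivity-trait and neutral-marker summaries. The neutral-marker
#' sensitivity analogue `neutral_omega` (what omega would be if the neutral
#' alleles encoded it) is the drift null against which selection on the
#' sensitivity trait is judged.
#'
#' @param developed The cohort after development.
#' @param dev The `"plast_development"` result it came from (for the
#'   start/end phenotypes), or `NULL` to skip the variance ratio.
#' @param p Environmental parameter of the generation.
#' @param params A [selection_params()].
#' @return A one-row data.frame with columns `p`, `N`, `mean_stress`,
#'   `genetic_load`, `variance_ratio`, `mean_omega`, `sd_omega`,
#'   `mean_neutral`, `sd_neutral`, `neutral_omega`.
#' @export
generation_record <- function(developed, dev, p, params = selection_params()) {
  nu_trait <- rowSums(developed$nu)
  data.frame(
    p = p,
    N = developed$n,
    mean_stress = population_stress(developed, p, params$gamma),
    genetic_load = genetic_load(developed, p, developed$n, params),
    variance_ratio = if (is.null(dev)) NA_real_
                     else variance_ratio(dev$x_start, dev$x_end),
    mean_omega = mean(developed$omega),
    sd_omega = stats::sd(developed$omega),
    mean_neutral = mean(nu_trait),
    sd_neutral = stats::sd(nu_trait),
    neutral_omega = mean(cohort_neutral_omega(developed))
  )
}
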