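#' Selection and reproduction parameters
#'
#' Bundles the parameters of the fitness function and of inheritance.
#' Defaults are the simulator's standard parameterization: intrinsic
#' reproduction factor `R = 1`, carrying capacity `K = 1000`, stress
#' tolerance `gamma = 2.2`, no plasticity cost, allelic mutation rate
#' `1e-4` per locus per generation with unit-sd mutational effects.
#'
#' @param R Positive intrinsic reproduction factor.
#' @param K Positive carrying capacity: the population size above which
#'   baseline fitness drops below `R`.
#' @param gamma Positive stress tolerance (inflection scale of [stress()]);
#'   small values mean strong selection.
#' @param C Non-negative fitness cost per unit of sensitivity trait.
#' @param mu_m Allelic mutation rate per locus per generation, in `[0, 1]`;
#'   shared by all allele types.
#' @param sigma_m Non-negative sd of (normal, zero-mean) mutational effects.
#' @param lambda_mu_m Optional separate mutation rate for the sensitivity
#'   locus (default `NULL`: same as `mu_m`). Setting it to 0 freezes the
#'   sensitivity trait while everything else evolves.
#' @return A list of class `"selection_params"`.
#' @export
selection_params <- function(R = 1, K = 1000, gamma = 2.2, C = 0,
                             mu_m = 1e-4, sigma_m = 1, lambda_mu_m = NULL) {
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (K <= 0) stop("K must be > 0", call. = FALSE)
  if (R <= 0) stop("R must be > 0", call. = FALSE)
  if (C < 0) stop("C must be >= 0", call. = FALSE)
  if (mu_m < 0 || mu_m > 1) stop("mu_m must be in [0, 1]", call. = FALSE)
  if (sigma_m < 0) stop("sigma_m must be >= 0", call. = FALSE)
  if (!is.null(lambda_mu_m) && (lambda_mu_m < 0 || lambda_mu_m > 1)) {
    stop("lambda_mu_m must be in [0, 1]", call. = FALSE)
  }
  structure(list(R = R, K = K, gamma = gamma, C = C,
                 mu_m = mu_m, sigma_m = sigma_m, lambda_mu_m = lambda_mu_m),
            class = "selection_params")
}

#' Individual stress from phenotype-environment mismatch
#'
#' \deqn{\rho(x) = 1 - \exp\left(-\tfrac12 \left(\frac{x - p}{\gamma}\right)^2\right).}
#' Stress is 0 at a perfect match, increases monotonically with `|x - p|`
#' and is bounded above by 1 (asymptote). `gamma` sets the tolerance: small
#' gamma means strong selection.
#'
#' @param x Phenotype(s) at the end of development.
#' @param p Environmental parameter of the current generation.
#' @param gamma Positive stress tolerance (default 2.2).
#' @return Stress values in `[0, 1)`, vectorized.
#' @export
stress <- function(x, p, gamma = 2.2) {
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  -expm1(-0.5 * ((x - p) / gamma)^2)
}

#' Density-dependent individual fitness
#'
#' \deqn{W(x, \omega, N) = (1 - \rho(x)) \, R \, e^{1 - N/K} - \omega C.}
#' The `R exp(1 - N/K)` factor is the density-dependent baseline (equal to
#' `R` at `N = K`), depressed by stress; plastic individuals additionally
#' pay a cost `C` per unit of sensitivity. Fitness enters reproduction as an
#' individual's contribution to its pair's expected offspring number, and can
#' be negative when `C > 0` (pair rates are clamped at 0 by
#' [form_pairs()]).
#'
#' @param x Developed phenotype(s).
#' @param omega Sensitivity value(s).
#' @param N Population size at evaluation (the parental generation's size).
#' @param p Environmental parameter.
#' @param params A [selection_params()].
#' @return Fitness values, vectorized.
#' @export
fitness <- function(x, omega, N, p, params = selection_params()) {
  if (any(N < 1)) stop("N must be >= 1", call. = FALSE)
  (1 - stress(x, p, params$gamma)) * params$R * exp(1 - N / params$K) -
    omega * params$C
}

#' Assign sexes for one generation
#'
#' Sexes are a per-generation population operation: individuals are randomly
#' permuted and the first `floor(n/2)` labelled male, the remaining
#' `n - floor(n/2)` female.
#'
#' @param n Population size.
#' @return Character vector of `"M"`/`"F"`.
#' @export
assign_sexes <- function(n) {
  sex <- rep("F", n)
  m <- n %/% 2L
  if (m > 0) sex[sample.int(n, n)[seq_len(m)]] <- "M"
  sex
}

#' Form mating pairs and their reproduction rates
#'
#' Each female mates exactly once with a male drawn uniformly at random with
#' replacement (males can mate repeatedly). A pair's offspring count is
#' Poisson with rate `max(0, W_female + W_male)`; the clamp ensures a valid
#' rate when plasticity costs push fitness negative, reading as "no
#' reproduction".
#'
#' @param sex Character vector of `"M"`/`"F"` (from [assign_sexes()]).
#' @param W Fitness vector aligned with `sex`.
#' @return A data.frame with columns `mother`, `father` (indices) and `rate`.
#'   Zero rows when either sex is absent — the population then goes extinct
#'   at the reproduction step.
#' @export
form_pairs <- function(sex, W) {
  stopifnot(length(sex) == length(W))
  mothers <- which(sex == "F")
  males <- which(sex == "M")
  if (length(mothers) == 0L || length(males) == 0L) {
    return(data.frame(mother = integer(0), father = integer(0),
                      rate = numeric(0)))
  }
  fathers <- males[sample.int(length(males), length(mothers), replace = TRUE)]
  data.frame(mother = mothers, father = fathers,
             rate = pmax(0, W[mothers] + W[fathers]))
}

# Mendelian draw: for each offspring o and locus j, one allele chosen
# uniformly from parent idx[o]'s copies at locus j, independently across loci
# (free recombination, no linkage).
inherit_haplotype <- function(arr, idx) {
  n_off <- length(idx)
  L <- dim(arr)[2]
  c1 <- matrix(arr[idx, , 1], n_off, L)
  c2 <- matrix(arr[idx, , 2], n_off, L)
  pick <- matrix(stats::runif(n_off * L) < 0.5, n_off, L)
  out <- c2
  out[pick] <- c1[pick]
  out
}

# Add N(0, sigma_m) to each entry independently with probability mu_m.
# Skips all RNG draws when mu_m = 0 so that zero-rate components leave the
# random stream untouched.
mutate_values <- function(m, mu_m, sigma_m) {
  if (mu_m <= 0 || length(m) == 0L) return(m)
  hit <- stats::runif(length(m)) < mu_m
  if (any(hit)) m[hit] <- m[hit] + stats::rnorm(sum(hit), 0, sigma_m)
  m
}

#' Create offspring from parent pairs
#'
#' For each entry of `mothers`/`fathers` one offspring is produced. At every
#' locus (response, sensitivity, neutral) the offspring inherits one allele
#' copy per parent, chosen uniformly from that parent's two copies,
#' independently across loci (no linkage). Each transmitted allele copy then
#' mutates with probability `mu_m`, adding a `N(0, sigma_m^2)` deviate.
#' Offspring are born with all plastic loci active and their sensitivity
#' recomputed from the inherited lambda alleles; sexes are assigned at the
#' population level each generation, not at birth.
#'
#' When the cohort runs with a fixed sensitivity value, the lambda locus is
#' inert: inherited unchanged with no mutation draws.
#'
#' @param cohort Parental [found_cohort()] cohort (diploid).
#' @param mothers,fathers Equal-length integer vectors of parent indices,
#'   one offspring per entry.
#' @param params A [selection_params()].
#' @return The offspring cohort (`n = length(mothers)`), undeveloped.
#' @export
make_offspring <- function(cohort, mothers, fathers,
                           params = selection_params()) {
  stopifnot(inherits(cohort, "plast_cohort"), cohort$ploidy == 2L,
            length(mothers) == length(fathers))
  n_off <- length(mothers)
  off <- cohort
  if (n_off == 0L) return(empty_cohort(cohort))

  mum <- params$mu_m
  sdm <- params$sigma_m
  lam_mu <- if (!is.null(cohort$fixed_omega)) 0
            else if (!is.null(params$lambda_mu_m)) params$lambda_mu_m
            else mum

  hm <- mutate_values(inherit_haplotype(cohort$resp, mothers), mum, sdm)
  hf <- mutate_values(inherit_haplotype(cohort$resp, fathers), mum, sdm)
  off$resp <- array(c(hm, hf), dim = c(n_off, cohort$L, 2L))

  lam3 <- array(cohort$lam, dim = c(cohort$n, 1L, 2L))
  nu3 <- array(cohort$nu, dim = c(cohort$n, 1L, 2L))
  off$lam <- cbind(
    mutate_values(inherit_haplotype(lam3, mothers), lam_mu, sdm),
    mutate_values(inherit_haplotype(lam3, fathers), lam_mu, sdm)
  )
  off$nu <- cbind(
    mutate_values(inherit_haplotype(nu3, mothers), mum, sdm),
    mutate_values(inherit_haplotype(nu3, fathers), mum, sdm)
  )

  off$n <- n_off
  off$tags <- matrix(1, n_off, cohort$L - cohort$B)
  off$omega <- cohort_omega(off)
  off$x <- cohort_phenotypes(off)
  off
}

# Clonal reproduction for the haploid asexual mode: each parent produces
# Poisson(max(0, 2 W)) offspring, matching the per-capita expectation of the
# diploid two-parent rate structure.
make_offspring_haploid <- function(cohort, parents, params) {
  n_off <- length(parents)
  off <- cohort
  if (n_off == 0L) return(empty_cohort(cohort))
  mum <- params$mu_m
  sdm <- params$sigma_m
  lam_mu <- if (!is.null(cohort$fixed_omega)) 0
            else if (!is.null(params$lambda_mu_m)) params$lambda_mu_m
            else mum
  off$resp <- array(
    mutate_values(matrix(cohort$resp[parents, , 1], n_off, cohort$L), mum, sdm),
    dim = c(n_off, cohort$L, 1L)
  )
  off$lam <- matrix(mutate_values(cohort$lam[parents, 1], lam_mu, sdm), n_off, 1L)
  off$nu <- matrix(mutate_values(cohort$nu[parents, 1], mum, sdm), n_off, 1L)
  off$n <- n_off
  off$tags <- matrix(1, n_off, cohort$L - cohort$B)
  off$omega <- cohort_omega(off)
  off$x <- cohort_phenotypes(off)
  off
}

#' Advance a population by one generation
#'
#' One full generation: (1) the (newborn) cohort develops for `tau` days
#' under the environment `p`; (2) fitness is evaluated on post-development
#' phenotypes at the parental population size `N`; (3) sexes are assigned by
#' random permutation (`floor(N/2)` males); (4) each female is paired with a
#' random male and the pair's offspring number is drawn from
#' Poisson(max(0, W_f + W_m)); (5) offspring entirely replace the parents.
#' Generations are non-overlapping; the population is extinct when the total
#' offspring count is zero (or when a sex is missing). Haploid cohorts
#' reproduce clonally with per-individual rate `max(0, 2 W)`.
#'
#' @param cohort The newborn parental cohort.
#' @param p Environmental parameter of this generation.
#' @param params A [selection_params()].
#' @param tau Development time in days.
#' @return A list with elements `cohort` (next generation, newborn),
#'   `developed` (the parental cohort after development), `record` (a
#'   one-row data.frame of [generation_record()] metrics for the parental
#'   generation) and `extinct` (TRUE when the next generation is empty).
#' @export
advance_generation <- function(cohort, p, params = selection_params(),
                               tau = 33) {
  stopifnot(inherits(cohort, "plast_cohort"))
  if (cohort$n == 0L) {
    return(list(cohort = cohort, developed = cohort, record = NULL,
                extinct = TRUE))
  }
  n <- cohort$n
  dev <- develop(cohort, p, tau = tau)
  ch <- dev$cohort
  W <- fitness(ch$x, ch$omega, n, p, params)
  rec <- generation_record(ch, dev, p, params)

  if (ch$ploidy == 2L) {
    sex <- assign_sexes(n)
    pairs <- form_pairs(sex, W)
    counts <- if (nrow(pairs) > 0L) stats::rpois(nrow(pairs), pairs$rate)
              else integer(0)
    off <- make_offspring(ch, rep(pairs$mother, counts),
                          rep(pairs$father, counts), params)
  } else {
    counts <- stats::rpois(n, pmax(0, 2 * W))
    off <- make_offspring_haploid(ch, rep(seq_len(n), counts), params)
  }
  list(cohort = off, developed = ch, record = rec, extinct = off$n == 0L)
}
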