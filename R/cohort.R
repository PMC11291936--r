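#' Found a cohort of individuals
#'
#' A cohort is the package's population container: parallel matrices holding,
#' for `n` individuals, the response-trait alleles (`n x L x ploidy` array),
#' the single-locus sensitivity alleles, a neutral marker locus, the
#' per-individual activation tags of the plastic loci, and the derived
#' phenotype `x` and sensitivity `omega`. Individuals are founded (and later
#' born) with every plastic locus active; activation tags are somatic and are
#' never inherited.
#'
#' The sensitivity trait can be genetically encoded (`fixed_omega = NULL`,
#' omega computed from the lambda alleles via [compute_sensitivity()]) or
#' clamped to a common fixed value for the whole cohort (`fixed_omega`
#' numeric), which is how the fixed-plasticity protocols run.
#'
#' @param n Number of individuals.
#' @param L,B Number of response loci and of non-plastic loci (`1 <= B <= L`).
#' @param ploidy 1 (haploid, asexual) or 2 (diploid, sexual).
#' @param sigma_G Pre-development trait standard deviation used by the
#'   default allele sampling rule (variance `sigma_G^2/(ploidy*L)` per copy).
#' @param distribution Founder trait shape, see [init_response_alleles()].
#' @param allele_sd Optional per-copy allele sd override.
#' @param s,combination Sensitivity scale and convention, see
#'   [compute_sensitivity()].
#' @param fixed_omega If non-NULL, all individuals share this sensitivity
#'   value and the lambda alleles are inert (not mutated).
#' @param lambda_init,nu_init Initial allelic values of the sensitivity and
#'   neutral loci (default 0, the non-plastic founding condition).
#' @return An object of class `"plast_cohort"`.
#' @export
found_cohort <- function(n, L = 10, B = 1, ploidy = 2, sigma_G = 1,
                         distribution = "normal", allele_sd = NULL,
                         s = 42, combination = "divide",
                         fixed_omega = NULL, lambda_init = 0, nu_init = 0) {
  B <- as.integer(B)
  L <- as.integer(L)
  if (B < 1L || B > L) stop("need 1 <= B <= L", call. = FALSE)
  if (!ploidy %in% c(1, 2)) stop("ploidy must be 1 or 2", call. = FALSE)
  resp <- init_response_alleles(n, L, sigma_G = sigma_G,
                                distribution = distribution,
                                ploidy = ploidy, allele_sd = allele_sd)
  ch <- structure(
    list(
      resp  = resp,
      lam   = matrix(lambda_init, n, ploidy),
      nu    = matrix(nu_init, n, ploidy),
      tags  = matrix(1, n, L - B),
      x     = numeric(n),
      omega = numeric(n),
      n = as.integer(n), L = L, B = B, ploidy = as.integer(ploidy),
      s = s, combination = combination, fixed_omega = fixed_omega
    ),
    class = "plast_cohort"
  )
  ch$omega <- cohort_omega(ch)
  ch$x <- cohort_phenotypes(ch)
  ch
}

#' @export
print.plast_cohort <- function(x, ...) {
  cat(sprintf(
    "<plast_cohort> n = %d, L = %d (B = %d non-plastic), ploidy = %d, %s\n",
    x$n, x$L, x$B, x$ploidy,
    if (is.null(x$fixed_omega)) "omega encoded"
    else sprintf("omega fixed at %g", x$fixed_omega)
  ))
  if (x$n > 0) {
    cat(sprintf("  mean x = %.4g, mean omega = %.4g\n",
                mean(x$x), mean(x$omega)))
  }
  invisible(x)
}

# n x L matrix of per-locus allele sums (haploid: the single copy).
locus_sums <- function(ch) {
  m <- matrix(ch$resp[, , 1], ch$n, ch$L)
  if (ch$ploidy == 2) m <- m + matrix(ch$resp[, , 2], ch$n, ch$L)
  m
}

# Phenotypes for given tags (default: the cohort's current tags).
cohort_phenotypes <- function(ch, tags = ch$tags) {
  ls <- locus_sums(ch)
  base <- rowSums(ls[, seq_len(ch$B), drop = FALSE])
  np <- ch$L - ch$B
  if (np == 0) return(base)
  base + rowSums(ls[, ch$B + seq_len(np), drop = FALSE] * tags)
}

# All-active phenotypes: the reference state without epigenetic alterations.
cohort_phenotypes_unaltered <- function(ch) {
  rowSums(locus_sums(ch))
}

cohort_omega <- function(ch) {
  if (!is.null(ch$fixed_omega)) return(rep(ch$fixed_omega, ch$n))
  compute_sensitivity(ch$lam, s = ch$s, combination = ch$combination)
}

# Neutral-marker analogue of omega: what the sensitivity trait would be if
# the neutral alleles encoded it. Serves as the drift null for omega.
cohort_neutral_omega <- function(ch) {
  compute_sensitivity(ch$nu, s = ch$s, combination = ch$combination)
}

#' Extract one individual's response genome
#'
#' Convenience accessor returning individual `i`'s alleles as a
#' [response_genome()], e.g. to enumerate its attainable phenotypes.
#'
#' @param cohort A [found_cohort()] cohort.
#' @param i Individual index.
#' @return A `"response_genome"`.
#' @export
cohort_genome <- function(cohort, i) {
  stopifnot(inherits(cohort, "plast_cohort"), i >= 1, i <= cohort$n)
  response_genome(matrix(cohort$resp[i, , ], cohort$L, cohort$ploidy),
                  B = cohort$B)
}

# Empty cohort preserving genome parameters (extinction state).
empty_cohort <- function(template) {
  ch <- template
  ch$resp <- array(numeric(0), dim = c(0, template$L, template$ploidy))
  ch$lam <- matrix(numeric(0), 0, template$ploidy)
  ch$nu <- matrix(numeric(0), 0, template$ploidy)
  ch$tags <- matrix(numeric(0), 0, template$L - template$B)
  ch$x <- numeric(0)
  ch$omega <- numeric(0)
  ch$n <- 0L
  ch
}
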