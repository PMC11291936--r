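#' Construct a multilocus response-trait genome
#'
#' A response genome encodes the single quantitative response trait as `L`
#' additive loci with real-valued alleles (one allele per locus per parental
#' copy). The first `B` loci are non-plastic and always expressed; the
#' remaining `L - B` loci are plastic, i.e. their contribution is gated by
#' per-individual activation tags that can flip during development (see
#' [develop()]). Allele values are unbounded reals; no clipping is applied
#' anywhere in the package.
#'
#' @param alleles Numeric matrix of allele values with `L` rows (loci) and
#'   `ploidy` columns (parental copies). A numeric vector is taken as a
#'   one-column (haploid) matrix.
#' @param B Integer number of non-plastic loci, `1 <= B <= L`. At least one
#'   locus must be non-plastic so that the trait is defined even when every
#'   plastic locus is silenced.
#' @return An object of class `"response_genome"` with fields `alleles`,
#'   `L`, `B` and `ploidy`.
#' @seealso [compute_phenotype()], [enumerate_attainable_phenotypes()]
#' @examples
#' g <- response_genome(matrix(1, 10, 2), B = 1)
#' compute_phenotype(g, rep(1, 9))
#' @export
response_genome <- function(alleles, B) {
  if (is.vector(alleles) && is.numeric(alleles)) {
    alleles <- matrix(alleles, ncol = 1)
  }
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "double"
  ploidy <- ncol(alleles)
  L <- nrow(alleles)
  if (!ploidy %in% c(1L, 2L)) {
    stop("ploidy (number of allele columns) must be 1 or 2", call. = FALSE)
  }
  if (!all(is.finite(alleles))) {
    stop("allele values must be finite reals", call. = FALSE)
  }
  B <- as.integer(B)
  if (length(B) != 1L || is.na(B) || B < 1L || B > L) {
    stop("B must satisfy 1 <= B <= L (at least one non-plastic locus)",
         call. = FALSE)
  }
  structure(
    list(alleles = alleles, L = L, B = B, ploidy = ploidy),
    class = "response_genome"
  )
}

#' @export
print.response_genome <- function(x, ...) {
  cat(sprintf(
    "<response_genome> L = %d loci (%d non-plastic), ploidy = %d\n",
    x$L, x$B, x$ploidy
  ))
  invisible(x)
}

#' Map a genotype and activation state to the response phenotype
#'
#' The response trait is the sum of per-locus allele sums over the `B`
#' non-plastic loci, plus the allele sums of those plastic loci whose
#' activation tag is 1:
#' \deqn{x = \sum_{j=1}^{B}(l_{j1}+l_{j2}) + \sum_{j=B+1}^{L}(l_{j1}+l_{j2})\,a_j.}
#' For haploid genomes the per-locus sum is the single allele value. The map
#' is deterministic and many-to-one in both directions: distinct genotypes can
#' share a phenotype, and a single genotype attains up to `2^(L-B)` phenotypes
#' across activation states.
#'
#' @param genome A [response_genome()].
#' @param tags Integer/numeric vector of activation tags (0 or 1), one per
#'   plastic locus (length `L - B`). Defaults to all-active, the state in
#'   which every individual is born and the reference state used for genetic
#'   load.
#' @return The phenotype, a single numeric value.
#' @export
compute_phenotype <- function(genome, tags = rep(1, genome$L - genome$B)) {
  stopifnot(inherits(genome, "response_genome"))
  np <- genome$L - genome$B
  if (length(tags) != np) {
    stop(sprintf("tags must have length L - B = %d, got %d", np, length(tags)),
         call. = FALSE)
  }
  if (!all(tags %in% c(0, 1))) {
    stop("activation tags must be 0 or 1", call. = FALSE)
  }
  ls <- rowSums(genome$alleles)
  sum(ls[seq_len(genome$B)]) +
    if (np > 0) sum(ls[genome$B + seq_len(np)] * tags) else 0
}

#' Sensitivity trait from sensitivity-locus alleles
#'
#' The heritable sensitivity trait \eqn{\omega \ge 0} controls how strongly
#' the epimutation rate responds to phenotype-environment mismatch
#' ([epimutation_rate()]); \eqn{\omega = 0} is the non-plastic condition. It
#' is encoded by a single locus with real-valued alleles \eqn{\lambda_k} and
#' computed from \eqn{|\lambda_1 + \lambda_2|} (haploid: \eqn{|\lambda|})
#' together with a positive scale `s` used to calibrate simulations. The
#' default convention divides by `s`, so that with mutational effects of
#' standard deviation 1 a single mutation yields \eqn{\omega \approx 1/42
#' \approx 0.024}, the same order as the moderate sensitivity regime; the
#' alternative conventions are provided for sensitivity analysis.
#'
#' @param lambda Numeric vector of sensitivity alleles (length = ploidy), or
#'   a matrix with one row per individual for vectorized evaluation.
#' @param s Positive scaling parameter (default 42).
#' @param combination How `s` combines with `|sum(lambda)|`: `"divide"`
#'   (default), `"multiply"` or `"power"`.
#' @return Non-negative numeric, one value per individual. Zero iff the
#'   allele sum is zero (for `"power"`, zero is mapped to zero).
#' @export
compute_sensitivity <- function(lambda, s = 42,
                                combination = c("divide", "multiply", "power")) {
  combination <- match.arg(combination)
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0) {
    stop("scale s must be a positive real", call. = FALSE)
  }
  tot <- if (is.matrix(lambda)) rowSums(lambda) else sum(lambda)
  a <- abs(tot)
  switch(combination,
    divide   = a / s,
    multiply = a * s,
    power    = ifelse(a == 0, 0, a^s)
  )
}

#' Enumerate the phenotypes attainable by a genotype
#'
#' Every genotype can express up to `2^(L-B)` distinct phenotypes, one per
#' activation state of its plastic loci: this is the genetic limit of
#' plasticity. The full set is enumerated by accumulating subset sums of the
#' plastic per-locus allele sums over the baseline (non-plastic) value.
#'
#' @param genome A [response_genome()].
#' @param guard Maximum number of plastic loci to enumerate (default 20, i.e.
#'   about one million states); larger genomes are refused.
#' @return Sorted numeric vector of distinct attainable phenotypes. Always
#'   contains the baseline-only (all tags 0) and all-active phenotypes.
#' @examples
#' # all-ones diploid genome with L = 10, B = 1: the even numbers 2..20
#' g <- response_genome(matrix(1, 10, 2), B = 1)
#' enumerate_attainable_phenotypes(g)
#' @export
enumerate_attainable_phenotypes <- function(genome, guard = 20L) {
  stopifnot(inherits(genome, "response_genome"))
  np <- genome$L - genome$B
  if (np > guard) {
    stop(sprintf(
      "refusing to enumerate 2^%d activation states (guard is 2^%d)",
      np, guard
    ), call. = FALSE)
  }
  ls <- rowSums(genome$alleles)
  base <- sum(ls[seq_len(genome$B)])
  sums <- 0
  for (v in ls[genome$B + seq_len(np)]) {
    sums <- c(sums, sums + v)
  }
  sort(unique(base + sums))
}

#' Sample founder response-trait alleles
#'
#' Default (`distribution = "normal"`): alleles are iid normal with mean 0
#' and variance `sigma_G^2 / (ploidy * L)`, so that the all-active trait
#' (the sum over all `ploidy * L` allele copies) has standard deviation
#' `sigma_G` before development. `allele_sd` overrides the per-copy standard
#' deviation directly (e.g. unit-variance alleles for single-generation
#' developmental cohorts).
#'
#' Two non-normal *trait*-shape alternatives are provided for founding
#' cohorts whose pre-development trait distribution is not Gaussian:
#' `"bimodal"` (equal mixture of normals centred at -2 and +2, sd 0.5) and
#' `"asymmetric"` (mean-centred lognormal, `sdlog = 0.6`, right-skewed).
#' Because a sum of iid non-normal alleles is washed towards normality, these
#' shapes are imposed on the trait: target traits are drawn from the named
#' distribution and alleles are constructed as `trait/(ploidy*L)` plus
#' zero-sum jitter, so each individual's all-active trait equals its target
#' exactly while alleles remain heterogeneous.
#'
#' @param n Number of individuals (>= 1).
#' @param L Number of response loci (>= 1).
#' @param sigma_G Positive standard deviation of the all-active trait before
#'   development (ignored when `allele_sd` is given).
#' @param distribution `"normal"`, `"asymmetric"` or `"bimodal"`.
#' @param ploidy 1 or 2.
#' @param allele_sd Optional per-allele-copy standard deviation overriding
#'   the `sigma_G^2/(ploidy*L)` rule (normal sampling only).
#' @return Numeric array of dim `c(n, L, ploidy)`.
#' @export
init_response_alleles <- function(n, L, sigma_G = 1,
                                  distribution = c("normal", "asymmetric", "bimodal"),
                                  ploidy = 2, allele_sd = NULL) {
  distribution <- match.arg(distribution)
  if (n < 1 || L < 1) stop("need n >= 1 and L >= 1", call. = FALSE)
  if (is.null(allele_sd)) {
    if (!is.finite(sigma_G) || sigma_G <= 0) {
      stop("sigma_G must be a positive real", call. = FALSE)
    }
    allele_sd <- sigma_G / sqrt(ploidy * L)
  }
  nc <- L * ploidy
  if (distribution == "normal") {
    return(array(stats::rnorm(n * nc, 0, allele_sd), dim = c(n, L, ploidy)))
  }
  traits <- switch(distribution,
    bimodal = stats::rnorm(n, mean = sample(c(-2, 2), n, replace = TRUE), sd = 0.5),
    asymmetric = stats::rlnorm(n, meanlog = 0, sdlog = 0.6) - exp(0.6^2 / 2)
  )
  alleles_from_traits(traits, L = L, ploidy = ploidy, jitter_sd = allele_sd)
}

# Build an n x L x ploidy allele array whose all-active trait equals `traits`
# exactly: equal share per copy plus per-individual mean-centred jitter.
alleles_from_traits <- function(traits, L, ploidy, jitter_sd) {
  n <- length(traits)
  nc <- L * ploidy
  e <- matrix(stats::rnorm(n * nc, 0, jitter_sd), n, nc)
  e <- e - rowMeans(e)
  array(traits / nc + e, dim = c(n, L, ploidy))
}
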