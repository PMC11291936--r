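#' Worked-example fixture: one genotype, many phenotypes
#'
#' The canonical illustration of a single genotype expressing many
#' phenotypes: a diploid genome with `L = 10` loci (`B = 1` non-plastic) and
#' every allele equal to 1. Depending on the activation states of the 9
#' plastic loci, its phenotype can be any even number from 2 (baseline only)
#' to 20 (all active) — 10 distinct values out of `2^9 = 512` activation
#' states.
#'
#' @return A list with elements `genome` (a [response_genome()]) and
#'   `expected` (the attainable set `seq(2, 20, by = 2)`).
#' @export
fixture_even_numbers <- function() {
  list(
    genome = response_genome(matrix(1, 10, 2), B = 1),
    expected = seq(2, 20, by = 2)
  )
}

#' Worked-example fixture: many genotypes, one phenotype
#'
#' Four diploid genotype variants (`L = 10`, `B = 1`) that all express the
#' phenotype `x = 2` when every locus is active, illustrating the
#' many-to-one direction of the genotype-phenotype map:
#' (a) both alleles equal to 1 at a single locus, all others 0;
#' (b) one allele equal to 1 at each of two loci, all others 0;
#' (c) all `2L` allele copies equal to `1/L`;
#' (d) widely varying positive and negative allele values averaging `1/L`.
#'
#' @return A list of four [response_genome()] objects named `a`-`d`, each
#'   with all-active phenotype 2.
#' @export
fixture_many_to_one <- function() {
  L <- 10
  a <- matrix(0, L, 2); a[1, ] <- 1
  b <- matrix(0, L, 2); b[1, 1] <- 1; b[2, 1] <- 1
  cc <- matrix(1 / L, L, 2)
  # alternating large +/- values whose grand mean is exactly 1/L
  d <- matrix(rep(c(3, -3), length.out = 2 * L), L, 2)
  d <- d + (2 - sum(d)) / (2 * L)
  list(
    a = response_genome(a, B = 1),
    b = response_genome(b, B = 1),
    c = response_genome(cc, B = 1),
    d = response_genome(d, B = 1)
  )
}

#' Deterministic founding cohorts with pinned trait shapes
#'
#' Thin wrapper over [found_cohort()] producing cohorts whose
#' pre-development trait distribution has a named shape (`"normal"`,
#' `"asymmetric"`, `"bimodal"`; see [init_response_alleles()] for the pinned
#' shape parameters). Used by tests and worked examples for the
#' non-Gaussian founding variants.
#'
#' @param distribution Trait shape.
#' @param n Cohort size (>= 2).
#' @param omega Common fixed sensitivity value.
#' @param seed Optional integer seed making the fixture deterministic.
#' @param ... Passed on to [found_cohort()].
#' @return A [found_cohort()] cohort.
#' @export
fixture_cohort <- function(distribution = c("normal", "asymmetric", "bimodal"),
                           n = 1000, omega = 0.03, seed = NULL, ...) {
  distribution <- match.arg(distribution)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  found_cohort(n, distribution = distribution, fixed_omega = omega, ...)
}

#' Read / write explicit genotypes as JSON
#'
#' Serializes a single explicit genotype (allele matrix, locus counts and
#' activation tags) to the plain-text JSON fixture format
#' `{L, B, ploidy, alleles, tags}`, and back.
#'
#' @param genome A [response_genome()].
#' @param tags Activation tags to store (default all-active).
#' @param path File path.
#' @return `write_genome_json()` returns `path` invisibly;
#'   `read_genome_json()` returns a list with elements `genome` and `tags`.
#' @export
write_genome_json <- function(genome, path,
                              tags = rep(1, genome$L - genome$B)) {
  stopifnot(inherits(genome, "response_genome"))
  jsonlite::write_json(
    list(L = genome$L, B = genome$B, ploidy = genome$ploidy,
         alleles = genome$alleles, tags = as.integer(tags)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_genome_json
#' @param path File path to read.
#' @export
read_genome_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  alleles <- matrix(as.numeric(obj$alleles), obj$L, obj$ploidy)
  list(genome = response_genome(alleles, B = obj$B),
       tags = as.integer(obj$tags))
}
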