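#' Daily epimutation probability
#'
#' Probability that a plastic locus flips its activation state on a given
#' day, as a function of the mismatch between the current phenotype `x` and
#' the environmental parameter `p`:
#' \deqn{\mu_e(x \mid \omega, p) = 1 - \exp(-\omega (x - p)^2).}
#' The rate is 0 when the phenotype matches the environment or when the
#' individual is non-plastic (`omega = 0`), and increases monotonically with
#' both `omega` and `|x - p|`, saturating below 1. This mismatch feedback is
#' what makes development learning-like: individuals that drift towards the
#' optimum flip ever more rarely and are eventually absorbed there.
#'
#' @param x Phenotype(s).
#' @param p Environmental parameter.
#' @param omega Non-negative sensitivity value(s).
#' @return Probabilities in `[0, 1)` (saturating to 1 only beyond double
#'   precision), vectorized over the inputs.
#' @export
epimutation_rate <- function(x, p, omega) {
  if (any(omega < 0)) stop("omega must be non-negative", call. = FALSE)
  -expm1(-omega * (x - p)^2)
}

#' One day of development for a cohort
#'
#' The per-individual rate is evaluated once from the start-of-day phenotype;
#' each plastic locus then flips its activation tag independently with that
#' probability (simultaneous application across loci, which keeps loci
#' exchangeable), and the phenotype is recomputed from the new tags. Allele
#' values and non-plastic loci are never touched.
#'
#' @param cohort A [found_cohort()] cohort.
#' @param p Environmental parameter experienced on this day.
#' @return The updated cohort; the per-individual rates that were applied are
#'   attached as attribute `"mu_e"`.
#' @export
develop_day <- function(cohort, p) {
  stopifnot(inherits(cohort, "plast_cohort"))
  n <- cohort$n
  np <- cohort$L - cohort$B
  mu <- epimutation_rate(cohort$x, p, cohort$omega)
  if (n > 0 && np > 0) {
    flip <- matrix(stats::runif(n * np) < mu, n, np)
    cohort$tags <- abs(cohort$tags - flip)
    cohort$x <- cohort_phenotypes(cohort)
  }
  attr(cohort, "mu_e") <- mu
  cohort
}

#' Develop a cohort for a full developmental period
#'
#' Applies [develop_day()] `tau` times under a constant environment `p` (the
#' environment changes only between generations). Development is the only
#' stage at which phenotypes change; there is no mortality during
#' development, and mismatch has fitness consequences only at selection.
#'
#' @param cohort A [found_cohort()] cohort (typically newborn: all tags
#'   active).
#' @param p Environmental parameter for this generation.
#' @param tau Development time in days (>= 1, default 33).
#' @param record_trajectories If TRUE, keep the full per-individual per-day
#'   phenotype and rate trajectories.
#' @return A list of class `"plast_development"` with elements
#'   \describe{
#'     \item{cohort}{the developed cohort,}
#'     \item{x_start, x_end}{phenotypes before and after development,}
#'     \item{mean_mu}{per-day mean realized epimutation rate (length `tau`),}
#'     \item{X}{if recorded, `(tau+1) x n` matrix of phenotypes (row 1 = day
#'       0, pre-development),}
#'     \item{MU}{if recorded, `tau x n` matrix of realized rates.}
#'   }
#' @export
develop <- function(cohort, p, tau = 33, record_trajectories = FALSE) {
  stopifnot(inherits(cohort, "plast_cohort"))
  tau <- as.integer(tau)
  if (tau < 1L) stop("tau must be >= 1", call. = FALSE)
  n <- cohort$n
  np <- cohort$L - cohort$B
  x_start <- cohort$x

  # precompute what is constant during development
  ls <- locus_sums(cohort)
  base <- rowSums(ls[, seq_len(cohort$B), drop = FALSE])
  P <- ls[, cohort$B + seq_len(np), drop = FALSE]
  tags <- cohort$tags
  x <- cohort$x
  omega <- cohort$omega

  X <- if (record_trajectories) matrix(NA_real_, tau + 1L, n) else NULL
  MU <- if (record_trajectories) matrix(NA_real_, tau, n) else NULL
  if (record_trajectories) X[1L, ] <- x
  mean_mu <- numeric(tau)

  for (d in seq_len(tau)) {
    mu <- -expm1(-omega * (x - p)^2)
    mean_mu[d] <- if (n > 0) mean(mu) else NA_real_
    if (n > 0 && np > 0) {
      flip <- matrix(stats::runif(n * np) < mu, n, np)
      tags <- abs(tags - flip)
      x <- base + rowSums(P * tags)
    }
    if (record_trajectories) {
      MU[d, ] <- mu
      X[d + 1L, ] <- x
    }
  }

  cohort$tags <- tags
  cohort$x <- x
  structure(
    list(cohort = cohort, x_start = x_start, x_end = x,
         mean_mu = mean_mu, X = X, MU = MU, tau = tau, p = p),
    class = "plast_development"
  )
}

#' Tidy a recorded development trajectory
#'
#' @param x A `"plast_development"` result with recorded trajectories.
#' @param ... Unused.
#' @return A data.frame with columns `individual`, `day` (0 = pre-development),
#'   `x` and `mu_e` (`NA` on day 0).
#' @export
as.data.frame.plast_development <- function(x, ...) {
  if (is.null(x$X)) {
    stop("development was run without record_trajectories = TRUE",
         call. = FALSE)
  }
  n <- ncol(x$X)
  tau <- x$tau
  data.frame(
    individual = rep(seq_len(n), each = tau + 1L),
    day = rep(0:tau, times = n),
    x = as.vector(x$X),
    mu_e = as.vector(rbind(NA_real_, x$MU))
  )
}
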