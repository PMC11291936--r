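#' Single-generation development protocol
#'
#' Follows one cohort through a single developmental period under a fixed
#' environment, with a common sensitivity value for all individuals and no
#' selection or reproduction. This isolates the action and the limits of the
#' plasticity mechanism itself: moderate sensitivity canalizes the cohort
#' towards the environment (variance ratio < 1), excessive sensitivity
#' produces developmental noise (ratio near or above 1), and `omega = 0` is
#' the non-plastic control with ratio exactly 1.
#'
#' Defaults follow the single-generation study design: 100 individuals,
#' `L = 10` loci with unit-variance alleles per copy, environment `p = 2`,
#' 33 days of development.
#'
#' @param n Cohort size.
#' @param omega Common fixed sensitivity value.
#' @param p Environmental parameter.
#' @param tau Development time in days.
#' @param L,B Loci counts.
#' @param allele_sd Per-allele-copy sd (default 1; set `NULL` with
#'   `sigma_G` to use the `sigma_G^2/2L` founding rule instead).
#' @param sigma_G Trait sd for the founding rule when `allele_sd = NULL`.
#' @param distribution Founder trait shape, see [init_response_alleles()].
#' @param record_trajectories Keep full per-day trajectories.
#' @param seed Optional integer seed.
#' @return The `"plast_development"` result (see [develop()]) with the
#'   variance ratio appended as element `variance_ratio`.
#' @export
run_protocol1 <- function(n = 100, omega = 0.03, p = 2, tau = 33,
                          L = 10, B = 1, allele_sd = 1, sigma_G = 1,
                          distribution = "normal",
                          record_trajectories = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- found_cohort(n, L = L, B = B, sigma_G = sigma_G,
                     allele_sd = allele_sd, distribution = distribution,
                     fixed_omega = omega)
  dev <- develop(ch, p, tau = tau, record_trajectories = record_trajectories)
  dev$variance_ratio <- variance_ratio(dev$x_start, dev$x_end)
  dev
}

# Shared generation loop for the evolutionary protocols.
run_generations <- function(cohort, n_generations, env, params, tau) {
  records <- vector("list", n_generations)
  extinct_at <- NA_integer_
  for (t in seq_len(n_generations)) {
    p <- env_value(env, t)
    step <- advance_generation(cohort, p, params, tau = tau)
    records[[t]] <- cbind(t = t, step$record)
    cohort <- step$cohort
    if (step$extinct) {
      extinct_at <- t
      break
    }
  }
  out <- do.call(rbind, records[!vapply(records, is.null, logical(1))])
  attr(out, "extinct") <- !is.na(extinct_at)
  attr(out, "extinct_at") <- extinct_at
  attr(out, "final_cohort") <- cohort
  out
}

#' Fixed-sensitivity evolutionary protocol
#'
#' Evolves the response-trait alleles by selection, recombination, allelic
#' mutation and drift while every individual shares the same fixed
#' sensitivity value (the sensitivity locus is inert and plasticity costs
#' are meaningless, so `C = 0` is enforced). Comparing a plastic
#' (`fixed_omega > 0`) against a non-plastic (`fixed_omega = 0`) run under
#' the same environmental regime shows how epimutation-driven plasticity
#' steers evolution: lower population stress, higher genetic load, and
#' canalized (sub-unit) variance ratios under moderate change.
#'
#' @param n_generations Number of generations.
#' @param fixed_omega Common sensitivity value (0 = non-plastic control).
#' @param env An [environment_spec()].
#' @param params A [selection_params()]; its `C` is forced to 0.
#' @param founding_n Founding population size (default `params$K`).
#' @param tau Development time in days.
#' @param L,B,sigma_G Genome parameters for the founders (trait variance
#'   `sigma_G^2` via the `sigma_G^2/(2L)` per-copy rule).
#' @param seed Optional integer seed.
#' @return A data.frame of per-generation records (`t` plus the
#'   [generation_record()] columns) with attributes `extinct`,
#'   `extinct_at` and `final_cohort`.
#' @export
run_protocol2 <- function(n_generations = 2000, fixed_omega = 0.03,
                          env = environment_spec("periodic", A = 1, period = 200),
                          params = selection_params(),
                          founding_n = params$K, tau = 33,
                          L = 10, B = 1, sigma_G = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params$C <- 0
  ch <- found_cohort(founding_n, L = L, B = B, sigma_G = sigma_G,
                     fixed_omega = fixed_omega)
  run_generations(ch, n_generations, env, params, tau)
}

#' Evolving-sensitivity protocol
#'
#' Like the fixed-sensitivity protocol, but the sensitivity trait is
#' genetically encoded and free to evolve: lambda alleles recombine and
#' mutate like response alleles, and omega is recomputed each generation.
#' All founders start non-plastic (`lambda = 0`, hence `omega = 0`) and a
#' neutral marker locus (`nu = 0` founders, identical inheritance and
#' mutation, no fitness effect) is tracked as the drift null: selection on
#' plasticity is diagnosed by the evolved mean omega exceeding the
#' neutral-marker sensitivity analogue.
#'
#' @param n_generations Number of generations.
#' @param cost_C Plasticity cost per unit omega (the fitness cost of the
#'   plasticity machinery).
#' @param env An [environment_spec()].
#' @param params A [selection_params()]; its `C` is replaced by `cost_C`.
#' @param founding_n Founding population size (default `params$K`).
#' @param tau Development time in days.
#' @param L,B,sigma_G Genome parameters for the founders.
#' @param s,combination Sensitivity scale and convention.
#' @param ploidy 2 for the sexual diploid model, 1 for the asexual haploid
#'   variant (clonal reproduction).
#' @param seed Optional integer seed.
#' @return As [run_protocol2()], with `mean_omega`, `sd_omega` and the
#'   neutral-marker columns now informative.
#' @export
run_protocol3 <- function(n_generations = 2000, cost_C = 0,
                          env = environment_spec("constant"),
                          params = selection_params(),
                          founding_n = params$K, tau = 33,
                          L = 10, B = 1, sigma_G = 1,
                          s = 42, combination = "divide",
                          ploidy = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params$C <- cost_C
  ch <- found_cohort(founding_n, L = L, B = B, ploidy = ploidy,
                     sigma_G = sigma_G, s = s, combination = combination,
                     fixed_omega = NULL, lambda_init = 0, nu_init = 0)
  run_generations(ch, n_generations, env, params, tau)
}

#' Run replicate simulations with derived seeds
#'
#' Runs `n_replicates` independent replicates of an evolutionary protocol,
#' each with its own child seed derived deterministically from
#' `master_seed` (the master seeds the base RNG once and child seeds are
#' drawn as `sample.int(2^31 - 2, n_replicates)`). Two calls with the same
#' master seed are bit-identical; runs with the same master seed but
#' different protocol arguments (e.g. plastic vs non-plastic) share child
#' seeds and are therefore paired.
#'
#' @param fun A protocol function returning a per-generation data.frame
#'   ([run_protocol2()] or [run_protocol3()]).
#' @param n_replicates Number of replicates.
#' @param master_seed Integer master seed.
#' @param ... Arguments passed on to `fun` (everything except `seed`).
#' @return One data.frame stacking all replicate records with a leading
#'   `replicate` column and a logical `extinct` column; the child seeds are
#'   attached as attribute `seeds`.
#' @export
run_replicates <- function(fun, n_replicates, master_seed, ...) {
  stopifnot(n_replicates >= 1)
  set.seed(master_seed)
  seeds <- sample.int(2147483646L, n_replicates)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rec <- fun(..., seed = seeds[r])
    out[[r]] <- cbind(replicate = r,
                      as.data.frame(rec),
                      extinct = isTRUE(attr(rec, "extinct")))
  }
  res <- do.call(rbind, out)
  attr(res, "seeds") <- seeds
  res
}
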