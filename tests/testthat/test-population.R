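test_that("stress closed forms hold", {
  expect_identical(stress(2, 2, 2.2), 0)
  # mismatch of one tolerance unit: 1 - exp(-1/2), frozen
  expect_equal(stress(4.4, 2.2, 2.2), 0.3934693402873666, tolerance = 1e-12)
  big <- stress(1e6 * 2.2, 0, 2.2)
  expect_lte(big, 1)
  expect_gt(big, 1 - 1e-9)
  expect_error(stress(1, 0, gamma = 0), "gamma")
  expect_error(stress(1, 0, gamma = -1), "gamma")
})

test_that("fitness matches the published baseline and cost structure", {
  pars <- selection_params(R = 1, K = 1000)
  expect_equal(fitness(2, 0, N = 1000, p = 2, pars), 1)
  # stress -> 1 with no cost: fitness -> 0
  expect_equal(fitness(1e7, 0, N = 1000, p = 0, pars), 0, tolerance = 1e-9)
  pars_c <- selection_params(C = 0.5)
  expect_equal(fitness(2, 0.03, N = 1000, p = 2, pars_c), 0.985)
  # strictly decreasing in omega when C > 0; can go negative
  w <- fitness(2, c(0, 1, 5), N = 1000, p = 2, pars_c)
  expect_true(all(diff(w) < 0))
  expect_lt(w[3], 0)
  # bounded by the density-dependent baseline
  expect_lte(fitness(0.3, 0, N = 500, p = 0, pars),
             pars$R * exp(1 - 500 / pars$K))
})

test_that("parameter constructors reject invalid values", {
  expect_error(selection_params(gamma = 0), "gamma")
  expect_error(selection_params(K = -1), "K")
  expect_error(selection_params(mu_m = 2), "mu_m")
  expect_error(selection_params(lambda_mu_m = -0.1), "lambda_mu_m")
})

test_that("pair formation handles missing sexes and clamps rates", {
  expect_identical(nrow(form_pairs(rep("F", 5), rep(1, 5))), 0L)
  expect_identical(nrow(form_pairs(rep("M", 5), rep(1, 5))), 0L)
  # a single male fathers every pair
  set.seed(3)
  sex <- c("M", rep("F", 6))
  pr <- form_pairs(sex, rep(1, 7))
  expect_true(all(pr$father == 1))
  expect_identical(sort(pr$mother), 2:7)
  # negative fitness sums clamp to zero, never negative
  pr2 <- form_pairs(sex, rep(-2, 7))
  expect_true(all(pr2$rate == 0))
})

test_that("sex assignment splits floor(n/2) males per generation", {
  set.seed(9)
  for (n in c(1L, 2L, 7L, 100L)) {
    sex <- assign_sexes(n)
    expect_identical(sum(sex == "M"), n %/% 2L)
    expect_identical(sum(sex == "F"), n - n %/% 2L)
  }
})

test_that("inheritance is Mendelian: no mutation conserves parental alleles", {
  set.seed(14)
  ch <- found_cohort(20)
  pars <- selection_params(mu_m = 0)
  off <- make_offspring(ch, mothers = rep(1:10, 4), fathers = rep(11:20, 4), pars)
  for (o in 1:40) {
    m <- ((o - 1) %% 10) + 1
    f <- m + 10
    for (j in 1:10) {
      expect_true(off$resp[o, j, 1] %in% ch$resp[m, j, ])
      expect_true(off$resp[o, j, 2] %in% ch$resp[f, j, ])
    }
  }
  # homozygous identical parents reproduce exactly
  ch2 <- found_cohort(2)
  ch2$resp[1, , ] <- ch2$resp[2, , ] <- matrix(rep(rnorm(10), 2), 10, 2)
  off2 <- make_offspring(ch2, 1, 2, pars)
  expect_equal(matrix(off2$resp[1, , ], 10, 2),
               matrix(ch2$resp[1, , ], 10, 2))
  # certain mutations of zero effect change nothing
  off3 <- make_offspring(ch2, 1, 2, selection_params(mu_m = 1, sigma_m = 0))
  expect_equal(matrix(off3$resp[1, , ], 10, 2),
               matrix(ch2$resp[1, , ], 10, 2))
})

test_that("mutation incidence matches the per-copy rate binomially", {
  set.seed(25)
  ch <- found_cohort(10)
  ch$resp[] <- 0                    # any non-zero transmitted copy is a mutant
  n_off <- 5000
  off <- make_offspring(ch, sample(10, n_off, TRUE), sample(10, n_off, TRUE),
                        selection_params(mu_m = 0.01))
  n_copies <- n_off * 10 * 2
  frac <- mean(off$resp != 0)
  se <- sqrt(0.01 * 0.99 / n_copies)
  expect_lt(abs(frac - 0.01), 3 * se)
})

test_that("offspring are born all-active with recomputed sensitivity", {
  set.seed(33)
  ch <- found_cohort(10, fixed_omega = NULL)
  ch$lam <- matrix(rnorm(20), 10, 2)
  ch$omega <- compute_sensitivity(ch$lam, ch$s)
  off <- make_offspring(ch, 1:5, 6:10, selection_params(mu_m = 0))
  expect_true(all(off$tags == 1))
  expect_equal(off$omega, compute_sensitivity(off$lam, ch$s))
  expect_equal(off$x, rowSums(matrix(off$resp[, , 1], 5, 10)) +
                       rowSums(matrix(off$resp[, , 2], 5, 10)))
})

test_that("a lone individual cannot reproduce and the line goes extinct", {
  set.seed(2)
  ch <- found_cohort(1, fixed_omega = 0)
  step <- advance_generation(ch, p = 0, selection_params(K = 10), tau = 5)
  expect_true(step$extinct)
  expect_identical(step$cohort$n, 0L)
  # an extinct population is a flagged no-op
  step2 <- advance_generation(step$cohort, p = 0, selection_params(K = 10))
  expect_true(step2$extinct)
  expect_null(step2$record)
})

test_that("expected population size is stable for optimal founders at carrying capacity", {
  # identical optimal non-plastic founders, C = 0, N = K: E[offspring per
  # pair] = 2, F ~ N/2, so E[N'] ~ N; check mean drift < 5% over replicates
  set.seed(55)
  K <- 200
  sizes <- replicate(200, {
    ch <- found_cohort(K, fixed_omega = 0)
    ch$resp[] <- 0
    ch$x <- cohort_phenotypes(ch)
    advance_generation(ch, p = 0, selection_params(K = K, mu_m = 0),
                       tau = 1)$cohort$n
  })
  expect_lt(abs(mean(sizes) - K) / K, 0.05)
})

test_that("without selection or mutation, allele means drift without bias", {
  set.seed(66)
  ch <- found_cohort(60, fixed_omega = 0)
  founder_mean <- mean(ch$resp)
  # gamma so large that stress is ~0 for everyone: pure drift
  means <- replicate(400, {
    mean(advance_generation(ch, p = 0,
                            selection_params(K = 60, mu_m = 0, gamma = 1e9),
                            tau = 1)$cohort$resp)
  })
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - founder_mean), 3 * se)
})

test_that("haploid clonal reproduction runs and preserves structure", {
  set.seed(44)
  ch <- found_cohort(80, ploidy = 1, fixed_omega = NULL)
  expect_identical(dim(ch$resp), c(80L, 10L, 1L))
  step <- advance_generation(ch, p = 0, selection_params(K = 80), tau = 5)
  expect_false(step$extinct)
  expect_identical(step$cohort$ploidy, 1L)
  expect_true(all(step$cohort$tags == 1))
})
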