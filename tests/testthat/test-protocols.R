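test_that("single-generation protocol reproduces the control and plastic cases", {
  d0 <- run_protocol1(n = 300, omega = 0, seed = 1)
  expect_identical(d0$variance_ratio, 1)
  d1 <- run_protocol1(n = 300, omega = 0.03, seed = 1)
  expect_lt(d1$variance_ratio, 1)
})

test_that("protocol runs are bit-reproducible given a seed", {
  a <- run_protocol2(n_generations = 12, fixed_omega = 0.03,
                     params = selection_params(K = 80), founding_n = 80,
                     seed = 123)
  b <- run_protocol2(n_generations = 12, fixed_omega = 0.03,
                     params = selection_params(K = 80), founding_n = 80,
                     seed = 123)
  expect_identical(a, b)
  c <- run_protocol2(n_generations = 12, fixed_omega = 0.03,
                     params = selection_params(K = 80), founding_n = 80,
                     seed = 124)
  expect_false(identical(a$mean_stress, c$mean_stress))
})

test_that("replicate runner derives child seeds deterministically and pairs runs", {
  r1 <- run_replicates(run_protocol2, 3, 99, n_generations = 8,
                       fixed_omega = 0.03,
                       params = selection_params(K = 60), founding_n = 60)
  r2 <- run_replicates(run_protocol2, 3, 99, n_generations = 8,
                       fixed_omega = 0.03,
                       params = selection_params(K = 60), founding_n = 60)
  expect_identical(r1, r2)
  # each replicate equals a standalone run with its child seed
  seeds <- attr(r1, "seeds")
  solo <- run_protocol2(n_generations = 8, fixed_omega = 0.03,
                        params = selection_params(K = 60), founding_n = 60,
                        seed = seeds[2])
  rep2 <- r1[r1$replicate == 2, names(solo)]
  rownames(rep2) <- NULL
  expect_equal(rep2, as.data.frame(solo), ignore_attr = TRUE)
})

test_that("non-plastic populations keep a variance ratio of exactly one", {
  r <- run_protocol2(n_generations = 15, fixed_omega = 0,
                     env = environment_spec("periodic", A = 1, period = 200),
                     params = selection_params(K = 100), founding_n = 100,
                     seed = 7)
  expect_true(all(r$variance_ratio == 1))
})

test_that("fixed-omega runs match evolving-omega runs with a frozen sensitivity locus", {
  pars <- selection_params(K = 80, lambda_mu_m = 0)
  a <- run_protocol2(n_generations = 20, fixed_omega = 0,
                     env = environment_spec("periodic", A = 1, period = 200),
                     params = pars, founding_n = 80, seed = 31)
  b <- run_protocol3(n_generations = 20, cost_C = 0,
                     env = environment_spec("periodic", A = 1, period = 200),
                     params = pars, founding_n = 80, seed = 31)
  cols <- c("t", "p", "N", "mean_stress", "genetic_load", "variance_ratio",
            "mean_neutral", "sd_neutral")
  expect_equal(as.data.frame(a)[, cols], as.data.frame(b)[, cols],
               ignore_attr = TRUE)
  expect_true(all(b$mean_omega == 0))
})

test_that("the sensitivity trait cannot evolve without mutational input", {
  r <- run_protocol3(n_generations = 25, cost_C = 0,
                     params = selection_params(K = 60, mu_m = 0),
                     founding_n = 60, seed = 5)
  expect_true(all(r$mean_omega == 0))
  expect_true(all(r$neutral_omega == 0))
})

test_that("the neutral marker is selection-free across replicate populations", {
  # elevated mutation rate so the marker actually moves, then check the
  # grand mean across replicates stays at its founding value of zero
  res <- run_replicates(run_protocol3, 100, 202, n_generations = 15,
                        cost_C = 0, params = selection_params(K = 50, mu_m = 0.01),
                        founding_n = 50)
  fin <- final_records(res)
  se <- sd(fin$mean_neutral) / sqrt(nrow(fin))
  expect_lt(abs(mean(fin$mean_neutral)), 3 * se)
})

test_that("extinction truncates the record and is flagged", {
  # tiny population under crushing stress dies out quickly
  r <- run_protocol2(n_generations = 50, fixed_omega = 0,
                     env = environment_spec("directional", eta = 50),
                     params = selection_params(K = 6, gamma = 0.5),
                     founding_n = 6, seed = 13)
  expect_true(attr(r, "extinct"))
  expect_lt(nrow(r), 50)
  expect_identical(attr(r, "extinct_at"), max(r$t))
})
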