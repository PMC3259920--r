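test_that("noise-free trajectories equal the deterministic recursion", {
  # identity: no mortality, no recruitment
  p0 <- model_params(0, 0, 0, 0, 0, 0)
  sc <- sim_scenario(p0, initial_size = 100, n_years = 5,
                     reproductions = rep(0L, 5), seed = 1)
  traj <- generate_latent_trajectory(sc)
  expect_equal(traj$N, rep(100, 6))
  expect_equal(traj$N, traj$mu)

  # pure decay at half survival
  ph <- model_params(0.3, 0.1, 0.1, 0, 0, 0)
  sc <- sim_scenario(ph, initial_size = 100, n_years = 6,
                     reproductions = rep(0L, 6), seed = 1)
  traj <- generate_latent_trajectory(sc)
  expect_equal(traj$N, 100 * 0.5^(0:6))

  # recursion with recruitment, checked term by term
  p <- model_params(0.148, 0.049, 0.085, 3.788, 0, 0)
  R <- c(3L, 4L, 5L)
  sc <- sim_scenario(p, initial_size = 100, n_years = 3,
                     reproductions = R, seed = 1)
  traj <- generate_latent_trajectory(sc)
  exp_N <- Reduce(function(N, R_t) 0.718 * N + 3.788 * R_t, R,
                  accumulate = TRUE, init = 100)
  expect_equal(traj$N, exp_N)

  expect_error(sim_scenario(p, initial_size = -3, n_years = 2,
                            per_capita_rate = 0.1), "positive")
  expect_error(sim_scenario(p, initial_size = 10, n_years = 2,
                            reproductions = c(1L, 1L),
                            per_capita_rate = 0.1), "exactly one")
  expect_error(model_params(0.6, 0.3, 0.2, 1, 0, 0), "exceed")
})

test_that("process noise leaves the median at the deterministic prediction", {
  p <- model_params(0.1, 0.05, 0.05, 2, 0.1, 0)
  mu1 <- 0.8 * 100 + 2 * 5
  draws <- vapply(1:10000, function(k) {
    sc <- sim_scenario(p, initial_size = 100, n_years = 1,
                       reproductions = 5L, seed = k)
    generate_latent_trajectory(sc)$N[2]
  }, numeric(1))
  # Monte-Carlo error of the sample median: 1.2533 * sd / sqrt(n)
  mc_se <- 1.2533 * sd(draws) / sqrt(length(draws))
  expect_lt(abs(median(draws) - mu1), 3 * mc_se)
})

test_that("seeds make trajectories reproducible and distinct", {
  p <- model_params(0.1, 0.05, 0.05, 2, 0.2, 0)
  sc1 <- sim_scenario(p, 100, 8, per_capita_rate = 0.1, seed = 5)
  sc2 <- sim_scenario(p, 100, 8, per_capita_rate = 0.1, seed = 6)
  expect_identical(generate_latent_trajectory(sc1),
                   generate_latent_trajectory(sc1))
  expect_false(identical(generate_latent_trajectory(sc1)$N,
                         generate_latent_trajectory(sc2)$N))
})

test_that("census observations follow the gamma-Poisson mixture moments", {
  # a zero population is observed as zero
  z <- list(years = 1:5, N = rep(0, 5))
  expect_equal(generate_census_observations(z, 10, seed = 1)$nobs,
               rep(0L, 5))

  flat <- list(years = seq_len(1e5), N = rep(100, 1e5))
  # workaround: years must be consecutive, which seq_len provides
  pois <- generate_census_observations(flat, 0, seed = 2)$nobs
  expect_equal(mean(pois), 100, tolerance = 0.01)
  expect_equal(var(pois), 100, tolerance = 0.05)

  mixed <- generate_census_observations(flat, 20, seed = 3)$nobs
  expect_equal(mean(mixed), 100, tolerance = 0.01)
  expect_equal(var(mixed), 500, tolerance = 0.05)

  expect_error(generate_census_observations(flat, -1), "non-negative")
})

test_that("hazard and annual-probability conversions invert each other", {
  probs <- c(nonpoaching = 0.148, verified = 0.050, cryptic = 0.085)
  h <- hazards_from_annual_probs(probs)
  expect_equal(annual_probs_from_hazards(h), probs, tolerance = 1e-12)
  expect_equal(annual_probs_from_hazards(study_hazards()), probs,
               tolerance = 1e-12)
  expect_equal(hazards_from_annual_probs(probs * 0), probs * 0)
  expect_error(hazards_from_annual_probs(c(0.6, 0.5, 0.2)), "less than 1")
})

test_that("individual histories realize the competing-risks model", {
  # no hazards, no transmitter failure: everyone survives monitoring
  rec <- generate_individual_histories(c(0, 0, 0), 50, 5,
                                       contact_loss_rate = 0, seed = 1)
  expect_true(all(rec$fate == "alive_at_end"))

  # one cohort year: cause-specific death fractions match the closed form
  h <- c(nonpoaching = 0.16, verified = 0.05, cryptic = 0.09)
  rec <- generate_individual_histories(h, 4000, 1, entry_spread = 0,
                                       contact_loss_rate = 0, seed = 2)
  p_expect <- annual_probs_from_hazards(h)
  fracs <- c(mean(rec$fate == "death_nonpoaching"),
             mean(rec$fate == "death_verified_poaching"),
             mean(rec$fate == "cryptic_loss"))
  se <- sqrt(p_expect * (1 - p_expect) / 4000)
  expect_true(all(abs(fracs - p_expect) < 4 * se))

  expect_error(generate_individual_histories(c(-0.1, 0, 0), 10, 1), "non-negative")
})

test_that("generated evidence lets the classifier recover every true fate", {
  rec <- generate_individual_histories(study_hazards(), 300, 10, seed = 9)
  truth_to_code <- c(alive_at_end = "ALIVE",
                     death_nonpoaching = "NONPOACHING_DEATH",
                     death_verified_poaching = "VERIFIED_POACHED",
                     cryptic_loss = "CRYPTIC_POACHED",
                     contact_lost_other = "CENSORED")
  expect_identical(classify_fate(rec), unname(truth_to_code[rec$fate]))
  # every truth label occurs in a cohort this size, so the check has power
  expect_setequal(unique(rec$fate), names(truth_to_code))
})
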