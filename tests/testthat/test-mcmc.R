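test_that("sampling is bit-reproducible under a fixed seed", {
  cs <- synthetic_study_series()
  ps <- study_priors()
  tiny <- mcmc_settings("quick", chains = 2, n_keep = 400, burn_in = 400)
  d1 <- run_mcmc(cs, ps, tiny, seed = 3)
  d2 <- run_mcmc(cs, ps, tiny, seed = 3)
  expect_identical(d1$chains, d2$chains)
  d3 <- run_mcmc(cs, ps, tiny, seed = 4)
  expect_false(identical(d1$chains[[1]], d3$chains[[1]]))
})

test_that("adapted acceptance rates sit in the working range", {
  d <- cached_study_fit()
  acc <- unlist(d$accept)
  expect_true(all(acc >= 0.1 & acc <= 0.6))
})

test_that("with no data the sampler reproduces the priors", {
  empty <- census_series(integer(0), integer(0), integer(0))
  d <- run_mcmc(empty, study_priors(), mcmc_settings("quick"), seed = 11)
  tau <- overlap_table(d)
  expect_true(all(tau$tau >= 95))
})

test_that("thinning leaves posterior medians unchanged within MC error", {
  cs <- synthetic_study_series()
  ps <- study_priors()
  d1 <- run_mcmc(cs, ps, mcmc_settings("quick", chains = 3, n_keep = 6000,
                                       burn_in = 5000, thin = 1), seed = 2)
  d5 <- run_mcmc(cs, ps, mcmc_settings("quick", chains = 3, n_keep = 6000,
                                       burn_in = 5000, thin = 5), seed = 2)
  s1 <- summarize_posterior(d1)
  s5 <- summarize_posterior(d5)
  for (pm in c("m", "v")) {
    expect_equal(s1$median[s1$parameter == pm],
                 s5$median[s5$parameter == pm], tolerance = 0.05)
  }
})

test_that("an independent Gibbs sampler reaches the same posterior", {
  # rjags fits the identical model (explicit gamma-Poisson observation
  # stage, cryptic rate reparameterized to keep JAGS parents valid) on the
  # same data; pooled medians must agree within Monte-Carlo error.
  library(rjags)
  cs <- synthetic_study_series()
  model_str <- "
  model {
    m ~ dbeta(sh_m1, sh_m2)
    v ~ dbeta(sh_v1, sh_v2)
    u ~ dunif(0, 1)
    c <- u * (1 - m - v)
    l ~ dgamma(sh_l, ra_l)
    sproc ~ dunif(0, 25)
    snobs ~ dunif(0, 50)
    taup <- 1 / (sproc * sproc)
    N[1] ~ dlnorm(log(n1), 4)
    for (t in 2:T) {
      mu[t] <- (1 - m - v - c) * N[t-1] + l * R[t]
      N[t] ~ dlnorm(log(mu[t]), taup)
    }
    for (t in 1:T) {
      sh[t] <- N[t] * N[t] / (snobs * snobs)
      ra[t] <- N[t] / (snobs * snobs)
      lam[t] ~ dgamma(sh[t], ra[t])
      nobs[t] ~ dpois(lam[t])
    }
  }"
  ps <- study_priors()
  dat <- list(nobs = cs$nobs, R = cs$reproductions, T = nrow(cs),
              n1 = max(cs$nobs[1], 1),
              sh_m1 = ps$m$shape1, sh_m2 = ps$m$shape2,
              sh_v1 = ps$v$shape1, sh_v2 = ps$v$shape2,
              sh_l = ps$l$shape, ra_l = ps$l$rate)
  inits <- lapply(1:3, function(k) {
    list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 100 + k)
  })
  jm <- jags.model(textConnection(model_str), data = dat, inits = inits,
                   n.chains = 3, quiet = TRUE)
  update(jm, 30000, progress.bar = "none")
  samp <- coda.samples(jm, c("m", "v", "c", "l"), n.iter = 100000, thin = 5,
                       progress.bar = "none")
  jq <- summary(samp)$quantiles[, 3]

  d <- cached_study_fit()
  s <- summarize_posterior(d)
  med <- setNames(s$median, s$parameter)
  expect_lt(abs(med["m"] - jq["m"]), 0.01)
  expect_lt(abs(med["v"] - jq["v"]), 0.01)
  expect_lt(abs(med["c"] - jq["c"]), 0.05)
  expect_lt(abs(med["l"] - jq["l"]), 0.4)
})

test_that("Heidelberger-Welch calibrates on null and drifting chains", {
  pass_null <- vapply(1:100, function(s) {
    set.seed(s)
    heidelberger_welch(rnorm(10000))$stationarity_pass
  }, logical(1))
  expect_gte(mean(pass_null), 0.90)

  pass_drift <- vapply(1:60, function(s) {
    set.seed(s)
    heidelberger_welch(rnorm(10000) +
                         seq(0, 5, length.out = 10000))$stationarity_pass
  }, logical(1))
  expect_lte(mean(pass_drift), 0.05)

  degen <- heidelberger_welch(rep(2.5, 500))
  expect_true(degen$stationarity_pass)
  expect_true(degen$halfwidth_pass)
  expect_true(degen$degenerate)

  expect_error(heidelberger_welch(rnorm(50)), "at least 100")
})

test_that("the overlap statistic integrates the pointwise minimum", {
  set.seed(13)
  ps <- study_priors()
  # self overlap: posterior drawn from the prior itself
  x <- prior_sample(ps, "m", 1e5)
  tau <- prior_posterior_overlap(x, function(z) prior_density(ps, "m", z),
                                 c(0, 1))
  expect_gte(tau, 0.95)

  # uniform(0, 1/2) draws against a uniform(0, 1) prior overlap by half
  y <- runif(5e4, 0, 0.5)
  tau2 <- prior_posterior_overlap(y, function(z) dunif(z), c(0, 1))
  expect_lt(abs(tau2 - 0.5), 0.02)

  expect_error(prior_posterior_overlap(runif(2000) + 0.5,
                                       function(z) dunif(z), c(0, 1)),
               "outside")
  expect_error(prior_posterior_overlap(runif(500), function(z) dunif(z),
                                       c(0, 1)), "at least 1000")
})

test_that("posterior summaries report pooled quantiles", {
  m <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "x"))
  s <- summarize_posterior(m)
  expect_equal(s$median, 2)

  set.seed(2)
  z <- matrix(rnorm(2e5), ncol = 1, dimnames = list(NULL, "z"))
  sz <- summarize_posterior(z)
  expect_equal(sz$sd, 1, tolerance = 0.01)
  expect_equal(sz$lo95, qnorm(0.025), tolerance = 0.02)

  d <- cached_study_fit()
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws_csv(d, path)
  long <- read.csv(path)
  expect_setequal(unique(long$parameter),
                  c("m", "v", "c", "l", "sigma_proc", "sigma_nobs"))
  expect_equal(nrow(long), 6 * 6 * 10000)
})
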