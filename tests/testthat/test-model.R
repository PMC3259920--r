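test_that("the process median is survivors plus recruits", {
  p0 <- model_params(0, 0, 0, 0, 0.1, 0)
  expect_equal(process_median(123.4, p0, 7), 123.4)

  p <- model_params(0.148, 0.049, 0.085, 3.788, 0.05, 10)
  expect_equal(process_median(100, p, 3), 100 * 0.718 + 3.788 * 3)

  # recruitment-only limit as the previous size vanishes
  expect_equal(process_median(1e-12, p, 2), 3.788 * 2, tolerance = 1e-9)

  expect_error(process_median(-5, p, 1), "positive")
  expect_error(process_median(100, list(m = 0.6, v = 0.3, c = 0.2, l = 1), 1),
               "exceed")
  expect_error(model_params(0.6, 0.3, 0.2, 1, 0.1, 1), "exceed")
})

test_that("the process density is lognormal with the median as its centre", {
  med <- 80
  s <- 0.2
  expect_equal(process_logdensity(med, med, s),
               -log(med * s * sqrt(2 * pi)))

  # normalization by quadrature
  total <- integrate(function(x) exp(process_logdensity(x, 50, 0.3)),
                     0, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)

  # symmetry in log space: x * f(x) is symmetric around the median
  for (k in c(1.3, 2, 5)) {
    expect_equal(process_logdensity(med * k, med, s) + log(med * k),
                 process_logdensity(med / k, med, s) + log(med / k))
  }

  expect_equal(process_logdensity(-1, med, s), -Inf)
  expect_equal(process_logdensity(10, -2, s), -Inf)
})

test_that("the marginal observation density is the gamma-Poisson mixture", {
  # Poisson reduction at zero observation sd
  expect_equal(observation_logdensity(0L, 1, 0), -1)
  expect_equal(observation_logdensity(0:10, 4, 0), dpois(0:10, 4, log = TRUE))

  # normalization
  p <- exp(observation_logdensity(0:3000, 100, 20))
  expect_equal(sum(p), 1, tolerance = 1e-8)

  # mixture simulation oracle: empirical pmf of explicit lambda draws
  set.seed(31)
  n <- 2e5
  lam <- rgamma(n, shape = 100^2 / 20^2, rate = 100 / 20^2)
  k <- rpois(n, lam)
  emp <- tabulate(k + 1L, nbins = 601) / n
  pmf <- exp(observation_logdensity(0:600, 100, 20))
  expect_lt(sum(abs(emp - pmf)) / 2, 0.02) # total variation within MC error
  expect_equal(mean(k), 100, tolerance = 0.01)
  expect_equal(var(k), 100 + 20^2, tolerance = 0.05)

  expect_error(observation_logdensity(3L, -1, 2), "positive")
})

test_that("the joint log posterior equals its hand-summed components", {
  ps <- study_priors()
  data <- census_series(2001:2003, c(50L, 60L, 75L), c(0L, 5L, 6L))
  p <- list(m = 0.15, v = 0.05, c = 0.1, l = 3.5,
            sigma_proc = 0.08, sigma_nobs = 6)
  latent <- c(52, 61, 73)

  expected <- dbeta(p$m, ps$m$shape1, ps$m$shape2, log = TRUE) +
    dbeta(p$v, ps$v$shape1, ps$v$shape2, log = TRUE) +
    dunif(p$c, 0, 1, log = TRUE) +
    dgamma(p$l, shape = ps$l$shape, rate = ps$l$rate, log = TRUE) +
    dunif(p$sigma_proc, 0, 25, log = TRUE) +
    dunif(p$sigma_nobs, 0, 50, log = TRUE) +
    dlnorm(latent[1], log(50), 0.5, log = TRUE) +
    dlnorm(latent[2], log(0.7 * latent[1] + 3.5 * 5), 0.08, log = TRUE) +
    dlnorm(latent[3], log(0.7 * latent[2] + 3.5 * 6), 0.08, log = TRUE) +
    sum(dnbinom(data$nobs, size = latent^2 / 36, mu = latent, log = TRUE))
  expect_equal(log_posterior(p, latent, data, ps), expected,
               tolerance = 1e-12)

  # out-of-support values yield -Inf, not errors
  expect_equal(log_posterior(modifyList(p, list(c = 1.4)), latent, data, ps),
               -Inf)
  expect_equal(log_posterior(modifyList(p, list(sigma_proc = 0)),
                             latent, data, ps), -Inf)
  expect_equal(log_posterior(p, c(-1, 61, 73), data, ps), -Inf)
  expect_error(log_posterior(p, latent[1:2], data, ps), "length")

  # empty series: prior-only
  empty <- census_series(integer(0), integer(0), integer(0))
  prior_part <- dbeta(p$m, ps$m$shape1, ps$m$shape2, log = TRUE) +
    dbeta(p$v, ps$v$shape1, ps$v$shape2, log = TRUE) +
    dgamma(p$l, shape = ps$l$shape, rate = ps$l$rate, log = TRUE) +
    log(1) + dunif(p$sigma_proc, 0, 25, log = TRUE) +
    dunif(p$sigma_nobs, 0, 50, log = TRUE)
  expect_equal(log_posterior(p, numeric(0), empty, ps), prior_part)
})

test_that("the compiled posterior agrees with the reference implementation", {
  ps <- study_priors()
  pc <- crypticpoach:::prior_to_codes(ps)
  data <- census_series(1999:2009, c(74L, 83L, 93L, 104L, 119L, 134L, 152L,
                                     172L, 194L, 221L, 251L),
                        c(0L, 8L, 9L, 10L, 12L, 13L, 15L, 17L, 19L, 22L, 25L))
  set.seed(12)
  for (k in 1:20) {
    p <- list(m = runif(1, 0.05, 0.3), v = runif(1, 0.01, 0.1),
              c = runif(1, 0, 0.5), l = runif(1, 1, 8),
              sigma_proc = runif(1, 0.01, 2), sigma_nobs = runif(1, 0.1, 40))
    latent <- data$nobs * exp(rnorm(11, 0, 0.2))
    r_val <- log_posterior(p, latent, data, ps)
    cpp_val <- crypticpoach:::.lp_cpp(
      unlist(p), latent, as.integer(data$nobs),
      as.numeric(data$reproductions), pc$fam, pc$p1, pc$p2)
    expect_equal(cpp_val, r_val, tolerance = 1e-10)
  }
})

test_that("census series validate their contract", {
  expect_error(census_series(c(1999, 2001), c(1L, 2L), c(0L, 0L)),
               "consecutive")
  expect_error(census_series(1999:2000, c(-1L, 2L), c(0L, 0L)),
               "non-negative")
  expect_error(census_series(1999:2000, c(1.5, 2), c(0L, 0L)), "integers")
  cs <- census_series(1999:2000, c(10L, 12L), c(1L, 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_census_csv(cs, path)
  expect_equal(as.data.frame(read_census_csv(path)), as.data.frame(cs))
})
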