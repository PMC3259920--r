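param_names <- c("m", "v", "c", "l", "sigma_proc", "sigma_nobs")

prior_to_codes <- function(priors) {
  fam <- integer(6)
  p1 <- p2 <- numeric(6)
  for (j in seq_along(param_names)) {
    sp <- priors[[param_names[j]]]
    if (sp$family == "beta") {
      fam[j] <- 0L; p1[j] <- sp$shape1; p2[j] <- sp$shape2
    } else if (sp$family == "gamma") {
      fam[j] <- 1L; p1[j] <- sp$shape; p2[j] <- sp$rate
    } else if (sp$family == "uniform") {
      fam[j] <- 2L; p1[j] <- sp$min; p2[j] <- sp$max
    } else stop("unsupported prior family: ", sp$family)
  }
  list(fam = fam, p1 = p1, p2 = p2)
}

#' MCMC settings profiles
#'
#' Bundles chain count, burn-in, kept draws and thinning. The
#' \code{"desk"} profile (6 chains, 50,000 kept draws each after 20,000
#' burn-in iterations, thinning by 5) is sized for interactive use on one
#' CPU; \code{"replica"} mirrors the published analysis (6 chains, 100,000
#' burn-in, 1,000,000 post-burn-in iterations thinned by 10);
#' \code{"quick"} (4 chains, 5,000 kept after 4,000 burn-in, thin 2) is for
#' smoke tests and examples.
#'
#' @param profile One of \code{"desk"}, \code{"replica"}, \code{"quick"}.
#' @param chains,n_keep,burn_in,thin Optional overrides of the profile.
#' @return A list of settings for [run_mcmc()].
#' @export
mcmc_settings <- function(profile = c("desk", "replica", "quick"),
                          chains = NULL, n_keep = NULL, burn_in = NULL,
                          thin = NULL) {
  profile <- match.arg(profile)
  s <- switch(profile,
    desk = list(chains = 6L, n_keep = 50000L, burn_in = 20000L, thin = 5L),
    replica = list(chains = 6L, n_keep = 100000L, burn_in = 100000L, thin = 10L),
    quick = list(chains = 4L, n_keep = 5000L, burn_in = 4000L, thin = 2L)
  )
  if (!is.null(chains)) s$chains <- as.integer(chains)
  if (!is.null(n_keep)) s$n_keep <- as.integer(n_keep)
  if (!is.null(burn_in)) s$burn_in <- as.integer(burn_in)
  if (!is.null(thin)) s$thin <- as.integer(thin)
  if (any(unlist(s) < 1L)) stop("all MCMC settings must be positive")
  s$profile <- profile
  s
}

draw_init <- function(priors, data, max_tries = 100) {
  pc <- prior_to_codes(priors)
  T <- nrow(data)
  for (k in seq_len(max_tries)) {
    m <- prior_sample(priors, "m", 1)
    v <- prior_sample(priors, "v", 1)
    cc <- stats::runif(1, 0, max(1e-3, 1 - m - v))
    l <- prior_sample(priors, "l", 1)
    # start the sds in a plausible mid-range rather than the far prior tail
    sp <- stats::runif(1, 0.05, 0.5)
    sn <- stats::runif(1, 1, 20)
    params <- c(m, v, cc, l, sp, sn)
    latent <- if (T > 0) pmax(data$nobs, 1) * exp(stats::rnorm(T, 0, 0.05)) else numeric(0)
    lp <- .lp_cpp(params, latent, as.integer(data$nobs),
                  as.numeric(data$reproductions), pc$fam, pc$p1, pc$p2)
    if (is.finite(lp)) return(list(params = params, latent = latent))
  }
  stop("could not find a finite-posterior initial state after ",
       max_tries, " attempts")
}

#' Sample the posterior of the state-space model
#'
#' Adaptive random-walk Metropolis-within-Gibbs sampler over the six model
#' parameters and the latent annual population sizes. Each quantity is
#' updated in its own block on a transformed scale (logit for the three
#' mortality probabilities, log for recruitment, the two sds, and the latent
#' sizes); proposal step sizes adapt toward 40 per cent acceptance during
#' burn-in only, then freeze, so the kept draws come from a fixed-kernel
#' Markov chain. Chains are initialized from the priors (total mortality
#' constrained below one, sds started mid-range) and run sequentially with
#' per-chain seeds \code{seed + chain - 1}, making the output reproducible
#' bit for bit. An empty census series is allowed and yields draws from the
#' priors themselves.
#'
#' @param data A [census_series()] (possibly with zero rows).
#' @param priors A \code{prior_set}.
#' @param settings A list from [mcmc_settings()].
#' @param seed Integer seed.
#' @param target_accept Acceptance rate targeted by the adaptation.
#' @return A \code{posterior_draws} object: per-chain draw matrices (columns
#'   \code{m}, \code{v}, \code{c}, \code{l}, \code{sigma_proc},
#'   \code{sigma_nobs}, then \code{N_<year>}), per-chain post-burn-in
#'   acceptance rates and adapted step sizes, the settings, seeds, data and
#'   priors.
#' @export
run_mcmc <- function(data, priors, settings = mcmc_settings("desk"),
                     seed = 1L, target_accept = 0.4) {
  pc <- prior_to_codes(priors)
  T <- nrow(data)
  cols <- c(param_names, if (T > 0) paste0("N_", data$year))
  chains <- vector("list", settings$chains)
  accept <- vector("list", settings$chains)
  steps <- vector("list", settings$chains)
  chain_seeds <- seed + seq_len(settings$chains) - 1L
  for (ch in seq_len(settings$chains)) {
    set.seed(chain_seeds[ch])
    init <- draw_init(priors, data)
    res <- .mwg_chain(as.integer(data$nobs), as.numeric(data$reproductions),
                      pc$fam, pc$p1, pc$p2, init$params, init$latent,
                      settings$burn_in, settings$n_keep, settings$thin,
                      target_accept)
    colnames(res$draws) <- cols
    if (any(res$accept == 0, na.rm = TRUE)) {
      bad <- cols[which(res$accept == 0)]
      stop("chain ", ch, ": no proposals accepted after adaptation for block(s): ",
           paste(bad, collapse = ", "))
    }
    chains[[ch]] <- res$draws
    accept[[ch]] <- stats::setNames(as.numeric(res$accept), cols)
    steps[[ch]] <- stats::setNames(as.numeric(res$step), cols)
  }
  structure(list(
    chains = chains, accept = accept, step = steps,
    settings = settings, seed = seed, chain_seeds = chain_seeds,
    data = data, priors = priors
  ), class = "posterior_draws")
}

#' Pool draws across chains
#'
#' @param draws A \code{posterior_draws}.
#' @return Matrix of pooled post-burn-in draws (rows = draws).
#' @export
pool_draws <- function(draws) {
  do.call(rbind, draws$chains)
}

#' @export
print.posterior_draws <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "Posterior draws: %d chains x %d kept (burn-in %d, thin %d), seed %d\n",
    s$chains, s$n_keep, s$burn_in, s$thin, x$seed))
  cat(sprintf("  %d sampled quantities over %d data years\n",
              ncol(x$chains[[1]]), nrow(x$data)))
  acc <- colMeans(do.call(rbind, x$accept))
  cat(sprintf("  acceptance rates %.2f-%.2f (mean %.2f)\n",
              min(acc), max(acc), mean(acc)))
  invisible(x)
}

#' Summarize a posterior sample
#'
#' Pooled-chain medians, standard deviations and central 95 per cent
#' credible intervals for every sampled quantity.
#'
#' @param draws A \code{posterior_draws} or a numeric matrix of draws with
#'   column names.
#' @return A data.frame with columns \code{parameter}, \code{median},
#'   \code{sd}, \code{lo95}, \code{hi95}.
#' @export
summarize_posterior <- function(draws) {
  mat <- if (inherits(draws, "posterior_draws")) pool_draws(draws) else as.matrix(draws)
  if (nrow(mat) == 0) stop("no draws to summarize")
  qs <- t(apply(mat, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
                names = FALSE))
  data.frame(
    parameter = colnames(mat),
    median = qs[, 1],
    sd = apply(mat, 2, stats::sd),
    lo95 = qs[, 2],
    hi95 = qs[, 3],
    row.names = NULL
  )
}

#' Persist posterior draws as long-format CSV
#'
#' Columns \code{chain}, \code{iteration}, \code{parameter}, \code{value}.
#'
#' @param draws A \code{posterior_draws}.
#' @param path Output file.
#' @param parameters Which columns to write (default: the six model
#'   parameters, leaving out the latent states).
#' @return \code{path}, invisibly.
#' @export
write_draws_csv <- function(draws, path, parameters = param_names) {
  rows <- lapply(seq_along(draws$chains), function(ch) {
    m <- draws$chains[[ch]][, parameters, drop = FALSE]
    data.frame(
      chain = ch,
      iteration = rep(seq_len(nrow(m)), times = ncol(m)),
      parameter = rep(colnames(m), each = nrow(m)),
      value = as.vector(m)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
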