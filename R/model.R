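#' Construct an annual census series
#'
#' Bundles the annual monitoring data the state-space model is fitted to:
#' the observed population count and the number of pack reproductions per
#' year. A "year" labels a winter season by its later calendar year, so the
#' 1998/1999 winter is year 1999.
#'
#' @param years Integer vector of consecutive year labels.
#' @param nobs Non-negative integer counts (observed population size).
#' @param reproductions Non-negative integer counts of pack breeding events.
#' @return A \code{census_series}: data.frame with columns \code{year},
#'   \code{nobs}, \code{reproductions}.
#' @export
census_series <- function(years, nobs, reproductions) {
  years <- as.integer(years)
  if (length(nobs) != length(years) || length(reproductions) != length(years)) {
    stop("'years', 'nobs' and 'reproductions' must have equal length")
  }
  if (length(years) > 1L && any(diff(years) != 1L)) {
    stop("'years' must be consecutive")
  }
  if (any(nobs < 0) || any(reproductions < 0)) {
    stop("counts must be non-negative")
  }
  if (any(nobs != round(nobs)) || any(reproductions != round(reproductions))) {
    stop("counts must be integers")
  }
  structure(
    data.frame(year = years, nobs = as.integer(nobs),
               reproductions = as.integer(reproductions)),
    class = c("census_series", "data.frame")
  )
}

#' Read / write a census series as CSV
#'
#' The CSV has a header row and columns \code{year,nobs,reproductions},
#' one row per year with years strictly increasing.
#'
#' @param path File path.
#' @param x A \code{census_series}.
#' @return [read_census_csv()]: a \code{census_series};
#'   [write_census_csv()]: \code{path}, invisibly.
#' @export
read_census_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("year", "nobs", "reproductions")
  if (!all(need %in% names(df))) {
    stop("census CSV must have columns: ", paste(need, collapse = ", "))
  }
  census_series(df$year, df$nobs, df$reproductions)
}

#' @rdname read_census_csv
#' @export
write_census_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("year", "nobs", "reproductions")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Model parameters
#'
#' The six unknowns of the state-space model: \code{m}, \code{v}, \code{c}
#' are per-capita annual probabilities of dying from non-poaching causes,
#' verified poaching, and cryptic poaching; \code{l} is per-pack recruitment
#' (pups of ~6 months per reproduction); \code{sigma_proc} is the process sd
#' on the log scale; \code{sigma_nobs} the observation sd in count units.
#'
#' @param m,v,c Annual death probabilities in \code{[0, 1]} with
#'   \code{m + v + c <= 1}.
#' @param l Per-pack recruitment, non-negative.
#' @param sigma_proc Log-scale process sd, non-negative.
#' @param sigma_nobs Observation sd, non-negative.
#' @return A named list of class \code{model_params}.
#' @export
model_params <- function(m, v, c, l, sigma_proc, sigma_nobs) {
  vals <- c(m = m, v = v, c = c, l = l,
            sigma_proc = sigma_proc, sigma_nobs = sigma_nobs)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  if (m < 0 || v < 0 || c < 0 || m > 1 || v > 1 || c > 1) {
    stop("'m', 'v', 'c' must lie in [0, 1]")
  }
  if (m + v + c > 1) stop("total mortality m + v + c must not exceed 1")
  if (l < 0) stop("'l' must be non-negative")
  if (sigma_proc < 0 || sigma_nobs < 0) stop("sds must be non-negative")
  structure(as.list(vals), class = "model_params")
}

#' Deterministic one-step median of the population process
#'
#' The median next population size: survivors plus recruits,
#' \code{(1 - m - v - c) * prev_size + l * reproductions}. The three
#' mortality probabilities act per capita on the previous year's population;
#' recruitment enters per breeding pack.
#'
#' @param prev_size Previous true population size, positive.
#' @param params A \code{model_params} (or list with \code{m}, \code{v},
#'   \code{c}, \code{l}).
#' @param reproductions Number of pack reproductions this year.
#' @return Predicted median size, a positive number.
#' @export
process_median <- function(prev_size, params, reproductions) {
  if (!is.finite(prev_size) || prev_size <= 0) stop("'prev_size' must be positive")
  s <- params$m + params$v + params$c
  if (s > 1) stop("total mortality m + v + c must not exceed 1")
  (1 - s) * prev_size + params$l * reproductions
}

#' Lognormal process log density
#'
#' Log density of the true size \code{current} given the deterministic
#' median: \code{log(current)} is normal with mean \code{log(median)} and sd
#' \code{sigma_proc}, so \code{median} is the distribution's median, not its
#' mean. Out-of-support values give \code{-Inf} rather than an error.
#'
#' @param current Proposed true size.
#' @param median Deterministic median prediction.
#' @param sigma_proc Log-scale sd, positive.
#' @return Log density (scalar or vector).
#' @export
process_logdensity <- function(current, median, sigma_proc) {
  n <- max(length(current), length(median))
  current <- rep_len(current, n)
  median <- rep_len(median, n)
  out <- rep(-Inf, n)
  ok <- is.finite(current) & current > 0 & is.finite(median) & median > 0
  if (any(ok)) {
    out[ok] <- stats::dlnorm(current[ok], meanlog = log(median[ok]),
                             sdlog = sigma_proc, log = TRUE)
  }
  out
}

#' Marginal observation log density (gamma-Poisson / negative binomial)
#'
#' The count model is hierarchical: a Poisson mean is drawn from a gamma
#' distribution with mean equal to the latent size and sd
#' \code{sigma_nobs}, and the count is Poisson given that mean. Integrating
#' the Poisson mean out analytically yields a negative binomial with mean
#' \code{latent_size} and variance \code{latent_size + sigma_nobs^2}, which
#' is what this function evaluates; at \code{sigma_nobs = 0} it reduces to
#' the Poisson log pmf. All gamma-function work is done in log space.
#'
#' @param observed_count Non-negative integer count(s).
#' @param latent_size True population size, positive.
#' @param sigma_nobs Observation sd, non-negative.
#' @return Log pmf value(s).
#' @export
observation_logdensity <- function(observed_count, latent_size, sigma_nobs) {
  if (any(!is.finite(latent_size)) || any(latent_size <= 0)) {
    stop("'latent_size' must be positive")
  }
  if (sigma_nobs < 0) stop("'sigma_nobs' must be non-negative")
  if (sigma_nobs == 0) {
    return(stats::dpois(observed_count, lambda = latent_size, log = TRUE))
  }
  size <- latent_size^2 / sigma_nobs^2  # gamma shape = NB dispersion
  stats::dnbinom(observed_count, size = size, mu = latent_size, log = TRUE)
}

# Log density of the initial latent state: lognormal centred on the first
# observed count with log-sd 0.5 (weakly informative; the model is otherwise
# silent about year one).
initial_state_logdensity <- function(n1, first_obs, sdlog = 0.5) {
  if (!is.finite(n1) || n1 <= 0) return(-Inf)
  centre <- max(first_obs, 1)
  stats::dlnorm(n1, meanlog = log(centre), sdlog = sdlog, log = TRUE)
}

#' Joint log posterior of the state-space model
#'
#' Sum of the prior log densities of the six parameters, the initial-state
#' log density (lognormal centred on the first observed count, log-sd 0.5),
#' the lognormal process log densities for years 2..T, and the negative
#' binomial observation log densities for years 1..T. Returns \code{-Inf}
#' for parameter or latent values outside the support rather than raising.
#' Each mortality probability must lie in \code{[0, 1]}, but their sum is
#' not constrained jointly: a year's predicted median only has to stay
#' positive, which recruitment can ensure even when total mortality exceeds
#' one, so the joint prior stays the product of the independent marginals.
#'
#' @param params A \code{model_params} or named list of the six unknowns.
#' @param latent Positive numeric vector of latent sizes, one per data year.
#' @param data A \code{census_series}.
#' @param priors A \code{prior_set}.
#' @return Scalar log posterior (possibly \code{-Inf}).
#' @export
log_posterior <- function(params, latent, data, priors) {
  T <- nrow(data)
  if (length(latent) != T) stop("'latent' length must match the number of data years")
  p <- params
  vals <- c(p$m, p$v, p$c, p$l, p$sigma_proc, p$sigma_nobs)
  if (any(!is.finite(vals))) return(-Inf)
  if (p$m < 0 || p$m > 1 || p$v < 0 || p$v > 1 || p$c < 0 || p$c > 1) return(-Inf)
  if (p$l < 0 || p$sigma_proc <= 0 || p$sigma_nobs < 0) return(-Inf)

  lp <- prior_density(priors, "m", p$m, log = TRUE) +
    prior_density(priors, "v", p$v, log = TRUE) +
    prior_density(priors, "c", p$c, log = TRUE) +
    prior_density(priors, "l", p$l, log = TRUE) +
    prior_density(priors, "sigma_proc", p$sigma_proc, log = TRUE) +
    prior_density(priors, "sigma_nobs", p$sigma_nobs, log = TRUE)
  if (!is.finite(lp)) return(-Inf)
  if (T == 0L) return(lp)

  if (any(!is.finite(latent)) || any(latent <= 0)) return(-Inf)
  lp <- lp + initial_state_logdensity(latent[1], data$nobs[1])
  if (T > 1L) {
    mu <- (1 - p$m - p$v - p$c) * latent[-T] + p$l * data$reproductions[-1]
    if (any(mu <= 0)) return(-Inf)
    lp <- lp + sum(stats::dlnorm(latent[-1], meanlog = log(mu),
                                 sdlog = p$sigma_proc, log = TRUE))
  }
  lp <- lp + sum(observation_logdensity(data$nobs, latent, p$sigma_nobs))
  if (!is.finite(lp)) return(-Inf)
  lp
}
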