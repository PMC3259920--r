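#' Posterior-predictive counterfactual population projections
#'
#' Re-runs the population process over the data years for each posterior
#' draw with selected mortality terms removed: \code{"no_cryptic"} sets the
#' cryptic poaching probability to zero, \code{"no_poaching"} zeroes both
#' verified and cryptic poaching, \code{"custom"} applies user overrides,
#' and \code{"fitted"} simply summarizes the fitted latent states. Each
#' trajectory starts at that draw's own latent size in the first year and
#' propagates with that draw's parameters and process noise. Reproductions
#' are scaled per capita by default: the fitted per-capita reproduction rate
#' \code{rho_t = R_t / N_[t-1]} (observed reproductions over that draw's
#' latent size) is applied to the counterfactual population, so a larger
#' counterfactual population breeds proportionally more. With
#' \code{reproduction = "fixed_series"} the observed reproduction counts are
#' reused unchanged, which caps recruitment at its historical level.
#'
#' @param draws A \code{posterior_draws} from [run_mcmc()].
#' @param data A [census_series()]; defaults to the series the model was
#'   fitted to.
#' @param scenario One of \code{"fitted"}, \code{"no_cryptic"},
#'   \code{"no_poaching"}, \code{"custom"}.
#' @param set_rates Named numeric overrides of \code{m}, \code{v}, \code{c}
#'   for \code{scenario = "custom"}; negative values are rejected.
#' @param reproduction \code{"per_capita"} (default) or
#'   \code{"fixed_series"}.
#' @param n_draws Number of posterior draws to propagate (subsampled evenly
#'   from the pooled chains; all draws if fewer).
#' @param seed Integer seed for the process noise.
#' @return A \code{scenario_result}: \code{years}, \code{scenario},
#'   \code{draws} (matrix, rows = posterior draws, columns = years) and
#'   \code{summary} (data.frame \code{year}, \code{median}, \code{lo95},
#'   \code{hi95}).
#' @export
simulate_counterfactual <- function(draws, data = draws$data,
                                    scenario = c("fitted", "no_cryptic",
                                                 "no_poaching", "custom"),
                                    set_rates = NULL,
                                    reproduction = c("per_capita", "fixed_series"),
                                    n_draws = 2000, seed = 1L) {
  scenario <- match.arg(scenario)
  reproduction <- match.arg(reproduction)
  T <- nrow(data)
  if (T < 2) stop("need at least two data years to project")
  pooled <- pool_draws(draws)
  lat_cols <- paste0("N_", data$year)
  if (!all(lat_cols %in% colnames(pooled))) {
    stop("the fitted draws do not cover the requested years")
  }
  idx <- if (nrow(pooled) > n_draws) {
    round(seq(1, nrow(pooled), length.out = n_draws))
  } else seq_len(nrow(pooled))
  pooled <- pooled[idx, , drop = FALSE]
  nd <- nrow(pooled)

  if (scenario == "fitted") {
    mat <- pooled[, lat_cols, drop = FALSE]
  } else {
    m <- pooled[, "m"]; v <- pooled[, "v"]; cc <- pooled[, "c"]
    if (scenario == "no_cryptic") {
      cc <- rep(0, nd)
    } else if (scenario == "no_poaching") {
      v <- rep(0, nd); cc <- rep(0, nd)
    } else {
      if (is.null(set_rates)) stop("scenario 'custom' needs 'set_rates'")
      if (any(set_rates < 0)) stop("scenario would set a negative mortality rate")
      if ("m" %in% names(set_rates)) m <- rep(set_rates[["m"]], nd)
      if ("v" %in% names(set_rates)) v <- rep(set_rates[["v"]], nd)
      if ("c" %in% names(set_rates)) cc <- rep(set_rates[["c"]], nd)
    }
    l <- pooled[, "l"]; sp <- pooled[, "sigma_proc"]
    lat <- pooled[, lat_cols, drop = FALSE]
    set.seed(seed)
    mat <- matrix(NA_real_, nd, T)
    mat[, 1] <- lat[, 1]
    surv <- 1 - m - v - cc
    for (t in 2:T) {
      Rt <- if (reproduction == "per_capita") {
        data$reproductions[t] / lat[, t - 1] * mat[, t - 1]
      } else rep(data$reproductions[t], nd)
      mu <- surv * mat[, t - 1] + l * Rt
      mat[, t] <- stats::rlnorm(nd, meanlog = log(mu), sdlog = sp)
    }
  }
  colnames(mat) <- lat_cols
  qs <- t(apply(mat, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
                names = FALSE))
  structure(list(
    years = data$year, scenario = scenario,
    reproduction = if (scenario == "fitted") NA_character_ else reproduction,
    draws = mat,
    summary = data.frame(year = data$year, median = qs[, 1],
                         lo95 = qs[, 2], hi95 = qs[, 3])
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%d posterior draws):\n", x$scenario, nrow(x$draws)))
  print(transform(x$summary, median = round(median, 1),
                  lo95 = round(lo95, 1), hi95 = round(hi95, 1)),
        row.names = FALSE)
  invisible(x)
}

#' Write a scenario result to CSV
#'
#' Columns \code{year,median,lo95,hi95}.
#'
#' @param x A \code{scenario_result}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_scenario_csv <- function(x, path) {
  utils::write.csv(x$summary, path, row.names = FALSE)
  invisible(path)
}

#' Geometric mean annual growth rate
#'
#' \code{100 * ((last / first)^(1 / n_intervals) - 1)}, the constant annual
#' percentage growth that carries \code{first} to \code{last} over
#' \code{n_intervals} years.
#'
#' @param first_size,last_size Positive population sizes.
#' @param n_intervals Number of annual intervals between them.
#' @return Growth rate in percent.
#' @examples
#' annual_growth_rate(74, 263, 10)
#' @export
annual_growth_rate <- function(first_size, last_size, n_intervals) {
  if (!is.finite(first_size) || !is.finite(last_size) ||
      first_size <= 0 || last_size <= 0) {
    stop("population sizes must be positive")
  }
  if (n_intervals < 1) stop("'n_intervals' must be at least 1")
  100 * ((last_size / first_size)^(1 / n_intervals) - 1)
}

#' Per-year population deficit between two scenarios
#'
#' The number of animals per year separating scenario \code{a} from
#' scenario \code{b}: the difference of their per-year medians (additive
#' across scenario pairs), plus quantiles of the draw-wise differences when
#' both scenarios were propagated from the same posterior draws.
#'
#' @param a,b \code{scenario_result} objects over the same years.
#' @return Data.frame with columns \code{year}, \code{median_diff}, and —
#'   when draw counts match — \code{diff_median}, \code{diff_lo95},
#'   \code{diff_hi95} summarizing the draw-wise differences.
#' @export
population_deficit <- function(a, b) {
  if (!identical(a$years, b$years)) stop("scenario year ranges differ")
  out <- data.frame(year = a$years,
                    median_diff = a$summary$median - b$summary$median)
  if (nrow(a$draws) == nrow(b$draws)) {
    d <- a$draws - b$draws
    qs <- t(apply(d, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
                  names = FALSE))
    out$diff_median <- qs[, 1]
    out$diff_lo95 <- qs[, 2]
    out$diff_hi95 <- qs[, 3]
  }
  out
}

#' Census, fitted and counterfactual trajectories in one figure
#'
#' Base-graphics plot: census counts as points, fitted posterior median with
#' its 95 per cent credible band, counterfactual medians as extra lines, and
#' a shaded band between the first counterfactual and the fitted median —
#' the animals theoretically lost to the mortality source that scenario
#' removes.
#'
#' @param fitted A \code{scenario_result} with scenario \code{"fitted"}.
#' @param counterfactuals Named list of \code{scenario_result} objects.
#' @param data A [census_series()].
#' @param main Plot title.
#' @return Invisibly, \code{NULL}; called for the plot side effect.
#' @export
plot_scenarios <- function(fitted, counterfactuals = list(), data,
                           main = "Fitted and counterfactual population") {
  ylim <- range(0, data$nobs, fitted$summary$hi95,
                vapply(counterfactuals, function(s) max(s$summary$median),
                       numeric(1)))
  plot(data$year, data$nobs, pch = 17, ylim = ylim,
       xlab = "year", ylab = "population size", main = main)
  if (length(counterfactuals)) {
    cf1 <- counterfactuals[[1]]
    graphics::polygon(c(cf1$years, rev(cf1$years)),
                      c(cf1$summary$median, rev(fitted$summary$median)),
                      col = "grey85", border = NA)
    for (k in seq_along(counterfactuals)) {
      graphics::lines(counterfactuals[[k]]$years,
                      counterfactuals[[k]]$summary$median,
                      lty = 1, lwd = 2, col = k + 1)
      graphics::points(counterfactuals[[k]]$years,
                       counterfactuals[[k]]$summary$median,
                       pch = c(1, 5, 0)[1 + (k - 1) %% 3], col = k + 1)
    }
  }
  graphics::lines(fitted$years, fitted$summary$median, lwd = 2)
  graphics::points(fitted$years, fitted$summary$median, pch = 15)
  graphics::lines(fitted$years, fitted$summary$lo95, lty = 2)
  graphics::lines(fitted$years, fitted$summary$hi95, lty = 2)
  graphics::points(data$year, data$nobs, pch = 17)
  if (length(counterfactuals)) {
    graphics::legend("topleft", bty = "n",
                     legend = c("census", "fitted median", names(counterfactuals)),
                     pch = c(17, 15, rep(1, length(counterfactuals))),
                     col = c(1, 1, seq_along(counterfactuals) + 1))
  }
  invisible(NULL)
}
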