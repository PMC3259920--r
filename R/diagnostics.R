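#' Heidelberger-Welch convergence tests
#'
#' Runs the Heidelberger-Welch stationarity and half-width tests on each
#' column of a draw matrix (or each sampled quantity of a
#' \code{posterior_draws}, chains pooled per chain and reported per chain
#' mean). The stationarity test applies a Cramer-von-Mises test to the
#' standardized cumulative-sum (Brownian bridge) of the chain, discarding
#' initial 10 per cent chunks up to half the chain until it passes; the
#' half-width test passes when the half-width of the 95 per cent interval
#' for the mean, using the spectral density at frequency zero, is below
#' \code{epsilon} times the absolute mean. A zero-variance chain cannot be
#' tested and is reported as passing by convention, flagged degenerate.
#'
#' @param chain Numeric vector, matrix (columns = quantities), or
#'   \code{posterior_draws} (each chain tested separately and combined by
#'   all-chains-pass).
#' @param alpha Significance level of the stationarity test.
#' @param epsilon Half-width tolerance relative to the mean.
#' @return A data.frame with one row per quantity (and chain, for
#'   \code{posterior_draws} input): \code{parameter}, \code{chain},
#'   \code{stationarity_pass}, \code{start_iteration}, \code{pvalue},
#'   \code{halfwidth_ratio}, \code{halfwidth_pass}, \code{degenerate}.
#' @export
heidelberger_welch <- function(chain, alpha = 0.05, epsilon = 0.1) {
  if (inherits(chain, "posterior_draws")) {
    out <- lapply(seq_along(chain$chains), function(ch) {
      r <- heidelberger_welch(chain$chains[[ch]], alpha, epsilon)
      r$chain <- ch
      r
    })
    return(do.call(rbind, out))
  }
  mat <- if (is.matrix(chain)) chain else matrix(chain, ncol = 1,
                                                 dimnames = list(NULL, "chain"))
  if (nrow(mat) < 100) stop("need a chain of at least 100 draws")
  one <- function(x, nm) {
    if (stats::sd(x) == 0) {
      return(data.frame(parameter = nm, chain = 1L, stationarity_pass = TRUE,
                        start_iteration = 1, pvalue = NA_real_,
                        halfwidth_ratio = 0, halfwidth_pass = TRUE,
                        degenerate = TRUE))
    }
    hd <- coda::heidel.diag(coda::mcmc(x), eps = epsilon, pvalue = alpha)
    mean_est <- hd[1, "mean"]
    hw <- hd[1, "halfwidth"]
    ratio <- if (is.na(hw) || mean_est == 0) NA_real_ else abs(hw / mean_est)
    data.frame(
      parameter = nm, chain = 1L,
      stationarity_pass = isTRUE(hd[1, "stest"] == 1),
      start_iteration = hd[1, "start"],
      pvalue = hd[1, "pvalue"],
      halfwidth_ratio = ratio,
      halfwidth_pass = isTRUE(hd[1, "htest"] == 1),
      degenerate = FALSE
    )
  }
  out <- do.call(rbind, lapply(seq_len(ncol(mat)), function(j) {
    one(mat[, j], colnames(mat)[j] %||% paste0("V", j))
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kernel density estimate with boundary reflection, evaluated on a grid.
reflected_kde <- function(draws, grid, lower, upper) {
  bw <- stats::bw.nrd0(draws)
  pad <- 4 * bw
  rng <- range(grid)
  d0 <- stats::density(draws, bw = bw, n = 4096,
                       from = rng[1] - pad, to = rng[2] + pad)
  f0 <- function(x) {
    y <- stats::approx(d0$x, d0$y, xout = x, yleft = 0, yright = 0)$y
    y
  }
  f <- f0(grid)
  if (is.finite(lower)) f <- f + f0(2 * lower - grid)
  if (is.finite(upper)) f <- f + f0(2 * upper - grid)
  f
}

trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Prior-posterior overlap statistic
#'
#' The overlap coefficient \code{tau = integral of min(prior density,
#' posterior density)}: near 1 when the data add no information beyond the
#' prior, small when the posterior departs from it. The posterior density is
#' a kernel estimate of the draws with boundary reflection on bounded
#' supports; the integral is evaluated by the trapezoid rule on a
#' 2048-point grid spanning the support (bounded sides) or the combined
#' range of prior mass and draws (unbounded sides).
#'
#' @param draws Numeric vector of at least 1000 posterior draws.
#' @param prior A function returning the prior density at a vector of
#'   points.
#' @param support Length-2 numeric: support of the prior; entries may be
#'   infinite.
#' @return Overlap in \code{[0, 1]}.
#' @export
prior_posterior_overlap <- function(draws, prior, support = c(-Inf, Inf)) {
  if (length(draws) < 1000) stop("need at least 1000 posterior draws")
  lo <- support[1]
  hi <- support[2]
  eps <- 1e-9
  if (any(draws < lo - eps | draws > hi + eps)) {
    stop("posterior draws fall outside the prior support")
  }
  bw <- stats::bw.nrd0(draws)
  glo <- if (is.finite(lo)) lo else min(draws) - 4 * bw
  ghi <- if (is.finite(hi)) hi else max(draws) + 4 * bw
  grid <- seq(glo, ghi, length.out = 2048)
  post <- reflected_kde(draws, grid, lo, hi)
  pri <- prior(grid)
  pri[!is.finite(pri)] <- 0
  min(1, trapezoid(grid, pmin(pri, post)))
}

#' Overlap table for a fitted model
#'
#' Computes [prior_posterior_overlap()] for each model parameter of a
#' \code{posterior_draws} against its own prior.
#'
#' @param draws A \code{posterior_draws}.
#' @param parameters Which parameters to evaluate.
#' @return Data.frame with columns \code{parameter} and \code{tau}
#'   (percent).
#' @export
overlap_table <- function(draws,
                          parameters = c("m", "v", "c", "l",
                                         "sigma_proc", "sigma_nobs")) {
  pooled <- pool_draws(draws)
  priors <- draws$priors
  tau <- vapply(parameters, function(pm) {
    supp <- prior_support(priors, pm)
    if (!is.finite(supp[2])) {
      # cap the grid at the far prior tail for unbounded parameters
      sp <- priors[[pm]]
      if (sp$family == "gamma") {
        supp[2] <- max(stats::qgamma(1 - 1e-8, sp$shape, sp$rate),
                       max(pooled[, pm]))
      }
    }
    prior_posterior_overlap(pooled[, pm],
                            function(x) prior_density(priors, pm, x),
                            supp)
  }, numeric(1))
  data.frame(parameter = parameters, tau = 100 * unname(tau))
}
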