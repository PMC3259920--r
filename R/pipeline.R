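round_half_up <- function(x) floor(x + 0.5)

#' Headline mortality shares
#'
#' From the three posterior median mortality probabilities, the share of
#' total mortality attributable to poaching,
#' \code{100 * (v + c) / (m + v + c)}, and the share of poaching that is
#' cryptic, \code{100 * c / (v + c)}, both rounded half-up to whole
#' percent.
#'
#' @param m_median,v_median,c_median Non-negative posterior medians of the
#'   non-poaching, verified-poaching and cryptic-poaching probabilities;
#'   their sum must be positive, and the cryptic share requires
#'   \code{v + c > 0}.
#' @return Named numeric vector \code{c(poaching_share, cryptic_share)} in
#'   percent.
#' @examples
#' derive_headline_shares(0.142, 0.046, 0.103)
#' @export
derive_headline_shares <- function(m_median, v_median, c_median) {
  if (any(c(m_median, v_median, c_median) < 0)) {
    stop("rates must be non-negative")
  }
  tot <- m_median + v_median + c_median
  if (tot <= 0) stop("total mortality must be positive")
  poach <- v_median + c_median
  if (poach <= 0) {
    stop("no poaching mortality: the cryptic share is undefined")
  }
  c(poaching_share = unname(round_half_up(100 * poach / tot)),
    cryptic_share = unname(round_half_up(100 * c_median / poach)))
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

resolve_priors <- function(config, rates) {
  choice <- config$priors %||% "derived"
  if (inherits(choice, "prior_set")) return(choice)
  if (identical(choice, "study")) return(study_prior_set())
  if (identical(choice, "uninformative")) {
    return(build_prior_set(NULL, 1, 1, uninformative_all = TRUE))
  }
  if (!identical(choice, "derived")) stop("unknown priors option: ", choice)
  if (is.null(rates)) {
    mom <- study_telemetry_moments()
    return(build_prior_set(mom, mom$litter_mean, mom$litter_sd))
  }
  build_prior_set(rates,
                  config$litter_mean %||% study_telemetry_moments()$litter_mean,
                  config$litter_sd %||% study_telemetry_moments()$litter_sd)
}

#' Run the full estimation pipeline
#'
#' Orchestrates every stage on one configuration: classify telemetry
#' records (when supplied), estimate cause-specific mortality with
#' competing risks, build the prior set, fit the state-space model by MCMC,
#' run Heidelberger-Welch convergence checks, compute prior-posterior
#' overlap, project the requested counterfactual scenarios, and assemble a
#' report. Any stage failure aborts with an error message naming the
#' stage. Results are deterministic given the configuration: every
#' stochastic step derives its seed from \code{config$seed}.
#'
#' @param config A named list (or path to a JSON/YAML file holding one)
#'   with entries: \code{census} (a [census_series()] or CSV path;
#'   default: [synthetic_study_series()]), optional \code{records} (an
#'   \code{individual_records} or CSV path), \code{priors}
#'   (\code{"derived"}, \code{"study"}, \code{"uninformative"}, or a
#'   \code{prior_set}), \code{litter_mean}/\code{litter_sd},
#'   \code{mcmc} (list passed to [mcmc_settings()] overrides; default
#'   profile \code{"desk"}), \code{profile}, \code{scenarios} (character,
#'   default \code{c("no_cryptic", "no_poaching")}), \code{reproduction}
#'   (\code{"per_capita"} or \code{"fixed_series"}), \code{n_boot},
#'   \code{seed}, and optional \code{out_dir}.
#' @return Invisibly, a list with \code{config}, \code{fates},
#'   \code{rates}, \code{priors}, \code{draws}, \code{convergence},
#'   \code{overlap}, \code{posterior}, \code{scenarios} (per scenario the
#'   summary and 2009-style final-year medians), \code{headline} (shares,
#'   observed and counterfactual growth) and \code{results} (the
#'   machine-readable report list, written to
#'   \code{out_dir/results.json} when \code{out_dir} is set, along with
#'   CSV tables).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- stage_wrap("config", {
      if (grepl("\\.ya?ml$", config)) {
        if (!requireNamespace("yaml", quietly = TRUE)) {
          stop("reading YAML configs needs the 'yaml' package")
        }
        yaml::read_yaml(config)
      } else {
        jsonlite::read_json(config, simplifyVector = TRUE)
      }
    })
  }
  seed <- as.integer(config$seed %||% 1L)

  census <- stage_wrap("input", {
    cs <- config$census
    if (is.null(cs)) cs <- synthetic_study_series()
    if (is.character(cs)) {
      if (!file.exists(cs)) stop("census file not found: ", cs)
      cs <- read_census_csv(cs)
    }
    cs
  })

  records <- stage_wrap("input", {
    rc <- config$records
    if (is.character(rc)) {
      if (!file.exists(rc)) stop("records file not found: ", rc)
      rc <- read_records_csv(rc)
    }
    rc
  })

  fates <- NULL
  rates <- NULL
  if (!is.null(records)) {
    fates <- stage_wrap("classify", classify_fate(records))
    rates <- stage_wrap("rates", estimate_cause_specific_rates(
      records, fate = fates, n_boot = config$n_boot %||% 1000, seed = seed))
  }

  priors <- stage_wrap("priors", resolve_priors(config, rates))

  settings <- stage_wrap("fit", do.call(mcmc_settings, c(
    list(profile = config$profile %||% "desk"), config$mcmc)))
  draws <- stage_wrap("fit", run_mcmc(census, priors, settings, seed = seed))

  convergence <- stage_wrap("diagnose", heidelberger_welch(draws))
  overlap <- stage_wrap("overlap", overlap_table(draws))
  posterior <- stage_wrap("report", summarize_posterior(draws))

  scen_names <- config$scenarios %||% c("no_cryptic", "no_poaching")
  repro_mode <- config$reproduction %||% "per_capita"
  fitted <- stage_wrap("counterfactual", simulate_counterfactual(
    draws, census, "fitted", seed = seed))
  scenarios <- stage_wrap("counterfactual", {
    out <- lapply(scen_names, function(sc) {
      simulate_counterfactual(draws, census, sc, reproduction = repro_mode,
                              seed = seed + match(sc, scen_names))
    })
    stats::setNames(out, scen_names)
  })

  headline <- stage_wrap("report", {
    med <- stats::setNames(posterior$median, posterior$parameter)
    shares <- derive_headline_shares(med["m"], med["v"], med["c"])
    Tn <- nrow(census)
    obs_growth <- annual_growth_rate(census$nobs[1], census$nobs[Tn], Tn - 1)
    final <- vapply(scenarios, function(s) s$summary$median[Tn], numeric(1))
    growth <- vapply(scenarios, function(s) {
      annual_growth_rate(s$summary$median[1], s$summary$median[Tn], Tn - 1)
    }, numeric(1))
    list(shares = shares, observed_growth = obs_growth,
         final_year = census$year[Tn],
         counterfactual_final = final, counterfactual_growth = growth)
  })

  results <- list(
    config = config[setdiff(names(config), c("census", "records", "priors"))],
    seed = seed,
    priors = lapply(unclass(priors), function(sp) sp[names(sp)]),
    posterior = posterior[posterior$parameter %in% param_names, ],
    overlap = overlap,
    convergence_pass = all(convergence$stationarity_pass),
    headline = headline,
    scenarios = lapply(scenarios, function(s) s$summary)
  )
  if (!is.null(rates)) {
    results$rates <- lapply(
      rates[c("nonpoaching", "verified_poaching", "cryptic_poaching")],
      function(x) x[c("estimate", "sd", "n_events")])
  }

  if (!is.null(config$out_dir)) {
    stage_wrap("report", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(results, file.path(config$out_dir, "results.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      utils::write.csv(posterior, file.path(config$out_dir, "posterior_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(overlap, file.path(config$out_dir, "overlap.csv"),
                       row.names = FALSE)
      utils::write.csv(convergence, file.path(config$out_dir, "convergence.csv"),
                       row.names = FALSE)
      write_scenario_csv(fitted, file.path(config$out_dir, "scenario_fitted.csv"))
      for (sc in names(scenarios)) {
        write_scenario_csv(scenarios[[sc]],
                           file.path(config$out_dir, paste0("scenario_", sc, ".csv")))
      }
    })
  }

  invisible(list(
    config = config, fates = fates, rates = rates, priors = priors,
    draws = draws, convergence = convergence, overlap = overlap,
    posterior = posterior, fitted = fitted, scenarios = scenarios,
    headline = headline, results = results
  ))
}
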