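# Shared fixtures: priors built from the published telemetry moments, and a
# cached fit of the synthetic study reconstruction so several test files can
# interrogate one MCMC run.

study_priors <- function() {
  mom <- study_telemetry_moments()
  build_prior_set(mom, mom$litter_mean, mom$litter_sd)
}

.fit_cache <- new.env(parent = emptyenv())

cached_study_fit <- function() {
  if (is.null(.fit_cache$study)) {
    cs <- synthetic_study_series()
    .fit_cache$study <- run_mcmc(
      cs, study_priors(),
      mcmc_settings("quick", chains = 6, n_keep = 10000, burn_in = 16000),
      seed = 1
    )
  }
  .fit_cache$study
}

# A degenerate posterior: every draw identical, zero process noise. Lets the
# counterfactual machinery be checked against exact recursions.
point_mass_draws <- function(m, v, c, l, sigma_nobs, latent, data,
                             n = 50, sigma_proc = 0) {
  stopifnot(length(latent) == nrow(data))
  row <- c(m = m, v = v, c = c, l = l,
           sigma_proc = sigma_proc, sigma_nobs = sigma_nobs,
           stats::setNames(latent, paste0("N_", data$year)))
  mat <- matrix(rep(row, each = n), nrow = n,
                dimnames = list(NULL, names(row)))
  structure(list(chains = list(mat), accept = list(), step = list(),
                 settings = list(chains = 1L, n_keep = n, burn_in = 0L,
                                 thin = 1L, profile = "point"),
                 seed = 0L, chain_seeds = 0L, data = data, priors = NULL),
            class = "posterior_draws")
}

# Records with explicit evidence, for classifier tests.
make_record <- function(battery = NA_real_, searches = 0L, resident = FALSE,
                        dna_absence = FALSE, police = FALSE, body = FALSE,
                        necropsy = FALSE, tissue = FALSE,
                        monitored_to_end = FALSE,
                        entry = 0, exit = 1, id = "W001") {
  structure(data.frame(
    id = id, entry_time = entry, exit_time = exit, fate = NA_character_,
    monitored_to_end = monitored_to_end,
    battery_fraction_remaining = battery,
    aerial_searches_done = searches,
    was_resident = resident,
    dna_confirms_absence = dna_absence,
    police_report_poaching_attempt = police,
    body_recovered = body,
    necropsy_illegal_kill = necropsy,
    tissue_dna_match_conviction = tissue
  ), class = c("individual_records", "data.frame"))
}
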