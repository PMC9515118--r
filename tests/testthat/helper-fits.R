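# One small shared fit, built lazily and cached for the whole test run, so
# posterior-dependent tests do not each pay for their own MCMC.

.fit_cache <- new.env(parent = emptyenv())

shared_hyper <- function() {
  group_hyper(mu_r0 = 1.0, mu_gamma0 = 2.5, mu_tau0 = 6.7,
              mu_dr_right = 1e-9, mu_dr_left = 1e-9,
              mu_dgamma_right = 1e-9, mu_dgamma_left = 0.6,
              mu_dtau_right = 1e-9, mu_dtau_left = 1e-9,
              sigma = 0.25)
}

shared_trials <- function() {
  if (is.null(.fit_cache$trials))
    .fit_cache$trials <- simulate_dataset(shared_hyper(), 8, seed = 2024)
  .fit_cache$trials
}

shared_fit <- function() {
  if (is.null(.fit_cache$fit))
    .fit_cache$fit <- suppressWarnings(
      fit_rdu(shared_trials(), "kahneman_tversky", "gain",
              mcmc_config("test", chains = 2, warmup = 150, sampling = 300, max_leapfrog = 16),
              seed = 99))
  .fit_cache$fit
}
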