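make_toy_trials <- function(n = 10, seed = 77, subjects = 1) {
  h <- group_hyper(sigma = 0.3)
  d <- simulate_dataset(h, subjects, seed = seed)
  d <- d[d$domain == "gain", ]
  d[seq_len(min(n, nrow(d))), ]
}

params_for <- function(trials, r = 0.9, gamma = 2, tau = 5) {
  expand.grid(subject = unique(trials$subject),
              condition = c("sham", "right", "left"),
              stringsAsFactors = FALSE) |>
    transform(r = r, gamma = gamma, tau = tau)
}

test_that("choice log-likelihood matches a per-trial product oracle", {
  spec <- model_spec("kahneman_tversky", "gain")
  trials <- make_toy_trials(10)
  params <- params_for(trials)
  got <- log_likelihood(trials, params, spec)
  want <- vapply(seq_len(nrow(trials)), function(t) {
    p_a <- oracle_choice_prob(trials$xA_best[t], trials$xA_worst[t],
                              trials$xB_best[t], trials$xB_worst[t],
                              trials$p_best[t], 0.9, 2, 5,
                              "kahneman_tversky", "gain")
    log(if (trials$choice[t] == "A") p_a else 1 - p_a)
  }, numeric(1))
  expect_equal(got$pointwise, want, tolerance = 1e-12)
  expect_equal(got$total, sum(want), tolerance = 1e-12)
})

test_that("log-likelihood limiting cases behave", {
  spec <- model_spec("linear", "gain")
  # a single trial between identical options carries probability 1/2
  tr <- data.frame(subject = 1, session = 1, condition = "sham",
                   domain = "gain", mpl_id = "m", row_index = 1,
                   xA_best = 100, xA_worst = 50, xB_best = 100,
                   xB_worst = 50, p_best = 0.4, choice = "A")
  prm <- data.frame(subject = 1, condition = "sham", r = 1, gamma = 1, tau = 2)
  expect_equal(log_likelihood(tr, prm, spec)$total, log(0.5))
  # deterministic-limit params with consistent choices: log-lik -> 0-
  # (rows at exact expected-value ties stay at probability 1/2 and are
  # excluded)
  trials <- make_toy_trials(60)
  pa <- rdurisk:::choice_prob_rows(trials, preference_params(1, 1, 1e6),
                                   "linear")
  trials <- trials[abs(pa - 0.5) > 1e-3, ]
  pa <- pa[abs(pa - 0.5) > 1e-3]
  trials$choice <- ifelse(pa > 0.5, "A", "B")
  prm2 <- params_for(trials, r = 1, gamma = 1, tau = 1e6)
  ll <- log_likelihood(trials, prm2, spec)$total
  expect_lte(ll, 0)
  expect_gt(ll, -1e-6)
})

test_that("likelihood is invariant to trial order", {
  spec <- model_spec("prelec1", "gain")
  trials <- make_toy_trials(40)
  params <- params_for(trials)
  set.seed(1)
  shuffled <- trials[sample(nrow(trials)), ]
  expect_equal(log_likelihood(trials, params, spec)$total,
               log_likelihood(shuffled, params, spec)$total,
               tolerance = 1e-12)
})

test_that("compiled and reference likelihoods agree", {
  spec <- model_spec("kahneman_tversky", "gain")
  trials <- make_toy_trials(60, subjects = 2)
  md <- rdurisk:::model_data(trials, spec)
  K <- md$K
  set.seed(6)
  z <- rnorm(2 * K + md$n_sub * K, 0, 0.4)
  pw_cpp <- rdurisk:::cpp_pointwise_loglik_one(z, md)
  # compose the constrained per-subject parameters the same way in R
  tab <- spec$params
  sig <- exp(z[K + seq_len(K)])
  params <- do.call(rbind, lapply(seq_along(md$subjects), function(i) {
    ci <- vapply(seq_len(K), function(k) {
      constrain(z[k] + sig[k] * z[2 * K + (i - 1) * K + k],
                tab$lower[k], tab$upper[k])
    }, numeric(1))
    names(ci) <- tab$name
    do.call(rbind, lapply(c("sham", "right", "left"), function(cc) {
      add <- function(b, dr, dl) max(
        b + switch(cc, sham = 0, right = ci[[dr]], left = ci[[dl]]), 1e-6)
      data.frame(subject = md$subjects[i], condition = cc,
                 r = add(ci[["r0"]], "dr_right", "dr_left"),
                 gamma = add(ci[["gamma0"]], "dgamma_right", "dgamma_left"),
                 tau = add(ci[["tau0"]], "dtau_right", "dtau_left"))
    }))
  }))
  pw_r <- log_likelihood(trials, params, spec)$pointwise
  expect_equal(pw_cpp, pw_r, tolerance = 1e-10)
})

test_that("the joint log density reduces to the prior without data", {
  spec <- model_spec("kahneman_tversky", "gain")
  empty <- make_toy_trials(5)[0, ]
  tab <- spec$params
  K <- nrow(tab)
  set.seed(9)
  for (i in 1:5) {
    z <- rnorm(2 * K, 0, 1)
    want <- sum(dnorm(z[seq_len(K)], tab$prior_mean, tab$prior_sd, log = TRUE)) +
      sum(dnorm(z[K + seq_len(K)], 0, 3, log = TRUE))
    expect_equal(log_density(z, empty, spec), want, tolerance = 1e-10)
  }
  # finite at the origin on a small simulated dataset
  trials <- make_toy_trials(400, subjects = 4)
  z0 <- rep(0, 2 * K + 4 * K)
  expect_true(is.finite(log_density(z0, trials, spec)))
})

test_that("analytic gradients match numerical differentiation", {
  spec <- model_spec("kahneman_tversky", "gain")
  trials <- make_toy_trials(200, subjects = 3)
  md <- rdurisk:::model_data(trials, spec)
  K <- md$K
  set.seed(13)
  z <- rnorm(2 * K + 3 * K, 0, 0.4)
  g <- rdurisk:::cpp_log_density_grad(z, md)
  num <- vapply(seq_along(z), function(j) {
    e <- 1e-5
    zp <- z; zp[j] <- zp[j] + e
    zm <- z; zm[j] <- zm[j] - e
    (rdurisk:::cpp_log_density(zp, md) -
       rdurisk:::cpp_log_density(zm, md)) / (2 * e)
  }, numeric(1))
  expect_equal(g$grad, num, tolerance = 1e-5)
})

test_that("fitting is deterministic by seed and respects bounds", {
  trials <- shared_trials()
  cfg <- mcmc_config("test", chains = 2, warmup = 60, sampling = 60, max_leapfrog = 16)
  f1 <- suppressWarnings(fit_rdu(trials, "linear", "gain", cfg, seed = 4))
  f2 <- suppressWarnings(fit_rdu(trials, "linear", "gain", cfg, seed = 4))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_rdu(trials, "linear", "gain", cfg, seed = 5))
  expect_false(identical(f1$draws, f3$draws))
  # all constrained draws respect their bounds
  fit <- shared_fit()
  tab <- fit$spec$params
  for (k in seq_len(nrow(tab))) {
    smp <- as.vector(fit$draws[, , paste0("mu_", tab$name[k])])
    expect_true(all(smp > tab$lower[k]))
    if (is.finite(tab$upper[k])) expect_true(all(smp < tab$upper[k]))
    expect_true(all(fit$draws[, , paste0("sigma_", tab$name[k])] > 0))
  }
  expect_equal(dim(fit$draws)[1:2], c(300, 2))
  expect_equal(nrow(fit$loglik), 600)
  expect_equal(ncol(fit$loglik), sum(shared_trials()$domain == "gain"))
})

test_that("the paper-scale configuration implies 32,000 kept draws", {
  cfg <- mcmc_config("paper")
  expect_equal(cfg$chains, 8L)
  expect_equal(cfg$warmup, 1000L)
  expect_equal(cfg$sampling, 4000L)
  expect_equal(total_draws(cfg), 32000L)
})

test_that("posterior serialization writes a complete columnar table", {
  fit <- shared_fit()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_posterior(fit, path)
  long <- read.delim(path)
  expect_equal(nrow(long),
               total_draws(fit$config) * length(dimnames(fit$draws)[[3]]))
  expect_true(file.exists(paste0(path, ".meta.json")))
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  expect_equal(meta$family, "kahneman_tversky")
  expect_true(file.exists(paste0(path, ".loglik.tsv")))
  # round-trip of one parameter column
  sub <- long[long$parameter == "mu_tau0" & long$chain == 1, ]
  expect_equal(sub$value[order(sub$draw)], fit$draws[, 1, "mu_tau0"])
})

test_that("split R-hat and ESS behave on known chains", {
  set.seed(19)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(abs(rhat(good) - 1), 0.01)
  expect_gt(ess(good), 0.6 * 4000)
  expect_lte(ess(good), 4000)
  bad <- cbind(rnorm(500, 0), rnorm(500, 10))
  expect_gt(rhat(bad), 2)
  # strongly autocorrelated chains have small ESS
  ar <- replicate(4, as.vector(arima.sim(list(ar = 0.99), 500)))
  expect_lt(ess(ar), 200)
  fit1 <- shared_fit()
  fit1chain <- fit1
  fit1chain$config$chains <- 1L
  expect_error(diagnostics(fit1chain), "2 chains")
})

test_that("prior marginals of constrained draws match transform sampling", {
  # prior-only model: fitted draws of a bounded parameter must match
  # direct transform-sampling of its prior (Kolmogorov-Smirnov)
  spec <- model_spec("kahneman_tversky", "gain")
  empty <- make_toy_trials(5)[0, ]
  md <- rdurisk:::model_data_allow_empty(empty, spec)
  set.seed(23)
  res <- rdurisk:::cpp_hmc_chain(md, rnorm(18, 0, 0.5), 300, 1500, 16, 0.8)
  k_dg_left <- which(spec$params$name == "dgamma_left")
  drawn <- constrain(res$draws[, k_dg_left], -1.5, 1.5)
  direct <- constrain(rnorm(2000, 0, 1), -1.5, 1.5)
  ks <- suppressWarnings(ks.test(drawn, direct))
  expect_gt(ks$p.value, 0.001)
})
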