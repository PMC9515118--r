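#' MCMC configuration
#'
#' The `"paper"` profile is the full-scale configuration (8 chains, 1000
#' warm-up and 4000 sampling iterations each, i.e. 32,000 kept draws per
#' parameter). The `"test"` profile (2 chains, 1000/1000, trajectory
#' length up to 48) is a desk-scale configuration sized so that
#' group-level inference on a dozen-subject dataset is well mixed within
#' seconds-to-minutes; it is a first-class feature for reduced-scale
#' validation runs.
#'
#' @param profile `"paper"` or `"test"`; explicit arguments override the
#'   profile values.
#' @param chains,warmup,sampling Number of chains and per-chain iteration
#'   counts.
#' @param max_leapfrog Upper bound of the jittered leapfrog-step count.
#' @param adapt_delta Target acceptance probability for step-size
#'   adaptation.
#' @return An object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(profile = c("paper", "test"), chains = NULL,
                        warmup = NULL, sampling = NULL, max_leapfrog = NULL,
                        adapt_delta = 0.8) {
  profile <- match.arg(profile)
  def <- if (profile == "paper") c(8L, 1000L, 4000L, 32L)
         else c(2L, 1000L, 1000L, 48L)
  max_leapfrog <- max_leapfrog %||% def[4]
  cfg <- list(profile = profile,
              chains = as.integer(chains %||% def[1]),
              warmup = as.integer(warmup %||% def[2]),
              sampling = as.integer(sampling %||% def[3]),
              max_leapfrog = as.integer(max_leapfrog),
              adapt_delta = adapt_delta)
  stopifnot(cfg$chains >= 1, cfg$warmup >= 1, cfg$sampling >= 1)
  class(cfg) <- "mcmc_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kept posterior draws implied by a configuration
#' @param config An [mcmc_config()].
#' @return `chains * sampling`.
#' @export
total_draws <- function(config) config$chains * config$sampling

# complete-pooling maximum likelihood of (r, gamma, tau) on one domain's
# trials; used to initialize chains in the interior of the parameter space
# (far from the saturation region of the probit transforms, where gradients
# vanish and short warm-ups can strand a chain)
pooled_mle <- function(trials, family, domain) {
  trials <- trials[trials$domain == domain, , drop = FALSE]
  s <- if (domain == "gain") 1 else -1
  nll <- function(lpar) {
    r <- exp(lpar[1]); g <- exp(lpar[2]); tau <- exp(lpar[3])
    if (family == "linear") g <- 1
    w <- prob_weight(trials$p_best, g, family)
    u <- function(x) sign(x) * abs(x)^r
    eu_a <- w * u(trials$xA_best) + (1 - w) * u(trials$xA_worst)
    eu_b <- w * u(trials$xB_best) + (1 - w) * u(trials$xB_worst)
    if (any(eu_a * eu_b <= 0)) return(1e10)
    h <- s * tau / r * (log(abs(eu_a)) - log(abs(eu_b)))
    -sum(ifelse(trials$choice == "A", -log1p(exp(-h)), -log1p(exp(h))))
  }
  fit <- stats::optim(log(c(1, 1.5, 3)), nll, method = "Nelder-Mead",
                      control = list(maxit = 1000))
  est <- exp(fit$par)
  # clip into the interior of the admissible supports
  c(r = min(max(est[1], 0.1), 4.5),
    gamma = min(max(est[2], 0.2), 5.5),
    tau = min(max(est[3], 0.3), 60))
}

# unconstrained initial point centred on the pooled MLE: group means at the
# MLE baselines, shift means at zero, modest group SDs, subjects at the
# group means
init_from_mle <- function(mle, spec, n_sub) {
  tab <- spec$params
  K <- nrow(tab)
  mu <- vapply(seq_len(K), function(k) {
    if (!is.na(tab$cond[k])) return(0)
    unconstrain(mle[[tab$target[k]]], tab$lower[k], tab$upper[k])
  }, numeric(1))
  c(mu, rep(log(0.2), K), rep(0, n_sub * K))
}

# assemble the data/model list handed to the compiled log density
model_data <- function(trials, spec) {
  trials <- trials[trials$domain == spec$domain, , drop = FALSE]
  if (!nrow(trials)) stop("no trials in the requested domain", call. = FALSE)
  subjects <- sort(unique(trials$subject))
  tab <- spec$params
  list(
    K = nrow(tab), n_sub = length(subjects),
    family = match(spec$family, weighting_families()) - 1L,
    lower = tab$lower, upper = tab$upper,
    prior_mean = tab$prior_mean, prior_sd = tab$prior_sd,
    target = match(tab$target, c("r", "gamma", "tau")) - 1L,
    condk = ifelse(is.na(tab$cond), 0L, match(tab$cond, c("right", "left"))),
    sub = match(trials$subject, subjects) - 1L,
    cond = match(trials$condition, c("sham", "right", "left")) - 1L,
    y = as.integer(trials$choice == "A"),
    sgn = ifelse(trials$domain == "gain", 1, -1),
    p_best = trials$p_best,
    outcomes = as.matrix(trials[, c("xA_best", "xA_worst",
                                    "xB_best", "xB_worst")]),
    subjects = subjects, trials = trials
  )
}

#' Bernoulli log-likelihood of observed choices
#'
#' Reference (pure-R) evaluation of the choice likelihood given composed
#' per-subject-and-condition preference parameters. Used as the
#' independent check of the compiled likelihood and for toy examples.
#'
#' @param trials Trial records (one domain).
#' @param params Data frame with columns `subject`, `condition`, `r`,
#'   `gamma`, `tau` — one row per subject-condition present in `trials`.
#' @param spec A [model_spec()].
#' @return List with `total` (scalar) and `pointwise` (per-trial vector).
#' @export
log_likelihood <- function(trials, params, spec) {
  trials <- trials[trials$domain == spec$domain, , drop = FALSE]
  key <- paste(trials$subject, trials$condition)
  pkey <- paste(params$subject, params$condition)
  idx <- match(key, pkey)
  if (anyNA(idx)) stop("params missing for some subject-condition", call. = FALSE)
  pw <- vapply(seq_len(nrow(trials)), function(t) {
    i <- idx[t]
    pp <- preference_params(params$r[i], params$gamma[i], params$tau[i])
    pr <- lottery_pair(
      lottery(trials$xA_best[t], trials$xA_worst[t], trials$p_best[t]),
      lottery(trials$xB_best[t], trials$xB_worst[t], trials$p_best[t]))
    p_a <- choice_prob(pr, pp, spec$family, trials$domain[t])
    if (trials$choice[t] == "A") log(p_a) else log1p(-p_a)
  }, numeric(1))
  if (any(!is.finite(pw))) stop("non-finite log-likelihood term", call. = FALSE)
  list(total = sum(pw), pointwise = pw)
}

#' Joint log density of the hierarchical model
#'
#' Log prior of the group-level means and SDs plus the non-centered
#' hierarchy plus the choice log-likelihood, evaluated at an unconstrained
#' parameter vector (see `param_layout`). The group-SD prior is expressed
#' on the log scale (normal(0, 3) on `log sigma`), which is exactly the
#' lognormal(0, 3) prior on `sigma` after the change of variables.
#'
#' @param z Unconstrained parameter vector.
#' @param trials Trial records (may have zero rows for a prior-only check).
#' @param spec A [model_spec()].
#' @return Scalar log density (`-Inf` outside the support).
#' @export
log_density <- function(z, trials, spec) {
  md <- model_data_allow_empty(trials, spec)
  cpp_log_density(z, md)
}

model_data_allow_empty <- function(trials, spec) {
  if (nrow(trials[trials$domain == spec$domain, , drop = FALSE]) == 0L) {
    tab <- spec$params
    list(K = nrow(tab), n_sub = 0L,
         family = match(spec$family, weighting_families()) - 1L,
         lower = tab$lower, upper = tab$upper,
         prior_mean = tab$prior_mean, prior_sd = tab$prior_sd,
         target = match(tab$target, c("r", "gamma", "tau")) - 1L,
         condk = ifelse(is.na(tab$cond), 0L,
                        match(tab$cond, c("right", "left"))),
         sub = integer(0), cond = integer(0), y = integer(0),
         sgn = numeric(0), p_best = numeric(0),
         outcomes = matrix(numeric(0), 0, 4))
  } else model_data(trials, spec)
}

constrained_names <- function(tab, subjects) {
  # subject blocks are parameter-type-fastest: r0[1], ..., dtau_left[1],
  # r0[2], ...
  c(paste0("mu_", tab$name), paste0("sigma_", tab$name),
    as.vector(outer(tab$name, seq_along(subjects),
                    function(nm, i) sprintf("%s[%d]", nm, i))))
}

# map an unconstrained draw matrix (draws x dim) to the constrained scale
constrain_draws <- function(draws, tab, n_sub) {
  K <- nrow(tab)
  out <- matrix(NA_real_, nrow(draws), 2L * K + n_sub * K)
  for (k in seq_len(K)) {
    out[, k] <- constrain(draws[, k], tab$lower[k], tab$upper[k])
    out[, K + k] <- exp(draws[, K + k])
    if (n_sub > 0) {
      sig <- exp(draws[, K + k])
      for (i in seq_len(n_sub)) {
        zz <- draws[, k] + sig * draws[, 2L * K + (i - 1L) * K + k]
        out[, 2L * K + (i - 1L) * K + k] <-
          constrain(zz, tab$lower[k], tab$upper[k])
      }
    }
  }
  out
}

#' Fit the hierarchical rank-dependent-utility model
#'
#' Samples the posterior with a self-contained Hamiltonian Monte Carlo
#' sampler (static trajectories with jittered length, dual-averaging
#' step-size adaptation and a diagonal mass matrix estimated during
#' warm-up). Chains run sequentially from one seeded RNG stream, so results
#' are reproducible given `seed`.
#'
#' @param trials Trial records (see [simulate_dataset()] / [read_trials()]).
#' @param family One of [weighting_families()].
#' @param domain Domain whose choices enter the likelihood.
#' @param config An [mcmc_config()].
#' @param seed Integer seed.
#' @param store_loglik Keep the draws x trials pointwise log-likelihood
#'   matrix (needed for WAIC/LOO).
#' @param init `"mle"` starts every chain near the complete-pooling maximum
#'   likelihood point (jittered per chain); `"random"` uses independent
#'   N(0, 0.5) unconstrained starts.
#' @return An object of class `"rdu_fit"`: constrained draws
#'   (`$draws`, iterations x chains x parameters), sampler metadata,
#'   convergence diagnostics and, optionally, `$loglik`.
#' @export
fit_rdu <- function(trials, family = "kahneman_tversky",
                    domain = c("gain", "loss"),
                    config = mcmc_config("test"), seed = 1L,
                    store_loglik = TRUE, init = c("mle", "random")) {
  domain <- match.arg(domain)
  init <- match.arg(init)
  spec <- model_spec(family, domain)
  md <- model_data(trials, spec)
  K <- md$K; n_sub <- md$n_sub
  dim <- 2L * K + n_sub * K
  z_base <- if (init == "mle")
    init_from_mle(pooled_mle(trials, spec$family, domain), spec, n_sub)
  else rep(0, dim)

  chains <- vector("list", config$chains)
  info <- vector("list", config$chains)
  with_seed(seed, {
    for (ch in seq_len(config$chains)) {
      z0 <- if (init == "mle") z_base + stats::rnorm(dim, 0, 0.1)
            else stats::rnorm(dim, 0, 0.5)
      res <- cpp_hmc_chain(md, z0, config$warmup, config$sampling,
                           config$max_leapfrog, config$adapt_delta)
      chains[[ch]] <- res$draws
      info[[ch]] <- res[c("step_size", "accept_rate", "divergences")]
    }
  })

  div <- sum(vapply(info, function(x) x$divergences, numeric(1)))
  if (div > 0)
    warning(sprintf("%d divergent transitions after warm-up", div),
            call. = FALSE)

  pnames <- constrained_names(spec$params, md$subjects)
  draws <- array(NA_real_,
                 c(config$sampling, config$chains, length(pnames)),
                 dimnames = list(NULL, NULL, pnames))
  for (ch in seq_len(config$chains))
    draws[, ch, ] <- constrain_draws(chains[[ch]], spec$params, n_sub)

  loglik <- NULL
  if (store_loglik) {
    loglik <- do.call(rbind, lapply(chains, cpp_pointwise_loglik, model = md))
  }

  fit <- structure(list(
    spec = spec, config = config, seed = seed,
    subjects = md$subjects, n_trials = nrow(md$trials),
    trials = md$trials, model_data = md[setdiff(names(md), "trials")],
    unconstrained = chains, draws = draws, loglik = loglik,
    sampler = info), class = "rdu_fit")
  fit$diagnostics <- diagnostics(fit)
  fit
}

#' @export
print.rdu_fit <- function(x, ...) {
  cat(sprintf("<rdu_fit> %s / %s: %d subjects, %d trials, %d chains x %d draws\n",
              x$spec$family, x$spec$domain, length(x$subjects), x$n_trials,
              x$config$chains, x$config$sampling))
  grp <- group_names(x)
  d <- x$diagnostics
  cat(sprintf("  max split-Rhat (group level): %.3f; min ESS: %.0f\n",
              max(d$rhat[grp], na.rm = TRUE), min(d$ess[grp], na.rm = TRUE)))
  invisible(x)
}

group_names <- function(fit) {
  paste0("mu_", fit$spec$params$name)
}

#' Extract posterior draws
#'
#' @param fit An `"rdu_fit"`.
#' @param pars Parameter names (constrained scale); default all.
#' @return Matrix with `chains * sampling` rows (chains stacked) and one
#'   column per parameter.
#' @export
posterior_draws <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "rdu_fit"))
  pnames <- dimnames(fit$draws)[[3]]
  pars <- pars %||% pnames
  bad <- setdiff(pars, pnames)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out <- apply(fit$draws[, , pars, drop = FALSE], 3, rbind)
  colnames(out) <- pars
  out
}

#' Serialize posterior draws to a columnar table
#'
#' Long format (`chain`, `draw`, `parameter`, `value`) written as
#' tab-separated text, with a JSON metadata sidecar (`<path>.meta.json`)
#' recording family, domain, configuration and seed. The pointwise
#' log-likelihood, when present, is saved separately next to it.
#'
#' @param fit An `"rdu_fit"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(fit, path) {
  stopifnot(inherits(fit, "rdu_fit"))
  pnames <- dimnames(fit$draws)[[3]]
  long <- expand.grid(draw = seq_len(fit$config$sampling),
                      chain = seq_len(fit$config$chains),
                      parameter = pnames, stringsAsFactors = FALSE)
  long$value <- as.vector(fit$draws)
  long <- long[c("chain", "draw", "parameter", "value")]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(family = fit$spec$family, domain = fit$spec$domain,
               chains = fit$config$chains, warmup = fit$config$warmup,
               sampling = fit$config$sampling, seed = fit$seed,
               subjects = length(fit$subjects), trials = fit$n_trials)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             paste0(path, ".meta.json"))
  if (!is.null(fit$loglik))
    utils::write.table(fit$loglik, paste0(path, ".loglik.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
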