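#' Equal-tailed credible interval
#'
#' Percentile interval using the default quantile interpolation (type 7).
#'
#' @param samples Numeric vector of at least 100 posterior samples (fewer
#'   are accepted for degenerate checks but give crude intervals).
#' @param level Interval mass in `(0, 1)`, typically 0.89 or 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(samples, level = 0.95) {
  stopifnot(is.numeric(samples), length(samples) >= 2L)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must lie in (0, 1)", call. = FALSE)
  a <- (1 - level) / 2
  unname(stats::quantile(samples, c(a, 1 - a), type = 7))
}

#' Prior density of a group-level shift at zero
#'
#' Under the standard-normal prior on the unconstrained group mean and the
#' matched-scale Phi transform onto `(a, b)`, the implied prior on the
#' constrained shift is uniform, so the density at zero is `1 / (b - a)`
#' (1/4 for the `r` shifts, 1/3 for the `gamma` shifts, 1/10 for the `tau`
#' shifts). A Monte-Carlo path (`method = "sample"`) estimates the same
#' density from transformed prior draws as a cross-check.
#'
#' @param lower,upper Bounds of the shift parameter.
#' @param method `"analytic"` or `"sample"`.
#' @param n_draws,seed Monte-Carlo settings for `method = "sample"`.
#' @return Prior density at zero.
#' @export
prior_density_at_zero <- function(lower, upper,
                                  method = c("analytic", "sample"),
                                  n_draws = 1e5, seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.finite(lower), is.finite(upper), lower < 0, upper > 0)
  if (method == "analytic") return(1 / (upper - lower))
  with_seed(seed, {
    draws <- constrain(stats::rnorm(n_draws), lower, upper)
    density_at(draws, 0)
  })
}

density_at <- function(samples, x0, bw = NULL) {
  bw <- bw %||% stats::bw.nrd0(samples)
  mean(stats::dnorm(x0, mean = samples, sd = bw))
}

#' Savage-Dickey Bayes factor at zero
#'
#' `BF10 = prior density at 0 / posterior density at 0` for the point null
#' `H0: delta = 0` nested in `H1: delta != 0`. The posterior density is a
#' Gaussian kernel density estimate at zero (Silverman's rule-of-thumb
#' bandwidth by default).
#'
#' @param posterior_samples Posterior draws of the shift parameter on the
#'   constrained scale.
#' @param prior_density_at_zero Prior density of the shift at zero (see
#'   [prior_density_at_zero()]).
#' @param bw Kernel bandwidth; default Silverman.
#' @return BF10 (values above 1 favour a non-zero shift).
#' @export
savage_dickey_bf <- function(posterior_samples, prior_density_at_zero,
                             bw = NULL) {
  stopifnot(length(posterior_samples) >= 100L, prior_density_at_zero > 0)
  bw <- bw %||% stats::bw.nrd0(posterior_samples)
  if (mean(abs(posterior_samples) <= bw) < 0.01)
    warning("fewer than 1% of samples within one bandwidth of zero; ",
            "density estimate at zero may be unstable", call. = FALSE)
  prior_density_at_zero / density_at(posterior_samples, 0, bw)
}

#' Classify Bayes-factor evidence
#'
#' Jeffreys-style bins: (1, 3) anecdotal, (3, 10) moderate, (10, 30)
#' strong, (30, 100) very strong, > 100 extreme evidence for H1;
#' reciprocal bins for H0; exactly 1 is equivocal.
#'
#' @param bf10 Bayes factor in favour of H1, `> 0`.
#' @return Character label.
#' @export
classify_evidence <- function(bf10) {
  if (!is.numeric(bf10) || length(bf10) != 1L || !is.finite(bf10) || bf10 <= 0)
    stop("bf10 must be a positive number", call. = FALSE)
  if (bf10 == 1) return("equivocal")
  b <- max(bf10, 1 / bf10)
  strength <- if (b <= 3) "anecdotal" else if (b <= 10) "moderate" else
    if (b <= 30) "strong" else if (b <= 100) "very strong" else "extreme"
  sprintf("%s evidence for %s", strength, if (bf10 > 1) "H1" else "H0")
}

#' Summaries of the six stimulation-shift parameters
#'
#' Posterior mean, 89% and 95% equal-tailed credible intervals,
#' Savage-Dickey BF10 and its evidence label for each group-level shift
#' (`mu_dr_right`, ..., `mu_dtau_left`), on the constrained scale on which
#' the shifts are reported.
#'
#' @param fit An `"rdu_fit"` of a model containing all six shifts (i.e. a
#'   non-linear weighting family).
#' @return Data frame of class `"effect_table"` with one row per shift.
#' @export
effect_table <- function(fit) {
  stopifnot(inherits(fit, "rdu_fit"))
  tab <- fit$spec$params
  deltas <- tab[!is.na(tab$cond), , drop = FALSE]
  if (nrow(deltas) != 6L)
    stop("effect table requires all six shift parameters (non-linear family)",
         call. = FALSE)
  rows <- lapply(seq_len(nrow(deltas)), function(k) {
    nm <- paste0("mu_", deltas$name[k])
    if (!nm %in% dimnames(fit$draws)[[3]])
      stop("parameter not found in fit: ", nm, call. = FALSE)
    smp <- as.vector(fit$draws[, , nm])
    ci89 <- credible_interval(smp, 0.89)
    ci95 <- credible_interval(smp, 0.95)
    bf <- savage_dickey_bf(smp, prior_density_at_zero(deltas$lower[k],
                                                      deltas$upper[k]))
    data.frame(parameter = nm, mean = mean(smp),
               ci89_lower = ci89[1], ci89_upper = ci89[2],
               ci95_lower = ci95[1], ci95_upper = ci95[2],
               bf10 = bf, evidence = classify_evidence(bf),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("effect_table", "data.frame")
  out
}
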