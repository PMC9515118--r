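logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

check_ll_matrix <- function(ll) {
  ll <- as.matrix(ll)
  if (nrow(ll) < 2L) stop("at least 2 draws are required", call. = FALSE)
  if (any(!is.finite(ll)))
    stop("pointwise log-likelihood contains non-finite entries", call. = FALSE)
  ll
}

#' Widely applicable information criterion
#'
#' `lppd_i = log mean_s exp(ll_si)` (log-sum-exp stabilized),
#' `p_waic_i = var_s(ll_si)`, `waic = -2 * (lppd - p_waic)`.
#'
#' @param ll Pointwise log-likelihood matrix, draws x observations.
#' @return List with `waic`, `se`, `p_waic`, `elpd_waic` and the pointwise
#'   `elpd_i`.
#' @export
waic <- function(ll) {
  ll <- check_ll_matrix(ll)
  S <- nrow(ll)
  lppd_i <- apply(ll, 2, logsumexp) - log(S)
  p_i <- apply(ll, 2, stats::var)
  elpd_i <- lppd_i - p_i
  list(waic = -2 * sum(elpd_i),
       se = 2 * sqrt(ncol(ll) * stats::var(elpd_i)),
       p_waic = sum(p_i), elpd_waic = sum(elpd_i), elpd_i = elpd_i)
}

# Generalized Pareto fit to tail exceedances (Zhang & Stephens 2009
# profile-posterior estimator, with the weak shrinkage of the shape toward
# 0.5 used by the published PSIS procedure). Returns shape k and scale
# sigma in the (k, sigma) parameterization with quantile
# q(p) = sigma/k * ((1-p)^(-k) - 1).
gpd_fit <- function(y) {
  y <- sort(y)
  n <- length(y)
  m <- 30L + floor(sqrt(n))
  ystar <- y[max(1L, floor(n / 4 + 0.5))]
  jj <- seq_len(m)
  theta <- 1 / y[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * ystar)
  prof <- vapply(theta, function(th) {
    k <- -mean(log1p(-th * y))
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- exp(prof - logsumexp(prof))
  theta_hat <- sum(theta * w)
  k <- -mean(log1p(-theta_hat * y))
  sigma <- k / theta_hat
  k <- (n * k + 5) / (n + 10)  # shrink shape toward 0.5
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smoothed importance weights for one observation: raw log weights
# in, stabilized log weights and the tail shape out.
psis_weights <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  khat <- NA_real_
  if (M >= 5) {
    ord <- order(lw)
    tail_ids <- ord[(S - M + 1L):S]
    cutoff <- lw[ord[S - M]]
    exc <- exp(lw[tail_ids]) - exp(cutoff)
    if (any(exc > 0)) {
      fit <- gpd_fit(exc[exc > 0])
      khat <- fit$k
      if (is.finite(khat)) {
        pr <- (seq_len(M) - 0.5) / M
        sm <- exp(cutoff) + vapply(pr, qgpd, numeric(1),
                                   k = fit$k, sigma = fit$sigma)
        sm <- log(pmin(sm, exp(max(lw))))
        lw[tail_ids[order(lw[tail_ids])]] <- sm
      }
    } else khat <- -Inf
  }
  list(lw = lw, khat = khat)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Importance ratios `1 / p(y_i | theta_s)` are stabilized by fitting a
#' generalized Pareto distribution to the largest 20% of the weights and
#' replacing them with expected order statistics, per the published PSIS
#' procedure. Observations with a tail-shape estimate above 0.7 are
#' flagged.
#'
#' @param ll Pointwise log-likelihood matrix, draws x observations.
#' @return List with `looic`, `se`, `elpd_loo`, `p_loo`, pointwise
#'   `elpd_i` and `pareto_k`.
#' @export
psis_loo <- function(ll) {
  ll <- check_ll_matrix(ll)
  S <- nrow(ll); N <- ncol(ll)
  lppd_i <- apply(ll, 2, logsumexp) - log(S)
  elpd_i <- numeric(N)
  k_i <- numeric(N)
  for (i in seq_len(N)) {
    ps <- psis_weights(-ll[, i])
    elpd_i[i] <- logsumexp(ll[, i] + ps$lw) - logsumexp(ps$lw)
    k_i[i] <- ps$khat
  }
  n_bad <- sum(is.finite(k_i) & k_i > 0.7)
  if (n_bad > 0)
    warning(sprintf("%d observation(s) with Pareto k > 0.7", n_bad),
            call. = FALSE)
  list(looic = -2 * sum(elpd_i),
       se = 2 * sqrt(N * stats::var(elpd_i)),
       elpd_loo = sum(elpd_i), p_loo = sum(lppd_i - elpd_i),
       elpd_i = elpd_i, pareto_k = k_i)
}

#' Compare fitted models by LOOIC and WAIC
#'
#' @param fits Named list of `"rdu_fit"` objects fitted to the same trials
#'   (pointwise log-likelihood stored).
#' @return A `"comparison_report"`: per-model criteria table and the
#'   selected model.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1L, !is.null(names(fits)))
  n_obs <- vapply(fits, function(f) ncol(f$loglik), numeric(1))
  if (length(unique(n_obs)) != 1L)
    stop("models were fitted to different numbers of trials", call. = FALSE)
  rows <- lapply(names(fits), function(nm) {
    w <- waic(fits[[nm]]$loglik)
    l <- psis_loo(fits[[nm]]$loglik)
    data.frame(model = nm, looic = l$looic, looic_se = l$se,
               waic = w$waic, waic_se = w$se, p_loo = l$p_loo,
               p_waic = w$p_waic,
               max_pareto_k = suppressWarnings(
                 max(l$pareto_k[is.finite(l$pareto_k)], -Inf)),
               n_pareto_k_high = sum(is.finite(l$pareto_k) &
                                       l$pareto_k > 0.7),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, selected = select_model(tab)),
            class = "comparison_report")
}

#' Select the best model from a criteria table
#'
#' Smallest LOOIC wins; LOOIC ties (within 1e-8) fall back to WAIC, then to
#' the simpler model (fewer weighting parameters, i.e. earlier in
#' [weighting_families()] order, else first listed).
#'
#' @param tab Data frame with columns `model`, `looic`, `waic` (as produced
#'   by [compare_models()]).
#' @return The selected model name.
#' @export
select_model <- function(tab) {
  if (inherits(tab, "comparison_report")) tab <- tab$table
  stopifnot(nrow(tab) >= 1L)
  simplicity <- match(tab$model, weighting_families(), nomatch = 99L)
  ord <- order(round(tab$looic, 8), round(tab$waic, 8), simplicity,
               seq_len(nrow(tab)))
  tab$model[ord[1]]
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$table, row.names = FALSE)
  cat("selected:", x$selected, "\n")
  invisible(x)
}

#' Posterior predictive choice accuracy
#'
#' Draws `n_samples` parameter vectors from the joint posterior, predicts
#' every choice (modal rule by default: the option with choice probability
#' above one half; `method = "sample"` draws the prediction from the
#' choice distribution instead) and reports the distribution of the
#' proportion of correctly predicted choices.
#'
#' @param fit An `"rdu_fit"` with stored pointwise log-likelihood.
#' @param n_samples Number of posterior samples to use (at most the number
#'   of kept draws).
#' @param method `"modal"` or `"sample"`.
#' @param seed Optional seed for the subsample (and the sampled
#'   predictions).
#' @return List with `median`, `ci95` and the per-sample `accuracy`.
#' @export
ppc_accuracy <- function(fit, n_samples = 1000L,
                         method = c("modal", "sample"), seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "rdu_fit"), !is.null(fit$loglik))
  S <- nrow(fit$loglik)
  if (n_samples > S) stop("n_samples exceeds the number of draws", call. = FALSE)
  with_seed(seed, {
    rows <- if (n_samples == S) seq_len(S) else sample.int(S, n_samples)
    # exp(ll) is the probability assigned to the observed choice, so the
    # modal prediction is correct exactly when it exceeds 1/2 (ties, a
    # measure-zero event on this design, break toward the observed choice)
    pobs <- exp(fit$loglik[rows, , drop = FALSE])
    acc <- if (method == "modal") {
      rowMeans(pobs >= 0.5)
    } else {
      rowMeans(matrix(stats::runif(length(pobs)), nrow(pobs)) < pobs)
    }
    list(median = stats::median(acc),
         ci95 = credible_interval(acc, 0.95),
         accuracy = acc)
  })
}
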