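#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the standard between/within variance
#' ratio is computed over the resulting `2 * chains` sequences.
#'
#' @param x Matrix of draws, iterations x chains (at least 2 chains, or 1
#'   chain of at least 4 iterations which is then split).
#' @return Scalar R-hat (`NA` for constant draws).
#' @export
rhat <- function(x) {
  x <- split_chains(as.matrix(x))
  m <- ncol(x); n <- nrow(x)
  if (m < 2L) stop("at least 2 (split) chains are required", call. = FALSE)
  if (stats::sd(x) == 0) return(NA_real_)
  means <- colMeans(x)
  vars <- apply(x, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

split_chains <- function(x) {
  n <- nrow(x)
  if (n < 4L) return(x)
  h <- n %/% 2L
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1L):n, , drop = FALSE])
}

#' Effective sample size
#'
#' Autocorrelation-based ESS of split chains using Geyer's initial
#' monotone positive sequence to truncate the lag sums.
#'
#' @inheritParams rhat
#' @return Scalar ESS (capped at the total number of draws).
#' @export
ess <- function(x) {
  x <- split_chains(as.matrix(x))
  m <- ncol(x); n <- nrow(x)
  if (m < 2L) stop("at least 2 (split) chains are required", call. = FALSE)
  if (stats::sd(x) == 0) return(NA_real_)
  vars <- apply(x, 2, stats::var)
  means <- colMeans(x)
  W <- mean(vars)
  var_plus <- (n - 1) / n * W + stats::var(means)
  if (var_plus == 0) return(NA_real_)
  # chain-averaged autocovariances
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = n - 1L, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # Geyer: sum pairs (rho_0 + rho_1), (rho_2 + rho_3), ... while the pair
  # sums stay positive and non-increasing
  max_pairs <- length(rho) %/% 2L
  psum <- numeric(0)
  for (k in seq_len(max_pairs)) {
    s <- rho[2 * k - 1] + rho[2 * k]
    if (s < 0) break
    if (length(psum) && s > psum[length(psum)]) s <- psum[length(psum)]
    psum <- c(psum, s)
  }
  tau_int <- max(2 * sum(psum) - 1, 1e-12)
  min(m * n / tau_int, m * n)
}

#' Convergence diagnostics of a fit
#'
#' Split R-hat and effective sample size for every constrained parameter.
#'
#' @param fit An `"rdu_fit"` (at least two chains).
#' @return List of class `"rdu_diagnostics"` with named vectors `rhat` and
#'   `ess`.
#' @export
diagnostics <- function(fit) {
  stopifnot(inherits(fit, "rdu_fit"))
  if (fit$config$chains < 2L)
    stop("diagnostics require at least 2 chains", call. = FALSE)
  pnames <- dimnames(fit$draws)[[3]]
  r <- vapply(pnames, function(p) rhat(fit$draws[, , p]), numeric(1))
  e <- vapply(pnames, function(p) ess(fit$draws[, , p]), numeric(1))
  structure(list(rhat = r, ess = e), class = "rdu_diagnostics")
}

#' @export
print.rdu_diagnostics <- function(x, ...) {
  cat(sprintf("<rdu_diagnostics> max Rhat %.4f, min ESS %.0f (%d parameters)\n",
              max(x$rhat, na.rm = TRUE), min(x$ess, na.rm = TRUE),
              length(x$rhat)))
  invisible(x)
}
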