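#' Map an unconstrained value into a bounded support
#'
#' Positively-bounded parameters use the exponential transform
#' (`(0, Inf) -> exp(z)`); two-sided bounds use the Phi transform
#' (`(a, b) -> a + (b - a) * pnorm(z)`). Both are strictly monotone with
#' closed-form inverses.
#'
#' @param z Unconstrained real value(s).
#' @param lower,upper Bounds of the support; `upper = Inf` selects the
#'   exponential transform (then `lower` must be 0).
#' @return Constrained value(s).
#' @export
constrain <- function(z, lower, upper) {
  check_bounds(lower, upper)
  if (is.infinite(upper)) exp(z) else lower + (upper - lower) * stats::pnorm(z)
}

#' @rdname constrain
#' @param x Constrained value(s) inside the support.
#' @export
unconstrain <- function(x, lower, upper) {
  check_bounds(lower, upper)
  if (is.infinite(upper)) {
    if (any(x <= 0)) stop("x must be positive", call. = FALSE)
    log(x)
  } else {
    if (any(x <= lower | x >= upper)) stop("x outside (lower, upper)", call. = FALSE)
    stats::qnorm((x - lower) / (upper - lower))
  }
}

check_bounds <- function(lower, upper) {
  stopifnot(length(lower) == 1L, length(upper) == 1L)
  if (is.infinite(upper)) {
    if (lower != 0) stop("half-open supports must be (0, Inf)", call. = FALSE)
  } else if (!is.finite(lower) || !(lower < upper)) {
    stop("bounds must satisfy lower < upper", call. = FALSE)
  }
  invisible(TRUE)
}

# Parameter-type table of the hierarchical model: one row per group-level
# quantity. Baselines are bounded per the stated parameter space; the six
# condition deltas have symmetric two-sided bounds wide relative to typical
# baseline magnitudes. Prior means/SDs apply to the group mean on the
# unconstrained scale; all group SDs have a lognormal(0, 3) prior.
param_table <- function(family) {
  tab <- data.frame(
    name  = c("r0", "gamma0", "tau0", "dr_right", "dr_left",
              "dgamma_right", "dgamma_left", "dtau_right", "dtau_left"),
    target = c("r", "gamma", "tau", "r", "r", "gamma", "gamma", "tau", "tau"),
    cond  = c(NA, NA, NA, "right", "left", "right", "left", "right", "left"),
    lower = c(0, 0, 0, -2, -2, -1.5, -1.5, -5, -5),
    upper = c(5, 6, Inf, 2, 2, 1.5, 1.5, 5, 5),
    prior_mean = c(0, 1, 0, 0, 0, 0, 0, 0, 0),
    prior_sd   = c(5, 3, 10, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  if (match_family(family) == "linear")
    tab <- tab[tab$target != "gamma", , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Specification of one hierarchical model
#'
#' Collects the weighting family, the outcome domain that the likelihood is
#' evaluated on, and the parameter-type table (bounds, transforms, group
#' priors).
#'
#' @param family One of [weighting_families()].
#' @param domain `"gain"` or `"loss"`.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(family = weighting_families(),
                       domain = c("gain", "loss")) {
  family <- match_family(family)
  domain <- match.arg(domain)
  structure(list(family = family, domain = domain,
                 params = param_table(family)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> family=%s domain=%s (%d group-level types)\n",
              x$family, x$domain, nrow(x$params)))
  invisible(x)
}

# layout of the unconstrained parameter vector for n subjects and K types:
# [mu_1..mu_K | log_sigma_1..log_sigma_K | eta_{subject 1, 1..K}, ...]
param_layout <- function(spec, n_subjects) {
  K <- nrow(spec$params)
  list(K = K, n_subjects = n_subjects, dim = 2L * K + n_subjects * K,
       mu = seq_len(K), log_sigma = K + seq_len(K),
       eta = function(i) 2L * K + (i - 1L) * K + seq_len(K))
}
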