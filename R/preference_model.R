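#' Probability weighting families
#'
#' Closed set of the one-parameter weighting functions used for estimation:
#' `"linear"` (`w(p) = p`), `"kahneman_tversky"`
#' (`w(p) = p^g / (p^g + (1-p)^g)^(1/g)`) and `"prelec1"`
#' (`w(p) = exp(-(-log p)^a)`).
#' @return Character vector of family names.
#' @export
weighting_families <- function() c("linear", "kahneman_tversky", "prelec1")

match_family <- function(family) match.arg(family, weighting_families())

#' Constant relative risk aversion utility
#'
#' `U(x) = x^r` for `x >= 0` and `-(-x)^r` for `x < 0`. In the gain domain
#' `r < 1` is risk aversion and `r > 1` risk seeking; the interpretation
#' reverses for losses.
#'
#' @param x Monetary outcome(s), signed.
#' @param r Risk-preference coefficient, `> 0`.
#' @return Utility value(s).
#' @export
crra_utility <- function(x, r) {
  stopifnot(is.numeric(x), is.numeric(r), length(r) == 1L)
  if (!is.finite(r) || r <= 0) stop("r must be positive", call. = FALSE)
  sign(x) * abs(x)^r
}

#' Probability weighting function
#'
#' Endpoints are exact (`w(0) = 0`, `w(1) = 1`; the Prelec endpoint is the
#' limit). Interior probabilities are clamped to `[1e-12, 1 - 1e-12]` before
#' taking logs.
#'
#' @param p Probability (vectorized), in `[0, 1]`.
#' @param param Curvature parameter (`gamma`, or `alpha` for Prelec), `> 0`.
#' @param family One of [weighting_families()].
#' @return Decision weight(s) in `[0, 1]`.
#' @export
prob_weight <- function(p, param, family = weighting_families()) {
  family <- match_family(family)
  stopifnot(is.numeric(p), is.numeric(param), length(param) == 1L)
  if (!is.finite(param) || param <= 0) stop("param must be positive", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]", call. = FALSE)
  if (family == "linear") return(p)
  w <- numeric(length(p))
  at0 <- p == 0; at1 <- p == 1
  w[at1] <- 1
  mid <- !(at0 | at1)
  if (any(mid)) {
    pm <- pmin(pmax(p[mid], 1e-12), 1 - 1e-12)
    w[mid] <- if (family == "kahneman_tversky") {
      pm^param / (pm^param + (1 - pm)^param)^(1 / param)
    } else {
      exp(-(-log(pm))^param)
    }
  }
  w
}

#' Rank-dependent utility of a lottery
#'
#' The best outcome receives weight `w(p_best)`; the worst outcome receives
#' the complement `1 - w(p_best)`, so the decision weights always sum to 1.
#'
#' @param lottery A [lottery()].
#' @param params A [preference_params()] (or any list with `r` and `gamma`).
#' @param family One of [weighting_families()].
#' @return Weighted utility of the lottery.
#' @export
rdu_value <- function(lottery, params, family = weighting_families()) {
  family <- match_family(family)
  w <- prob_weight(lottery$p_best, if (family == "linear") 1 else params$gamma,
                   family)
  w * crra_utility(lottery$x_best, params$r) +
    (1 - w) * crra_utility(lottery$x_worst, params$r)
}

#' Preference parameters of one subject in one condition
#'
#' @param r Risk-preference coefficient, `> 0`.
#' @param gamma Weighting-function curvature (`alpha` for Prelec), `> 0`.
#' @param tau Inverse temperature (choice consistency), `> 0`; `tau = 1/mu`
#'   where `mu` is the Luce noise parameter.
#' @return An object of class `"preference_params"`.
#' @export
preference_params <- function(r, gamma = 1, tau = 1) {
  stopifnot(r > 0, gamma > 0, tau > 0)
  structure(list(r = as.numeric(r), gamma = as.numeric(gamma),
                 tau = as.numeric(tau)),
            class = "preference_params")
}

#' Luce-form choice probability
#'
#' Probability of choosing option A:
#' `P(A) = plogis(tau * (1/r) * log(EU_A / EU_B))` in the gain domain. With
#' CRRA losses both weighted utilities are negative and the preference
#' ordering on `|EU|` reverses, so in the loss domain the sign of the
#' log-ratio term is flipped: the option with the larger (less negative)
#' weighted utility keeps choice probability above one half. The `1/r`
#' factor is the value-function transformation that decorrelates `r` and
#' the noise parameter.
#'
#' @param pair A [lottery_pair()].
#' @param params A [preference_params()].
#' @param family One of [weighting_families()].
#' @param domain `"gain"` or `"loss"`.
#' @return Probability in `(0, 1)`.
#' @export
choice_prob <- function(pair, params, family = weighting_families(),
                        domain = c("gain", "loss")) {
  domain <- match.arg(domain)
  family <- match_family(family)
  eu_a <- rdu_value(pair$option_a, params, family)
  eu_b <- rdu_value(pair$option_b, params, family)
  if (!is.finite(eu_a) || !is.finite(eu_b) || eu_a * eu_b <= 0)
    stop("weighted utilities must be nonzero and share a sign", call. = FALSE)
  s <- if (domain == "gain") 1 else -1
  stats::plogis(s * params$tau * (1 / params$r) * (log(abs(eu_a)) - log(abs(eu_b))))
}

#' Simulate one binary choice
#'
#' Bernoulli draw from [choice_prob()] using the current RNG stream.
#'
#' @inheritParams choice_prob
#' @return `"A"` or `"B"`.
#' @export
simulate_choice <- function(pair, params, family = weighting_families(),
                            domain = c("gain", "loss")) {
  p <- choice_prob(pair, params, family, domain)
  if (stats::runif(1) < p) "A" else "B"
}
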