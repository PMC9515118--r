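#' Two-outcome lottery
#'
#' A lottery pays `x_best` with probability `p_best` and `x_worst` with the
#' complementary probability. By convention `x_best >= x_worst` and, within a
#' domain, outcomes do not change sign: gains satisfy `x_best > x_worst >= 0`,
#' losses `x_worst < x_best <= 0` (mixed lotteries are not represented).
#' Degenerate lotteries with `x_best == x_worst` are allowed.
#'
#' @param x_best Best monetary outcome (monetary units, signed).
#' @param x_worst Worst monetary outcome.
#' @param p_best Probability of the best outcome, in `[0, 1]`.
#' @return An object of class `"lottery"`.
#' @examples
#' l <- lottery(260, 180, p_best = 0.20)
#' expected_value(l)  # 196
#' @export
lottery <- function(x_best, x_worst, p_best) {
  stopifnot(is.numeric(x_best), is.numeric(x_worst), is.numeric(p_best),
            length(x_best) == 1L, length(x_worst) == 1L, length(p_best) == 1L)
  if (!is.finite(p_best) || p_best < 0 || p_best > 1)
    stop("p_best must lie in [0, 1]", call. = FALSE)
  if (x_best < x_worst)
    stop("x_best must be >= x_worst", call. = FALSE)
  if (sign(x_best) * sign(x_worst) < 0)
    stop("mixed-sign lotteries are not supported", call. = FALSE)
  p_worst <- 1 - p_best
  # probabilities come from a decimal grid; complement is exact to 1e-12
  stopifnot(abs(p_best + p_worst - 1) < 1e-12)
  structure(
    list(x_best = as.numeric(x_best), x_worst = as.numeric(x_worst),
         p_best = as.numeric(p_best), p_worst = as.numeric(p_worst)),
    class = "lottery"
  )
}

#' @export
print.lottery <- function(x, ...) {
  cat(sprintf("<lottery> %g with p=%g, %g with p=%g (EV %g, SD %g)\n",
              x$x_best, x$p_best, x$x_worst, x$p_worst,
              expected_value(x), lottery_sd(x)))
  invisible(x)
}

#' Expected value of a lottery
#'
#' @param lottery A [lottery()].
#' @return `p_best * x_best + p_worst * x_worst`.
#' @export
expected_value <- function(lottery) {
  stopifnot(inherits(lottery, "lottery"))
  lottery$p_best * lottery$x_best + lottery$p_worst * lottery$x_worst
}

#' Standard deviation of a lottery's payoff
#'
#' Used to label the "riskier" (higher-spread) option of a pair.
#'
#' @param lottery A [lottery()].
#' @return Standard deviation of the payoff distribution.
#' @export
lottery_sd <- function(lottery) {
  stopifnot(inherits(lottery, "lottery"))
  ev <- expected_value(lottery)
  sqrt(lottery$p_best * (lottery$x_best - ev)^2 +
         lottery$p_worst * (lottery$x_worst - ev)^2)
}

#' Sign-mirror a lottery into the opposite domain
#'
#' Negates both outcomes and relabels best/worst accordingly: the mirrored
#' best outcome is `-x_worst` and carries probability `p_worst`.
#'
#' @param lottery A [lottery()].
#' @return The mirrored [lottery()].
#' @export
mirror_lottery <- function(lottery) {
  stopifnot(inherits(lottery, "lottery"))
  lottery(-lottery$x_worst, -lottery$x_best, p_best = lottery$p_worst)
}

#' Binary lottery-choice question
#'
#' A pair of lotteries sharing their outcome probabilities, as in an MPL row.
#' Exactly one option must have the (weakly) larger outcome spread; for
#' non-degenerate rows the spread ordering is strict.
#'
#' @param option_a,option_b [lottery()] objects with equal `p_best`.
#' @param row_index Row within the MPL (1-based).
#' @param mpl_id Identifier of the parent MPL.
#' @return An object of class `"lottery_pair"`.
#' @export
lottery_pair <- function(option_a, option_b, row_index = 1L, mpl_id = "mpl") {
  stopifnot(inherits(option_a, "lottery"), inherits(option_b, "lottery"))
  if (abs(option_a$p_best - option_b$p_best) > 1e-12)
    stop("options must share outcome probabilities", call. = FALSE)
  structure(
    list(option_a = option_a, option_b = option_b,
         row_index = as.integer(row_index), mpl_id = as.character(mpl_id)),
    class = "lottery_pair"
  )
}

spread <- function(l) abs(l$x_best - l$x_worst)

#' @export
print.lottery_pair <- function(x, ...) {
  cat(sprintf("<lottery_pair> %s row %d, p_best=%g\n  A: %g/%g  B: %g/%g\n",
              x$mpl_id, x$row_index, x$option_a$p_best,
              x$option_a$x_best, x$option_a$x_worst,
              x$option_b$x_best, x$option_b$x_worst))
  invisible(x)
}
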