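# Straight-line reference implementations used as independent oracles.
# These deliberately re-derive every formula step by step and share no code
# with the package internals.

oracle_crra <- function(x, r) if (x >= 0) x^r else -((-x)^r)

oracle_weight <- function(p, g, family) {
  if (family == "linear") return(p)
  if (p == 0) return(0)
  if (p == 1) return(1)
  if (family == "kahneman_tversky") {
    p^g / (p^g + (1 - p)^g)^(1 / g)
  } else {
    exp(-(-log(p))^g)
  }
}

oracle_rdu <- function(x_best, x_worst, p_best, r, g, family) {
  w <- oracle_weight(p_best, g, family)
  w * oracle_crra(x_best, r) + (1 - w) * oracle_crra(x_worst, r)
}

oracle_choice_prob <- function(xa_best, xa_worst, xb_best, xb_worst, p_best,
                               r, g, tau, family, domain) {
  eua <- oracle_rdu(xa_best, xa_worst, p_best, r, g, family)
  eub <- oracle_rdu(xb_best, xb_worst, p_best, r, g, family)
  s <- if (domain == "gain") 1 else -1
  1 / (1 + exp(-(s * tau * (1 / r) * log(abs(eua) / abs(eub)))))
}

# random valid (pair, params) instance on the gain or loss scale
random_instance <- function(domain = "gain") {
  xs <- sort(stats::runif(4, 10, 500))
  # safe option inside the risky option's range; same-probability rows
  inst <- list(xa_best = xs[3], xa_worst = xs[2],
               xb_best = xs[4], xb_worst = xs[1],
               p_best = sample(mpl_probability_grid()[2:15], 1),
               r = stats::runif(1, 0.3, 2.5),
               g = stats::runif(1, 0.5, 4),
               tau = stats::runif(1, 0.5, 15))
  if (domain == "loss") {
    mir <- inst
    mir$xa_best <- -inst$xa_worst; mir$xa_worst <- -inst$xa_best
    mir$xb_best <- -inst$xb_worst; mir$xb_worst <- -inst$xb_best
    mir$p_best <- 1 - inst$p_best
    inst <- mir
  }
  inst
}

make_pair <- function(inst) {
  lottery_pair(lottery(inst$xa_best, inst$xa_worst, inst$p_best),
               lottery(inst$xb_best, inst$xb_worst, inst$p_best))
}
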