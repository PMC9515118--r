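test_that("CRRA utility follows the two-branch power form", {
  expect_equal(crra_utility(180, 1), 180)
  expect_equal(crra_utility(-100, 0.5), -10)
  expect_equal(crra_utility(260, 0.5), sqrt(260))   # ~16.1245
  expect_equal(crra_utility(0, 0.7), 0)
  expect_error(crra_utility(10, 0), "positive")
  expect_error(crra_utility(10, -1), "positive")
})

test_that("probability weighting reduces to identity at parameter 1", {
  p <- mpl_probability_grid()
  for (fam in weighting_families())
    expect_equal(prob_weight(p, 1, fam), p, tolerance = 1e-12)
})

test_that("weighting families match direct formula evaluation", {
  # Kahneman-Tversky at (0.5, 2.5): p^g / (p^g + (1-p)^g)^(1/g)
  expect_equal(prob_weight(0.5, 2.5, "kahneman_tversky"),
               0.5^2.5 / (0.5^2.5 + 0.5^2.5)^(1 / 2.5), tolerance = 1e-12)
  expect_equal(prob_weight(0.5, 2.5, "kahneman_tversky"), 0.268,
               tolerance = 1e-3)
  # Prelec fixed point at 1/e for any curvature
  for (a in c(0.4, 1, 2.7))
    expect_equal(prob_weight(exp(-1), a, "prelec1"), exp(-1),
                 tolerance = 1e-12)
  # exact endpoints
  for (fam in weighting_families()) {
    expect_identical(prob_weight(0, 2.5, fam), 0)
    expect_identical(prob_weight(1, 2.5, fam), 1)
  }
  expect_error(prob_weight(1.01, 2, "prelec1"), "\\[0, 1\\]")
  expect_error(prob_weight(0.5, 0, "prelec1"), "positive")
})

test_that("weighting is monotone on [0,1] for curvature >= 1", {
  p <- seq(0, 1, by = 0.01)
  for (fam in c("kahneman_tversky", "prelec1"))
    for (g in c(1, 1.5, 2.5, 4))
      expect_true(all(diff(prob_weight(p, g, fam)) > -1e-12))
})

test_that("rank-dependent value composes weighting and utility", {
  row6 <- example_mpl()[[6]]   # p = 0.20, EV(A) = 196
  expect_equal(rdu_value(row6$option_a, preference_params(1, 1), "linear"), 196)
  # degenerate certainty
  l1 <- lottery(260, 180, 1)
  expect_equal(rdu_value(l1, preference_params(0.5, 2.5), "kahneman_tversky"),
               sqrt(260))
  # composition oracle at r = 0.5, gamma = 2.5, p = 0.5
  w <- oracle_weight(0.5, 2.5, "kahneman_tversky")
  expect_equal(rdu_value(lottery(260, 180, 0.5), preference_params(0.5, 2.5),
                         "kahneman_tversky"),
               w * sqrt(260) + (1 - w) * sqrt(180), tolerance = 1e-12)
  expect_equal(w * sqrt(260) + (1 - w) * sqrt(180), 14.142, tolerance = 1e-3)
})

test_that("choice rule gives indifference, determinism and the row-9 value", {
  same <- lottery_pair(lottery(100, 50, 0.4), lottery(100, 50, 0.4))
  pp <- preference_params(0.8, 2, 3)
  expect_equal(choice_prob(same, pp, "kahneman_tversky", "gain"), 0.5)
  row9 <- example_mpl()[[9]]   # EVs 220 vs 200
  expect_gt(choice_prob(row9, preference_params(1, 1, 1e6), "linear", "gain"),
            1 - 1e-9)
  expect_equal(choice_prob(row9, preference_params(1, 1, 6.68), "linear", "gain"),
               1 / (1 + exp(-6.68 * log(220 / 200))), tolerance = 1e-12)
  expect_equal(choice_prob(row9, preference_params(1, 1, 6.68), "linear", "gain"),
               0.654, tolerance = 1e-3)
})

test_that("choice probabilities match a brute-force oracle to 1e-12", {
  set.seed(100)
  for (i in 1:100) {
    domain <- if (i %% 2) "gain" else "loss"
    fam <- sample(weighting_families(), 1)
    inst <- random_instance(domain)
    got <- choice_prob(make_pair(inst),
                       preference_params(inst$r, inst$g, inst$tau),
                       fam, domain)
    want <- oracle_choice_prob(inst$xa_best, inst$xa_worst, inst$xb_best,
                               inst$xb_worst, inst$p_best, inst$r, inst$g,
                               inst$tau, fam, domain)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("choice probabilities are complementary under option swap", {
  set.seed(101)
  for (i in 1:100) {
    domain <- if (i %% 2) "gain" else "loss"
    inst <- random_instance(domain)
    pp <- preference_params(inst$r, inst$g, inst$tau)
    pr <- make_pair(inst)
    swapped <- lottery_pair(pr$option_b, pr$option_a)
    p1 <- choice_prob(pr, pp, "prelec1", domain)
    p2 <- choice_prob(swapped, pp, "prelec1", domain)
    expect_equal(p1 + p2, 1, tolerance = 1e-12)
  }
})

test_that("linear weighting with r = 1 recovers expected value", {
  set.seed(102)
  for (i in 1:20) {
    inst <- random_instance("gain")
    pp <- preference_params(1, 1, 2)
    expect_equal(rdu_value(make_pair(inst)$option_a, pp, "linear"),
                 expected_value(make_pair(inst)$option_a), tolerance = 1e-10)
  }
})

test_that("in the deterministic limit the higher-RDU option is preferred in both domains", {
  set.seed(103)
  for (i in 1:25) {
    inst_g <- random_instance("gain")
    pp <- preference_params(inst_g$r, inst_g$g, 1e8)
    pr_g <- make_pair(inst_g)
    pg <- choice_prob(pr_g, pp, "kahneman_tversky", "gain")
    better_a <- rdu_value(pr_g$option_a, pp, "kahneman_tversky") >
      rdu_value(pr_g$option_b, pp, "kahneman_tversky")
    expect_equal(pg > 0.5, better_a)
    inst_l <- random_instance("loss")
    pr_l <- make_pair(inst_l)
    pl <- choice_prob(pr_l, pp, "kahneman_tversky", "loss")
    better_a_l <- rdu_value(pr_l$option_a, pp, "kahneman_tversky") >
      rdu_value(pr_l$option_b, pp, "kahneman_tversky")
    expect_equal(pl > 0.5, better_a_l)
  }
})

test_that("simulated choices are reproducible and calibrated", {
  row9 <- example_mpl()[[9]]
  pp <- preference_params(1, 1, 6.68)
  set.seed(5); a <- replicate(20, simulate_choice(row9, pp, "linear", "gain"))
  set.seed(5); b <- replicate(20, simulate_choice(row9, pp, "linear", "gain"))
  expect_identical(a, b)
  # deterministic limit
  det <- preference_params(1, 1, 1e9)
  expect_true(all(replicate(10, simulate_choice(row9, det, "linear", "gain")) == "A"))
  # empirical rate within 3 binomial SDs
  p_true <- choice_prob(row9, pp, "linear", "gain")
  set.seed(6)
  n <- 2e4
  rate <- mean(replicate(n, simulate_choice(row9, pp, "linear", "gain")) == "A")
  expect_lt(abs(rate - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})
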