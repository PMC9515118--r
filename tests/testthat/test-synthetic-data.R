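test_that("population draws shrink to the group means as SD vanishes", {
  h <- group_hyper(sigma = 1e-9)
  sp <- draw_subject_params(h, 5, seed = 1)
  expect_equal(sp$r0, rep(1.03, 5), tolerance = 1e-6)
  expect_equal(sp$gamma0, rep(2.5, 5), tolerance = 1e-6)
  expect_equal(sp$tau0, rep(6.68, 5), tolerance = 1e-6)
  expect_equal(sp$dgamma_left, rep(0.61, 5), tolerance = 1e-6)
})

test_that("population draws are deterministic by seed and respect bounds", {
  h <- group_hyper(sigma = 0.5)
  expect_identical(draw_subject_params(h, 20, seed = 8),
                   draw_subject_params(h, 20, seed = 8))
  sp <- draw_subject_params(h, 200, seed = 9)
  expect_true(all(sp$r0 > 0 & sp$r0 < 5))
  expect_true(all(sp$gamma0 > 0 & sp$gamma0 < 6))
  expect_true(all(sp$tau0 > 0))
  expect_true(all(abs(sp$dr_right) < 2))
  expect_true(all(abs(sp$dgamma_left) < 1.5))
  expect_true(all(abs(sp$dtau_left) < 5))
})

test_that("sample means match the generating means (Monte Carlo)", {
  # on the unconstrained scale the subject draws are exactly normal around
  # the unconstrained group mean
  h <- group_hyper(sigma = 0.25)
  sp <- draw_subject_params(h, 1e4, seed = 10)
  z <- unconstrain(sp$r0, 0, 5)
  expect_lt(abs(mean(z) - unconstrain(1.03, 0, 5)), 3 * 0.25 / sqrt(1e4))
  # at small SD the transform is locally linear, so the constrained mean
  # tracks the constrained group mean too
  h2 <- group_hyper(sigma = 0.02)
  sp2 <- draw_subject_params(h2, 1e4, seed = 11)
  sd_r0 <- sd(sp2$r0)
  expect_lt(abs(mean(sp2$r0) - 1.03), 3 * sd_r0 / sqrt(1e4) + 1e-3)
})

test_that("condition composition follows the shift equations", {
  subj <- list(r0 = 1.0, gamma0 = 2.5, tau0 = 6.7,
               dr_right = 0.236, dr_left = -0.1,
               dgamma_right = 0.2, dgamma_left = 0.61,
               dtau_right = 0.5, dtau_left = -1)
  sham <- condition_params(subj, "sham")
  expect_equal(unclass(sham)[c("r", "gamma", "tau")],
               list(r = 1.0, gamma = 2.5, tau = 6.7))
  right <- condition_params(subj, "right")
  expect_equal(right$r, 1.236)
  expect_equal(right$gamma, 2.7)
  expect_equal(right$tau, 7.2)
  left <- condition_params(subj, "left")
  expect_equal(left$gamma, 2.5 + 0.61)
  # zero deltas leave all conditions identical
  subj0 <- within(as.list(subj), {
    dr_right <- dr_left <- dgamma_right <- dgamma_left <- 0
    dtau_right <- dtau_left <- 0
  })
  expect_equal(condition_params(subj0, "right"), condition_params(subj0, "sham"))
  # truncation at the positive floor
  subj_neg <- within(as.list(subj), dtau_left <- -7)
  expect_equal(condition_params(subj_neg, "left")$tau, 1e-6)
  expect_error(condition_params(subj_neg, "left", floor = NULL),
               "non-positive")
})

test_that("a simulated experiment has the full crossed structure", {
  h <- group_hyper(sigma = 0.25)
  d <- simulate_dataset(h, 4, seed = 21)
  expect_equal(nrow(d), 4 * 3 * 96)
  expect_equal(as.vector(table(d$domain)), c(576, 576))
  # one session per condition per subject
  tab <- table(d$subject, d$condition)
  expect_true(all(tab == 96))
  # counterbalancing rotates condition order across subjects
  ord <- unique(d[d$subject %in% 1:2, c("subject", "session", "condition")])
  expect_false(identical(ord$condition[ord$subject == 1],
                         ord$condition[ord$subject == 2]))
  expect_identical(simulate_dataset(h, 2, seed = 5),
                   simulate_dataset(h, 2, seed = 5))
})

test_that("deterministic-limit choices depend only on the lottery content", {
  h <- group_hyper(mu_tau0 = 5000, mu_dgamma_left = 1e-9, sigma = 1e-9)
  # rows near indifference stay coin flips even at huge tau; exclude them
  pp <- preference_params(1.03, 2.5, 5000)
  pick_risky <- function(d) {
    key <- with(d, order(subject, condition, domain, mpl_id, row_index))
    d <- d[key, ]
    pa <- rdurisk:::choice_prob_rows(d, pp, "kahneman_tversky")
    sd_of <- function(b, w, p) abs(b - w) * sqrt(p * (1 - p))
    risky_a <- with(d, sd_of(xA_best, xA_worst, p_best) >=
                      sd_of(xB_best, xB_worst, p_best))
    keep <- abs(pa - 0.5) > 0.1 & d$p_best > 0 & d$p_best < 1
    ifelse(d$choice == "A", risky_a, !risky_a)[keep]
  }
  d1 <- simulate_dataset(h, 2, seed = 31)
  d2 <- simulate_dataset(h, 2, seed = 32)
  expect_identical(pick_risky(d1), pick_risky(d2))
})

test_that("a positive left-TMS weighting shift strengthens the S-shape", {
  # larger curvature overweights large probabilities: at p_best >= 0.9 the
  # wide-spread option becomes more attractive under left stimulation
  h <- group_hyper(mu_gamma0 = 1.8, mu_dgamma_left = 0.9, mu_tau0 = 8,
                   sigma = 0.05)
  d <- simulate_dataset(h, 30, seed = 33)
  d <- d[d$domain == "gain" & d$p_best >= 0.9 & d$p_best < 1, ]
  sd_of <- function(b, w, p) abs(b - w) * sqrt(p * (1 - p))
  risky_a <- with(d, sd_of(xA_best, xA_worst, p_best) >
                    sd_of(xB_best, xB_worst, p_best))
  risky_chosen <- ifelse(d$choice == "A", risky_a, !risky_a)
  rate <- tapply(risky_chosen, d$condition, mean)
  expect_gt(rate[["left"]], rate[["sham"]])
})
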