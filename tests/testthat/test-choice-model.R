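test_that("gain and loss utilities match direct power-function evaluation", {
  # linear cases
  expect_equal(utility_gain(10, rho = 1, prob = 0.5), 5)
  expect_equal(utility_loss(-10, rho = 1, lam = 2, prob = 0.5), -10)
  # zero amounts
  expect_equal(utility_gain(0, rho = 0.92, prob = 0.5), 0)
  expect_equal(utility_loss(0, rho = 0.92, lam = 2.22, prob = 0.5), 0)
  # curved cases against an independent evaluation
  expect_equal(utility_gain(10, 0.92, 0.5), 0.5 * exp(0.92 * log(10)),
               tolerance = 1e-12)
  expect_equal(utility_gain(10, 0.92, 0.5), 4.158819, tolerance = 1e-6)
  expect_equal(utility_loss(-6, 0.92, 2.22, 0.5), -5.770615,
               tolerance = 1e-6)
  # lambda = 1 mirror symmetry
  expect_equal(utility_loss(-10, 1, 1, 0.5), -utility_gain(10, 1, 0.5))
  # domain errors
  expect_error(utility_gain(-1, 0.92), "must be >= 0")
  expect_error(utility_loss(1, 0.92, 2), "must be <= 0")
})

test_that("option utilities and choice probabilities follow the softmax model", {
  gl <- data.frame(family = "gain_loss", gamble_gain = 10, gamble_loss = -10,
                   guaranteed = 0, outcome_prob = 0.5)
  u <- option_utilities(gl, value_params(1, 1, 1))
  expect_equal(u$u_gamble, 0)
  expect_equal(u$u_guaranteed, 0)

  go <- data.frame(family = "gain_only", gamble_gain = 10, gamble_loss = 0,
                   guaranteed = 5, outcome_prob = 0.5)
  u2 <- option_utilities(go, value_params(1, 1, 1))
  expect_equal(u2$u_gamble, 5)
  expect_equal(u2$u_guaranteed, 5)

  mix <- data.frame(family = "gain_loss", gamble_gain = 10, gamble_loss = -6,
                    guaranteed = 0, outcome_prob = 0.5)
  u3 <- option_utilities(mix, value_params(0.92, 2.22, 1))
  expect_equal(u3$u_gamble - u3$u_guaranteed, -1.611797, tolerance = 1e-6)
  expect_equal(p_gamble(mix, value_params(0.92, 2.22, 1)), 0.1663393,
               tolerance = 1e-6)
  # equal utilities or zero consistency give a coin flip
  expect_equal(p_gamble(gl, value_params(1, 1, 7)), 0.5)
  expect_equal(p_gamble(mix, value_params(0.92, 2.22, 0)), 0.5)
  # numerically stable deep in saturation
  expect_equal(p_gamble(mix, value_params(0.92, 2.22, 500)), 0)
  expect_true(is.finite(log_likelihood(cbind(mix, chose_gamble = 1),
                                       value_params(0.92, 2.22, 500))))
})

test_that("p_gamble is monotone in gain, loss magnitude and loss aversion", {
  base <- data.frame(family = "gain_loss", gamble_gain = 6, gamble_loss = -4,
                     guaranteed = 0, outcome_prob = 0.5)
  gains <- seq(2, 12, by = 0.5)
  pg <- vapply(gains, function(g) {
    d <- base; d$gamble_gain <- g
    p_gamble(d, value_params(0.92, 2.22, 5))
  }, numeric(1))
  expect_true(all(diff(pg) > 0))
  lams <- seq(0.5, 4, by = 0.25)
  pl <- vapply(lams, function(l)
    p_gamble(base, value_params(0.92, l, 5)), numeric(1))
  expect_true(all(diff(pl) < 0))
  losses <- seq(-1, -8, by = -0.5)
  pz <- vapply(losses, function(x) {
    d <- base; d$gamble_loss <- x
    p_gamble(d, value_params(0.92, 2.22, 5))
  }, numeric(1))
  expect_true(all(diff(pz) < 0))
})

test_that("session parameter construction is exponential and always positive", {
  eff <- list(theta_base = log(c(0.92, 2.22, 25.9)),
              delta_stress = c(0.1, -0.2, 0.3),
              delta_day = c(0, log(2.57 / 2.22), log(34.3 / 25.9)))
  ctx0 <- list(stress_indicator = 0, day_indicator = 0, delta_cortisol = 0)
  p0 <- session_params(eff, ctx0, "condition")
  expect_equal(c(p0$rho, p0$lam, p0$mu), c(0.92, 2.22, 25.9),
               tolerance = 1e-12)
  # day-2 loss aversion hits the intended endpoint exactly
  ctx1 <- list(stress_indicator = 0, day_indicator = 1, delta_cortisol = 0)
  expect_equal(session_params(eff, ctx1, "condition")$lam, 2.57,
               tolerance = 1e-12)
  # covariate variant with zero cortisol equals the zero-stress condition
  p_cov <- session_params(eff, ctx0, "covariate")
  expect_equal(unclass(p_cov), unclass(p0))
  # positivity for arbitrary finite inputs
  with_seed(99, for (i in 1:200) {
    e <- list(theta_base = rnorm(3, 0, 3), delta_stress = rnorm(3, 0, 3),
              delta_day = rnorm(3, 0, 3))
    cx <- list(stress_indicator = sample(0:1, 1),
               day_indicator = sample(0:1, 1),
               delta_cortisol = rnorm(1))
    p <- session_params(e, cx, sample(c("condition", "covariate"), 1))
    expect_true(p$rho > 0 && p$lam > 0 && p$mu > 0)
  })
})

test_that("log-likelihood equals the brute-force oracle", {
  expect_equal(log_likelihood(cbind(data.frame(family = "gain_loss",
                                               gamble_gain = 10,
                                               gamble_loss = -6,
                                               guaranteed = 0,
                                               outcome_prob = 0.5),
                                    chose_gamble = 1),
                              value_params(0.92, 2.22, 1)),
               -1.793725, tolerance = 1e-6)
  # coin-flip likelihood
  ch <- random_choices(40, seed = 8)
  expect_equal(log_likelihood(ch, value_params(1, 1, 0)), 40 * log(0.5))
  # random 20-trial instances vs the independent implementation
  for (s in 1:10) {
    ch <- random_choices(20, seed = 1000 + s)
    pars <- with_seed(2000 + s,
                      c(exp(rnorm(1, 0, 0.3)), exp(rnorm(1, 0.6, 0.4)),
                        exp(rnorm(1, 1.5, 1))))
    expect_equal(log_likelihood(ch, value_params(pars[1], pars[2], pars[3])),
                 oracle_loglik(ch, pars[1], pars[2], pars[3]),
                 tolerance = 1e-10)
  }
  # expected-value reduction at lambda = rho = 1
  tr <- generate_trial_set(seed = 12)
  u <- option_utilities(tr, value_params(1, 1, 1))
  ev <- 0.5 * (tr$gamble_gain + tr$gamble_loss)
  expect_equal(u$u_gamble, ev, tolerance = 1e-12)
})

test_that("simulated choices are reproducible and match model frequencies", {
  tr <- generate_trial_set(seed = 21)
  ch1 <- simulate_choices(tr, paper_baseline(), seed = 5)
  expect_identical(ch1, simulate_choices(tr, paper_baseline(), seed = 5))
  # realized outcomes always come from the chosen option
  gam <- ch1$chose_gamble == 1
  expect_true(all(ch1$realized_outcome[!gam] == ch1$guaranteed[!gam]))
  expect_true(all(ch1$realized_outcome[gam] == ch1$gamble_gain[gam] |
                    ch1$realized_outcome[gam] == ch1$gamble_loss[gam]))
  # mu = 0 agent gambles at chance
  big <- do.call(rbind, replicate(67, tr, simplify = FALSE))
  ch0 <- simulate_choices(big, value_params(1, 1, 0), seed = 6)
  expect_lt(abs(mean(ch0$chose_gamble) - 0.5), 0.015)
  # saturation: strongly favorable gambles are all taken at high mu
  fav <- data.frame(family = "gain_loss",
                    gamble_gain = rep(12, 200), gamble_loss = -1,
                    guaranteed = 0, outcome_prob = 0.5)
  chs <- simulate_choices(fav, value_params(1, 1, 100), seed = 7)
  expect_equal(mean(chs$chose_gamble), 1)
  # mean empirical gamble rate tracks the analytic mean probability
  p_bar <- mean(p_gamble(tr, paper_baseline()))
  rates <- vapply(1:50, function(s)
    mean(simulate_choices(tr, paper_baseline(), seed = s)$chose_gamble),
    numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - p_bar), 3 * se + 1e-8)
})
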