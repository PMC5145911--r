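test_that("Rhat is near 1 for iid chains and large for separated chains", {
  m <- with_seed(1, matrix(rnorm(4000), ncol = 4))
  expect_lt(abs(rhat(m, "rank") - 1), 0.01)
  expect_lt(abs(rhat(m, "classic") - 1), 0.01)
  # two chains with means 10 SDs apart
  m2 <- with_seed(2, cbind(rnorm(500), rnorm(500, 10)))
  # rank normalization bounds the statistic; classic grows without limit
  expect_gt(rhat(m2, "rank"), 1.5)
  expect_gt(rhat(m2, "classic"), 5)
  # classic variant matches the textbook formula computed independently
  for (s in 1:5) {
    m3 <- with_seed(100 + s, matrix(rnorm(240 * 3, sd = runif(1, 0.5, 2)),
                                    ncol = 3))
    expect_equal(rhat(m3, "classic"), oracle_split_rhat(m3),
                 tolerance = 1e-12)
  }
  # within-chain drift is caught by splitting
  drift <- matrix(rep(seq(0, 5, length.out = 400), 3), ncol = 3)
  drift <- drift + with_seed(3, matrix(rnorm(1200, sd = 0.1), ncol = 3))
  expect_gt(rhat(drift, "classic"), 1.5)
  # degenerate chains are flagged, not crashed
  expect_true(is.na(rhat(matrix(1, 100, 4), "classic")))
})

test_that("credible intervals are central and match a quantile oracle", {
  x <- as.numeric(1:100)
  ci <- credible_interval(x, 0.95)
  # independent type-7 interpolation oracle
  q7 <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p
    v[floor(h) + 1] + (h - floor(h)) * (v[min(floor(h) + 2, length(v))] -
                                          v[floor(h) + 1])
  }
  expect_equal(ci, c(q7(x, 0.025), q7(x, 0.975)), tolerance = 1e-12)
  expect_equal(credible_interval(rep(3.3, 10)), c(3.3, 3.3))
  z <- with_seed(5, rnorm(100000))
  expect_equal(credible_interval(z, 0.95), c(-1.96, 1.96), tolerance = 0.03)
  expect_true(diff(credible_interval(z, 0.5)) <
                diff(credible_interval(z, 0.95)))
})

test_that("max level excluding zero matches the empirical-CDF formula", {
  # constructed vector with exactly 12% of mass below zero
  v <- c(seq(-1, -0.01, length.out = 12), seq(0.01, 1, length.out = 88))
  expect_equal(as.numeric(max_level_excluding_zero(v)), 0.76)
  # brute-force level scan: largest level whose central interval excludes 0
  scan_oracle <- function(x) {
    levels <- seq(0.001, 0.999, by = 0.001)
    ok <- vapply(levels, function(l) {
      ci <- quantile(x, c((1 - l) / 2, 1 - (1 - l) / 2))
      ci[1] > 0 || ci[2] < 0
    }, logical(1))
    if (!any(ok)) 0 else max(levels[ok])
  }
  for (s in 1:6) {
    x <- with_seed(300 + s, rnorm(400, mean = runif(1, -0.5, 0.5)))
    expect_lt(abs(as.numeric(max_level_excluding_zero(x)) - scan_oracle(x)),
              2 / length(x) + 0.002)
  }
  # all-positive samples cap at the resolution limit
  r <- max_level_excluding_zero(1:50)
  expect_equal(as.numeric(r), 49 / 50)
  expect_equal(attr(r, "resolution"), 1 / 50)
  # symmetric samples around zero give level ~ 0
  sym <- c(-(1:50), 1:50)
  expect_equal(as.numeric(max_level_excluding_zero(sym)), 0)
})

test_that("the sampler's likelihood equals the reference log-likelihood", {
  st <- tiny_study(n = 4L, seed = 51)
  prep <- stressrisk:::.prep_fit_data(st, "condition")
  with_seed(61, for (rep in 1:5) {
    rho <- exp(rnorm(prep$J, 0, 0.2))
    lam <- exp(rnorm(prep$J, 0.7, 0.2))
    mu <- exp(rnorm(prep$J, 2, 0.5))
    cpp <- stressrisk:::.cpp_total_loglik(prep$gain, prep$lossmag, prep$guar,
                                          prep$y, prep$sess_start,
                                          rho, lam, mu, log(1e-12))
    ref <- 0
    ch <- st$choices[order(match(st$choices$subject_id,
                                 prep$subject_ids), st$choices$day), ]
    key <- paste(ch$subject_id, ch$day)
    for (j in seq_len(prep$J)) {
      d <- ch[key == unique(key)[j], ]
      ref <- ref + log_likelihood(d, value_params(rho[j], lam[j], mu[j]))
    }
    expect_equal(cpp, ref, tolerance = 1e-8)
  })
})

test_that("fit output dimensions follow the MCMC configuration", {
  expect_equal(mcmc_config()$chains * mcmc_config()$draws, 12000L)
  st <- tiny_study(n = 4L, seed = 52)
  mc <- mcmc_config(2, 40, 30)
  fit <- fit_hierarchical(st, "condition", mc, seed = 9)
  expect_equal(dim(fit$draws), c(30L, 2L, 18L + 9L * 4L))
  expect_equal(fit$meta$kept_total, 60L)
  expect_true(all(c("thetaM[rho]", "thetaV[mu]", "dSM[lam]", "dDV[rho]",
                    "z0[s001,rho]", "zD[s004,mu]") %in%
                    dimnames(fit$draws)[[3]]))
  # reproducible under the same seed
  fit2 <- fit_hierarchical(st, "condition", mc, seed = 9)
  expect_identical(fit$draws, fit2$draws)
  fit3 <- fit_hierarchical(st, "condition", mc, seed = 10)
  expect_false(identical(fit$draws, fit3$draws))
})

test_that("covariate fits require and use per-session cortisol", {
  st <- tiny_study(n = 4L, seed = 53)
  mc <- mcmc_config(2, 40, 30)
  fit <- fit_hierarchical(st, "covariate", mc, seed = 9)
  expect_true("dCM[lam]" %in% dimnames(fit$draws)[[3]])
  expect_equal(fit$meta$variant, "covariate")
  broken <- st
  broken$sessions$delta_cortisol[1] <- NA
  expect_error(fit_hierarchical(broken, "covariate", mc, seed = 9),
               "delta_cortisol")
  # reconstruction contexts respect the variant
  expect_error(reconstruct_params(fit, "stress"), "condition variant")
  b <- reconstruct_params(fit, "baseline")
  z <- reconstruct_params(fit, list(cortisol_at = 0))
  expect_equal(unclass(b), unclass(z))
})

test_that("parameter reconstruction applies posterior-mean effects", {
  st <- tiny_study(n = 4L, seed = 54)
  fit <- fit_hierarchical(st, "condition", mcmc_config(2, 40, 30), seed = 3)
  gm <- vapply(c("thetaM[lam]", "dDM[lam]"), function(p)
    mean(param_draws(fit, p)), numeric(1))
  expect_equal(reconstruct_params(fit, "day2")$lam,
               unname(exp(gm[1] + gm[2])), tolerance = 1e-12)
  expect_equal(reconstruct_params(fit, "baseline")$lam, unname(exp(gm[1])),
               tolerance = 1e-12)
  rep <- fit_report(fit)
  expect_true(all(c("baseline", "day2", "stress") %in%
                    names(rep$recovered)))
  expect_true(all(rep$effect_CIs$day[, "low"] <= rep$effect_CIs$day[, "high"]))
})

test_that("gender-subset fits enter only the filtered subjects", {
  hy <- group_hyper(theta_V = c(0.05, 0.05, 0.05),
                    deltaS_V = c(0.02, 0.02, 0.02),
                    deltaD_V = c(0.02, 0.02, 0.02))
  st <- simulate_study(study_config(n_subjects = 120L, hyper = hy),
                       seed = 88)
  expect_equal(sum(st$subjects$gender == "male"), 56L)
  fit <- subset_fit(st, gender = "male", variant = "condition",
                    mcmc = mcmc_config(1, 10, 10), seed = 4)
  expect_equal(fit$meta$n_subjects, 56L)
  expect_error(subset_fit(tiny_study(4L, seed = 90), gender = "other",
                          mcmc = mcmc_config(1, 10, 10), seed = 1),
               "leaves < 2")
})
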