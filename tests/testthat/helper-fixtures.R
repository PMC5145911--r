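# shared fixtures and independent oracles, built in code at test time

paper_baseline <- function() value_params(0.92, 2.22, 25.9)

# a small cohort for fit-shaped tests (kept tiny so fits stay fast)
tiny_study <- function(n = 8L, seed = 404, day_effects = FALSE) {
  hy <- group_hyper(theta_M = log(c(0.92, 2.22, 25.9)),
                    theta_V = c(0.05, 0.05, 0.05),
                    deltaS_V = c(0.02, 0.02, 0.02),
                    deltaD_M = if (day_effects) c(0, 0.15, 0.28) else
                      c(0, 0, 0),
                    deltaD_V = c(0.02, 0.02, 0.02))
  st <- withCallingHandlers(
    simulate_study(study_config(n_subjects = n, hyper = hy), seed = seed),
    warning = function(w) {
      if (grepl("most even split", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  st
}

tiny_mcmc <- function(chains = 2L, warmup = 150L, draws = 150L)
  mcmc_config(chains, warmup, draws)

# independent brute-force choice log-likelihood: plain R loop, explicit
# powers and logistic, no shared code with the package internals
oracle_loglik <- function(choices, rho, lam, mu) {
  total <- 0
  for (r in seq_len(nrow(choices))) {
    g <- choices$gamble_gain[r]
    l <- choices$gamble_loss[r]
    s <- choices$guaranteed[r]
    ug <- 0.5 * g^rho + 0.5 * (-lam) * (-l)^rho
    us <- if (s >= 0) s^rho else -lam * (-s)^rho
    d <- mu * (ug - us)
    # stable log-probabilities via base R's logistic CDF
    lp <- if (choices$chose_gamble[r] == 1) plogis(d, log.p = TRUE) else
      plogis(-d, log.p = TRUE)
    total <- total + max(lp, log(1e-12))
  }
  total
}

# random valid choice table for property tests
random_choices <- function(n, seed) {
  with_seed(seed, {
    fam <- sample(c("gain_loss", "gain_only"), n, replace = TRUE)
    gain <- round(runif(n, 2, 12), 2)
    loss <- ifelse(fam == "gain_loss", -round(runif(n, 1, 6), 2), 0)
    guar <- ifelse(fam == "gain_loss", 0, round(gain * runif(n, .3, .7), 2))
    data.frame(family = fam, gamble_gain = gain, gamble_loss = loss,
               guaranteed = guar, outcome_prob = 0.5,
               chose_gamble = sample(0:1, n, replace = TRUE))
  })
}

# classic split-chain potential-scale-reduction, textbook formula written
# out independently of the package implementation
oracle_split_rhat <- function(mat) {
  n2 <- floor(nrow(mat) / 2)
  sub <- cbind(mat[1:n2, , drop = FALSE],
               mat[(nrow(mat) - n2 + 1):nrow(mat), , drop = FALSE])
  m <- ncol(sub)
  chain_means <- colMeans(sub)
  W <- sum(apply(sub, 2, function(x) sum((x - mean(x))^2) / (n2 - 1))) / m
  B <- n2 / (m - 1) * sum((chain_means - mean(chain_means))^2)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}
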