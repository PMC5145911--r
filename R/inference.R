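#' MCMC configuration
#'
#' The study-scale default keeps 3000 draws per chain after 3000 warmup
#' iterations on each of 4 chains (12,000 kept draws per parameter). A
#' reduced desk-scale configuration (4 x 500 warmup x 500 kept) is provided
#' for parameter-recovery checks and interactive work.
#'
#' @param chains number of chains.
#' @param warmup warmup (adaptation) iterations per chain, discarded.
#' @param draws kept iterations per chain.
#' @param thin thinning interval.
#' @return list of class `sr_mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, warmup = 3000L, draws = 3000L,
                        thin = 1L) {
  stopifnot(chains >= 1, warmup >= 0, draws >= 1, thin >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), thin = as.integer(thin)),
            class = "sr_mcmc_config")
}

#' @rdname mcmc_config
#' @export
mcmc_config_desk <- function() mcmc_config(4L, 500L, 500L)

#' Prior configuration for the hierarchical model
#'
#' Weakly informative defaults on the log scale: population means
#' Normal(0, 5), effect means Normal(0, 2), population SDs half-Normal(0, 2).
#'
#' @param mean_sd prior SD of the baseline population means.
#' @param effect_sd prior SD of the stress/day/covariate effect means.
#' @param sd_scale half-normal scale of all population SDs.
#' @return list of class `sr_prior`.
#' @export
prior_config <- function(mean_sd = 5, effect_sd = 2, sd_scale = 2) {
  structure(list(mean_sd = mean_sd, effect_sd = effect_sd,
                 sd_scale = sd_scale), class = "sr_prior")
}

## internal: flatten a study into the per-trial / per-session arrays the
## compiled sampler consumes. Sessions are (subject, day) blocks in subject
## order; indices are 0-based for C++.
.prep_fit_data <- function(study, variant = c("condition", "covariate")) {
  variant <- match.arg(variant)
  ch <- study$choices
  need <- c("subject_id", "day", "condition", "gamble_gain", "gamble_loss",
            "guaranteed", "chose_gamble")
  miss <- setdiff(need, names(ch))
  if (length(miss))
    stop("choice data lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(is.na(ch$chose_gamble))) {
    n_drop <- sum(is.na(ch$chose_gamble))
    message("dropping ", n_drop, " trial(s) with missing choice")
    ch <- ch[!is.na(ch$chose_gamble), ]
  }
  subject_ids <- unique(ch$subject_id)
  ch <- ch[order(match(ch$subject_id, subject_ids), ch$day), ]
  skey <- paste(ch$subject_id, ch$day)
  sess <- unique(skey)
  sess_start <- c(0L, cumsum(as.integer(table(factor(skey, levels = sess)))))
  first <- match(sess, skey)
  ssub <- match(ch$subject_id[first], subject_ids) - 1L
  sday <- as.numeric(ch$day[first])
  smod <- if (variant == "condition") {
    as.numeric(ch$condition[first])
  } else {
    sc <- study$sessions
    if (is.null(sc) || is.null(sc$delta_cortisol))
      stop("covariate variant requires per-session `delta_cortisol` ",
           "(see prepare_cortisol())", call. = FALSE)
    idx <- match(paste(ch$subject_id[first], ch$day[first]),
                 paste(sc$subject_id, sc$day))
    if (any(is.na(idx)) || any(!is.finite(sc$delta_cortisol[idx])))
      stop("delta_cortisol missing for some subject-day; covariate model ",
           "needs it for every session", call. = FALSE)
    as.numeric(sc$delta_cortisol[idx])
  }
  list(gain = as.numeric(ch$gamble_gain),
       lossmag = as.numeric(-pmin(ch$gamble_loss, 0)),
       guar = as.numeric(ch$guaranteed),
       y = as.integer(ch$chose_gamble),
       sess_start = as.integer(sess_start), ssub = as.integer(ssub),
       sday = sday, smod = smod,
       S = length(subject_ids), J = length(sess),
       subject_ids = subject_ids, variant = variant)
}

## internal: complete-pooling MLE of (rho, lam, mu) used to initialize chains
.pooled_mle <- function(prep) {
  N <- length(prep$gain)
  nll <- function(lp) {
    -.cpp_total_loglik(prep$gain, prep$lossmag, prep$guar, prep$y,
                       c(0L, N), exp(lp[1]), exp(lp[2]), exp(lp[3]),
                       log(1e-12))
  }
  fit <- optim(log(c(1, 2, 5)), nll, method = "Nelder-Mead",
               control = list(maxit = 500))
  fit$par
}

## internal: parameter-name vector for the draws array
.param_names <- function(prep) {
  eff <- if (prep$variant == "condition") "S" else "C"
  hyper <- c(paste0("thetaM[", .par_names, "]"),
             paste0("thetaV[", .par_names, "]"),
             paste0("d", eff, "M[", .par_names, "]"),
             paste0("d", eff, "V[", .par_names, "]"),
             paste0("dDM[", .par_names, "]"),
             paste0("dDV[", .par_names, "]"))
  zn <- function(tag) as.vector(vapply(.par_names, function(k)
    paste0(tag, "[", prep$subject_ids, ",", k, "]"),
    character(length(prep$subject_ids))))
  c(hyper, zn("z0"), zn(paste0("z", eff)), zn("zD"))
}

#' Fit the hierarchical prospect-theory model
#'
#' Estimates the group-level means and SDs of the log-scale baselines and of
#' the stress (or cortisol-covariate) and day effects, together with all
#' subject-level effects, from trial-level choice data. Subject effects are
#' Gaussian around the group means; session parameters arise by
#' exponentiating the summed effects; choices are Bernoulli in the softmax
#' probability. Sampling uses an adaptive Metropolis-within-Gibbs scheme on
#' a non-centered parameterization (subject effect = mean + SD x standard
#' normal deviate), with chains initialized at a complete-pooling maximum
#' likelihood estimate plus chain-specific jitter. Fully reproducible given
#' `seed`.
#'
#' @param study an `sr_study` (from [simulate_study()] or [read_study()]).
#'   For the covariate variant, `study$sessions$delta_cortisol` must be
#'   present for every subject-day.
#' @param variant `"condition"` (binary Stress indicator) or `"covariate"`
#'   (session Delta-cortisol).
#' @param mcmc an [mcmc_config()].
#' @param seed integer seed.
#' @param prior a [prior_config()].
#' @param init_jitter SD of the chain-specific jitter on initial values.
#' @return object of class `sr_fit`: `draws` (kept-iterations x chains x
#'   parameters array with dimnames), `loglik` (kept x chains matrix of
#'   total log-likelihood), and `meta` (config, seed, variant, subject ids).
#' @export
fit_hierarchical <- function(study,
                             variant = c("condition", "covariate"),
                             mcmc = mcmc_config(), seed,
                             prior = prior_config(), init_jitter = 0.1) {
  variant <- match.arg(variant)
  stopifnot(inherits(mcmc, "sr_mcmc_config"), inherits(prior, "sr_prior"))
  prep <- .prep_fit_data(study, variant)
  mle <- with_seed(substream_seed(seed, "init"), .pooled_mle(prep))
  P <- 18L + 9L * prep$S
  draws <- array(NA_real_, c(mcmc$draws, mcmc$chains, P))
  loglik <- matrix(NA_real_, mcmc$draws, mcmc$chains)
  for (cc in seq_len(mcmc$chains)) {
    res <- with_seed(substream_seed(seed, paste0("chain", cc)), {
      init <- c(mle + rnorm(3, 0, init_jitter),          # thetaM
                c(0.1, 0.2, 0.2),                        # thetaV
                rnorm(3, 0, init_jitter / 2),            # dSM / dCM
                rep(0.05, 3),                            # dSV / dCV
                rnorm(3, 0, init_jitter / 2),            # dDM
                rep(0.05, 3))                            # dDV
      .cpp_run_chain(prep$gain, prep$lossmag, prep$guar, prep$y,
                     prep$sess_start, prep$ssub, prep$sday, prep$smod,
                     prep$S, mcmc$warmup, mcmc$draws, mcmc$thin,
                     init, c(prior$mean_sd, prior$effect_sd,
                             prior$sd_scale), log(1e-12))
    })
    draws[, cc, ] <- res$draws
    loglik[, cc] <- res$loglik
  }
  dimnames(draws) <- list(NULL, paste0("chain", seq_len(mcmc$chains)),
                          .param_names(prep))
  structure(list(draws = draws, loglik = loglik,
                 meta = list(mcmc = mcmc, prior = prior, seed = seed,
                             variant = variant,
                             subject_ids = prep$subject_ids,
                             n_subjects = prep$S, n_sessions = prep$J,
                             n_trials = length(prep$gain),
                             kept_total = mcmc$draws * mcmc$chains),
                 prep = prep),
            class = "sr_fit")
}

#' @export
print.sr_fit <- function(x, ...) {
  m <- x$meta
  cat(sprintf("hierarchical fit (%s variant): %d subjects, %d trials\n",
              m$variant, m$n_subjects, m$n_trials))
  cat(sprintf("%d chains x %d kept (after %d warmup) = %d draws/parameter\n",
              m$mcmc$chains, m$mcmc$draws, m$mcmc$warmup, m$kept_total))
  b <- reconstruct_params(x, "baseline")
  cat("posterior-mean baseline: "); print(b)
  invisible(x)
}

#' Extract pooled draws of one parameter
#'
#' @param fit an `sr_fit`.
#' @param param parameter name, e.g. `"thetaM[rho]"`.
#' @return numeric vector of length kept x chains.
#' @export
param_draws <- function(fit, param) {
  if (!param %in% dimnames(fit$draws)[[3]])
    stop("unknown parameter: ", param, call. = FALSE)
  as.vector(fit$draws[, , param])
}

#' Split-chain potential-scale-reduction diagnostic (Rhat)
#'
#' Each chain is split in half; Rhat is the square root of the ratio of the
#' pooled-variance estimate to the mean within-chain variance. The default
#' `"rank"` method applies the diagnostic to rank-normalized draws (the
#' modern robust variant); `"classic"` uses the draws as-is. Values near 1
#' indicate convergence. Degenerate (zero-variance) parameters yield `NA`
#' rather than an error.
#'
#' @param x an `sr_fit` (returns a named vector over all parameters) or an
#'   iterations-x-chains matrix (returns a scalar).
#' @param method `"rank"` or `"classic"`.
#' @return Rhat value(s).
#' @export
rhat <- function(x, method = c("rank", "classic")) {
  method <- match.arg(method)
  if (inherits(x, "sr_fit")) {
    pn <- dimnames(x$draws)[[3]]
    return(vapply(pn, function(p) rhat(x$draws[, , p, drop = TRUE], method),
                  numeric(1)))
  }
  m <- as.matrix(x)
  n2 <- floor(nrow(m) / 2)
  if (n2 < 2 || ncol(m) < 1) stop("need >= 2 chains x >= 4 iterations",
                                  call. = FALSE)
  halves <- cbind(m[seq_len(n2), , drop = FALSE],
                  m[(nrow(m) - n2 + 1):nrow(m), , drop = FALSE])
  if (method == "rank") {
    r <- matrix(rank(halves, ties.method = "average"), nrow = n2)
    halves <- qnorm((r - 3 / 8) / (length(halves) + 1 / 4))
  }
  W <- mean(apply(halves, 2, var))
  B <- n2 * var(colMeans(halves))
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

#' Central credible interval
#'
#' Equal-tailed interval from the sample quantiles at
#' \eqn{((1-level)/2,\ 1-(1-level)/2)}.
#'
#' @param samples numeric draw vector (length >= 2).
#' @param level interval mass in (0, 1).
#' @return numeric `c(low, high)`.
#' @export
credible_interval <- function(samples, level = 0.95) {
  stopifnot(length(samples) >= 2, level > 0, level < 1)
  unname(quantile(samples, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Largest central interval level excluding zero
#'
#' The widest equal-tailed credible level whose interval still excludes
#' zero: \eqn{2 |\hat F(0) - 0.5|} with \eqn{\hat F} the empirical CDF
#' (counting ties as below). When zero lies outside the sample range the
#' level is capped at the sample resolution, \eqn{(n-1)/n}, reported via the
#' `"resolution"` attribute.
#'
#' @param samples numeric draw vector (length >= 10).
#' @return scalar level in `[0, 1]` with attribute `resolution = 1/n`.
#' @export
max_level_excluding_zero <- function(samples) {
  n <- length(samples)
  if (n < 10) stop("need >= 10 samples", call. = FALSE)
  Fhat <- mean(samples <= 0)
  lev <- if (Fhat == 0 || Fhat == 1) (n - 1) / n else 2 * abs(Fhat - 0.5)
  structure(lev, resolution = 1 / n)
}

## internal: posterior means of the group-level mean vectors
.group_means <- function(fit) {
  eff <- if (fit$meta$variant == "condition") "S" else "C"
  gm <- function(tag) vapply(.par_names, function(k)
    mean(param_draws(fit, paste0(tag, "[", k, "]"))), numeric(1))
  list(thetaM = gm("thetaM"), dSM = gm(paste0("d", eff, "M")),
       dDM = gm("dDM"))
}

#' Reconstruct natural-scale parameters from posterior means
#'
#' Applies the session-parameter construction to the posterior means of the
#' group-level means: `"baseline"` is \eqn{e^{\theta_M}}, `"day2"` adds the
#' day-effect mean, `"stress"` adds the stress-effect mean (condition
#' variant), and a numeric `cortisol_at` value scales the covariate-effect
#' mean (covariate variant).
#'
#' @param fit an `sr_fit`.
#' @param context `"baseline"`, `"day2"`, `"stress"`, or
#'   `list(cortisol_at = x)`.
#' @return a [value_params()].
#' @export
reconstruct_params <- function(fit, context = "baseline") {
  g <- .group_means(fit)
  lp <- if (identical(context, "baseline")) {
    g$thetaM
  } else if (identical(context, "day2")) {
    g$thetaM + g$dDM
  } else if (identical(context, "stress")) {
    if (fit$meta$variant != "condition")
      stop("`stress` context requires the condition variant", call. = FALSE)
    g$thetaM + g$dSM
  } else if (is.list(context) && !is.null(context$cortisol_at)) {
    if (fit$meta$variant != "covariate")
      stop("`cortisol_at` context requires the covariate variant",
           call. = FALSE)
    g$thetaM + context$cortisol_at * g$dSM
  } else stop("unknown context", call. = FALSE)
  th <- exp(lp)
  value_params(th[1], th[2], th[3])
}

#' Credible intervals for the group-level effect means
#'
#' @param fit an `sr_fit`.
#' @param effect `"stress"` (or `"cortisol"` for covariate fits) or
#'   `"day"`.
#' @param level interval mass.
#' @return 3 x 2 matrix (rows rho/lam/mu, columns low/high).
#' @export
effect_ci <- function(fit, effect = c("stress", "day", "cortisol"),
                      level = 0.95) {
  effect <- match.arg(effect)
  tag <- if (effect == "day") "dDM" else
    if (fit$meta$variant == "condition") "dSM" else "dCM"
  out <- t(vapply(.par_names, function(k)
    credible_interval(param_draws(fit, paste0(tag, "[", k, "]")), level),
    numeric(2)))
  colnames(out) <- c("low", "high")
  out
}

#' Posterior-mean subject-level effect values
#'
#' Per-subject posterior means of the realized effect
#' (mean + SD x subject deviate), e.g. each subject's day-effect on
#' loss aversion. Used for payment-effect correlations.
#'
#' @param fit an `sr_fit`.
#' @param effect `"day"`, or `"stress"`/`"cortisol"` per variant.
#' @return n_subjects x 3 matrix (columns rho/lam/mu), rownames subject ids.
#' @export
subject_effect_means <- function(fit, effect = c("day", "stress",
                                                 "cortisol")) {
  effect <- match.arg(effect)
  eff <- if (fit$meta$variant == "condition") "S" else "C"
  tags <- if (effect == "day") c("dDM", "dDV", "zD") else
    c(paste0("d", eff, "M"), paste0("d", eff, "V"), paste0("z", eff))
  ids <- fit$meta$subject_ids
  out <- vapply(.par_names, function(k) {
    m <- param_draws(fit, paste0(tags[1], "[", k, "]"))
    v <- param_draws(fit, paste0(tags[2], "[", k, "]"))
    vapply(ids, function(id)
      mean(m + v * param_draws(fit, paste0(tags[3], "[", id, ",", k, "]"))),
      numeric(1))
  }, numeric(length(ids)))
  rownames(out) <- ids
  out
}

#' Summary report of a hierarchical fit
#'
#' Reconstructed baseline / Day-2 / stress (or cortisol) parameters,
#' credible intervals for the effect means with zero-exclusion flags, and
#' convergence diagnostics for the group-level parameters.
#'
#' @param fit an `sr_fit`.
#' @param level credible level for the intervals.
#' @return list of class `sr_fit_report`.
#' @export
fit_report <- function(fit, level = 0.95) {
  variant <- fit$meta$variant
  eff_name <- if (variant == "condition") "stress" else "cortisol"
  recovered <- list(baseline = reconstruct_params(fit, "baseline"),
                    day2 = reconstruct_params(fit, "day2"))
  recovered[[eff_name]] <- if (variant == "condition")
    reconstruct_params(fit, "stress") else
      reconstruct_params(fit, list(cortisol_at = 0.20))
  cis <- list(day = effect_ci(fit, "day", level))
  cis[[eff_name]] <- effect_ci(fit, eff_name, level)
  excl <- lapply(cis, function(ci) ci[, "low"] > 0 | ci[, "high"] < 0)
  group_idx <- dimnames(fit$draws)[[3]][1:18]
  rh <- vapply(group_idx, function(p)
    rhat(fit$draws[, , p, drop = TRUE]), numeric(1))
  structure(list(variant = variant, recovered = recovered,
                 effect_CIs = cis, excluded_zero = excl,
                 rhat_group = rh, rhat_group_mean = mean(rh, na.rm = TRUE),
                 level = level, meta = fit$meta),
            class = "sr_fit_report")
}

#' @export
print.sr_fit_report <- function(x, ...) {
  cat(sprintf("== hierarchical model report (%s variant) ==\n", x$variant))
  for (nm in names(x$recovered)) {
    p <- x$recovered[[nm]]
    cat(sprintf("%-9s rho = %.3f  lambda = %.3f  mu = %.3f\n", nm,
                p$rho, p$lam, p$mu))
  }
  for (nm in names(x$effect_CIs)) {
    ci <- x$effect_CIs[[nm]]
    for (k in rownames(ci))
      cat(sprintf("%.0f%% CI %s effect on %-4s [%7.3f %7.3f]%s\n",
                  100 * x$level, nm, k, ci[k, 1], ci[k, 2],
                  if (x$excluded_zero[[nm]][k]) "  * excludes zero" else ""))
  }
  cat(sprintf("mean group-level Rhat = %.3f\n", x$rhat_group_mean))
  invisible(x)
}

#' Refit the model on a subject subset
#'
#' Filters the study to the requested gender and refits the identical model
#' (e.g. the male-only sensitivity analysis).
#'
#' @param study an `sr_study`.
#' @param gender `"male"` or `"female"`.
#' @inheritParams fit_hierarchical
#' @return an `sr_fit`.
#' @export
subset_fit <- function(study, gender = "male",
                       variant = c("condition", "covariate"),
                       mcmc = mcmc_config(), seed,
                       prior = prior_config()) {
  keep <- study$subjects$subject_id[study$subjects$gender == gender]
  if (length(keep) < 2) stop("gender filter leaves < 2 subjects",
                             call. = FALSE)
  sub <- study
  sub$subjects <- study$subjects[study$subjects$subject_id %in% keep, ]
  sub$choices <- study$choices[study$choices$subject_id %in% keep, ]
  sub$sessions <- study$sessions[study$sessions$subject_id %in% keep, ]
  sub$cortisol <- study$cortisol[study$cortisol$subject_id %in% keep, ]
  fit_hierarchical(sub, variant = variant, mcmc = mcmc, seed = seed,
                   prior = prior)
}
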