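#' Value parameters of the prospect-theory choice model
#'
#' Bundles the three parameters of the value/choice model on their natural
#' scale: risk attitude `rho` (utility curvature, risk neutral at 1), loss
#' aversion `lam` (losses weighted `lam` times gains, neutral at 1), and
#' choice consistency `mu` (softmax inverse temperature; 0 is random choice).
#'
#' @param rho risk attitude, > 0.
#' @param lam loss aversion, > 0.
#' @param mu consistency, >= 0 (`mu = 0` is the pure-noise limit).
#' @return list of class `sr_params`.
#' @export
#' @examples
#' value_params(0.92, 2.22, 25.9)
value_params <- function(rho, lam, mu) {
  stopifnot_scalar(rho, "rho"); stopifnot_scalar(lam, "lam")
  stopifnot_scalar(mu, "mu")
  if (rho <= 0 || lam <= 0 || mu < 0)
    stop("need rho > 0, lam > 0, mu >= 0", call. = FALSE)
  structure(list(rho = unname(rho), lam = unname(lam), mu = unname(mu)),
            class = "sr_params")
}

#' @export
print.sr_params <- function(x, ...) {
  cat(sprintf("value params: rho = %.4g, lambda = %.4g, mu = %.4g\n",
              x$rho, x$lam, x$mu))
  invisible(x)
}

#' Utility of a potential gain
#'
#' \eqn{u(x^+) = p \, x^{\rho}} for non-negative amounts. Vectorized over `x`.
#'
#' @param x monetary amount(s), >= 0.
#' @param rho risk attitude, > 0.
#' @param prob outcome probability in `[0, 1]`.
#' @return utility value(s).
#' @export
utility_gain <- function(x, rho, prob = 0.5) {
  if (any(x < 0)) stop("utility_gain: x must be >= 0 (route losses to ",
                       "utility_loss)", call. = FALSE)
  if (rho <= 0) stop("rho must be > 0", call. = FALSE)
  prob * x^rho
}

#' Utility of a potential loss
#'
#' \eqn{u(x^-) = -p \, \lambda \, (-x)^{\rho}} for non-positive amounts.
#' Vectorized over `x`.
#'
#' @param x monetary amount(s), <= 0.
#' @param rho risk attitude, > 0.
#' @param lam loss aversion, > 0.
#' @param prob outcome probability in `[0, 1]`.
#' @return utility value(s), <= 0.
#' @export
utility_loss <- function(x, rho, lam, prob = 0.5) {
  if (any(x > 0)) stop("utility_loss: x must be <= 0", call. = FALSE)
  if (rho <= 0 || lam <= 0) stop("need rho > 0 and lam > 0", call. = FALSE)
  prob * (-lam) * (-x)^rho
}

#' Utilities of the gamble and the guaranteed option
#'
#' The gamble's utility is the sum of its two equiprobable branch utilities
#' (the losing branch of a gain-only trial pays 0 and contributes 0); the
#' guaranteed utility is evaluated at probability 1.
#'
#' @param trials an `sr_trials` data frame (or any data frame with
#'   `gamble_gain`, `gamble_loss`, `guaranteed`).
#' @param params a [value_params()].
#' @return data frame with columns `u_gamble`, `u_guaranteed`.
#' @export
option_utilities <- function(trials, params) {
  stopifnot(inherits(params, "sr_params"))
  u_g <- utility_gain(trials$gamble_gain, params$rho, 0.5) +
    utility_loss(trials$gamble_loss, params$rho, params$lam, 0.5)
  gg <- trials$guaranteed
  u_s <- ifelse(gg >= 0, utility_gain(pmax(gg, 0), params$rho, 1),
                utility_loss(pmin(gg, 0), params$rho, params$lam, 1))
  data.frame(u_gamble = u_g, u_guaranteed = u_s)
}

#' Softmax probability of choosing the gamble
#'
#' \eqn{P(\mathrm{gamble}) = \left(1 + e^{-\mu(u_g - u_s)}\right)^{-1}},
#' evaluated in a numerically stable log-sigmoid form; saturates smoothly for
#' large \eqn{|\mu \Delta u|}.
#'
#' @inheritParams option_utilities
#' @return vector of probabilities in `(0, 1)` (up to floating-point
#'   saturation).
#' @export
#' @examples
#' tr <- generate_trial_set(seed = 1)
#' summary(p_gamble(tr, value_params(0.92, 2.22, 25.9)))
p_gamble <- function(trials, params) {
  u <- option_utilities(trials, params)
  plogis(params$mu * (u$u_gamble - u$u_guaranteed))
}

#' Session-level value parameters from subject effects
#'
#' Builds the natural-scale parameters of one subject-session as
#' \eqn{\theta_{i,j} = e^{\theta_i + m_j \Delta\theta_{Si} + Day_j
#' \Delta\theta_{Di}}} componentwise for (\eqn{\rho, \lambda, \mu}), where the
#' modulator \eqn{m_j} is the binary stress indicator (condition variant) or
#' the session's \eqn{\Delta}Cortisol value (covariate variant). The
#' exponential guarantees strictly positive outputs for any finite inputs.
#'
#' @param effects list with numeric 3-vectors `theta_base`, `delta_stress`,
#'   `delta_day` (log-scale, ordered rho/lam/mu).
#' @param ctx list with `stress_indicator` (0/1), `day_indicator` (0/1) and,
#'   for the covariate variant, `delta_cortisol`.
#' @param variant `"condition"` or `"covariate"`.
#' @return a [value_params()].
#' @export
session_params <- function(effects, ctx,
                           variant = c("condition", "covariate")) {
  variant <- match.arg(variant)
  mod <- if (variant == "condition") ctx$stress_indicator else
    ctx$delta_cortisol
  if (is.null(mod) || !is.finite(mod))
    stop("session context lacks a finite modulator for variant ", variant,
         call. = FALSE)
  lp <- effects$theta_base + mod * effects$delta_stress +
    ctx$day_indicator * effects$delta_day
  if (any(!is.finite(lp))) stop("non-finite subject effects", call. = FALSE)
  th <- exp(lp)
  value_params(th[1], th[2], th[3])
}

## stable per-trial Bernoulli log-likelihood terms; probabilities clipped to
## [1e-12, 1 - 1e-12] so a saturated trial cannot produce -Inf
.ll_terms <- function(chose, s, clip = 1e-12) {
  lt <- ifelse(chose == 1, -log1p(exp(-pmin(s, 700))),
               -log1p(exp(pmin(s, 700))))
  ## exact stable form for |s| > 700
  big <- abs(s) > 700
  if (any(big)) {
    lt[big] <- ifelse((chose[big] == 1) == (s[big] > 0), 0, -abs(s[big]))
  }
  pmax(lt, log(clip))
}

#' Bernoulli log-likelihood of observed choices
#'
#' Sum over trials of \eqn{\log P(\mathrm{gamble})} or
#' \eqn{\log(1 - P(\mathrm{gamble}))} per the recorded choice, computed in a
#' stable log-sigmoid form with probabilities clipped to
#' `[1e-12, 1 - 1e-12]`.
#'
#' @param choices data frame with the trial value columns plus `chose_gamble`
#'   (0/1).
#' @param params a [value_params()].
#' @return scalar log-likelihood, finite and <= 0.
#' @export
log_likelihood <- function(choices, params) {
  if (!is.data.frame(choices) || nrow(choices) == 0)
    stop("`choices` must be a non-empty data frame", call. = FALSE)
  u <- option_utilities(choices, params)
  s <- params$mu * (u$u_gamble - u$u_guaranteed)
  sum(.ll_terms(choices$chose_gamble, s))
}

#' Simulate choices (and realized outcomes) on a trial set
#'
#' Generative counterpart of the softmax rule: each choice is Bernoulli in
#' the model's P(gamble); a chosen gamble resolves its branch with
#' probability 0.5. Reproducible given `seed`.
#'
#' @param trials an `sr_trials` data frame.
#' @param params a [value_params()].
#' @param seed integer seed.
#' @return `choices` data frame: the trial columns plus `chose_gamble` (0/1)
#'   and `realized_outcome` (dollars).
#' @export
simulate_choices <- function(trials, params, seed) {
  p <- p_gamble(trials, params)
  with_seed(seed, {
    chose <- rbinom(nrow(trials), 1L, p)
    win <- rbinom(nrow(trials), 1L, 0.5)
    realized <- ifelse(chose == 1,
                       ifelse(win == 1, trials$gamble_gain,
                              trials$gamble_loss),
                       trials$guaranteed)
    out <- cbind(as.data.frame(trials), chose_gamble = chose,
                 realized_outcome = realized)
    rownames(out) <- NULL
    out
  })
}
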