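#' Configuration for the 150-trial risky-choice task
#'
#' The task mixes two trial families: "gain-loss" trials offer a 50/50 gamble
#' between a gain and a loss against a guaranteed $0, and "gain-only" trials
#' offer a 50/50 gamble between a gain and $0 against a smaller guaranteed
#' amount. Jointly the two families make risk attitude, loss aversion and
#' consistency separately identifiable.
#'
#' All dollar amounts live on a $0.25 grid. A fraction `anchor_frac` of
#' gain-loss gains is anchored (with jitter) to the loss-aversion indifference
#' line \eqn{gain = \lambda_{ref}^{1/\rho_{ref}} \times loss}, and half of the
#' gain-only guaranteed amounts sit at the certainty-equivalent fraction
#' \eqn{0.5^{1/\rho_{ref}}} of the gain, so that a substantial share of trials has a
#' non-degenerate choice probability even for highly consistent agents; see
#' [design_informativeness()].
#'
#' @param n_gain_loss,n_gain_only trial counts per family (default 120 / 30).
#' @param gain_range,loss_range gain-loss family ranges in dollars (loss as
#'   positive magnitude).
#' @param gain_only_range gain range for gain-only trials.
#' @param guar_frac_range guaranteed amount as a fraction of the gain-only
#'   gain, for the un-anchored trials.
#' @param step monetary grid step in dollars.
#' @param anchor_frac fraction of gain-loss trials anchored near
#'   indifference.
#' @param anchor_jitter jitter (dollars) around the anchored gain.
#' @param go_anchor_frac fraction of gain-only trials whose guaranteed amount
#'   is pinned to the gamble's certainty equivalent at the reference
#'   curvature.
#' @param ref_rho,ref_lam reference value-function parameters used for
#'   anchoring and for the informativeness check.
#' @param max_tries redraw attempts before declaring the config infeasible.
#' @return a list of class `sr_design_config`.
#' @export
trial_design_config <- function(n_gain_loss = 120L, n_gain_only = 30L,
                                gain_range = c(2, 12), loss_range = c(1, 6),
                                gain_only_range = c(3, 12),
                                guar_frac_range = c(0.3, 0.7),
                                step = 0.25, anchor_frac = 0.65,
                                anchor_jitter = 0.25, go_anchor_frac = 0.8,
                                ref_rho = 0.92, ref_lam = 2.2,
                                max_tries = 200L) {
  cfg <- list(n_gain_loss = as.integer(n_gain_loss),
              n_gain_only = as.integer(n_gain_only),
              gain_range = gain_range, loss_range = loss_range,
              gain_only_range = gain_only_range,
              guar_frac_range = guar_frac_range, step = step,
              anchor_frac = anchor_frac, anchor_jitter = anchor_jitter,
              go_anchor_frac = go_anchor_frac,
              ref_rho = ref_rho, ref_lam = ref_lam,
              max_tries = as.integer(max_tries))
  if (any(c(gain_range, loss_range, gain_only_range) <= 0) || step <= 0)
    stop("design value ranges and step must be positive", call. = FALSE)
  ## feasibility: enough grid points for unique triples
  n_gl_grid <- length(seq(gain_range[1], gain_range[2], by = step)) *
    length(seq(loss_range[1], loss_range[2], by = step))
  n_go_grid <- length(seq(gain_only_range[1], gain_only_range[2], by = step)) *
    max(1, length(seq(guar_frac_range[1], guar_frac_range[2], by = 0.05)))
  if (n_gl_grid < cfg$n_gain_loss || n_go_grid < cfg$n_gain_only)
    stop("infeasible design config: value grids admit fewer unique ",
         "combinations than the requested trial counts", call. = FALSE)
  class(cfg) <- "sr_design_config"
  cfg
}

round_to_step <- function(x, step) round(x / step) * step

draw_gain_loss <- function(n, cfg) {
  gain_grid <- seq(cfg$gain_range[1], cfg$gain_range[2], by = cfg$step)
  loss_grid <- seq(cfg$loss_range[1], cfg$loss_range[2], by = cfg$step)
  ratio <- cfg$ref_lam^(1 / cfg$ref_rho)
  ## anchored losses are restricted so the anchored gain stays on the grid
  ## without clamping away from the indifference line
  l_max <- (cfg$gain_range[2] - cfg$step - cfg$anchor_jitter) / ratio
  loss_grid_a <- loss_grid[loss_grid <= l_max]
  anchored <- runif(n) < cfg$anchor_frac
  lossm <- ifelse(anchored, sample(loss_grid_a, n, replace = TRUE),
                  sample(loss_grid, n, replace = TRUE))
  g_anch <- round_to_step(ratio * lossm + runif(n, -cfg$anchor_jitter,
                                                cfg$anchor_jitter), cfg$step)
  g_anch <- pmin(cfg$gain_range[2], pmax(cfg$gain_range[1], g_anch))
  gain <- ifelse(anchored, g_anch, sample(gain_grid, n, replace = TRUE))
  data.frame(family = "gain_loss", gamble_gain = gain, gamble_loss = -lossm,
             guaranteed = 0, stringsAsFactors = FALSE)
}

draw_gain_only <- function(n, cfg) {
  gain_grid <- seq(cfg$gain_only_range[1], cfg$gain_only_range[2],
                   by = cfg$step)
  gain <- sample(gain_grid, n, replace = TRUE)
  anchored <- runif(n) < cfg$go_anchor_frac
  ## anchored trials pin the guaranteed amount to the grid point nearest the
  ## gamble's certainty equivalent at the reference curvature
  f_star <- 0.5^(1 / cfg$ref_rho)
  frac <- runif(n, cfg$guar_frac_range[1], cfg$guar_frac_range[2])
  guar <- ifelse(anchored, round_to_step(gain * f_star, cfg$step),
                 round_to_step(gain * frac, cfg$step))
  guar <- pmin(gain - cfg$step, pmax(cfg$step, guar))
  data.frame(family = "gain_only", gamble_gain = gain, gamble_loss = 0,
             guaranteed = guar, stringsAsFactors = FALSE)
}

#' Generate one session's trial set
#'
#' Draws the default 120 gain-loss + 30 gain-only trials on the configured
#' monetary grids, enforces uniqueness of every (gain, loss, guaranteed)
#' triple by redrawing duplicates, and randomizes trial order. Deterministic
#' given `seed`.
#'
#' @param config a [trial_design_config()].
#' @param seed integer seed.
#' @return a `data.frame` of class `sr_trials` with columns `trial_index`
#'   (0-based presentation order), `family`, `gamble_gain`, `gamble_loss`
#'   (\eqn{\le 0}), `guaranteed`, `outcome_prob` (0.5 throughout).
#' @export
#' @examples
#' tr <- generate_trial_set(seed = 1)
#' table(tr$family)
generate_trial_set <- function(config = trial_design_config(), seed) {
  stopifnot(inherits(config, "sr_design_config"))
  with_seed(seed, {
    draw_unique <- function(n, drawer) {
      out <- drawer(n, config)
      tries <- 0L
      repeat {
        key <- paste(out$gamble_gain, out$gamble_loss, out$guaranteed)
        dup <- duplicated(key)
        if (!any(dup)) return(out)
        tries <- tries + 1L
        if (tries > config$max_tries)
          stop("infeasible design config: could not draw ", n,
               " unique value triples within ", config$max_tries,
               " redraw rounds", call. = FALSE)
        out[dup, ] <- drawer(sum(dup), config)
      }
    }
    gl <- draw_unique(config$n_gain_loss, draw_gain_loss)
    go <- draw_unique(config$n_gain_only, draw_gain_only)
    trials <- rbind(gl, go)
    trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
    trials <- data.frame(trial_index = seq_len(nrow(trials)) - 1L, trials,
                         outcome_prob = 0.5, row.names = NULL,
                         stringsAsFactors = FALSE)
    class(trials) <- c("sr_trials", "data.frame")
    trials
  })
}

#' Validate a trial set against the task-design invariants
#'
#' Checks that both trial families are present (required for the joint
#' identifiability of \eqn{\rho}, \eqn{\lambda} and \eqn{\mu}), that each
#' family satisfies its structural constraints, that outcome probabilities
#' are 0.5 and value triples unique.
#'
#' @param trials an `sr_trials` data frame.
#' @return list of class `sr_validation` with elements `pass` (logical) and
#'   `messages` (character vector of failures, empty on pass).
#' @export
validate_trial_set <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0)
    stop("`trials` must be a non-empty data frame", call. = FALSE)
  msgs <- character()
  need <- c("trial_index", "family", "gamble_gain", "gamble_loss",
            "guaranteed", "outcome_prob")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    msgs <- sprintf("missing columns: %s", paste(miss, collapse = ", "))
  } else {
    if (!any(trials$family == "gain_loss"))
      msgs <- c(msgs, "gain_loss family missing")
    if (!any(trials$family == "gain_only"))
      msgs <- c(msgs, "gain_only family missing")
    bad_fam <- setdiff(unique(trials$family), c("gain_loss", "gain_only"))
    if (length(bad_fam))
      msgs <- c(msgs, sprintf("unknown family: %s",
                              paste(bad_fam, collapse = ", ")))
    gl <- trials[trials$family == "gain_loss", ]
    if (nrow(gl) && !all(gl$gamble_gain > 0 & gl$gamble_loss < 0 &
                           gl$guaranteed == 0))
      msgs <- c(msgs, paste("gain_loss invariant violated (need gain > 0,",
                            "loss < 0, guaranteed = 0)"))
    go <- trials[trials$family == "gain_only", ]
    if (nrow(go) && !all(go$gamble_gain > 0 & go$gamble_loss == 0 &
                           go$guaranteed > 0 &
                           go$guaranteed < go$gamble_gain))
      msgs <- c(msgs, paste("gain_only invariant violated (need gain > 0,",
                            "low branch = 0, 0 < guaranteed < gain)"))
    if (!all(trials$outcome_prob == 0.5))
      msgs <- c(msgs, "outcome_prob must be 0.5 on every trial")
    key <- paste(trials$gamble_gain, trials$gamble_loss, trials$guaranteed)
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate value triples present")
  }
  structure(list(pass = length(msgs) == 0L, messages = msgs),
            class = "sr_validation")
}

#' @export
print.sr_validation <- function(x, ...) {
  cat(if (x$pass) "trial set: PASS\n" else "trial set: FAIL\n")
  for (m in x$messages) cat(" -", m, "\n")
  invisible(x)
}

#' Fraction of trials with a non-degenerate choice probability
#'
#' Design calibration check: the share of trials whose model-predicted
#' P(gamble) falls strictly inside `(lo, hi)` at reference parameters. Trials
#' outside the band are effectively deterministic for such an agent and carry
#' almost no likelihood information about \eqn{\mu}; the default design
#' targets at least 30% inside the band at the task-typical parameter
#' values rho = 0.92, lambda = 2.2, mu = 25.9.
#'
#' @param trials an `sr_trials` data frame.
#' @param params a [value_params()]; defaults to task-typical values.
#' @param lo,hi band edges.
#' @return scalar fraction in `[0, 1]`.
#' @export
design_informativeness <- function(trials,
                                   params = value_params(0.92, 2.2, 25.9),
                                   lo = 0.05, hi = 0.95) {
  p <- p_gamble(trials, params)
  mean(p > lo & p < hi)
}

#' Write / read a trial set as CSV
#'
#' Dollar columns are written as two-decimal strings.
#'
#' @param trials an `sr_trials` data frame.
#' @param path file path.
#' @return `write_trials_csv` returns `path` invisibly; `read_trials_csv`
#'   returns an `sr_trials` data frame.
#' @export
write_trials_csv <- function(trials, path) {
  out <- trials[, c("trial_index", "family", "gamble_gain", "gamble_loss",
                    "guaranteed")]
  for (cc in c("gamble_gain", "gamble_loss", "guaranteed"))
    out[[cc]] <- sprintf("%.2f", out[[cc]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  for (cc in c("gamble_gain", "gamble_loss", "guaranteed"))
    tr[[cc]] <- as.numeric(tr[[cc]])
  tr$outcome_prob <- 0.5
  class(tr) <- c("sr_trials", "data.frame")
  tr
}
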