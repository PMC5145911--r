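#' Population-level (group) hyperparameters
#'
#' Log-scale population means and SDs for subject baselines and for the
#' stress- and day-effect terms, ordered (rho, lam, mu). Defaults reproduce
#' the task-typical population: baselines exp(theta_M) = (0.92, 2.22, 25.9)
#' with baseline SDs (0.24, 0.84, 0.87), zero mean stress/day effects and
#' small effect heterogeneity (0.1) — effect SDs are not separately
#' identified in typical datasets of this size, so a small nonzero default
#' keeps the generative model honest without drowning the means.
#'
#' @param theta_M,theta_V baseline log-scale mean / SD 3-vectors.
#' @param deltaS_M,deltaS_V stress-effect (or cortisol-covariate) mean / SD.
#' @param deltaD_M,deltaD_V day-effect mean / SD.
#' @param degenerate_ok allow zero SDs (simulation-only degenerate mode).
#' @return list of class `sr_hyper`.
#' @export
group_hyper <- function(theta_M = log(c(0.92, 2.22, 25.9)),
                        theta_V = c(0.24, 0.84, 0.87),
                        deltaS_M = c(0, 0, 0), deltaS_V = c(0.1, 0.1, 0.1),
                        deltaD_M = c(0, 0, 0), deltaD_V = c(0.1, 0.1, 0.1),
                        degenerate_ok = FALSE) {
  h <- list(theta_M = theta_M, theta_V = theta_V, deltaS_M = deltaS_M,
            deltaS_V = deltaS_V, deltaD_M = deltaD_M, deltaD_V = deltaD_V,
            degenerate_ok = isTRUE(degenerate_ok))
  for (nm in c("theta_M", "theta_V", "deltaS_M", "deltaS_V", "deltaD_M",
               "deltaD_V"))
    if (length(h[[nm]]) != 3L || any(!is.finite(h[[nm]])))
      stop(sprintf("`%s` must be a finite 3-vector (rho, lam, mu)", nm),
           call. = FALSE)
  sds <- c(h$theta_V, h$deltaS_V, h$deltaD_V)
  if (any(sds < 0) || (!h$degenerate_ok && any(sds == 0)))
    stop("population SDs must be > 0 (or set degenerate_ok = TRUE)",
         call. = FALSE)
  class(h) <- "sr_hyper"
  h
}

#' Draw subject-level effects from the population
#'
#' Each subject's log-scale baseline and effect terms are drawn independently
#' Gaussian around the population means with the population SDs.
#'
#' @param hyper a [group_hyper()].
#' @param n_subjects number of subjects, >= 1.
#' @param seed integer seed.
#' @return data frame with one row per subject, columns
#'   `theta_rho, theta_lam, theta_mu, dS_rho, ..., dD_mu`.
#' @export
draw_population <- function(hyper, n_subjects, seed) {
  stopifnot(inherits(hyper, "sr_hyper"), n_subjects >= 1)
  with_seed(seed, {
    draw3 <- function(m, s) vapply(1:3, function(k)
      rnorm(n_subjects, m[k], s[k]), numeric(n_subjects))
    tb <- matrix(draw3(hyper$theta_M, hyper$theta_V), nrow = n_subjects)
    dS <- matrix(draw3(hyper$deltaS_M, hyper$deltaS_V), nrow = n_subjects)
    dD <- matrix(draw3(hyper$deltaD_M, hyper$deltaD_V), nrow = n_subjects)
    out <- data.frame(tb, dS, dD)
    names(out) <- c(paste0("theta_", .par_names), paste0("dS_", .par_names),
                    paste0("dD_", .par_names))
    out
  })
}

## internal: one subject's effects as the list session_params() expects
subject_effects <- function(pop, i) {
  list(theta_base = as.numeric(pop[i, 1:3]),
       delta_stress = as.numeric(pop[i, 4:6]),
       delta_day = as.numeric(pop[i, 7:9]))
}

#' Assign subjects to the four condition groups and genders
#'
#' The fully crossed two-day design yields groups SS, SC, CS, CC (first
#' letter = Day 1 condition, Stress or Control). Subjects are split evenly
#' across groups (30 per group at the default n = 120) and genders match the
#' study mix (64 female / 56 male at n = 120, scaled proportionally
#' otherwise), both shuffled by seed.
#'
#' @param n_subjects cohort size (a most-even group split is used, with a
#'   warning, when not divisible by 4).
#' @param seed integer seed.
#' @param n_male number of males; default scales 56/120.
#' @return data frame with `subject_id`, `gender`, `group`.
#' @export
assign_design <- function(n_subjects = 120L, seed, n_male = NULL) {
  n_subjects <- as.integer(n_subjects)
  sizes <- rep(n_subjects %/% 4L, 4L) +
    c(rep(1L, n_subjects %% 4L), rep(0L, 4L - n_subjects %% 4L))
  if (n_subjects %% 4L != 0L)
    warning("n_subjects not divisible by 4; using the most even split (",
            paste(sizes, collapse = "/"), ")")
  if (is.null(n_male)) n_male <- round(n_subjects * 56 / 120)
  with_seed(seed, {
    groups <- sample(rep(c("SS", "SC", "CS", "CC"), times = sizes))
    gender <- sample(rep(c("male", "female"),
                         c(n_male, n_subjects - n_male)))
    data.frame(subject_id = sprintf("s%03d", seq_len(n_subjects)),
               gender = gender, group = groups, stringsAsFactors = FALSE)
  })
}

#' Cortisol simulation settings
#'
#' Group-by-day mean changes from baseline (sample 1) to pre-task (sample 3),
#' in the panel's concentration units, default to the task-typical pattern:
#' modest declines under Control (afternoon drift) and increases under
#' Stress. Timepoints 2 and 4 interpolate the same trajectory. Noise is
#' additive Gaussian per timepoint.
#'
#' @param delta3_mean 4x2 matrix (rows SS, SC, CS, CC; cols Day 1, Day 2) of
#'   mean sample-3 minus sample-1 changes.
#' @param baseline_mean,baseline_sd mean and between-session SD of the
#'   baseline (sample 1) concentration.
#' @param noise_sd per-timepoint additive noise SD.
#' @param floor minimum reported concentration.
#' @return list of class `sr_cortisol_config`.
#' @export
cortisol_config <- function(delta3_mean = rbind(SS = c(0.17, 0.11),
                                                SC = c(0.10, 0.01),
                                                CS = c(-0.01, 0.16),
                                                CC = c(-0.05, -0.01)),
                            baseline_mean = 0.15, baseline_sd = 0.03,
                            noise_sd = 0.03, floor = 0.01) {
  structure(list(delta3_mean = delta3_mean, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, noise_sd = noise_sd,
                 floor = floor),
            class = "sr_cortisol_config")
}

#' Simulate one subject-day cortisol panel
#'
#' Four timepoints: baseline (1), post-manipulation (2), pre-task (3),
#' post-task (4). With `noise_sd = 0` and `baseline_sd = 0` the sample-3
#' minus sample-1 change equals the configured group-by-day mean exactly.
#'
#' @param group one of `"SS", "SC", "CS", "CC"`.
#' @param day 0 (Day 1) or 1 (Day 2).
#' @param config a [cortisol_config()].
#' @param seed integer seed.
#' @return numeric vector `c(c1, c2, c3, c4)`.
#' @export
simulate_cortisol <- function(group, day, config = cortisol_config(), seed) {
  stopifnot(group %in% rownames(config$delta3_mean), day %in% c(0, 1))
  d3 <- config$delta3_mean[group, day + 1L]
  with_seed(seed, {
    c1 <- config$baseline_mean + rnorm(1, 0, config$baseline_sd)
    traj <- c1 + d3 * c(0, 0.5, 1, 0.8)
    panel <- traj + c(0, rnorm(3, 0, config$noise_sd))
    ## noise on c1 is already the baseline draw; keep c3 - c1 centered on d3
    pmax(panel, config$floor)
  })
}

#' Full study configuration for the synthetic cohort
#'
#' Defaults emulate the target study design: 120 participants in four
#' crossed Stress/Control groups of 30, two sessions of 150 choices each,
#' four cortisol samples per session, $30 endowment with 15 randomly paid
#' trials.
#'
#' @param n_subjects cohort size.
#' @param design a [trial_design_config()].
#' @param hyper a [group_hyper()].
#' @param cortisol a [cortisol_config()].
#' @param generative `"condition"` (binary stress indicator modulates the
#'   effects) or `"covariate"` (the session's Delta-cortisol does).
#' @param shared_trials if `TRUE` every session uses one fixed trial set;
#'   default draws an independent set per subject-day.
#' @param endowment,n_paid payment-rule constants (dollars, trials).
#' @return list of class `sr_study_config`.
#' @export
study_config <- function(n_subjects = 120L, design = trial_design_config(),
                         hyper = group_hyper(),
                         cortisol = cortisol_config(),
                         generative = c("condition", "covariate"),
                         shared_trials = FALSE, endowment = 30,
                         n_paid = 15L) {
  structure(list(n_subjects = as.integer(n_subjects), design = design,
                 hyper = hyper, cortisol = cortisol,
                 generative = match.arg(generative),
                 shared_trials = isTRUE(shared_trials),
                 endowment = endowment, n_paid = as.integer(n_paid)),
            class = "sr_study_config")
}

#' Simulate a complete two-day study
#'
#' Composes the task generator, population draw, group/gender assignment,
#' cortisol panels and choice simulation into a study bundle. One master seed
#' spawns named substreams (`design`, `population`, `trials`, `cortisol`,
#' `choices`, `payment`) so components can be regenerated independently.
#'
#' @param config a [study_config()].
#' @param seed master integer seed.
#' @return list of class `sr_study` with data frames `subjects`
#'   (`subject_id`, `gender`, `group`), `choices` (one row per trial:
#'   `subject_id`, `day`, `condition`, trial columns, `chose_gamble`,
#'   `realized_outcome`), `cortisol` (long: `subject_id`, `day`, `timepoint`,
#'   `concentration`), `sessions` (`subject_id`, `day`, `condition`,
#'   `delta_cortisol`, `adjusted_endowment`), plus `config`, `seed` and the
#'   generating `population`.
#' @export
#' @examples
#' \donttest{
#' st <- simulate_study(study_config(n_subjects = 8L), seed = 1)
#' nrow(st$choices)  # 8 x 2 x 150
#' }
simulate_study <- function(config = study_config(), seed) {
  stopifnot(inherits(config, "sr_study_config"))
  subjects <- assign_design(config$n_subjects,
                            seed = substream_seed(seed, "design"))
  n <- nrow(subjects)
  pop <- draw_population(config$hyper, n,
                         seed = substream_seed(seed, "population"))
  shared <- if (config$shared_trials)
    generate_trial_set(config$design, seed = substream_seed(seed, "trials"))
  choices <- vector("list", 2L * n)
  cort <- vector("list", 2L * n)
  sessions <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    sid <- subjects$subject_id[i]
    grp <- subjects$group[i]
    eff <- subject_effects(pop, i)
    for (day in 0:1) {
      k <- k + 1L
      stress <- as.integer(substr(grp, day + 1L, day + 1L) == "S")
      panel <- simulate_cortisol(grp, day, config$cortisol,
                                 seed = substream_seed(seed,
                                   paste0("cortisol/", sid, "/", day)))
      dcort <- delta_cortisol_log(delta_cortisol_raw(panel[1], panel[3]))
      ctx <- list(stress_indicator = stress, day_indicator = day,
                  delta_cortisol = dcort)
      pars <- session_params(eff, ctx, config$generative)
      trials <- if (config$shared_trials) shared else
        generate_trial_set(config$design,
                           seed = substream_seed(seed,
                             paste0("trials/", sid, "/", day)))
      ch <- simulate_choices(trials, pars,
                             seed = substream_seed(seed,
                               paste0("choices/", sid, "/", day)))
      pay <- compute_payment(ch, endowment = config$endowment,
                             n_paid = config$n_paid,
                             seed = substream_seed(seed,
                               paste0("payment/", sid, "/", day)))
      choices[[k]] <- cbind(subject_id = sid, day = day, condition = stress,
                            ch, stringsAsFactors = FALSE)
      cort[[k]] <- data.frame(subject_id = sid, day = day, timepoint = 1:4,
                              concentration = panel,
                              stringsAsFactors = FALSE)
      sessions[[k]] <- data.frame(subject_id = sid, day = day,
                                  condition = stress, delta_cortisol = dcort,
                                  adjusted_endowment = pay,
                                  stringsAsFactors = FALSE)
    }
  }
  structure(list(subjects = subjects,
                 choices = do.call(rbind, choices),
                 cortisol = do.call(rbind, cort),
                 sessions = do.call(rbind, sessions),
                 population = pop, config = config, seed = seed),
            class = "sr_study")
}

#' @export
print.sr_study <- function(x, ...) {
  cat(sprintf("synthetic study: %d subjects, %d choice records, %d cortisol samples\n",
              nrow(x$subjects), nrow(x$choices), nrow(x$cortisol)))
  print(table(x$subjects$group))
  invisible(x)
}

#' Write / read a study bundle
#'
#' Persists `choices.csv`, `cortisol.csv`, `subjects.csv`, `sessions.csv` and
#' a `manifest.json` recording the seed and configuration.
#'
#' @param study an `sr_study`.
#' @param dir output directory (created if absent).
#' @return `write_study` returns `dir` invisibly; `read_study` returns an
#'   `sr_study`-like list (without the generating population).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(study$choices, file.path(dir, "choices.csv"), row.names = FALSE)
  write.csv(study$cortisol, file.path(dir, "cortisol.csv"),
            row.names = FALSE)
  write.csv(study$subjects, file.path(dir, "subjects.csv"),
            row.names = FALSE)
  write.csv(study$sessions, file.path(dir, "sessions.csv"),
            row.names = FALSE)
  manifest <- list(seed = study$seed,
                   n_subjects = study$config$n_subjects,
                   generative = study$config$generative,
                   shared_trials = study$config$shared_trials,
                   endowment = study$config$endowment,
                   n_paid = study$config$n_paid)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  structure(list(subjects = read.csv(file.path(dir, "subjects.csv"),
                                     stringsAsFactors = FALSE),
                 choices = read.csv(file.path(dir, "choices.csv"),
                                    stringsAsFactors = FALSE),
                 cortisol = read.csv(file.path(dir, "cortisol.csv"),
                                     stringsAsFactors = FALSE),
                 sessions = read.csv(file.path(dir, "sessions.csv"),
                                     stringsAsFactors = FALSE),
                 manifest = man, seed = man$seed),
            class = "sr_study")
}
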