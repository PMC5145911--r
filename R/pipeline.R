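#' Empirical probability of gambling
#'
#' Simple fraction of responded trials on which the gamble was chosen — the
#' coarse behavioral measure that conflates risk attitude, loss aversion and
#' consistency, reported alongside the model-based analysis.
#'
#' @param choices data frame with a `chose_gamble` column (NA = no
#'   response).
#' @return proportion in `[0, 1]`.
#' @export
p_gamble_empirical <- function(choices) {
  y <- choices$chose_gamble
  y <- y[!is.na(y)]
  if (length(y) == 0) stop("no responded trials", call. = FALSE)
  mean(y == 1)
}

#' Apply the payment rule to one session
#'
#' `n_paid` distinct trials are drawn uniformly at random and their realized
#' outcomes summed with the endowment, producing the session's adjusted
#' endowment. Reproducible given `seed`.
#'
#' @param choices session choice data frame with `realized_outcome`.
#' @param endowment starting endowment in dollars.
#' @param n_paid number of randomly selected paid trials.
#' @param seed integer seed.
#' @return adjusted endowment in dollars.
#' @export
#' @examples
#' tr <- generate_trial_set(seed = 1)
#' ch <- simulate_choices(tr, value_params(0.92, 2.22, 25.9), seed = 2)
#' compute_payment(ch, seed = 3)
compute_payment <- function(choices, endowment = 30, n_paid = 15L, seed) {
  if (nrow(choices) < n_paid)
    stop("fewer than ", n_paid, " trials with realized outcomes",
         call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(nrow(choices), n_paid)
    endowment + sum(choices$realized_outcome[idx])
  })
}

#' Correlate Day-1 payment changes with subject-level effect estimates
#'
#' Pairs each subject's change in endowment at the end of Day 1 (adjusted
#' endowment minus the starting endowment) with their posterior-mean day
#' effects on rho, lambda and mu, and reports linear (Pearson) and rank
#' (Spearman) correlations with p-values via [stats::cor.test()]. Pairing is
#' enforced by subject id.
#'
#' @param payment_change named numeric vector (names = subject ids) of Day-1
#'   endowment changes.
#' @param effect_means matrix from [subject_effect_means()] (rownames =
#'   subject ids, columns rho/lam/mu).
#' @return data frame with one row per parameter: `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`, `n`. Zero-variance inputs yield `NA`.
#' @export
effect_correlations <- function(payment_change, effect_means) {
  ids <- intersect(names(payment_change), rownames(effect_means))
  if (length(ids) != length(payment_change) ||
      length(ids) != nrow(effect_means))
    stop("payment_change and effect_means must cover the same subjects",
         call. = FALSE)
  if (length(ids) < 3) stop("need >= 3 paired subjects", call. = FALSE)
  x <- payment_change[ids]
  out <- lapply(colnames(effect_means), function(k) {
    yy <- effect_means[ids, k]
    if (sd(x) == 0 || sd(yy) == 0)
      return(data.frame(param = k, pearson_r = NA_real_,
                        pearson_p = NA_real_, spearman_rho = NA_real_,
                        spearman_p = NA_real_, n = length(ids)))
    pe <- cor.test(x, yy, method = "pearson")
    sp <- suppressWarnings(cor.test(x, yy, method = "spearman"))
    data.frame(param = k, pearson_r = unname(pe$estimate),
               pearson_p = pe$p.value,
               spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
               n = length(ids))
  })
  do.call(rbind, out)
}

#' Per-session behavioral summaries
#'
#' @param study an `sr_study`.
#' @return data frame with `subject_id`, `day`, `condition`,
#'   `p_gamble_empirical`, `n_responded`, and (when available)
#'   `adjusted_endowment`.
#' @export
session_summaries <- function(study) {
  ch <- study$choices
  key <- interaction(ch$subject_id, ch$day, drop = TRUE)
  rows <- lapply(split(ch, key), function(d)
    data.frame(subject_id = d$subject_id[1], day = d$day[1],
               condition = d$condition[1],
               p_gamble_empirical = p_gamble_empirical(d),
               n_responded = sum(!is.na(d$chose_gamble)),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(study$sessions)) {
    idx <- match(paste(out$subject_id, out$day),
                 paste(study$sessions$subject_id, study$sessions$day))
    out$adjusted_endowment <- study$sessions$adjusted_endowment[idx]
  }
  out[order(out$subject_id, out$day), ]
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a study, preprocesses cortisol (change scores,
#' modified-log transform, outlier exclusion), fits the condition and
#' covariate hierarchical models, optionally refits both on male subjects
#' only, summarizes empirical gambling, and correlates Day-1 payment changes
#' with the subject-level day effects. All stages are driven by one master
#' seed.
#'
#' @param config an [study_config()] (used when `study` is `NULL`).
#' @param seed master integer seed.
#' @param study optionally, an existing `sr_study` to analyze instead of
#'   simulating one.
#' @param mcmc an [mcmc_config()] used for every fit.
#' @param variants model variants to fit.
#' @param male_only also refit each variant on male subjects.
#' @param out_dir if non-NULL, write the report bundle (JSON + text tables)
#'   there.
#' @return list of class `sr_report` with elements `study_summary`,
#'   `cortisol`, `exclusions`, `fits`, `reports`, `gambling`,
#'   `correlations`, `seed`.
#' @export
run_full_analysis <- function(config = study_config(), seed, study = NULL,
                              mcmc = mcmc_config_desk(),
                              variants = c("condition", "covariate"),
                              male_only = TRUE, out_dir = NULL) {
  if (is.null(study)) study <- simulate_study(config, seed)
  ## cortisol preprocessing + exclusions
  cort <- prepare_cortisol(study$cortisol)
  excl <- exclude_cortisol_outliers(study$cortisol)
  study_cov <- study
  if (length(excl$excluded_ids)) {
    keep <- excl$kept_ids
    study_cov$subjects <- study$subjects[
      study$subjects$subject_id %in% keep, ]
    study_cov$choices <- study$choices[
      study$choices$subject_id %in% keep, ]
    study_cov$sessions <- study$sessions[
      study$sessions$subject_id %in% keep, ]
    study_cov$cortisol <- study$cortisol[
      study$cortisol$subject_id %in% keep, ]
  }
  fits <- list(); reports <- list()
  for (v in variants) {
    st <- if (v == "covariate") study_cov else study
    fits[[v]] <- fit_hierarchical(st, variant = v, mcmc = mcmc,
                                  seed = substream_seed(seed,
                                                        paste0("fit/", v)))
    reports[[v]] <- fit_report(fits[[v]])
    if (isTRUE(male_only)) {
      nm <- paste0(v, "_male")
      fits[[nm]] <- subset_fit(st, gender = "male", variant = v,
                               mcmc = mcmc,
                               seed = substream_seed(seed,
                                                     paste0("fit/", nm)))
      reports[[nm]] <- fit_report(fits[[nm]])
    }
  }
  gambling <- session_summaries(study)
  ## payment-change correlations against the condition fit's day effects
  correlations <- NULL
  if ("condition" %in% names(fits) && !is.null(study$sessions)) {
    d1 <- study$sessions[study$sessions$day == 0, ]
    pay <- setNames(d1$adjusted_endowment - study$config$endowment,
                    d1$subject_id)
    em <- subject_effect_means(fits$condition, "day")
    correlations <- effect_correlations(pay[rownames(em)], em)
  }
  out <- structure(list(study_summary = list(
    n_subjects = nrow(study$subjects),
    groups = as.list(table(study$subjects$group)),
    n_choices = nrow(study$choices)),
    cortisol = cort, exclusions = excl$excluded_ids, fits = fits,
    reports = reports, gambling = gambling, correlations = correlations,
    seed = seed), class = "sr_report")
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' Write a report bundle to disk
#'
#' JSON summary plus plain-text tables mirroring the fit reports.
#'
#' @param report an `sr_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(seed = report$seed, study = report$study_summary,
             exclusions = report$exclusions)
  for (nm in names(report$reports)) {
    r <- report$reports[[nm]]
    js[[paste0("model_", nm)]] <- list(
      recovered = lapply(r$recovered, function(p)
        list(rho = p$rho, lam = p$lam, mu = p$mu)),
      effect_CIs = lapply(r$effect_CIs, function(ci)
        apply(ci, 1, as.list)),
      excluded_zero = r$excluded_zero,
      rhat_group_mean = r$rhat_group_mean)
  }
  if (!is.null(report$correlations))
    js$payment_correlations <- report$correlations
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w"); on.exit(close(con))
  sink(con)
  for (nm in names(report$reports)) {
    cat("\n### model:", nm, "\n")
    print(report$reports[[nm]])
  }
  if (!is.null(report$correlations)) {
    cat("\n### Day-1 payment-change correlations with day effects\n")
    print(report$correlations)
  }
  sink()
  write.csv(report$gambling, file.path(dir, "gambling.csv"),
            row.names = FALSE)
  invisible(dir)
}
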