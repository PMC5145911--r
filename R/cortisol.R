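#' Raw cortisol change score
#'
#' Change in concentration between the baseline (sample 1) and pre-task
#' (sample 3) timepoints. Vectorized.
#'
#' @param c1,c3 concentrations at timepoints 1 and 3.
#' @return `c3 - c1`.
#' @export
delta_cortisol_raw <- function(c1, c3) {
  if (any(is.na(c1)) || any(is.na(c3)))
    stop("missing cortisol timepoint (need both samples 1 and 3)",
         call. = FALSE)
  c3 - c1
}

#' Modified-log transform of the cortisol change score
#'
#' \eqn{\Delta\mathrm{Cortisol} = \log(\Delta_{raw} + 0.5) - \log(0.5)}.
#' Strictly increasing, reduces the positive skew of raw change scores while
#' mapping 0 to 0 (zero change keeps its meaning). The 0.5 offset is applied
#' in the panel's native concentration units, so the transform is not
#' unit-invariant.
#'
#' @param delta_raw raw change score(s); must exceed -0.5.
#' @return transformed value(s).
#' @export
#' @examples
#' delta_cortisol_log(0.16)           # ~0.278
#' delta_cortisol_inv(delta_cortisol_log(0.16))
delta_cortisol_log <- function(delta_raw) {
  bad <- delta_raw <= -0.5
  if (any(bad))
    stop("delta_raw must be > -0.5 for the modified-log transform; got ",
         paste(signif(delta_raw[bad], 4), collapse = ", "), call. = FALSE)
  log(delta_raw + 0.5) - log(0.5)
}

#' @rdname delta_cortisol_log
#' @param value transformed value(s) to invert.
#' @export
delta_cortisol_inv <- function(value) {
  exp(value) * 0.5 - 0.5
}

#' Derive change scores for every subject-day
#'
#' Reshapes a long cortisol table (subject_id, day, timepoint, concentration)
#' into one row per subject-day with `delta_raw` and `delta_cortisol`.
#' Subject-days missing sample 1 or 3 are dropped with a warning.
#'
#' @param cortisol long-format cortisol data frame.
#' @param standardize z-score `delta_cortisol` across subject-days (off by
#'   default; the covariate enters the model in raw modified-log units).
#' @return data frame `subject_id`, `day`, `c1`..`c4`, `delta_raw`,
#'   `delta_cortisol`.
#' @export
prepare_cortisol <- function(cortisol, standardize = FALSE) {
  key <- interaction(cortisol$subject_id, cortisol$day, drop = TRUE)
  rows <- lapply(split(cortisol, key), function(d) {
    cc <- setNames(rep(NA_real_, 4), paste0("c", 1:4))
    cc[paste0("c", d$timepoint)] <- d$concentration
    data.frame(subject_id = d$subject_id[1], day = d$day[1], t(cc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- !is.na(out$c1) & !is.na(out$c3)
  if (any(!ok)) {
    warning(sum(!ok), " subject-day(s) lack sample 1 or 3; dropped from ",
            "covariate analyses")
    out <- out[ok, ]
  }
  out$delta_raw <- delta_cortisol_raw(out$c1, out$c3)
  out$delta_cortisol <- delta_cortisol_log(out$delta_raw)
  if (isTRUE(standardize))
    out$delta_cortisol <- as.numeric(scale(out$delta_cortisol))
  out[order(out$subject_id, out$day), ]
}

#' Exclude subjects with extreme overall cortisol levels
#'
#' Computes each subject's mean concentration across all of their samples,
#' then flags subjects whose mean exceeds the rest of the group's mean by
#' more than `threshold_sd` standard deviations, where mean and SD are
#' computed leave-one-out (excluding the candidate). With an inclusive SD a
#' z-score of 30 would be unattainable — a single extreme subject among n
#' peers can reach at most about \eqn{\sqrt{n}} inclusive SDs — so the
#' leave-one-out form is the reading under which the rule can operate at
#' all. One-sided (high side only), single pass, deterministic. Zero
#' leave-one-out SD with a zero mean difference excludes nobody.
#'
#' @param cortisol long-format cortisol data frame.
#' @param threshold_sd exclusion threshold in SD units (default 30).
#' @return list with `kept_ids`, `excluded_ids`, and the `subject_means`
#'   table used for the rule.
#' @export
exclude_cortisol_outliers <- function(cortisol, threshold_sd = 30) {
  means <- tapply(cortisol$concentration, cortisol$subject_id, mean)
  if (length(means) < 2L)
    stop("need at least 2 subjects for outlier exclusion", call. = FALSE)
  excluded <- character()
  if (is.finite(threshold_sd)) {
    flag <- vapply(seq_along(means), function(i) {
      rest <- means[-i]
      s <- sd(rest)
      s > 0 && means[i] > mean(rest) + threshold_sd * s
    }, logical(1))
    excluded <- names(means)[flag]
  }
  list(kept_ids = setdiff(names(means), excluded),
       excluded_ids = excluded,
       subject_means = data.frame(subject_id = names(means),
                                  mean_concentration = as.numeric(means),
                                  stringsAsFactors = FALSE))
}
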