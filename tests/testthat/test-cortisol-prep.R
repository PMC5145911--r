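test_that("raw change scores subtract baseline from pre-task", {
  expect_equal(delta_cortisol_raw(0.1, 0.1), 0)
  expect_equal(delta_cortisol_raw(0.10, 0.26), 0.16)
  expect_equal(delta_cortisol_raw(0.20, 0.15), -0.05)
  expect_error(delta_cortisol_raw(NA, 0.2), "missing")
})

test_that("modified-log transform maps zero to zero and round-trips", {
  expect_equal(delta_cortisol_log(0), 0)
  expect_equal(delta_cortisol_log(0.5), log(2), tolerance = 1e-12)
  expect_equal(delta_cortisol_log(0.16), 0.27763174, tolerance = 1e-7)
  expect_error(delta_cortisol_log(-0.6), "-0.5")
  # monotone increasing
  x <- seq(-0.45, 2, by = 0.01)
  expect_true(all(diff(delta_cortisol_log(x)) > 0))
  # inverse round-trips to 1e-12
  expect_equal(delta_cortisol_inv(delta_cortisol_log(x)), x,
               tolerance = 1e-12)
})

test_that("subject-day table derives change scores and drops missing panels", {
  st <- tiny_study(n = 5L, seed = 12)
  tab <- prepare_cortisol(st$cortisol)
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$delta_raw, tab$c3 - tab$c1, tolerance = 1e-12)
  expect_equal(tab$delta_cortisol, log(tab$delta_raw + 0.5) - log(0.5),
               tolerance = 1e-12)
  # a panel missing sample 3 is dropped with a warning
  broken <- st$cortisol[!(st$cortisol$subject_id == "s001" &
                            st$cortisol$day == 0 &
                            st$cortisol$timepoint == 3), ]
  expect_warning(tab2 <- prepare_cortisol(broken), "dropped")
  expect_equal(nrow(tab2), 9L)
  # optional z-scoring
  tabz <- prepare_cortisol(st$cortisol, standardize = TRUE)
  expect_equal(mean(tabz$delta_cortisol), 0, tolerance = 1e-12)
  expect_equal(sd(tabz$delta_cortisol), 1, tolerance = 1e-12)
})

test_that("outlier exclusion removes only extreme subject means, one-sided", {
  # constructed fixture: 119 ordinary subjects, one at a huge mean
  make_long <- function(means) {
    do.call(rbind, lapply(seq_along(means), function(i)
      data.frame(subject_id = sprintf("s%03d", i), day = 0, timepoint = 1:4,
                 concentration = means[i] + c(-0.001, 0, 0.001, 0))))
  }
  means <- c(with_seed(4, rnorm(119, 0.1, 0.01)), 100)
  long <- make_long(means)
  res <- exclude_cortisol_outliers(long, threshold_sd = 30)
  expect_equal(res$excluded_ids, "s120")
  expect_equal(length(res$kept_ids), 119L)
  # single pass: re-running on the kept set removes no one
  kept <- long[long$subject_id %in% res$kept_ids, ]
  expect_equal(exclude_cortisol_outliers(kept, 30)$excluded_ids, character())
  # low-side outliers are never excluded
  means_lo <- c(with_seed(5, rnorm(119, 0.1, 0.01)), -100)
  expect_equal(exclude_cortisol_outliers(make_long(means_lo),
                                         30)$excluded_ids, character())
  # vacuous threshold and identical subjects
  expect_equal(exclude_cortisol_outliers(long, Inf)$excluded_ids,
               character())
  same <- make_long(rep(0.1, 10))
  expect_equal(exclude_cortisol_outliers(same, 30)$excluded_ids, character())
  expect_error(exclude_cortisol_outliers(make_long(0.1)), "at least 2")
})
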