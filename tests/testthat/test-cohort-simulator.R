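test_that("population draws recover the generating hyperparameters", {
  hy <- group_hyper()
  # degenerate mode pins every subject at the population mean
  hy0 <- group_hyper(theta_V = c(0, 0, 0), deltaS_V = c(0, 0, 0),
                     deltaD_V = c(0, 0, 0), degenerate_ok = TRUE)
  pop0 <- draw_population(hy0, 5, seed = 1)
  expect_true(all(abs(pop0$theta_rho - log(0.92)) < 1e-12))
  expect_true(all(pop0$dS_lam == 0))
  # CLT check on the loss-aversion baseline at the task-typical SD
  pop <- draw_population(hy, 5000, seed = 2)
  expect_lt(abs(mean(pop$theta_lam) - log(2.22)), 3 * 0.84 / sqrt(5000))
  # generator defaults sit at the task-typical parameter values
  expect_equal(exp(hy$theta_M), c(0.92, 2.22, 25.9), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(group_hyper(theta_V = c(0, 1, 1)), "SDs must be > 0")
})

test_that("design assignment balances groups and matches the gender mix", {
  des <- assign_design(120, seed = 1)
  expect_equal(unname(table(des$group)[c("SS", "SC", "CS", "CC")]),
               rep(30L, 4), ignore_attr = TRUE)
  expect_equal(sum(des$gender == "male"), 56L)
  expect_equal(sum(des$gender == "female"), 64L)
  des8 <- assign_design(8, seed = 2)
  expect_true(all(table(des8$group) == 2L))
  expect_warning(assign_design(30, seed = 3), "most even split")
})

test_that("cortisol panels reproduce the configured group-by-day changes", {
  cfg0 <- cortisol_config(noise_sd = 0)
  # deterministic change scores at zero noise
  p_cs2 <- simulate_cortisol("CS", 1, cfg0, seed = 1)
  expect_equal(p_cs2[3] - p_cs2[1], 0.16, tolerance = 1e-12)
  p_cc1 <- simulate_cortisol("CC", 0, cfg0, seed = 2)
  expect_equal(p_cc1[3] - p_cc1[1], -0.05, tolerance = 1e-12)
  # noisy panels recover the configured mean within Monte-Carlo error
  cfg <- cortisol_config()
  d3 <- vapply(1:2000, function(s)
    diff(simulate_cortisol("SS", 0, cfg, seed = s)[c(1, 3)]), numeric(1))
  expect_lt(abs(mean(d3) - 0.17), 3 * sd(d3) / sqrt(2000))
})

test_that("a simulated study has exactly the configured dimensions", {
  st <- tiny_study(n = 8L)
  expect_equal(nrow(st$subjects), 8L)
  expect_equal(nrow(st$choices), 8L * 2L * 150L)
  expect_equal(nrow(st$cortisol), 8L * 2L * 4L)
  expect_equal(nrow(st$sessions), 16L)
  # two sessions per subject, day 0 then 1; condition follows the group code
  for (i in seq_len(8)) {
    ses <- st$sessions[st$sessions$subject_id == st$subjects$subject_id[i], ]
    expect_equal(ses$day, c(0, 1))
    code <- strsplit(st$subjects$group[i], "")[[1]]
    expect_equal(ses$condition, as.integer(code == "S"))
  }
  # reproducibility under the master seed
  st2 <- tiny_study(n = 8L)
  expect_identical(st$choices, st2$choices)
  # trial sets differ across subject-days by default
  t1 <- st$choices[st$choices$subject_id == "s001" & st$choices$day == 0,
                   "gamble_gain"]
  t2 <- st$choices[st$choices$subject_id == "s002" & st$choices$day == 0,
                   "gamble_gain"]
  expect_false(identical(t1, t2))
  # shared_trials reuses one set everywhere
  cfgs <- study_config(n_subjects = 4L, shared_trials = TRUE)
  sts <- simulate_study(cfgs, seed = 11)
  sets <- split(sts$choices$gamble_gain,
                paste(sts$choices$subject_id, sts$choices$day))
  sets <- lapply(sets, sort)
  expect_true(all(vapply(sets, identical, logical(1), sets[[1]])))
})

test_that("zero-covariate generation equals zero-stress condition generation", {
  # flat cortisol (all change scores 0) makes the covariate modulator 0 on
  # every session; with stress effects degenerate at 0 the two generative
  # modes must produce identical choices under the same master seed
  flat <- cortisol_config(delta3_mean = matrix(0, 4, 2,
                                               dimnames = list(
                                                 c("SS", "SC", "CS", "CC"),
                                                 NULL)),
                          noise_sd = 0, baseline_sd = 0)
  hy <- group_hyper(deltaS_M = c(0, 0, 0), deltaS_V = c(0, 0, 0),
                    degenerate_ok = TRUE)
  cfg_cond <- study_config(n_subjects = 4L, hyper = hy, cortisol = flat,
                           generative = "condition")
  cfg_cov <- study_config(n_subjects = 4L, hyper = hy, cortisol = flat,
                          generative = "covariate")
  st_cond <- simulate_study(cfg_cond, seed = 31)
  st_cov <- simulate_study(cfg_cov, seed = 31)
  expect_identical(st_cond$choices, st_cov$choices)
  expect_true(all(st_cov$sessions$delta_cortisol == 0))
})

test_that("study bundles round-trip through disk", {
  st <- tiny_study(n = 4L, seed = 77)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(dir, c("choices.csv", "cortisol.csv",
                                               "subjects.csv", "sessions.csv",
                                               "manifest.json")))))
  back <- read_study(dir)
  expect_equal(back$choices$chose_gamble, st$choices$chose_gamble)
  expect_equal(back$sessions$delta_cortisol, st$sessions$delta_cortisol,
               tolerance = 1e-12)
  expect_equal(back$seed, 77)
})
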