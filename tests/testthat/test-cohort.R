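test_that("cohort generator reproduces the study structure", {
  tb <- make_cohort(seed = 1)
  expect_s3_class(tb, "cohort_table")
  expect_identical(length(unique(tb$subject_id)), 34L)
  expect_identical(length(unique(tb$exam_id)), 40L)
  per <- table(tb$parameter) / (8)                  # 8 tissues
  expect_true(all(per == 40))                       # 40 exam rows per parameter
  expect_true(all(tb$pna_weeks >= 0))
  expect_true(all(tb$pma_weeks >= 33.5 & tb$pma_weeks <= 53))
  expect_true(all(tb$ga_weeks >= 27.8 & tb$ga_weeks <= 42.2))
  expect_equal(tb$pna_weeks, tb$pma_weeks - tb$ga_weeks)
  # repeat exams share subject ids
  ex <- unique(tb[c("subject_id", "exam_id")])
  expect_identical(nrow(ex), 40L)
  expect_identical(sum(duplicated(ex$subject_id)), 6L)
  # determinism
  expect_identical(make_cohort(seed = 1), tb)
  expect_false(identical(make_cohort(seed = 2)$value_ms, tb$value_ms))
})

test_that("exclusion flags emulate the study's data losses", {
  tb <- make_cohort(seed = 3, n_afi_missing = 8, n_t2_motion_excluded = 1,
                    n_pathology = 3)
  t2 <- tb[tb$parameter == "T2" & tb$tissue == "white_matter", ]
  expect_identical(sum(is.na(t2$value_ms)), 8L)
  expect_true(all(t2$excluded[is.na(t2$value_ms)]))
  expect_identical(sum(t2$exclude_reason == "motion"), 1L)
  path_subj <- attr(tb, "truth")$pathology_subjects
  expect_length(path_subj, 3)
  expect_true(all(tb$excluded[tb$subject_id %in% path_subj]))
  # toggling exclusions changes the fit and the bookkeeping
  f_excl <- fit_age_model(tb, "white_matter", "T1")
  tb2 <- tb; tb2$excluded <- FALSE
  f_all <- fit_age_model(tb2, "white_matter", "T1")
  expect_gt(f_all$n_obs, f_excl$n_obs)
  expect_false(isTRUE(all.equal(f_all$t40wk_ms, f_excl$t40wk_ms)))
})

test_that("noiseless cohorts are recovered exactly (degenerate fit)", {
  gm0 <- generating_model(between_subject_sd_ms = c(T1 = 0, T2 = 0),
                          residual_sd_ms = c(T1 = 0, T2 = 0))
  tb <- make_cohort(n_subjects = 12, n_exams = 12, gm = gm0, seed = 2,
                    tissues = "cerebellum", parameters = "T1")
  f <- fit_age_model(tb, "cerebellum", "T1")
  expect_equal(f$t40wk_ms, 2653, tolerance = 1e-8)
  expect_equal(f$delta_ms_per_week, -43, tolerance = 1e-8)
  expect_true(f$singular)
  expect_equal(f$random_intercept_sd, 0)
})

test_that("shifting the age origin moves only the intercept", {
  gm0 <- generating_model(between_subject_sd_ms = c(T1 = 0, T2 = 0),
                          residual_sd_ms = c(T1 = 0, T2 = 0))
  tb <- make_cohort(n_subjects = 12, n_exams = 12, gm = gm0, seed = 4,
                    tissues = "white_matter", parameters = "T1")
  f <- fit_age_model(tb, "white_matter", "T1")
  tb2 <- tb
  tb2$pma_weeks <- tb2$pma_weeks + 5     # regression origin moves to 35 wk
  f2 <- fit_age_model(tb2, "white_matter", "T1")
  expect_equal(f2$delta_ms_per_week, f$delta_ms_per_week, tolerance = 1e-8)
  expect_equal(f2$t40wk_ms, f$t40wk_ms - 5 * f$delta_ms_per_week,
               tolerance = 1e-6)
})

test_that("zero random-intercept variance reduces the fit to OLS", {
  # with no subject effect in the generator, REML shrinks the
  # random-intercept variance to the boundary in most replicates; on those
  # the mixed slope equals the OLS slope exactly
  gm0 <- generating_model(between_subject_sd_ms = c(T1 = 1e-9, T2 = 1e-9),
                          residual_sd_ms = c(T1 = 100, T2 = 4))
  checked <- 0L
  for (s in 1:12) {
    tb <- make_cohort(gm = gm0, seed = s, tissues = "thalamus",
                      parameters = "T1")
    f <- fit_age_model(tb, "thalamus", "T1")
    if (!f$singular) next
    d <- tb[!tb$excluded, ]
    d$pma_c <- d$pma_weeks - 40
    ols <- stats::lm(value_ms ~ pma_c, data = d)
    expect_equal(f$delta_ms_per_week, unname(stats::coef(ols)["pma_c"]),
                 tolerance = 1e-6)
    checked <- checked + 1L
  }
  expect_gte(checked, 3L)
})

test_that("variance components are recovered in balanced repeat designs", {
  gm <- generating_model()     # between 50, residual 100 for T1
  res <- with_seed(31, sapply(1:200, function(i) {
    tb <- make_cohort(n_subjects = 34, n_exams = 68, gm = gm,
                      seed = sample.int(1e6, 1), tissues = "white_matter",
                      parameters = "T1")
    f <- fit_age_model(tb, "white_matter", "T1", ci = "wald-normal")
    c(f$random_intercept_sd, f$residual_sd)
  }))
  expect_lt(abs(stats::median(res[1, ]) - 50) / 50, 0.2)
  expect_lt(abs(stats::median(res[2, ]) - 100) / 100, 0.2)
})

test_that("results table covers every tissue and parameter", {
  tb <- make_cohort(seed = 6)
  res <- make_results_table(tb)
  expect_identical(nrow(res), 16L)
  expect_true(all(res$n_obs == 40))
  expect_true(all(is.finite(res$t40wk_ms)))
  expect_true(all(res$t40wk_lo <= res$t40wk_ms & res$t40wk_ms <= res$t40wk_hi))
  md <- render_results_markdown(res)
  expect_length(md, 18)
  # a tissue below the subject threshold yields a missing row
  res2 <- make_results_table(tb[tb$tissue != "pvfwm" |
                                  tb$subject_id <= 3, ])
  expect_true(is.na(res2$t40wk_ms[res2$tissue == "pvfwm" &
                                    res2$parameter == "T1"]))
})

test_that("null-slope p-values are uniform (type-I calibration)", {
  gm <- generating_model(tissue_lines = {
    tl <- reference_tissue_lines()
    tl$d1_ms_per_week <- 0            # brainstem-like: no age dependence
    tl
  })
  p <- with_seed(77, sapply(1:400, function(i) {
    tb <- make_cohort(gm = gm, seed = sample.int(1e6, 1),
                      tissues = "brainstem", parameters = "T1")
    fit_age_model(tb, "brainstem", "T1")$p_value_pma
  }))
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(p > 0.05), 0.9)      # close to the nominal 95%
})
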