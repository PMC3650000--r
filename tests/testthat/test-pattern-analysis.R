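test_that("the pipeline is deterministic and audits every finding", {
  co <- generate_cohort(simulation_config(seed = 14))
  cfg <- analysis_config()
  a <- run_pattern_analysis(co, cfg)
  b <- run_pattern_analysis(co, cfg)
  expect_equal(tidy(a), tidy(b))
  expect_equal(pattern_audit(a), pattern_audit(b))
  # every finding corresponds to a rejected audit row
  f <- tidy(a)
  aud <- pattern_audit(a)
  for (i in seq_len(nrow(f))) {
    hit <- aud$stratum == f$stratum[i] & aud$taxon == f$taxon[i] &
      aud$pattern == f$pattern[i]
    expect_true(any(hit & aud$rejected))
  }
  # screened-out findings stay in the full table but carry the flag
  expect_true(all(c("screened_out", "welch_tier") %in% names(f)))
})

test_that("an empty or degenerate cohort yields empty findings, no error", {
  empty <- cohort_table(tibble::tibble(
    subject_id = character(), stratum = character(), outcome = double(),
    t1_d4 = double(), t1_d10 = double()
  ))
  res <- suppressWarnings(run_pattern_analysis(empty))
  expect_equal(nrow(tidy(res)), 0)
  expect_equal(nrow(pattern_audit(res)), 0)
})

test_that("posthoc screening discards patterns with unconvincing contrasts", {
  # contrast group mean exactly zero -> contrast test cannot be significant
  co <- symmetric_cohort()
  out <- posthoc_screen(co, "tax1", "++", analysis_config())
  expect_true(out$screened_out)
  expect_equal(out$screen_reason, "contrast_not_significant")

  # strong contrast at -1.0: screening keeps the pattern, Welch agrees with
  # the hand-coded oracle
  set.seed(6)
  y_pat <- rnorm(30, 0, 0.5)
  y_con <- rnorm(30, -1, 0.5)
  co2 <- cohort_table(tibble::tibble(
    subject_id = paste0("s", 1:60), stratum = "A",
    outcome = c(y_pat, y_con),
    t1_d4 = rep(c(1, 0), each = 30), t1_d10 = rep(c(1, 0), each = 30)
  ))
  out2 <- posthoc_screen(co2, "t1", "+X", analysis_config())
  expect_false(out2$screened_out)
  expect_lte(out2$contrast_p, 0.05)
  expect_equal(out2$welch_p, welch_oracle(y_pat, y_con), tolerance = 1e-10)
  expect_equal(out2$welch_tier, "strict")

  # a contrast group of one subject is inconclusive -> screened out
  co3 <- cohort_table(tibble::tibble(
    subject_id = paste0("s", 1:5), stratum = "A",
    outcome = c(0.1, 0.2, -0.1, 0.05, 2),
    t1_d4 = c(1, 1, 1, 1, 0), t1_d10 = c(1, 1, 1, 1, 1)
  ))
  out3 <- posthoc_screen(co3, "t1", "+X", analysis_config())
  expect_true(out3$screened_out)
  expect_equal(out3$screen_reason, "contrast_inconclusive")
})

test_that("reported findings carry coherent group statistics", {
  co <- generate_cohort(simulation_config(seed = 23))
  res <- run_pattern_analysis(co)
  f <- tidy(res)
  skip_if(nrow(f) == 0)
  # group means/ses match an independent match_subjects pass on the stratum
  parts <- split_strata(co)
  for (i in seq_len(min(nrow(f), 10))) {
    g <- match_subjects(parts[[f$stratum[i]]], f$taxon[i], f$final_pattern[i])
    expect_equal(f$n[i], g$n)
    expect_equal(f$mean[i], g$mean)
    expect_equal(f$se[i], g$se)
    cg <- match_subjects(parts[[f$stratum[i]]], f$taxon[i],
                         crude_contrast(f$final_pattern[i]))
    expect_equal(f$contrast_n[i], cg$n)
    expect_equal(f$contrast_mean[i], cg$mean)
  }
  # the trail always starts at the entry pattern and ends at the final one
  for (i in seq_len(nrow(f))) {
    tr <- f$trail[[i]]
    expect_equal(tr$pattern[1], f$pattern[i])
    expect_equal(tr$pattern[nrow(tr)], f$final_pattern[i])
  }
})

test_that("autoplot and print methods work on real results", {
  co <- generate_cohort(simulation_config(seed = 23))
  res <- run_pattern_analysis(co)
  expect_s3_class(autoplot(res), "ggplot")
  expect_output(print(res), "Detection-pattern analysis")
  ts <- run_time_specific(co)
  expect_s3_class(autoplot(ts), "ggplot")
  expect_output(print(ts), "Time-specific")
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_equal(g$delta, 0.67)
})
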