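test_that("the binary-regressor fit is the difference in group means", {
  y <- c(0.4, 0.6, 0.5, 0.1, 0.3, 0.2)
  d <- c(1, 1, 1, 0, 0, 0)
  eff <- fit_timepoint_effect(y, d)
  expect_equal(eff$beta, 0.5 - 0.2)
  expect_equal(eff$df, 4)
  expect_true(eff$estimable)
  # constant detection is inestimable, not an error
  flat <- fit_timepoint_effect(y, rep(1, 6))
  expect_false(flat$estimable)
  expect_true(is.na(flat$beta))
})

test_that("the fit matches lm, the pooled t test, and a normal-equations oracle", {
  set.seed(12)
  for (i in 1:20) {
    n <- 20
    d <- rbinom(n, 1, 0.5)
    if (length(unique(d)) < 2) next
    y <- rnorm(n, mean = 0.3 * d)
    eff <- fit_timepoint_effect(y, d)
    fit <- summary(lm(y ~ d))$coefficients
    expect_equal(eff$beta, fit["d", "Estimate"], tolerance = 1e-10)
    expect_equal(eff$se, fit["d", "Std. Error"], tolerance = 1e-10)
    expect_equal(eff$p_value, fit["d", "Pr(>|t|)"], tolerance = 1e-10)
    tt <- t.test(y[d == 1], y[d == 0], var.equal = TRUE)
    expect_equal(eff$p_value, tt$p.value, tolerance = 1e-12)
    # independent normal-equations oracle: beta = (X'X)^-1 X'y
    X <- cbind(1, d)
    coef <- solve(t(X) %*% X, t(X) %*% y)
    resid <- y - X %*% coef
    s2 <- sum(resid^2) / (n - 2)
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    expect_equal(eff$beta, as.vector(coef)[2], tolerance = 1e-10)
    expect_equal(eff$se, as.vector(se), tolerance = 1e-10)
  }
})

test_that("the vectorised core reproduces the single fits with missing data", {
  set.seed(77)
  n <- 40
  det <- matrix(rbinom(n * 6, 1, 0.5), n, 6)
  det[sample(length(det), 20)] <- NA
  y <- rnorm(n)
  y[c(3, 9)] <- NA
  core <- detpat:::timepoint_effects_core(det, y)
  for (j in 1:6) {
    single <- fit_timepoint_effect(y, det[, j])
    expect_equal(core$beta[j], single$beta)
    expect_equal(core$se[j], single$se)
    expect_equal(core$p_value[j], single$p_value)
    expect_equal(core$estimable[j], single$estimable)
  }
})

test_that("run_time_specific handles degenerate cohorts and nests decisions", {
  # constant detections everywhere: nothing estimable, but no error
  flat <- cohort_table(tibble::tibble(
    subject_id = paste0("s", 1:6), stratum = "A", outcome = rnorm(6),
    t1_d4 = 1, t1_d10 = 1
  ))
  res <- run_time_specific(flat)
  expect_s3_class(res, "timepoint_analysis")
  expect_false(any(tidy(res)$estimable))
  expect_equal(sum(tidy(res)$rejected), 0)

  # strict rejections are always a subset of relaxed rejections
  for (seed in 1:4) {
    plus <- grep("^[+]", enumerate_patterns(4), value = TRUE)
    cfg <- simulation_config(seed = seed, n_per_stratum = c(F = 60, M = 60),
                             n_taxa = 6,
                             effect_map = setNames(rep(0.35, 8), plus))
    res <- run_time_specific(generate_cohort(cfg))
    tab <- tidy(res)
    expect_true(all(!tab$rejected | tab$rejected_relaxed))
    expect_true(all(tab$tier[tab$rejected] == "strict"))
  }
})

test_that("a strong planted effect is detected with high power", {
  # day-4 detection of the driver taxon shifts the outcome by 1.0 Z-units
  plus <- grep("^[+]", enumerate_patterns(4), value = TRUE)
  cfg <- simulation_config(n_per_stratum = c(A = 108), seed = 88,
                           baseline = 0,
                           effect_map = setNames(rep(1.0, 8), plus),
                           n_replicates = 150)
  truth <- function(stratum, taxon, component) {
    if (taxon == "probe01") "+" else "null"
  }
  rep <- simulate_operating_characteristics(
    cfg, "time_specific", truth = truth,
    power_targets = tibble::tibble(taxon = "probe01", component = "4"))
  expect_gt(rep$power$power, 0.9)
  expect_equal(rep$n_replicates, 150)
})
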