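test_that("pattern enumeration is complete, distinct and well ordered", {
  p4 <- enumerate_patterns(4)
  expect_length(p4, 16)
  expect_length(unique(p4), 16)
  expect_equal(p4[1], "++++")
  expect_equal(p4[16], "----")
  expect_equal(enumerate_patterns(1), c("+", "-"))

  # brute-force oracle at T = 3: build all length-3 strings by nested loops
  oracle <- character()
  for (a in c("+", "-")) for (b in c("+", "-")) for (c in c("+", "-")) {
    oracle <- c(oracle, paste0(a, b, c))
  }
  expect_setequal(enumerate_patterns(3), oracle)
  expect_length(enumerate_patterns(3), 8)
  expect_error(enumerate_patterns(0), ">= 1")
})

test_that("pattern parsing enforces the contiguous-suffix invariant", {
  expect_equal(parse_pattern("++-X"), "++-X")
  expect_error(parse_pattern("XXXX"), "at least one")
  expect_error(parse_pattern("+X-X"), "suffix")
  expect_error(parse_pattern("+a--"), "may only contain")
})

test_that("match_subjects finds exactly the agreeing subjects", {
  co <- tiny_cohort()
  g <- match_subjects(co, "tax1", "+++-")
  expect_equal(g$subject_ids[[1]], c("s1"))
  expect_equal(g$n, 1L)
  g2 <- match_subjects(co, "tax1", "+XXX")
  expect_equal(g2$subject_ids[[1]], c("s1", "s2", "s3", "s4"))
  expect_equal(g2$mean, mean(c(0.1, -0.2, 0.3, 1.5)))
  # no matching subjects: flagged, not an error
  g3 <- match_subjects(co, "tax1", "-+++")
  expect_equal(g3$n, 0L)
  expect_true(is.na(g3$mean))
  expect_error(match_subjects(co, "tax1", "XXXX"), "at least one")
  expect_error(match_subjects(co, "nope", "+XXX"), "unknown taxon")
})

test_that("testable_patterns applies an inclusive frequency floor", {
  # 20 subjects: pattern '++' 12 times (60%), '--' 3 times (15%), '+-' 5 (25%)
  det <- rbind(
    matrix(rep(c(1, 1), 12), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 0), 3), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 0), 5), ncol = 2, byrow = TRUE)
  )
  co <- cohort_table(tibble::tibble(
    subject_id = paste0("s", 1:20), stratum = "A",
    outcome = rnorm(20),
    t1_d4 = det[, 1], t1_d10 = det[, 2]
  ))
  tp <- testable_patterns(co, "t1", min_freq = 0.15)
  expect_setequal(tp$pattern, c("++", "+-", "--")) # 15% boundary included
  tp2 <- testable_patterns(co, "t1", min_freq = 0.16)
  expect_setequal(tp2$pattern, c("++", "+-"))

  # all subjects sharing one pattern leaves exactly one testable pattern
  mono <- cohort_table(tibble::tibble(
    subject_id = paste0("s", 1:10), stratum = "A", outcome = rnorm(10),
    t1_d4 = 1, t1_d10 = 1
  ))
  expect_equal(testable_patterns(mono, "t1")$pattern, "++")
})

test_that("full patterns partition the complete-case subjects", {
  set.seed(42)
  co <- generate_cohort(simulation_config(seed = 42, missing_rate = 0.1,
                                          n_per_stratum = c(A = 80)))
  for (tx in c("probe01", "probe07")) {
    groups <- vapply(enumerate_patterns(4),
                     function(p) match_subjects(co, tx, p)$n, 0L)
    det <- as.data.frame(co)[, paste0(tx, "_d", timepoints(co))]
    n_complete <- sum(stats::complete.cases(det) & !is.na(co$outcome))
    expect_equal(sum(groups), n_complete)
  }
})

test_that("crude_contrast is a fixed-point-free involution", {
  expect_equal(crude_contrast("++XX"), "--XX")
  expect_equal(crude_contrast("+-+-"), "-+-+")
  pats <- c(enumerate_patterns(4), "++-X", "+XXX", "-+XX")
  for (p in pats) {
    expect_equal(crude_contrast(crude_contrast(p)), p)
    expect_false(crude_contrast(p) == p)
  }
})

test_that("reduce_right trims exactly one relevant position from the right", {
  expect_equal(reduce_right("++++"), "+++X")
  expect_equal(reduce_right("+-+X"), "+-XX")
  expect_error(reduce_right("+XXX"), "at least one relevant")
  # T - 1 reductions of any full pattern leave only position 1 relevant
  for (p in enumerate_patterns(4)) {
    q <- p
    for (i in 1:3) q <- reduce_right(q)
    expect_equal(substr(q, 2, 4), "XXX")
    expect_equal(substr(q, 1, 1), substr(p, 1, 1))
  }
})

test_that("reducing a pattern never shrinks its matched group", {
  co <- generate_cohort(simulation_config(seed = 9, n_per_stratum = c(A = 60)))
  for (p in c("++++", "+-+-", "---+", "-+--")) {
    ids <- match_subjects(co, "probe03", p)$subject_ids[[1]]
    q <- p
    while (n_relevant_chars(q) >= 2) {
      q <- reduce_right(q)
      ids_q <- match_subjects(co, "probe03", q)$subject_ids[[1]]
      expect_true(all(ids %in% ids_q))
      ids <- ids_q
    }
  }
})
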