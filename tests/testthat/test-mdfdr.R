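test_that("bonferroni pooling scales the family minimum and caps at one", {
  expect_equal(bonferroni_pool(c(0.01, 0.5, 0.2, 0.8)), 0.04)
  expect_equal(bonferroni_pool(c(1, 1, 1, 1)), 1)
  expect_equal(bonferroni_pool(0.3), 0.3)
  expect_equal(bonferroni_pool(c(0.4, 0.5, 0.6)), 1)
  expect_error(bonferroni_pool(numeric()), "non-empty")
  expect_error(bonferroni_pool(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("bh_select agrees with a brute-force step-up oracle", {
  sel <- bh_select(c(0.001, 0.02, 0.04, 0.9), 0.05)
  expect_equal(sel$R, 2L)
  expect_equal(sel$rejected, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_select(rep(1, 6), 0.05)$R, 0L)
  expect_equal(bh_select(rep(0, 6), 0.05)$R, 6L)

  set.seed(2024)
  for (i in 1:1000) {
    n <- sample(1:10, 1)
    p <- round(runif(n), sample(c(1, 2, 3, 6), 1))
    alpha <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    got <- bh_select(p, alpha)
    want <- bh_oracle(p, alpha)
    expect_equal(got$R, want$R)
    expect_equal(sum(got$rejected), want$R)
    expect_true(all(p[got$rejected] <= sort(p)[max(want$R, 1)]))
    # and agreement with the standard adjusted-p route
    expect_equal(got$rejected, p.adjust(p, "BH") <= alpha)
  }
})

test_that("mdfdr_decide matches a straight-line oracle and keeps structure", {
  one <- tibble::tibble(family = "f", component = "c", p_value = 0.01)
  d1 <- mdfdr_decide(one, alpha = 0.05)
  expect_equal(d1$R, 1L)
  expect_true(d1$components$rejected)
  expect_equal(d1$components$alpha_star, 0.05)

  all1 <- tibble::tibble(family = rep(c("a", "b"), each = 3),
                         component = rep(1:3, 2), p_value = 1)
  d2 <- mdfdr_decide(all1, alpha = 0.05)
  expect_equal(d2$R, 0L)
  expect_false(any(d2$components$rejected))
  expect_true(all(d2$components$alpha_star == 0))

  set.seed(31)
  for (i in 1:200) {
    nfam <- sample(1:6, 1)
    pv <- purrr::map(seq_len(nfam), function(f) {
      m <- sample(1:5, 1)
      tibble::tibble(family = paste0("f", f), component = seq_len(m),
                     p_value = round(runif(m)^sample(1:3, 1), 4))
    }) |> purrr::list_rbind()
    alpha <- sample(c(0.05, 0.1, 0.2), 1)
    got <- mdfdr_decide(pv, alpha)
    want <- mdfdr_oracle(pv, alpha)
    expect_equal(got$R, want$R)
    expect_equal(got$components$rejected, want$component_rejected)
    # no orphan components
    expect_true(all(!got$components$rejected | got$components$family_rejected))
  }
})

test_that("sequential reduction follows the halving cascade hand-traces", {
  # p = 0.004 at every stage, alpha* = 0.01: four-point pattern passes its
  # gate (0.005), the three-point pattern is accepted at 0.005, but the next
  # gate (0.0025) fails -> final pattern has three relevant positions
  fn1 <- function(p) 0.004
  r1 <- sequential_reduction("++++", fn1, alpha_star = 0.01)
  expect_equal(r1$final_pattern, "+++X")
  expect_equal(r1$trail$level, c(0.01, 0.005))
  expect_equal(r1$trail$gate, c(0.005, 0.0025))
  expect_equal(r1$trail$continued, c(TRUE, FALSE))

  # entry rejected at alpha* = 0.005 but 0.004 > gate 0.0025: no reduction
  r2 <- sequential_reduction("++++", fn1, alpha_star = 0.005)
  expect_equal(r2$final_pattern, "++++")
  expect_false(any(r2$trail$continued))

  # p = 0 throughout: cascade runs all the way down to one relevant position
  r3 <- sequential_reduction("+---", function(p) 0, alpha_star = 0.01)
  expect_equal(r3$final_pattern, "+XXX")
  expect_equal(r3$trail$level, 0.01 / 2^(0:3))

  expect_error(sequential_reduction("++++", function(p) 0.5, 0.01),
               "already rejected")
})

test_that("sequential reduction never revokes the entry rejection", {
  set.seed(55)
  for (i in 1:100) {
    ps <- new.env()
    fn <- function(p) {
      if (!exists(p, envir = ps)) assign(p, runif(1, 0, 0.02), envir = ps)
      get(p, envir = ps)
    }
    alpha_star <- runif(1, 0.005, 0.05)
    entry <- sample(enumerate_patterns(4), 1)
    p_entry <- fn(entry)
    if (p_entry > alpha_star) next
    r <- sequential_reduction(entry, fn, alpha_star)
    # entry stays rejected: trail starts at the entry pattern at alpha*
    expect_equal(r$trail$pattern[1], entry)
    expect_equal(r$trail$level[1], alpha_star)
    expect_lte(p_entry, alpha_star)
    # levels halve at every step of the trail
    if (nrow(r$trail) > 1) {
      expect_equal(r$trail$level, alpha_star / 2^(seq_len(nrow(r$trail)) - 1))
      # every accepted reduced pattern met its level
      expect_true(all(r$trail$p_value[-1] <= r$trail$level[-1]))
    }
    # the final pattern is the last trail entry
    expect_equal(r$final_pattern, r$trail$pattern[nrow(r$trail)])
  }
})
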