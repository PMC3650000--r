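# Small hand-built cohorts used across test files.

# Five subjects, one taxon, four days; detections chosen so every pattern
# membership below can be checked by eye.
tiny_cohort <- function() {
  cohort_table(tibble::tibble(
    subject_id = paste0("s", 1:5),
    stratum = "A",
    outcome = c(0.1, -0.2, 0.3, 1.5, -1.0),
    tax1_d4  = c(1, 1, 1, 1, 0),
    tax1_d10 = c(1, 1, 0, 1, 0),
    tax1_d30 = c(1, 1, 1, 0, 0),
    tax1_d120 = c(0, 1, 0, 0, 0)
  ))
}

# Cohort whose outcome is exactly symmetric around zero within each
# detection group, handy for zero-statistic edge cases.
symmetric_cohort <- function() {
  cohort_table(tibble::tibble(
    subject_id = paste0("s", 1:8),
    stratum = "A",
    outcome = c(1, -1, 2, -2, 0.5, -0.5, 1.5, -1.5),
    tax1_d4  = c(1, 1, 1, 1, 0, 0, 0, 0),
    tax1_d10 = c(1, 1, 1, 1, 0, 0, 0, 0)
  ))
}

n_relevant_chars <- function(p) sum(strsplit(p, "")[[1]] != "X")

# Independent Welch test written straight from the Satterthwaite formulas.
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Brute-force BH step-up: try every k explicitly.
bh_oracle <- function(p, alpha) {
  n <- length(p)
  sp <- sort(p)
  R <- 0L
  for (k in seq_len(n)) {
    if (sp[k] <= k * alpha / n) R <- k
  }
  rejected <- rep(FALSE, n)
  if (R > 0L) {
    thr <- sp[R]
    ord <- order(p)
    rejected[ord[seq_len(R)]] <- TRUE
  }
  list(R = R, rejected = rejected)
}

# Straight-line implementation of the full two-level controller, kept
# deliberately naive and separate from the package's vectorised path.
mdfdr_oracle <- function(pvalues, alpha) {
  fams <- unique(pvalues$family)
  pooled <- vapply(fams, function(f) {
    p <- pvalues$p_value[pvalues$family == f]
    min(1, length(p) * min(p))
  }, 0)
  sel <- bh_oracle(pooled, alpha)
  R <- sel$R
  rejected <- logical(nrow(pvalues))
  for (i in seq_len(nrow(pvalues))) {
    f <- match(pvalues$family[i], fams)
    if (sel$rejected[f]) {
      m <- sum(pvalues$family == pvalues$family[i])
      rejected[i] <- pvalues$p_value[i] <= R * alpha / (length(fams) * m)
    }
  }
  list(R = R, component_rejected = rejected)
}
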