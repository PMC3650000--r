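#' Analysis configuration
#'
#' Bundles the tuning parameters of the detection-pattern analysis.
#'
#' @param alpha Mixed directional FDR level for the pattern (and
#'   time-specific) analysis; default 0.05.
#' @param delta Equivalence margin in outcome units; default 0.67, the
#'   conventional change-in-Z-score half-width for expected infant growth.
#' @param min_pattern_freq Minimum observed frequency for a pattern to be
#'   testable; default 0.15. The boundary is inclusive.
#' @param screen_alpha_contrast Level of the post-hoc crude-contrast
#'   difference-from-zero test; default 0.05.
#' @param screen_alpha_welch Level of the post-hoc Welch comparison between
#'   a pattern and its crude contrast; default 0.10, relaxed relative to
#'   `screen_alpha_contrast` because only the two groups' subjects enter.
#' @param stratify Analyse strata separately; default TRUE.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, delta = 0.67,
                            min_pattern_freq = 0.15,
                            screen_alpha_contrast = 0.05,
                            screen_alpha_welch = 0.10,
                            stratify = TRUE) {
  levels <- c(alpha = alpha, screen_alpha_contrast = screen_alpha_contrast,
              screen_alpha_welch = screen_alpha_welch,
              min_pattern_freq = min_pattern_freq)
  bad <- names(levels)[!is.finite(levels) | levels <= 0 | levels >= 1]
  if (length(bad)) {
    stop("configuration value(s) outside (0, 1): ",
         paste(bad, collapse = ", "), ".", call. = FALSE)
  }
  if (!is.finite(delta) || delta <= 0) {
    stop("`delta` must be > 0.", call. = FALSE)
  }
  structure(list(alpha = alpha, delta = delta,
                 min_pattern_freq = min_pattern_freq,
                 screen_alpha_contrast = screen_alpha_contrast,
                 screen_alpha_welch = screen_alpha_welch,
                 stratify = isTRUE(stratify)),
            class = "analysis_config")
}

# --- internal matrix-level machinery ---------------------------------------

# Outcomes of the subjects (rows of det, complete cases assumed) matching a
# pattern string at its relevant positions.
match_outcomes_matrix <- function(det, y, pattern) {
  ch <- pattern_chars(pattern)
  rel <- which(ch != "X")
  want <- as.integer(ch[rel] == "+")
  hit <- rep(TRUE, nrow(det))
  for (k in seq_along(rel)) {
    hit <- hit & det[, rel[k]] == want[k]
  }
  y[hit]
}

group_equivalence_p <- function(yk, delta) {
  n <- length(yk)
  if (n < 2L) return(NA_real_)
  se <- stats::sd(yk) / sqrt(n)
  if (!is.finite(se) || se <= 0) return(NA_real_)
  m <- mean(yk)
  max(stats::pt((m - delta) / se, n - 1),
      stats::pt((m + delta) / se, n - 1, lower.tail = FALSE))
}

# Full pattern pipeline for one stratum. det_by_taxon: named list of n x T
# 0/1/NA matrices; y: outcome vector. Returns list(audit, findings).
pattern_stratum_core <- function(det_by_taxon, y, config) {
  pats <- NULL
  per_taxon <- list()
  for (tx in names(det_by_taxon)) {
    det <- det_by_taxon[[tx]]
    if (is.null(pats)) pats <- enumerate_patterns(ncol(det))
    keep <- stats::complete.cases(det) & !is.na(y)
    n_complete <- sum(keep)
    if (n_complete == 0L) next
    st <- pattern_group_stats(det[keep, , drop = FALSE], y[keep])
    freq <- st$count / n_complete
    testable <- freq >= config$min_pattern_freq & st$n_y >= 2L &
      is.finite(st$se) & st$se > 0
    if (!any(testable)) next
    sel <- which(testable)
    p <- pmax(stats::pt((st$mean[sel] - config$delta) / st$se[sel],
                        st$n_y[sel] - 1),
              stats::pt((st$mean[sel] + config$delta) / st$se[sel],
                        st$n_y[sel] - 1, lower.tail = FALSE))
    per_taxon[[tx]] <- list(
      det = det[keep, , drop = FALSE], y = y[keep],
      pattern = pats[sel], n = st$count[sel], freq = freq[sel],
      mean = st$mean[sel], se = st$se[sel], p_value = p
    )
  }
  if (!length(per_taxon)) {
    return(list(audit = empty_audit(), findings = empty_findings()))
  }
  fam_levels <- names(per_taxon)
  fam_idx <- rep(seq_along(per_taxon),
                 vapply(per_taxon, function(z) length(z$p_value), 0L))
  p_all <- unlist(lapply(per_taxon, `[[`, "p_value"), use.names = FALSE)
  dec <- mdfdr_core(fam_idx, length(fam_levels), p_all, config$alpha)
  audit <- tibble::tibble(
    taxon = fam_levels[fam_idx],
    pattern = unlist(lapply(per_taxon, `[[`, "pattern"), use.names = FALSE),
    n = unlist(lapply(per_taxon, `[[`, "n"), use.names = FALSE),
    freq = unlist(lapply(per_taxon, `[[`, "freq"), use.names = FALSE),
    mean = unlist(lapply(per_taxon, `[[`, "mean"), use.names = FALSE),
    se = unlist(lapply(per_taxon, `[[`, "se"), use.names = FALSE),
    p_value = p_all,
    pooled_p = dec$pooled_p[fam_idx],
    alpha_star = dec$alpha_star[fam_idx],
    family_rejected = dec$fam_rejected[fam_idx],
    rejected = dec$comp_rejected
  )
  findings <- lapply(which(dec$comp_rejected), function(i) {
    tx <- fam_levels[fam_idx[i]]
    info <- per_taxon[[tx]]
    pvalue_fn <- function(pt_str) {
      group_equivalence_p(match_outcomes_matrix(info$det, info$y, pt_str),
                          config$delta)
    }
    red <- sequential_reduction(audit$pattern[i], pvalue_fn,
                                dec$alpha_star[fam_idx[i]])
    screen_finding(tx, audit$pattern[i], audit$p_value[i],
                   dec$alpha_star[fam_idx[i]], red, info, config)
  })
  findings <- if (length(findings)) {
    purrr::list_rbind(findings)
  } else {
    empty_findings()
  }
  list(audit = audit, findings = findings)
}

# Post-hoc screen of one rejected-and-reduced pattern against its crude
# contrast; returns a one-row findings tibble.
screen_finding <- function(taxon, entry_pattern, entry_p, alpha_star,
                           red, info, config) {
  final <- red$final_pattern
  y_final <- match_outcomes_matrix(info$det, info$y, final)
  contrast <- crude_contrast(final)
  y_contrast <- match_outcomes_matrix(info$det, info$y, contrast)
  n_f <- length(y_final)
  n_c <- length(y_contrast)
  contrast_p <- NA_real_
  welch_p <- NA_real_
  welch_tier <- "none"
  if (n_c < 2L || stats::sd(y_contrast) == 0) {
    screened_out <- TRUE
    reason <- "contrast_inconclusive"
  } else {
    contrast_p <- one_sample_difference(y_contrast)
    if (contrast_p > config$screen_alpha_contrast) {
      screened_out <- TRUE
      reason <- "contrast_not_significant"
    } else {
      screened_out <- FALSE
      reason <- ""
      welch_p <- welch_two_sample(y_final, y_contrast)
      welch_tier <- if (welch_p <= config$screen_alpha_contrast) {
        "strict"
      } else if (welch_p <= config$screen_alpha_welch) {
        "nominal"
      } else {
        "none"
      }
    }
  }
  tibble::tibble(
    taxon = taxon,
    pattern = entry_pattern,
    equivalence_p = entry_p,
    alpha_star = alpha_star,
    final_pattern = final,
    n = n_f,
    mean = if (n_f) mean(y_final) else NA_real_,
    se = if (n_f >= 2L) stats::sd(y_final) / sqrt(n_f) else NA_real_,
    final_p = group_equivalence_p(y_final, config$delta),
    contrast_pattern = contrast,
    contrast_n = n_c,
    contrast_mean = if (n_c) mean(y_contrast) else NA_real_,
    contrast_se = if (n_c >= 2L) stats::sd(y_contrast) / sqrt(n_c)
                  else NA_real_,
    contrast_p = contrast_p,
    welch_p = welch_p,
    welch_tier = welch_tier,
    screened_out = screened_out,
    screen_reason = reason,
    trail = list(red$trail)
  )
}

empty_audit <- function() {
  tibble::tibble(taxon = character(), pattern = character(), n = integer(),
                 freq = double(), mean = double(), se = double(),
                 p_value = double(), pooled_p = double(),
                 alpha_star = double(), family_rejected = logical(),
                 rejected = logical())
}

empty_findings <- function() {
  tibble::tibble(taxon = character(), pattern = character(),
                 equivalence_p = double(), alpha_star = double(),
                 final_pattern = character(), n = integer(), mean = double(),
                 se = double(), final_p = double(),
                 contrast_pattern = character(), contrast_n = integer(),
                 contrast_mean = double(), contrast_se = double(),
                 contrast_p = double(), welch_p = double(),
                 welch_tier = character(), screened_out = logical(),
                 screen_reason = character(), trail = list())
}

# --- public pipeline -------------------------------------------------------

#' Detection-pattern analysis of a longitudinal cohort
#'
#' The full pattern pipeline, per stratum: (1) tabulate testable full
#' detection patterns per taxon ([testable_patterns()]); (2) test each for
#' equivalence of its mean outcome to zero within `delta`
#' ([equivalence_to_zero()]); (3) control the mixed directional FDR with
#' taxa as families and testable patterns as components ([mdfdr_decide()]);
#' (4) trim superfluous trailing time points off each rejected pattern by
#' the sequential reduction cascade ([sequential_reduction()]); (5) screen
#' each final pattern against its crude contrast: the contrast group's mean
#' must differ from zero, and a Welch test then compares pattern and
#' contrast means. Findings whose contrast screen fails are flagged
#' `screened_out` and excluded from the significant-findings report, but
#' retained in the audit.
#'
#' @param cohort A [cohort_table()].
#' @param config An [analysis_config()].
#' @return Object of class `pattern_analysis`: `tidy()` returns the
#'   findings (one row per mdFDR-rejected pattern, with reduction trail and
#'   screening columns), `pattern_audit()` every tested component,
#'   `glance()` a one-row summary, `autoplot()` a means-and-intervals plot
#'   of unscreened findings and their contrasts.
#' @export
run_pattern_analysis <- function(cohort, config = analysis_config()) {
  cohort <- cohort_table(cohort)
  if (!inherits(config, "analysis_config")) {
    stop("`config` must be an analysis_config().", call. = FALSE)
  }
  pieces <- if (config$stratify) {
    split_strata(cohort)
  } else {
    ungrouped <- tibble::as_tibble(as.data.frame(cohort))
    ungrouped$stratum <- "all"
    list(all = cohort_table(ungrouped))
  }
  res <- purrr::imap(pieces, function(co, label) {
    det_by_taxon <- stats::setNames(
      lapply(taxa(co), detection_matrix, cohort = co), taxa(co))
    out <- pattern_stratum_core(det_by_taxon, co$outcome, config)
    if (nrow(out$audit)) out$audit$stratum <- label
    if (nrow(out$findings)) out$findings$stratum <- label
    out
  })
  audit <- purrr::list_rbind(lapply(res, `[[`, "audit"))
  findings <- purrr::list_rbind(lapply(res, `[[`, "findings"))
  audit <- if (nrow(audit)) {
    dplyr::relocate(audit, "stratum")
  } else {
    tibble::add_column(empty_audit(), stratum = character(), .before = 1)
  }
  findings <- if (nrow(findings)) {
    dplyr::relocate(findings, "stratum")
  } else {
    tibble::add_column(empty_findings(), stratum = character(), .before = 1)
  }
  structure(
    list(findings = findings, audit = audit, config = config),
    class = "pattern_analysis"
  )
}

#' @rdname run_pattern_analysis
#' @param x A `pattern_analysis` object.
#' @export
pattern_audit <- function(x) {
  stopifnot(inherits(x, "pattern_analysis"))
  x$audit
}

#' Post-hoc crude-contrast screen of a reduced pattern
#'
#' Stand-alone version of the screening step: given a taxon and a (possibly
#' reduced) pattern, matches the pattern's group and its crude contrast in
#' the cohort, tests the contrast mean against zero at
#' `config$screen_alpha_contrast`, and, when the contrast is significant,
#' compares the two groups by a Welch test at `config$screen_alpha_welch`.
#' A non-significant or inconclusive contrast screens the pattern out.
#'
#' @param cohort A [cohort_table()].
#' @param taxon Taxon label.
#' @param pattern Pattern string (the final, reduced pattern).
#' @param config An [analysis_config()].
#' @return One-row tibble with the screening columns of
#'   [run_pattern_analysis()] findings.
#' @export
posthoc_screen <- function(cohort, taxon, pattern, config = analysis_config()) {
  cohort <- cohort_table(cohort)
  parse_pattern(pattern)
  det <- detection_matrix(cohort, taxon)
  keep <- stats::complete.cases(det) & !is.na(cohort$outcome)
  info <- list(det = det[keep, , drop = FALSE], y = cohort$outcome[keep])
  red <- list(final_pattern = pattern, trail = tibble::tibble())
  out <- screen_finding(taxon, pattern, NA_real_, NA_real_, red, info, config)
  out[, setdiff(names(out), c("equivalence_p", "alpha_star", "trail"))]
}

#' @export
print.pattern_analysis <- function(x, ...) {
  kept <- sum(!x$findings$screened_out)
  cat("Detection-pattern analysis (alpha = ", x$config$alpha,
      ", delta = ", x$config$delta, ")\n", sep = "")
  cat("  components tested: ", nrow(x$audit), "\n", sep = "")
  cat("  patterns rejected: ", nrow(x$findings),
      " (", kept, " surviving the crude-contrast screen)\n", sep = "")
  invisible(x)
}

#' @export
print.timepoint_analysis <- function(x, ...) {
  cat("Time-specific detection analysis (alpha = ", x$alpha, " / ",
      x$alpha_relaxed, " relaxed)\n", sep = "")
  cat("  effects fitted: ", nrow(x$effects), "\n", sep = "")
  cat("  strict rejections: ", sum(x$effects$rejected),
      ", relaxed: ", sum(x$effects$rejected_relaxed), "\n", sep = "")
  invisible(x)
}
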