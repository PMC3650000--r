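#' Longitudinal detection patterns
#'
#' A detection pattern describes a taxon's presence history across the ordered
#' sampling time points as one character per time point: `"+"` (detected),
#' `"-"` (non-detected) or `"X"` (irrelevant -- the time point no longer
#' constrains group membership). Irrelevant positions may only appear as a
#' contiguous right-hand suffix, because the reduction process that introduces
#' them works strictly from the right side of the pattern.
#'
#' @param pattern A pattern string such as `"++-X"`.
#' @return `parse_pattern()` returns the validated pattern string (invisibly
#'   classed for internal use); it throws an error for malformed input.
#' @examples
#' parse_pattern("++-X")
#' crude_contrast("++XX")
#' reduce_right("++++")
#' @name pattern
NULL

pattern_chars <- function(pattern) strsplit(pattern, "", fixed = TRUE)[[1]]

#' @rdname pattern
#' @export
parse_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern)) {
    stop("`pattern` must be a single string over {+, -, X}.", call. = FALSE)
  }
  ch <- pattern_chars(pattern)
  if (length(ch) < 1L || !all(ch %in% c("+", "-", "X"))) {
    stop("`pattern` may only contain '+', '-' and 'X': got \"", pattern, "\".",
         call. = FALSE)
  }
  irr <- ch == "X"
  if (all(irr)) {
    stop("a pattern needs at least one non-irrelevant position.", call. = FALSE)
  }
  if (any(irr) && !all(irr[seq(which(irr)[1], length(ch))])) {
    stop("irrelevant ('X') positions must form a contiguous right-hand suffix.",
         call. = FALSE)
  }
  pattern
}

n_relevant <- function(pattern) {
  sum(pattern_chars(pattern) != "X")
}

#' Enumerate all full detection patterns
#'
#' Lists every full (no irrelevant positions) pattern over `n_timepoints`
#' time points in lexicographic order with detection sorting first, so the
#' all-detected pattern leads and the all-non-detected pattern closes the
#' list. With four time points this is the familiar 16-pattern display.
#'
#' @param n_timepoints Number of ordered sampling time points (>= 1).
#' @return Character vector of `2^n_timepoints` distinct pattern strings.
#' @examples
#' enumerate_patterns(2)
#' length(enumerate_patterns(4))
#' @export
enumerate_patterns <- function(n_timepoints) {
  if (!is.numeric(n_timepoints) || length(n_timepoints) != 1L ||
      is.na(n_timepoints) || n_timepoints < 1 ||
      n_timepoints != as.integer(n_timepoints)) {
    stop("`n_timepoints` must be a single integer >= 1.", call. = FALSE)
  }
  n_timepoints <- as.integer(n_timepoints)
  grid <- expand.grid(rep(list(c("+", "-")), n_timepoints),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse columns so the
  # first time point is the most significant position.
  apply(as.matrix(grid[, rev(seq_len(n_timepoints)), drop = FALSE]),
        1L, paste, collapse = "")
}

#' Flip a pattern into its crude contrast
#'
#' Swaps detected and non-detected at every relevant position and leaves
#' irrelevant positions alone. The crude contrast of a significant pattern
#' defines the comparison population used by the post-hoc screen.
#'
#' @inheritParams pattern
#' @return The contrasted pattern string.
#' @examples
#' crude_contrast("++XX")  # "--XX"
#' @export
crude_contrast <- function(pattern) {
  parse_pattern(pattern)
  chartr("+-", "-+", pattern)
}

#' Drop the rightmost relevant position of a pattern
#'
#' Replaces the rightmost non-irrelevant symbol with `"X"`. Reduction is only
#' ever performed from the right side: a later exposure cannot confound an
#' earlier one, so right-truncation relaxes the pattern without introducing
#' confounding.
#'
#' @inheritParams pattern
#' @return The reduced pattern string.
#' @examples
#' reduce_right("++++")  # "+++X"
#' @export
reduce_right <- function(pattern) {
  parse_pattern(pattern)
  ch <- pattern_chars(pattern)
  rel <- which(ch != "X")
  if (length(rel) < 2L) {
    stop("cannot reduce \"", pattern,
         "\": a pattern must keep at least one relevant position.",
         call. = FALSE)
  }
  ch[rel[length(rel)]] <- "X"
  paste(ch, collapse = "")
}

# integer id of a full pattern in enumerate_patterns() order (1-based)
pattern_id <- function(pattern) {
  ch <- pattern_chars(pattern)
  1L + sum((ch == "-") * 2L^(rev(seq_along(ch)) - 1L))
}

#' Match subjects to a detection pattern
#'
#' Finds the subjects whose detection history for one taxon agrees with the
#' pattern at every relevant position (irrelevant positions are
#' unconstrained) and summarises their outcome. A subject is only eligible if
#' its detection data for the taxon are complete at all time points, so that
#' membership in a full pattern is well defined.
#'
#' @param cohort A [cohort_table()].
#' @param taxon A taxon label present in the cohort.
#' @inheritParams pattern
#' @return One-row tibble: `taxon`, `pattern`, `n`, `subject_ids` (list
#'   column), `mean`, `se`. With no matching subjects `n` is 0 and `mean`/`se`
#'   are `NA` (never an error). Subjects with incomplete detection data for
#'   the taxon, or a missing outcome, are not eligible.
#' @export
match_subjects <- function(cohort, taxon, pattern) {
  cohort <- cohort_table(cohort)
  parse_pattern(pattern)
  det <- detection_matrix(cohort, taxon)
  if (nchar(pattern) != ncol(det)) {
    stop("pattern length ", nchar(pattern), " does not match the cohort's ",
         ncol(det), " time points.", call. = FALSE)
  }
  keep <- stats::complete.cases(det) & !is.na(cohort$outcome)
  ch <- pattern_chars(pattern)
  rel <- which(ch != "X")
  want <- as.integer(ch[rel] == "+")
  hit <- keep
  for (k in seq_along(rel)) {
    hit <- hit & det[, rel[k]] == want[k]
  }
  hit[is.na(hit)] <- FALSE
  ids <- cohort$subject_id[hit]
  y <- cohort$outcome[hit]
  n <- length(y)
  tibble::tibble(
    taxon = taxon,
    pattern = pattern,
    n = n,
    subject_ids = list(ids),
    mean = if (n >= 1L) mean(y) else NA_real_,
    se = if (n >= 2L) stats::sd(y) / sqrt(n) else NA_real_
  )
}

#' Testable full patterns for a taxon
#'
#' Tabulates the full detection patterns observed for one taxon among its
#' complete-case subjects and keeps those frequent enough to test. A pattern
#' observed less than `min_freq` of the time is dropped for lack of power;
#' the boundary is inclusive, so a pattern at exactly the floor is testable.
#' Frequencies are relative to the analysable subjects for that taxon --
#' complete detection data at every time point and a non-missing outcome --
#' not the full cohort.
#'
#' @inheritParams match_subjects
#' @param min_freq Minimum observed pattern frequency in (0, 1); default 0.15.
#' @return Tibble with one row per testable pattern: `taxon`, `pattern`, `n`,
#'   `freq`, `mean`, `se`, ordered as in [enumerate_patterns()].
#' @export
testable_patterns <- function(cohort, taxon, min_freq = 0.15) {
  cohort <- cohort_table(cohort)
  if (!is.numeric(min_freq) || length(min_freq) != 1L ||
      is.na(min_freq) || min_freq <= 0 || min_freq >= 1) {
    stop("`min_freq` must be a single proportion in (0, 1).", call. = FALSE)
  }
  det <- detection_matrix(cohort, taxon)
  keep <- stats::complete.cases(det) & !is.na(cohort$outcome)
  n_complete <- sum(keep)
  pats <- enumerate_patterns(ncol(det))
  if (n_complete == 0L) {
    warning("no complete-case subjects for taxon '", taxon,
            "'; no testable patterns.", call. = FALSE)
    return(tibble::tibble(taxon = character(), pattern = character(),
                          n = integer(), freq = double(),
                          mean = double(), se = double()))
  }
  summ <- pattern_group_stats(det[keep, , drop = FALSE],
                              cohort$outcome[keep])
  freq <- summ$count / n_complete
  sel <- which(freq >= min_freq)
  tibble::tibble(
    taxon = taxon,
    pattern = pats[sel],
    n = summ$count[sel],
    freq = freq[sel],
    mean = summ$mean[sel],
    se = summ$se[sel]
  )
}

# Per-full-pattern counts, outcome means and standard errors for a
# complete-case detection matrix (1 = detected). Outcome NAs are excluded
# from the moments but the subjects still count towards pattern frequency.
# Groups are indexed in enumerate_patterns() order (all-detected first).
pattern_group_stats <- function(det, outcome) {
  T <- ncol(det)
  ngrp <- 2L^T
  weights <- 2L^(rev(seq_len(T)) - 1L)
  id <- 1L + as.integer((1L - det) %*% weights)
  count <- tabulate(id, ngrp)
  ok <- !is.na(outcome)
  n_y <- tabulate(id[ok], ngrp)
  sy <- numeric(ngrp)
  syy <- numeric(ngrp)
  if (any(ok)) {
    grp <- sort(unique(id[ok]))
    sy[grp] <- as.vector(rowsum(outcome[ok], id[ok]))
    syy[grp] <- as.vector(rowsum(outcome[ok]^2, id[ok]))
  }
  m <- ifelse(n_y >= 1L, sy / pmax(n_y, 1L), NA_real_)
  v <- pmax((syy - pmax(n_y, 1L) * ifelse(is.na(m), 0, m)^2) /
              pmax(n_y - 1L, 1L), 0)
  list(count = count, n_y = n_y, mean = m,
       se = ifelse(n_y >= 2L, sqrt(v / pmax(n_y, 1L)), NA_real_))
}
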