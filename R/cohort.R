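#' Longitudinal detection cohort tables
#'
#' A cohort table is a tibble with one row per subject and columns
#' `subject_id`, `stratum`, `outcome` (the continuous growth outcome, e.g.
#' change in weight-for-age Z-score between birth and ~6 months), followed by
#' one 0/1/NA detection column per taxon and time point named
#' `<taxon>_d<day>` (e.g. `probe13_d30`). `cohort_table()` validates a data
#' frame in this layout and records the taxa and sampling days as attributes.
#'
#' @param x A data frame in the layout above.
#' @return A validated `cohort_tbl` (a tibble subclass). Accessors: `taxa()`
#'   returns the taxon labels, `timepoints()` the ordered sampling days.
#' @examples
#' df <- tibble::tibble(
#'   subject_id = c("s1", "s2"), stratum = "F", outcome = c(0.1, -0.5),
#'   tax1_d4 = c(1, 0), tax1_d10 = c(1, NA)
#' )
#' cohort <- cohort_table(df)
#' taxa(cohort)
#' timepoints(cohort)
#' @export
cohort_table <- function(x) {
  if (inherits(x, "cohort_tbl")) {
    return(x)
  }
  if (!is.data.frame(x)) {
    stop("`x` must be a data frame.", call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  need <- c("subject_id", "stratum", "outcome")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), ".", call. = FALSE)
  }
  det_cols <- setdiff(names(x), need)
  parsed <- parse_detection_names(det_cols)
  if (nrow(parsed) == 0L) {
    stop("cohort has no detection columns (expected names like 'tax1_d4').",
         call. = FALSE)
  }
  days <- sort(unique(parsed$day))
  if (length(days) < 2L) {
    stop("a cohort needs detections at >= 2 time points.", call. = FALSE)
  }
  taxa <- unique(parsed$taxon)
  want <- as.vector(outer(days, taxa, function(d, tx) paste0(tx, "_d", d)))
  absent <- setdiff(want, det_cols)
  if (length(absent)) {
    stop("incomplete taxon x day grid; missing column(s): ",
         paste(utils::head(absent, 5L), collapse = ", "),
         if (length(absent) > 5L) ", ..." else "", ".", call. = FALSE)
  }
  if (anyDuplicated(x$subject_id)) {
    dup <- unique(x$subject_id[duplicated(x$subject_id)])
    stop("duplicate subject_id(s): ",
         paste(utils::head(dup, 5L), collapse = ", "), ".", call. = FALSE)
  }
  if (!is.numeric(x$outcome)) {
    stop("`outcome` must be numeric.", call. = FALSE)
  }
  if (any(is.infinite(x$outcome))) {
    stop("`outcome` must be finite or NA.", call. = FALSE)
  }
  for (cn in want) {
    v <- x[[cn]]
    if (!is.numeric(v) && !is.logical(v)) {
      stop("detection column '", cn, "' must be numeric 0/1/NA.",
           call. = FALSE)
    }
    bad <- !is.na(v) & !(v %in% c(0, 1))
    if (any(bad)) {
      stop("detection column '", cn, "' has value(s) outside {0, 1, NA}: ",
           paste(utils::head(unique(v[bad]), 3L), collapse = ", "),
           ".", call. = FALSE)
    }
    x[[cn]] <- as.integer(v)
  }
  if (any(is.na(x$stratum) | x$stratum == "")) {
    warning("subjects with empty stratum label assigned to 'unlabelled'.",
            call. = FALSE)
    x$stratum[is.na(x$stratum) | x$stratum == ""] <- "unlabelled"
  }
  x <- x[, c(need, want)]
  structure(x,
            class = c("cohort_tbl", class(tibble::tibble())),
            taxa = taxa, days = days)
}

parse_detection_names <- function(cols) {
  m <- regmatches(cols, regexec("^(.+)_d([0-9]+)$", cols))
  ok <- lengths(m) == 3L
  tibble::tibble(
    column = cols[ok],
    taxon = vapply(m[ok], `[[`, "", 2L),
    day = as.numeric(vapply(m[ok], `[[`, "", 3L))
  )
}

#' @rdname cohort_table
#' @export
taxa <- function(x) attr(cohort_table(x), "taxa")

#' @rdname cohort_table
#' @export
timepoints <- function(x) attr(cohort_table(x), "days")

# n x T integer detection matrix for one taxon (columns in day order)
detection_matrix <- function(cohort, taxon) {
  if (!taxon %in% attr(cohort, "taxa")) {
    stop("unknown taxon '", taxon, "'.", call. = FALSE)
  }
  days <- attr(cohort, "days")
  cols <- paste0(taxon, "_d", days)
  m <- as.matrix(as.data.frame(cohort)[, cols])
  dimnames(m) <- list(cohort$subject_id, cols)
  storage.mode(m) <- "integer"
  m
}

#' Read and write cohort tables
#'
#' `read_cohort()` loads a delimited text file (TSV by default, or CSV by
#' extension) with the [cohort_table()] layout; `write_cohort()` writes one
#' back in the same dialect. The round trip is lossless, including
#' missingness. Missing values are never imputed.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` file.
#' @return `read_cohort()` returns a validated `cohort_tbl`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  x <- reader(path, show_col_types = FALSE, progress = FALSE,
              na = c("", "NA"))
  prob <- readr::problems(x)
  if (nrow(prob) > 0L) {
    stop("malformed cohort file '", path, "': parse problem at line ",
         prob$row[1L], " (", prob$expected[1L], ").", call. = FALSE)
  }
  x$subject_id <- as.character(x$subject_id)
  x$stratum <- as.character(x$stratum)
  cohort_table(x)
}

#' @rdname read_cohort
#' @param cohort A [cohort_table()].
#' @export
write_cohort <- function(cohort, path) {
  cohort <- cohort_table(cohort)
  out <- tibble::as_tibble(as.data.frame(cohort))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(out, path, na = "NA")
  } else {
    readr::write_tsv(out, path, na = "NA")
  }
  invisible(path)
}

#' Dichotomise intensity readings into detection calls
#'
#' Converts continuous probe intensities into 0/1 detection indicators using
#' a per-taxon threshold: strictly above the threshold is detected (1), at or
#' below is non-detected (0), missing stays missing. The thresholds are the
#' caller's responsibility (e.g. array-specific detection limits).
#'
#' @param intensities A data frame of intensity columns named `<taxon>_d<day>`
#'   (other columns are passed through unchanged).
#' @param thresholds Named numeric vector, one threshold per taxon.
#' @return The input with intensity columns replaced by 0/1/NA detections.
#' @examples
#' df <- tibble::tibble(a_d4 = c(5, 3, NA), a_d10 = c(2, 4, 1))
#' dichotomise(df, c(a = 3))
#' @export
dichotomise <- function(intensities, thresholds) {
  if (!is.data.frame(intensities)) {
    stop("`intensities` must be a data frame.", call. = FALSE)
  }
  if (is.null(names(thresholds)) || any(names(thresholds) == "") ||
      !is.numeric(thresholds)) {
    stop("`thresholds` must be a named numeric vector (one per taxon).",
         call. = FALSE)
  }
  parsed <- parse_detection_names(names(intensities))
  missing_thr <- setdiff(unique(parsed$taxon), names(thresholds))
  if (length(missing_thr)) {
    stop("no threshold supplied for taxon/taxa: ",
         paste(missing_thr, collapse = ", "), ".", call. = FALSE)
  }
  out <- tibble::as_tibble(intensities)
  for (i in seq_len(nrow(parsed))) {
    cn <- parsed$column[i]
    thr <- thresholds[[parsed$taxon[i]]]
    out[[cn]] <- as.integer(out[[cn]] > thr)
  }
  out
}

#' Split a cohort into per-stratum cohorts
#'
#' Partitions the subjects by stratum label (e.g. sex); the analyses are run
#' fully independently within each stratum. Strata with fewer than two
#' subjects are dropped with a warning, since no inference is possible there.
#'
#' @param cohort A [cohort_table()].
#' @return Named list of `cohort_tbl`, one per retained stratum.
#' @export
split_strata <- function(cohort) {
  cohort <- cohort_table(cohort)
  pieces <- split(tibble::as_tibble(as.data.frame(cohort)), cohort$stratum)
  small <- names(pieces)[vapply(pieces, nrow, 0L) < 2L]
  if (length(small)) {
    warning("stratum/strata with < 2 subjects excluded from inference: ",
            paste(small, collapse = ", "), ".", call. = FALSE)
    pieces <- pieces[setdiff(names(pieces), small)]
  }
  lapply(pieces, cohort_table)
}
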