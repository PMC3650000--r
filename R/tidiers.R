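#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for analysis objects
#'
#' `tidy()` returns the per-hypothesis tables (effects, findings, or
#' per-replicate false discovery proportions); `glance()` returns a one-row
#' summary.
#'
#' @param x A `timepoint_analysis`, `pattern_analysis` or
#'   `simulation_report` object.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name detpat-tidiers
NULL

#' @rdname detpat-tidiers
#' @method tidy timepoint_analysis
#' @export
tidy.timepoint_analysis <- function(x, ...) {
  x$effects
}

#' @rdname detpat-tidiers
#' @method glance timepoint_analysis
#' @export
glance.timepoint_analysis <- function(x, ...) {
  tibble::tibble(
    n_effects = nrow(x$effects),
    n_estimable = sum(x$effects$estimable),
    n_strict = sum(x$effects$rejected),
    n_relaxed = sum(x$effects$rejected_relaxed),
    alpha = x$alpha,
    alpha_relaxed = x$alpha_relaxed
  )
}

#' @rdname detpat-tidiers
#' @method tidy pattern_analysis
#' @export
tidy.pattern_analysis <- function(x, ...) {
  x$findings
}

#' @rdname detpat-tidiers
#' @method glance pattern_analysis
#' @export
glance.pattern_analysis <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$audit),
    n_rejected = nrow(x$findings),
    n_unscreened = sum(!x$findings$screened_out),
    alpha = x$config$alpha,
    delta = x$config$delta,
    min_pattern_freq = x$config$min_pattern_freq
  )
}

#' @rdname detpat-tidiers
#' @method tidy simulation_report
#' @export
tidy.simulation_report <- function(x, ...) {
  tibble::tibble(replicate = seq_len(x$n_replicates), fdp = x$fdp)
}

#' @rdname detpat-tidiers
#' @method glance simulation_report
#' @export
glance.simulation_report <- function(x, ...) {
  tibble::tibble(
    analysis = x$analysis,
    n_replicates = x$n_replicates,
    empirical_mdfdr = x$empirical_mdfdr,
    mc_se = x$mc_se,
    total_rejections = x$total_rejections,
    false_rejections = x$false_rejections,
    recovery_rate = x$recovery_rate,
    alpha = x$alpha
  )
}

#' Plot methods
#'
#' `autoplot()` renders each result type with ggplot2:
#' a `pattern_analysis` as the means and 95% confidence intervals of the
#' unscreened final patterns and their crude contrasts, with reference
#' lines at zero and at +/- the equivalence margin; a `timepoint_analysis`
#' as per-day detection effects with 95% confidence intervals coloured by
#' significance tier; a `simulation_report` as the distribution of
#' per-replicate false discovery proportions against the nominal level.
#'
#' @param object An analysis object.
#' @param ... Unused.
#' @return A ggplot.
#' @name detpat-autoplot
NULL

#' @rdname detpat-autoplot
#' @method autoplot pattern_analysis
#' @export
autoplot.pattern_analysis <- function(object, ...) {
  f <- object$findings[!object$findings$screened_out, , drop = FALSE]
  delta <- object$config$delta
  if (!nrow(f)) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no unscreened findings") +
             ggplot2::theme_void())
  }
  long <- dplyr::bind_rows(
    dplyr::transmute(f, stratum = .data$stratum, taxon = .data$taxon,
                     pattern = .data$final_pattern, group = "pattern",
                     n = .data$n, mean = .data$mean, se = .data$se),
    dplyr::transmute(f, stratum = .data$stratum, taxon = .data$taxon,
                     pattern = .data$final_pattern, group = "crude contrast",
                     n = .data$contrast_n, mean = .data$contrast_mean,
                     se = .data$contrast_se)
  ) |>
    dplyr::mutate(
      label = paste0(.data$stratum, ": ", .data$taxon, " ", .data$pattern),
      lo = .data$mean + stats::qt(0.025, .data$n - 1) * .data$se,
      hi = .data$mean + stats::qt(0.975, .data$n - 1) * .data$se
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean, y = .data$label,
                                     colour = .data$group)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "solid",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(-delta, delta),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "mean outcome (change in Z-score), 95% CI",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname detpat-autoplot
#' @method autoplot timepoint_analysis
#' @export
autoplot.timepoint_analysis <- function(object, ...) {
  e <- object$effects[object$effects$estimable, , drop = FALSE]
  if (!nrow(e)) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no estimable effects") +
             ggplot2::theme_void())
  }
  e <- dplyr::mutate(
    e,
    lo = .data$beta + stats::qt(0.025, .data$df) * .data$se,
    hi = .data$beta + stats::qt(0.975, .data$df) * .data$se,
    day = factor(.data$day, levels = sort(unique(.data$day)))
  )
  ggplot2::ggplot(e, ggplot2::aes(x = .data$beta, y = .data$taxon,
                                  colour = .data$tier)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             fatten = 1.5) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$stratum),
                        cols = ggplot2::vars(.data$day)) +
    ggplot2::labs(x = "detection effect on outcome (95% CI)", y = NULL,
                  colour = "tier") +
    ggplot2::theme_minimal()
}

#' @rdname detpat-autoplot
#' @method autoplot simulation_report
#' @export
autoplot.simulation_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fdp)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$alpha, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_vline(xintercept = object$empirical_mdfdr,
                        colour = "blue") +
    ggplot2::labs(x = "per-replicate false discovery proportion",
                  y = "replicates") +
    ggplot2::theme_minimal()
}
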