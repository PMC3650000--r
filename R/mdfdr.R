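#' Bonferroni-pooled family p-value
#'
#' Pools a family's component p-values into a single family-level p-value,
#' `min(1, m * min(p))` for a family of m components. The pooled values are
#' the statistics fed to the Benjamini-Hochberg selection across families.
#'
#' @param p Numeric vector of component p-values in \[0, 1\], length >= 1.
#' @return The pooled p-value.
#' @examples
#' bonferroni_pool(c(0.01, 0.5, 0.2, 0.8))  # 0.04
#' @export
bonferroni_pool <- function(p) {
  if (length(p) < 1L || anyNA(p) || any(p < 0 | p > 1)) {
    stop("`p` must be a non-empty vector of p-values in [0, 1].",
         call. = FALSE)
  }
  min(1, length(p) * min(p))
}

#' Benjamini-Hochberg step-up selection
#'
#' The standard step-up rule: with sorted p-values p_(1) <= ... <= p_(n),
#' R = max{ k : p_(k) <= k * alpha / n } (0 if no such k), and the R
#' hypotheses with the smallest p-values are rejected.
#'
#' @param p Numeric vector of p-values.
#' @param alpha Level in (0, 1).
#' @return List with `R` (number rejected) and `rejected` (logical vector
#'   aligned with `p`).
#' @export
bh_select <- function(p, alpha) {
  if (length(p) < 1L || anyNA(p) || any(p < 0 | p > 1)) {
    stop("`p` must be a non-empty vector of p-values in [0, 1].",
         call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single level in (0, 1).", call. = FALSE)
  }
  n <- length(p)
  ord <- order(p)
  ok <- p[ord] <= seq_len(n) * alpha / n
  R <- if (any(ok)) max(which(ok)) else 0L
  rejected <- logical(n)
  if (R > 0L) rejected[ord[seq_len(R)]] <- TRUE
  list(R = as.integer(R), rejected = rejected)
}

#' Mixed directional FDR decision over a family/component structure
#'
#' Two-level multiple-testing controller for hypotheses organised into
#' families (taxa) of components (time points, or testable patterns):
#' each family is summarised by its Bonferroni-pooled p-value
#' ([bonferroni_pool()]); Benjamini-Hochberg selection ([bh_select()]) at
#' level `alpha` across the n families rejects R of them; within each
#' rejected family j, component k is rejected when
#' p_jk <= alpha_star_j = R * alpha / (n * m_j), where m_j is the family's
#' component count. With no family rejections no component is rejected.
#' This controls the mixed directional false discovery rate -- the expected
#' proportion of wrongly rejected (or wrongly signed) components among all
#' component rejections -- at level `alpha`.
#'
#' @param pvalues A data frame with columns `family`, `component` and
#'   `p_value` (one row per component hypothesis).
#' @param alpha Level in (0, 1).
#' @return An object of class `mdfdr_decision`: a list with `components`
#'   (input tibble plus `pooled_p`, `alpha_star`, `family_rejected`,
#'   `rejected`), `families` (per-family summary), `R`, and `alpha`.
#' @examples
#' pv <- tibble::tibble(
#'   family = rep(c("taxA", "taxB"), each = 2),
#'   component = rep(c("d4", "d10"), 2),
#'   p_value = c(0.001, 0.2, 0.8, 0.9)
#' )
#' mdfdr_decide(pv, alpha = 0.05)
#' @export
mdfdr_decide <- function(pvalues, alpha = 0.05) {
  if (!is.data.frame(pvalues) ||
      !all(c("family", "component", "p_value") %in% names(pvalues))) {
    stop("`pvalues` needs columns family, component, p_value.",
         call. = FALSE)
  }
  if (nrow(pvalues) < 1L) {
    stop("`pvalues` must have at least one component hypothesis.",
         call. = FALSE)
  }
  comp <- tibble::as_tibble(pvalues)
  if (anyNA(comp$p_value) || any(comp$p_value < 0 | comp$p_value > 1)) {
    stop("component p-values must lie in [0, 1].", call. = FALSE)
  }
  fam_levels <- unique(comp$family)
  core <- mdfdr_core(match(comp$family, fam_levels), length(fam_levels),
                     comp$p_value, alpha)
  fam <- tibble::tibble(
    family = fam_levels,
    m = core$m,
    pooled_p = core$pooled_p,
    rejected = core$fam_rejected,
    alpha_star = core$alpha_star
  )
  idx <- match(comp$family, fam_levels)
  comp$pooled_p <- core$pooled_p[idx]
  comp$alpha_star <- core$alpha_star[idx]
  comp$family_rejected <- core$fam_rejected[idx]
  comp$rejected <- core$comp_rejected
  structure(
    list(components = comp, families = fam, R = core$R, alpha = alpha),
    class = "mdfdr_decision"
  )
}

# Lean vector core of the two-level procedure (no data-frame overhead); the
# simulation harness calls this directly once per replicate and stratum.
mdfdr_core <- function(family_idx, n_fam, p, alpha) {
  m <- tabulate(family_idx, n_fam)
  minp <- rep(Inf, n_fam)
  agg <- tapply(p, family_idx, min)
  minp[as.integer(names(agg))] <- agg
  pooled_p <- pmin(1, m * minp)
  sel <- bh_select(pooled_p, alpha)
  R <- sel$R
  alpha_star <- if (R > 0L) R * alpha / (n_fam * m) else rep(0, n_fam)
  comp_rejected <- sel$rejected[family_idx] & p <= alpha_star[family_idx]
  list(m = m, pooled_p = pooled_p, fam_rejected = sel$rejected, R = R,
       alpha_star = alpha_star, comp_rejected = comp_rejected)
}

#' @export
print.mdfdr_decision <- function(x, ...) {
  cat("Mixed directional FDR decision (alpha = ", x$alpha, ")\n", sep = "")
  cat("  families: ", nrow(x$families), ", rejected R = ", x$R, "\n",
      sep = "")
  cat("  component rejections: ", sum(x$components$rejected), " of ",
      nrow(x$components), "\n", sep = "")
  invisible(x)
}

#' Sequential right-side pattern reduction
#'
#' Alpha-recycling cascade that tries to trim superfluous trailing time
#' points off a pattern already rejected (found equivalent to zero) at level
#' `alpha_star`. At each stage the current level L (starting at
#' `alpha_star`) is Bonferroni-split in half: if the current pattern's
#' p-value is <= L/2, half of the level is banked to preserve the current
#' rejection and the right-reduced pattern is tested at the other half. A
#' reduced pattern that passes becomes current with L halved and the cascade
#' continues; otherwise the cascade stops. The entry rejection is never
#' revoked, and the cascade also stops at an irreducible (single relevant
#' position) pattern.
#'
#' @param pattern The rejected full pattern string.
#' @param pvalue_fn Function mapping a pattern string to its equivalence
#'   p-value (NA for an untestable pattern, which stops the cascade).
#' @param alpha_star Level at which `pattern` was rejected; the entry
#'   p-value must satisfy `pvalue_fn(pattern) <= alpha_star`.
#' @return List with `final_pattern` and `trail`, a tibble with one row per
#'   stage: `pattern`, `p_value`, `level`, `gate`, `continued`.
#' @export
sequential_reduction <- function(pattern, pvalue_fn, alpha_star) {
  parse_pattern(pattern)
  if (!is.numeric(alpha_star) || length(alpha_star) != 1L ||
      is.na(alpha_star) || alpha_star <= 0) {
    stop("`alpha_star` must be a single positive level.", call. = FALSE)
  }
  p_cur <- pvalue_fn(pattern)
  if (is.na(p_cur) || p_cur > alpha_star) {
    stop("`pattern` must enter already rejected: p = ", format(p_cur),
         " > alpha_star = ", format(alpha_star), ".", call. = FALSE)
  }
  current <- pattern
  level <- alpha_star
  steps <- list()
  repeat {
    gate <- level / 2
    reducible <- n_relevant(current) >= 2L
    gate_open <- reducible && p_cur <= gate
    if (!gate_open) {
      steps[[length(steps) + 1L]] <- tibble::tibble(
        pattern = current, p_value = p_cur, level = level,
        gate = gate, continued = FALSE)
      break
    }
    nxt <- reduce_right(current)
    p_nxt <- pvalue_fn(nxt)
    continued <- !is.na(p_nxt) && p_nxt <= gate
    steps[[length(steps) + 1L]] <- tibble::tibble(
      pattern = current, p_value = p_cur, level = level,
      gate = gate, continued = continued)
    if (!continued) break
    current <- nxt
    p_cur <- p_nxt
    level <- gate
  }
  list(final_pattern = current, trail = dplyr::bind_rows(steps))
}
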