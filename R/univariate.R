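#' Mann-Whitney U test for one metabolite
#'
#' Two-sided rank-sum comparison of two groups. The U statistic is
#' computed from rank sums with midranks for ties. The p-value is exact
#' (full enumeration) when the combined sample size is at most 12 and no
#' ties are present, and otherwise uses the normal approximation with tie
#' and continuity corrections.
#'
#' @param group_a,group_b Numeric vectors, each with at least one value.
#' @return List with `U` (statistic for `group_a`) and `p`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) < 1L || length(group_b) < 1L) {
    stop("each group needs at least one observation", call. = FALSE)
  }
  pooled <- c(group_a, group_b)
  has_ties <- anyDuplicated(pooled) > 0L
  exact <- (length(pooled) <= 12L) && !has_ties
  ranks <- rank(pooled)
  u <- sum(ranks[seq_along(group_a)]) -
    length(group_a) * (length(group_a) + 1) / 2
  if (length(unique(pooled)) == 1L) {
    return(list(U = u, p = 1))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  list(U = u, p = min(ht$p.value, 1))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1; the
#' input order is preserved.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-metabolite log2 fold change (Prem over Term)
#'
#' Ratio of group means (or medians) of PQN-normalized intensities, on
#' the log2 scale, with the Term group as reference: positive values mean
#' higher levels in the Prem group. Must be computed before autoscaling
#' (autoscaled values can be negative, making ratios undefined).
#'
#' @param x PQN-normalized, strictly positive matrix (samples x
#'   metabolites).
#' @param groups Factor or character vector with levels `Term` and
#'   `Prem`, aligned with rows of `x`.
#' @param estimator `"mean"` (default) or `"median"`.
#' @return Named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(x, groups, estimator = c("mean", "median")) {
  estimator <- match.arg(estimator)
  x <- as.matrix(x)
  if (!is.null(attr(x, "state")) && attr(x, "state") == "autoscaled") {
    stop("fold changes must be computed on PQN-normalized, not autoscaled, data",
         call. = FALSE)
  }
  groups <- as.factor(as.character(groups))
  if (!all(c("Term", "Prem") %in% levels(groups))) {
    stop("groups must contain both 'Term' and 'Prem'", call. = FALSE)
  }
  f <- if (estimator == "mean") colMeans else function(m) apply(m, 2L, stats::median)
  m_prem <- f(x[groups == "Prem", , drop = FALSE])
  m_term <- f(x[groups == "Term", , drop = FALSE])
  if (any(m_prem == 0) || any(m_term == 0)) {
    stop("zero group mean: fold change undefined", call. = FALSE)
  }
  log2(m_prem / m_term)
}

#' Univariate two-group screen of all metabolites
#'
#' Runs the Mann-Whitney U test per metabolite, adjusts p-values by
#' Benjamini-Hochberg, computes log2 fold changes (Prem over Term), and
#' classifies each metabolite by the volcano rule: significant when the
#' adjusted p-value is below `alpha` and |log2FC| exceeds `fc_threshold`.
#'
#' @param x PQN-normalized matrix (samples x metabolites).
#' @param groups Group labels (`Term`/`Prem`) aligned with rows.
#' @param alpha FDR significance threshold (default 0.05).
#' @param fc_threshold Absolute log2 fold-change threshold (default 0.6).
#' @param estimator Fold-change estimator, `"mean"` or `"median"`.
#' @return A data.frame of class `"univariate_table"` with columns
#'   `metabolite`, `U`, `p`, `p_adj`, `log2fc`, `significant`,
#'   `direction` (`up`/`down`/`ns`), plus attributes `alpha`,
#'   `fc_threshold` and `counts` (up, down, ns).
#' @export
univariate_screen <- function(x, groups, alpha = 0.05, fc_threshold = 0.6,
                              estimator = "mean") {
  x <- as.matrix(x)
  groups <- as.factor(as.character(groups))
  res <- lapply(seq_len(ncol(x)), function(j) {
    mann_whitney_u(x[groups == "Prem", j], x[groups == "Term", j])
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  tab <- data.frame(
    metabolite = colnames(x),
    U = vapply(res, `[[`, numeric(1), "U"),
    p = p,
    p_adj = bh_fdr(p),
    log2fc = as.numeric(log2_fold_change(x, groups, estimator)),
    stringsAsFactors = FALSE
  )
  volcano_table(tab, alpha = alpha, fc_threshold = fc_threshold)
}

#' Classify a univariate table by the volcano rule
#'
#' @param univ Data frame with at least `p_adj` and `log2fc` columns.
#' @param alpha FDR threshold.
#' @param fc_threshold Absolute log2 fold-change threshold.
#' @return The table with `significant` and `direction` columns and a
#'   `counts` attribute (named vector: up, down, ns), classed
#'   `"univariate_table"`.
#' @export
volcano_table <- function(univ, alpha = 0.05, fc_threshold = 0.6) {
  stopifnot(all(c("p_adj", "log2fc") %in% names(univ)))
  sig <- univ$p_adj < alpha & abs(univ$log2fc) > fc_threshold
  direction <- ifelse(!sig, "ns", ifelse(univ$log2fc > 0, "up", "down"))
  univ$significant <- sig
  univ$direction <- direction
  attr(univ, "alpha") <- alpha
  attr(univ, "fc_threshold") <- fc_threshold
  attr(univ, "counts") <- c(up = sum(direction == "up"),
                            down = sum(direction == "down"),
                            ns = sum(direction == "ns"))
  class(univ) <- c("univariate_table", "data.frame")
  univ
}

#' @export
print.univariate_table <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("Univariate screen: %d metabolites (FDR < %g, |log2FC| > %g)\n",
              nrow(x), attr(x, "alpha"), attr(x, "fc_threshold")))
  cat(sprintf("  up in Prem: %d   down in Prem: %d   not significant: %d\n",
              cnt["up"], cnt["down"], cnt["ns"]))
  NextMethod()
}

#' Volcano plot of a univariate screen
#'
#' @param x A `"univariate_table"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.univariate_table <- function(x, ...) {
  col <- c(ns = "grey60", up = "#E6B800", down = "#3366CC")[x$direction]
  graphics::plot(x$log2fc, -log10(pmax(x$p_adj, 1e-300)), col = col, pch = 16,
                 xlab = "log2 fold change (Prem / Term)",
                 ylab = "-log10 adjusted p", ...)
  graphics::abline(h = -log10(attr(x, "alpha")), lty = 2)
  graphics::abline(v = c(-1, 1) * attr(x, "fc_threshold"), lty = 2)
  invisible(x)
}
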