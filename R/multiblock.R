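#' Build a block map from a function annotation table
#'
#' Converts a wide metabolite-to-function annotation (up to three labels
#' per metabolite) into a block -> member-metabolite map, restricted to
#' metabolites present in the feature matrix. Blocks retaining fewer
#' than three members are discarded; unannotated metabolites belong to
#' no block.
#'
#' @param annotation data.frame in the [read_blocks()] layout:
#'   `metabolite_id`, `function1..3` (blank = no annotation).
#' @param metabolites_present Character vector of metabolite ids present
#'   in the analysis matrix.
#' @return Named list of class `"block_map"` (block label -> character
#'   vector of member metabolites), with attribute `discarded` naming the
#'   blocks removed by the size filter.
#' @export
assign_blocks <- function(annotation, metabolites_present) {
  need <- c("metabolite_id", "function1", "function2", "function3")
  if (!all(need %in% names(annotation))) {
    stop("annotation must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ann <- annotation[annotation$metabolite_id %in% metabolites_present, ]
  long <- do.call(rbind, lapply(c("function1", "function2", "function3"),
    function(col) {
      data.frame(metabolite = ann$metabolite_id, block = ann[[col]],
                 stringsAsFactors = FALSE)
    }))
  long <- long[!is.na(long$block) & nzchar(long$block), ]
  dup <- duplicated(paste(long$metabolite, long$block))
  long <- long[!dup, ]
  per_met <- table(long$metabolite)
  if (any(per_met > 3L)) {
    stop("metabolite(s) annotated to more than three functions: ",
         paste(names(per_met)[per_met > 3L], collapse = ", "), call. = FALSE)
  }
  blocks <- split(long$metabolite, long$block)
  sizes <- lengths(blocks)
  discarded <- names(blocks)[sizes < 3L]
  blocks <- blocks[sizes >= 3L]
  if (length(blocks) == 0L) {
    stop("no block retains three or more member metabolites", call. = FALSE)
  }
  if (length(discarded) > 0L) {
    message(length(discarded), " block(s) discarded (<3 members): ",
            paste(discarded, collapse = ", "))
  }
  blocks <- blocks[order(names(blocks))]
  structure(blocks, class = "block_map", discarded = discarded)
}

#' @export
print.block_map <- function(x, ...) {
  cat(sprintf("Block map: %d retained blocks (sizes %s)\n", length(x),
              paste(range(lengths(x)), collapse = "-")))
  disc <- attr(x, "discarded")
  if (length(disc)) cat("  discarded (<3 members):",
                        paste(disc, collapse = ", "), "\n")
  invisible(x)
}

#' Weighted per-block OPLS-DA superscores
#'
#' Fits an OPLS-DA model (one predictive plus `n_orthogonal` orthogonal
#' components) on each block's member columns of the autoscaled matrix,
#' extracts the predictive score t1 (sign fixed by the largest-magnitude
#' weight), and scales it by a block weight accounting for block size:
#' \eqn{\omega_k = \sqrt{n_k} / \sqrt{\sum_m n_m}} (default, so
#' \eqn{\sum_k \omega_k^2 = 1}) or \eqn{\omega_k = n_k / \sum_m n_m}.
#' Blocks too degenerate for orthogonal filtering fall back to a plain
#' PLS-DA t1 with a warning.
#'
#' @param x Autoscaled feature matrix.
#' @param y Two-level class labels.
#' @param blocks A `"block_map"` from [assign_blocks()].
#' @param weighting `"sqrt"` (default) or `"linear"`.
#' @param n_orthogonal Orthogonal components per block model (default 1).
#' @return A samples x blocks matrix of class `"block_scores"` with
#'   attributes `weights`, `n_k` and `weighting`.
#' @export
block_superscores <- function(x, y, blocks, weighting = c("sqrt", "linear"),
                              n_orthogonal = 1L) {
  weighting <- match.arg(weighting)
  xs <- ensure_autoscaled(x)
  missing_cols <- setdiff(unique(unlist(blocks)), colnames(xs))
  if (length(missing_cols) > 0L) {
    stop("block members absent from the matrix: ",
         paste(utils::head(missing_cols, 5L), collapse = ", "), call. = FALSE)
  }
  n_k <- lengths(blocks)
  w_k <- switch(weighting,
                sqrt = sqrt(n_k) / sqrt(sum(n_k)),
                linear = n_k / sum(n_k))
  scores <- matrix(0, nrow(xs), length(blocks),
                   dimnames = list(rownames(xs), names(blocks)))
  for (k in seq_along(blocks)) {
    xb <- xs[, blocks[[k]], drop = FALSE]
    t1 <- tryCatch(
      oplsda(structure(xb, state = "autoscaled"), y,
             n_orthogonal = n_orthogonal)$scores[, 1L],
      error = function(e) {
        warning("block ", names(blocks)[k],
                ": OPLS-DA failed (", conditionMessage(e),
                "); falling back to PLS-DA t1", call. = FALSE)
        plsda(structure(xb, state = "autoscaled"), y, ncomp = 1L)$scores[, 1L]
      })
    scores[, k] <- w_k[k] * t1
  }
  structure(scores, class = c("block_scores", "matrix", "array"),
            weights = w_k, n_k = n_k, weighting = weighting,
            block_map = blocks, n_orthogonal = n_orthogonal)
}

#' @export
print.block_scores <- function(x, ...) {
  cat(sprintf("Block superscores: %d samples x %d blocks (%s weighting)\n",
              nrow(x), ncol(x), attr(x, "weighting")))
  invisible(x)
}

#' Sanity-check the blocked model against the unblocked one
#'
#' Fits a PLS-DA on the block superscores and compares its t1 with the
#' t1 of the unblocked model on the full autoscaled matrix. Reports the
#' sign-aligned Pearson correlation between the two score vectors, both
#' models' R2Y/Q2Y and permutation p-values, and a verdict: the blocked
#' representation is considered a similar mapping when |r| is at least
#' `r_threshold`.
#'
#' Because the superscores are themselves fitted to the class labels,
#' the blocked model's permutation test rebuilds the per-block OPLS-DA
#' superscores under every permuted labeling; permuting labels over the
#' fixed score matrix would inherit the original labels' overfitting and
#' overstate significance.
#'
#' @param x Autoscaled full feature matrix.
#' @param y Two-level class labels.
#' @param scores `"block_scores"` from [block_superscores()].
#' @param r_threshold Distortion flag threshold on |r| (default 0.7).
#' @param n_permutations Permutations for the validation tests.
#' @param ncomp Components for both PLS-DA models (capped at the number
#'   of blocks).
#' @param seed Optional seed.
#' @return List of class `"blocked_validation"`: `r`, `distorted`,
#'   `unblocked` and `blocked` permutation summaries.
#' @export
validate_blocked_model <- function(x, y, scores, r_threshold = 0.7,
                                   n_permutations = 200L, ncomp = 2L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xs <- ensure_autoscaled(x)
  enc <- encode_y(y)
  ncomp_b <- min(ncomp, ncol(scores), nrow(scores) - 1L)
  fit_un <- plsda(xs, y, ncomp = ncomp)
  fit_bl <- plsda(unclass(scores), y, ncomp = ncomp_b)
  r <- stats::cor(fit_un$scores[, 1L], fit_bl$scores[, 1L])
  perm_un <- permutation_test(xs, y, ncomp = ncomp,
                              n_permutations = n_permutations)
  bmap <- attr(scores, "block_map")
  if (is.null(bmap)) {
    stop("scores must come from block_superscores() (block map missing)",
         call. = FALSE)
  }
  obs_q2 <- cross_validate_q2(unclass(scores), enc$f, ncomp = ncomp_b)
  perm_r2 <- perm_q2 <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    yb <- sample(enc$f)
    sb <- unclass(suppressWarnings(block_superscores(
      xs, yb, bmap, weighting = attr(scores, "weighting"),
      n_orthogonal = attr(scores, "n_orthogonal"))))
    perm_r2[b] <- plsda(sb, yb, ncomp = ncomp_b)$R2Y
    perm_q2[b] <- cross_validate_q2(sb, yb, ncomp = ncomp_b)
  }
  perm_bl <- structure(list(
    R2Y = fit_bl$R2Y, Q2Y = obs_q2,
    permuted_R2Y = perm_r2, permuted_Q2Y = perm_q2,
    p_R2Y = (1 + sum(perm_r2 >= fit_bl$R2Y)) / (n_permutations + 1),
    p_Q2 = (1 + sum(perm_q2 >= obs_q2)) / (n_permutations + 1),
    n_permutations = n_permutations, ncomp = ncomp_b
  ), class = "plsda_permutation")
  structure(list(r = abs(r), distorted = abs(r) < r_threshold,
                 r_threshold = r_threshold,
                 unblocked = perm_un, blocked = perm_bl),
            class = "blocked_validation")
}

#' @export
print.blocked_validation <- function(x, ...) {
  cat("Blocked vs unblocked PLS-DA comparison\n")
  cat(sprintf("  |r(t1 blocked, t1 unblocked)| = %.3f -> %s\n", x$r,
              if (x$distorted) "DISTORTED mapping" else "similar mapping"))
  cat(sprintf("  unblocked: R2Y %.3f (p %.4f), Q2Y %.3f (p %.4f)\n",
              x$unblocked$R2Y, x$unblocked$p_R2Y,
              x$unblocked$Q2Y, x$unblocked$p_Q2))
  cat(sprintf("  blocked:   R2Y %.3f (p %.4f), Q2Y %.3f (p %.4f)\n",
              x$blocked$R2Y, x$blocked$p_R2Y,
              x$blocked$Q2Y, x$blocked$p_Q2))
  invisible(x)
}

#' Random-forest Gini importance of blocks
#'
#' Grows a classification forest of the block superscores against the
#' group label and ranks blocks by Mean Decrease Gini. The selection
#' threshold is read off a normality plot of the importances
#' ([normality_threshold()]), or can be forced manually.
#'
#' @param scores `"block_scores"` matrix.
#' @param y Two-level class labels.
#' @param n_trees Number of trees (default 500; fewer than 50 gives a
#'   warning about unstable importances).
#' @param seed Optional seed for the forest.
#' @param threshold Optional manual importance threshold.
#' @param k_sd,min_tail Passed to [normality_threshold()].
#' @return data.frame of class `"importance_table"` sorted by decreasing
#'   importance: `block`, `mean_decrease_gini`, `selected`; attribute
#'   `threshold`.
#' @export
random_forest_importance <- function(scores, y, n_trees = 500L, seed = NULL,
                                     threshold = NULL, k_sd = 2,
                                     min_tail = 1) {
  enc <- encode_y(y)
  if (n_trees < 50L) {
    warning("fewer than 50 trees gives unstable Gini importances",
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x = unclass(scores), y = enc$f,
                                   ntree = n_trees)
  gini <- rf$importance[, "MeanDecreaseGini"]
  if (is.null(threshold) && length(gini) < 10L) {
    warning("fewer than 10 blocks: the normality-plot rule is unreliable, ",
            "no block selected (set `threshold` manually to select)",
            call. = FALSE)
    threshold <- Inf
  }
  nt <- normality_threshold(gini, k_sd = k_sd, min_tail = min_tail,
                            threshold = threshold)
  out <- data.frame(block = colnames(scores),
                    mean_decrease_gini = as.numeric(gini),
                    selected = nt$selected,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_decrease_gini), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- nt$threshold
  class(out) <- c("importance_table", "data.frame")
  out
}

#' @export
print.importance_table <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf("Random-forest block importance: %d of %d blocks selected (threshold %s)\n",
              sum(x$selected), nrow(x),
              if (is.finite(thr)) format(thr, digits = 4) else "+Inf"))
  NextMethod()
}
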