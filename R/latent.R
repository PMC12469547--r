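# Sign convention used throughout: the largest-magnitude element of each
# weight vector is made positive, so scores and loadings are reproducible
# across runs and platforms.
fix_sign <- function(w) {
  if (w[which.max(abs(w))] < 0) -1 else 1
}

encode_y <- function(y) {
  f <- as.factor(as.character(y))
  if (nlevels(f) != 2L) {
    stop("PLS-DA requires exactly two classes; got ", nlevels(f), call. = FALSE)
  }
  if ("Term" %in% levels(f)) f <- stats::relevel(f, "Term")
  dummy <- as.numeric(f == levels(f)[2L])
  list(f = f, dummy = dummy, levels = levels(f))
}

ensure_autoscaled <- function(x) {
  x <- as.matrix(x)
  if (identical(attr(x, "state"), "autoscaled")) return(x)
  autoscale(x)
}

#' Fit a PLS-DA model by NIPALS
#'
#' Partial least squares discriminant analysis for a binary contrast: the
#' class is dummy-coded 0/1, centered, and regressed on the autoscaled
#' feature matrix by the NIPALS PLS1 algorithm. For component a, the
#' weight vector is \eqn{w_a \propto X_a^T y_a} (unit norm), scores
#' \eqn{t_a = X_a w_a}, X-loadings \eqn{p_a = X_a^T t_a / t_a^T t_a},
#' y-loading \eqn{c_a = y_a^T t_a / t_a^T t_a}, after which both X and y
#' are deflated. R2Y is the fraction of class variance explained.
#'
#' @param x Feature matrix (samples x features). Autoscaled input (from
#'   [autoscale()]) is used as is; anything else is autoscaled first and
#'   the scaling parameters are stored for prediction.
#' @param y Two-level class labels aligned with rows of `x`. If one of
#'   the levels is `"Term"` it is used as the reference (coded 0).
#' @param ncomp Number of predictive components (default 2).
#' @return An object of class `"plsda"`: list with `weights`, `loadings`,
#'   `scores`, `y_loadings`, `R2Y`, `ssy` (per-component explained class
#'   sum of squares), `center`, `scale`, `levels`, `y`, `fitted`.
#' @seealso [oplsda()], [vip()], [cross_validate_q2()],
#'   [permutation_test()]
#' @examples
#' x <- matrix(rnorm(40 * 6), 40, 6)
#' x[1:20, 1] <- x[1:20, 1] + 2
#' fit <- plsda(x, rep(c("A", "B"), each = 20))
#' fit$R2Y
#' @export
plsda <- function(x, y, ncomp = 2L) {
  xs <- ensure_autoscaled(x)
  enc <- encode_y(y)
  if (length(enc$dummy) != nrow(xs)) {
    stop("length of y must match the number of samples", call. = FALSE)
  }
  if (ncomp < 1L) stop("ncomp must be at least 1", call. = FALSE)
  rank_bound <- min(nrow(xs) - 1L, ncol(xs))
  if (ncomp > rank_bound) {
    stop("ncomp exceeds the rank bound min(n - 1, p) = ", rank_bound,
         call. = FALSE)
  }
  y0 <- enc$dummy - mean(enc$dummy)
  Xa <- xs; ya <- y0
  p <- ncol(xs)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, nrow(xs), ncomp)
  C <- ssy <- numeric(ncomp)
  tol <- 1e-12 * sum(y0^2)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 || sum(ya^2) < tol) {
      stop("component ", a, " exceeds the effective rank of X'y; ",
           "reduce ncomp", call. = FALSE)
    }
    w <- w / nw
    s <- fix_sign(w)
    w <- s * w
    t <- drop(Xa %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) {
      stop("component ", a, " has a degenerate score; reduce ncomp",
           call. = FALSE)
    }
    pl <- drop(crossprod(Xa, t)) / tt
    cc <- sum(ya * t) / tt
    Xa <- Xa - tcrossprod(t, pl)
    ya <- ya - cc * t
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; C[a] <- cc
    ssy[a] <- cc^2 * tt
  }
  dimnames(W) <- dimnames(P) <- list(colnames(xs), paste0("comp", seq_len(ncomp)))
  dimnames(Tm) <- list(rownames(xs), paste0("comp", seq_len(ncomp)))
  fitted_y <- drop(Tm %*% C) + mean(enc$dummy)
  structure(list(
    kind = "plsda",
    n_predictive = ncomp, n_orthogonal = 0L,
    weights = W, loadings = P, scores = Tm, y_loadings = C,
    ssy = ssy,
    R2Y = 1 - sum(ya^2) / sum(y0^2),
    center = attr(xs, "center"), scale = attr(xs, "scale"),
    levels = enc$levels, y = enc$f, y_mean = mean(enc$dummy),
    fitted = fitted_y
  ), class = "plsda")
}

#' Fit an OPLS-DA model (Trygg-Wold orthogonal filtering)
#'
#' Two-class orthogonal PLS-DA with one predictive component. For each of
#' `n_orthogonal` rounds, the y-predictive weight \eqn{w \propto X^T y}
#' is computed, the X-loading of its score is split into a part collinear
#' with w and an orthogonal remainder \eqn{w_o \propto p - (w^T p) w},
#' and the orthogonal score \eqn{t_o = X w_o} is deflated from X. The
#' final predictive score t1 is computed from the filtered matrix and is
#' orthogonal to every orthogonal score by construction.
#'
#' @inheritParams plsda
#' @param n_orthogonal Number of orthogonal components to remove
#'   (default 1).
#' @return An object of class `c("oplsda", "plsda")` with the predictive
#'   `weights`/`loadings`/`scores`/`y_loadings` (one component) plus
#'   `orthogonal_weights`, `orthogonal_loadings`, `orthogonal_scores`.
#' @export
oplsda <- function(x, y, n_orthogonal = 1L) {
  xs <- ensure_autoscaled(x)
  enc <- encode_y(y)
  if (n_orthogonal < 0L) stop("n_orthogonal must be non-negative", call. = FALSE)
  rank_bound <- min(nrow(xs) - 1L, ncol(xs))
  if (rank_bound < n_orthogonal + 1L) {
    stop("rank of X too small for ", n_orthogonal,
         " orthogonal + 1 predictive component", call. = FALSE)
  }
  y0 <- enc$dummy - mean(enc$dummy)
  p <- ncol(xs)
  Xa <- xs
  Wo <- Po <- matrix(0, p, n_orthogonal)
  To <- matrix(0, nrow(xs), n_orthogonal)
  k <- 0L
  while (k < n_orthogonal) {
    w <- drop(crossprod(Xa, y0))
    w <- w / sqrt(sum(w^2))
    t <- drop(Xa %*% w)
    pl <- drop(crossprod(Xa, t)) / sum(t^2)
    wo <- pl - sum(w * pl) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) break  # no orthogonal structure left to remove
    wo <- wo / nwo
    wo <- fix_sign(wo) * wo
    to <- drop(Xa %*% wo)
    po <- drop(crossprod(Xa, to)) / sum(to^2)
    Xa <- Xa - tcrossprod(to, po)
    k <- k + 1L
    Wo[, k] <- wo; Po[, k] <- po; To[, k] <- to
  }
  Wo <- Wo[, seq_len(k), drop = FALSE]
  Po <- Po[, seq_len(k), drop = FALSE]
  To <- To[, seq_len(k), drop = FALSE]
  w <- drop(crossprod(Xa, y0))
  w <- w / sqrt(sum(w^2))
  s <- fix_sign(w)
  w <- s * w
  t1 <- drop(Xa %*% w)
  tt <- sum(t1^2)
  pl <- drop(crossprod(Xa, t1)) / tt
  cc <- sum(y0 * t1) / tt
  dimnames(To) <- list(rownames(xs), if (k) paste0("ortho", seq_len(k)))
  structure(list(
    kind = "oplsda",
    n_predictive = 1L, n_orthogonal = k,
    weights = matrix(w, p, 1, dimnames = list(colnames(xs), "comp1")),
    loadings = matrix(pl, p, 1, dimnames = list(colnames(xs), "comp1")),
    scores = matrix(t1, nrow(xs), 1, dimnames = list(rownames(xs), "comp1")),
    y_loadings = cc,
    ssy = cc^2 * tt,
    orthogonal_weights = Wo, orthogonal_loadings = Po,
    orthogonal_scores = To,
    R2Y = 1 - sum((y0 - cc * t1)^2) / sum(y0^2),
    center = attr(xs, "center"), scale = attr(xs, "scale"),
    levels = enc$levels, y = enc$f, y_mean = mean(enc$dummy),
    fitted = cc * t1 + mean(enc$dummy)
  ), class = c("oplsda", "plsda"))
}

#' Variable importance in projection scores
#'
#' VIP for feature j over the predictive components of a fitted model:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a w_{aj}^2 / \sum_a SSY_a}}
#' with \eqn{SSY_a = c_a^2 t_a^T t_a} and p the number of features, so
#' the squared scores average to 1.
#'
#' @param model A fitted [plsda()] or [oplsda()] model.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  if (!inherits(model, "plsda")) stop("vip() needs a fitted plsda/oplsda model",
                                      call. = FALSE)
  W <- model$weights
  ssy <- model$ssy
  p <- nrow(W)
  wt <- sweep(W^2, 2L, ssy, "*")
  stats::setNames(sqrt(p * rowSums(wt) / sum(ssy)), rownames(W))
}

make_stratified_folds <- function(f, n_folds) {
  fold <- integer(length(f))
  for (lv in levels(f)) {
    idx <- which(f == lv)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Cross-validated Q2Y of a PLS-DA model
#'
#' Stratified k-fold cross-validation of the centered dummy response:
#' \eqn{Q2Y = 1 - PRESS / SS_{tot}}, where PRESS accumulates squared
#' out-of-fold prediction errors. Column centering and scaling are
#' re-estimated on each training fold and applied to the held-out fold,
#' so no scaling information leaks from the test samples.
#'
#' @inheritParams plsda
#' @param n_folds Number of folds (default 7).
#' @param seed Optional integer seed for the fold assignment.
#' @return Q2Y (a scalar; at most 1, negative when the model predicts
#'   worse than the class mean).
#' @export
cross_validate_q2 <- function(x, y, ncomp = 2L, n_folds = 7L, seed = NULL) {
  x <- as.matrix(x)
  enc <- encode_y(y)
  if (!is.null(seed)) set.seed(seed)
  dummy <- enc$dummy
  for (try in 1:25) {
    fold <- make_stratified_folds(enc$f, n_folds)
    ok <- all(vapply(seq_len(n_folds), function(k) {
      length(unique(enc$f[fold != k])) == 2L
    }, logical(1)))
    if (ok) break
    if (try == 25) stop("could not build folds with both classes in every ",
                        "training split", call. = FALSE)
  }
  press <- 0
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    if (!any(!tr)) next
    xtr <- x[tr, , drop = FALSE]
    ctr <- colMeans(xtr)
    sds <- apply(xtr, 2L, stats::sd)
    sds[sds <= 0 | !is.finite(sds)] <- 1
    fit <- plsda(structure(apply_scaling(xtr, ctr, sds), state = "autoscaled"),
                 enc$f[tr], ncomp = ncomp)
    xte <- apply_scaling(x[!tr, , drop = FALSE], ctr, sds)
    pred <- predict_dummy(fit, xte)
    press <- press + sum((dummy[!tr] - pred)^2)
  }
  1 - press / sum((dummy - mean(dummy))^2)
}

# Predict the dummy-coded response for already-scaled new data.
predict_dummy <- function(model, x_scaled) {
  W <- model$weights; P <- model$loadings; C <- model$y_loadings
  Wstar <- W %*% solve(crossprod(P, W))
  drop(x_scaled %*% Wstar %*% C) + model$y_mean
}

#' Permutation validation of a PLS-DA model
#'
#' Refits the model under `n_permutations` uniformly permuted class
#' labels, recording R2Y and cross-validated Q2Y each time (folds are
#' re-drawn per permutation). Permutation p-values use the add-one
#' estimator \eqn{(1 + \#\{perm \ge obs\}) / (B + 1)}, so they are never
#' zero.
#'
#' @inheritParams cross_validate_q2
#' @param n_permutations Number of label permutations (default 200).
#' @return An object of class `"plsda_permutation"`: list with
#'   `R2Y`, `Q2Y`, `permuted_R2Y`, `permuted_Q2Y`, `p_R2Y`, `p_Q2`,
#'   `n_permutations`.
#' @export
permutation_test <- function(x, y, ncomp = 2L, n_permutations = 200L,
                             n_folds = 7L, seed = NULL) {
  if (n_permutations < 1L) stop("n_permutations must be at least 1",
                                call. = FALSE)
  x <- as.matrix(x)
  enc <- encode_y(y)
  if (!is.null(seed)) set.seed(seed)
  obs_fit <- plsda(x, enc$f, ncomp = ncomp)
  obs_q2 <- cross_validate_q2(x, enc$f, ncomp = ncomp, n_folds = n_folds)
  perm_r2 <- perm_q2 <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    yb <- sample(enc$f)
    perm_r2[b] <- plsda(x, yb, ncomp = ncomp)$R2Y
    perm_q2[b] <- cross_validate_q2(x, yb, ncomp = ncomp, n_folds = n_folds)
  }
  structure(list(
    R2Y = obs_fit$R2Y, Q2Y = obs_q2,
    permuted_R2Y = perm_r2, permuted_Q2Y = perm_q2,
    p_R2Y = (1 + sum(perm_r2 >= obs_fit$R2Y)) / (n_permutations + 1),
    p_Q2 = (1 + sum(perm_q2 >= obs_q2)) / (n_permutations + 1),
    n_permutations = n_permutations, ncomp = ncomp
  ), class = "plsda_permutation")
}

#' @export
print.plsda_permutation <- function(x, ...) {
  cat(sprintf("Permutation validation (%d permutations, %d components)\n",
              x$n_permutations, x$ncomp))
  cat(sprintf("  R2Y = %.3f (p = %.4f)   Q2Y = %.3f (p = %.4f)\n",
              x$R2Y, x$p_R2Y, x$Q2Y, x$p_Q2))
  invisible(x)
}

#' Normality-plot threshold for non-negative importance scores
#'
#' Operationalizes the visual rule of reading a selection threshold off a
#' normal probability plot. Scores are sorted against Blom plotting
#' positions, a reference line is fitted by least squares to the central
#' `central` fraction of points, and a point is flagged as deviating when
#' its residual above the line exceeds `k_sd` pointwise order-statistic
#' standard errors (the classic QQ confidence band, which widens in the
#' tails). The threshold is placed at the largest gap between consecutive
#' sorted scores adjoining the deviating upper tail, so a detached cloud
#' of outliers is separated from the bulk even when the outliers distort
#' the bulk's plotting positions. If no upper-tail point deviates (or
#' fewer than `min_tail` do), the threshold is `+Inf` and nothing is
#' selected.
#'
#' @param scores Non-negative numeric scores (VIP, Gini importance,
#'   betweenness, ...); at least 10 values.
#' @param k_sd Band width multiplier (default 2).
#' @param min_tail Minimum size of the deviating suffix needed before any
#'   selection is made (default 1).
#' @param central Fraction of central points used to fit the reference
#'   line (default 0.5).
#' @param threshold Optional manual threshold overriding the automatic
#'   rule (e.g. the conventional VIP cut-offs 1.5 or 1.4).
#' @return An object of class `"normality_threshold"`: list with
#'   `threshold`, `selected` (logical, input order), `n_selected`, and
#'   the QQ fit pieces (`sorted`, `quantiles`, `fit`, `band`).
#' @export
normality_threshold <- function(scores, k_sd = 2, min_tail = 1,
                                central = 0.5, threshold = NULL) {
  scores <- as.numeric(scores)
  if (!is.null(threshold)) {
    sel <- scores >= threshold
    return(structure(list(threshold = threshold, selected = sel,
                          n_selected = sum(sel), manual = TRUE),
                     class = "normality_threshold"))
  }
  n <- length(scores)
  if (n < 10L) {
    stop("need at least 10 scores for the normality-plot rule; ",
         "supply a manual threshold instead", call. = FALSE)
  }
  o <- order(scores)
  xs <- scores[o]
  pp <- (seq_len(n) - 3 / 8) / (n + 1 / 4)
  q <- stats::qnorm(pp)
  lo <- floor(n * (1 - central) / 2) + 1L
  hi <- n - lo + 1L
  idx <- lo:hi
  fit <- stats::lm.fit(cbind(1, q[idx]), xs[idx])
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  r <- xs - (a + b * q)
  band <- abs(b) * sqrt(pp * (1 - pp) / n) / stats::dnorm(q)
  dev <- r > k_sd * band
  j <- n + 1L
  for (i in n:1) { if (dev[i]) j <- i else break }
  if (j > n || (n + 1L - j) < min_tail) {
    thr <- Inf
  } else {
    seg <- max(j - 1L, 1L):n
    cut <- seg[which.max(diff(xs[seg]))] + 1L
    thr <- xs[cut]
  }
  sel <- scores >= thr
  structure(list(threshold = thr, selected = sel, n_selected = sum(sel),
                 manual = FALSE, sorted = xs, quantiles = q,
                 fit = c(intercept = unname(a), slope = unname(b)),
                 band = band, k_sd = k_sd),
            class = "normality_threshold")
}

#' @export
print.normality_threshold <- function(x, ...) {
  cat(sprintf("Normality-plot threshold: %s (%d selected%s)\n",
              if (is.finite(x$threshold)) format(x$threshold, digits = 4)
              else "+Inf",
              x$n_selected, if (isTRUE(x$manual)) ", manual" else ""))
  invisible(x)
}

#' @export
plot.normality_threshold <- function(x, ...) {
  if (isTRUE(x$manual)) {
    stop("nothing to plot for a manual threshold", call. = FALSE)
  }
  graphics::plot(x$quantiles, x$sorted, pch = 16,
                 col = ifelse(x$sorted >= x$threshold, "red", "grey30"),
                 xlab = "theoretical normal quantile", ylab = "score", ...)
  graphics::abline(x$fit["intercept"], x$fit["slope"], col = "blue")
  if (is.finite(x$threshold)) graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}
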