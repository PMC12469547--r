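#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("%s model: %d predictive component(s)",
              toupper(sub("plsda", "PLS-DA", sub("oplsda", "OPLS-DA", x$kind))),
              x$n_predictive))
  if (x$n_orthogonal > 0L) cat(sprintf(" + %d orthogonal", x$n_orthogonal))
  cat("\n")
  cat(sprintf("  classes: %s (reference) vs %s\n", x$levels[1], x$levels[2]))
  cat(sprintf("  %d samples, %d features, R2Y = %.3f\n",
              nrow(x$scores), nrow(x$weights), x$R2Y))
  invisible(x)
}

#' @export
summary.plsda <- function(object, ...) {
  v <- vip(object)
  out <- list(kind = object$kind, n_predictive = object$n_predictive,
              n_orthogonal = object$n_orthogonal, R2Y = object$R2Y,
              ssy = object$ssy, levels = object$levels,
              top_vip = sort(v, decreasing = TRUE)[seq_len(min(10, length(v)))])
  class(out) <- "summary.plsda"
  out
}

#' @export
print.summary.plsda <- function(x, ...) {
  cat(sprintf("%s: R2Y = %.3f (%s vs %s)\n", x$kind, x$R2Y,
              x$levels[1], x$levels[2]))
  cat("  per-component explained class SS:",
      paste(format(x$ssy, digits = 3), collapse = ", "), "\n")
  cat("  top VIP features:\n")
  print(round(x$top_vip, 3))
  invisible(x)
}

#' Regression coefficients of a fitted PLS-DA model
#'
#' Coefficients mapping autoscaled features to the centered dummy
#' response, \eqn{B = W (P^T W)^{-1} c}.
#'
#' @param object A fitted [plsda()] or [oplsda()] model.
#' @param ... Unused.
#' @export
coef.plsda <- function(object, ...) {
  B <- object$weights %*% solve(crossprod(object$loadings, object$weights)) %*%
    matrix(object$y_loadings, ncol = 1)
  stats::setNames(drop(B), rownames(object$weights))
}

#' Predict group membership for new samples
#'
#' @param object A fitted [plsda()] or [oplsda()] model.
#' @param newdata Matrix of raw (unscaled) intensities with the model's
#'   feature columns; the training centering/scaling is applied.
#' @param type `"class"` for predicted labels, `"response"` for the
#'   dummy-scale prediction, `"scores"` for projected predictive scores.
#' @param ... Unused.
#' @export
predict.plsda <- function(object, newdata,
                          type = c("class", "response", "scores"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)[, rownames(object$weights), drop = FALSE]
  xs <- apply_scaling(x, object$center, object$scale)
  if (type == "scores") {
    W <- object$weights; P <- object$loadings
    Wstar <- W %*% solve(crossprod(P, W))
    return(xs %*% Wstar)
  }
  yhat <- predict_dummy(object, xs)
  if (type == "response") return(yhat)
  factor(object$levels[(yhat > 0.5) + 1L], levels = object$levels)
}

#' @export
residuals.plsda <- function(object, ...) {
  dummy <- as.numeric(object$y == object$levels[2L])
  dummy - object$fitted
}

#' @export
fitted.plsda <- function(object, ...) object$fitted

#' Score plot of a fitted PLS-DA / OPLS-DA model
#'
#' Plots t1 against the second predictive component (PLS-DA with
#' `ncomp >= 2`) or against the first orthogonal score (OPLS-DA), with
#' samples coloured by class.
#'
#' @param x A fitted model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.plsda <- function(x, ...) {
  t1 <- x$scores[, 1L]
  if (x$n_predictive >= 2L) {
    t2 <- x$scores[, 2L]; ylab <- "t2"
  } else if (x$n_orthogonal >= 1L) {
    t2 <- x$orthogonal_scores[, 1L]; ylab <- "t1 orthogonal"
  } else {
    t2 <- seq_along(t1); ylab <- "sample index"
  }
  col <- c("#3366CC", "#CC3333")[as.integer(x$y)]
  graphics::plot(t1, t2, col = col, pch = 16, xlab = "t1", ylab = ylab, ...)
  graphics::legend("topright", legend = x$levels, col = c("#3366CC", "#CC3333"),
                   pch = 16, bty = "n")
  invisible(x)
}
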