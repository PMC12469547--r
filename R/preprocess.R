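#' Probabilistic quotient normalization
#'
#' Removes per-sample multiplicative dilution from a strictly positive
#' intensity matrix. The reference spectrum is the per-metabolite median
#' across all samples (both groups pooled, the standard choice); each
#' sample's dilution coefficient is the median over metabolites of its
#' intensity-to-reference quotients, and the sample's row is divided by
#' that coefficient.
#'
#' @param x Numeric matrix, samples x metabolites, strictly positive.
#'   Missing or non-positive values are refused: impute or filter
#'   upstream before normalizing.
#' @param reference Either `"median"` (pooled per-metabolite median) or a
#'   numeric vector of length `ncol(x)` supplying the reference spectrum.
#' @return An object of class `"pqn_result"`: list with `normalized`
#'   (matrix, attribute `state = "pqn"`), `reference_spectrum` and
#'   `dilution_coefficients`.
#' @examples
#' x <- rbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4))
#' pqn_normalize(x)$dilution_coefficients
#' @export
pqn_normalize <- function(x, reference = "median") {
  x <- as.matrix(x)
  if (anyNA(x)) {
    stop("missing intensities: impute or filter upstream before PQN",
         call. = FALSE)
  }
  if (any(x <= 0)) {
    stop("non-positive intensities: filter or impute upstream before PQN",
         call. = FALSE)
  }
  if (is.character(reference)) {
    reference <- match.arg(reference, "median")
    ref <- if (nrow(x) >= 2L) apply(x, 2L, stats::median) else as.numeric(x[1L, ])
  } else {
    if (length(reference) != ncol(x)) {
      stop("numeric reference must have one entry per metabolite", call. = FALSE)
    }
    ref <- as.numeric(reference)
  }
  usable <- ref > 0
  if (!any(usable)) stop("reference spectrum is all zero", call. = FALSE)
  q <- sweep(x[, usable, drop = FALSE], 2L, ref[usable], "/")
  coef <- apply(q, 1L, stats::median)
  normalized <- x / coef
  attr(normalized, "state") <- "pqn"
  structure(list(normalized = normalized,
                 reference_spectrum = stats::setNames(ref, colnames(x)),
                 dilution_coefficients = stats::setNames(coef, rownames(x))),
            class = "pqn_result")
}

#' @export
print.pqn_result <- function(x, ...) {
  cat("PQN normalization\n")
  cat(sprintf("  %d samples x %d metabolites\n",
              nrow(x$normalized), ncol(x$normalized)))
  cat(sprintf("  dilution coefficients: median %.3f, range [%.3f, %.3f]\n",
              stats::median(x$dilution_coefficients),
              min(x$dilution_coefficients), max(x$dilution_coefficients)))
  invisible(x)
}

#' Autoscale a feature matrix
#'
#' Centers each metabolite to mean 0 and scales it to unit sample
#' standard deviation (n - 1 denominator). Constant columns cannot be
#' scaled and are dropped with a warning. The centering and scaling
#' vectors are retained as attributes so held-out samples can be placed
#' on the same scale with [apply_scaling()].
#'
#' @param x Numeric matrix with at least two rows.
#' @return The scaled matrix with attributes `center`, `scale` and
#'   `state = "autoscaled"`.
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    stop("autoscaling needs at least two samples (sd undefined)",
         call. = FALSE)
  }
  ctr <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  const <- sds <= 0 | !is.finite(sds)
  if (any(const)) {
    warning("dropping ", sum(const), " constant column(s): ",
            paste(utils::head(colnames(x)[const], 5L), collapse = ", "),
            call. = FALSE)
    x <- x[, !const, drop = FALSE]
    ctr <- ctr[!const]; sds <- sds[!const]
  }
  if (ncol(x) == 0L) stop("all columns constant; nothing to scale", call. = FALSE)
  out <- sweep(sweep(x, 2L, ctr, "-"), 2L, sds, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sds
  attr(out, "state") <- "autoscaled"
  out
}

#' Apply stored autoscaling parameters to new samples
#'
#' @param x Matrix of new samples (columns matching the training matrix).
#' @param center,scale Numeric vectors, e.g. the `center` and `scale`
#'   attributes of an [autoscale()] result.
#' @return Scaled matrix.
#' @export
apply_scaling <- function(x, center, scale) {
  x <- as.matrix(x)
  sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
}
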