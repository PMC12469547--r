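#' Shrinkage partial correlations of block superscores
#'
#' Estimates the Gaussian graphical model of one group's block scores.
#' The sample correlation matrix R is shrunk toward the identity,
#' \eqn{R^* = \lambda I + (1 - \lambda) R}, with the analytic
#' Schafer-Strimmer/Ledoit-Wolf intensity
#' \eqn{\lambda^* = \sum_{i \ne j} \widehat{Var}(r_{ij}) /
#' \sum_{i \ne j} r_{ij}^2} clipped to \[0, 1\]; partial correlations
#' come from the inverse, \eqn{pcor_{ij} = -\Omega_{ij} /
#' \sqrt{\Omega_{ii}\Omega_{jj}}} with \eqn{\Omega = (R^*)^{-1}}.
#'
#' @param x Numeric matrix (samples of one group x blocks); at least 5
#'   samples and 3 blocks.
#' @param lambda Optional shrinkage override in \[0, 1\] (0 = no
#'   shrinkage, 1 = diagonal).
#' @return List with `pcor` (partial-correlation matrix), `lambda`, and
#'   `n` (sample count).
#' @export
shrinkage_partial_correlation <- function(x, lambda = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); G <- ncol(x)
  if (n < 5L) stop("need at least 5 samples per group", call. = FALSE)
  if (G < 3L) stop("need at least 3 blocks", call. = FALSE)
  R <- stats::cor(x)
  if (is.null(lambda)) {
    # Var-hat(r_ij) from the standardized cross-products w_kij.
    xs <- scale(x) / sqrt(n - 1)          # so crossprod(xs) = R
    num <- 0; den <- 0
    w_bar_fac <- n / ((n - 1)^3)
    xc <- scale(x)
    for (i in seq_len(G - 1L)) {
      wi <- xc[, i]
      for (j in (i + 1L):G) {
        w <- wi * xc[, j]
        num <- num + w_bar_fac * sum((w - mean(w))^2)
        den <- den + R[i, j]^2
      }
    }
    lambda <- if (den > 0) min(max(num / den, 0), 1) else 1
  }
  Rstar <- (1 - lambda) * R
  diag(Rstar) <- 1
  Om <- tryCatch(solve(Rstar), error = function(e) {
    stop("shrunken correlation matrix is singular; raise the lambda floor",
         call. = FALSE)
  })
  d <- sqrt(diag(Om))
  pcor <- -Om / tcrossprod(d)
  diag(pcor) <- 1
  dimnames(pcor) <- dimnames(R)
  list(pcor = pcor, lambda = lambda, n = n)
}

#' Edge p-values from the analytic null of partial correlations
#'
#' Two-sided p-values under the null density of sample partial
#' correlations, \eqn{f_0(r;\kappa) \propto (1-r^2)^{(\kappa-3)/2}} with
#' \eqn{\kappa = n - (G - 2) - 1} degrees of freedom (floored at 3),
#' using the Beta representation \eqn{r^2 \sim Beta(1/2, (\kappa-1)/2)}.
#'
#' @param pcor Partial-correlation matrix (entries in \[-1, 1\]).
#' @param n_samples Sample count behind the estimate.
#' @param n_nodes Number of nodes G (default `ncol(pcor)`).
#' @return Matrix of p-values (diagonal NA).
#' @export
edge_pvalues <- function(pcor, n_samples, n_nodes = ncol(pcor)) {
  kappa <- max(n_samples - (n_nodes - 2) - 1, 3)
  p <- stats::pbeta(pcor^2, 1 / 2, (kappa - 1) / 2, lower.tail = FALSE)
  p[pcor^2 >= 1] <- 0
  diag(p) <- NA_real_
  p
}

edge_table <- function(pcor, p) {
  G <- ncol(pcor)
  idx <- which(upper.tri(pcor), arr.ind = TRUE)
  nodes <- colnames(pcor)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(G))
  data.frame(node_a = nodes[idx[, 1L]], node_b = nodes[idx[, 2L]],
             pcor = pcor[idx], p = p[idx], stringsAsFactors = FALSE)
}

#' Build a full partial-correlation network for one group
#'
#' @param scores Block-score matrix restricted to one group's samples.
#' @param lambda Optional shrinkage override (see
#'   [shrinkage_partial_correlation()]).
#' @return Object of class `"metab_network"`: list with `nodes`, `edges`
#'   (`node_a`, `node_b`, `pcor`, `p`), `kind = "full"`, `lambda`, `n`.
#' @export
build_network <- function(scores, lambda = NULL) {
  sp <- shrinkage_partial_correlation(scores, lambda = lambda)
  p <- edge_pvalues(sp$pcor, sp$n)
  structure(list(nodes = colnames(sp$pcor),
                 edges = edge_table(sp$pcor, p),
                 kind = "full", lambda = sp$lambda, n = sp$n),
            class = "metab_network")
}

#' @export
print.metab_network <- function(x, ...) {
  cat(sprintf("%s network: %d nodes, %d edges", x$kind, length(x$nodes),
              nrow(x$edges)))
  if (!is.null(x$lambda)) cat(sprintf(" (lambda = %.3f)", x$lambda))
  cat("\n")
  if (!is.null(x$betweenness)) {
    top <- sort(x$betweenness, decreasing = TRUE)
    top <- top[top > 0]
    if (length(top)) {
      cat("  top betweenness:",
          paste(sprintf("%s=%.1f", names(utils::head(top, 5)),
                        utils::head(top, 5)), collapse = ", "), "\n")
    }
  }
  invisible(x)
}

order_edges <- function(edges) {
  edges[order(edges$p, -abs(edges$pcor), edges$node_a, edges$node_b), ,
        drop = FALSE]
}

#' Minimal network: fewest interactions covering every node
#'
#' Edges are ranked by ascending p-value (ties: |pcor| descending, then
#' lexicographic pair). The shortest prefix of that ranking in which
#' every node is incident to at least one retained edge is kept
#' (`criterion = "coverage"`, default); `"connectivity"` instead extends
#' the prefix until the retained graph is a single connected component.
#'
#' @param full A `"metab_network"` with all-pairs edges.
#' @param criterion `"coverage"` or `"connectivity"`.
#' @return A `"metab_network"` of kind `"minimal"`.
#' @export
minimal_network <- function(full, criterion = c("coverage", "connectivity")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(full, "metab_network"))
  edges <- order_edges(full$edges)
  nodes <- full$nodes
  if (length(nodes) == 1L || nrow(edges) == 0L) {
    keep <- edges[integer(0), ]
  } else if (criterion == "coverage") {
    covered <- stats::setNames(rep(FALSE, length(nodes)), nodes)
    cut <- nrow(edges)
    for (i in seq_len(nrow(edges))) {
      covered[edges$node_a[i]] <- TRUE
      covered[edges$node_b[i]] <- TRUE
      if (all(covered)) { cut <- i; break }
    }
    keep <- edges[seq_len(cut), , drop = FALSE]
  } else {
    g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
    igraph::V(g)$name <- nodes
    cut <- nrow(edges)
    for (i in seq_len(nrow(edges))) {
      g <- igraph::add_edges(g, c(edges$node_a[i], edges$node_b[i]))
      if (igraph::components(g)$no == 1L) { cut <- i; break }
    }
    keep <- edges[seq_len(cut), , drop = FALSE]
  }
  rownames(keep) <- NULL
  structure(list(nodes = nodes, edges = keep, kind = "minimal",
                 criterion = criterion, lambda = full$lambda, n = full$n),
            class = "metab_network")
}

edge_keys <- function(edges) {
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  paste(a, b, sep = "--")
}

#' Differential (Prem-specific) network
#'
#' Subtracts the Term group's minimal interactions from the Prem group's:
#' the differential edge set is `edges(prem) \ edges(term)` as unordered
#' pairs, with edge attributes taken from the Prem network. All nodes are
#' kept (possibly isolated), and unweighted shortest-path betweenness
#' centrality is attached per node.
#'
#' @param prem,term Minimal `"metab_network"`s over the same node set.
#' @return A `"metab_network"` of kind `"differential"` with a
#'   `betweenness` element.
#' @export
differential_network <- function(prem, term) {
  stopifnot(inherits(prem, "metab_network"), inherits(term, "metab_network"))
  if (!setequal(prem$nodes, term$nodes)) {
    stop("the two networks must share the same node set", call. = FALSE)
  }
  keep <- !(edge_keys(prem$edges) %in% edge_keys(term$edges))
  edges <- prem$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  net <- structure(list(nodes = prem$nodes, edges = edges,
                        kind = "differential", lambda = prem$lambda,
                        n = prem$n),
                   class = "metab_network")
  net$betweenness <- betweenness_centrality(net)
  net
}

#' Betweenness centrality of a network's nodes
#'
#' Unweighted shortest-path betweenness (Brandes algorithm via igraph),
#' counting each unordered pair once, with no normalization; pairs in
#' different components contribute nothing.
#'
#' @param net A `"metab_network"`.
#' @return Named numeric vector over all nodes (isolated nodes get 0).
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "metab_network"))
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  igraph::V(g)$name <- net$nodes
  if (nrow(net$edges) > 0L) {
    g <- igraph::add_edges(g, rbind(net$edges$node_a, net$edges$node_b))
  }
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  stats::setNames(as.numeric(b), net$nodes)
}

#' Select hub blocks from betweenness scores
#'
#' Applies the normality-plot threshold to the betweenness centralities
#' of a differential network and returns the blocks at or above the
#' threshold in decreasing order.
#'
#' @param betweenness Named numeric vector (>= 10 nodes unless a manual
#'   `threshold` is given).
#' @param threshold Optional manual threshold.
#' @param k_sd,min_tail Passed to [normality_threshold()].
#' @return List with `hubs` (character, descending betweenness),
#'   `threshold` and the full `selector` object.
#' @export
select_hub_blocks <- function(betweenness, threshold = NULL, k_sd = 2,
                              min_tail = 1) {
  if (is.null(threshold) && length(betweenness) < 10L) {
    stop("fewer than 10 nodes: supply a manual threshold", call. = FALSE)
  }
  nt <- normality_threshold(betweenness, k_sd = k_sd, min_tail = min_tail,
                            threshold = threshold)
  sel <- betweenness[nt$selected]
  list(hubs = names(sort(sel, decreasing = TRUE)), threshold = nt$threshold,
       selector = nt)
}
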