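# Shared fixtures and independent oracles, built in code at test time.

# Small two-class matrix with a mean shift on the first `n_signal` columns.
make_two_class <- function(n_per_class = 15, p = 6, shift = 2, n_signal = 2,
                           seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  grp <- rep(c("Term", "Prem"), each = n_per_class)
  x[grp == "Prem", seq_len(n_signal)] <- x[grp == "Prem", seq_len(n_signal)] + shift
  colnames(x) <- paste0("f", seq_len(p))
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  list(x = x, groups = factor(grp, levels = c("Term", "Prem")))
}

edge_keys_of <- function(edges) {
  paste(pmin(edges$node_a, edges$node_b), pmax(edges$node_a, edges$node_b),
        sep = "--")
}

# Build a metab_network object by hand from an edge table.
toy_network <- function(nodes, edges, kind = "full") {
  structure(list(nodes = nodes, edges = edges, kind = kind,
                 lambda = NULL, n = NA_integer_),
            class = "metab_network")
}

# Brute-force betweenness via minimal-length walk counts from adjacency
# powers: walks of the geodesic length are exactly the geodesics.
brute_betweenness <- function(nodes, edges) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      A[edges$node_a[r], edges$node_b[r]] <- 1
      A[edges$node_b[r], edges$node_a[r]] <- 1
    }
  }
  pow <- vector("list", n)
  pow[[1]] <- A
  for (d in seq_len(n - 1)[-1]) pow[[d]] <- pow[[d - 1]] %*% A
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  for (d in seq_len(n - 1)) {
    reached <- pow[[d]] > 0 & !is.finite(dist)
    dist[reached] <- d
  }
  sigma <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(dist[i, j])) sigma[i, j] <- pow[[dist[i, j]]][i, j]
  }
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(dist[s, t])) next
      if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t]) {
        b[v] <- b[v] + pow[[dist[s, v]]][s, v] * pow[[dist[v, t]]][v, t] /
          sigma[s, t]
      }
    }
  }
  stats::setNames(b, nodes)
}

# Random undirected graph as an edge table over <= max_nodes nodes.
random_graph <- function(max_nodes = 8, p_edge = 0.4) {
  n <- sample(3:max_nodes, 1)
  nodes <- paste0("N", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  data.frame(node_a = pairs[keep, 1], node_b = pairs[keep, 2],
             pcor = runif(sum(keep), -1, 1), p = runif(sum(keep)),
             stringsAsFactors = FALSE) -> e
  list(nodes = nodes, edges = e)
}

# Independent partial-correlation oracle: correlation of the residuals of
# each variable regressed on all the others.
pcor_by_regression <- function(x) {
  G <- ncol(x)
  out <- diag(1, G)
  dimnames(out) <- list(colnames(x), colnames(x))
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    rest <- x[, -c(i, j), drop = FALSE]
    ri <- stats::lm.fit(cbind(1, rest), x[, i])$residuals
    rj <- stats::lm.fit(cbind(1, rest), x[, j])$residuals
    out[i, j] <- out[j, i] <- stats::cor(ri, rj)
  }
  out
}
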