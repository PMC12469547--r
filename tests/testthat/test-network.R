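test_that("partial correlations at zero shrinkage match the regression oracle", {
  set.seed(61)
  x <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, letters[1:4]))
  x[, 2] <- x[, 1] + rnorm(50, sd = 0.5)
  x[, 3] <- x[, 2] + rnorm(50, sd = 0.5)
  sp <- shrinkage_partial_correlation(x, lambda = 0)
  oracle <- pcor_by_regression(x)
  expect_lt(max(abs(sp$pcor - oracle)), 1e-10)
})

test_that("a Gaussian chain is conditionally independent across the middle", {
  set.seed(62)
  n <- 2000
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n, sd = sqrt(1 - 0.64))
  z <- 0.8 * y + rnorm(n, sd = sqrt(1 - 0.64))
  sp <- shrinkage_partial_correlation(cbind(x = x, y = y, z = z), lambda = 0)
  expect_lt(abs(sp$pcor["x", "z"]), 0.05)
  expect_gt(sp$pcor["x", "y"], 0.5)
})

test_that("full shrinkage removes every association and lambda is bounded", {
  set.seed(63)
  x <- matrix(rnorm(40 * 5), 40, 5)
  sp1 <- shrinkage_partial_correlation(x, lambda = 1)
  off <- sp1$pcor[upper.tri(sp1$pcor)]
  expect_true(all(abs(off) < 1e-12))
  sp_auto <- shrinkage_partial_correlation(x)
  expect_gte(sp_auto$lambda, 0)
  expect_lte(sp_auto$lambda, 1)
  expect_error(shrinkage_partial_correlation(x[1:4, ]), "5 samples")
  expect_error(shrinkage_partial_correlation(x[, 1:2]), "3 blocks")
})

test_that("edge p-values follow the analytic null", {
  p0 <- edge_pvalues(matrix(c(1, 0, 0, 1), 2), n_samples = 30)
  expect_equal(p0[1, 2], 1)
  # monotone in |pcor| for fixed kappa
  r <- seq(0, 0.9, by = 0.1)
  pc <- diag(2)
  pv <- vapply(r, function(ri) {
    pc[1, 2] <- pc[2, 1] <- ri
    edge_pvalues(pc, 50, 10)[1, 2]
  }, numeric(1))
  expect_true(all(diff(pv) < 0))
  pc[1, 2] <- pc[2, 1] <- 1
  expect_equal(edge_pvalues(pc, 50, 10)[1, 2], 0)
  # uniform under independence (lambda = 0 estimates)
  set.seed(64)
  x <- matrix(rnorm(200 * 30), 200, 30)
  sp <- shrinkage_partial_correlation(x, lambda = 0)
  pm <- edge_pvalues(sp$pcor, 200)
  pu <- pm[upper.tri(pm)]
  ks <- suppressWarnings(ks.test(pu, "punif"))
  expect_lt(unname(ks$statistic), 0.15)
})

test_that("minimal networks keep the cheapest covering prefix", {
  edges <- data.frame(
    node_a = c("A", "C", "A", "B", "A", "B"),
    node_b = c("B", "D", "C", "D", "D", "C"),
    pcor = c(0.9, 0.8, 0.5, 0.2, 0.1, 0.05),
    p = c(0.001, 0.002, 0.01, 0.2, 0.5, 0.9),
    stringsAsFactors = FALSE
  )
  net <- toy_network(LETTERS[1:4], edges)
  mn <- minimal_network(net)
  expect_setequal(edge_keys_of(mn$edges), c("A--B", "C--D"))
  # two nodes: the single edge
  net2 <- toy_network(c("A", "B"),
                      data.frame(node_a = "A", node_b = "B", pcor = 0.1,
                                 p = 0.9))
  expect_equal(nrow(minimal_network(net2)$edges), 1)
  # a node whose edges all have p = 1 still gets covered
  edges3 <- edges
  edges3$p[edges3$node_a == "C" | edges3$node_b == "C"] <- 1
  mn3 <- minimal_network(toy_network(LETTERS[1:4], edges3))
  expect_true(any(grepl("C", edge_keys_of(mn3$edges))))
})

test_that("a planted star is recovered exactly as the minimal network", {
  set.seed(65)
  n <- 300
  hub <- rnorm(n)
  leaves <- sapply(1:4, function(i) 0.8 * hub + rnorm(n, sd = 0.6))
  x <- cbind(H = hub, L1 = leaves[, 1], L2 = leaves[, 2], L3 = leaves[, 3],
             L4 = leaves[, 4])
  mn <- minimal_network(build_network(x))
  expect_setequal(edge_keys_of(mn$edges),
                  c("H--L1", "H--L2", "H--L3", "H--L4"))
})

test_that("dropping the last retained edge always isolates a node", {
  set.seed(66)
  for (i in 1:20) {
    g <- random_graph(8, p_edge = 0.8)
    if (nrow(g$edges) < 2) next
    covered_nodes <- unique(c(g$edges$node_a, g$edges$node_b))
    mn <- minimal_network(toy_network(covered_nodes, g$edges))
    e <- mn$edges
    last <- e[nrow(e), ]
    rest <- e[-nrow(e), ]
    incident <- unique(c(rest$node_a, rest$node_b))
    expect_false(all(c(last$node_a, last$node_b) %in% incident))
  }
})

test_that("differential networks follow the set algebra of edge subtraction", {
  mk <- function(keys) {
    ab <- do.call(rbind, strsplit(keys, "--"))
    toy_network(LETTERS[1:4],
                data.frame(node_a = ab[, 1], node_b = ab[, 2],
                           pcor = 0.5, p = 0.01, stringsAsFactors = FALSE),
                kind = "minimal")
  }
  prem <- mk(c("A--B", "B--C"))
  term <- mk(c("B--C", "C--D"))
  dn <- differential_network(prem, term)
  expect_equal(edge_keys_of(dn$edges), "A--B")
  expect_setequal(dn$nodes, LETTERS[1:4])
  # identical networks -> empty; disjoint -> unchanged
  expect_equal(nrow(differential_network(prem, prem)$edges), 0)
  disjoint <- differential_network(mk(c("A--B")), mk(c("C--D")))
  expect_equal(edge_keys_of(disjoint$edges), "A--B")
  # label swap mirrors the subtraction
  swapped <- differential_network(term, prem)
  expect_equal(edge_keys_of(swapped$edges), "C--D")
  bad <- mk("A--B"); bad$nodes <- LETTERS[2:5]
  expect_error(differential_network(prem, bad), "node set")
})

test_that("betweenness matches hand values and brute-force enumeration", {
  path <- toy_network(c("A", "B", "C"),
                      data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
                                 pcor = 0.5, p = 0.01))
  b <- betweenness_centrality(path)
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))
  k4 <- t(combn(LETTERS[1:4], 2))
  complete <- toy_network(LETTERS[1:4],
                          data.frame(node_a = k4[, 1], node_b = k4[, 2],
                                     pcor = 0.5, p = 0.01))
  expect_true(all(betweenness_centrality(complete) == 0))
  set.seed(67)
  for (i in 1:30) {
    g <- random_graph(8)
    net <- toy_network(g$nodes, g$edges)
    expect_equal(betweenness_centrality(net),
                 brute_betweenness(g$nodes, g$edges), tolerance = 1e-10)
  }
})

test_that("hub selection flags the architectural hub and nothing on empty graphs", {
  hub_found <- vapply(1:20, function(s) {
    set.seed(700 + s)
    leaves <- paste0("L", 1:11)
    edges <- data.frame(node_a = "H", node_b = sample(leaves, 5),
                        pcor = 0.5, p = 0.01, stringsAsFactors = FALSE)
    net <- toy_network(c("H", leaves), edges, kind = "differential")
    b <- betweenness_centrality(net)
    identical(select_hub_blocks(b)$hubs, "H")
  }, logical(1))
  expect_gte(mean(hub_found), 0.9)

  empty <- toy_network(paste0("N", 1:12),
                       data.frame(node_a = character(0),
                                  node_b = character(0),
                                  pcor = numeric(0), p = numeric(0)))
  b0 <- betweenness_centrality(empty)
  expect_true(all(b0 == 0))
  expect_length(select_hub_blocks(b0)$hubs, 0)
  expect_error(select_hub_blocks(c(a = 1, b = 2)), "manual")
  expect_length(select_hub_blocks(c(a = 1, b = 2), threshold = 1.5)$hubs, 1)
})
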