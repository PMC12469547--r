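toy_annotation <- function() {
  data.frame(
    metabolite_id = paste0("M", 1:9),
    function1 = c("A", "A", "A", "B", "B", "C", "C", "C", "C"),
    function2 = c("", "", "", "", "", "", "A", "", ""),
    function3 = "",
    stringsAsFactors = FALSE
  )
}

test_that("blocks below three members are discarded and membership capped", {
  bm <- suppressMessages(assign_blocks(toy_annotation(), paste0("M", 1:9)))
  expect_setequal(names(bm), c("A", "C"))       # B has only 2 members
  expect_setequal(attr(bm, "discarded"), "B")
  expect_setequal(bm$A, c("M1", "M2", "M3", "M7"))
  # restriction to the metabolites actually present
  bm2 <- suppressMessages(assign_blocks(toy_annotation(), paste0("M", 1:5)))
  expect_setequal(names(bm2), "A")
  expect_error(suppressMessages(assign_blocks(toy_annotation(), "M1")),
               "no block")
  # >3 function columns rejected at read time
  tmp <- withr::local_tempfile(fileext = ".csv")
  bad <- cbind(toy_annotation(), function4 = "D")
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_blocks(tmp), "three function")
})

test_that("the default emulation retains the expected number of blocks", {
  d <- generate_dataset(synth_config(seed = 13))
  bm <- suppressMessages(assign_blocks(d$blocks, colnames(d$features)))
  expect_equal(length(bm), 14)
})

test_that("a rank-one block falls back to the member profile", {
  y <- factor(rep(c("Term", "Prem"), each = 8), levels = c("Term", "Prem"))
  set.seed(51)
  prof <- rnorm(16) + 0.8 * (as.numeric(y) - 1.5)
  x <- cbind(m1 = prof, m2 = prof, m3 = prof, m4 = rnorm(16),
             m5 = rnorm(16), m6 = rnorm(16))
  xs <- autoscale(x)
  bm <- structure(list(dup = c("m1", "m2", "m3"),
                       other = c("m4", "m5", "m6")),
                  class = "block_map")
  sc <- block_superscores(xs, y, bm)
  expect_gt(abs(cor(unclass(sc)[, "dup"], xs[, "m1"])), 1 - 1e-8)
})

test_that("block weights follow the square-root rule and conserve energy", {
  dat <- make_two_class(n_per_class = 12, p = 8, seed = 52)
  bm <- structure(list(b1 = c("f1", "f2", "f3"),
                       b2 = c("f4", "f5", "f6", "f7", "f8")),
                  class = "block_map")
  sc <- block_superscores(dat$x, dat$groups, bm)
  w <- attr(sc, "weights")
  expect_equal(sum(w^2), 1, tolerance = 1e-12)
  expect_equal(unname(w[2] / w[1]), sqrt(5 / 3), tolerance = 1e-12)
  lin <- block_superscores(dat$x, dat$groups, bm, weighting = "linear")
  expect_equal(sum(attr(lin, "weights")), 1, tolerance = 1e-12)

  # duplicating a block's membership changes only its weight, by sqrt(2)
  x2 <- cbind(dat$x, `f1b` = dat$x[, "f1"], `f2b` = dat$x[, "f2"],
              `f3b` = dat$x[, "f3"])
  bm2 <- structure(list(b1 = c("f1", "f2", "f3", "f1b", "f2b", "f3b"),
                        b2 = c("f4", "f5", "f6", "f7", "f8")),
                   class = "block_map")
  sc2 <- block_superscores(autoscale(x2), dat$groups, bm2)
  # same total membership count across maps is not preserved, so compare
  # the unweighted block score against the weighted ratio
  r1 <- unclass(sc)[, "b1"] / attr(sc, "weights")["b1"]
  r2 <- unclass(sc2)[, "b1"] / attr(sc2, "weights")["b1"]
  expect_gt(abs(cor(r1, r2)), 1 - 1e-8)
  expect_equal(unname(attr(sc2, "n_k")["b1"] / attr(sc, "n_k")["b1"]), 2)
})

test_that("on null data the blocked model is not permutation-significant", {
  # per-block t1 scores are supervised, so they separate the groups
  # in-sample even without real signal; the calibrated guard against that
  # overfitting is the permutation test of the blocked model
  set.seed(53)
  ok <- vapply(1:5, function(s) {
    d <- generate_dataset(synth_config(n_term = 30, n_prem = 20,
                                       n_metabolites = 40, n_blocks = 6,
                                       frac_differential = 0,
                                       n_prem_specific_edges = 0, seed = s))
    g <- factor(d$metadata$group, levels = c("Term", "Prem"))
    xs <- autoscale(pqn_normalize(d$features)$normalized)
    bm <- suppressMessages(assign_blocks(d$blocks, colnames(xs)))
    sc <- block_superscores(xs, g, bm)
    rep <- validate_blocked_model(xs, g, sc, n_permutations = 49)
    rep$blocked$p_Q2 > 0.05 && rep$unblocked$p_Q2 > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("the blocked model maps samples like the unblocked one", {
  d <- generate_dataset(synth_config(seed = 54))
  g <- factor(d$metadata$group, levels = c("Term", "Prem"))
  xs <- autoscale(pqn_normalize(d$features)$normalized)
  bm <- suppressMessages(assign_blocks(d$blocks, colnames(xs)))
  sc <- block_superscores(xs, g, bm)
  set.seed(1)
  rep <- validate_blocked_model(xs, g, sc, n_permutations = 99)
  expect_gte(rep$r, 0.7)
  expect_false(rep$distorted)
  expect_lte(rep$unblocked$p_Q2, 0.05)
  expect_lte(rep$blocked$p_Q2, 0.05)

  # single block holding every metabolite reproduces the unblocked t1
  bm_all <- structure(list(all = colnames(xs)), class = "block_map")
  sc_all <- block_superscores(xs, g, bm_all)
  fit_un <- plsda(xs, g)
  expect_gt(abs(cor(unclass(sc_all)[, 1], fit_un$scores[, 1])), 0.95)
})

test_that("Gini importance finds the signal-bearing block", {
  top <- vapply(1:20, function(s) {
    d <- generate_dataset(synth_config(
      n_term = 40, n_prem = 25, n_metabolites = 40, n_blocks = 8,
      frac_differential = 0.12, differential_blocks = "B01",
      max_blocks_per_metabolite = 1,
      log2fc_magnitudes = c(0.8, 1.2), n_prem_specific_edges = 0, seed = s))
    g <- factor(d$metadata$group, levels = c("Term", "Prem"))
    xs <- autoscale(pqn_normalize(d$features)$normalized)
    bm <- suppressMessages(assign_blocks(d$blocks, colnames(xs)))
    sc <- block_superscores(xs, g, bm)
    imp <- suppressWarnings(random_forest_importance(sc, g, seed = 1000 + s))
    imp$block[1] == "B01"
  }, logical(1))
  expect_gte(mean(top), 0.95)
})

test_that("permuted labels rarely select blocks, and never many", {
  # supervised superscores overfit permuted labels too, so one spurious
  # block can detach on the Gini normality plot in a minority of datasets;
  # the permutation test of the blocked model is the calibrated guard
  # (see the null-data test above)
  n_sel <- vapply(1:20, function(s) {
    d <- generate_dataset(synth_config(n_term = 30, n_prem = 20,
                                       n_metabolites = 48, n_blocks = 12,
                                       seed = s))
    set.seed(2000 + s)
    g <- sample(factor(d$metadata$group, levels = c("Term", "Prem")))
    xs <- autoscale(pqn_normalize(d$features)$normalized)
    bm <- suppressMessages(assign_blocks(d$blocks, colnames(xs)))
    sc <- block_superscores(xs, g, bm)
    imp <- random_forest_importance(sc, g, seed = 3000 + s)
    sum(imp$selected)
  }, numeric(1))
  expect_gte(mean(n_sel == 0), 0.65)
  expect_lt(mean(n_sel), 1)       # far below any real-signal selection
  expect_lte(max(n_sel), 3)
})

test_that("tiny forests are flagged as unstable", {
  dat <- make_two_class(p = 10, seed = 55)
  bm <- structure(list(b1 = paste0("f", 1:5), b2 = paste0("f", 6:10)),
                  class = "block_map")
  sc <- block_superscores(dat$x, dat$groups, bm)
  expect_warning(random_forest_importance(sc, dat$groups, n_trees = 10,
                                          seed = 1, threshold = 1),
                 "unstable")
})
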