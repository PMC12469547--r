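test_that("the first NIPALS weight equals the dominant eigenvector of X'yy'X", {
  set.seed(31)
  for (i in 1:20) {
    x <- autoscale(matrix(rnorm(10 * 4), 10, 4))
    y <- factor(sample(rep(c("A", "B"), 5)))
    fit <- plsda(x, y, ncomp = 1)
    yc <- as.numeric(y == levels(y)[2]); yc <- yc - mean(yc)
    ev <- eigen(tcrossprod(crossprod(x, yc)))$vectors[, 1]
    ev <- ev * sign(ev[which.max(abs(ev))])
    expect_lt(max(abs(fit$weights[, 1] - ev)), 1e-8)
  }
})

test_that("a single perfectly separating column yields a saturated model", {
  y <- factor(rep(c("Term", "Prem"), each = 6), levels = c("Term", "Prem"))
  x <- cbind(sep = as.numeric(y == "Prem"))
  fit <- plsda(autoscale(x), y, ncomp = 1)
  expect_equal(fit$R2Y, 1, tolerance = 1e-12)
  expect_equal(unname(fit$weights[, 1]), 1)
  expect_equal(vip(fit), c(sep = 1))
})

test_that("the fit is invariant to reordering the samples", {
  dat <- make_two_class(seed = 32)
  fit <- plsda(dat$x, dat$groups)
  set.seed(33)
  perm <- sample(nrow(dat$x))
  fit_p <- plsda(dat$x[perm, ], dat$groups[perm])
  expect_equal(fit$R2Y, fit_p$R2Y)
  expect_equal(fit$weights, fit_p$weights, tolerance = 1e-10)
  expect_equal(fit$scores[perm, ], fit_p$scores[, ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("invalid fits are refused", {
  dat <- make_two_class()
  expect_error(plsda(dat$x, rep("A", nrow(dat$x))), "two classes")
  expect_error(plsda(dat$x, dat$groups, ncomp = 50), "rank")
  x1 <- cbind(a = as.numeric(dat$groups == "Prem"))
  expect_error(plsda(autoscale(x1), dat$groups, ncomp = 2), "rank")
})

test_that("VIP matches the closed form and its normalization invariant", {
  # feature 1 carries the class, feature 2 is exactly orthogonal to y
  y <- factor(rep(c("Term", "Prem"), each = 10), levels = c("Term", "Prem"))
  yc <- as.numeric(y == "Prem") - 0.5
  set.seed(34)
  noise <- rnorm(20)
  noise <- residuals(lm(noise ~ yc))
  x <- cbind(f1 = yc + rnorm(20, sd = 1e-6), f2 = noise)
  fit <- plsda(autoscale(x), y, ncomp = 1)
  expect_equal(unname(vip(fit)), c(sqrt(2), 0), tolerance = 1e-3)

  # direct formula oracle on random fits, plus sum(VIP^2) = p
  for (i in 1:5) {
    dat <- make_two_class(p = 7, seed = 40 + i)
    fit <- plsda(dat$x, dat$groups, ncomp = 3)
    v <- vip(fit)
    ssy <- fit$y_loadings^2 * colSums(fit$scores^2)
    direct <- sqrt(ncol(dat$x) *
                     colSums(t(fit$weights^2) * ssy) / sum(ssy))
    expect_equal(unname(v), unname(direct), tolerance = 1e-10)
    expect_equal(sum(v^2), ncol(dat$x), tolerance = 1e-8)
  }
})

test_that("OPLS-DA separates predictive from orthogonal variation", {
  set.seed(36)
  x <- matrix(rnorm(20 * 6), 20, 6)
  y <- factor(rep(c("Term", "Prem"), each = 10), levels = c("Term", "Prem"))
  fit <- oplsda(autoscale(x), y, n_orthogonal = 1)
  # predictive score orthogonal to every orthogonal score
  expect_lt(abs(sum(fit$scores[, 1] * fit$orthogonal_scores[, 1])),
            1e-8 * sqrt(sum(fit$scores^2) * sum(fit$orthogonal_scores^2)))
  # known equivalence: OPLS (1+1) explains the class exactly as well as a
  # 2-component PLS on the same data
  fit2 <- plsda(autoscale(x), y, ncomp = 2)
  expect_equal(fit$R2Y, fit2$R2Y, tolerance = 1e-10)
})

test_that("with no orthogonal structure the OPLS t1 equals the PLS t1", {
  # rank-1 y-correlated X plus tiny noise: nothing orthogonal to remove
  y <- factor(rep(c("Term", "Prem"), each = 8), levels = c("Term", "Prem"))
  yc <- as.numeric(y == "Prem") - 0.5
  set.seed(37)
  x <- outer(yc, c(1, -2, 0.5)) + matrix(rnorm(48, sd = 1e-4), 16, 3)
  xs <- autoscale(x)
  fo <- oplsda(xs, y, n_orthogonal = 1)
  fp <- plsda(xs, y, ncomp = 1)
  expect_lt(sum(fo$orthogonal_scores^2) / sum(fo$scores^2), 1e-4)
  expect_gt(abs(cor(fo$scores[, 1], fp$scores[, 1])), 1 - 1e-6)
})

test_that("cross-validated Q2 penalizes null models and rewards real signal", {
  set.seed(38)
  q2_null <- replicate(30, {
    x <- matrix(rnorm(28 * 8), 28, 8)
    y <- factor(rep(c("A", "B"), each = 14))
    cross_validate_q2(x, y, ncomp = 2)
  })
  expect_lte(mean(q2_null), 0)

  d <- generate_dataset(synth_config(seed = 39))
  g <- factor(d$metadata$group, levels = c("Term", "Prem"))
  x <- pqn_normalize(d$features)$normalized
  expect_gt(cross_validate_q2(x, g, ncomp = 2, seed = 1), 0.5)
})

test_that("duplicating every sample does not destroy predictive ability", {
  dat <- make_two_class(n_per_class = 12, shift = 1.5, seed = 41)
  q1 <- cross_validate_q2(dat$x, dat$groups, seed = 5)
  q2 <- cross_validate_q2(rbind(dat$x, dat$x),
                          factor(c(as.character(dat$groups),
                                   as.character(dat$groups)),
                                 levels = c("Term", "Prem")), seed = 5)
  expect_gt(q2, q1 - 0.1)
})

test_that("permutation validation is calibrated, bounded and deterministic", {
  dat <- make_two_class(n_per_class = 10, p = 6, shift = 6, n_signal = 6,
                        seed = 42)
  res <- permutation_test(dat$x, dat$groups, n_permutations = 200, seed = 7)
  expect_equal(res$p_Q2, 1 / 201)  # smallest attainable
  expect_equal(res$p_R2Y, 1 / 201)
  res2 <- permutation_test(dat$x, dat$groups, n_permutations = 200, seed = 7)
  expect_identical(res, res2)
  expect_error(permutation_test(dat$x, dat$groups, n_permutations = 0),
               "at least 1")
})

test_that("normality-plot threshold isolates planted outliers and stays quiet on normal data", {
  exact <- vapply(1:20, function(s) {
    set.seed(400 + s)
    x <- c(rnorm(200, 5, 1), rnorm(10, 12, 0.5))
    nt <- normality_threshold(x)
    nt$n_selected == 10 && all(which(nt$selected) > 200)
  }, logical(1))
  expect_gte(mean(exact), 0.9)

  quiet <- vapply(1:20, function(s) {
    set.seed(500 + s)
    is.infinite(normality_threshold(rnorm(150))$threshold)
  }, logical(1))
  expect_gte(mean(quiet), 0.85)

  # manual override reproduces the conventional VIP cut-offs
  v <- c(seq(0.1, 1.4, length.out = 50), 1.6, 1.8)
  man <- normality_threshold(v, threshold = 1.5)
  expect_equal(man$n_selected, 2)
  expect_error(normality_threshold(c(1, 2, 3)), "at least 10")
})

test_that("PLS-DA methods behave as a classical fitted model", {
  dat <- make_two_class(n_per_class = 14, shift = 2.5, seed = 43)
  fit <- plsda(dat$x, dat$groups)
  expect_s3_class(fit, "plsda")
  expect_output(print(fit), "PLS-DA")
  expect_output(print(summary(fit)), "top VIP")
  pred <- predict(fit, dat$x)
  expect_gt(mean(pred == dat$groups), 0.9)
  expect_length(coef(fit), ncol(dat$x))
  expect_equal(length(residuals(fit)), nrow(dat$x))
  expect_equal(unname(fitted(fit) + residuals(fit)),
               as.numeric(dat$groups == "Prem"), tolerance = 1e-10)
  # scores route through the same projection as the stored scores
  sc <- predict(fit, dat$x, type = "scores")
  expect_gt(abs(cor(sc[, 1], fit$scores[, 1])), 0.999)
})

test_that("PLS-DA agrees with an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  dat <- make_two_class(n_per_class = 12, p = 8, shift = 1.5, seed = 44)
  fit <- plsda(dat$x, dat$groups, ncomp = 2)
  ref <- mixOmics::plsda(scale(dat$x), dat$groups, ncomp = 2, scale = FALSE)
  expect_gt(abs(cor(fit$scores[, 1], ref$variates$X[, 1])), 0.999)
})
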